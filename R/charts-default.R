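#' Default agent statecharts
#'
#' The shipped charts are reconstructions of the behavior the cancer model
#' needs, written in this package's own chart dialect; the tumor chart nests
#' the three live modes inside an `alive` super-state with an absorbing
#' `necrotic` sibling, and the endothelial chart uses two orthogonal regions
#' (activation and sprouting role) so that both dimensions of an endothelial
#' cell's behavior evolve concurrently.
#'
#' Timers are counters, not wall clocks: every simulation step delivers one
#' `tick` event per agent with the sensed surroundings in the dispatch
#' context, and cycle/hypoxia counters live in that context.
#'
#' @name default_charts
NULL

#' The default tumor-cell statechart
#'
#' States: `alive` (compound: `proliferating` initial, `quiescent`,
#' `hypoxic`) and absorbing `necrotic`.  All transitions are driven by the
#' `tick` event, guarded on the context fields `o2` (local oxygen), `free`
#' (free face-neighbor count), `hyp` (consecutive hypoxic steps including
#' the current one) and `p` (the [tumor_params()] in force):
#'
#' * `o2 >= T_div` with a free neighbor: proliferating (cycle counter runs);
#' * `T_hyp <= o2 < T_div`, or no free neighbor: quiescent (cycle frozen);
#' * `o2 < T_hyp`: hypoxic (secretes VEGF, hypoxia counter runs);
#' * `hyp >= n_nec`: the `alive` super-state exits to `necrotic`, which is
#'   never left.  Because the necrosis transition leaves from the
#'   super-state, recovery transitions inside `alive` take inner-first
#'   priority while recovery is still possible.
#'
#' @return a valid `sc_chart`
#' @export
tumor_chart <- function() {
  root <- sc_state("tumor", "compound", initial = "alive", children = list(
    sc_state("alive", "compound", initial = "proliferating", children = list(
      sc_state("proliferating"),
      sc_state("quiescent"),
      sc_state("hypoxic")
    )),
    sc_state("necrotic")
  ))
  guards <- list(
    can_divide = function(ctx) ctx$o2 >= ctx$p$T_div && ctx$free > 0L,
    must_quiesce = function(ctx) {
      ctx$o2 >= ctx$p$T_hyp && (ctx$o2 < ctx$p$T_div || ctx$free == 0L)
    },
    is_hypoxic = function(ctx) ctx$o2 < ctx$p$T_hyp,
    lethal_hypoxia = function(ctx) ctx$hyp >= ctx$p$n_nec
  )
  transitions <- list(
    sc_transition("t1", "proliferating", "hypoxic", "tick", guard = "is_hypoxic"),
    sc_transition("t2", "proliferating", "quiescent", "tick", guard = "must_quiesce"),
    sc_transition("t3", "quiescent", "hypoxic", "tick", guard = "is_hypoxic"),
    sc_transition("t4", "quiescent", "proliferating", "tick", guard = "can_divide"),
    sc_transition("t5", "hypoxic", "proliferating", "tick", guard = "can_divide"),
    sc_transition("t6", "hypoxic", "quiescent", "tick", guard = "must_quiesce"),
    sc_transition("t7", "alive", "necrotic", "tick", guard = "lethal_hypoxia",
                  actions = "necrose")
  )
  sc_chart(root, transitions, guards = guards)
}

#' The default endothelial-cell statechart
#'
#' Root orthogonal state with two concurrent regions: `activation`
#' (`inactive` initial, `activated`; driven by the `activate` event when
#' local VEGF crosses the activation threshold) and `sprouting` (`stalk`
#' initial, `tip`; driven by `become_tip` / `become_stalk` as sprout tips
#' move and leave stalk cells behind).
#'
#' @return a valid `sc_chart`
#' @export
endothelial_chart <- function() {
  root <- sc_state("endothelial", "orthogonal", children = list(
    sc_state("activation", "compound", initial = "inactive", children = list(
      sc_state("inactive"),
      sc_state("activated")
    )),
    sc_state("sprouting", "compound", initial = "stalk", children = list(
      sc_state("stalk"),
      sc_state("tip")
    ))
  ))
  transitions <- list(
    sc_transition("e1", "inactive", "activated", "activate",
                  actions = "start_sprout"),
    sc_transition("e2", "stalk", "tip", "become_tip"),
    sc_transition("e3", "tip", "stalk", "become_stalk")
  )
  sc_chart(root, transitions)
}
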