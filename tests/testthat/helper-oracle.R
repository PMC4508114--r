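# Helpers shared across the suite: a random generator for flat charts and
# an explicit transition-table simulator used as an independent oracle for
# the statechart engine.

# A flat chart: one compound root over `n_states` basic leaves, up to
# `n_trans` transitions among them over the given event alphabet.
random_flat_chart <- function(n_states = 5, n_trans = 10,
                              events = c("e1", "e2", "e3")) {
  leaves <- paste0("S", seq_len(n_states))
  root <- sc_state("root", "compound", initial = leaves[1],
                   children = lapply(leaves, sc_state))
  trs <- lapply(seq_len(n_trans), function(j) {
    sc_transition(sprintf("t%02d", j),
                  source = sample(leaves, 1), target = sample(leaves, 1),
                  trigger = sample(events, 1))
  })
  sc_chart(root, trs)
}

# Deterministic next-state table for a flat chart: rows = states, cols =
# events; the enabled transition with the lexicographically lowest id wins
# (mirroring the engine's documented tie-break).  Built straight from the
# transition list, independently of the engine's dispatch tables.
flat_transition_table <- function(n_states, transitions, events) {
  states <- paste0("S", seq_len(n_states))
  tab <- matrix(rep(states, length(events)), nrow = n_states,
                dimnames = list(states, events))
  info <- lapply(transitions, unclass)
  ids <- vapply(info, `[[`, character(1), "id")
  src <- vapply(info, `[[`, character(1), "source")
  trg <- vapply(info, `[[`, character(1), "trigger")
  tgt <- vapply(info, `[[`, character(1), "target")
  for (s in states) {
    for (ev in events) {
      hit <- which(src == s & trg == ev)
      if (length(hit)) tab[s, ev] <- tgt[hit[order(ids[hit])[1]]]
    }
  }
  tab
}

# Simulate an event sequence on the table; returns the visited leaf states.
# Integer-indexed internally so the acceptance-scale runs stay fast.
table_simulate <- function(tab, start, events_seq) {
  states <- rownames(tab)
  tint <- matrix(match(tab, states), nrow(tab))
  cur <- match(start, states)
  ev_idx <- match(events_seq, colnames(tab))
  out <- integer(length(events_seq))
  for (i in seq_along(events_seq)) {
    e <- ev_idx[i]
    if (!is.na(e)) cur <- tint[cur, e]
    out[i] <- cur
  }
  states[out]
}

# Leaf trajectory of the engine on the same sequence.
engine_simulate <- function(chart, events_seq) {
  inst <- enter_initial(chart)
  basic <- chart$basic
  ids <- chart$node_id
  out <- character(length(events_seq))
  for (i in seq_along(events_seq)) {
    inst <- dispatch(inst, events_seq[i])[[1L]]
    a <- inst$active
    out[i] <- ids[basic[a[basic]][1L]]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small chart with k independent orthogonal regions, each a 2-state toggle
# driven by its own event; used for the product-machine property.
toggle_regions_chart <- function(k) {
  regions <- lapply(seq_len(k), function(i) {
    sc_state(sprintf("R%d", i), "compound", initial = sprintf("A%d", i),
             children = list(sc_state(sprintf("A%d", i)),
                             sc_state(sprintf("B%d", i))))
  })
  root <- sc_state("root", "orthogonal", children = regions)
  trs <- unlist(lapply(seq_len(k), function(i) {
    list(sc_transition(sprintf("f%d", i), sprintf("A%d", i), sprintf("B%d", i),
                       sprintf("ev%d", i)),
         sc_transition(sprintf("g%d", i), sprintf("B%d", i), sprintf("A%d", i),
                       sprintf("ev%d", i)))
  }), recursive = FALSE)
  sc_chart(root, trs)
}
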