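#' Simulation configuration
#'
#' A `sim_config` gathers everything a run needs: grid geometry, time step,
#' step count, seed, field transport coefficients, tumor and angiogenesis
#' parameters, and the scenario switches (vessels on/off, VEGF secretion
#' level, branching allowed).  All quantities are in relative units; the
#' lattice spacing is one cell diameter.
#'
#' @param dims grid dimensions (3 integers, each >= 3)
#' @param spacing lattice spacing
#' @param dt time-step length
#' @param n_steps number of steps a run executes
#' @param seed RNG seed (single global Mersenne-Twister stream)
#' @param snapshot_every metrics are recorded at step 0, every this many
#'   steps, and at the final step
#' @param baseline_o2 uniform initial oxygen concentration
#' @param vessels_enabled whether the parent vessel exists (the
#'   no-angiogenesis experiment sets this to `FALSE`)
#' @param vessel_axis,vessel_offset parent-vessel layout: the axis it runs
#'   along and its fixed transverse coordinates
#' @param fields list with `D_O2`, `k_decay_O2`, `D_V`, `k_decay_V`
#' @param tumor a [tumor_params()] (or a list of overrides)
#' @param angio an [angio_params()] (or a list of overrides)
#' @param record_path if set, the run is recorded to this stream file
#' @param kill_mode what killing a tumor cell means: `"remove"` it from
#'   space or mark it `"necrose"`
#' @param check_invariants run (slow) structural checks after every step
#' @return a validated `sim_config`
#' @export
sim_config <- function(dims = c(40L, 40L, 40L), spacing = 1, dt = 1,
                       n_steps = 500L, seed = 1L, snapshot_every = 10L,
                       baseline_o2 = 1.0, vessels_enabled = TRUE,
                       vessel_axis = 1L, vessel_offset = c(1L, 1L),
                       fields = list(), tumor = list(), angio = list(),
                       record_path = NULL, kill_mode = "remove",
                       check_invariants = FALSE) {
  f_def <- list(D_O2 = 0.15, k_decay_O2 = 0.006, D_V = 0.15, k_decay_V = 0.002)
  f <- utils::modifyList(f_def, as.list(fields))
  tp <- if (inherits(tumor, "tumor_params")) tumor else do.call(tumor_params, as.list(tumor))
  ap <- if (inherits(angio, "angio_params")) angio else do.call(angio_params, as.list(angio))
  config <- structure(list(
    dims = as.integer(dims), spacing = spacing, dt = dt,
    n_steps = as.integer(n_steps), seed = as.integer(seed),
    snapshot_every = as.integer(snapshot_every), baseline_o2 = baseline_o2,
    vessels_enabled = isTRUE(vessels_enabled),
    vessel_axis = as.integer(vessel_axis),
    vessel_offset = as.integer(vessel_offset),
    fields = f, tumor = tp, angio = ap,
    record_path = record_path, kill_mode = kill_mode,
    check_invariants = isTRUE(check_invariants)
  ), class = "sim_config")
  validate_config(config)
  config
}

config_error <- function(msg) {
  stop(structure(class = c("oncosim_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Validate a simulation configuration
#'
#' Checks grid size, the diffusion stability bound `D*dt/h^2 <= 1/6` for
#' both fields, decay factors, threshold ordering and probability ranges.
#' Raises a condition of class `oncosim_config_error` on the first failure.
#'
#' @param config a `sim_config`
#' @return the config, invisibly
#' @export
validate_config <- function(config) {
  if (length(config$dims) != 3L || any(config$dims < 3L)) {
    config_error("dims must be three integers, each >= 3")
  }
  if (config$spacing <= 0 || config$dt <= 0) {
    config_error("spacing and dt must be positive")
  }
  if (config$n_steps < 0L) config_error("n_steps must be >= 0")
  if (config$snapshot_every < 1L) config_error("snapshot_every must be >= 1")
  if (config$baseline_o2 < 0) config_error("baseline_o2 must be >= 0")
  h2 <- config$spacing^2
  for (nm in c("D_O2", "D_V")) {
    lam <- config$fields[[nm]] * config$dt / h2
    if (config$fields[[nm]] < 0) config_error(sprintf("%s must be >= 0", nm))
    if (lam > 1 / 6 + 1e-12) {
      config_error(sprintf("stability bound violated for %s: D*dt/h^2 = %.4g > 1/6",
                           nm, lam))
    }
  }
  for (nm in c("k_decay_O2", "k_decay_V")) {
    k <- config$fields[[nm]]
    if (k < 0 || k * config$dt > 1) {
      config_error(sprintf("%s*dt must lie in [0, 1]", nm))
    }
  }
  if (!(config$tumor$T_hyp < config$tumor$T_div)) {
    config_error("tumor thresholds must satisfy T_hyp < T_div")
  }
  if (!(config$vessel_axis %in% 1:3)) config_error("vessel_axis must be 1, 2 or 3")
  other <- setdiff(1:3, config$vessel_axis)
  if (any(config$vessel_offset < 1L) || any(config$vessel_offset > config$dims[other])) {
    config_error("parent vessel line lies outside the grid")
  }
  if (!(config$kill_mode %in% c("remove", "necrose"))) {
    config_error("kill_mode must be 'remove' or 'necrose'")
  }
  invisible(config)
}

#' Load a configuration from a YAML or JSON file
#'
#' Top-level keys mirror the [sim_config()] arguments; `fields`, `tumor`
#' and `angio` are nested maps of overrides.
#'
#' @param path file path
#' @param ... overrides applied on top of the file (e.g. `seed`, `n_steps`)
#' @return a validated `sim_config`
#' @export
load_config <- function(path, ...) {
  if (!file.exists(path)) config_error(sprintf("config file '%s' not found", path))
  doc <- tryCatch({
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
  }, error = function(e) config_error(sprintf("cannot parse '%s': %s", path,
                                              conditionMessage(e))))
  args <- utils::modifyList(as.list(doc), list(...))
  known <- names(formals(sim_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) {
    config_error(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, args)
}

#' Scenario presets
#'
#' Ready-made configurations for the qualitative experiments the model is
#' built around:
#'
#' * `"baseline"` — vascularized tumor, default parameters;
#' * `"no-angio"` — no vessels at all: the tumor grows, stalls and dies off;
#' * `"low-vegf"` / `"high-vegf"` — weak vs strong VEGF secretion by
#'   hypoxic cells, contrasting the speed and extent of vessel recruitment;
#' * `"no-branch"` — vessels may elongate but never branch (defective
#'   vessel growth); the tumor grows towards the sparse oxygen supply,
#'   hugging the vessels;
#' * `"branch-control"` — same geometry and seeds as `"no-branch"` but with
#'   branching enabled, for paired comparisons.
#'
#' @param name preset name
#' @param ... overrides forwarded to [sim_config()] (e.g. `seed`,
#'   `n_steps`, `dims`)
#' @return a validated `sim_config`
#' @export
scenario_config <- function(name = c("baseline", "no-angio", "low-vegf",
                                     "high-vegf", "no-branch", "branch-control"),
                            ...) {
  name <- match.arg(name)
  base <- list(dims = c(34L, 34L, 34L), n_steps = 420L)
  preset <- switch(name,
    "baseline" = base,
    "no-angio" = list(dims = c(40L, 40L, 40L), n_steps = 500L,
                      vessels_enabled = FALSE),
    "low-vegf" = c(base, list(tumor = list(s_V = 0.3))),
    "high-vegf" = c(base, list(tumor = list(s_V = 1.5))),
    "no-branch" = c(base, list(angio = list(allow_branching = FALSE))),
    "branch-control" = base
  )
  args <- utils::modifyList(preset, list(...))
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config %s, %d steps, dt=%g, seed=%d, vessels=%s>\n",
              paste(x$dims, collapse = "x"), x$n_steps, x$dt, x$seed,
              if (x$vessels_enabled) "on" else "off"))
  invisible(x)
}
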