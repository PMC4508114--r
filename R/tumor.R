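#' Tumor-cell agents
#'
#' Tumor cells occupy one voxel each, sense local oxygen and crowding, and
#' run the default tumor statechart once per step.  Proliferating cells
#' advance a cycle counter and divide into a free face-neighbor voxel every
#' `n_cyc` steps; hypoxic cells secrete VEGF and die (irreversibly) after
#' `n_nec` consecutive hypoxic steps; necrotic cells stay in place, consume
#' nothing and secrete nothing.
#'
#' @name tumor_agents
NULL

#' Tumor-cell parameters
#'
#' All quantities are in relative units on the shared lattice.
#'
#' @param T_div oxygen threshold for proliferation
#' @param T_hyp oxygen threshold below which a cell is hypoxic
#'   (`T_hyp < T_div`); between the two thresholds the cell is quiescent
#' @param n_cyc cell-cycle length in steps (one division per `n_cyc`
#'   proliferating steps)
#' @param n_nec consecutive hypoxic steps before irreversible necrosis
#' @param k_O2 oxygen consumed per live cell per unit time
#' @param s_V VEGF secreted per hypoxic cell per unit time
#' @return a `tumor_params` list
#' @export
tumor_params <- function(T_div = 0.30, T_hyp = 0.08, n_cyc = 10L,
                         n_nec = 40L, k_O2 = 0.03, s_V = 1.0) {
  p <- list(T_div = T_div, T_hyp = T_hyp, n_cyc = as.integer(n_cyc),
            n_nec = as.integer(n_nec), k_O2 = k_O2, s_V = s_V)
  if (any(vapply(p, function(x) x < 0, logical(1)))) {
    stop("tumor parameters must be >= 0", call. = FALSE)
  }
  if (!(p$T_hyp < p$T_div)) stop("T_hyp must be < T_div", call. = FALSE)
  if (p$n_cyc < 1L || p$n_nec < 1L) stop("n_cyc and n_nec must be >= 1", call. = FALSE)
  class(p) <- "tumor_params"
  p
}

# Construct a tumor cell.  `chart` is the shared chart definition; every
# cell gets its own instance (initial configuration = proliferating).
new_tumor_cell <- function(id, voxel, chart, parent = NA_integer_) {
  list(id = as.integer(id), type = "tumor_cell", voxel = as.integer(voxel),
       inst = enter_initial(chart), state = "proliferating",
       cycle = 0L, hyp = 0L, parent = as.integer(parent))
}

#' Sense a tumor cell's surroundings
#'
#' @param cell a tumor cell
#' @param o2 the oxygen `scalar_field`
#' @param occ occupancy array (0 = free voxel)
#' @param lattice precomputed lattice tables from the simulator
#' @return `list(o2 = local oxygen, free = free face-neighbor count)`
#' @export
sense <- function(cell, o2, occ, lattice) {
  lin <- vox_to_lin(cell$voxel, lattice$dims)
  nbs <- lattice_neighbors(lattice, lin)
  list(o2 = o2$values[lin], free = sum(occ[nbs] == 0L))
}

#' Advance one tumor cell by one step
#'
#' Dispatches `tick` into the cell's statechart with the sensed readings in
#' the context, then applies the counter logic: the cycle counter advances
#' only while proliferating and emits a division intent when it reaches
#' `n_cyc`; the hypoxia counter counts consecutive steps below `T_hyp` and
#' resets whenever oxygen recovers.  Necrotic cells are inert.
#'
#' @param cell a tumor cell
#' @param readings output of [sense()]
#' @param params [tumor_params()]
#' @return `list(cell = updated cell, divide = logical, secrete = VEGF
#'   amount per unit time (0 unless hypoxic))`
#' @export
tick_tumor <- function(cell, readings, params) {
  if (cell$state == "necrotic") {
    return(list(cell = cell, divide = FALSE, secrete = 0))
  }
  hyp_next <- if (readings$o2 < params$T_hyp) cell$hyp + 1L else 0L
  ctx <- list(o2 = readings$o2, free = readings$free, hyp = hyp_next, p = params)
  res <- dispatch(cell$inst, "tick", ctx)
  cell$inst <- res$instance
  cell$state <- sc_leaf_state(cell$inst)
  cell$hyp <- hyp_next
  divide <- FALSE
  secrete <- 0
  if (cell$state == "proliferating") {
    cell$cycle <- cell$cycle + 1L
    if (cell$cycle >= params$n_cyc) {
      divide <- TRUE
      cell$cycle <- 0L
    }
  } else if (cell$state == "hypoxic") {
    secrete <- params$s_V
  }
  list(cell = cell, divide = divide, secrete = secrete)
}

#' Apply a queued division
#'
#' Places a daughter cell in a uniformly chosen free face-neighbor voxel
#' (consuming one draw from the global RNG stream).  If crowding removed all
#' free neighbors between intent and application, the division is dropped.
#'
#' @param cell the dividing (mother) cell
#' @param occ occupancy array
#' @param lattice lattice tables
#' @param next_id id for the daughter
#' @param chart the shared tumor chart
#' @return the daughter tumor cell, or `NULL` if no free neighbor remains
#' @export
apply_divide <- function(cell, occ, lattice, next_id, chart) {
  lin <- vox_to_lin(cell$voxel, lattice$dims)
  free <- free_neighbors(lattice, occ, lin)
  if (length(free) == 0L) return(NULL)
  pick <- if (length(free) == 1L) free else free[sample.int(length(free), 1L)]
  new_tumor_cell(next_id, lin_to_vox(pick, lattice$dims), chart,
                 parent = cell$id)
}

#' Apply tumor metabolism to the fields
#'
#' Every live (non-necrotic) cell consumes `k_O2 * dt` oxygen at its voxel
#' (clamped at zero); every hypoxic cell deposits `s_V * dt` VEGF at its
#' voxel.  Cells are processed in ascending id order; with one cell per
#' voxel the updates are independent.
#'
#' @param cells list of tumor cells (ascending id)
#' @param o2,vegf `scalar_field`s
#' @param params [tumor_params()]
#' @param dt time step
#' @return `list(o2 = , vegf = )` updated fields
#' @export
apply_metabolism <- function(cells, o2, vegf, params, dt) {
  if (length(cells)) {
    states <- vapply(cells, `[[`, character(1), "state")
    live <- states != "necrotic"
    if (any(live)) {
      vox <- vapply(cells[live], `[[`, integer(3), "voxel")
      lin <- vox[1, ] + (vox[2, ] - 1L) * o2$dims[1] +
        (vox[3, ] - 1L) * o2$dims[1] * o2$dims[2]
      o2$values[lin] <- pmax(0, o2$values[lin] - params$k_O2 * dt)
    }
    hyp <- states == "hypoxic"
    if (any(hyp)) {
      vox <- vapply(cells[hyp], `[[`, integer(3), "voxel")
      lin <- vox[1, ] + (vox[2, ] - 1L) * vegf$dims[1] +
        (vox[3, ] - 1L) * vegf$dims[1] * vegf$dims[2]
      vegf$values[lin] <- vegf$values[lin] + params$s_V * dt
    }
  }
  list(o2 = o2, vegf = vegf)
}
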