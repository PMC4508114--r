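#' Endothelial agents and the vessel network
#'
#' Blood vessels are chains of endothelial cells linked by `pred`
#' (predecessor) references into a forest rooted in the initial parent
#' vessel.  Stalk cells on the parent vessel activate when local VEGF
#' crosses the activation threshold and spawn a migrating tip; tips climb
#' the VEGF gradient (with a small exploration probability), leaving a new
#' stalk cell behind at every move (elongation), and may branch with a
#' probability proportional to local VEGF.  Every endothelial cell delivers
#' oxygen at its voxel (perfusion).
#'
#' @name vasculature
NULL

#' Angiogenesis parameters
#'
#' @param T_V VEGF threshold activating parent-vessel cells
#' @param p_move per-step probability that a tip attempts a move
#' @param epsilon exploration probability: a moving tip steps to a uniform
#'   free neighbor instead of the up-gradient one
#' @param beta branching coefficient; a tip branches with probability
#'   `min(1, beta * local VEGF)` per step
#' @param s_O2 oxygen delivered per endothelial cell per unit time
#' @param allow_branching set `FALSE` to forbid branching entirely (the
#'   "vessels may only elongate" experiment)
#' @return an `angio_params` list
#' @export
angio_params <- function(T_V = 0.05, p_move = 0.7, epsilon = 0.1,
                         beta = 0.03, s_O2 = 1.0, allow_branching = TRUE) {
  p <- list(T_V = T_V, p_move = p_move, epsilon = epsilon, beta = beta,
            s_O2 = s_O2, allow_branching = isTRUE(allow_branching))
  if (p$T_V < 0 || p$beta < 0 || p$s_O2 < 0) {
    stop("angiogenesis rates must be >= 0", call. = FALSE)
  }
  if (p$p_move < 0 || p$p_move > 1 || p$epsilon < 0 || p$epsilon > 1) {
    stop("p_move and epsilon must lie in [0, 1]", call. = FALSE)
  }
  class(p) <- "angio_params"
  p
}

new_endothelial_cell <- function(id, voxel, chart, role = "stalk",
                                 pred = NA_integer_, sprout = 0L,
                                 activated = FALSE) {
  inst <- enter_initial(chart)
  if (activated) inst <- dispatch(inst, "activate")$instance
  if (role == "tip") inst <- dispatch(inst, "become_tip")$instance
  list(id = as.integer(id), type = "endothelial_cell",
       voxel = as.integer(voxel), role = role, inst = inst,
       pred = as.integer(pred), sprout = as.integer(sprout))
}

#' Build the initial parent vessel
#'
#' A straight chain of (inactive) stalk endothelial cells spanning the grid
#' along one axis at a fixed offset in the two transverse coordinates,
#' pred-linked in order.
#'
#' @param dims grid dimensions
#' @param axis 1, 2 or 3: the axis the vessel runs along
#' @param offset integer 2-vector: the fixed coordinates on the other two
#'   axes (in axis order)
#' @param chart the endothelial `sc_chart` (shared by all cells)
#' @param start_id id of the first cell; the chain uses consecutive ids
#' @return a `vessel_network`
#' @export
init_parent_vessel <- function(dims, axis = 1L, offset = c(1L, 1L),
                               chart = endothelial_chart(), start_id = 1L) {
  dims <- as.integer(dims)
  axis <- as.integer(axis)
  if (!(axis %in% 1:3)) stop("axis must be 1, 2 or 3", call. = FALSE)
  other <- setdiff(1:3, axis)
  offset <- as.integer(offset)
  if (any(offset < 1L) || any(offset > dims[other])) {
    stop("parent vessel line lies outside the grid", call. = FALSE)
  }
  network <- empty_network()
  prev <- NA_integer_
  for (i in seq_len(dims[axis])) {
    voxel <- integer(3)
    voxel[axis] <- i
    voxel[other] <- offset
    id <- start_id + i - 1L
    cell <- new_endothelial_cell(id, voxel, chart, role = "stalk", pred = prev)
    network$cells[[id]] <- cell
    network$order <- c(network$order, id)
    network$root_ids <- c(network$root_ids, id)
    prev <- id
  }
  network
}

empty_network <- function() {
  structure(list(cells = list(), order = integer(), root_ids = integer(),
                 tip_ids = integer(), branch_events = list(),
                 n_sprouts = 0L, n_activations = 0L),
            class = "vessel_network")
}

#' Number of endothelial cells in a network
#' @param network a `vessel_network`
#' @export
network_size <- function(network) length(network$order)

# linear voxel indices of all endothelial cells, in ascending id order
network_lins <- function(network, dims) {
  vapply(network$order, function(id) {
    vox_to_lin(network$cells[[id]]$voxel, dims)
  }, integer(1))
}

#' Activate parent-vessel cells above the VEGF threshold
#'
#' Each still-inactive cell of the parent vessel whose local VEGF is at
#' least `T_V` receives the `activate` event and, if it has a free
#' face-neighbor voxel, spawns a tip cell there — in the free neighbor with
#' maximal VEGF (ties break to the lowest voxel index).  Each spawned tip
#' starts a new sprout.  Cells are visited in ascending id order.
#'
#' @param network a `vessel_network`
#' @param vegf the VEGF `scalar_field`
#' @param params [angio_params()]
#' @param occ occupancy array (updated with spawned tips)
#' @param lattice lattice tables
#' @param chart the endothelial chart
#' @param next_id next free agent id
#' @return `list(network, occ, next_id)`
#' @export
activate <- function(network, vegf, params, occ, lattice, chart, next_id) {
  for (id in network$root_ids) {
    cell <- network$cells[[id]]
    if (!is_in(cell$inst, "inactive")) next
    lin <- vox_to_lin(cell$voxel, lattice$dims)
    if (vegf$values[lin] < params$T_V) next
    cell$inst <- dispatch(cell$inst, "activate")$instance
    network$cells[[id]] <- cell
    network$n_activations <- network$n_activations + 1L
    free <- free_neighbors(lattice, occ, lin)
    if (length(free) > 0L) {
      dest <- free[which.max(vegf$values[free])]
      network$n_sprouts <- network$n_sprouts + 1L
      tip <- new_endothelial_cell(next_id, lin_to_vox(dest, lattice$dims),
                                  chart, role = "tip", pred = id,
                                  sprout = network$n_sprouts, activated = TRUE)
      network$cells[[next_id]] <- tip
      network$order <- c(network$order, next_id)
      network$tip_ids <- c(network$tip_ids, next_id)
      occ[dest] <- next_id
      next_id <- next_id + 1L
    }
  }
  list(network = network, occ = occ, next_id = next_id)
}

#' Move one sprout tip (elongation)
#'
#' With probability `p_move` the tip attempts a move; a moving tip steps to
#' the free face-neighbor voxel of maximal VEGF (ties to the lowest voxel
#' index), or — with probability `epsilon` — to a uniformly chosen free
#' neighbor.  The vacated voxel is filled by a new stalk cell spliced into
#' the pred chain behind the tip.  A tip with no free neighbor stalls.
#' RNG draws, in order: the move draw; then (only if moving and a free
#' neighbor exists) the exploration draw; then (only if exploring) the
#' neighbor choice.
#'
#' @inheritParams activate
#' @param tip_id id of a tip cell
#' @return `list(network, occ, next_id)`
#' @export
tip_step <- function(network, tip_id, vegf, params, occ, lattice, chart, next_id) {
  cell <- network$cells[[tip_id]]
  if (is.null(cell) || cell$role != "tip") {
    stop(sprintf("id %s is not a tip cell", tip_id), call. = FALSE)
  }
  if (stats::runif(1) >= params$p_move) {
    return(list(network = network, occ = occ, next_id = next_id))
  }
  lin <- vox_to_lin(cell$voxel, lattice$dims)
  free <- free_neighbors(lattice, occ, lin)
  if (length(free) == 0L) {
    return(list(network = network, occ = occ, next_id = next_id))
  }
  dest <- if (stats::runif(1) < params$epsilon) {
    if (length(free) == 1L) free else free[sample.int(length(free), 1L)]
  } else {
    free[which.max(vegf$values[free])]
  }
  stalk <- new_endothelial_cell(next_id, cell$voxel, chart, role = "stalk",
                                pred = cell$pred, sprout = cell$sprout,
                                activated = TRUE)
  network$cells[[next_id]] <- stalk
  network$order <- c(network$order, next_id)
  cell$pred <- next_id
  cell$voxel <- lin_to_vox(dest, lattice$dims)
  network$cells[[tip_id]] <- cell
  occ[lin] <- next_id
  occ[dest] <- tip_id
  list(network = network, occ = occ, next_id = next_id + 1L)
}

#' Attempt a branch at one sprout tip
#'
#' With probability `min(1, beta * local VEGF)` the tip spawns a second tip
#' in a free face-neighbor voxel distinct from its own next-move direction
#' (the up-gradient free neighbor), chosen uniformly among the candidates.
#' The new tip starts a new sprout branching off the cell behind the
#' current tip, and the branch event `(step, voxel, local VEGF)` is
#' recorded.  A no-op when `allow_branching` is `FALSE` (no RNG draws).
#'
#' @inheritParams tip_step
#' @param step current step index, recorded with the branch event
#' @return `list(network, occ, next_id)`
#' @export
branch_step <- function(network, tip_id, vegf, params, occ, lattice, chart,
                        next_id, step = 0L) {
  if (!params$allow_branching) {
    return(list(network = network, occ = occ, next_id = next_id))
  }
  cell <- network$cells[[tip_id]]
  if (is.null(cell) || cell$role != "tip") {
    stop(sprintf("id %s is not a tip cell", tip_id), call. = FALSE)
  }
  lin <- vox_to_lin(cell$voxel, lattice$dims)
  v_local <- vegf$values[lin]
  p <- min(1, params$beta * v_local)
  if (p <= 0) return(list(network = network, occ = occ, next_id = next_id))
  if (stats::runif(1) >= p) {
    return(list(network = network, occ = occ, next_id = next_id))
  }
  free <- free_neighbors(lattice, occ, lin)
  if (length(free) < 2L) {
    return(list(network = network, occ = occ, next_id = next_id))
  }
  headed <- free[which.max(vegf$values[free])]
  cand <- setdiff(free, headed)
  dest <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  network$n_sprouts <- network$n_sprouts + 1L
  tip <- new_endothelial_cell(next_id, lin_to_vox(dest, lattice$dims), chart,
                              role = "tip", pred = cell$pred,
                              sprout = network$n_sprouts, activated = TRUE)
  network$cells[[next_id]] <- tip
  network$order <- c(network$order, next_id)
  network$tip_ids <- c(network$tip_ids, next_id)
  occ[dest] <- next_id
  network$branch_events[[length(network$branch_events) + 1L]] <-
    list(step = as.integer(step), voxel = cell$voxel, vegf = v_local)
  list(network = network, occ = occ, next_id = next_id + 1L)
}

#' Deliver oxygen from the vessel network
#'
#' Every endothelial cell — parent vessel and sprouts, stalk and tip — adds
#' `s_O2 * dt` oxygen at its voxel.
#'
#' @param network a `vessel_network`
#' @param o2 the oxygen `scalar_field`
#' @param params [angio_params()]
#' @param dt time step
#' @return the updated oxygen field
#' @export
perfuse <- function(network, o2, params, dt) {
  if (network_size(network) == 0L || params$s_O2 <= 0) return(o2)
  lin <- network_lins(network, o2$dims)
  o2$values[lin] <- o2$values[lin] + params$s_O2 * dt
  o2
}

#' Branch events as a data.frame
#' @param network a `vessel_network`
#' @return data.frame with columns `step, x, y, z, vegf`
#' @export
branch_events <- function(network) {
  ev <- network$branch_events
  data.frame(
    step = vapply(ev, function(e) e$step, integer(1)),
    x = vapply(ev, function(e) e$voxel[1], integer(1)),
    y = vapply(ev, function(e) e$voxel[2], integer(1)),
    z = vapply(ev, function(e) e$voxel[3], integer(1)),
    vegf = vapply(ev, function(e) e$vegf, numeric(1))
  )
}

#' Vessel snapshot as a data.frame
#' @param network a `vessel_network`
#' @return data.frame with columns `id, x, y, z, role, pred, sprout`
#' @export
network_snapshot <- function(network) {
  cells <- network$cells[network$order]
  data.frame(
    id = vapply(cells, `[[`, integer(1), "id"),
    x = vapply(cells, function(c) c$voxel[1], integer(1)),
    y = vapply(cells, function(c) c$voxel[2], integer(1)),
    z = vapply(cells, function(c) c$voxel[3], integer(1)),
    role = vapply(cells, `[[`, character(1), "role"),
    pred = vapply(cells, `[[`, integer(1), "pred"),
    sprout = vapply(cells, `[[`, integer(1), "sprout")
  )
}

#' Check the vessel-network invariants
#'
#' Verifies that pred links form a forest rooted in the parent vessel(s),
#' that no two endothelial cells share a voxel, and that no cell's pred
#' points at a tip (tips have no successor).
#'
#' @param network a `vessel_network`
#' @return character vector of violations (empty when consistent)
#' @export
check_network <- function(network) {
  v <- character()
  lins <- vapply(network$order, function(id) {
    vox <- network$cells[[id]]$voxel
    vox[1] * 1e6 + vox[2] * 1e3 + vox[3]
  }, numeric(1))
  if (anyDuplicated(lins)) v <- c(v, "two endothelial cells share a voxel")
  roots <- network$root_ids
  for (id in network$order) {
    cell <- network$cells[[id]]
    seen <- integer()
    cur <- cell
    while (!is.na(cur$pred)) {
      if (cur$id %in% seen) { v <- c(v, sprintf("pred cycle at id %d", id)); break }
      seen <- c(seen, cur$id)
      nxt <- network$cells[[cur$pred]]
      if (is.null(nxt)) { v <- c(v, sprintf("dangling pred at id %d", cur$id)); break }
      if (nxt$role == "tip") v <- c(v, sprintf("tip %d has successor %d", nxt$id, cur$id))
      cur <- nxt
    }
    if (is.na(cur$pred) && !(cur$id %in% roots)) {
      v <- c(v, sprintf("cell %d not rooted in the parent vessel", id))
    }
  }
  unique(v)
}
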