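#' Simulation orchestrator
#'
#' [init_scenario()] builds the initial state (a single founder tumor cell
#' at the grid center, a parent vessel along one edge when vessels are
#' enabled, a uniform oxygen baseline, zero VEGF); [sim_step()] advances the
#' coupled system by one step in a fixed phase order; [sim_run()] executes
#' a whole configuration and collects the metrics table and (optionally) a
#' recorded message stream.  A single global RNG stream, seeded once from
#' the configuration and snapshotted inside the state, makes runs
#' bit-reproducible.
#'
#' @name simulator
NULL

invariant_error <- function(msg, state = NULL) {
  dump <- if (!is.null(state)) {
    sprintf(" [step %d, %d tumor cells, %d endothelial cells]",
            state$step, length(state$tumor_ids), network_size(state$network))
  } else ""
  stop(structure(class = c("oncosim_invariant_error", "error", "condition"),
                 list(message = paste0(msg, dump), call = NULL)))
}

#' Initialize a scenario
#'
#' @param config a validated [sim_config()]
#' @return a `sim_state`: step counter, agent stores, vessel network,
#'   oxygen and VEGF fields, occupancy array (one agent of any type per
#'   voxel), RNG snapshot and id counter
#' @export
init_scenario <- function(config) {
  validate_config(config)
  dims <- config$dims
  lattice <- make_lattice(dims)
  o2 <- scalar_field(dims, h = config$spacing, D = config$fields$D_O2,
                     k_decay = config$fields$k_decay_O2,
                     values = config$baseline_o2)
  vegf <- scalar_field(dims, h = config$spacing, D = config$fields$D_V,
                       k_decay = config$fields$k_decay_V, values = 0)
  occ <- array(0L, dim = dims)
  t_chart <- tumor_chart()
  e_chart <- endothelial_chart()

  founder_voxel <- as.integer(ceiling(dims / 2))
  founder <- new_tumor_cell(1L, founder_voxel, t_chart)
  cells <- list()
  cells[[1L]] <- founder
  occ[founder_voxel[1], founder_voxel[2], founder_voxel[3]] <- 1L
  next_id <- 2L

  network <- empty_network()
  if (config$vessels_enabled) {
    network <- init_parent_vessel(dims, axis = config$vessel_axis,
                                  offset = config$vessel_offset,
                                  chart = e_chart, start_id = next_id)
    for (id in network$order) {
      vox <- network$cells[[id]]$voxel
      if (occ[vox[1], vox[2], vox[3]] != 0L) {
        config_error("parent vessel overlaps the founder cell")
      }
      occ[vox[1], vox[2], vox[3]] <- id
    }
    next_id <- next_id + network_size(network)
  }

  set.seed(config$seed)
  state <- list(
    step = 0L, cells = cells, tumor_ids = 1L, network = network,
    o2 = o2, vegf = vegf, occ = occ, lattice = lattice,
    t_chart = t_chart, e_chart = e_chart,
    founder_voxel = founder_voxel, next_id = next_id,
    rng = get(".Random.seed", envir = globalenv()),
    pending_events = list()
  )
  class(state) <- "sim_state"
  state
}

#' Advance the simulation by one step
#'
#' Phase order (fixed; the single RNG stream is consumed in exactly this
#' order):
#' 1. perfusion — every endothelial cell deposits oxygen;
#' 2. tumor metabolism — live cells consume oxygen, hypoxic cells secrete
#'    VEGF;
#' 3. one diffusion/decay step on both fields;
#' 4. agent ticks — tumor cells in ascending id order, then endothelial
#'    activation, then every tip (ascending id): move, then branch;
#' 5. queued divisions applied in ascending mother id;
#' 6. step counter and bookkeeping.
#'
#' @param state a `sim_state`
#' @param config the `sim_config` in force
#' @return the successor `sim_state`
#' @export
sim_step <- function(state, config) {
  assign(".Random.seed", state$rng, envir = globalenv())
  dt <- config$dt
  lattice <- state$lattice

  # 1. perfusion
  state$o2 <- perfuse(state$network, state$o2, config$angio, dt)

  # 2. tumor metabolism
  met <- apply_metabolism(state$cells[state$tumor_ids], state$o2, state$vegf,
                          config$tumor, dt)
  state$o2 <- met$o2
  state$vegf <- met$vegf

  # 3. field transport
  state$o2 <- diffuse_decay_step(state$o2, dt)
  state$vegf <- diffuse_decay_step(state$vegf, dt)

  # 4a. tumor ticks
  divide_queue <- integer()
  cells <- state$cells
  occ <- state$occ
  o2 <- state$o2
  for (id in state$tumor_ids) {
    cell <- cells[[id]]
    if (cell$state == "necrotic") next
    lin <- vox_to_lin(cell$voxel, lattice$dims)
    nbs <- lattice$nb[lin, ]
    nbs <- nbs[!is.na(nbs)]
    readings <- list(o2 = o2$values[lin], free = sum(occ[nbs] == 0L))
    res <- tick_tumor(cell, readings, config$tumor)
    cells[[id]] <- res$cell
    if (res$divide) divide_queue <- c(divide_queue, id)
  }
  state$cells <- cells

  # 4b. endothelial activation, 4c. tip moves and branches
  if (config$vessels_enabled && network_size(state$network) > 0L) {
    act <- activate(state$network, state$vegf, config$angio, occ, lattice,
                    state$e_chart, state$next_id)
    network <- act$network; occ <- act$occ; next_id <- act$next_id
    for (tid in network$tip_ids) {
      mv <- tip_step(network, tid, state$vegf, config$angio, occ, lattice,
                     state$e_chart, next_id)
      network <- mv$network; occ <- mv$occ; next_id <- mv$next_id
      br <- branch_step(network, tid, state$vegf, config$angio, occ, lattice,
                        state$e_chart, next_id, step = state$step + 1L)
      network <- br$network; occ <- br$occ; next_id <- br$next_id
    }
    state$network <- network
    state$next_id <- next_id
  }

  # 5. divisions
  for (id in divide_queue) {
    daughter <- apply_divide(state$cells[[id]], occ, lattice,
                             state$next_id, state$t_chart)
    if (!is.null(daughter)) {
      state$cells[[state$next_id]] <- daughter
      state$tumor_ids <- c(state$tumor_ids, state$next_id)
      occ[vox_to_lin(daughter$voxel, lattice$dims)] <- state$next_id
      state$next_id <- state$next_id + 1L
    }
  }
  state$occ <- occ

  # 6. bookkeeping
  state$step <- state$step + 1L
  state$rng <- get(".Random.seed", envir = globalenv())
  if (config$check_invariants) {
    bad <- check_state(state)
    if (length(bad)) invariant_error(paste(bad, collapse = "; "), state)
  }
  state
}

#' Check the joint state invariants
#'
#' Occupancy consistency (every agent sits where the occupancy array says,
#' no two agents share a voxel), vessel-network structure
#' ([check_network()]), and statechart configuration consistency for every
#' agent.
#'
#' @param state a `sim_state`
#' @return character vector of violations (empty when consistent)
#' @export
check_state <- function(state) {
  v <- character()
  expect_occ <- array(0L, dim = state$lattice$dims)
  for (id in state$tumor_ids) {
    cell <- state$cells[[id]]
    lin <- vox_to_lin(cell$voxel, state$lattice$dims)
    if (expect_occ[lin] != 0L) {
      v <- c(v, sprintf("two agents at voxel of tumor cell %d", id))
    }
    expect_occ[lin] <- id
    if (length(check_configuration(cell$inst))) {
      v <- c(v, sprintf("inconsistent chart configuration in tumor cell %d", id))
    }
  }
  for (id in state$network$order) {
    cell <- state$network$cells[[id]]
    lin <- vox_to_lin(cell$voxel, state$lattice$dims)
    if (expect_occ[lin] != 0L) {
      v <- c(v, sprintf("two agents at voxel of endothelial cell %d", id))
    }
    expect_occ[lin] <- id
  }
  if (!identical(as.vector(expect_occ), as.vector(state$occ))) {
    v <- c(v, "occupancy array out of sync with agent positions")
  }
  v <- c(v, check_network(state$network))
  v
}

#' Metrics for the current state
#'
#' One row of the run's metrics table: tumor counts by state, endothelial
#' and sprout counts, branch events to date, tumor radius (largest distance
#' of a non-necrotic cell from the founder voxel), asphericity of the live
#' cells, mean radial position of live and necrotic cells, and field
#' totals.  Distances are in lattice spacings from the founder voxel.
#'
#' @param state a `sim_state`
#' @return a one-row data.frame
#' @export
metrics_row <- function(state) {
  cells <- state$cells[state$tumor_ids]
  states <- vapply(cells, `[[`, character(1), "state")
  n_p <- sum(states == "proliferating")
  n_q <- sum(states == "quiescent")
  n_h <- sum(states == "hypoxic")
  n_n <- sum(states == "necrotic")
  live <- states != "necrotic"
  pos <- if (length(cells)) {
    t(vapply(cells, `[[`, integer(3), "voxel"))
  } else {
    matrix(integer(), ncol = 3)
  }
  dist_founder <- if (nrow(pos)) {
    sqrt(rowSums((pos - matrix(state$founder_voxel, nrow(pos), 3,
                               byrow = TRUE))^2))
  } else numeric()
  asph <- NA_real_
  if (sum(live) >= 2L) {
    lp <- pos[live, , drop = FALSE]
    if (nrow(unique(lp)) >= 2L) asph <- asphericity(lp)
  }
  ev <- state$network$branch_events
  data.frame(
    step = state$step,
    n_proliferating = n_p, n_quiescent = n_q, n_hypoxic = n_h,
    n_necrotic = n_n, n_live = n_p + n_q + n_h,
    n_endothelial = network_size(state$network),
    n_sprouts = state$network$n_sprouts,
    n_branch_events = length(ev),
    radius = if (any(live)) max(dist_founder[live]) else NA_real_,
    asphericity = asph,
    mean_r_live = if (any(live)) mean(dist_founder[live]) else NA_real_,
    mean_r_necrotic = if (n_n > 0L) mean(dist_founder[!live]) else NA_real_,
    total_o2 = total_mass(state$o2),
    total_vegf = total_mass(state$vegf)
  )
}

#' Run a configuration to completion
#'
#' Executes `n_steps` steps from [init_scenario()].  Metrics are collected
#' at step 0, every `snapshot_every` steps, and at the final step.  When
#' `config$record_path` is set, the full message stream (header, then one
#' XML step document per line) is written there.
#'
#' @param config a validated [sim_config()]
#' @return `list(metrics = data.frame, state = final sim_state,
#'   record_path = path or NULL)`
#' @export
sim_run <- function(config) {
  state <- init_scenario(config)
  recording <- !is.null(config$record_path)
  rec_lines <- character()
  prev_scene <- list()
  if (recording) {
    rec_lines <- encode_run_header(config)
    d0 <- scene_step_document(state, prev_scene)
    rec_lines <- c(rec_lines, d0$doc)
    prev_scene <- d0$scene
    state$pending_events <- list()
  }
  rows <- list(metrics_row(state))
  for (i in seq_len(config$n_steps)) {
    state <- sim_step(state, config)
    if (recording) {
      d <- scene_step_document(state, prev_scene)
      rec_lines <- c(rec_lines, d$doc)
      prev_scene <- d$scene
    }
    state$pending_events <- list()
    if (state$step %% config$snapshot_every == 0L || i == config$n_steps) {
      rows[[length(rows) + 1L]] <- metrics_row(state)
    }
  }
  metrics <- do.call(rbind, rows)
  metrics <- metrics[!duplicated(metrics$step), , drop = FALSE]
  rownames(metrics) <- NULL
  if (recording) {
    con <- file(config$record_path, open = "wb")
    writeLines(rec_lines, con, sep = "\n", useBytes = TRUE)
    close(con)
  }
  list(metrics = metrics, state = state,
       record_path = config$record_path)
}

#' Asphericity of a point cloud
#'
#' From the eigenvalues `l1 >= l2 >= l3` of the gyration tensor of the
#' positions: `A = (l1 - (l2 + l3) / 2) / (l1 + l2 + l3)`.  0 for an
#' isotropic cloud, 1/4 for a planar disc, 1 for a line.
#'
#' @param positions numeric matrix (n x 3) with at least two distinct rows
#' @return a number in `[0, 1]`
#' @export
asphericity <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2L || nrow(unique(positions)) < 2L) {
    stop("asphericity is undefined for fewer than two distinct points",
         call. = FALSE)
  }
  centered <- sweep(positions, 2, colMeans(positions))
  gyr <- crossprod(centered) / nrow(positions)
  ev <- sort(eigen(gyr, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  (ev[1] - (ev[2] + ev[3]) / 2) / sum(ev)
}

command_error <- function(msg) {
  stop(structure(class = c("oncosim_command_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

find_agent <- function(state, id) {
  if (id >= 1L && id <= length(state$cells) && !is.null(state$cells[[id]]) &&
      state$cells[[id]]$type == "tumor_cell" && id %in% state$tumor_ids) {
    return(state$cells[[id]])
  }
  if (id <= length(state$network$cells) && id >= 1L &&
      !is.null(state$network$cells[[id]])) {
    return(state$network$cells[[id]])
  }
  NULL
}

#' Kill an object
#'
#' Kills a specific agent by id, or a uniformly drawn agent of a type
#' (`type = "tumor_cell"` or `"endothelial_cell"`; the random victim
#' consumes one draw from the run's RNG stream).  Killing a tumor cell
#' either removes it from space or marks it necrotic, per
#' `config$kill_mode`.  Only endothelial tips can be killed (stalk cells
#' hold the vessel together).
#'
#' @param state a `sim_state`
#' @param config the `sim_config`
#' @param id agent id, or `NULL` with `type` for a random victim
#' @param type agent type for random selection
#' @return the updated state
#' @export
kill_object <- function(state, config, id = NULL, type = NULL) {
  if (is.null(id)) {
    if (is.null(type)) command_error("kill needs an id or a type")
    assign(".Random.seed", state$rng, envir = globalenv())
    pool <- if (type == "tumor_cell") {
      state$tumor_ids[vapply(state$cells[state$tumor_ids], `[[`,
                             character(1), "state") != "necrotic"]
    } else if (type == "endothelial_cell") {
      state$network$tip_ids
    } else command_error(sprintf("unknown type '%s'", type))
    if (length(pool) == 0L) command_error(sprintf("no killable %s", type))
    id <- if (length(pool) == 1L) pool else pool[sample.int(length(pool), 1L)]
    state$rng <- get(".Random.seed", envir = globalenv())
  }
  id <- as.integer(id)
  agent <- find_agent(state, id)
  if (is.null(agent)) command_error(sprintf("unknown object id %d", id))
  lin <- vox_to_lin(agent$voxel, state$lattice$dims)
  if (agent$type == "tumor_cell") {
    if (config$kill_mode == "necrose") {
      cell <- agent
      cell$inst$active[] <- FALSE
      ch <- cell$inst$chart
      cell$inst$active[match(c("tumor", "necrotic"), ch$node_id)] <- TRUE
      cell$state <- "necrotic"
      state$cells[[id]] <- cell
    } else {
      state$cells[id] <- list(NULL)
      state$tumor_ids <- setdiff(state$tumor_ids, id)
      state$occ[lin] <- 0L
    }
  } else {
    if (agent$role != "tip") command_error("only endothelial tips can be killed")
    network <- state$network
    network$cells[id] <- list(NULL)
    network$order <- setdiff(network$order, id)
    network$tip_ids <- setdiff(network$tip_ids, id)
    state$network <- network
    state$occ[lin] <- 0L
  }
  state
}

#' Create an object at a free voxel
#'
#' Inserts a new agent in its chart's initial configuration: a parentless
#' tumor cell, or an endothelial root cell (a new one-cell vessel).
#'
#' @param state a `sim_state`
#' @param config the `sim_config`
#' @param type `"tumor_cell"` or `"endothelial_cell"`
#' @param voxel integer 3-vector; must be free
#' @return the updated state
#' @export
create_object <- function(state, config, type, voxel) {
  voxel <- as.integer(voxel)
  if (any(voxel < 1L) || any(voxel > state$lattice$dims)) {
    command_error("voxel outside the grid")
  }
  lin <- vox_to_lin(voxel, state$lattice$dims)
  if (state$occ[lin] != 0L) command_error("voxel is occupied")
  id <- state$next_id
  if (type == "tumor_cell") {
    state$cells[[id]] <- new_tumor_cell(id, voxel, state$t_chart)
    state$tumor_ids <- c(state$tumor_ids, id)
  } else if (type == "endothelial_cell") {
    network <- state$network
    network$cells[[id]] <- new_endothelial_cell(id, voxel, state$e_chart)
    network$order <- c(network$order, id)
    network$root_ids <- c(network$root_ids, id)
    state$network <- network
  } else {
    command_error(sprintf("unknown type '%s'", type))
  }
  state$occ[lin] <- id
  state$next_id <- id + 1L
  state
}

#' Query an object
#'
#' @param state a `sim_state`
#' @param id agent id
#' @return list with `type`, `voxel`, `state` tag, `parent` (tumor) or
#'   `pred` (endothelial), and the local oxygen and VEGF concentrations
#' @export
query_object <- function(state, id) {
  agent <- find_agent(state, as.integer(id))
  if (is.null(agent)) command_error(sprintf("unknown object id %s", id))
  lin <- vox_to_lin(agent$voxel, state$lattice$dims)
  if (agent$type == "tumor_cell") {
    list(type = "tumor_cell", voxel = agent$voxel, state = agent$state,
         parent = agent$parent, o2 = state$o2$values[lin],
         vegf = state$vegf$values[lin])
  } else {
    list(type = "endothelial_cell", voxel = agent$voxel, state = agent$role,
         pred = agent$pred, o2 = state$o2$values[lin],
         vegf = state$vegf$values[lin])
  }
}

#' Mean distance from live tumor cells to the nearest vessel voxel
#'
#' A morphology summary for the defective-vessel-growth comparison: how
#' closely the living tumor mass tracks the vasculature.  Distances are in
#' lattice spacings between voxel centers.
#'
#' @param state a `sim_state`
#' @return mean over live (non-necrotic) tumor cells of the Euclidean
#'   distance to the nearest endothelial cell; `NA` if either set is empty
#' @export
live_vessel_distance <- function(state) {
  cells <- state$cells[state$tumor_ids]
  if (length(cells) == 0L || network_size(state$network) == 0L) return(NA_real_)
  states <- vapply(cells, `[[`, character(1), "state")
  live <- cells[states != "necrotic"]
  if (length(live) == 0L) return(NA_real_)
  lp <- t(vapply(live, `[[`, integer(3), "voxel"))
  vp <- t(vapply(state$network$order, function(id) {
    state$network$cells[[id]]$voxel
  }, integer(3)))
  d2 <- outer(rowSums(lp^2), rowSums(vp^2), `+`) - 2 * tcrossprod(lp, vp)
  mean(sqrt(pmax(apply(d2, 1, min), 0)))
}

#' Tumor-cell snapshot as a data.frame
#' @param state a `sim_state`
#' @return data.frame with columns `id, type, x, y, z, state, parent`
#' @export
cells_snapshot <- function(state) {
  cells <- state$cells[state$tumor_ids]
  data.frame(
    id = vapply(cells, `[[`, integer(1), "id"),
    type = "tumor_cell",
    x = vapply(cells, function(c) c$voxel[1], integer(1)),
    y = vapply(cells, function(c) c$voxel[2], integer(1)),
    z = vapply(cells, function(c) c$voxel[3], integer(1)),
    state = vapply(cells, `[[`, character(1), "state"),
    parent = vapply(cells, `[[`, integer(1), "parent")
  )
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state step %d: %d tumor cells, %d endothelial cells>\n",
              x$step, length(x$tumor_ids), network_size(x$network)))
  invisible(x)
}
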