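vessel_fixture <- function(dims = c(7, 7, 7), axis = 1, offset = c(1, 1)) {
  chart <- endothelial_chart()
  network <- init_parent_vessel(dims, axis, offset, chart, start_id = 1L)
  lattice <- oncosim:::make_lattice(dims)
  occ <- array(0L, dim = dims)
  for (id in network$order) {
    v <- network$cells[[id]]$voxel
    occ[v[1], v[2], v[3]] <- id
  }
  list(chart = chart, network = network, lattice = lattice, occ = occ,
       next_id = network_size(network) + 1L)
}

test_that("the parent vessel is a pred-linked chain of stalk cells", {
  fx <- vessel_fixture(dims = c(6, 7, 8), axis = 2, offset = c(1, 1))
  net <- fx$network
  expect_equal(network_size(net), 7)
  snap <- network_snapshot(net)
  expect_true(all(snap$role == "stalk"))
  expect_equal(sum(is.na(snap$pred)), 1)      # one chain root
  expect_equal(nrow(branch_events(net)), 0)
  expect_identical(check_network(net), character())
  expect_error(init_parent_vessel(c(5, 5, 5), 1, c(9, 1)), "outside")
})

test_that("activation requires the VEGF threshold and picks the best neighbor", {
  fx <- vessel_fixture()
  params <- angio_params(T_V = 0.5)
  vegf <- scalar_field(c(7, 7, 7))

  # VEGF everywhere zero: nothing activates
  out <- activate(fx$network, vegf, params, fx$occ, fx$lattice, fx$chart,
                  fx$next_id)
  expect_equal(network_size(out$network), network_size(fx$network))
  expect_equal(out$network$n_activations, 0)

  # one root cell above threshold: exactly one tip, in the max-VEGF neighbor
  vegf <- add_source(vegf, c(4, 1, 1), 1)      # at the 4th vessel cell
  vegf <- add_source(vegf, c(4, 2, 1), 0.4)    # its +y neighbor, the best free one
  vegf <- add_source(vegf, c(4, 1, 2), 0.2)
  out <- activate(fx$network, vegf, params, fx$occ, fx$lattice, fx$chart,
                  fx$next_id)
  expect_equal(out$network$n_activations, 1)
  expect_equal(out$network$n_sprouts, 1)
  tip_id <- out$network$tip_ids
  expect_length(tip_id, 1)
  tip <- out$network$cells[[tip_id]]
  expect_equal(tip$role, "tip")
  expect_equal(tip$voxel, c(4L, 2L, 1L))
  expect_equal(tip$pred, 4L)
  expect_true(is_in(out$network$cells[[4L]]$inst, "activated"))
  # already-activated cells do not re-activate
  out2 <- activate(out$network, vegf, params, out$occ, fx$lattice, fx$chart,
                   out$next_id)
  expect_equal(out2$network$n_activations, 1)
})

test_that("tips climb a VEGF ramp strictly and elongate behind themselves", {
  fx <- vessel_fixture()
  params <- angio_params(T_V = 0.01, p_move = 1, epsilon = 0)
  # activate exactly one root cell (VEGF bump at cell 4 only) ...
  act_field <- add_source(scalar_field(c(7, 7, 7)), c(4, 1, 1), 1)
  out <- activate(fx$network, act_field, params, fx$occ, fx$lattice, fx$chart,
                  fx$next_id)
  # ... then let its tip migrate on a +y VEGF ramp
  vegf <- scalar_field(c(7, 7, 7))
  for (j in 1:7) vegf$values[, j, ] <- j
  net <- out$network; occ <- out$occ; nid <- out$next_id
  tid <- net$tip_ids[1]
  set.seed(1)
  ys <- integer()
  for (k in 1:4) {
    mv <- tip_step(net, tid, vegf, params, occ, fx$lattice, fx$chart, nid)
    net <- mv$network; occ <- mv$occ; nid <- mv$next_id
    ys <- c(ys, net$cells[[tid]]$voxel[2])
  }
  expect_identical(ys, c(3L, 4L, 5L, 6L))   # strictly up the ramp from y = 2
  expect_identical(check_network(net), character())
  # elongation: the sprout behind the tip is a chain of stalk cells
  snap <- network_snapshot(net)
  expect_equal(sum(snap$role == "tip"), 1)
  expect_equal(network_size(net), network_size(fx$network) + 1 + 4)

  # p_move = 0 stalls
  frozen <- tip_step(net, tid, vegf, angio_params(p_move = 0), occ,
                     fx$lattice, fx$chart, nid)
  expect_identical(network_snapshot(frozen$network), snap)
})

test_that("a boxed-in tip stalls", {
  fx <- vessel_fixture()
  params <- angio_params(T_V = 0.01, p_move = 1, epsilon = 0)
  vegf <- scalar_field(c(7, 7, 7), values = 1)
  out <- activate(fx$network, vegf, params, fx$occ, fx$lattice, fx$chart,
                  fx$next_id)
  net <- out$network; occ <- out$occ
  tid <- net$tip_ids[1]
  occ[, , ] <- 99L  # wall everything
  tv <- net$cells[[tid]]$voxel
  occ[tv[1], tv[2], tv[3]] <- tid
  set.seed(2)
  mv <- tip_step(net, tid, vegf, params, occ, fx$lattice, fx$chart, 50L)
  expect_equal(mv$network$cells[[tid]]$voxel, tv)
  expect_equal(network_size(mv$network), network_size(net))
})

test_that("branching follows min(1, beta * VEGF) and records events", {
  fx <- vessel_fixture()
  params <- angio_params(T_V = 0.01, p_move = 1, epsilon = 0, beta = 1)
  # activate a single root cell, then branch its tip under uniform VEGF
  act_field <- add_source(scalar_field(c(7, 7, 7)), c(4, 1, 1), 1)
  out <- activate(fx$network, act_field, params, fx$occ, fx$lattice, fx$chart,
                  fx$next_id)
  vegf <- scalar_field(c(7, 7, 7), values = 2)
  net <- out$network; occ <- out$occ; nid <- out$next_id
  tid <- net$tip_ids[1]

  # beta * V >= 1 with free candidates: branches with certainty
  set.seed(3)
  br <- branch_step(net, tid, vegf, params, occ, fx$lattice, fx$chart, nid,
                    step = 7L)
  expect_equal(br$network$n_sprouts, 2)
  ev <- branch_events(br$network)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$step, 7L)
  expect_equal(ev$vegf, 2)
  expect_identical(check_network(br$network), character())
  # the new tip is not in the up-gradient direction the mother tip heads to
  new_tip <- setdiff(br$network$tip_ids, tid)
  expect_equal(br$network$cells[[new_tip]]$role, "tip")

  # V = 0: probability zero, no draw consumed, no event
  zero <- scalar_field(c(7, 7, 7))
  nb <- branch_step(net, tid, zero, params, occ, fx$lattice, fx$chart, nid)
  expect_equal(nb$network$n_sprouts, 1)

  # allow_branching = FALSE is a contract-level no-op
  off <- angio_params(beta = 1, allow_branching = FALSE)
  nb2 <- branch_step(net, tid, vegf, off, occ, fx$lattice, fx$chart, nid)
  expect_equal(network_size(nb2$network), network_size(net))
  expect_equal(nrow(branch_events(nb2$network)), 0)
})

test_that("a run with branching disabled produces no branch events and few sprouts", {
  cfg <- scenario_config("no-branch", seed = 5, dims = c(20, 20, 20),
                         n_steps = 150)
  res <- sim_run(cfg)
  net <- res$state$network
  expect_equal(length(net$branch_events), 0)
  expect_lte(net$n_sprouts, net$n_activations)
})

test_that("perfusion adds oxygen per endothelial cell with a closed form", {
  fx <- vessel_fixture(dims = c(5, 5, 5))
  o2 <- scalar_field(c(5, 5, 5))   # D = 0, no decay, no consumers
  params <- angio_params(s_O2 = 0.8)
  n <- 6
  for (i in seq_len(n)) o2 <- perfuse(fx$network, o2, params, dt = 0.5)
  expect_equal(total_mass(o2), n * 5 * 0.8 * 0.5, tolerance = 1e-12)
  # s_O2 = 0 leaves the field untouched
  o2b <- perfuse(fx$network, o2, angio_params(s_O2 = 0), 1)
  expect_equal(o2b$values, o2$values)
  # empty network leaves the field untouched
  o2c <- perfuse(oncosim:::empty_network(), o2, params, 1)
  expect_equal(o2c$values, o2$values)
})

test_that("chemotaxis: tip distance to a static VEGF peak never increases", {
  fx <- vessel_fixture(dims = c(9, 9, 9))
  params <- angio_params(T_V = 1e-6, p_move = 1, epsilon = 0)
  peak <- c(7, 7, 7)
  vegf <- scalar_field(c(9, 9, 9))
  for (x in 1:9) for (y in 1:9) for (z in 1:9) {
    vegf$values[x, y, z] <- exp(-0.3 * sum((c(x, y, z) - peak)^2))
  }
  vegf <- add_source(vegf, c(3, 1, 1), 1)  # trigger activation on the vessel
  out <- activate(fx$network, vegf, params, fx$occ, fx$lattice, fx$chart,
                  fx$next_id)
  net <- out$network; occ <- out$occ; nid <- out$next_id
  tid <- net$tip_ids[1]
  set.seed(4)
  d_prev <- sqrt(sum((net$cells[[tid]]$voxel - peak)^2))
  for (k in 1:20) {
    mv <- tip_step(net, tid, vegf, params, occ, fx$lattice, fx$chart, nid)
    net <- mv$network; occ <- mv$occ; nid <- mv$next_id
    d <- sqrt(sum((net$cells[[tid]]$voxel - peak)^2))
    expect_lte(d, d_prev)
    d_prev <- d
    if (d <= 1) break
  }
  expect_lte(d_prev, 1)   # reaches adjacency with the peak
})

test_that("endothelial count never decreases over a run", {
  cfg <- scenario_config("baseline", seed = 6, dims = c(20, 20, 20),
                         n_steps = 120, snapshot_every = 10)
  res <- sim_run(cfg)
  ec <- res$metrics$n_endothelial
  expect_true(all(diff(ec) >= 0))
})
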