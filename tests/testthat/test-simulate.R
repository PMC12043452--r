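test_that("initialization seeds every voxel at capacity in stable composition", {
  p <- toy_params()
  cfg <- sim_config(capacity = 1e6)
  mask <- synthesize_ellipsoid_mask(0.05, spacing = 1, seed = 2)
  tm <- initialize_tumor(mask, p, cfg)
  expect_equal(sum(tm$state), sum(mask$occupancy) * cfg$capacity)
  sc <- stable_composition(p)
  init <- nephrosim:::.aggregate_fractions(tm$state, tm$op$layout)
  expect_equal(unname(init / 100), unname(sc$fractions), tolerance = 1e-9)

  # spatial and aggregate modes agree on the initial composition
  tms <- initialize_tumor(mask, p, sim_config(mode = "spatial"))
  inits <- nephrosim:::.aggregate_fractions(tms$state, tms$op$layout)
  expect_equal(inits, init, tolerance = 1e-12)
  expect_error(initialize_tumor(voxel_mask(array(0L, c(3, 3, 3))), p, cfg),
               "empty mask")
})

test_that("untreated tumors grow exponentially at the dominant rate", {
  p <- toy_params()
  tm <- initialize_tumor(1, p, sim_config())
  empty_plan <- treatment_plan(numeric(0), character(0), 10)
  out <- simulate_tumor(tm, empty_plan, split_ckr(0), keep_trajectory = TRUE)
  expect_lt(out$dv, 0)  # negative reduction: growth
  lam <- growth_rate(p)
  traj <- out$trajectory
  emp <- (traj$volume[241] / traj$volume[1])^(1 / 240)
  expect_equal(emp, lam, tolerance = 0.01 * lam)
  # composition stays at the stable point during free growth
  expect_equal(out$prolif_final, out$prolif_initial, tolerance = 1e-6)
})

test_that("composition percentages sum to 100 initially and finally", {
  p <- toy_params()
  tm <- initialize_tumor(1, p, sim_config())
  out <- simulate_tumor(tm, patient_plan("P2"), split_ckr(0.7))
  expect_equal(out$prolif_initial + out$dormant_initial + out$diff_initial +
                 out$dead_initial, 100, tolerance = 1e-6)
  expect_equal(out$prolif_final + out$dormant_final + out$diff_final +
                 out$dead_final, 100, tolerance = 1e-6)
  expect_lte(out$dv, 100)
})

test_that("tumor reduction is monotone in the total cell-kill ratio", {
  cal <- calibrate_doubling_time(kinetic_reference())
  tm <- initialize_tumor(126.25, cal$params, sim_config())
  grid <- seq(0, 1, length.out = 11)
  dvs <- vapply(grid, function(x)
    simulate_tumor(tm, patient_plan("P1"), split_ckr(x))$dv, 0)
  expect_true(all(diff(dvs) > 0))
})

test_that("repeated full-strength administrations clear the viable pool", {
  # each day of combined VCR+ACT at total CKR 1 leaves (1-0.4)(1-0.6) = 24%
  # of the viable cells; six such days plus a clearance window leave the
  # tumor almost entirely cleared, dead products expiring within TA/TN hours
  p <- toy_params(NLIMP = 1)
  tm <- initialize_tumor(1, p, sim_config())
  days <- rep(1:10, each = 2)
  drugs <- rep(c("VCR", "ACT"), 10)
  out <- simulate_tumor(tm, treatment_plan(days, drugs, 3), split_ckr(1))
  expect_gt(out$dv, 99.5)
  expect_lt(out$volume_final, 0.005 * out$volume_initial)
})

test_that("aggregate and spatial modes agree on the predicted reduction", {
  p <- toy_params()
  mask <- synthesize_ellipsoid_mask(0.1, spacing = 1, seed = 4)
  plan <- treatment_plan(c(1, 2), c("VCR", "ACT"), 2)
  agg <- simulate_tumor(initialize_tumor(mask, p, sim_config()), plan,
                        split_ckr(0.6))
  spa <- simulate_tumor(initialize_tumor(mask, p,
                                         sim_config(mode = "spatial")),
                        plan, split_ckr(0.6))
  expect_lt(abs(agg$dv - spa$dv), 0.1)
})

test_that("simulation horizon must cover the plan", {
  p <- toy_params()
  tm <- initialize_tumor(1, p, sim_config())
  expect_error(simulate_tumor(tm, patient_plan("P1"), split_ckr(0.5),
                              horizon_days = 10), "truncates")
})

test_that("mesh restructuring conserves cells and removes emptied voxels", {
  p <- toy_params()
  cfg <- sim_config(mode = "spatial", capacity = 1000)
  occ <- array(0L, c(9, 9, 7))          # solid block with free margin
  occ[3:7, 3:7, 3:5] <- 1L
  mask <- voxel_mask(occ)
  tm <- initialize_tumor(mask, p, cfg)

  # all voxels exactly at capacity: nothing changes
  r0 <- restructure_mesh(tm)
  expect_equal(ncol(r0$state), ncol(tm$state))
  expect_equal(sum(r0$state), sum(tm$state), tolerance = 1e-9)

  # random loads: exact conservation for many random meshes
  set.seed(99)
  for (i in 1:100) {
    tmi <- tm
    scale <- runif(ncol(tm$state), 0.02, 1.8)
    tmi$state <- sweep(tm$state, 2, scale, `*`)
    ri <- restructure_mesh(tmi, seed = i)
    expect_equal(sum(ri$state), sum(tmi$state), tolerance = 1e-9)
    loads <- colSums(ri$state)
    expect_true(all(loads > 0))
  }

  # a mesh diluted to 8% load consolidates: sub-threshold voxels merge
  # until every survivor sits above the removal threshold, so the occupied
  # count is bounded below by total mass / capacity and shrinks towards it
  tms <- tm
  tms$state <- tm$state * 0.08
  for (i in 1:12) tms <- restructure_mesh(tms, seed = i)
  frac <- ncol(tms$state) / ncol(tm$state)
  expect_lt(frac, 0.7)
  expect_gte(ncol(tms$state), ceiling(0.08 * ncol(tm$state)))
  expect_true(all(colSums(tms$state) >=
                    cfg$removal_threshold * cfg$capacity))
  expect_equal(sum(tms$state), 0.08 * sum(tm$state), tolerance = 1e-9)

  # growth: overloaded voxels spill into new neighbours
  tmg <- tm
  tmg$state <- tm$state * 2
  rg <- restructure_mesh(tmg)
  expect_gt(ncol(rg$state), ncol(tmg$state))
  expect_equal(sum(rg$state), sum(tmg$state), tolerance = 1e-9)
})
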