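test_that("parameter validation enforces the model's domains", {
  expect_error(kinetic_params(Td = -1), "Td")
  expect_error(kinetic_params(Psym = 1.2), "Psym")
  expect_error(kinetic_params(NLIMP = 0), "NLIMP")
  expect_error(kinetic_params(NLIMP = 2.5), "NLIMP")
  expect_s3_class(kinetic_reference(), "kinetic_params")
})

test_that("cycle phase split preserves the total and keeps phases >= 1 h", {
  expect_identical(split_cycle_phases(23), c(9L, 8L, 4L, 2L))
  for (tc in c(4, 5, 8, 11.5, 23, 34.5, 60, 191)) {
    ph <- split_cycle_phases(tc)
    expect_identical(sum(ph), max(4L, as.integer(round(tc))))
    expect_true(all(ph >= 1L))
  }
})

test_that("the transition operator is linear, nonnegative and conservative", {
  op <- transition_operator(toy_params())
  expect_true(all(op$A@x >= 0))
  expect_equal(as.numeric(op$A %*% numeric(op$layout$n)),
               numeric(op$layout$n))

  # explicit bookkeeping: cells after = before + births - cleared dead.
  # births add one extra cell per completed mitosis (surviving M fraction),
  # clearance removes the last apoptosis/necrosis age slots.
  p <- toy_params()
  lay <- op$layout
  du <- op$durations
  m_slots <- c(lay$prolif[seq_len(length(lay$prolif)) %% du$Tc == 0])
  for (seed in 1:5) {
    s <- random_state(op, seed)
    after <- as.numeric(op$A %*% s)
    births <- (1 - p$RA) * sum(s[m_slots])
    cleared <- s[lay$apop[du$TA]] + s[lay$necr[du$TN]]
    expect_equal(sum(after), sum(s) + births - cleared, tolerance = 1e-12)
  }
})

test_that("G0 stays empty without post-mitotic quiescence", {
  p <- toy_params(Psleep = 0, RA = 0)
  op <- transition_operator(p)
  s <- numeric(op$layout$n)
  s[1] <- 1  # a single cycling stem cohort
  for (h in 1:200) s <- as.numeric(op$A %*% s)
  expect_equal(sum(s[op$layout$dormant]), 0)
})

test_that("growth rate has the closed-form doubling limit", {
  # pure symmetric division, no deaths, no dormancy: doubling every Tc hours
  p <- kinetic_params(Tc = 23, Psym = 1, Psleep = 0, RA = 0, RADiff = 0,
                      RNDiff = 0, PG0toG1 = 0)
  expect_equal(growth_rate(p)^23, 2, tolerance = 1e-9)
  # overwhelming apoptosis: regression
  expect_lt(growth_rate(kinetic_params(RA = 0.9)), 1)
})

test_that("free-growth check admits the reference and rejects blocked division", {
  expect_true(free_growth_check(kinetic_reference()))
  expect_false(free_growth_check(kinetic_params(RA = 0.9)))
  # all division routes blocked: lone LIMP mitosis, all daughters dormant
  # forever
  blocked <- kinetic_params(Psym = 0, NLIMP = 1, Psleep = 1, PG0toG1 = 0)
  expect_false(free_growth_check(blocked))
})

test_that("renewal-root growth rate agrees with power iteration and the
           explicit trajectory", {
  for (p in list(kinetic_reference(), toy_params(),
                 toy_params(Psleep = 0.5, Psym = 0.7, NLIMP = 3))) {
    lam <- growth_rate(p)
    op <- transition_operator(p)
    # independent route 1: shifted power iteration on the stem block
    pi_lam <- nephrosim:::.stem_eigen(op)$lambda
    expect_equal(lam, pi_lam, tolerance = 1e-9)
    # independent route 2: slope of log total cells over a long free run
    traj <- trajectory_growth_factor(op, rep(1, op$layout$n), 2000)
    expect_equal(lam, traj, tolerance = 1e-4)
  }
  # in a regressing tumor the slowest-decaying lineage sets the rate; the
  # trajectory oracle must still agree with the live-operator fallback
  reg <- toy_params(Psleep = 0.5, Psym = 0.1, NLIMP = 1)
  op <- transition_operator(reg)
  lam <- growth_rate(reg)
  expect_lt(lam, 1)
  traj <- trajectory_growth_factor(op, rep(1, op$layout$n), 3000)
  expect_equal(lam, traj, tolerance = 1e-4)
})

test_that("stable composition is a true eigenvector with sane aggregates", {
  p <- kinetic_reference()
  sc <- stable_composition(p)
  expect_equal(sum(sc$fractions), 1, tolerance = 1e-12)
  expect_true(all(sc$state >= 0))
  resid <- as.numeric(sc$op$A %*% sc$state) - sc$lambda * sc$state
  expect_lt(max(abs(resid)), 1e-12)

  # no quiescence entry: no dormant mass
  sc0 <- stable_composition(kinetic_params(Psleep = 0))
  expect_equal(sc0$fractions[["dormant"]], 0)

  expect_error(stable_composition(kinetic_params(RA = 0.9)), "free growth")
})

test_that("long free-growth runs converge to the stable composition", {
  p <- toy_params(NLIMP = 2)
  sc <- stable_composition(p)
  op <- sc$op
  s <- rep(1, op$layout$n)
  for (h in 1:3000) {
    s <- as.numeric(op$A %*% s)
    if (h %% 100 == 0) s <- s / sum(s)  # keep numbers in range
  }
  s <- s / sum(s)
  lay <- op$layout
  emp <- c(prolif = sum(s[lay$prolif]), dormant = sum(s[lay$dormant]),
           diff = sum(s[lay$diff]),
           dead = sum(s[lay$apop]) + sum(s[lay$necr]))
  expect_equal(emp, sc$fractions, tolerance = 1e-3)
})

test_that("clock dilation slows growth monotonically", {
  p <- kinetic_reference()
  l1 <- growth_rate(nephrosim:::dilate_params(p, 2))
  l2 <- growth_rate(nephrosim:::dilate_params(p, 3))
  expect_lt(l2, l1)
  expect_lt(l1, growth_rate(p))
})

test_that("doubling-time calibration is a fixed point when Td already matches", {
  p <- kinetic_reference()
  d1 <- doubling_time(p)
  matched <- kinetic_params(Td = d1 / 24)
  cal <- calibrate_doubling_time(matched)
  expect_lt(abs(cal$s - 1), 0.05)
  expect_lt(abs(cal$doubling_hours - d1) / d1, 0.01)
})

test_that("calibration recovers the sampled doubling time within 1%", {
  ref <- kinetic_reference()
  n_checked <- 0
  for (i in 1:20) {
    vp <- sample_vp(ref, deviation = 0.5, seed = 202, vp_index = i)
    cal <- tryCatch(calibrate_doubling_time(vp),
                    nephrosim_calibration_error = function(e) NULL)
    if (is.null(cal)) next  # inadmissible draw (no growth / out of bracket)
    n_checked <- n_checked + 1
    expect_lt(abs(cal$doubling_hours - vp$Td * 24) / (vp$Td * 24), 0.01)
  }
  expect_gte(n_checked, 10)
})

test_that("calibrated clocks reproduce Td in explicit simulation", {
  ref <- kinetic_reference()
  n_done <- 0
  for (i in 1:10) {
    vp <- sample_vp(ref, deviation = 0.5, seed = 202, vp_index = i)
    cal <- tryCatch(calibrate_doubling_time(vp),
                    nephrosim_calibration_error = function(e) NULL)
    if (is.null(cal)) next
    sc <- stable_composition(cal$params)
    gf <- trajectory_growth_factor(sc$op, sc$state, 3000)
    emp_doubling <- log(2) / log(gf)
    expect_lt(abs(emp_doubling - vp$Td * 24) / (vp$Td * 24), 0.015)
    n_done <- n_done + 1
    if (n_done >= 2) break
  }
  expect_gte(n_done, 2)
})
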