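# shared test helpers: small parameter sets and explicit-trajectory oracles

# cheap kinetics for structural tests: short phases keep the operator tiny
toy_params <- function(...) {
  args <- utils::modifyList(
    list(Td = 2, Tc = 8, TG0 = 4, TN = 3, TA = 2, RA = 0.01, RADiff = 0.02,
         RNDiff = 0.01, PG0toG1 = 0.05, NLIMP = 1, Psym = 0.6, Psleep = 0.2),
    list(...))
  do.call(kinetic_params, args)
}

# explicit hourly trajectory of total cell count from a given start state
trajectory_totals <- function(op, state, hours) {
  tot <- numeric(hours + 1)
  tot[1] <- sum(state)
  for (h in seq_len(hours)) {
    state <- as.numeric(op$A %*% state)
    tot[h + 1] <- sum(state)
  }
  tot
}

# asymptotic per-hour growth factor fitted from the tail of a trajectory
trajectory_growth_factor <- function(op, state, hours, tail_frac = 0.5) {
  tot <- trajectory_totals(op, state, hours)
  tail_idx <- seq(floor(hours * (1 - tail_frac)) + 1, hours + 1)
  exp(stats::coef(stats::lm(log(tot[tail_idx]) ~ tail_idx))[[2]])
}

random_state <- function(op, seed) {
  set.seed(seed)
  stats::runif(op$layout$n)
}
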