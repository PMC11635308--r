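# Independent oracles used across the suite.  None of these call the
# package's integrator.

# closed-form logistic trajectory
logistic_solution <- function(t, r, k, n0) {
  k * n0 * exp(r * t) / (k + n0 * (exp(r * t) - 1))
}

# Equal-capacity steady state via the composition law: N_i* = n0_i * g^{r_i}
# with the single scalar g fixed by sum_i N_i* = K (valid when at least one
# rate is positive; exponents may be negative).  Solved by uniroot on log g.
composition_steady_state <- function(n0, rates, k) {
  stopifnot(length(unique(k)) == 1L, any(rates > 0), sum(n0) < k[1])
  K <- k[1]
  f <- function(logg) sum(n0 * exp(rates * logg)) - K
  # at this log g the largest positive-rate term alone reaches K, so f > 0
  pos <- rates > 0
  upper <- min(log(K / n0[pos]) / rates[pos])
  logg <- stats::uniroot(f, c(0, upper), tol = 1e-14)$root
  n0 * exp(rates * logg)
}

# naive fixed-step Euler integration of the shared-sum LV system
euler_lv <- function(n0, rates, k, dt, t_end) {
  y <- n0
  steps <- round(t_end / dt)
  for (i in seq_len(steps)) {
    y <- y + dt * (rates * y * (1 - sum(y) / k))
    y <- pmax(y, 0)
  }
  y
}

# a community whose growth rates at temp = 30 are exactly `rates`
# (all optima at 30, so each species' rate there is its r_peak)
flat_rate_community <- function(rates, k = 1, n0 = 0.01) {
  community(
    species_id = paste0("sp", seq_along(rates)),
    t_min = 0, t_opt = 30, t_max = 35,
    r_peak = rates, death_slope = 0, k = k, n0 = n0
  )
}

# random valid right-skewed community for property tests (call set.seed first)
random_community <- function(n_species) {
  t_opt <- sort(stats::runif(n_species, 28, 42))
  community(
    species_id = paste0("sp", seq_len(n_species)),
    t_min = 0,
    t_opt = t_opt,
    t_max = t_opt + stats::runif(n_species, 2, 6),
    r_peak = stats::runif(n_species, 0.3, 1.5),
    death_slope = 0.1,
    k = 1, n0 = 0.01
  )
}
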