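test_that("lv_derivatives matches the printed competition equations", {
  # logistic equilibrium
  expect_equal(lv_derivatives(1, 0.7, 1), 0)
  # hand evaluation: sum N = 0.6, bracket = 0.4
  expect_equal(lv_derivatives(c(0.2, 0.2, 0.2), c(0.5, 0.3, 0.1), c(1, 1, 1)),
               c(0.04, 0.024, 0.008))
  # negative rate declines below capacity
  expect_equal(lv_derivatives(0.5, -0.2, 1), -0.05)
  # extinct species have zero derivative
  expect_equal(lv_derivatives(c(0, 0.3), c(0.8, 0.5), c(1, 1))[1], 0)
  expect_error(lv_derivatives(c(0.1, 0.2), 0.5, c(1, 1)), "equal length")
})

test_that("single-species dynamics match the closed-form logistic solution", {
  # r(T) = 0.5 at the optimum by construction
  comm <- community("solo", t_min = 0, t_opt = 37, t_max = 40,
                    r_peak = 0.5, death_slope = 0, k = 1, n0 = 0.01)
  times <- seq(0, 45, length.out = 10)
  traj <- lv_trajectory(comm, temp = 37, times = times)
  expect_equal(traj$density, logistic_solution(times, 0.5, 1, 0.01),
               tolerance = 1e-6)
  st <- steady_state(comm, 37)
  expect_true(st$converged)
  expect_equal(st$densities$density, 1, tolerance = 1e-6)
})

test_that("a lone species above its critical maximum dies out exactly", {
  comm <- community("solo", 0, 37, 40, death_slope = 0.1, k = 1, n0 = 0.5)
  st <- steady_state(comm, 45)  # rate = -0.5
  expect_identical(st$densities$density, 0)
  expect_identical(dominant_species(st), "none")
})

test_that("a community whose every rate is negative goes fully extinct", {
  comm <- community(c("a", "b"), 0, c(10, 12), c(18, 20),
                    death_slope = 0.1, k = 1, n0 = 0.01)
  st <- steady_state(comm, 30)  # both rates negative
  expect_identical(st$densities$density, c(0, 0))
})

test_that("equal-capacity outcomes obey the composition conservation law", {
  # ln(N_i*/N_i(0)) / r_i is a community-wide constant
  comm <- flat_rate_community(c(0.9, 0.6, 0.3))
  st <- steady_state(comm, 30)
  ratios <- log(st$densities$density / comm$n0) / st$densities$rate
  expect_equal(max(ratios) / min(ratios), 1, tolerance = 1e-3)
  # and the full steady state matches the independent uniroot oracle
  oracle <- composition_steady_state(comm$n0, c(0.9, 0.6, 0.3), comm$k)
  expect_equal(st$densities$density, oracle, tolerance = 1e-4)
  # capacity ceiling
  expect_equal(sum(st$densities$density), 1, tolerance = 1e-6)
})

test_that("the composition law extends to mixed-sign rates: a declining
          species freezes at its remnant once competitors fill the capacity", {
  comm <- community(
    species_id = c("dying", "strong", "weak"),
    t_min = 0, t_opt = c(10, 30, 30), t_max = c(20, 35, 35),
    r_peak = c(1, 0.8, 0.3), death_slope = 0.04, k = 1, n0 = 0.01
  )
  st <- steady_state(comm, 30)  # rates: -0.4, 0.8, 0.3
  oracle <- composition_steady_state(comm$n0, st$densities$rate, comm$k)
  expect_equal(st$densities$density, oracle, tolerance = 1e-3)
  expect_gt(st$densities$density[1], 0)  # remnant, not extinction
})

test_that("permuting species order permutes the outcome identically", {
  set.seed(11)
  comm <- random_community(3)
  perm <- c(3, 1, 2)
  st1 <- steady_state(comm, 36)
  st2 <- steady_state(comm[perm, ], 36)
  expect_equal(st2$densities$density, st1$densities$density[perm],
               tolerance = 1e-9)
  expect_identical(st2$densities$species_id, st1$densities$species_id[perm])
})

test_that("the adaptive integrator agrees with naive fixed-step Euler", {
  set.seed(7)
  for (i in 1:3) {
    n <- sample(2:4, 1)
    comm <- random_community(n)
    temp <- runif(1, 28, 40)
    rates <- growth_rate(comm, temp)$rate
    t_end <- 120
    euler <- euler_lv(comm$n0, rates, comm$k, dt = 0.002, t_end = t_end)
    traj <- lv_trajectory(comm, temp, times = c(0, t_end))
    adaptive <- traj$density[traj$time == t_end]
    live <- euler > 1e-8
    expect_equal(adaptive[live], euler[live], tolerance = 1e-3)
  }
})

test_that("steady states carry convergence diagnostics and tidy/glance work", {
  st <- steady_state(default_community(), 37)
  td <- tidy(st)
  expect_named(td, c("species_id", "density", "relative_density", "rate",
                     "extinct"))
  expect_equal(sum(td$relative_density), 1, tolerance = 1e-9)
  gl <- glance(st)
  expect_true(gl$converged)
  expect_lt(gl$max_abs_derivative, 1e-9)
  expect_true(all(td$density >= 0))
})

test_that("dominance classification handles strict max, ties, and extinction", {
  expect_identical(dominant_species(c(a = 0.5, b = 0.3, c = 0.2)), "a")
  expect_identical(dominant_species(c(a = 0.4, b = 0.4, c = 0.2)), "tie")
  expect_identical(
    dominant_species(c(a = 0.4, b = 0.4 * (1 - 1e-5), c = 0.2),
                     tie_tol = 1e-6), "a")
  expect_identical(dominant_species(c(a = 0, b = 0, c = 0)), "none")
})
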