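# small draws and coarse grids here; the full battery runs in
# test-acceptance.R

test_that("pairwise matchups enumerate every unordered pair unchanged", {
  comm3 <- default_community()
  pw <- pairwise_matchups(comm3)
  expect_length(pw, 3L)
  expect_setequal(names(pw), c("S3_vs_S1", "S3_vs_S2", "S1_vs_S2"))
  # species rows are preserved verbatim
  expect_equal(pw$S3_vs_S2, comm3[c(1, 3), ])

  expect_length(pairwise_matchups(comm3[1:2, ]), 1L)
  comm4 <- community(letters[1:4], 0, c(30, 32, 34, 36), c(36, 38, 40, 42))
  expect_length(pairwise_matchups(comm4), 6L)
  expect_error(pairwise_matchups(comm3[1, ]), "at least two")
})

test_that("scenario generation is seeded, countable, and id-labelled", {
  spec <- scenario_spec(n_draws = 4, seed = 99)
  a <- generate_scenarios(spec)
  b <- generate_scenarios(spec)
  expect_identical(a, b)  # bit-for-bit under the same seed
  # 4 draws x 3 axes + 3 pairwise matchups
  expect_equal(nrow(a), 15L)
  expect_setequal(unique(a$axis),
                  c("skewness", "spacing", "normalization", "pairwise"))
  expect_true(all(grepl("^(skewness|spacing|normalization|pairwise)",
                        a$scenario_id)))
  # a different seed gives different draws
  c <- generate_scenarios(scenario_spec(n_draws = 4, seed = 100))
  expect_false(identical(a$value, c$value))
})

test_that("a degenerate point range reproduces the centred spacing rule", {
  spec <- scenario_spec(axes = "spacing", spacing_range = c(5, 5),
                        n_draws = 1, include_pairwise = FALSE, seed = 1)
  scn <- generate_scenarios(spec)
  comm <- scn$community[[1]]
  expect_equal(sort(comm$t_opt), c(32, 37, 42))
  # per-species hot-side offsets ride along with the optima
  expect_equal(sort(comm$t_max - comm$t_opt), c(4, 4, 5))
})

test_that("skewness draws move t_max around a fixed optimum and normalization
          draws alternate the normalize switch", {
  spec <- scenario_spec(axes = c("skewness", "normalization"), n_draws = 2,
                        include_pairwise = FALSE, seed = 5)
  scn <- generate_scenarios(spec)
  sk <- dplyr::filter(scn, .data$axis == "skewness")
  base <- default_community()
  for (i in seq_len(nrow(sk))) {
    comm <- sk$community[[i]]
    expect_equal(comm$t_opt, base$t_opt)
    expect_equal(tpc_skewness(comm)$skewness, rep(sk$value[i], 3))
  }
  norm <- dplyr::filter(scn, .data$axis == "normalization")
  expect_setequal(norm$normalize, c(TRUE, FALSE))
  expect_true(any(grepl("_norm$", norm$scenario_id)))
  expect_true(any(grepl("_raw$", norm$scenario_id)))
})

test_that("invalid draws are rejected and exhausting redraws is an error", {
  # spacing of 40 degC pushes the lowest optimum below the shared t_min
  spec <- scenario_spec(axes = "spacing", spacing_range = c(40, 40),
                        n_draws = 1, include_pairwise = FALSE)
  expect_error(generate_scenarios(spec), "100 attempts")
  expect_error(scenario_spec(n_draws = 0), "n_draws")
  expect_error(scenario_spec(spacing_range = c(-1, 2)), "spacing_range")
})

test_that("a small default-regime ensemble keeps the dominance pattern in
          every scenario", {
  spec <- scenario_spec(n_draws = 2, seed = 3)
  scn <- generate_scenarios(spec)
  summ <- evaluate_robustness(scn, step = 1)
  expect_equal(summ$n_failed, 0L)
  # persistence of the intermediate species holds on every axis
  expect_equal(summ$n_intermediate_persists, summ$n_scenarios)
  rec <- tidy(summ)
  # common-skew, spacing and pairwise variations keep pairwise curve
  # crossings single, so the hand-over stays monotone there; independent
  # per-species skews (the normalization axis) may legitimately cross twice
  expect_true(all(rec$monotone[rec$axis != "normalization"]))
  expect_named(rec, c("scenario_id", "axis", "draw", "value", "normalize",
                      "failed", "monotone", "intermediate_persists",
                      "any_tie", "all_converged", "n_ties", "message"))
  # reproducible bit-for-bit: rerun everything under the same seed
  summ2 <- evaluate_robustness(generate_scenarios(spec), step = 1)
  expect_identical(tidy(summ), tidy(summ2))
  expect_identical(summ$details, summ2$details)
})

test_that("pairwise winners carry the higher growth rate and agree with the
          three-species ranking restricted to the pair", {
  comm <- default_community()
  three <- run_temperature_sweep(comm, step = 2)
  for (pair in pairwise_matchups(comm)) {
    sw <- run_temperature_sweep(pair, step = 2)
    td <- tidy(sw)
    for (temp in sw$grid) {
      at_t <- td[td$temperature == temp, ]
      if (any(at_t$density > 0) && !any(duplicated(at_t$density))) {
        winner <- at_t$species_id[which.max(at_t$density)]
        expect_identical(winner, at_t$species_id[which.max(at_t$rate)])
        # restriction of the three-species outcome to this pair
        t3 <- dplyr::filter(tidy(three), .data$temperature == temp,
                            .data$species_id %in% at_t$species_id)
        expect_identical(winner, t3$species_id[which.max(t3$density)])
      }
    }
  }
})

test_that("evaluate_robustness rejects empty input and survives per-scenario
          failure", {
  expect_error(evaluate_robustness(tibble::tibble()), "non-empty")
  good <- generate_scenarios(scenario_spec(n_draws = 1, axes = "skewness",
                                           include_pairwise = FALSE))
  bad <- tibble::tibble(scenario_id = "broken", axis = "manual", draw = 1L,
                        value = NA_real_, normalize = TRUE,
                        community = list(tibble::tibble(bogus = 1)))
  summ <- evaluate_robustness(dplyr::bind_rows(good, bad), step = 2)
  expect_equal(summ$n_failed, 1L)
  expect_equal(summ$n_scenarios, 2L)
  expect_false(any(is.na(tidy(summ)$message[tidy(summ)$failed])))
})
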