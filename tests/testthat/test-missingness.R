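test_that("raw observation predictions follow the linear-probability model", {
  p <- cohort_params(n = 2000)
  coh <- generate_cohort(p, seed = 3)

  # all coefficients zero: every individual sits at the intercept
  expect_equal(outcome_observation_probability(coh, flat_outcome_spec(0.8)),
               rep(0.8, nrow(coh)))

  # stated coefficient values for a specific covariate pattern
  spec <- outcome_missingness_spec(0.2, gamma7 = 0.1, alpha = 0.5)
  i <- which(coh$sex == 1 & coh$mumed == 2 & coh$bf == 3)[1]
  raw <- outcome_observation_probability(coh, spec)
  expect_equal(raw[i], 0.5 + 0.04 + 0.10 + 0.14 + 0.1 * coh$iq[i],
               tolerance = 1e-12)

  # interaction coefficients scale 1:2:3 across breastfeeding groups
  spec_int <- outcome_missingness_spec(0.2, gamma7 = 0.1, gamma8 = -0.025,
                                       alpha = 0.5)
  expect_equal(spec_int$gamma[8:10], c(-0.025, -0.05, -0.075))
  j <- which(coh$sex == 0 & coh$mumed == 0 & coh$bf == 2)[1]
  raw_int <- outcome_observation_probability(coh, spec_int)
  expect_equal(raw_int[j], 0.5 + 0.12 + (0.1 - 0.05) * coh$iq[j],
               tolerance = 1e-12)

  expect_error(outcome_observation_probability(coh,
               outcome_missingness_spec(0.2)), "alpha")
})

test_that("MAR calibration returns the exact-expectation intercept", {
  p <- cohort_params()
  a <- calibrate_alpha(p, outcome_missingness_spec(0.2), seed = 11,
                       n_calib = 2e5)
  # all predictions lie inside [0, 1], so no trial-and-improvement is needed
  # and alpha equals (1 - target) - E[gamma terms] = 0.8 - 0.14225
  expect_equal(as.numeric(a), 0.65775, tolerance = 1e-12)
  expect_false(attr(a, "adjusted"))
})

test_that("trial-and-improvement calibration hits the target despite truncation", {
  p <- cohort_params()
  for (case in list(list(target = 0.2, g7 = 0.2), list(target = 0.8, g7 = 0.1))) {
    spec <- outcome_missingness_spec(case$target, gamma7 = case$g7)
    a <- calibrate_alpha(p, spec, seed = 21, n_calib = 5e5)
    spec$alpha <- as.numeric(a)
    fresh <- generate_cohort(cohort_params(n = 100000), seed = 31)
    fresh <- apply_outcome_missingness(fresh, spec, seed = 32)
    expect_lt(abs(mean(!fresh$iq_observed) - case$target), 0.01)
  }
  # the 80%-missing case genuinely needs adjustment (negative predictions)
  spec80 <- outcome_missingness_spec(0.8, gamma7 = 0.1)
  a80 <- calibrate_alpha(p, spec80, seed = 21, n_calib = 5e5)
  expect_true(attr(a80, "adjusted"))
})

test_that("negative predictions force missingness; predictions above 1 force observation", {
  p <- cohort_params(n = 50000)
  coh <- generate_cohort(p, seed = 5)

  spec <- flat_outcome_spec(0.1, target = 0.8, gamma7 = 0.3)
  coh2 <- apply_outcome_missingness(coh, spec, seed = 6)
  raw <- coh2$pr_iq_obs
  expect_gt(sum(raw < 0), 0)
  expect_gt(sum(raw > 1), 0)
  expect_true(all(!coh2$iq_observed[raw < 0]))
  expect_true(all(coh2$iq_observed[raw > 1]))
  expect_equal(attr(coh2, "n_negative"), sum(raw < 0))

  # with non-negative covariate terms, raw < 0 implies iq < -alpha / gamma7
  spec_m <- outcome_missingness_spec(0.8, gamma7 = 0.1, alpha = 0.05)
  coh3 <- apply_outcome_missingness(coh, spec_m, seed = 7)
  neg <- coh3$pr_iq_obs < 0
  expect_true(all(coh3$iq[neg] < -0.05 / 0.1))
})

test_that("MAR missingness is independent of the outcome within covariate cells", {
  p <- cohort_params(n = 200000)
  spec <- outcome_missingness_spec(0.4)
  spec$alpha <- as.numeric(calibrate_alpha(p, spec, seed = 41, n_calib = 2e5))
  coh <- apply_outcome_missingness(generate_cohort(p, seed = 42), spec, seed = 43)
  cell <- interaction(coh$sex, coh$mumed, coh$bf)
  for (cl in levels(cell)) {
    idx <- cell == cl
    d_obs <- coh$iq[idx & coh$iq_observed]
    d_mis <- coh$iq[idx & !coh$iq_observed]
    se <- sqrt(var(coh$iq[idx]) * (1 / length(d_obs) + 1 / length(d_mis)))
    expect_lt(abs(mean(d_obs) - mean(d_mis)), 5 * se)
  }
})

test_that("MNAR missingness selects on the outcome", {
  p <- cohort_params(n = 100000)
  spec <- outcome_missingness_spec(0.4, gamma7 = 0.1)
  spec$alpha <- as.numeric(calibrate_alpha(p, spec, seed = 51, n_calib = 2e5))
  coh <- apply_outcome_missingness(generate_cohort(p, seed = 52), spec, seed = 53)
  # higher outcome, more likely observed: observed mean exceeds overall mean
  expect_gt(mean(coh$iq[coh$iq_observed]), mean(coh$iq) + 0.02)
})

test_that("proxy missingness has the stated rate and direction", {
  p <- cohort_params(n = 100000)
  coh <- generate_cohort(p, seed = 61)

  mcar <- apply_proxy_missingness(coh, proxy_missingness_spec(0.8, 0), seed = 62)
  expect_lt(abs(mean(!mcar$ks4_observed) - 0.2), 0.01)

  up <- apply_proxy_missingness(coh, proxy_missingness_spec(0.8, 0.10), seed = 63)
  expect_lt(abs(mean(!up$ks4_observed) - 0.2), 0.01)   # E[KS4] = 0 keeps the rate
  lo_q <- coh$ks4 < quantile(coh$ks4, 0.25)
  expect_gt(mean(!up$ks4_observed[lo_q]), mean(!up$ks4_observed[!lo_q]))

  dn <- apply_proxy_missingness(coh, proxy_missingness_spec(0.8, -0.10), seed = 64)
  expect_lt(mean(!dn$ks4_observed[lo_q]), mean(!dn$ks4_observed[!lo_q]))

  # pi = 1, delta = 0 leaves the proxy complete
  full <- apply_proxy_missingness(coh, proxy_missingness_spec(1, 0), seed = 65)
  expect_true(all(full$ks4_observed))
})
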