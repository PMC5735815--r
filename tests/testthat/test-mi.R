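test_that("Rubin pooling reproduces the hand-computed example and identities", {
  pooled <- pool_rubin(estimates = c(0.1, 0.3), variances = c(0.01, 0.01))
  expect_equal(pooled$estimate, 0.2)
  expect_equal(pooled$W, 0.01)
  expect_equal(pooled$B, 0.02)
  expect_equal(pooled$T, 0.04)

  # identities hold to machine precision on arbitrary inputs
  set.seed(1)
  for (rep in 1:5) {
    M <- sample(3:40, 1)
    est <- matrix(rnorm(M * 3), M, 3, dimnames = list(NULL, c("a", "b", "c")))
    vr <- matrix(rexp(M * 3), M, 3)
    p <- pool_rubin(est, vr)
    expect_equal(p$T, p$W + (1 + 1 / M) * p$B, tolerance = 1e-14)
    expect_equal(p$r, (1 + 1 / M) * p$B / p$W, tolerance = 1e-14)
    expect_equal(p$df, (M - 1) * (1 + 1 / p$r)^2, tolerance = 1e-12)
    expect_equal(p$fmi, (p$r + 2 / (p$df + 3)) / (p$r + 1), tolerance = 1e-14)
    expect_true(all(p$fmi >= 0 & p$fmi <= 1))
    expect_true(all(p$B >= 0))
  }

  # degenerate case: identical estimates have no between variance
  pd <- pool_rubin(rep(0.5, 10), rep(0.02, 10))
  expect_equal(pd$B, 0)
  expect_equal(pd$T, pd$W)
  expect_equal(pd$fmi, 0)

  # FMI increases when between-imputation variance grows at fixed W
  base_est <- seq(-1, 1, length.out = 10)
  f1 <- pool_rubin(0.1 * base_est, rep(0.05, 10))$fmi
  f2 <- pool_rubin(0.2 * base_est, rep(0.05, 10))$fmi
  expect_gt(f2, f1)

  expect_error(pool_rubin(0.3, 0.01), "M >= 2")
})

test_that("proper draw handles edge cases and flags singular designs", {
  set.seed(2)
  X <- cbind(1, rnorm(50))
  y <- rnorm(50)
  expect_identical(proper_normal_linear_draw(X, y), y)  # nothing missing

  colnames(X) <- c("(Intercept)", "x1")
  Xs <- cbind(X, x1_copy = X[, 2])
  ys <- y; ys[1:5] <- NA
  expect_error(proper_normal_linear_draw(Xs, ys), "x1_copy")

  expect_error(proper_normal_linear_draw(X[1:3, ], c(NA, 1, 2)),
               "complete cases")
})

test_that("repeated proper imputation recovers the proxy-outcome slope", {
  # delete half the outcome completely at random; a univariate normal-linear
  # imputation from the proxy must recover the iq-on-ks4 slope, which equals
  # rho because both variables are standardized
  p <- cohort_params(n = 8000, rho = 0.7)
  coh <- generate_cohort(p, seed = 71)
  set.seed(72)
  y <- coh$iq
  y[sample(8000, 4000)] <- NA
  X <- cbind("(Intercept)" = 1, ks4 = coh$ks4)

  M <- 30
  est <- se <- numeric(M)
  for (m in 1:M) {
    y_imp <- proper_normal_linear_draw(X, y, seed = 100 + m)
    f <- lm(y_imp ~ coh$ks4)
    est[m] <- coef(f)[2]
    se[m] <- sqrt(diag(vcov(f)))[2]
  }
  pooled <- pool_rubin(est, se^2)
  expect_lt(abs(pooled$estimate - 0.7), 4 * pooled$se)
})

test_that("chained imputation with a single incomplete variable matches a direct proper draw", {
  p <- cohort_params(n = 4000, rho = 0.7)
  spec <- outcome_missingness_spec(0.4, gamma7 = 0.1, alpha = 0.46)
  coh <- apply_outcome_missingness(generate_cohort(p, seed = 81), spec, seed = 82)
  mis <- !coh$iq_observed

  imp <- chained_impute(coh, M = 8, cycles = 3, seed = 83)
  chained_vals <- unlist(lapply(1:8, function(m) imp$imputations[[m]]$iq))

  # oracle: the same imputations drawn directly from the univariate model
  X <- cbind(1, coh$sex, coh$mumed == 1, coh$mumed == 2,
             coh$bf == 1, coh$bf == 2, coh$bf == 3, coh$ks4)
  storage.mode(X) <- "double"
  y <- ifelse(mis, NA, coh$iq)
  set.seed(84)
  direct_vals <- unlist(lapply(1:8, function(m) {
    proper_normal_linear_draw(X, y)[mis]
  }))

  ks <- suppressWarnings(ks.test(chained_vals, direct_vals))
  expect_gt(ks$p.value, 0.01)
  # and both distributions centre near the observed-data conditional mean
  expect_lt(abs(mean(chained_vals) - mean(direct_vals)), 0.1)
})

test_that("completed datasets only vary where values were missing", {
  p <- cohort_params(n = 2000, rho = 0.5)
  spec <- outcome_missingness_spec(0.4, gamma7 = 0.1, alpha = 0.46)
  coh <- apply_outcome_missingness(generate_cohort(p, seed = 91), spec, seed = 92)
  coh <- apply_proxy_missingness(coh, proxy_missingness_spec(0.8, -0.1), seed = 93)

  imp <- chained_impute(coh, M = 3, cycles = 5, seed = 94)
  expect_setequal(imp$incomplete, c("iq", "ks4"))
  d1 <- complete_data(imp, 1)
  d2 <- complete_data(imp, 2)
  expect_false(any(is.na(d1$iq)) || any(is.na(d1$ks4)))
  expect_identical(d1$iq[coh$iq_observed], coh$iq[coh$iq_observed])
  expect_identical(d2$iq[coh$iq_observed], coh$iq[coh$iq_observed])
  expect_identical(d1$ks4[coh$ks4_observed], d2$ks4[coh$ks4_observed])
  expect_false(all(d1$iq[!coh$iq_observed] == d2$iq[!coh$iq_observed]))

  # substreams: re-running with the same seed reproduces every imputation
  imp2 <- chained_impute(coh, M = 3, cycles = 5, seed = 94)
  expect_identical(imp$imputations, imp2$imputations)
  # ...and imputation m is invariant to M (master seed spawns substreams)
  imp5 <- chained_impute(coh, M = 5, cycles = 5, seed = 94)
  expect_identical(imp5$imputations[1:3], imp$imputations)

  expect_error(chained_impute(coh, M = 1), "at least 2")
  expect_error(
    chained_impute(coh, M = 2,
                   models = list(imputation_model_spec("iq", "ks4"))),
    "ks4"
  )
  expect_error(imputation_model_spec("iq", c("sex", "iq")), "own predictor")
})
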