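#' Parameters of the synthetic cohort
#'
#' Defines the data-generating model for a birth-cohort-like dataset with a
#' standardized continuous outcome ("IQ"), a four-level breastfeeding-duration
#' exposure, two demographic covariates (child's sex, maternal education) and a
#' linked attainment-score proxy ("KS4") for the outcome.
#'
#' The outcome model is
#' \deqn{IQ = \beta_0 + \beta_1 sex + \beta_2 mumed_1 + \beta_3 mumed_2 +
#'   \beta_4 BF_1 + \beta_5 BF_2 + \beta_6 BF_3 + \varepsilon,}
#' with \eqn{\varepsilon \sim N(0, \sigma^2)} and \eqn{\sigma^2} solved so
#' that the outcome has variance exactly 1 (see
#' [solve_outcome_noise_variance()]). The proxy model is
#' \deqn{KS4 = \rho \, IQ + (\mathrm{covariate\ terms}) + \tau,}
#' with \eqn{\tau \sim N(0, \varphi^2)} solved so the proxy also has unit
#' variance; by default the covariate terms are zero so that
#' \eqn{\varphi^2 = 1 - \rho^2} and \eqn{\rho} is the outcome-proxy
#' correlation. Both variables live on the standard-deviation scale by design,
#' so results do not depend on the scale of any real-world instrument.
#'
#' Category codes: `sex` is 0 = male, 1 = female (so \eqn{\beta_1} is the
#' female-vs-male contrast); `mumed` is 0 = O-level or lower, 1 = A-level,
#' 2 = degree or higher; `bf` is 0 = never / under 1 month, 1 = 1 to <3
#' months, 2 = 3 to <6 months, 3 = 6+ months. Dummy variables `mumed1`,
#' `mumed2`, `bf1`, `bf2`, `bf3` are the corresponding indicators.
#'
#' @param n cohort size (default 10000).
#' @param beta numeric length-7 vector \eqn{(\beta_0, \ldots, \beta_6)} of
#'   outcome-model coefficients (intercept; sex; mumed1; mumed2; bf1; bf2;
#'   bf3). Defaults give the breastfeeding effects 0.1, 0.2, 0.3 used as
#'   truth throughout the simulation study.
#' @param mumed_probs length-3 probability vector over maternal-education
#'   categories; must sum to 1.
#' @param bf_probs_given_mumed 3 x 4 row-stochastic matrix: row `e` gives the
#'   breastfeeding-category probabilities for education level `e - 1`.
#' @param rho proxy-outcome regression coefficient in `[0, 1]`; with the
#'   default zero covariate effects this is also the outcome-proxy
#'   correlation.
#' @param proxy_cov_coeffs length-3 vector of direct effects of (sex, mumed1,
#'   mumed2) on the proxy, used by the sensitivity variant in which the
#'   attainment score depends on demographics as well as the outcome.
#'   Default all zero.
#' @return An object of class `cohort_params`.
#' @seealso [generate_cohort()], [enumerate_covariate_distribution()]
#' @examples
#' p <- cohort_params(n = 1000, rho = 0.9)
#' solve_outcome_noise_variance(p)
#' @export
cohort_params <- function(n = 10000,
                          beta = c(-0.4, -0.1, 0.4, 0.8, 0.1, 0.2, 0.3),
                          mumed_probs = c(0.5, 0.25, 0.25),
                          bf_probs_given_mumed = rbind(
                            c(0.50, 0.15, 0.15, 0.20),
                            c(0.30, 0.10, 0.20, 0.40),
                            c(0.15, 0.10, 0.15, 0.60)
                          ),
                          rho = 0.7,
                          proxy_cov_coeffs = c(0, 0, 0)) {
  if (length(n) != 1L || is.na(n) || n <= 0 || n != floor(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (length(beta) != 7L || anyNA(beta)) {
    stop("`beta` must be a length-7 numeric vector (beta0..beta6)", call. = FALSE)
  }
  .check_prob_vector(mumed_probs, 3L, "mumed_probs")
  bf_probs_given_mumed <- as.matrix(bf_probs_given_mumed)
  if (!all(dim(bf_probs_given_mumed) == c(3L, 4L))) {
    stop("`bf_probs_given_mumed` must be a 3 x 4 matrix", call. = FALSE)
  }
  for (e in 1:3) {
    .check_prob_vector(bf_probs_given_mumed[e, ], 4L,
                       sprintf("bf_probs_given_mumed[%d, ]", e))
  }
  if (length(rho) != 1L || is.na(rho) || rho < 0 || rho > 1) {
    stop("`rho` must be a single value in [0, 1]", call. = FALSE)
  }
  if (length(proxy_cov_coeffs) != 3L || anyNA(proxy_cov_coeffs)) {
    stop("`proxy_cov_coeffs` must be a length-3 numeric vector", call. = FALSE)
  }
  structure(
    list(
      n = as.integer(n),
      beta = as.numeric(beta),
      mumed_probs = as.numeric(mumed_probs),
      bf_probs_given_mumed = bf_probs_given_mumed,
      rho = as.numeric(rho),
      proxy_cov_coeffs = as.numeric(proxy_cov_coeffs)
    ),
    class = "cohort_params"
  )
}

.check_prob_vector <- function(p, len, name) {
  if (length(p) != len || anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop(sprintf("`%s` must be %d non-negative probabilities summing to 1",
                 name, len), call. = FALSE)
  }
  invisible(TRUE)
}

#' Exact joint distribution of the covariates
#'
#' Enumerates the 24-cell joint probability table over sex (2) x maternal
#' education (3) x breastfeeding duration (4). Sex is independent of the
#' education-by-breastfeeding block; breastfeeding depends on education
#' through the conditional rows of `bf_probs_given_mumed`. This table is the
#' exact-expectation oracle behind the noise-variance solvers and the
#' missingness-intercept calibration.
#'
#' @param params a [cohort_params()] object.
#' @return A data frame with columns `sex`, `mumed`, `bf`, `prob` (24 rows,
#'   probabilities summing to 1).
#' @examples
#' tab <- enumerate_covariate_distribution(cohort_params())
#' tapply(tab$prob, tab$bf, sum)  # marginal breastfeeding distribution
#' @export
enumerate_covariate_distribution <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  tab <- expand.grid(sex = 0:1, mumed = 0:2, bf = 0:3,
                     KEEP.OUT.ATTRS = FALSE)
  tab$prob <- 0.5 * params$mumed_probs[tab$mumed + 1L] *
    params$bf_probs_given_mumed[cbind(tab$mumed + 1L, tab$bf + 1L)]
  tab
}

# Linear predictor of the outcome model (including intercept) per table cell
# or per individual record; `d` needs columns sex, mumed, bf.
.outcome_linear_predictor <- function(d, beta) {
  beta[1] + beta[2] * d$sex +
    beta[3] * (d$mumed == 1L) + beta[4] * (d$mumed == 2L) +
    beta[5] * (d$bf == 1L) + beta[6] * (d$bf == 2L) + beta[7] * (d$bf == 3L)
}

# Direct covariate terms of the proxy model (sensitivity variant).
.proxy_cov_terms <- function(d, coeffs) {
  coeffs[1] * d$sex + coeffs[2] * (d$mumed == 1L) + coeffs[3] * (d$mumed == 2L)
}

#' Residual variance that standardizes the outcome
#'
#' Solves \eqn{\sigma^2 = 1 - Var(\mathrm{linear\ predictor})} exactly from
#' the enumerated covariate table, so the simulated outcome has variance
#' exactly 1 in expectation. With the default coefficients the linear
#' predictor has variance 0.16125 and \eqn{\sigma^2 = 0.83875}.
#'
#' @inheritParams enumerate_covariate_distribution
#' @return The residual variance \eqn{\sigma^2} (a single number).
#' @export
solve_outcome_noise_variance <- function(params) {
  tab <- enumerate_covariate_distribution(params)
  lp <- .outcome_linear_predictor(tab, params$beta)
  v <- sum(tab$prob * lp^2) - sum(tab$prob * lp)^2
  if (v > 1 + 1e-12) {
    stop(sprintf(paste0("linear predictor variance %.5f exceeds 1; ",
                        "the outcome cannot have unit variance"), v),
         call. = FALSE)
  }
  max(1 - v, 0)
}

#' Residual variance that standardizes the proxy
#'
#' Solves \eqn{\varphi^2 = 1 - Var(\rho\, IQ + \mathrm{covariate\ terms})}
#' so the proxy has variance exactly 1. With zero covariate effects this is
#' \eqn{1 - \rho^2}; otherwise the covariate variance and its covariance
#' with the outcome's linear predictor are obtained exactly from the
#' enumerated table (the outcome itself has unit variance by construction).
#'
#' @inheritParams enumerate_covariate_distribution
#' @return The residual variance \eqn{\varphi^2}.
#' @export
solve_proxy_noise_variance <- function(params) {
  tab <- enumerate_covariate_distribution(params)
  pc <- .proxy_cov_terms(tab, params$proxy_cov_coeffs)
  lp <- .outcome_linear_predictor(tab, params$beta)
  e_pc <- sum(tab$prob * pc)
  var_pc <- sum(tab$prob * pc^2) - e_pc^2
  cov_lp_pc <- sum(tab$prob * lp * pc) - sum(tab$prob * lp) * e_pc
  v <- params$rho^2 + var_pc + 2 * params$rho * cov_lp_pc
  if (v > 1 + 1e-12) {
    stop(sprintf(paste0("proxy linear predictor variance %.5f exceeds 1; ",
                        "the proxy cannot have unit variance"), v),
         call. = FALSE)
  }
  max(1 - v, 0)
}

#' Generate a complete synthetic cohort
#'
#' Draws covariates from their stated distributions by inverse-CDF on
#' uniforms (one seed stream determines the whole cohort), then the outcome
#' and proxy from their linear models with residual variances solved so both
#' have mean 0 and variance 1. When `proxy_cov_coeffs` is nonzero the proxy's
#' covariate contribution is centred at its exact expectation so the proxy
#' keeps mean 0.
#'
#' @inheritParams enumerate_covariate_distribution
#' @param seed optional integer; when supplied the generation is fully
#'   reproducible (same seed, same cohort).
#' @return A data frame of class `simulated_cohort` with columns `id`, `sex`,
#'   `mumed`, `bf`, `iq`, `ks4`, `iq_observed`, `ks4_observed` (flags start
#'   all `TRUE`) and attributes `sigma2`, `phi2` and `params`.
#' @examples
#' coh <- generate_cohort(cohort_params(n = 500), seed = 1)
#' cor(coh$iq, coh$ks4)
#' @export
generate_cohort <- function(params, seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n
  sigma2 <- solve_outcome_noise_variance(params)
  phi2 <- solve_proxy_noise_variance(params)

  sex <- as.integer(runif(n) < 0.5)
  mumed <- findInterval(runif(n), cumsum(params$mumed_probs)[1:2])
  bf_cum <- t(apply(params$bf_probs_given_mumed, 1, cumsum))
  u_bf <- runif(n)
  bf <- (u_bf > bf_cum[mumed + 1L, 1L]) + (u_bf > bf_cum[mumed + 1L, 2L]) +
    (u_bf > bf_cum[mumed + 1L, 3L])

  d <- data.frame(sex = sex, mumed = as.integer(mumed), bf = as.integer(bf))
  iq <- .outcome_linear_predictor(d, params$beta) +
    rnorm(n, 0, sqrt(sigma2))

  pc <- .proxy_cov_terms(d, params$proxy_cov_coeffs)
  tab <- enumerate_covariate_distribution(params)
  e_pc <- sum(tab$prob * .proxy_cov_terms(tab, params$proxy_cov_coeffs))
  ks4 <- params$rho * iq + (pc - e_pc) + rnorm(n, 0, sqrt(phi2))

  out <- data.frame(
    id = seq_len(n),
    sex = d$sex, mumed = d$mumed, bf = d$bf,
    iq = iq, ks4 = ks4,
    iq_observed = TRUE, ks4_observed = TRUE
  )
  class(out) <- c("simulated_cohort", "data.frame")
  attr(out, "sigma2") <- sigma2
  attr(out, "phi2") <- phi2
  attr(out, "params") <- params
  out
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated cohort: n = %d, outcome observed %d (%.1f%%), proxy observed %d (%.1f%%)\n",
    nrow(x), sum(x$iq_observed), 100 * mean(x$iq_observed),
    sum(x$ks4_observed), 100 * mean(x$ks4_observed)
  ))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
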