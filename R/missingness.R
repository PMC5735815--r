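#' Missingness mechanism for the outcome
#'
#' Specifies the linear-probability (identity-link binomial) model for the
#' probability that the outcome is observed:
#' \deqn{\Pr(IQ\ \mathrm{observed}) = \alpha + \gamma_1 sex + \gamma_2 mumed_1 +
#'   \gamma_3 mumed_2 + \gamma_4 BF_1 + \gamma_5 BF_2 + \gamma_6 BF_3 +
#'   \gamma_7 IQ + \gamma_8 BF_1 IQ + \gamma_9 BF_2 IQ + \gamma_{10} BF_3 IQ.}
#'
#' The covariate coefficients \eqn{\gamma_1, \ldots, \gamma_6} are fixed at
#' 0.04 (female vs male), 0.075 and 0.10 (A-level and degree vs O-level or
#' lower) and 0.08, 0.12, 0.14 (breastfeeding categories vs never).
#' \eqn{\gamma_7} is the MNAR strength: the change in observation
#' probability per SD of the outcome itself (0 gives MAR). When the
#' exposure-by-outcome interaction is active the interaction coefficients
#' scale linearly across breastfeeding groups: \eqn{\gamma_9 = 2\gamma_8},
#' \eqn{\gamma_{10} = 3\gamma_8} (with \eqn{\gamma_8 = -0.025} the outcome's
#' pull on observation weakens by 0.025 per consecutive group).
#'
#' Because the link is the identity, predictions can leave `[0, 1]`; see
#' [apply_outcome_missingness()] for how such predictions are handled and
#' [calibrate_alpha()] for how \eqn{\alpha} is tuned to hit a target
#' missingness fraction in spite of that.
#'
#' @param target_missing target fraction of missing outcome values, in (0, 1)
#'   (the study design uses 0.2, 0.4, 0.6, 0.8).
#' @param gamma7 MNAR strength per SD of the outcome (0, 0.05, 0.1 or 0.2 in
#'   the study design; 0 = MAR).
#' @param gamma8 interaction coefficient for the first breastfeeding group;
#'   `gamma9` and `gamma10` default to `2 * gamma8` and `3 * gamma8`.
#' @param alpha intercept on the probability scale; usually left `NULL` and
#'   set by [calibrate_alpha()].
#' @param gamma_cov the six fixed covariate coefficients
#'   \eqn{(\gamma_1, \ldots, \gamma_6)}.
#' @param gamma9,gamma10 override the proportional interaction defaults.
#' @return An object of class `outcome_missingness_spec`.
#' @export
outcome_missingness_spec <- function(target_missing,
                                     gamma7 = 0,
                                     gamma8 = 0,
                                     alpha = NULL,
                                     gamma_cov = c(0.04, 0.075, 0.10,
                                                   0.08, 0.12, 0.14),
                                     gamma9 = 2 * gamma8,
                                     gamma10 = 3 * gamma8) {
  if (length(target_missing) != 1L || is.na(target_missing) ||
      target_missing <= 0 || target_missing >= 1) {
    stop("`target_missing` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (length(gamma_cov) != 6L || anyNA(gamma_cov)) {
    stop("`gamma_cov` must be a length-6 numeric vector", call. = FALSE)
  }
  structure(
    list(
      target_missing = as.numeric(target_missing),
      gamma = c(as.numeric(gamma_cov), gamma7, gamma8, gamma9, gamma10),
      alpha = if (is.null(alpha)) NULL else as.numeric(alpha)
    ),
    class = "outcome_missingness_spec"
  )
}

#' Missingness mechanism for the linked proxy
#'
#' The proxy's observation probability depends only on the proxy itself:
#' \eqn{\Pr(KS4\ \mathrm{observed}) = \pi + \delta\, KS4}. The study design
#' fixes \eqn{\pi = 0.8} (20 percent missing proxy, since the proxy has mean
#' zero) and uses \eqn{\delta = -0.10} or \eqn{+0.10}; \eqn{\delta = 0} with
#' \eqn{\pi = 1} leaves the proxy complete.
#'
#' @param pi intercept on the probability scale (default 0.8).
#' @param delta change in observation probability per SD of the proxy.
#' @return An object of class `proxy_missingness_spec`.
#' @export
proxy_missingness_spec <- function(pi = 0.8, delta = 0) {
  if (length(pi) != 1L || is.na(pi) || pi < 0 || pi > 1) {
    stop("`pi` must be a single probability in [0, 1]", call. = FALSE)
  }
  if (length(delta) != 1L || !is.finite(delta)) {
    stop("`delta` must be a single finite number", call. = FALSE)
  }
  structure(list(pi = as.numeric(pi), delta = as.numeric(delta)),
            class = "proxy_missingness_spec")
}

#' Raw observation-probability predictions for the outcome
#'
#' Evaluates the linear-probability model on each individual and returns the
#' raw (un-truncated) predictions. Values below 0 or above 1 are returned as
#' is: truncation happens in [apply_outcome_missingness()], so that the
#' deterministic negative-prediction rule remains detectable.
#'
#' @param cohort a [generate_cohort()] data frame.
#' @param spec an [outcome_missingness_spec()] with `alpha` set.
#' @return Numeric vector of raw predictions, one per individual.
#' @export
outcome_observation_probability <- function(cohort, spec) {
  stopifnot(inherits(spec, "outcome_missingness_spec"))
  if (is.null(spec$alpha)) {
    stop("`spec$alpha` is not set; calibrate it first (see calibrate_alpha)",
         call. = FALSE)
  }
  spec$alpha + .observation_terms(cohort, spec$gamma)
}

# Non-intercept part of the outcome observation model. `gamma` is the full
# 10-vector (six covariate terms, gamma7, gamma8..gamma10).
.observation_terms <- function(d, gamma) {
  b1 <- d$bf == 1L
  b2 <- d$bf == 2L
  b3 <- d$bf == 3L
  gamma[1] * d$sex +
    gamma[2] * (d$mumed == 1L) + gamma[3] * (d$mumed == 2L) +
    gamma[4] * b1 + gamma[5] * b2 + gamma[6] * b3 +
    gamma[7] * d$iq +
    gamma[8] * b1 * d$iq + gamma[9] * b2 * d$iq + gamma[10] * b3 * d$iq
}

# Exact expectation of the non-intercept observation terms under the
# data-generating model: covariate terms from the 24-cell table; outcome
# terms use E[IQ] = 0 and E[BF_k IQ] = sum over cells with bf = k of
# prob * linear predictor (the noise is independent of the covariates).
.expected_observation_terms <- function(params, gamma) {
  tab <- enumerate_covariate_distribution(params)
  lp <- .outcome_linear_predictor(tab, params$beta)
  cov_part <- sum(tab$prob * .observation_terms(
    data.frame(sex = tab$sex, mumed = tab$mumed, bf = tab$bf, iq = 0),
    gamma
  ))
  e_bf_iq <- vapply(1:3, function(k) sum(tab$prob[tab$bf == k] * lp[tab$bf == k]),
                    numeric(1))
  cov_part + sum(gamma[8:10] * e_bf_iq)
}

#' Calibrate the missingness intercept to a target rate
#'
#' Solves for the intercept \eqn{\alpha} so the realized fraction of missing
#' outcome values matches `spec$target_missing`. The starting point is the
#' exact-expectation solution
#' \eqn{\alpha_0 = (1 - \mathrm{target}) - E[\mathrm{non\mbox{-}intercept\ terms}]},
#' computed from the enumerated covariate table and the outcome model. When
#' raw predictions fall outside `[0, 1]` (negative predictions force
#' missingness deterministically; predictions above 1 are truncated) the
#' identity-link expectation no longer equals the observation rate, and
#' \eqn{\alpha} is adjusted by trial and improvement: bisection against the
#' expected missing fraction
#' \eqn{1 - \mathrm{mean}\{\mathrm{clamp}(\alpha + \mathrm{terms}, 0, 1)\}}
#' on a large, independently seeded calibration cohort. That expectation is
#' the Rao-Blackwellized version of the realized Bernoulli rate, so the
#' calibration is deterministic given the calibration seed.
#'
#' @param params a [cohort_params()] object (the calibration cohort is drawn
#'   from the same data-generating model, with `n_calib` individuals).
#' @param spec an [outcome_missingness_spec()]; its `alpha` is ignored.
#' @param tol convergence tolerance on the missing fraction (default 0.002).
#' @param n_calib calibration cohort size (default 1e6, large enough that
#'   calibration error is negligible next to the study's Monte-Carlo error).
#' @param max_iter bisection iteration cap.
#' @param seed seed for the calibration cohort; keep this stream separate
#'   from the analysis replicates.
#' @return The calibrated intercept, with attributes `realized` (expected
#'   missing fraction at the returned alpha), `iterations` and `adjusted`
#'   (whether trial and improvement was needed beyond the exact start).
#' @export
calibrate_alpha <- function(params, spec, tol = 0.002, n_calib = 1e6,
                            max_iter = 80L, seed = 1L) {
  stopifnot(inherits(params, "cohort_params"),
            inherits(spec, "outcome_missingness_spec"))
  target <- spec$target_missing
  calib_params <- params
  calib_params$n <- as.integer(n_calib)
  coh <- generate_cohort(calib_params, seed = seed)
  terms <- .observation_terms(coh, spec$gamma)
  miss_at <- function(a) 1 - mean(pmin(pmax(a + terms, 0), 1))

  a0 <- (1 - target) - .expected_observation_terms(params, spec$gamma)
  f0 <- miss_at(a0)
  if (abs(f0 - target) <= tol) {
    return(structure(a0, realized = f0, iterations = 0L, adjusted = FALSE))
  }

  # miss_at is non-increasing in alpha; bracket the root then bisect
  lo <- a0; hi <- a0
  step <- 0.1
  for (i in 1:30) {
    if (miss_at(lo) < target) lo <- lo - step else break
  }
  for (i in 1:30) {
    if (miss_at(hi) > target) hi <- hi + step else break
  }
  if (miss_at(lo) < target || miss_at(hi) > target) {
    stop("calibration failed to bracket the target missing fraction",
         call. = FALSE)
  }
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    fm <- miss_at(mid)
    if (abs(fm - target) <= tol) {
      return(structure(mid, realized = fm, iterations = it, adjusted = TRUE))
    }
    if (it >= max_iter) {
      stop(sprintf(paste0("alpha calibration did not converge in %d ",
                          "iterations (target %.3f, best %.4f at alpha %.4f)"),
                   max_iter, target, fm, mid), call. = FALSE)
    }
    if (fm > target) lo <- mid else hi <- mid
  }
}

#' Impose missingness on the outcome
#'
#' Applies the linear-probability mechanism: individuals whose raw predicted
#' observation probability is negative are set to missing deterministically;
#' predictions above 1 are observed with certainty; otherwise a Bernoulli
#' draw with the predicted probability decides. The raw prediction is kept in
#' column `pr_iq_obs` and the count of negative predictions in attribute
#' `n_negative` (a key diagnostic for the most extreme scenarios, where the
#' deterministic rule makes the MNAR mechanism stronger than the linear
#' coefficients alone suggest).
#'
#' @inheritParams outcome_observation_probability
#' @param seed optional integer seed for the Bernoulli draws.
#' @return The cohort with `iq_observed` filled in, a `pr_iq_obs` column, and
#'   attribute `n_negative`.
#' @export
apply_outcome_missingness <- function(cohort, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  raw <- outcome_observation_probability(cohort, spec)
  p <- pmin(pmax(raw, 0), 1)
  cohort$iq_observed <- runif(nrow(cohort)) < p
  cohort$pr_iq_obs <- raw
  attr(cohort, "n_negative") <- sum(raw < 0)
  cohort
}

#' Impose missingness on the linked proxy
#'
#' Bernoulli draws with probability \eqn{\mathrm{clamp}(\pi + \delta KS4, 0, 1)}
#' per individual; missingness in the proxy depends only on the proxy itself.
#'
#' @inheritParams outcome_observation_probability
#' @param spec a [proxy_missingness_spec()].
#' @param seed optional integer seed.
#' @return The cohort with `ks4_observed` filled in.
#' @export
apply_proxy_missingness <- function(cohort, spec, seed = NULL) {
  stopifnot(inherits(spec, "proxy_missingness_spec"))
  if (!is.null(seed)) set.seed(seed)
  p <- pmin(pmax(spec$pi + spec$delta * cohort$ks4, 0), 1)
  cohort$ks4_observed <- runif(nrow(cohort)) < p
  cohort
}
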