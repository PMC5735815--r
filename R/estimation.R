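## Analysis-model fits (complete records, full data, multiple imputation)
## and the Monte-Carlo performance metrics computed over replicates.

.new_fit_result <- function(coef, se, n, method, extra = list()) {
  structure(
    c(list(coef = coef, se = se, n = n, method = method), extra),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Analysis-model fit (%s), n = %d\n", x$method, x$n))
  print(data.frame(estimate = x$coef, se = x$se))
  invisible(x)
}

# OLS of the outcome on the analysis design over the given rows.
.fit_analysis_model <- function(cohort, rows, method) {
  X <- .analysis_model_matrix(cohort)[rows, , drop = FALSE]
  y <- cohort$iq[rows]
  fit <- .ols_fit(X, y)
  .new_fit_result(setNames(fit$coef, fit$terms),
                  setNames(.ols_se(fit), fit$terms),
                  fit$n, method)
}

#' Complete-records analysis
#'
#' Fits the analysis model — outcome on sex, maternal-education and
#' breastfeeding indicators — by OLS restricted to individuals with the
#' outcome observed. The linked proxy never enters the analysis model (it is
#' an auxiliary variable only), so proxy missingness does not change the
#' complete-records estimate.
#'
#' @param cohort a cohort data frame with `iq_observed` set.
#' @return A `fit_result` with coefficient estimates, standard errors, the
#'   number of records used and method tag `"complete_records"`.
#' @export
fit_complete_records <- function(cohort) {
  .fit_analysis_model(cohort, cohort$iq_observed, "complete_records")
}

#' Full-data analysis (benchmark)
#'
#' The analysis model fitted to every record, ignoring observation flags.
#' Only meaningful on a cohort before missingness is imposed; used as the
#' benchmark the missing-data methods are compared against.
#'
#' @inheritParams fit_complete_records
#' @return A `fit_result` with method tag `"full_data"`.
#' @export
fit_full_data <- function(cohort) {
  .fit_analysis_model(cohort, rep(TRUE, nrow(cohort)), "full_data")
}

#' Multiple-imputation analysis
#'
#' Runs [chained_impute()] on the cohort, fits the analysis model to each
#' completed dataset, and pools with [pool_rubin()]. The imputation models
#' carry the linked proxy as an auxiliary variable; the analysis model does
#' not contain it.
#'
#' @inheritParams fit_complete_records
#' @param M number of imputations (study default 100).
#' @param cycles chained-equation sweeps per imputation.
#' @param seed optional master seed for the imputation streams.
#' @param models optional model overrides passed to [chained_impute()].
#' @return A `fit_result` with method tag `"mi"`, plus elements `fmi` (per
#'   analysis coefficient) and `pooled` (the full [pool_rubin()] table).
#' @export
fit_mi <- function(cohort, M = 100L, cycles = 10L, seed = NULL,
                   models = NULL) {
  any_missing <- !all(cohort$iq_observed) || !all(cohort$ks4_observed)
  if (!any_missing) {
    # nothing to impute: every completed copy is the data itself
    full <- fit_full_data(cohort)
    pooled <- pool_rubin(
      matrix(rep(full$coef, 2), nrow = 2, byrow = TRUE,
             dimnames = list(NULL, names(full$coef))),
      matrix(rep(full$se^2, 2), nrow = 2, byrow = TRUE)
    )
    return(.new_fit_result(full$coef, full$se, full$n, "mi",
                           list(fmi = setNames(pooled$fmi, pooled$term),
                                pooled = pooled, M = M)))
  }
  imp <- chained_impute(cohort, M = M, cycles = cycles, seed = seed,
                        models = models)
  est <- matrix(NA_real_, nrow = M, ncol = 7L)
  vr <- matrix(NA_real_, nrow = M, ncol = 7L)
  for (m in seq_len(M)) {
    f <- fit_full_data(complete_data(imp, m))
    est[m, ] <- f$coef
    vr[m, ] <- f$se^2
    if (m == 1L) colnames(est) <- colnames(vr) <- names(f$coef)
  }
  pooled <- pool_rubin(est, vr)
  .new_fit_result(setNames(pooled$estimate, pooled$term),
                  setNames(pooled$se, pooled$term),
                  nrow(cohort), "mi",
                  list(fmi = setNames(pooled$fmi, pooled$term),
                       pooled = pooled, M = M))
}

#' Monte-Carlo performance summary over replicates
#'
#' Aggregates replicate-level point estimates (and, for MI, per-replicate
#' fractions of missing information) into the study's performance metrics,
#' per coefficient and method:
#' bias = mean estimate minus truth; percent bias = 100 bias / truth;
#' empirical SE = standard deviation of the point estimates; MSE = mean
#' squared deviation from truth; and, for MI, the percent gain in precision
#' over complete records, 100 (Var_CR / Var_MI - 1), from the
#' replicate-level point-estimate variances, plus the mean FMI in percent.
#'
#' @param replicates long-format data frame with columns `method`
#'   (`"complete_records"` / `"mi"`), `replicate`, `coefficient`, `estimate`
#'   and optionally `fmi` (fractions).
#' @param truth named numeric vector of true coefficient values, e.g.
#'   `c(bf1 = 0.1, bf2 = 0.2, bf3 = 0.3)`.
#' @return A data frame with one row per coefficient x method:
#'   `coefficient`, `method`, `n_reps`, `mean_estimate`, `bias`,
#'   `percent_bias`, `empirical_se`, `mse`, `precision_gain` (MI rows only),
#'   `mean_fmi` (percent, MI rows only).
#' @export
summarize_replications <- function(replicates, truth) {
  needed <- c("method", "replicate", "coefficient", "estimate")
  if (!all(needed %in% names(replicates))) {
    stop(sprintf("`replicates` must contain columns: %s",
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  replicates <- replicates[replicates$coefficient %in% names(truth), ,
                           drop = FALSE]
  methods <- unique(replicates$method)
  counts <- table(replicates$method, replicates$coefficient)
  if (length(unique(as.vector(counts))) != 1L) {
    stop("mismatched replicate counts across methods/coefficients",
         call. = FALSE)
  }
  if (counts[1] < 2L) stop("need at least 2 replicates", call. = FALSE)

  cr_var <- NULL
  if ("complete_records" %in% methods) {
    cr <- replicates[replicates$method == "complete_records", ]
    cr_var <- tapply(cr$estimate, cr$coefficient, var)
  }
  rows <- list()
  for (method in methods) {
    sub <- replicates[replicates$method == method, ]
    for (cf in names(truth)) {
      e <- sub$estimate[sub$coefficient == cf]
      b <- mean(e) - truth[[cf]]
      gain <- NA_real_
      if (method == "mi" && !is.null(cr_var)) {
        gain <- 100 * (cr_var[[cf]] / var(e) - 1)
      }
      fmi <- NA_real_
      if (method == "mi" && "fmi" %in% names(sub)) {
        fmi <- 100 * mean(sub$fmi[sub$coefficient == cf])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        coefficient = cf, method = method, n_reps = length(e),
        mean_estimate = mean(e), bias = b,
        percent_bias = 100 * b / truth[[cf]],
        empirical_se = stats::sd(e),
        mse = mean((e - truth[[cf]])^2),
        precision_gain = gain, mean_fmi = fmi
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
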