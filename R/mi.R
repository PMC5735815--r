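## Chained-equations multiple imputation with proper normal-linear draws and
## Rubin's-rules pooling, written directly against the linear algebra (no
## imputation package behind it).

# Cholesky-based OLS. X must include the intercept column. Returns the pieces
# the posterior draw needs: coefficients, chol(X'X), residual sum of squares
# and residual df.
.ols_fit <- function(X, y) {
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 1L) {
    stop(sprintf("need at least %d complete cases to fit %d coefficients",
                 p + 1L, p), call. = FALSE)
  }
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (!is.null(R) && min(diag(R)) < 1e-6 * max(diag(R))) {
    R <- NULL  # numerically singular despite a completed factorization
  }
  if (is.null(R)) {
    q <- qr(X)
    bad <- colnames(X)[q$pivot[seq.int(q$rank + 1L, p)]]
    stop(sprintf("singular design; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  coef <- backsolve(R, backsolve(R, crossprod(X, y), transpose = TRUE))
  res <- y - drop(X %*% coef)
  rss <- sum(res^2)
  df <- n - p
  list(coef = drop(coef), R = R, rss = rss, df = df, n = n, p = p,
       sigma2 = rss / df,
       terms = colnames(X))
}

# Coefficient standard errors from an .ols_fit object.
.ols_se <- function(fit) {
  sqrt(diag(chol2inv(fit$R)) * fit$sigma2)
}

# One proper draw from the Bayesian linear-model posterior, plus imputation
# of X_mis rows: sigma2* ~ rss / chisq(df); beta* ~ N(beta_hat,
# sigma2* (X'X)^-1); y_mis = X_mis beta* + N(0, sigma2*).
.proper_draw_from_fit <- function(fit, X_mis) {
  sigma2_star <- fit$rss / rchisq(1L, fit$df)
  beta_star <- fit$coef +
    backsolve(fit$R, rnorm(fit$p)) * sqrt(sigma2_star)
  drop(X_mis %*% beta_star) + rnorm(nrow(X_mis), 0, sqrt(sigma2_star))
}

#' Proper normal-linear imputation draw
#'
#' Imputes the missing entries of `y` from a Bayesian linear regression of
#' the observed entries on `X`: the residual variance is drawn from its
#' scaled inverse-chi-square posterior (df = number of observed cases minus
#' number of coefficients), the coefficients from a multivariate normal
#' around the OLS fit with covariance scaled by the drawn variance, and each
#' missing value as the drawn linear predictor plus fresh normal noise.
#' Drawing the parameters, not just the noise, is what makes the imputation
#' "proper": between-imputation variance then reflects estimation
#' uncertainty, which Rubin's rules require.
#'
#' @param X numeric design matrix (including an intercept column) for all
#'   rows, observed and missing alike.
#' @param y numeric response with `NA` at the cells to impute.
#' @param seed optional integer seed; otherwise the current RNG stream is
#'   used.
#' @return `y` with the missing entries replaced by imputed values.
#' @export
proper_normal_linear_draw <- function(X, y, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) {
    stop("`X` and `y` must have the same number of rows", call. = FALSE)
  }
  mis <- is.na(y)
  if (!any(mis)) return(y)
  fit <- .ols_fit(X[!mis, , drop = FALSE], y[!mis])
  y[mis] <- .proper_draw_from_fit(fit, X[mis, , drop = FALSE])
  y
}

#' Specify one conditional imputation model
#'
#' @param target name of the incomplete variable (`"iq"` or `"ks4"`).
#' @param predictors character vector of predictor column names in the
#'   dummy-expanded cohort matrix; defaults (set inside [chained_impute()])
#'   follow the study design: every analysis-model variable plus the other
#'   linked variable.
#' @return An object of class `imputation_model_spec`.
#' @export
imputation_model_spec <- function(target, predictors) {
  if (target %in% predictors) {
    stop("the target variable cannot be its own predictor", call. = FALSE)
  }
  structure(list(target = target, predictors = predictors),
            class = "imputation_model_spec")
}

# Dummy-expanded covariate matrix shared by every model in this study:
# intercept, sex, two maternal-education indicators, three breastfeeding
# indicators.
.analysis_model_matrix <- function(d) {
  cbind(
    "(Intercept)" = rep(1, nrow(d)),
    sex = d$sex,
    mumed1 = as.numeric(d$mumed == 1L),
    mumed2 = as.numeric(d$mumed == 2L),
    bf1 = as.numeric(d$bf == 1L),
    bf2 = as.numeric(d$bf == 2L),
    bf3 = as.numeric(d$bf == 3L)
  )
}

#' Multiple imputation by chained equations
#'
#' Creates `M` completed copies of a cohort with missing outcome and/or
#' proxy values. Each incomplete variable is initialized by random draws from
#' its observed values, then re-imputed for `cycles` sweeps in visit order,
#' each time by a [proper_normal_linear_draw()] from its conditional model
#' given the current completed data. By default the conditional model for
#' each incomplete variable contains every analysis-model variable (sex,
#' maternal-education and breastfeeding indicators) plus the other linked
#' variable, mirroring an imputation model that carries the proxy as an
#' auxiliary variable.
#'
#' When only one variable is incomplete the chain is monotone: the fit
#' behind each draw never changes, every cycle's draw is from the same
#' posterior, and the result is distributionally identical to a single
#' proper draw (the package exploits this by caching the regression fit, and
#' tests exploit it as an oracle).
#'
#' @param cohort a cohort data frame with `iq_observed` / `ks4_observed`
#'   flags (see [apply_outcome_missingness()]).
#' @param M number of imputations (study default 100).
#' @param cycles chained-equation sweeps per imputation (default 10).
#' @param seed optional master seed; each imputation m runs on an
#'   independent substream derived from it, so changing `M` never reshuffles
#'   earlier imputations.
#' @param models optional list of [imputation_model_spec()]s overriding the
#'   defaults; visit order is list order.
#' @return An object of class `imputed_datasets`: the original cohort plus
#'   the imputed values for each copy. Extract copies with [complete_data()].
#' @export
chained_impute <- function(cohort, M = 100L, cycles = 10L, seed = NULL,
                           models = NULL) {
  if (M < 2L) stop("`M` must be at least 2", call. = FALSE)
  if (cycles < 1L) stop("`cycles` must be at least 1", call. = FALSE)

  base <- .analysis_model_matrix(cohort)
  vals <- list(iq = cohort$iq, ks4 = cohort$ks4)
  mis <- list(iq = !cohort$iq_observed, ks4 = !cohort$ks4_observed)
  incomplete <- names(mis)[vapply(mis, any, logical(1))]

  if (is.null(models)) {
    models <- lapply(incomplete, function(v) {
      other <- setdiff(c("iq", "ks4"), v)
      imputation_model_spec(v, c(colnames(base)[-1L], other))
    })
  } else {
    stopifnot(all(vapply(models, inherits, logical(1), "imputation_model_spec")))
    covered <- vapply(models, `[[`, character(1), "target")
    if (!all(incomplete %in% covered)) {
      stop(sprintf("no imputation model for incomplete variable(s): %s",
                   paste(setdiff(incomplete, covered), collapse = ", ")),
           call. = FALSE)
    }
  }
  targets <- vapply(models, `[[`, character(1), "target")

  # design builder for one model given current completed values
  build_X <- function(spec, cur) {
    extra <- intersect(spec$predictors, c("iq", "ks4"))
    cbind(base[, c("(Intercept)",
                   intersect(spec$predictors, colnames(base))), drop = FALSE],
          if (length(extra)) {
            m <- do.call(cbind, cur[extra])
            colnames(m) <- extra
            m
          })
  }

  # A model's fit is constant across cycles/imputations when none of its
  # predictors is itself incomplete (then the observed rows and their
  # predictor values never change). Cache those fits.
  static_fit <- vector("list", length(models))
  names(static_fit) <- targets
  for (i in seq_along(models)) {
    spec <- models[[i]]
    dyn <- intersect(spec$predictors, incomplete)
    if (length(dyn) == 0L) {
      X <- build_X(spec, vals)
      obs <- !mis[[spec$target]]
      static_fit[[i]] <- list(
        fit = .ols_fit(X[obs, , drop = FALSE], vals[[spec$target]][obs]),
        X_mis = X[mis[[spec$target]], , drop = FALSE]
      )
    }
  }

  imputations <- vector("list", M)
  for (m in seq_len(M)) {
    if (!is.null(seed)) set.seed(derive_seed(seed, "imp", m))
    cur <- vals
    for (v in incomplete) {           # initial fill: draws from observed values
      obs_vals <- vals[[v]][!mis[[v]]]
      cur[[v]][mis[[v]]] <- sample(obs_vals, sum(mis[[v]]), replace = TRUE)
    }
    for (cy in seq_len(cycles)) {
      for (i in seq_along(models)) {
        spec <- models[[i]]
        v <- spec$target
        if (!any(mis[[v]])) next
        if (!is.null(static_fit[[i]])) {
          cur[[v]][mis[[v]]] <- .proper_draw_from_fit(
            static_fit[[i]]$fit, static_fit[[i]]$X_mis)
        } else {
          X <- build_X(spec, cur)
          fit <- .ols_fit(X[!mis[[v]], , drop = FALSE], vals[[v]][!mis[[v]]])
          cur[[v]][mis[[v]]] <- .proper_draw_from_fit(
            fit, X[mis[[v]], , drop = FALSE])
        }
      }
    }
    imputations[[m]] <- lapply(incomplete, function(v) cur[[v]][mis[[v]]])
    names(imputations[[m]]) <- incomplete
  }

  structure(
    list(cohort = cohort, M = as.integer(M), cycles = as.integer(cycles),
         incomplete = incomplete, missing_index = mis,
         imputations = imputations),
    class = "imputed_datasets"
  )
}

#' Extract one completed dataset
#'
#' @param imp an [chained_impute()] result.
#' @param m which imputation, in `1:M`.
#' @return The cohort data frame with the m-th imputation's values filled
#'   into the originally missing cells; observed cells are identical across
#'   copies.
#' @export
complete_data <- function(imp, m) {
  stopifnot(inherits(imp, "imputed_datasets"), m >= 1L, m <= imp$M)
  d <- imp$cohort
  for (v in imp$incomplete) {
    d[[v]][imp$missing_index[[v]]] <- imp$imputations[[m]][[v]]
  }
  d
}

#' @export
print.imputed_datasets <- function(x, ...) {
  cat(sprintf("Chained-equations imputation: M = %d, cycles = %d\n",
              x$M, x$cycles))
  for (v in x$incomplete) {
    cat(sprintf("  %s: %d of %d cells imputed\n", v,
                sum(x$missing_index[[v]]), nrow(x$cohort)))
  }
  invisible(x)
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' Combines M per-imputation coefficient estimates and their squared
#' standard errors: pooled estimate \eqn{\bar Q} = mean of the estimates;
#' within-imputation variance W = mean of the variances; between-imputation
#' variance B = sample variance of the estimates; total variance
#' \eqn{T = W + (1 + 1/M) B}. The relative variance increase is
#' \eqn{r = (1 + 1/M) B / W}, the small-sample degrees of freedom
#' \eqn{\nu = (M - 1)(1 + 1/r)^2}, and the fraction of missing information
#' \eqn{FMI = (r + 2/(\nu + 3)) / (r + 1)} (the df-adjusted form matching
#' standard MI software; the large-sample \eqn{\lambda = (1 + 1/M) B / T}
#' is also returned for comparison).
#'
#' @param estimates M x p matrix (or length-M vector) of per-imputation
#'   point estimates.
#' @param variances matching matrix/vector of per-imputation squared
#'   standard errors.
#' @return A data frame of class `pooled_estimate` with one row per
#'   coefficient: `term`, `estimate`, `W`, `B`, `T`, `se`, `r`, `df`, `fmi`,
#'   `lambda`.
#' @examples
#' pool_rubin(estimates = c(0.1, 0.3), variances = c(0.01, 0.01))
#' @export
pool_rubin <- function(estimates, variances) {
  estimates <- as.matrix(estimates)
  variances <- as.matrix(variances)
  M <- nrow(estimates)
  if (M < 2L) stop("Rubin's rules need M >= 2", call. = FALSE)
  if (!all(dim(estimates) == dim(variances))) {
    stop("`estimates` and `variances` must have matching dimensions",
         call. = FALSE)
  }
  qbar <- colMeans(estimates)
  W <- colMeans(variances)
  B <- apply(estimates, 2L, var)
  Tv <- W + (1 + 1 / M) * B
  r <- (1 + 1 / M) * B / W
  nu <- ifelse(r > 0, (M - 1) * (1 + 1 / r)^2, Inf)
  fmi <- ifelse(r > 0, (r + 2 / (nu + 3)) / (r + 1), 0)
  lambda <- (1 + 1 / M) * B / Tv
  out <- data.frame(
    term = colnames(estimates) %||% paste0("q", seq_along(qbar)),
    estimate = qbar, W = W, B = B, T = Tv, se = sqrt(Tv),
    r = r, df = nu, fmi = fmi, lambda = lambda,
    row.names = NULL
  )
  class(out) <- c("pooled_estimate", "data.frame")
  attr(out, "M") <- M
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
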