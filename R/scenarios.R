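## The factorial scenario grid and the Monte-Carlo driver.

#' True values of the exposure coefficients
#'
#' The breastfeeding effects the simulation study estimates and compares
#' against: 0.1, 0.2, 0.3 for the three non-baseline duration categories.
#' @return Named numeric vector `c(bf1 = 0.1, bf2 = 0.2, bf3 = 0.3)`.
#' @export
true_exposure_effects <- function() c(bf1 = 0.1, bf2 = 0.2, bf3 = 0.3)

.scenario_id <- function(miss, rho, gamma7, interaction, proxy_delta) {
  px <- if (is.na(proxy_delta)) "None" else if (proxy_delta < 0) "Neg" else "Pos"
  sprintf("m%02d_r%03d_g%03d_int%s_px%s",
          round(100 * miss), round(100 * rho), round(100 * gamma7),
          if (interaction) "Y" else "N", px)
}

#' Build the full factorial scenario grid
#'
#' Enumerates the 100 study scenarios. The main set (64) crosses four
#' missing-outcome fractions (0.2, 0.4, 0.6, 0.8) with the MNAR strength
#' and outcome-proxy correlation: one MAR cell (gamma7 = 0, correlation
#' fixed at 0.7) plus three MNAR strengths (0.05, 0.1, 0.2) at five
#' correlations (0.1 to 0.9). The secondary sets (36) keep gamma7 = 0.1 and
#' add (a) the exposure-by-outcome interaction in the missingness model
#' (gamma8 = -0.025) at all five correlations (20 scenarios), and (b) 20%
#' MNAR missingness in the proxy itself (delta = -0.1 or +0.1) at
#' correlations 0.5 and 0.7 (16 scenarios).
#'
#' @return A data frame with one row per scenario: `scenario_id`, `set`
#'   (`"main"`, `"interaction"`, `"proxy"`), `missing_fraction`, `rho`,
#'   `gamma7`, `interaction`, `gamma8`, `proxy_delta` (`NA` = complete
#'   proxy).
#' @examples
#' g <- build_scenario_grid()
#' nrow(g)            # 100
#' table(g$set)       # 64 / 20 / 16
#' @export
build_scenario_grid <- function() {
  miss_levels <- c(0.2, 0.4, 0.6, 0.8)
  rho_levels <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  rows <- list()
  add <- function(set, miss, rho, gamma7, interaction, proxy_delta) {
    gamma8 <- if (interaction) -0.025 else 0
    rows[[length(rows) + 1L]] <<- data.frame(
      scenario_id = .scenario_id(miss, rho, gamma7, interaction, proxy_delta),
      set = set, missing_fraction = miss, rho = rho, gamma7 = gamma7,
      interaction = interaction, gamma8 = gamma8, proxy_delta = proxy_delta
    )
  }
  for (miss in miss_levels) {
    add("main", miss, 0.7, 0, FALSE, NA)              # MAR, correlation 0.7
    for (g7 in c(0.05, 0.1, 0.2)) {
      for (rho in rho_levels) add("main", miss, rho, g7, FALSE, NA)
    }
    for (rho in rho_levels) add("interaction", miss, rho, 0.1, TRUE, NA)
    for (delta in c(-0.1, 0.1)) {
      for (rho in c(0.5, 0.7)) add("proxy", miss, rho, 0.1, FALSE, delta)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run configuration
#'
#' Bundles the knobs of a Monte-Carlo run. The `"paper"` profile is the
#' study scale (R = 1000 replicates, M = 100 imputations, cohorts of
#' 10,000); the `"reduced"` profile (R = 200, M = 25) gives the same
#' qualitative picture at a fraction of the cost and is the scale used by
#' the package's own acceptance checks.
#'
#' @param seed master seed; every random stream in a run is derived from it.
#' @param R replicates per scenario.
#' @param M imputations per replicate.
#' @param n cohort size.
#' @param cycles chained-equation sweeps per imputation.
#' @param mi whether to run the MI arm at all (the complete-records arm
#'   always runs).
#' @param calib_n,calib_tol calibration cohort size and tolerance for
#'   [calibrate_alpha()].
#' @param profile `"paper"` or `"reduced"`; presets `R` and `M` unless they
#'   are given explicitly.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, R = NULL, M = NULL, n = 10000L,
                       cycles = 10L, mi = TRUE,
                       calib_n = 1e6, calib_tol = 0.002,
                       profile = c("paper", "reduced")) {
  profile <- match.arg(profile)
  defaults <- if (profile == "paper") c(R = 1000L, M = 100L) else c(R = 200L, M = 25L)
  structure(
    list(seed = as.integer(seed),
         R = as.integer(R %||% defaults[["R"]]),
         M = as.integer(M %||% defaults[["M"]]),
         n = as.integer(n), cycles = as.integer(cycles), mi = isTRUE(mi),
         calib_n = calib_n, calib_tol = calib_tol, profile = profile),
    class = "run_config"
  )
}

# Outcome-missingness spec for one grid row (alpha not yet calibrated).
.scenario_outcome_spec <- function(scenario) {
  outcome_missingness_spec(
    target_missing = scenario$missing_fraction,
    gamma7 = scenario$gamma7,
    gamma8 = scenario$gamma8
  )
}

# Alphas depend only on (target, gamma7, gamma8), not on the correlation or
# the proxy factors, so they are cached across the grid. The calibration
# stream is keyed by the same triple: independent of the analysis
# replicates and stable across grid subsets.
.alpha_for_scenario <- function(params, scenario, config, cache = NULL) {
  key <- sprintf("m%03d_g%03d_i%03d", round(1000 * scenario$missing_fraction),
                 round(1000 * scenario$gamma7), round(1000 * abs(scenario$gamma8)))
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  spec <- .scenario_outcome_spec(scenario)
  alpha <- calibrate_alpha(params, spec, tol = config$calib_tol,
                           n_calib = config$calib_n,
                           seed = derive_seed(config$seed, "calibrate", key))
  if (!is.null(cache)) cache[[key]] <- alpha
  alpha
}

#' Run one scenario
#'
#' Executes `config$R` independent replicates of the pipeline
#' generate cohort, impose missingness, complete-records fit, MI fit,
#' and summarizes them. The missingness intercept is calibrated once per
#' scenario on an independent stream. Replicate `k` runs on a seed derived
#' from `(master seed, scenario id, k)`, so its results do not depend on
#' which other scenarios are run; the MI stream of a replicate is derived
#' separately from its data stream, so changing `M` leaves the cohorts
#' untouched.
#'
#' @param scenario one row of [build_scenario_grid()] (or a one-row data frame
#'   with the same columns).
#' @param config a [run_config()].
#' @param params cohort parameters; the scenario's `rho` overrides the one in
#'   `params`, and `n` is taken from `config`.
#' @param alpha_cache optional environment for sharing calibrated intercepts
#'   across scenarios.
#' @return A list with `summary` (the [summarize_replications()] table plus
#'   scenario columns), `replicates` (long per-replicate estimates),
#'   `diagnostics` (per-replicate realized missingness and
#'   negative-prediction counts) and `alpha`.
#' @export
run_scenario <- function(scenario, config = run_config(),
                         params = cohort_params(), alpha_cache = NULL) {
  scenario <- as.list(scenario[1, , drop = FALSE])
  params$n <- config$n
  params$rho <- scenario$rho

  alpha <- .alpha_for_scenario(params, scenario, config, alpha_cache)
  spec <- .scenario_outcome_spec(scenario)
  spec$alpha <- as.numeric(alpha)
  proxy_spec <- if (!is.na(scenario$proxy_delta)) {
    proxy_missingness_spec(pi = 0.8, delta = scenario$proxy_delta)
  }

  R <- config$R
  reps <- vector("list", R)
  diags <- vector("list", R)
  truth <- true_exposure_effects()
  for (k in seq_len(R)) {
    rep_seed <- derive_seed(config$seed, scenario$scenario_id, k)
    set.seed(rep_seed)
    coh <- generate_cohort(params)
    coh <- apply_outcome_missingness(coh, spec)
    if (!is.null(proxy_spec)) coh <- apply_proxy_missingness(coh, proxy_spec)

    cr <- fit_complete_records(coh)
    rows <- data.frame(
      replicate = k, method = "complete_records",
      coefficient = names(truth), estimate = unname(cr$coef[names(truth)]),
      fmi = NA_real_
    )
    if (config$mi) {
      mi <- fit_mi(coh, M = config$M, cycles = config$cycles,
                   seed = derive_seed(rep_seed, "mi"))
      rows <- rbind(rows, data.frame(
        replicate = k, method = "mi",
        coefficient = names(truth), estimate = unname(mi$coef[names(truth)]),
        fmi = unname(mi$fmi[names(truth)])
      ))
    }
    reps[[k]] <- rows
    diags[[k]] <- data.frame(
      replicate = k,
      n_negative = attr(coh, "n_negative"),
      missing_iq = mean(!coh$iq_observed),
      missing_ks4 = mean(!coh$ks4_observed),
      mean_iq_negative = mean(coh$iq[coh$pr_iq_obs < 0])
    )
  }
  replicates <- do.call(rbind, reps)
  replicates <- cbind(scenario_id = scenario$scenario_id, replicates)
  diagnostics <- cbind(scenario_id = scenario$scenario_id,
                       do.call(rbind, diags))
  summary <- summarize_replications(replicates, truth)
  summary <- cbind(
    scenario_id = scenario$scenario_id, set = scenario$set,
    missing_fraction = scenario$missing_fraction, rho = scenario$rho,
    gamma7 = scenario$gamma7, interaction = scenario$interaction,
    proxy_delta = scenario$proxy_delta,
    summary,
    alpha = as.numeric(alpha),
    mean_n_negative = mean(diagnostics$n_negative),
    mean_missing_iq = mean(diagnostics$missing_iq),
    R = R, M = if (config$mi) config$M else NA_integer_,
    master_seed = config$seed
  )
  rownames(summary) <- NULL
  list(summary = summary, replicates = replicates,
       diagnostics = diagnostics, alpha = alpha)
}

#' Run several scenarios (or the whole grid)
#'
#' Loops [run_scenario()] over a grid, sharing the calibrated-intercept
#' cache, with per-scenario progress on stderr. Optionally writes the four
#' results files (`scenarios.csv`, `summary.csv`, `replicates.csv`,
#' `diagnostics.csv`) to a directory.
#'
#' @param grid data frame of scenarios (default the full
#'   [build_scenario_grid()]).
#' @param config a [run_config()].
#' @param params cohort parameters shared by all scenarios.
#' @param out_dir optional output directory for the CSV files.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list of combined `summary`, `replicates` and
#'   `diagnostics` data frames.
#' @export
run_grid <- function(grid = build_scenario_grid(), config = run_config(),
                     params = cohort_params(), out_dir = NULL,
                     quiet = FALSE) {
  cache <- new.env(parent = emptyenv())
  summaries <- replicates <- diagnostics <- list()
  for (i in seq_len(nrow(grid))) {
    sc <- grid[i, , drop = FALSE]
    if (!quiet) {
      message(sprintf("[%d/%d] %s (R = %d%s)", i, nrow(grid),
                      sc$scenario_id, config$R,
                      if (config$mi) sprintf(", M = %d", config$M) else ""))
    }
    res <- run_scenario(sc, config, params, alpha_cache = cache)
    summaries[[i]] <- res$summary
    replicates[[i]] <- res$replicates
    diagnostics[[i]] <- res$diagnostics
  }
  out <- list(
    summary = do.call(rbind, summaries),
    replicates = do.call(rbind, replicates),
    diagnostics = do.call(rbind, diagnostics)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(grid, file.path(out_dir, "scenarios.csv"), row.names = FALSE)
    write.csv(out$summary, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
    write.csv(out$replicates, file.path(out_dir, "replicates.csv"),
              row.names = FALSE)
    write.csv(out$diagnostics, file.path(out_dir, "diagnostics.csv"),
              row.names = FALSE)
  }
  invisible(out)
}

#' Reshape a summary into the printed-table layout
#'
#' Pivots the long [run_scenario()] summary into the side-by-side layout of
#' the study tables: one row per scenario x coefficient, complete-records
#' estimate (empirical SE), percent bias and MSE next to the MI versions,
#' with precision gain and FMI.
#'
#' @param summary combined `summary` data frame from [run_grid()] /
#'   [run_scenario()].
#' @return A wide data frame.
#' @export
results_table <- function(summary) {
  key <- c("scenario_id", "set", "missing_fraction", "rho", "gamma7",
           "interaction", "proxy_delta", "coefficient")
  cr <- summary[summary$method == "complete_records",
                c(key, "mean_estimate", "empirical_se", "percent_bias", "mse")]
  names(cr)[-seq_along(key)] <- paste0("cr_", names(cr)[-seq_along(key)])
  if (!any(summary$method == "mi")) return(cr)
  mi <- summary[summary$method == "mi",
                c(key[c(1, 8)], "mean_estimate", "empirical_se",
                  "percent_bias", "mse", "precision_gain", "mean_fmi")]
  names(mi)[-(1:2)] <- paste0("mi_", names(mi)[-(1:2)])
  merge(cr, mi, by = c("scenario_id", "coefficient"), sort = FALSE)
}
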