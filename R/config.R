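## YAML run configuration: blocks `cohort`, `missingness`, `mi`, `run`.

#' Read a study configuration file
#'
#' Parses a YAML file with up to four blocks and turns it into the package's
#' parameter objects, filling unspecified fields with the study defaults:
#'
#' \preformatted{
#' cohort:
#'   n: 10000
#'   beta: [-0.4, -0.1, 0.4, 0.8, 0.1, 0.2, 0.3]
#'   mumed_probs: [0.5, 0.25, 0.25]
#'   bf_probs_given_mumed:
#'     - [0.50, 0.15, 0.15, 0.20]
#'     - [0.30, 0.10, 0.20, 0.40]
#'     - [0.15, 0.10, 0.15, 0.60]
#'   rho: 0.7
#'   proxy_cov_coeffs: [0, 0, 0]
#' missingness:
#'   target_missing: 0.2
#'   gamma7: 0.1
#'   gamma8: 0
#'   proxy_pi: 0.8
#'   proxy_delta: 0      # 0 with proxy_pi 1 means complete proxy
#' mi:
#'   M: 100
#'   cycles: 10
#' run:
#'   seed: 1
#'   R: 1000
#'   n: 10000
#'   profile: paper      # or: reduced
#' }
#'
#' Category encodings used throughout: sex 0 = male / 1 = female; maternal
#' education 0 = O-level or lower / 1 = A-level / 2 = degree or higher;
#' breastfeeding 0 = never or under 1 month / 1 / 2 / 3 increasing duration.
#'
#' @param path path to the YAML file.
#' @return A list with elements `params` ([cohort_params()]), `outcome_spec`
#'   ([outcome_missingness_spec()] or `NULL` if no `missingness` block),
#'   `proxy_spec` ([proxy_missingness_spec()] or `NULL`) and `config`
#'   ([run_config()]).
#' @export
read_config <- function(path) {
  # keep YAML 1.1 from turning the bare key `n` into a boolean while still
  # honouring real yes/no values
  handlers <- list(
    "bool#yes" = function(x) if (toupper(x) %in% c("TRUE", "YES", "ON")) TRUE else x,
    "bool#no" = function(x) if (toupper(x) %in% c("FALSE", "NO", "OFF")) FALSE else x
  )
  raw <- yaml::read_yaml(path, handlers = handlers)
  ch <- raw$cohort %||% list()
  params <- cohort_params(
    n = ch$n %||% 10000,
    beta = unlist(ch$beta) %||% c(-0.4, -0.1, 0.4, 0.8, 0.1, 0.2, 0.3),
    mumed_probs = unlist(ch$mumed_probs) %||% c(0.5, 0.25, 0.25),
    bf_probs_given_mumed = if (is.null(ch$bf_probs_given_mumed)) {
      rbind(c(0.50, 0.15, 0.15, 0.20),
            c(0.30, 0.10, 0.20, 0.40),
            c(0.15, 0.10, 0.15, 0.60))
    } else {
      do.call(rbind, lapply(ch$bf_probs_given_mumed, unlist))
    },
    rho = ch$rho %||% 0.7,
    proxy_cov_coeffs = unlist(ch$proxy_cov_coeffs) %||% c(0, 0, 0)
  )
  ms <- raw$missingness
  outcome_spec <- if (!is.null(ms)) {
    outcome_missingness_spec(
      target_missing = ms$target_missing %||% 0.2,
      gamma7 = ms$gamma7 %||% 0,
      gamma8 = ms$gamma8 %||% 0,
      alpha = ms$alpha
    )
  }
  proxy_spec <- if (!is.null(ms) && !is.null(ms$proxy_delta)) {
    proxy_missingness_spec(pi = ms$proxy_pi %||% 0.8, delta = ms$proxy_delta)
  }
  mi <- raw$mi %||% list()
  rn <- raw$run %||% list()
  config <- run_config(
    seed = rn$seed %||% 1L,
    R = rn$R, M = mi$M,
    n = rn$n %||% params$n,
    cycles = mi$cycles %||% 10L,
    mi = rn$mi %||% TRUE,
    profile = rn$profile %||% "paper"
  )
  list(params = params, outcome_spec = outcome_spec,
       proxy_spec = proxy_spec, config = config)
}

#' Export a cohort to CSV
#'
#' Writes the per-individual records (id, covariates, outcome, proxy,
#' observation flags) as a plain CSV.
#'
#' @param cohort a cohort data frame.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("id", "sex", "mumed", "bf", "iq", "ks4",
            "iq_observed", "ks4_observed")
  write.csv(as.data.frame(cohort)[, cols], path, row.names = FALSE)
  invisible(path)
}
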