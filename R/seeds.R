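#' Derive a reproducible child seed from arbitrary labels
#'
#' Hashes its arguments (coerced to character) into an integer seed in
#' `[0, 2^31 - 2]`. Used throughout the scenario runner so that replicate `k`
#' of a scenario gets the same random stream regardless of which other
#' scenarios are run, and so that the imputation stream of a replicate is
#' independent of its data-generation stream (changing the number of
#' imputations never reshuffles the cohorts).
#'
#' @param ... labels (integers, numerics or strings) identifying the stream,
#'   e.g. `derive_seed(master, scenario_id, k)`.
#' @return A single integer usable with [set.seed()].
#' @examples
#' derive_seed(1, "m20_r070_g000_intN_pxNone", 42)
#' @export
derive_seed <- function(...) {
  parts <- unlist(lapply(list(...), function(x) as.character(x)))
  h <- 5381
  for (s in parts) {
    for (k in utf8ToInt(paste0(s, "\x1f"))) {
      # multiplicative hash; doubles are exact well past 2^46 so no overflow
      h <- (h * 69069 + k) %% 2147483647
    }
  }
  as.integer(h)
}
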