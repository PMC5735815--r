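# Independent brute-force oracles, deliberately written with plain nested
# loops so they share no code path with the package internals.

# Joint covariate distribution as a plain loop over all 24 cells.
oracle_joint_table <- function(mumed_probs, bf_rows) {
  out <- NULL
  for (sex in 0:1) {
    for (mumed in 0:2) {
      for (bf in 0:3) {
        out <- rbind(out, data.frame(
          sex = sex, mumed = mumed, bf = bf,
          prob = 0.5 * mumed_probs[mumed + 1] * bf_rows[mumed + 1, bf + 1]
        ))
      }
    }
  }
  out
}

# First and second moments of the outcome linear predictor by enumeration.
oracle_lp_moments <- function(beta, mumed_probs, bf_rows) {
  tab <- oracle_joint_table(mumed_probs, bf_rows)
  m1 <- 0; m2 <- 0
  for (i in seq_len(nrow(tab))) {
    lp <- beta[1] + beta[2] * tab$sex[i] +
      beta[3] * (tab$mumed[i] == 1) + beta[4] * (tab$mumed[i] == 2) +
      beta[5] * (tab$bf[i] == 1) + beta[6] * (tab$bf[i] == 2) +
      beta[7] * (tab$bf[i] == 3)
    m1 <- m1 + tab$prob[i] * lp
    m2 <- m2 + tab$prob[i] * lp^2
  }
  list(mean = m1, var = m2 - m1^2)
}

default_beta <- c(-0.4, -0.1, 0.4, 0.8, 0.1, 0.2, 0.3)
default_mumed_probs <- c(0.5, 0.25, 0.25)
default_bf_rows <- rbind(
  c(0.50, 0.15, 0.15, 0.20),
  c(0.30, 0.10, 0.20, 0.40),
  c(0.15, 0.10, 0.15, 0.60)
)

# Small missingness spec with every coefficient free, for unit tests that
# need degenerate mechanisms (e.g. all-zero covariate effects).
flat_outcome_spec <- function(alpha, target = 0.2, gamma7 = 0) {
  outcome_missingness_spec(
    target_missing = target, gamma7 = gamma7,
    alpha = alpha, gamma_cov = rep(0, 6)
  )
}
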