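---
title: "Simulating MNAR outcomes with linked proxies: models, mechanisms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating MNAR outcomes with linked proxies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(proxymi)
```

## The scientific question

Longitudinal cohort studies lose participants, and the loss is rarely
random: when an outcome such as adolescent IQ is missing *not* at random
(MNAR) — the probability of observing it depends on the value itself — a
complete-records regression of the outcome on an exposure is biased, and
multiple imputation (MI) from the analysis-model variables alone cannot fix
it. Administrative record linkage offers a way out: a *proxy* of the
outcome (here an educational attainment score observed for nearly
everyone), used as an auxiliary variable in the imputation model but never
in the analysis model, restores much of the missing information. The
closer the data, conditional on the proxy, get to missing-at-random (MAR),
the more of the bias MI removes.

`proxymi` implements a full Monte-Carlo framework for quantifying this:
a synthetic-cohort generator, a missingness generator, a
chained-equations MI engine with Rubin's-rules pooling, and a
100-scenario factorial study runner.

## The data-generating model

Each cohort of $n$ individuals (default 10{,}000) carries:

* `sex` — Bernoulli(0.5); 0 = male, 1 = female;
* `mumed` — maternal education, categories 0.5 / 0.25 / 0.25 (O-level or
  lower; A-level; degree or higher);
* `bf` — breastfeeding duration in four categories whose distribution
  depends on maternal education (longer durations for higher education);
  the marginal distribution implied by the defaults is
  (0.3625, 0.125, 0.1625, 0.35);
* the outcome
  $IQ = \beta_0 + \beta_1 sex + \beta_2 mumed_1 + \beta_3 mumed_2 +
  \beta_4 BF_1 + \beta_5 BF_2 + \beta_6 BF_3 + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$;
* the proxy $KS4 = \rho \, IQ + \tau$, $\tau \sim N(0, \varphi^2)$.

The defaults are $\beta = (-0.4, -0.1, 0.4, 0.8, 0.1, 0.2, 0.3)$; the
breastfeeding effects $(0.1, 0.2, 0.3)$ are the estimands of the whole
study. Both the outcome and the proxy are standardized *by construction*:
$\sigma^2$ and $\varphi^2$ are solved exactly from the enumerated 24-cell
covariate distribution so that each variable has mean 0 and variance 1
(`solve_outcome_noise_variance()` returns 0.83875 under the defaults, and
$\varphi^2 = 1-\rho^2$ when the proxy depends only on the outcome). This
keeps every result in SD units, independent of any instrument's scale, and
makes $\rho$ interpretable directly as the outcome–proxy correlation.

```{r}
p <- cohort_params(n = 5000, rho = 0.7)
solve_outcome_noise_variance(p)
coh <- generate_cohort(p, seed = 1)
c(mean = mean(coh$iq), var = var(coh$iq), cor = cor(coh$iq, coh$ks4))
```

A sensitivity variant lets the proxy also depend directly on sex and
maternal education (`proxy_cov_coeffs`). The defaults are zero; when they
are not, the covariate contribution is centred at its exact expectation and
$\varphi^2$ re-solved, so the proxy always keeps mean 0 and variance 1 —
whether to re-standardize was genuinely open, and we chose to, because the
study's whole design rests on scale-free variables.

## The missingness mechanisms

Missingness in the outcome follows a *linear-probability* (identity-link
binomial) model:

$$\Pr(IQ \text{ observed}) = \alpha + \gamma_1 sex + \dots + \gamma_6 BF_3
+ \gamma_7 IQ + \gamma_8 BF_1 IQ + \gamma_9 BF_2 IQ + \gamma_{10} BF_3 IQ.$$

$\gamma_1,\dots,\gamma_6$ are fixed (0.04, 0.075, 0.10, 0.08, 0.12, 0.14):
girls, children of more educated mothers, and breastfed children are
observed more often, mimicking real attrition patterns. $\gamma_7$ — the
change in observation probability per SD of the outcome itself — is the
MNAR dial: 0 gives MAR, and 0.05 / 0.1 / 0.2 give increasingly strong
selection. The interaction variant ($\gamma_8 = -0.025$,
$\gamma_9 = 2\gamma_8$, $\gamma_{10} = 3\gamma_8$) weakens the outcome's
pull on observation by 0.025 per breastfeeding group, so selection is
strongest among the never-breastfed.

Because the link is the identity, predictions can leave $[0,1]$. The rules
are: a negative prediction sets the outcome missing *deterministically*; a
prediction above 1 is observed with certainty (the only
probability-consistent reading — the mechanism itself only speaks about
negative predictions); anything else is a Bernoulli draw. The
deterministic rule matters: in the 80%-missing scenarios roughly a thousand
individuals per cohort are removed outright, all from the far low tail of
the outcome, which makes the effective mechanism *more* MNAR than the
linear coefficients suggest — and the package retains the raw predictions
and negative counts as diagnostics for exactly this reason.

The intercept $\alpha$ is what sets the overall missing fraction.
`calibrate_alpha()` starts from the exact-expectation solution
$\alpha_0 = (1-\text{target}) - E[\text{non-intercept terms}]$ (computable
in closed form from the enumerated covariate table and the outcome model)
and, whenever truncation makes that inexact, adjusts by trial and
improvement: bisection against the expected missing fraction
$1 - \overline{\text{clamp}(\alpha + \text{terms}, 0, 1)}$ on a calibration
cohort of $10^6$ (tolerance 0.002 on the fraction). Using the expectation
rather than realized Bernoulli draws removes one layer of noise and makes
calibration deterministic given its seed; the calibration stream is kept
separate from the analysis replicates, and $\alpha$ is fixed once per
scenario. Calibration error at this size is an order of magnitude below the
study's Monte-Carlo error.

Missingness in the proxy, when present, depends only on the proxy:
$\Pr(KS4 \text{ observed}) = \pi + \delta KS4$ with $\pi = 0.8$ (20%
missing, since the proxy is centred) and $\delta = \pm 0.10$.

## The MI engine

`chained_impute()` is a from-scratch chained-equations imputer for this
setting. Each incomplete variable gets a normal-linear conditional model
containing every analysis-model variable plus the other linked variable —
i.e. the proxy enters the imputation model for the outcome as an auxiliary
variable, and vice versa when the proxy is itself incomplete. Draws are
*proper*: residual variance from its scaled inverse-$\chi^2$ posterior,
coefficients from the matching multivariate normal, then fresh residual
noise per imputed cell. Missing cells are initialized by random draws from
the observed marginals (standard, and irrelevant after burn-in in this
linear setting); the chain then runs 10 sweeps per imputation in
declaration order (outcome, then proxy) — the conventional default of
mainstream MI software, configurable via `cycles`. When only one variable
is incomplete the pattern is monotone, every sweep redraws from the same
posterior, and the result is distributionally identical to a single proper
draw; the package caches the underlying regression fit in that case (an
exact optimization) and the test suite uses the equivalence as an oracle.

Per-imputation analysis fits are pooled by Rubin's rules
($\bar Q$, $W$, $B$, $T = W + (1+1/M)B$), with the df-adjusted fraction of
missing information
$\mathrm{FMI} = (r + 2/(\nu+3))/(r+1)$, $r = (1+1/M)B/W$,
$\nu = (M-1)(1+1/r)^2$ — the form mainstream MI software reports; the
large-sample $\lambda = (1+1/M)B/T$ is returned alongside for comparison.

```{r}
pool_rubin(estimates = c(0.1, 0.3), variances = c(0.01, 0.01))
```

## The study design and runner

`build_scenario_grid()` enumerates the 100 scenarios: a main set of 64
(4 missing fractions $\times$ [1 MAR cell at $\rho = 0.7$ + 3 MNAR
strengths $\times$ 5 correlations]), 20 interaction scenarios and 16
incomplete-proxy scenarios ($\delta = \pm 0.1$ at $\rho \in \{0.5, 0.7\}$).
`run_scenario()` runs $R$ independent replicates of
generate $\to$ impose missingness $\to$ complete-records OLS $\to$ MI,
and `summarize_replications()` turns the replicate estimates into the
performance metrics: bias and percent bias against the true effects
(0.1, 0.2, 0.3), empirical SE (SD of point estimates), MSE, mean FMI, and
the percent precision gain of MI over complete records,
$100(\mathrm{Var}_{CR}/\mathrm{Var}_{MI} - 1)$, computed from
replicate-level point-estimate variances. The variance-ratio-minus-one
form is the one consistent with reporting "0" when the two arms are
equally precise.

Reproducibility is seed-split: replicate $k$ of scenario $s$ runs on a
seed derived from (master seed, scenario id, $k$), so results are invariant
to which other scenarios run, and each replicate's MI stream is derived
separately so changing $M$ never reshuffles the cohorts.

```{r, eval = FALSE}
grid <- build_scenario_grid()
cfg <- run_config(seed = 1, profile = "reduced")  # R = 200, M = 25
res <- run_scenario(grid[grid$scenario_id == "m20_r090_g010_intN_pxNone", ],
                    cfg)
res$summary
```

## Problem sizes, numerical choices and degenerate inputs

* The full study scale is $R = 1000$ replicates, $M = 100$ imputations,
  $n = 10{,}000$ (`profile = "paper"`). The package's own acceptance
  checks use $R = 1000$ where only the complete-records arm is needed and
  the reduced profile ($R = 200$, $M = 25$) for MI arms, a scale at which
  the Monte-Carlo standard error of a percent-bias estimate for the
  smallest effect is about 2 points.
* OLS is computed by Cholesky on $X'X$; a factorization whose diagonal
  ratio falls below $10^{-6}$ is declared singular and the offending
  columns are named via a QR rank check. Imputation requires at least
  $p+1$ complete cases.
* $B = 0$ (all imputations identical) is handled as $r = 0$,
  $\nu = \infty$, FMI $= 0$.
* Configuration errors — probability vectors not summing to 1, a linear
  predictor whose variance exceeds 1 (no valid $\sigma^2$), $\rho$ outside
  $[0,1]$, an implied $\varphi^2 < 0$ — fail fast with explicit messages.
* Calibration failure (target unreachable within the iteration cap) is an
  error carrying the best iterate, never a silent approximation.

## What the generator does and does not emulate

The generator reproduces the *structure* that drives the missing-data
problem — a standardized outcome linear in a few demographic covariates, a
single standardized proxy linear in the outcome, attrition increasing in
the outcome and covariates — with parameter values of realistic magnitude
for a birth cohort. It deliberately does not emulate: the dozen-confounder
covariate set of a real cohort analysis, non-linear outcome–proxy
relationships (real attainment scores relate to IQ via polynomial terms),
measurement scales (everything is in SD units), or missingness in
covariates or exposure. Passing tests therefore demonstrate the method's
behaviour under a clean linear MNAR mechanism, not robustness to model
misspecification in real data; with unmeasured predictors of missingness,
proxy gains would shrink or even reverse.

## Known limitations

* The missingness mechanism is linear-probability by design; no
  logistic-link variant is provided.
* Only normal-linear conditional imputation models are implemented — no
  predictive-mean matching or categorical models, which this study does
  not need.
* FMI per scenario is reported as the mean of per-replicate FMIs
  (one natural choice among a few; documented rather than configurable).
* The runner is single-process; at this study's scale a full-grid paper
  run is hours, and the scenario-level seed splitting makes external
  parallelization trivial if wanted.
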