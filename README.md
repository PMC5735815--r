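# proxymi

Monte-Carlo framework for studying whether a **linked proxy of an
incomplete outcome**, used as an auxiliary variable in multiple imputation
(MI), rescues an analysis whose outcome is **missing not at random
(MNAR)**.

## The problem

In a birth cohort, an outcome such as adolescent IQ is lost to follow-up,
and often the probability of losing it depends on the value itself
(MNAR). A complete-records regression of the outcome on an exposure
(here, breastfeeding duration) is then biased, and MI using only the
analysis-model variables inherits the same bias. Record linkage to
administrative data can supply a *proxy* of the outcome — an attainment
score observed for nearly everyone — which belongs in the imputation
model but not in the analysis model. The better the proxy, the closer the
outcome is to missing-at-random given it, and the more bias MI removes.

`proxymi` simulates this end to end:

- **Cohort generator** — sex, 3-level maternal education, 4-level
  breastfeeding duration (education-dependent), an outcome
  `IQ = β₀ + β₁·sex + β₂·mumed₁ + β₃·mumed₂ + β₄·BF₁ + β₅·BF₂ + β₆·BF₃ + ε`
  and a proxy `KS4 = ρ·IQ + τ`. Residual variances are solved exactly from
  the enumerated covariate distribution so both variables have mean 0 and
  variance 1; the true exposure effects are β₄–β₆ = 0.1, 0.2, 0.3 (SD
  units).
- **Missingness generator** — a linear-probability model
  `Pr(IQ observed) = α + γ₁·sex + … + γ₆·BF₃ + γ₇·IQ + interactions`,
  with γ₇ the MNAR strength (0 = MAR); negative predictions force
  missingness deterministically, and α is calibrated by trial and
  improvement to hit a target missing fraction (20–80%). Optionally the
  proxy itself is MNAR: `Pr(KS4 observed) = π + δ·KS4`.
- **MI engine** — chained equations with proper normal-linear draws
  (posterior draws of residual variance and coefficients, then fresh
  noise), written from scratch; Rubin's-rules pooling with the
  df-adjusted fraction of missing information (FMI).
- **Study runner** — the 100-scenario factorial grid (missing fraction ×
  MNAR strength × outcome–proxy correlation ρ, plus interaction and
  incomplete-proxy variants), with replicate-level seed splitting and CSV
  outputs of bias, percent bias, empirical SE, MSE, precision gain and
  FMI.

## Worked example

One MNAR scenario — 20% missing outcome, MNAR strength γ₇ = 0.1, a strong
proxy (ρ = 0.9) — at a demonstration scale of 50 replicates and 25
imputations:

```r
library(proxymi)
grid <- build_scenario_grid()
cfg <- run_config(seed = 1, R = 50, M = 25, profile = "reduced")
res <- run_scenario(grid[grid$scenario_id == "m20_r090_g010_intN_pxNone", ], cfg)
res$summary[, c("method", "coefficient", "mean_estimate", "percent_bias",
                "empirical_se", "mse", "precision_gain", "mean_fmi")]
```

```
           method coefficient mean_estimate percent_bias empirical_se    mse
 complete_records         bf1        0.0855     -14.5327       0.0349 0.0014
 complete_records         bf2        0.1686     -15.6755       0.0368 0.0023
 complete_records         bf3        0.2606     -13.1199       0.0259 0.0022
               mi         bf1        0.0978      -2.2041       0.0300 0.0009
               mi         bf2        0.1923      -3.8339       0.0318 0.0011
               mi         bf3        0.2922      -2.5841       0.0231 0.0006
 precision_gain mean_fmi
             NA       NA
             NA       NA
             NA       NA
        35.2578   6.5669
        33.6834   5.6561
        26.3077   5.6187
```

Reading: selection on the outcome pulls the complete-records estimates of
the true effects (0.1, 0.2, 0.3) down by 13–16%, while MI with the linked
proxy as an auxiliary variable cuts the bias to a few percent, shrinks the
spread of the point estimates (the `empirical_se` columns), gains 26–35%
precision over complete records, and leaves only ~6% of the information
missing (`mean_fmi`). With a weak proxy (ρ = 0.1) the same run shows MI
mirroring the complete-records bias — the proxy is what does the work.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/proxymi.R grid --out scenarios.csv
Rscript inst/cli/proxymi.R run --scenario-id m20_r090_g010_intN_pxNone \
    --profile reduced --seed 1 --out results/
Rscript inst/cli/proxymi.R summarize --in results/ --out table.csv
Rscript inst/cli/proxymi.R calibrate --out alphas.csv
```

YAML configuration files (blocks `cohort`, `missingness`, `mi`, `run`) are
read by `read_config()`; see `?read_config` for the schema and category
encodings.

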