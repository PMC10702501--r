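# dcebr

Benefit-risk discrete choice experiments (DCEs) for treatment preferences,
end to end: D-efficient choice-task design, synthetic respondent
simulation, error-component logit estimation by maximum simulated
likelihood, relative attribute importance (RAI), minimal-acceptable-benefit
(MAB) trade-offs and subgroup heterogeneity.

The package implements the quantitative machinery of a patient-preference
study in relapsed/refractory multiple myeloma (RRMM): 296 patients across
six countries chose repeatedly between two hypothetical treatments
described by eight attributes — overall response rate (ORR, 25-85%),
duration of response (3-15 months), overall survival (OS, 6-24 months),
risks of peripheral neuropathy, ocular adverse events, cytokine release
syndrome (CRS) and severe diarrhea, and the mode of administration (IV/SC
schedules up to the one-time CAR-T procedure bundle). Because raw choice
data from such studies are rarely shareable, every stage is paired with a
seeded synthetic-respondent generator, so the full pipeline is testable
and reproducible.

## The model

Respondent *n* assigns alternative *j* in task *t* the utility

    U_ntj = x_ntj' beta + sigma * eta_n * 1[j = A] + eps_ntj

with dummy-coded levels `x` (23 part-worths against each attribute's
reference level), i.i.d. Gumbel noise `eps`, and a once-per-respondent
normal error component `eta` capturing panel correlation. The simulated
likelihood integrates over `eta` with antithetic scrambled Halton draws
and is maximised by BFGS with analytic gradients (Rcpp core). From the
fitted part-worths:

* **RAI**: each attribute's utility range as a share of the total range,
  summing to 100%, with Krinsky-Robb confidence intervals;
* **MAB/MRS**: the ORR percentage points (range linearised over 60
  points) or OS months (over 18 months) that exactly offset the utility
  loss of a risk or administration change.

## Worked example

```r
library(dcebr)

catalog <- default_catalog()                      # the 8-attribute catalog
design  <- generate_design(catalog, n_tasks = 36, n_blocks = 3, seed = 1)
design  <- add_validity_tasks(design)             # + stability & dominance

profiles <- simulate_profiles(296, seed = 2)      # six country strata
truth <- true_model(
  beta  = utilities_from_importance(catalog, rrmm_rai_scores()) * 0.04,
  sigma = 0.8, optout_rate = 0.05
)
choices <- simulate_choices(design, profiles, truth, seed = 3)

fit <- estimate_ecl(choices, catalog, ecl_settings(n_draws = 200, seed = 4))
fit
#> <ecl_fit> 296 respondents, 3552 choices, logLik -2062.451 (null -2462.059)
#> ...
#>  orr:85    1.24806   0.08783  14.2102 7.923e-46
#>  crs:high -0.58206   0.04257 -13.6718 1.496e-42
#>  sigma     0.84695   0.06410  13.2129 7.394e-40

rai_confidence_intervals(fit, catalog)[, c("attribute", "importance_percent")]
mab_table(fit, catalog)     # ten benefit-risk exchange rates with CIs
validity_summary(choices, design)
#> <dce_validity>
#>   stability consistency: 67.9%
#>   dominance pass rate:   82.1%
#>   opt-out rate:          5.0%
```

The printed coefficients are marginal utilities relative to each
attribute's reference level (lowest benefit, no risk, IV/SC every 3
weeks); `sigma` is the error-component spread, whose size relative to the
Gumbel scale (1.0) measures how strongly a respondent's choices hang
together. A one-call version of the whole analysis, including subgroup
heterogeneity and written reports, is

```r
res <- run_pipeline(default_config(seed = 1, out_dir = "out"))
```

and a thin CLI over the same pipeline ships at `inst/cli/dcebr`
(`dcebr report --config inst/extdata/demo_config.yaml`).

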