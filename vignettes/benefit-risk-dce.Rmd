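---
title: "Benefit-risk discrete choice experiments with dcebr: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benefit-risk discrete choice experiments with dcebr: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcebr)
```

## The problem

Patients with relapsed/refractory multiple myeloma (RRMM) face treatment
options that differ on efficacy (overall response rate, duration of
response, overall survival), on the risk of burdensome side effects
(cytokine release syndrome, peripheral neuropathy, ocular adverse events,
severe diarrhea) and on how the treatment is administered (from frequent
IV/SC dosing to the one-time CAR-T procedure bundle). A discrete choice
experiment (DCE) elicits how patients trade these off: respondents
repeatedly choose between two hypothetical treatments described by
attribute levels, and a random-utility model turns the choices into
marginal utilities, importance scores and benefit-risk exchange rates.

`dcebr` implements that pipeline end to end — design, simulation,
estimation, metrics, heterogeneity and quality control — for an
eight-attribute benefit-risk study of 296 RRMM patients across six
countries. Because individual-level choice data from such studies are
typically not shareable, the package pairs every analysis stage with a
synthetic-respondent generator so the whole machinery is testable.

## The choice model

Respondent $n$ facing task $t$ assigns alternative $j \in \{A, B\}$ the
utility

$$U_{ntj} = x_{ntj}^\top \beta \;+\; \sigma\,\eta_n\,\mathbf 1[j = A] \;+\;
\varepsilon_{ntj},$$

where $x_{ntj}$ dummy-codes the alternative's levels against each
attribute's reference level (23 indicators for the default catalog),
$\beta$ holds the part-worth utilities, $\varepsilon$ is i.i.d. standard
Gumbel, and $\eta_n \sim N(0,1)$ is drawn once per respondent. The
$\sigma\,\eta_n$ term is the error component: it induces correlation
between a respondent's choices beyond what the Gumbel noise allows. It is
attached to one alternative only; in a two-alternative forced choice a
component common to both alternatives would cancel from every utility
difference and be unidentifiable, whereas this placement makes $\sigma$
identifiable from panel correlation. Only $|\sigma|$ is identified — the
likelihood is an even function of $\sigma$ — and the fit reports the
absolute value.

The probability that respondent $n$ makes their observed sequence of
choices, marginalised over the error component, is a one-dimensional
integral that the package approximates by simulation:

$$P_n = \int \prod_t \Lambda\!\big(s_{nt}(\Delta x_{nt}^\top\beta +
\sigma\eta)\big)\, d\Phi(\eta) \;\approx\; \frac1R \sum_{r=1}^R \prod_t
\Lambda\!\big(s_{nt}(\Delta x_{nt}^\top\beta + \sigma\eta_{nr})\big),$$

with $\Lambda$ the logistic CDF, $\Delta x = x_A - x_B$ and $s = +1$ when A
was chosen, $-1$ otherwise. `estimate_ecl()` maximises $\sum_n \log P_n$ by
BFGS with the analytic gradient.

### Numerical choices

* **Draws.** $\eta_{nr}$ comes from a base-2 Halton sequence, burn-in of 10
  points, scrambled by a seeded uniform shift modulo 1, mapped through
  $\Phi^{-1}$, and antithetically paired (the second half of each
  respondent's draws mirrors the first). Antithetic pairing halves
  simulation variance for symmetric integrands and makes the simulated
  likelihood exactly even in $\sigma$, so relabelling the two alternatives
  is an exact symmetry of the estimator. Default $R = 500$ per respondent.
* **Start values.** Part-worths start at zero. The spread starts at $0.1$
  rather than zero: $\sigma = 0$ is a stationary point of the even
  likelihood where a gradient-based search can stall.
* **Convergence.** `optim(method = "BFGS")` with relative tolerance
  $10^{-9}$; non-convergence is reported in the `converged` flag, never as
  an error. Standard errors come from the inverse numerical Hessian
  (`optimHess`); a respondent-clustered sandwich covariance is available
  via `ecl_settings(robust = TRUE)`. A singular Hessian yields missing
  standard errors with a warning.
* **Validity tasks** (stability repeat, dominance test) are excluded from
  the likelihood by default — they are engagement checks, and the stability
  repeat would double-count its source task. Opt-out flags are ignored in
  estimation: the study analysed the forced choice, and opt-out is kept as
  a quality-control statistic.
* **Inference on $\sigma$ near zero** is unreliable: because the
  likelihood is even in $\sigma$, the Wald statistic at the $\sigma = 0$
  boundary is not asymptotically standard normal, and its nominal coverage
  is optimistic. The test suite therefore checks that a zero spread is
  recovered as *negligible in magnitude* rather than via its standard
  error.

## D-efficient designs

`generate_design()` searches for level assignments that minimise the
D-error of the paired conditional logit,
$\det\!\big(I(\beta_0)^{-1}\big)^{1/K}$, with
$I = \sum_t p_t(1-p_t)\,\Delta x_t \Delta x_t^\top$ the Fisher information
at prior coefficients $\beta_0$. The search is coordinate exchange: from a
random start, every task/alternative/attribute cell is offered each
alternative level in turn and a swap is accepted when the D-error strictly
decreases, for up to 20 sweeps (stopping early when a sweep makes no
improvement), optionally from several random restarts. The default prior
is zero (a utility-neutral design): the original study states a D-efficient
design without publishing priors, and the neutral prior is the reproducible
choice that adds no unstated inputs. Degenerate proposals — a task whose two
alternatives are level-identical, or a duplicate of another task — are never
accepted.

Tasks are then assigned to blocks (36 tasks into 3 blocks of 12 by
default) by a greedy rule that minimises the sum over attributes and
levels of the squared deviation of within-block level counts from
uniform; respondents are assigned to blocks round-robin for exact balance.
`add_validity_tasks()` appends per block a stability repeat of the third
task (position configurable) and a dominance task whose alternative A is
weakly best on every ordered attribute and strictly better on at least
one, with administration held equal across the pair — administration modes
have no assumed preference direction, so dominance is never built on them.
On small instances (at most a few hundred candidate tasks) the exchange
search provably attains the exhaustive-search minimum, which the test
suite verifies; on the full catalog it is compared against random designs.

`presentation_order()` reproduces the survey's ordering scheme: attribute
groups (benefit, risk, administration) in uniformly random order,
attributes shuffled within groups, groups contiguous.

## The synthetic-respondent generator

`simulate_profiles()` draws covariate profiles matching the study sample:
fixed country counts (US 100, UK 49, Italy 45, Germany 43, France 39,
Spain 20, apportioned proportionally for other sample sizes), age normal
with mean 63.8 and SD 8.0 years (truncated at 18, the eligibility floor),
52% male, 84% with a caregiver, response status 46/31/23%
(partial/complete/none) and fatigue severity 6/50/44%. Prior therapy
lines are $2 + \mathrm{Binomial}(6, 0.2)$ — at least two lines, as
eligibility requires, with median 3 and range 2-8.

`simulate_choices()` then applies the error-component model above,
optionally with interaction shifts $\gamma_c$ per covariate
($\beta_n = \beta + \sum_c z_{nc}\gamma_c$), and flags opt-outs
independently per task at a configurable rate; opt-outs never overwrite
the forced choice, mirroring how the survey collected them. The default
data-generating part-worths used across the package's tests and demo
pipeline set per-attribute utility ranges proportional to the study's
reported importance scores scaled by 0.04 (ranges between about 0.12 and
1.2 on the utility scale — typical magnitudes for estimated DCE
part-worths), with $\sigma = 0.8$ and a 5% opt-out rate.

What the generator does **not** emulate: item nonresponse and dropout,
straight-lining and other response heuristics, response times, attribute
non-attendance, and learning or fatigue across tasks. Passing tests
therefore show that the estimator recovers the model that generated the
data and that the metrics propagate it correctly — not that the model is
robust to the behavioural artefacts of real survey data.

## Importance scores and trade-offs

`compute_rai()` computes relative attribute importance: each attribute's
utility range (best minus worst level, reference included at zero) as a
percentage of the sum of ranges. The scores sum to 100 by construction and
are conditional on the level ranges studied. Krinsky-Robb confidence
intervals (`rai_confidence_intervals()`) resample coefficient vectors from
the fit's multivariate-normal approximation and report percentile bounds;
a covariance that has drifted off the positive-semidefinite cone is
repaired by eigenvalue clipping, with a warning.

`compute_mab()` converts a utility loss into the minimal acceptable
benefit on a benefit attribute's natural scale. The default linearisation
treats the benefit attribute's full range as linear: one unit of benefit
(an ORR percentage point, an OS month) is worth $\mathrm{range}/w$ utility,
with $w$ the scale width (60 points for ORR over 25-85%, 18 months for OS
over 6-24 months), so a utility loss $\Delta u$ requires
$\Delta u \cdot w / \mathrm{range}$ units of benefit. This linearisation
was chosen because it reproduces all ten of the study's published
trade-off values exactly from its published importance scores (e.g.
$11.9 / 29.8 \times 60 = 23.96 \approx 23.9$ ORR points for the CRS
change) — strong internal evidence that it is the calculation behind the
published figures; the acceptance suite pins all ten. A non-default
`method = "piecewise"` inverts the estimated piecewise-linear utility
curve instead and returns `NA` when the loss exceeds what the benefit
scale can offset. The administration trade-off (CAR-T bundle versus IV/SC
every 3 weeks) is the same calculation applied to a level-to-level utility
difference; IV/SC every 3 weeks is the catalog's administration reference
level for exactly this reason.

## Subgroup heterogeneity

`fit_with_interactions()` interacts every part-worth with a single binary
respondent characteristic (one characteristic per model, run repeatedly
across characteristics — the minimal specification that adds interaction
terms without inventing a joint multi-covariate model). Group-0 utilities
are the base part-worths; group-1 utilities add the interaction
coefficients. `subgroup_rai()` propagates the joint covariance through the
Krinsky-Robb resampling, and `subgroup_comparison()` tabulates both
groups' scores next to the interaction z-statistics. The p-values are
nominal and exploratory: no multiple-testing correction is applied, and
the report labels them as such. Note that an interacted model on the
default catalog doubles the coefficient count to 46, which needs at least
23 + 1 distinct task-by-group utility differences — the blocked 36-task
design provides 72.

## Quality control and the pipeline

`validity_summary()` reports the stability consistency rate (same choice
on the repeated task), the dominance pass rate and the opt-out rate, each
computed only over respondents who saw the relevant task and reported as
absent — not zero — when no validity tasks exist. No respondents are
excluded on failed validity checks: the rates are descriptive, matching
how such studies report them, and any filtering is left to the caller.

`run_pipeline()` chains design, simulation (or loading), estimation,
metrics, heterogeneity and validity, writing deterministic CSV/JSON/text
outputs; two runs with the same configuration are byte-identical, and an
`estimate-only` re-run on the written dataset reproduces the original fit.
Derived tables carry a provenance comment header with the seed and mode;
the design and choice CSVs stay comment-free so that read-write
round-trips are byte-identical. Report percentages and months are rounded
to one decimal.

## Problem sizes in the test suite

The packaged checks run at deliberately modest sizes chosen to exercise
each property well: parameter recovery uses 20 replicates of 500
respondents answering 12 tasks each from the blocked 36-task design, with
150 antithetic Halton draws; interval coverage uses 200 replicates of 300
respondents on a reduced four-attribute catalog with 50 draws; validity
null rates use 2,000 simulated random choosers. The demo pipeline ships at
90 respondents and 80 draws so a full end-to-end run takes seconds.

## Known limitations

* The error-component placement (alternative A only) is one of several
  identifiable conventions; a study-specific appendix formula, if one
  exists, should supersede it.
* Wald inference on $\sigma$ near zero is miscalibrated (see above); use
  likelihood comparisons if the presence of panel correlation is itself
  the question.
* No latent-class or full random-coefficients mixed logit, no
  willingness-to-pay-space estimation, no opt-out modelling beyond the QC
  rate.
* RAI scores are conditional on the attribute list and level ranges; they
  do not generalise to attributes or ranges outside the design.
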