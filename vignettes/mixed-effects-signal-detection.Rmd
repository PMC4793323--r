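---
title: "Mixed-effects signal detection for spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-effects signal detection for spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvmix)
```

## The problem

Spontaneous reporting systems (SRSs) such as JADER or FAERS collect suspected
adverse drug events (ADEs) passively. Their composition drifts over time:
newly approved drugs are adopted, publicity inflates reporting of particular
events (notoriety bias), and coding practice changes. A drug–event
association estimated while ignoring this drift confounds the association
with the reporting era.

`pvmix` implements a two-phase screen for such databases:

1. **Disproportionality screen.** Every combination of a generic drug (or a
   pooled drug class) with a reported high-level term (HLT) is tabulated at
   case level into a 2×2 contingency table and tested with Fisher's exact
   test. Combinations with a two-sided p-value below 0.01 *and* a crude odds
   ratio above 1 pass.
2. **Mixed-effects logistic regression.** For each screened HLT, the binary
   outcome "case reports the HLT" is regressed on use of DPP-4 inhibitors,
   use of GLP-1 receptor agonists, use of any hypoglycemic drug (an
   indication proxy for hyperglycemia), the number of concomitant suspected
   drugs, age in decades, and sex — with a random intercept per quarterly
   reporting period:

   $$\log\frac{P(Y_i = 1 \mid x_i, u)}{P(Y_i = 0 \mid x_i, u)}
     = x_i^\top \beta + u_{q(i)}, \qquad
     u_q \sim \mathcal{N}(0, \sigma^2) \text{ i.i.d.}$$

   The quarter-level intercept $u_q$ absorbs era-wide shifts in the odds of
   the event being reported. Association is judged by the class odds ratios
   $e^{\beta_j}$ with 99% two-sided Wald intervals; the model with and
   without the random effect are compared by AIC, the random-effect standard
   deviation counting as one parameter.

## Estimation

The marginal likelihood integrates the random intercept out cluster by
cluster:

$$\ell(\beta, \sigma) = \sum_q \log \int \prod_{i \in q}
  p(y_i \mid x_i^\top\beta + u)\, \varphi(u; 0, \sigma^2)\, du .$$

The integral is evaluated by (non-adaptive) Gauss–Hermite quadrature with the
substitution $u = \sqrt{2}\sigma x$ and weights normalized by $\sqrt\pi$; the
rule's nodes and weights come from the Golub–Welsch eigendecomposition of the
Jacobi matrix, with weights computed through the Christoffel function so they
stay positive up to 100 nodes. `fit_mixed()` maximizes $\ell$ jointly over
$(\beta, \log\sigma)$ by BFGS with analytic gradients, followed by Newton
polishing until the largest score component falls below `tol` (default
1e-8, at most 100 quasi-Newton iterations). Standard errors are the inverse
observed information of the marginal log-likelihood, obtained by central
differences of the analytic gradient in the $(\beta, \sigma)$
parameterization.

Numerical choices worth knowing:

* **Node count.** `n_quad = 8` by default. On quarter-sized clusters
  (hundreds of cases) non-adaptive quadrature is accurate at 8 nodes for the
  event rates this package targets; the test suite asserts stability against
  32 nodes and agreement with adaptive-quadrature fits from `lme4` at high
  node counts. Raise `n_quad` for very concentrated cluster likelihoods.
* **Boundary.** $\sigma$ is optimized on the log scale, which keeps it
  positive without constraints; an estimate below 1e-6 is snapped to the
  $\sigma = 0$ boundary, where the marginal likelihood equals the
  fixed-model likelihood exactly and the fit is reported with
  `boundary = TRUE`. If an interior "optimum" ever undercuts the nested
  fixed fit (a numerical artifact near the boundary), the boundary solution
  is reported instead, so the nesting inequality holds identically.
* **Degenerate designs.** A covariate with no variation (a drug class with
  no exposed case, a gated concomitant count that is zero everywhere) is
  dropped by `build_design()` and recorded in the `dropped_covariates`
  attribute; fitting proceeds on the estimable columns.
* **Separation.** Coefficients running past ±15 on the logit scale are
  treated as (quasi-)separation; the fit is returned but flagged
  unconverged, and the pipeline carries such HLTs as "undetermined" in the
  AIC comparison rather than aborting.
* **Fisher's test.** The two-sided p-value is the sum of hypergeometric
  point probabilities not exceeding the observed one, with the conventional
  relative slack of 1e-7 on the comparison — the same convention as
  `stats::fisher.test`, against which the implementation is cross-checked,
  and an exhaustive enumeration oracle covers every table with
  $N \le 60$. Tables with an empty margin get p = 1 and a `degenerate`
  flag.

## Coding decisions

Several constructions admit more than one reasonable reading; the package
fixes defaults and exposes switches:

* **Exposure** means *any* mention of a class drug regardless of its
  reported role (suspected/concomitant/interacting); `exposure_roles`
  restricts it (e.g. to suspected only).
* **The concomitant-suspected count** is the number of distinct
  suspected-role drugs in the case, excluding incretin-class members, and —
  when a phase-1 screen is supplied — restricted to drugs whose own Fisher
  screen against the target HLT was significant. Passing `screen = NULL`
  counts all non-incretin suspected drugs.
* **The hypoglycemic set** includes the incretin classes by default (it is
  an indication proxy, not a comparator set); `drug_classes()` can exclude
  them.
* **Age** enters as a single integer decade covariate with one coefficient.
* **Sex** is coded female = 0, male = 1; this affects intercepts, not the
  drug odds ratios.
* **The reporting quarter** is derived from one designated date column,
  configurable in the dialect, since real databases carry several candidate
  date fields.
* Phase 1 screens per generic drug *and* per pooled class; an HLT enters
  phase 2 if any of them flags it, and phase 2 fits one model per HLT
  containing both class indicators.

## The synthetic-report generator

Real SRS snapshots and the MedDRA dictionary are licensed, so the package
ships a seeded generator (`simulate_srs()`) that reproduces the statistical
structure the method assumes:

* quarterly report volumes growing linearly (default ≈ 400 → 1,500 per
  quarter over 21 quarters, ≈ 20,000 cases);
* a DPP-4 exposure share rising markedly across quarters (1% → 10%), a
  small GLP-1 share, a flat non-incretin hypoglycemic share, and a Poisson
  number of background drugs with suspected/concomitant roles;
* demographics with realistic missingness (≈ 6% missing age, 2.5% missing
  sex, so ≈ 8% of cases are excluded by the analyzability filter, in line
  with real snapshots);
* per HLT: one normal random intercept per quarter and Bernoulli events
  from the logistic model, reported as PT codes drawn from the HLT's
  children — including one PT with two HLT parents, mirroring the
  multi-parent links in real dictionaries;
* random streams split per stage (demography, exposure, per-HLT events), so
  adding an HLT never perturbs the other draws.

What the generator does **not** emulate: notoriety spikes, reporting delays,
duplicate reports, drug-name synonymy, or correlated events beyond the
shared-parent PT. Passing tests therefore demonstrate that the estimator
recovers the generative model it assumes — not that real reporting data
satisfy that model.

## Study sizes used by the checks

The test suite and `scripts/acceptance.R` use deliberately sized studies:

* *Exact primitives*: all 635,375 2×2 tables with $N \le 60$ against an
  enumeration oracle; the reference-margin table (234, 7031, 804, 179112)
  for the contingency arithmetic and the closed-form logistic slope.
* *Quadrature*: tiny 3-cluster designs against a 100,000-point trapezoid
  oracle for $\sigma \in \{0.1, 0.5, 1, 2\}$.
* *Recovery*: 50 replicates of ≈ 5,000 cases over 21 quarters with
  $\beta_{\text{DPP-4}} = 1.5$, $\sigma = 0.5$ on a commonly reported HLT
  (baseline intercept −1.8, ≈ 15% event rate). The common-event scenario is
  a deliberate test-design choice: with a rare event (< 1%) at this sample
  size the *estimator itself* — ours and `lme4::glmer`'s alike — carries the
  classic sparse-data bias of the logistic MLE (upward, on the order of
  +0.2 at ≈ 75 events and 7 parameters), which would swamp the
  implementation-fidelity signal the check is after. The generator's default
  pancreatitis-like HLT remains rare and realistic.
* *Calibration*: 1,000 null replicates of 1,200 cases generated directly at
  the design level (`simulate_design()`), checking that the 99% Wald CI
  excludes an odds ratio of 1 in at most 3% of replicates.
* *AIC contrast*: six replicates of a ≈ 2,000-case fixture in which only
  the two common HLTs carry quarter heterogeneity ($\sigma = 0.8$); the
  median case count of mixed-favoring HLTs must exceed that of
  fixed-favoring ones, and the $\sigma = 0$ HLTs must show non-negative
  mean AIC differences.

## Known limitations

* Non-adaptive quadrature loses accuracy when a cluster's likelihood is
  extremely concentrated relative to the prior (very large clusters with
  mid-range event rates); raise `n_quad` or expect small discrepancies
  against adaptive implementations.
* Wald intervals on $\sigma$ are unreliable near the boundary; the package
  reports `sigma_se = NA` with `boundary = TRUE` rather than a fabricated
  interval.
* The ML estimate of $\sigma$ is biased slightly downward with few clusters
  (≈ −5% at 21 clusters); this is a property of maximum likelihood, shared
  with every ML-fitting GLMM package.
* No penalized-likelihood rescue for separation, no multiple-testing
  correction (by design: the stringent 0.01/99% levels stand in for one),
  and case deduplication beyond case-ID uniqueness is out of scope.
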