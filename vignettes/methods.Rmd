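---
title: "Symptom-cluster phenotyping with registry outcomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom-cluster phenotyping with registry outcomes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models and procedures each stage implements, the tunable parameters that
matter, what the synthetic cohort generator does and does not emulate, and
the design choices made where the design was genuinely open. Nothing
stated here as an empirical property goes beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. Data model

A cohort is a subjects-by-variables table typed by a schema. Each
variable has a *kind* (binary, ordinal, nominal, continuous) and a *role*:

* **symptom** — binary questionnaire items and ordinal composites; the
  clustering inputs. Subject to survey missingness and imputation.
* **background** — survey covariates (age, BMI, sex, smoking, cohort,
  occupational exposure, education, SES); imputed like symptoms.
* **register** — administrative variables (comorbidity scores, flags).
  Register sources have near-complete coverage, so missing register
  cells are a validation error, never an imputation target.

Ordinal composites collapse a severity- or chronicity-ordered set of
binary items into one variable by the *highest-affirmative* rule: the
composite level is the index of the highest affirmative source, 0 when
none is affirmative. The constituent lists used in the original surveys
are not public, so the shipped rule is a policy with pluggable
per-composite definitions; the default analysis runs on the 31 binary
items directly. Symptom counting (a binary item counts when 1, an
ordinal when above its lowest level) happens before composite
construction, and the symptomatic/asymptomatic split at ≥ 1 symptom
defines both the clustering population and the mortality reference
group.

## 2. Synthetic cohort generator

The generator exists because the register-linked cohort data the
analysis is designed for cannot be redistributed. It plants exactly the
structure the pipeline assumes, which makes every downstream stage
testable against known truth:

* **Latent classes.** A subject is asymptomatic with probability 0.436
  (all symptom items 0), otherwise falls in one of five clusters with
  mixing 0.303/0.107/0.047/0.066/0.041 scaled to the symptomatic share —
  the published cluster proportions.
* **Symptom items.** 31 binary items over five domains, conditionally
  independent given the cluster, with per-cluster Bernoulli profiles
  loosely calibrated to the published cluster descriptions (e.g. the
  productive-cough cluster has 0.72 on chronic productive cough; the
  allergic-nasal cluster 0.95 on rhinitis ever). Conditional
  independence keeps the planted structure analytically checkable; a
  shared latent severity factor (`severity_correlation`) can induce
  realistic positive item correlation and is off by default.
* **Covariates.** Drawn independently of cluster from configured
  marginals: age N(48, 16) truncated to 16–75, BMI N(25.5, 4), 53%
  women, smoking 14% current / 23% former, a two-level cohort label
  (0.676/0.324), education and SES categoricals. Independence from the
  latent class is the default so crude and adjusted effects coincide in
  expectation; real cohorts confound, and the mortality machinery is
  exercised against that via the covariate effects below.
* **Survival.** Independent cause-specific exponential hazards
  (cardiovascular, respiratory, lung cancer, other) at reference
  2.0/0.3/0.2/2.5 per 1000 person-years, scaled by covariate log-HRs
  (0.085 per year of age, 0.40 male, 0.60/0.20 current/former smoking)
  and per-cluster per-cause log-HRs calibrated to the published adjusted
  estimates (all clusters but the allergic-nasal one raise mortality;
  the wheeze+dyspnea and productive-cough clusters carry the largest
  respiratory-cause effects). Observed time is the minimum of the
  latent times and a 21-year administrative end; the minimum-of-
  exponentials construction is the simplest generator consistent with
  both Cox and Fine-Gray estimation, so Fine-Gray recovery is checked
  against independent fitters rather than against the latent rates.
* **Missingness.** MCAR at 11.2% of survey cells by default; a MAR
  mechanism conditions the cell probability on cohort (per-cohort base
  rates) and age (logit-linear), leaving the conditioning variables
  observed.
* **ICD-10 histories.** Poisson counts of comorbidity-relevant contacts
  (rate 0.0726, giving ~93% of subjects no Charlson-relevant code) and
  other specialist contacts (rate 0.3), dated uniformly in the 11-year
  lookback window.

What the generator does **not** emulate: joint covariate dependence
beyond marginals, item wording differences between survey waves,
cause-of-death misclassification, and non-exponential baseline hazards.
Passing tests therefore demonstrate correctness of the machinery under
the stated generating model, not robustness to those real-data features.

## 3. Imputation

`mice_rf` is chained-equation imputation with random-forest
conditionals (`ranger`): categorical variables use probability forests
and a class draw; continuous variables use regression forests with a
predictive-mean-matching draw among the k = 5 nearest donors by
out-of-bag prediction, which keeps draws proper and within the observed
support. Visit order is ascending missingness; 10 sweeps by default
(the analysis scripts use 5, the test profile 3 — sweeps beyond the
first few change little in these data, and the problem sizes were
chosen to keep the default runs interactive). A variable missing for an
entire cohort drops `cohort` from its predictor set, so its values are
imputed from the remaining cohorts' distribution. The study design uses
m = 100 imputations; m is a parameter everywhere and the test profile
uses m = 3–5, which changes Monte-Carlo error only.

Descriptive pooling collapses the m tables cell-wise: mode for
categorical kinds (ties broken deterministically toward the
lower-ordered level), mean for continuous. Inferential pooling never
uses this table — it applies Rubin's rules to per-imputation estimates.

## 4. Clustering

The representative of a cluster is one frequency vector per attribute.
The subject-to-representative dissimilarity is the expectation of the
point-to-point mixed distance under those frequencies,

d(x, R) = Σ_j w_j Σ_c f_jc d_j(x_j, c),

with d_j the mismatch indicator (binary/nominal) or the normalised rank
difference (ordinal), so each attribute contributes at most w_j = 1.
For a binary attribute this reduces to 1 − f_j[x_j].

**Initialisation.** Subjects are one-hot/rank encoded, mean-centred and
hashed by the signs of `n_bits` (default 6) random hyperplane
projections. Non-empty buckets, sorted by size, seed the clusters: more
buckets than k are merged greedily by smallest expected
representative-to-representative distance; fewer are split on their
highest-entropy attribute. Random-hyperplane signatures were chosen
over value-similarity hashing for their simplicity and distribution-free
behaviour; the construction sits behind one function so a different
scheme can be swapped in.

**Iteration.** Assignment to the nearest representative (ties toward
the lowest cluster index) alternates with recomputing frequency vectors
from the assigned members; clusters emptied by an assignment are
reseeded with the farthest-from-its-representative subject drawn from a
cluster that keeps at least one member. Convergence is *zero label
changes* rather than an objective tolerance, avoiding float-platform
drift. One guard departs from the plain alternating scheme: a
frequency-vector update is not the minimiser of the summed
dissimilarity (the minimiser is degenerate at the attribute mode), so a
late-stage update can raise the objective and let labels oscillate.
When an update would do so, it is reverted and the fit stops, declared
converged. This keeps the logged objective trace non-increasing — a
property the test suite asserts over 20 seeded runs — while preserving
frequency-vector representatives, which degenerate mode updates would
not.

**Model selection.** `scan_k` fits k = 2..10 and reports objective,
mean silhouette (computed exactly under the mixed distance via
per-cluster level counts, O(n·k·L) rather than O(n²)) and cluster
sizes. The suggestion is the silhouette argmax with ties toward smaller
k, and is advisory: on realistically overlapping profiles the
silhouette favours coarse splits (the analysis scripts show it
suggesting 2 while the planted count is 5), which is exactly why the
study's cluster count was chosen jointly with subject-matter review.
The analysis fits k = 5.

## 5. Consensus across imputations

Cluster indices are arbitrary per run, so labels are aligned before
voting: the permutation maximising the contingency-table overlap with
the reference member (imputation 1 by default — any fixed reference
yields a consistent consensus) is found by an exact bitmask
dynamic-programming assignment solver (O(2^k·k), ample for k ≤ 20, and
verified against exhaustive permutation search for k ≤ 4). The
consensus label is the modal aligned label, ties toward the lowest
index; the agreement fraction (modal count / m) is reported per
subject. Consensus labels serve descriptive characterisation only; the
mortality models use each imputation's own labels, as the analysis
design prescribes. Subjects whose symptomatic status itself varies
across imputations (a handful near the ≥ 1 symptom boundary) are
excluded from the vote and characterised as asymptomatic.

## 6. Comorbidity index

The Charlson map ships as an editable structure of 3-character ICD-10
prefixes per category with integer weights — the classical categories,
with the chronic pulmonary block split so asthma (J45–J46) and COPD
(J40–J44) are separable. The *modified* score excludes those two
categories (they enter the models as individual flags, from self-report
or in-window register records, either source sufficing by default).
A category counts once regardless of record multiplicity; the window is
calendar-year based: survey year plus the 11 preceding years. The exact
Swedish register adaptation of the weights is not public; the shipped
map is the package's pinned default and every test value is hand-scored
against it.

## 7. Mortality analysis

Survival records run from the start of the survey year to death or the
administrative end of follow-up (21 years); subjects without a death
record are censored at the end. Underlying-cause ICD-10 codes map to
outcomes by prefix — C33–C34 lung cancer first, then I* cardiovascular,
J* respiratory, else "other"; the blocks are configuration. Cohorts
with register follow-up shorter than a configured minimum are excluded
with a recorded count.

Per imputation and outcome the model is Cox proportional hazards
(all-cause; Efron ties) or Fine-Gray (cause-specific; fitted by
weighted Cox on the `survival::finegray` expansion, which keeps
competing-event subjects in the risk set via censoring weights — with
zero competing events it coincides with Cox, a reduction the tests
check to 1e-6). The exposure is the cluster factor with the
asymptomatic group as reference; adjusted models add age, BMI, sex,
smoking, cohort, occupational exposure, education, SES, the modified
CCI category and the asthma/COPD flags, with SES and education as
unordered factors (first level reference). Crude models adjust for
nothing. Within a stratum defined by a confounder, that confounder is
dropped from the adjusted model.

No model is fitted below 10 events per estimated parameter; such
analyses are skipped and logged, never silently. A fit is usable for
pooling when all coefficients are finite and the exposure terms are
bounded away from a monotone-likelihood blow-up (|β| < 15); a drifting
*confounder* coefficient (a rare level with no events in a small
stratum) is recorded as a warning but does not discard the exposure
estimates, which are unaffected.

Pooling is on the log-HR scale (Rubin's rules assume approximate
normality, which holds for log-HR, not HR): T = W + (1 + 1/m)B, t-based
intervals with Barnard–Rubin degrees of freedom (reducing to the
classical (m−1)(1+1/r)² when the complete-data df is taken infinite,
the default). Proportionality is checked per covariate by the
zero-slope score test on scaled Schoenfeld residuals
(`survival::cox.zph`), with the residual series exported for plots.

## 8. Numerical conventions

* Every tie-break is deterministic toward the lowest index/level:
  assignment ties, majority-vote ties, mode ties in descriptive
  pooling, silhouette argmax ties in `scan_k`.
* All randomness flows from explicit integer seeds; per-imputation
  streams derive from (seed, table index), so results are reproducible
  and invariant to the order in which stages are rerun.
* Representative frequency vectors are validated to sum to 1 within
  1e-9; the clustering objective is recomputable from labels and
  representatives and the two agree within 1e-9 in the tests.
* Degenerate inputs fail loudly: missing cells in distance
  computations, registers with gaps, composites with partially missing
  sources, single-cluster silhouettes, zero-event Fine-Gray targets.

## 9. Problem sizes

The shipped profiles are chosen for interactive use: the `test` profile
runs n = 2000, m = 3; the analysis scripts run n = 5000, m = 5; recovery
and coverage checks in the test suite use n = 5000–20000 with 10–20
seeds or replicates. The `paper_scale` profile (n = 63060, m = 100,
k-scan 2–10) reproduces the design-scale configuration. Estimator
properties (bias of planted log-HRs, CI coverage, cluster recovery in
the strong-separation regime) are asserted at the smaller sizes with
tolerances matched to their Monte-Carlo error.

## 10. Known limitations

* Conditional independence of symptom items given cluster is optimistic;
  with the correlation knob on, cluster recovery degrades and no claim
  is made about it.
* The Charlson map is the classical one, not the (non-public) Swedish
  register adaptation; scores shift if the true adaptation differs.
* The silhouette is the only internal validity metric implemented;
  cluster-count choice on real data should combine it with
  subject-matter review, as the advisory-only design intends.
* Cause-of-death misclassification and primary-care (non-specialist)
  comorbidity are out of scope by design.
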