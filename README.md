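# respclust

Respiratory-symptom clustering and mortality analysis for mixed
binary/ordinal questionnaire data.

## The problem

Population surveys of respiratory health collect dozens of binary symptom
items (wheezing, dyspnea, coughing, night-time and nasal symptoms) plus a
few ordinal composites graded by chronicity or severity. Latent symptom
phenotypes in such data — identified *without* requiring a prior diagnosis —
can then be linked to register outcomes: specialist-care comorbidity
(Charlson index from ICD-10 codes) and cause-specific mortality. This
package implements that full analysis chain for epidemiologists working
with survey + register linkages:

1. **Schema-typed cohort tables** (`read_cohort`, `build_composites`,
   `count_symptoms`, `eligibility_split`) — binary/ordinal/nominal/continuous
   variables with symptom / background / register roles.
2. **Multiple imputation** (`mice_rf`, `pool_descriptive`) — chained
   equations with random-forest conditionals over the survey variables;
   register variables are never imputed.
3. **Clustering** (`lshkp_fit`, `scan_k`, `silhouette_mixed`) — an
   LSH-initialised k-representatives algorithm for mixed binary/ordinal
   attributes, run on subjects reporting at least one symptom.
4. **Consensus labels** (`align_labels`, `majority_vote`) — optimal label
   alignment across imputations and a deterministic majority vote.
5. **Comorbidity** (`compute_cci`, `cci_category`, `flag_asthma_copd`) —
   modified Charlson index (asthma and COPD excluded, adjusted for
   individually) with an 11-year lookback.
6. **Mortality** (`fit_cox`, `fit_fine_gray`, `rubin_pool`,
   `run_mortality_analysis`, `km_curve`, `check_proportionality`) —
   per-imputation Cox and Fine-Gray models against the asymptomatic
   reference, Rubin-pooled, guarded by a ≥10 events-per-covariate rule.
7. **Synthetic cohorts** (`generate_cohort`, `generate_survival`,
   `inject_missingness`, `generate_icd_histories`) — a generator with
   planted symptom clusters, configurable covariate marginals, survey
   missingness and competing-risks survival, so the whole pipeline is
   testable without access to individual-level register data.

## The core model

The clustering dissimilarity between a subject x and a cluster
representative R (one frequency vector f_j per attribute j) is

    d(x, R) = Σ_j w_j Σ_c f_jc d_j(x_j, c)

with d_j the mismatch indicator for binary/nominal attributes and the
normalised rank difference |rank(a) − rank(b)| / (L_j − 1) for an ordinal
attribute with L_j levels. Fitting alternates nearest-representative
assignment with frequency-vector updates, seeded from random-hyperplane
LSH buckets. Rubin's rules combine the m per-imputation log hazard
ratios: T = W + (1 + 1/m) B with W the mean within-imputation variance
and B the between-imputation variance.

## Worked example

```r
library(respclust)

cfg <- pipeline_config("test", seed = 1)   # n = 2000 subjects, m = 3
run <- run_pipeline(cfg, out_dir = "run1")

subset(run$mortality$results,
       outcome == "all_cause" & adjustment == "adjusted",
       c(cluster, hr, ci_low, ci_high))
```

```
  cluster        hr    ci_low   ci_high
 cluster1 0.9872793 0.8082895  1.205905
 cluster2 1.0361714 0.4004597  2.681047
 cluster3 1.4549323 0.6997280  3.025215
 cluster4 1.2038330 0.1139725 12.715474
 cluster5 1.3608298 0.9052505  2.045685
```

Each row is the Rubin-pooled hazard ratio (with 95% CI) for all-cause
mortality of one symptom cluster relative to the asymptomatic reference
group, adjusted for age, BMI, sex, smoking, cohort, occupational
exposure, education, SES, the modified Charlson category and the
asthma/COPD flags. The generator plants elevated hazards in all clusters
except cluster 2; at this test-profile sample size the point estimates
reflect that, while the intervals for the small clusters are wide —
cluster 4 (about 6% of subjects) also carries substantial
between-imputation variance because its membership shifts across the
m = 3 imputations. `run$mortality$skipped` lists every analysis withheld
by the events-per-covariate guard, with its reason.

The numbered scripts under `analysis/` run the same chain step by step
(simulate → impute → cluster → consensus → comorbidity → survival →
characterise) at n = 5000, m = 5, narrating what each stage found and
writing its tables under `results/`.

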