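# bcradiomics

MRI-radiomics analysis of biochemical recurrence (BCR) after radical
prostatectomy. The package implements, end to end, a workflow for asking
whether quantitative texture of the delineated tumor on pre-operative MRI
(T2-weighted and ADC volumes) predicts BCR — PSA rising above 0.2 ng/mL —
better than clinical covariates alone, and for evaluating that question on a
held-out testing side with survival methods. It is aimed at imaging
scientists who want a tested, reproducible reference implementation of this
class of pipeline, exercised on a fully synthetic cohort so that every stage
is verifiable without patient data.

## What it computes

**Wavelet filter bank.** Each volume is filtered by the coiflet-1 low (L) /
high (H) pass pair along the three axes of space without down-sampling
(stationary transform), producing eight sub-bands LLL…HHH aligned with the
tumor mask, plus the original: nine images per sequence.

**Texture features.** On each (sequence × sub-band × gray-level
discretization) combination, features of the gray-level size-zone matrix
(GLSZM), run-length matrix (GLRLM; 13 unique 3-D directions, merged) and
co-occurrence matrix (GLCM), plus first-order and shape descriptors. For a
GLSZM *s(i, j)* counting connected zones of gray level *i* and size *j*
(N_s zones in total):

    SZE   = (1/N_s) Σᵢⱼ s(i,j) / j²          small zone emphasis
    SZLGE = (1/N_s) Σᵢⱼ s(i,j) / (i²·j²)     small zone low gray-level emphasis
    HGRE  = (1/N_r) Σᵢⱼ i²·r(i,j)            high gray-level run emphasis (GLRLM)

**Harmonization, rebalancing, stability selection.** Features are z-scored
per scanner and per cohort side; the training side is rebalanced with SMOTE;
then the training table is sub-sampled 100 times (2:1, outcome-stratified)
and a feature variant is kept only if its absolute Pearson correlation with
BCR exceeds 0.3 in ≥ 95 of 100 subsamples. One variant per base feature
survives (highest mean |PC|), and survivors correlated above 0.7 are pruned.

**Survival evaluation.** Selected features and clinical covariates are
dichotomized at training-side Youden cutoffs; clinical-only, radiomics-only
and combined additive risk models are built on the training side (two-factor
combinations must beat the single anchor on a DeLong paired AUC test) and
evaluated on both sides via AUC, sensitivity/specificity, Kaplan–Meier
curves with the log-rank test, and Cox hazard ratios.

**Synthetic cohort.** `generate_cohort()` produces 107 patients (70/30
scanner mix, 16% event rate): ellipsoid tumor masks over Gaussian random
fields whose per-patient correlation length drives a Weibull
proportional-hazards outcome, clinical covariates with realistic marginals,
and per-scanner affine intensity distortions that the harmonization stage is
designed to remove.

## Worked example

```r
library(bcradiomics)

cohort <- generate_cohort(generator_config(seed = 1))
study  <- run_study(cohort, seed = 1)
study_report(study, cohort)
```

The report prints cohort characteristics by side, the univariate tables, the
selection summary and the model comparison. Abridged output from the run
above:

```
=== Feature selection ===
  1232 variant(s) analyzed, 49 SMOTE row(s) added, 10 selected
  ADC|ORIG|FBN16|GLSZM_SZE               mean |PC| 0.684 (100/100 subsamples)
  ADC|LLH|FBN32|GLCM_contrast            mean |PC| 0.596 (100/100 subsamples)
  ADC|LLH|FBN16|GLSZM_SZHGE              mean |PC| 0.592 (100/100 subsamples)
  ...
=== Model comparison ===
  clinical   factors: age
    train AUC 0.705  Se  73  Sp  68  logrank p 0.00645  HR 5.29
    test  AUC 0.783  Se  83  Sp  73  logrank p 0.00322  HR 13.34
  radiomics  factors: ADC|ORIG|FBN16|GLSZM_SZE
    train AUC 0.867  Se 100  Sp  73  logrank p 6.21e-07  HR 29.28
    test  AUC 0.883  Se 100  Sp  77  logrank p 0.000595  HR 16.05
  combined   factors: age + ADC|ORIG|FBN16|GLSZM_SZE
    train AUC 0.890  Se  73  Sp  92  logrank p 1.2e-07  HR 14.98
    test  AUC 0.944  Se  83  Sp  97  logrank p 7.22e-09  HR 54.96
```

Reading it: the stability step reduced 1,232 feature variants to 10, led by
small-zone emphasis (SZE) of the GLSZM on the unfiltered ADC image — the
construct that directly measures the zone fragmentation the generator links
to hazard. The radiomics-only model (that single dichotomized feature)
separates testing-side patients into risk groups with a hazard ratio of ~16
for biochemical relapse-free survival. On synthetic cohorts the planted
heterogeneity→hazard link is what the ADC texture features recover;
`cohort$truth` carries the latent parameters for verification.

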