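# methprog

Prognostic risk classification for non-metastatic clear cell renal cell
carcinoma (ccRCC) from genome-wide DNA methylation array data combined with
clinicopathological variables.

Roughly a quarter of ccRCC patients who are non-metastatic (M0) at diagnosis
progress to metastatic disease within five years of nephrectomy. Clinical
practice stratifies these patients with the Mayo (Leibovich) progression
score; `methprog` implements a pipeline that augments the clinical variables
with DNA methylation biomarkers to improve the specificity of that
stratification at a fixed, clinically motivated sensitivity. It is aimed at
biostatisticians and computational biologists working with Illumina
450K/EPIC-style β-value matrices and per-patient clinical tables.

## What the package computes

**Directed Cluster Analysis (DCA)** derives consensus methylation biomarkers
without using outcome labels:

1. For every CpG probe, the samples are split by *exact* one-dimensional
   2-means (the optimum is a sorted split, found by enumeration — no
   iterative relocation, no randomness). The group with the higher mean β is
   labeled 1, giving a binary profile vector per CpG.
2. CpGs whose smaller group holds < 10% of samples, or whose group means
   differ by < 0.20, are removed.
3. The surviving binary profiles are clustered with k-means (k = 40 at full
   scale), so CpGs that partition the cohort similarly share a cluster.
4. Each cluster yields a **consensus variable**: the per-sample mean β over
   its member CpGs — robust to single-CpG noise.

**Risk models.** Feature sets (12 clinical variables, 64 previously
identified prognostic CpGs, 40 DCA consensus variables, and their
combinations — the full combination is the *triple classifier*) are reduced
to five principal components (continuous features standardized,
categorical/ordinal features mean-centered) and fed to logistic regression
on 5-year progression. The posterior cutoff is then fixed so sensitivity is
at least 85%: with `n_pos` progressors the cutoff is the k-th largest
posterior among them, k = ⌈0.85 · n_pos⌉, and the reported figure of merit
is the specificity at that cutoff. A non-informative classifier evaluated
this way has expected specificity `(n_pos + 1 − k)/(n_pos + 1)` ≈ 19% for 20
progressors — the chance level every model must beat.

Around this core the package provides probe filtering (sex chromosomes,
multi-loci and SNP-proximal probes, EPIC-absent probes, detection p-value
and bead-count rules, promoter restriction, mQTL lists), Δβ calling against
tumor-free reference tissue (|Δβ| ≥ 0.2), global-hypomethylation outlier
flagging, clinical mean-imputation, the Mayo score, and the evaluation
battery: confusion metrics, chi-square (Yates for 2×2), Mann–Whitney U,
Cohen's κ, classifier-agreement dendrograms, ROC/AUC with DeLong
comparison, Kaplan–Meier cumulative incidence of progression
(pCIP\_5yr = 1 − S(60 months)) with log-rank tests, and a seeded
synthetic-cohort generator with planted cluster structure for end-to-end
testing without patient data.

## Worked example

```r
library(methprog)

cfg <- sim_config(n_tumor = 80, n_clusters = 4, probes_per_cluster = 25,
                  n_noise_probes = 300, alpha = -3.5, cluster_weights = c(3, 3, 2, 0))
sim <- simulate_cohort(cfg, seed = 42)

fit <- dca_fit(sim$tumors, pipeline_config(k = 4, seed = 42))
glance(fit)
#>   n_probes_in n_binarizable n_retained     k n_samples n_excluded_samples
#> 1         400           400        100     4        80                  0
```

All 100 planted cluster probes survive the prefilters while the 300
unimodal noise probes are removed; the 4 consensus variables are computed
for all 80 samples. Fitting the triple classifier:

```r
clin <- impute_clinical_means(sim$clinical)
features <- assemble_features(clin, pi_betas = sim$tumors, consensus = fit$consensus,
                              set_name = "triple", pi_cpg_ids = sim$pi_cpg_ids)
model <- fit_risk_model(features, clin$progress_event)
glance(model)
#>   set_name        n n_positive cutoff sensitivity specificity   auc
#> 1 clinical+pi+dca 80         28  0.426       0.857       0.865 0.947

mayo <- mayo_classify_cohort(clin)
confusion_metrics(mayo$mayo_call, clin$progress_event)
#>     tp    fp    tn    fn sensitivity specificity
#> 1   28    30    22     0           1       0.423
```

At ≥ 85% sensitivity the triple classifier reaches 86% specificity on this
cohort with strong planted methylation signal, versus 42% for the pooled
Mayo groups. The risk calls separate the survival curves:

```r
km <- km_cip(dplyr::mutate(clin, call = model$training$call),
             followup_months, progress_event, group = call)
tidy(km)
#>   group     n events   pcip
#> 1 HRP      31     24 0.774
#> 2 LRP      49      4 0.0816
km$logrank_p
#> 1.24e-11
```

i.e. a 77% vs 8% cumulative incidence of progression within five years in
the high- vs low-risk groups. `serialize_model()` /`deserialize_model()`
persist a fitted model as versioned JSON so new patients can be scored with
`predict()` without refitting; `autoplot()` methods draw the consensus
heatmap, the posterior distribution with its cutoff, and the cumulative
incidence curves.

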