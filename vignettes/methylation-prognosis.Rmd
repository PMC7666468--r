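---
title: "Methylation-based prognostic classification: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-based prognostic classification: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methprog)
```

# The problem

Among clear cell renal cell carcinoma (ccRCC) patients who are
non-metastatic (M0) at diagnosis, a substantial minority progress to
metastatic disease within five years of nephrectomy. Identifying them at
diagnosis matters: they are the candidates for intensified follow-up and
adjuvant therapy. The clinical standard is the Mayo (Leibovich) progression
score, built from T-stage, tumor size, N-stage, Fuhrman grade and necrosis.
`methprog` implements a pipeline that supplements those variables with DNA
methylation biomarkers — β-values from 450K/EPIC-style arrays, where β is
the methylated fraction of a CpG site in [0, 1] — and asks a sharply posed
question: *at a fixed, clinically acceptable sensitivity, how much
specificity can be gained?*

# Directed cluster analysis

DCA is an unsupervised biomarker construction. Its premise is that
prognostically relevant methylation changes affect coordinated groups of
promoter CpGs, and that the cohort splits into a hypermethylated and an
unmethylated subgroup at each such CpG.

1. **Binarization.** For each probe, samples are partitioned by 2-means on
   the single β dimension. The package computes this *exactly*: in one
   dimension the optimal 2-partition is a split of the sorted values, so
   enumerating the n − 1 sorted splits finds the global optimum
   deterministically. Iterative k-means would add a randomness source and
   can stall in local optima; the exact solver removes both concerns. Ties
   in the within-group sum of squares are broken toward the larger
   between-group mean difference (the stronger signal), then the earlier
   sorted split. Constant probes are non-binarizable and dropped. The
   higher-mean group is labeled 1, making the per-probe mean difference
   positive by construction, so the "absolute difference" filter below
   reduces to a plain threshold.
2. **Prefilters.** Probes with minority-group fraction below
   `min_group_fraction` (default 0.10) or group-mean difference below
   `min_mean_diff` (default 0.20 on the β scale) are removed. The removal
   conditions are strict "less than", so boundary probes (exactly 10%,
   exactly 0.20) are retained. These filters discard unimodal probes, whose
   2-means split reflects noise: under the generator's noise model more
   than 95% of unimodal probes fail them (verified in the test suite).
3. **Profile clustering.** The surviving binary profile vectors (probes as
   observations, samples as dimensions, squared Euclidean distance) are
   clustered with `stats::kmeans`, k = 40 at full scale, best of
   `n_restarts = 25` random starts under a fixed seed. The package uses the
   Hartigan–Wong algorithm: binary profiles contain many duplicated rows,
   on which Lloyd iterations frequently produce empty clusters, while
   Hartigan–Wong handles them robustly and stays deterministic given the
   seed. Cluster identifiers are renumbered in order of first appearance
   along the probe list so the labeling is reproducible.
4. **Consensus variables.** For each cluster and each sample the consensus
   variable is the mean β over member probes — by construction bounded by
   the member values and far less noisy than any single CpG. Consensus
   values are computed for *all* samples, including any excluded from
   fitting (below).

**Outlier handling.** Samples with an extreme number of hypomethylated
CpGs relative to tumor-free tissue (Δβ ≤ −0.2) would force heavily
unbalanced binarizations, so they are excluded from profile fitting and
reinstated when consensus variables are computed. The default rule flags a
sample whose hypo-CpG count exceeds median + 3 × IQR of all samples'
counts; the IQR is floored at one count so cohorts whose typical samples
have near-identical (often zero) counts do not degenerate into flagging
every sample with a single chance call. An absolute-count rule is available
(`outlier_rule = "absolute"`).

# Probe filtering and differential methylation

`filter_probes()` applies the standard array exclusions: sex-chromosome
probes; probes aligning to multiple loci; probes within 3 bp of a known
SNP; probes absent from the EPIC array; probes with detection p > 0.05 or
fewer than 3 beads in any sample (a probe with exactly 3 beads passes, the
exclusion being "fewer than 3"); non-promoter probes (outside TSS1500,
TSS200, 5'UTR, 1stExon — toggleable); and probes in user-supplied mQTL
catalogues (one ID per line, since published catalogues vary by version).
The exclusion report attributes each probe to the *first* failing rule in
that order; the retained set itself is order-independent. Detection
p-values and bead counts travel as optional probes-by-samples tables;
absent tables pass the rule with a logged message (array-level QC metadata
rarely accompanies shared β matrices, and never accompanies synthetic
data).

`call_dm_cpgs()` computes Δβ = β(tumor) − mean(β over tumor-free reference
samples) and calls a cell differentially methylated when |Δβ| ≥ 0.2
(`dm_threshold`), hyper- or hypomethylated by sign. The comparison carries
a 10⁻¹² float tolerance so exact boundary differences such as 0.40 − 0.60
are called despite binary floating point; zero deltas are never called.

# Risk models at fixed sensitivity

`assemble_features()` builds one of six feature sets: the 12
clinicopathological variables; the previously identified prognostic CpGs
(PI-CpGs, a user-supplied list, 64 at full scale); the 40 DCA consensus
variables; and the column concatenations clinical + PI-CpGs,
clinical + DCA, and the *triple* set (12 + 64 + 40 = 116 columns). Gender,
grade and TNM stage are coded as ordinal integers; one PCA is fitted per
feature set (not per block).

`fit_pca()` standardizes continuous columns and only mean-centers
categorical/ordinal ones — rescaling an ordinal code would give its
arbitrary unit the same weight as a standardized laboratory value — and
retains the first `n_components = 5` components. Each loading vector's
sign is fixed so its largest-magnitude element is positive, making the
serialized transform reproducible across platforms. A zero-variance
continuous column is an error naming the column.

`fit_risk_model()` fits maximum-likelihood logistic regression of the
5-year progression label on the five component scores. With five
predictors on cohorts of under a hundred patients, perfect separation is a
real possibility; on non-convergence or separation the package refits with
a tiny ridge penalty (10⁻⁶) and flags the model metadata. Evaluation is
in-sample (resubstitution) by default, matching the study design the
package reimplements; honest train/test evaluation is available simply by
fitting on a subset and calling `predict()` on the rest.

`choose_cutoff()` fixes the posterior cutoff at the target sensitivity
(default 0.85): with `n_pos` positives, the cutoff is the k-th largest
posterior among them, k = ⌈target · n_pos⌉, and a patient is called
high-risk (HRP) iff posterior ≥ cutoff. This is the largest threshold
meeting the target, so the returned specificity is maximal among
qualifying thresholds (verified against an exhaustive scan); with 20
positives at 85%, exactly 17 are called high-risk. Placing the cutoff *on*
the order statistic (rather than between adjacent values) keeps the
training call of the boundary patient stable under serialization at full
double precision (`digits = I(17)` in the JSON writer, which round-trips
doubles exactly).

## The chance level

What specificity would a non-informative classifier achieve under this
protocol? If scores are i.i.d. continuous and independent of the labels,
the cutoff is a uniform order statistic and
E[specificity] = (n_pos + 1 − k)/(n_pos + 1) — for 20 positives at 85%,
4/21 ≈ 19%. `chance_specificity()` returns this closed form alongside a
Monte-Carlo estimate, and also offers a `"refit"` convention that pushes
random Gaussian features through the full 5-PC logistic fit in-sample;
overfitting makes that variant *exceed* the closed form. An 11% chance
level has been reported for this protocol with an unstated simulation
design; since both conventions implemented here sit at or above 19%, the
package documents the discrepancy rather than treating 11% as a
reproducible quantity.

# The Mayo comparator

`mayo_score()` implements the Leibovich 2003 point table: T1a = 0,
T1b = 2, T2 = 3, T3–T4 = 4; tumor diameter ≥ 100 mm = 1; N1 = 2 (NX/N0 =
0); grade 1–2 = 0, grade 3 = 1, grade 4 = 3; necrosis = 1. Risk groups:
low 0–2, intermediate 3–5, high ≥ 6. A tumor of exactly 10 cm scores the
size point (the ≥ convention of the source system). Because intermediate-
and high-risk patients share a follow-up scheme, they are pooled into a
single high-risk analogue for comparison with the binary classifiers.
Score components are never imputed; a missing component is an error naming
the patients.

# Evaluation battery

Chi-square tests apply the Yates continuity correction for 2×2 tables and
none for larger ones; this matches the convention under which the
published gender comparisons (p = 0.888, 0.125, 0.139) reproduce, which is
how the package settled the choice. Mann–Whitney U uses the exact
distribution for tie-free samples of at most 20 per group and the
tie-corrected normal approximation otherwise. Cohen's κ = (p₀ − pₑ)/(1 −
pₑ) is computed from the 2×2 agreement table (degenerate margins with
perfect agreement give κ = 1; with disagreement they are an error).
Classifier agreement is summarized by the fraction of identical calls and
a dendrogram from average-linkage hierarchical clustering of the binary
call vectors under Euclidean distance (equal-height merges follow the
deterministic lowest-index convention of `stats::hclust`). ROC/AUC and the
DeLong paired comparison go through **pROC** with the score orientation
pinned (higher score = positive class); comparing a score vector with
itself returns p = 1 by convention rather than a 0/0 statistic.
Kaplan–Meier curves and log-rank tests go through **survival**, and
pCIP_5yr = 1 − S(60 months) with censoring at last follow-up.

# The synthetic-cohort generator

`simulate_cohort()` produces everything the pipeline consumes: tumor and
tumor-free β matrices, probe annotation, a clinical table with outcomes
and follow-up, a planted PI-CpG list, and the planted truth for scoring
recovery.

*Methylation.* Each planted cluster has a latent binary sample partition
whose minority fraction is drawn from [0.15, 0.45]; member probes draw β
from a beta distribution with mean 0.65 (methylated mode) for label-1
samples and 0.15 (unmethylated mode) for label-0 samples, concentration 80
(within-mode SD ≈ 0.05). Noise probes are unimodal around a per-probe mean
uniform in [0.2, 0.8]. Tumor-free reference samples (12, the size of a
typical reference panel) sit at the unmethylated mode on cluster probes
and at the per-probe mean on noise probes, so only planted biology is
differentially methylated. Optional outlier samples have all β multiplied
by 0.25, producing the global-hypomethylation signature the outlier rule
must catch. The beta-distribution parameterization respects the [0, 1]
support and the bimodality DCA assumes.

*Outcome.* Progression probability is plogis(α + Σ w_c z_c) on the latent
cluster labels — the generator's premise, mirroring the pipeline's, is
that the consensus variables carry the prognostic signal. Defaults
α = −2.6 and w = (1.5, 1.5, 1.0, 0, …) put the expected progressor
fraction near a quarter, the proportion seen in M0 cohorts with five-year
follow-up (20 of 78 in the calibration source). Progressors receive event
times uniform in (6, 59) months; non-progressors are censored beyond 60
months unless a censoring rate is configured. A null cohort is obtained
with zero weights, α = qlogis(20/78) and `clinical_group_effects = FALSE`.

*Clinical variables.* Continuous variables are drawn from zero-truncated
normals whose group-conditional means and SDs are the published cohort
summaries (e.g. hemoglobin 137.6 (17.3) g/L in non-progressors vs 121.1
(22.0) in progressors; tumor diameter 56.5 (31.2) vs 95.0 (44.8) mm; GGT
and ALP in µkat/L, calcium in mmol/L, creatinine in µmol/L). Grade and TNM
stage are sampled from the group-conditional count distributions; T-stage
is derived from TNM stage and diameter, nodal involvement occurs only in
stage III, and necrosis probability rises with grade, keeping the Mayo
components internally consistent. Variables are independent *given* the
group — the published marginals say nothing about their correlations.

## What the generator does not emulate

The independence-given-group assumption is the generator's most
consequential simplification. Real clinical variables are mutually
correlated, so the information in twelve of them is much less than twelve
independent group-shifted draws provide; on synthetic cohorts the
clinical-only classifier is therefore substantially *more* separable
in-sample than on real data, and the relative ordering of the six feature
sets — in particular the real-data finding that the triple classifier
tops the clinical one — should *not* be expected to reproduce on
synthetic cohorts and is not asserted by the test suite. What the tests do
establish is absolute, not relative: the DCA recovers planted probe
partitions (adjusted Rand index 1 in the default separable regime, over
ten seeds), planted outliers are recovered exactly, methylation
classifiers under planted signal far exceed the ≈19% chance level, and
with zero planted signal the held-out specificity matches the
order-statistic closed form. The generator also omits batch effects, probe
cross-hybridization structure, mQTL genotype structure and bead-level
noise; passing tests say nothing about robustness to those.

## The null-calibration protocol

In-sample posteriors from a 5-PC logistic fit are *not* independent of
the labels — overfitting lifts in-sample specificity above the chance
closed form even with pure noise features. The calibration therefore runs
the package's split path: DCA (unsupervised) on all samples, logistic fit
on one half, cutoff fixed at 85% sensitivity *on the held-out half*, and
specificity measured there. Under the null the held-out posteriors are
independent of the held-out labels, the cutoff is a uniform order
statistic, and E[specificity] = (n_pos + 1 − k)/(n_pos + 1) holds exactly
for the held-out class sizes; the suite checks agreement within
Monte-Carlo error over 50 seeds. Replicates whose halves contain fewer
than two patients of either class are skipped — a sensitivity target is
meaningless with one positive.

# Problem sizes and runtime choices

The full-scale configuration (100 tumors, 12 tumor-free samples, 6
clusters × 50 probes plus 2,000 noise probes) runs the complete pipeline
in about a second, and the property suite uses it for the cluster-recovery
checks; classifier-level replicate studies use a reduced cohort (80
tumors, 4 clusters × 15–25 probes, 100–300 noise probes) so that 50-seed
batteries finish in seconds. These sizes are the package's test design;
nothing in the methodology depends on them, and `sim_config()` scales all
of them.

# Known limitations

* Resubstitution evaluation overstates absolute performance; the fixed
  85% sensitivity is a training constraint, not a generalization
  guarantee. Use the split path for honest estimates.
* κ confidence intervals, competing-risk (Fine–Gray) estimation and
  multivariable Cox modeling are out of scope.
* The Mayo point table follows the published Leibovich 2003 system; sites
  using local variants must supply their own scoring.
* The PI-CpG list is an input; the package does not curate literature
  CpGs.
* Raw IDAT parsing, BMIQ/between-bead-type normalization and array QC are
  upstream of this package: the β matrix is assumed normalized.
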