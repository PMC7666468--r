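#' Synthetic-cohort configuration
#'
#' Parameters of the seeded generator that emulates the statistical
#' structure the analysis assumes: bimodal CpG clusters shared by latent
#' sample subgroups, unimodal noise probes, tumor-free reference samples
#' sitting at the unmethylated mode, optional globally hypomethylated
#' outlier samples, clinical variables calibrated group-wise to the
#' published cohort summaries, and a logistic outcome model linked to the
#' latent cluster labels.
#'
#' @param n_tumor Number of tumor samples (default 100).
#' @param n_tumor_free Number of tumor-free reference samples (default 12,
#'   the reference panel size of the study design emulated).
#' @param n_clusters Number of planted CpG clusters (default 6; the
#'   full-scale analysis uses 40).
#' @param probes_per_cluster Member probes per planted cluster (default 50).
#' @param n_noise_probes Unimodal noise probes (default 2000).
#' @param methylated_mode_mean,unmethylated_mode_mean Beta-scale means of
#'   the two modes (defaults 0.65 / 0.15, separation 0.5).
#' @param mode_concentration Beta-distribution precision (shape1 + shape2);
#'   higher is tighter around the mode (default 80, within-mode sd about
#'   0.05).
#' @param minority_fraction_range Range the latent minority-group fraction
#'   of each cluster is drawn from (default \[0.15, 0.45\]).
#' @param alpha Intercept of the logistic outcome model (default -2.6).
#' @param cluster_weights Per-cluster log-odds weights of the outcome
#'   model; default 1.5, 1.5, 1.0 on the first three clusters, 0 elsewhere.
#'   Set all zero (with `alpha = qlogis(20/78)`) for a null cohort.
#' @param clinical_group_effects When `FALSE`, clinical variables are drawn
#'   from the progression-free distributions for everyone (null clinical
#'   signal).
#' @param n_outlier_samples Globally hypomethylated outlier samples
#'   (default 0).
#' @param censoring_rate Fraction of non-progressors censored before 60
#'   months (default 0).
#' @param n_pi_cpgs Number of planted-cluster probes exported as the
#'   "previously identified" prognostic CpG list (default 64).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tumor = 100, n_tumor_free = 12, n_clusters = 6,
                       probes_per_cluster = 50, n_noise_probes = 2000,
                       methylated_mode_mean = 0.65,
                       unmethylated_mode_mean = 0.15,
                       mode_concentration = 80,
                       minority_fraction_range = c(0.15, 0.45),
                       alpha = -2.6, cluster_weights = NULL,
                       clinical_group_effects = TRUE,
                       n_outlier_samples = 0, censoring_rate = 0,
                       n_pi_cpgs = 64) {
  if (methylated_mode_mean <= unmethylated_mode_mean) {
    abort("Methylated mode mean must exceed the unmethylated mode mean.")
  }
  if (any(c(methylated_mode_mean, unmethylated_mode_mean) <= 0) ||
      any(c(methylated_mode_mean, unmethylated_mode_mean) >= 1)) {
    abort("Mode means must lie in (0, 1).")
  }
  if (minority_fraction_range[1] <= 0 || minority_fraction_range[2] > 0.5 ||
      minority_fraction_range[1] > minority_fraction_range[2]) {
    abort("`minority_fraction_range` must lie within (0, 0.5].")
  }
  if (is.null(cluster_weights)) {
    cluster_weights <- rep(0, n_clusters)
    cluster_weights[seq_len(min(3, n_clusters))] <-
      c(1.5, 1.5, 1.0)[seq_len(min(3, n_clusters))]
  }
  if (length(cluster_weights) != n_clusters) {
    abort("`cluster_weights` must have one weight per cluster.")
  }
  structure(
    list(
      n_tumor = as.integer(n_tumor), n_tumor_free = as.integer(n_tumor_free),
      n_clusters = as.integer(n_clusters),
      probes_per_cluster = as.integer(probes_per_cluster),
      n_noise_probes = as.integer(n_noise_probes),
      methylated_mode_mean = methylated_mode_mean,
      unmethylated_mode_mean = unmethylated_mode_mean,
      mode_concentration = mode_concentration,
      minority_fraction_range = minority_fraction_range,
      alpha = alpha, cluster_weights = cluster_weights,
      clinical_group_effects = clinical_group_effects,
      n_outlier_samples = as.integer(n_outlier_samples),
      censoring_rate = censoring_rate,
      n_pi_cpgs = as.integer(n_pi_cpgs)
    ),
    class = "sim_config"
  )
}

rbeta_mode <- function(n, mu, conc) {
  rbeta(n, shape1 = mu * conc, shape2 = (1 - mu) * conc)
}

sim_methylation_impl <- function(cfg) {
  n <- cfg$n_tumor
  tumor_ids <- sprintf("T%03d", seq_len(n))
  tf_ids <- sprintf("TF%02d", seq_len(cfg$n_tumor_free))
  n_cluster_probes <- cfg$n_clusters * cfg$probes_per_cluster
  n_probes <- n_cluster_probes + cfg$n_noise_probes
  probe_ids <- sprintf("cg%08d", seq_len(n_probes))

  z <- matrix(0L, n, cfg$n_clusters,
              dimnames = list(tumor_ids, sprintf("cluster_%d", seq_len(cfg$n_clusters))))
  minority_fraction <- numeric(cfg$n_clusters)
  tumors <- matrix(NA_real_, n_probes, n, dimnames = list(probe_ids, tumor_ids))
  tf <- matrix(NA_real_, n_probes, cfg$n_tumor_free,
               dimnames = list(probe_ids, tf_ids))

  for (c_ in seq_len(cfg$n_clusters)) {
    f <- runif(1, cfg$minority_fraction_range[1], cfg$minority_fraction_range[2])
    m <- max(1L, round(f * n))
    members <- sample(n, m)
    z[members, c_] <- 1L
    minority_fraction[c_] <- m / n
    rows <- (c_ - 1) * cfg$probes_per_cluster + seq_len(cfg$probes_per_cluster)
    for (r in rows) {
      v <- numeric(n)
      v[z[, c_] == 1L] <- rbeta_mode(m, cfg$methylated_mode_mean, cfg$mode_concentration)
      v[z[, c_] == 0L] <- rbeta_mode(n - m, cfg$unmethylated_mode_mean, cfg$mode_concentration)
      tumors[r, ] <- v
      tf[r, ] <- rbeta_mode(cfg$n_tumor_free, cfg$unmethylated_mode_mean,
                            cfg$mode_concentration)
    }
  }
  if (cfg$n_noise_probes > 0) {
    noise_rows <- n_cluster_probes + seq_len(cfg$n_noise_probes)
    mu <- runif(cfg$n_noise_probes, 0.2, 0.8)
    for (i in seq_len(cfg$n_noise_probes)) {
      r <- noise_rows[i]
      tumors[r, ] <- rbeta_mode(n, mu[i], cfg$mode_concentration)
      tf[r, ] <- rbeta_mode(cfg$n_tumor_free, mu[i], cfg$mode_concentration)
    }
  }

  outlier_ids <- character()
  if (cfg$n_outlier_samples > 0) {
    outlier_ids <- sample(tumor_ids, cfg$n_outlier_samples)
    tumors[, outlier_ids] <- tumors[, outlier_ids, drop = FALSE] * 0.25
  }

  annotation <- tibble::tibble(
    probe_id = probe_ids,
    chromosome = as.character(rep_len(1:22, n_probes)),
    region_label = "TSS200",
    flag_multi_loci = FALSE, flag_snp_within_3bp = FALSE,
    flag_absent_on_epic = FALSE, flag_mqtl = FALSE
  )
  truth <- list(
    probe_cluster = tibble::tibble(
      probe_id = probe_ids,
      cluster = c(rep(seq_len(cfg$n_clusters), each = cfg$probes_per_cluster),
                  rep(0L, cfg$n_noise_probes))
    ),
    sample_labels = z,
    minority_fraction = minority_fraction,
    outlier_ids = outlier_ids
  )
  list(tumors = matrix_to_beta_tbl(tumors), tumor_free = matrix_to_beta_tbl(tf),
       annotation = annotation, truth = truth)
}

#' Simulate a methylation matrix with planted cluster structure
#'
#' Generates tumor and tumor-free beta matrices: each planted cluster has a
#' latent binary sample partition (minority fraction drawn from the
#' configured range) and its member probes draw beta values from a beta
#' distribution around the methylated mode for label-1 samples and the
#' unmethylated mode for label-0 samples; noise probes are unimodal around
#' a per-probe random mean; tumor-free reference samples sit at the
#' unmethylated mode on cluster probes and at the noise probes' own means;
#' optional outlier samples are globally shifted toward zero. The
#' annotation marks every probe autosomal, promoter-region and flag-free.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `tumors`, `tumor_free` (probes-by-samples beta
#'   tibbles), `annotation`, and `truth` (planted probe partition, latent
#'   sample labels, minority fractions, outlier IDs).
#' @export
simulate_methylation <- function(cfg = sim_config(), seed = 1L) {
  withr::with_seed(as.integer(seed), sim_methylation_impl(cfg))
}

# Group-conditional clinical parameters: published cohort means/SDs for
# progression-free (pf) vs progressing (p) non-metastatic patients.
clinical_calibration <- function() {
  list(
    continuous = tibble::tibble(
      variable = c("age", "albumin", "alkaline_phosphatase", "calcium",
                   "creatinine", "ggt", "hemoglobin", "thrombocyte_count",
                   "tumor_diameter"),
      mean_pf = c(65.6, 40.6, 1.9, 2.35, 79.6, 0.76, 137.6, 251.7, 56.5),
      sd_pf = c(11.6, 4.1, 2.0, 0.14, 16.3, 1.17, 17.3, 77.7, 31.2),
      mean_p = c(64.2, 38.6, 2.2, 2.32, 86.0, 0.83, 121.1, 316.5, 95.0),
      sd_p = c(11.9, 7.2, 1.5, 0.13, 32.4, 1.21, 22.0, 175.4, 44.8)
    ),
    male_prob = c(pf = 32 / 58, p = 10 / 20),
    grade_prob = list(pf = c(12, 30, 15, 1) / 58, p = c(1, 6, 8, 5) / 20),
    tnm_prob = list(pf = c(39, 10, 9) / 58, p = c(5, 2, 13) / 20)
  )
}

sim_clinical_impl <- function(cfg, groups, patient_ids = NULL) {
  groups <- as.logical(groups)
  if (anyNA(groups)) abort("`groups` must be logical progress indicators.")
  n <- length(groups)
  ids <- patient_ids %||% sprintf("T%03d", seq_len(n))
  cal <- clinical_calibration()
  use_p <- groups & cfg$clinical_group_effects

  draw_trunc <- function(mu, sigma) {
    x <- rnorm(length(mu), mu, sigma)
    while (any(x < 0)) {
      i <- x < 0
      x[i] <- rnorm(sum(i), mu[i], sigma[i])
    }
    x
  }
  cont <- cal$continuous
  vals <- lapply(seq_len(nrow(cont)), function(i) {
    mu <- ifelse(use_p, cont$mean_p[i], cont$mean_pf[i])
    sigma <- ifelse(use_p, cont$sd_p[i], cont$sd_pf[i])
    draw_trunc(mu, sigma)
  })
  names(vals) <- cont$variable

  gender <- ifelse(runif(n) < ifelse(use_p, cal$male_prob["p"], cal$male_prob["pf"]),
                   "M", "F")
  grade <- vapply(use_p, function(p) {
    sample(1:4, 1, prob = if (p) cal$grade_prob$p else cal$grade_prob$pf)
  }, integer(1))
  tnm <- vapply(use_p, function(p) {
    sample(1:3, 1, prob = if (p) cal$tnm_prob$p else cal$tnm_prob$pf)
  }, integer(1))
  diameter <- vals$tumor_diameter
  t_stage <- ifelse(tnm == 1, ifelse(diameter <= 40, "T1a", "T1b"),
                    ifelse(tnm == 2, "T2",
                           ifelse(runif(n) < 0.1, "T4", "T3")))
  n_stage <- ifelse(tnm == 3 & runif(n) < 0.15, "N1", "N0")
  necrosis <- runif(n) < c(0.10, 0.25, 0.50, 0.80)[grade]

  as_clinical_table(dplyr::bind_cols(
    tibble::tibble(patient_id = ids, gender = gender,
                   morphological_grade = grade, tnm_stage = tnm,
                   t_stage = t_stage, n_stage = n_stage, necrosis = necrosis,
                   m_stage_at_dx = "M0"),
    tibble::as_tibble(vals)
  ))
}

#' Simulate clinical variables calibrated to the cohort summaries
#'
#' Continuous variables are drawn from zero-truncated normal distributions
#' whose group-specific means and SDs default to the published cohort's
#' values (e.g. hemoglobin 137.6 (17.3) g/L in non-progressors vs 121.1
#' (22.0) in progressors; tumor diameter 56.5 (31.2) vs 95.0 (44.8) mm);
#' grade and TNM stage are sampled from the group-specific count
#' distributions; Mayo components are derived consistently (T-stage from
#' TNM stage and diameter, nodal involvement only in stage III, necrosis
#' probability increasing with grade). Variables are independent given the
#' group.
#'
#' @param cfg A [sim_config()]; `clinical_group_effects = FALSE` gives
#'   every patient the progression-free distributions.
#' @param seed Integer seed.
#' @param groups Logical vector: will the patient progress within 5 years.
#' @param patient_ids Optional IDs (default `T001`, `T002`, ...).
#' @return A clinical tibble (without follow-up columns).
#' @export
simulate_clinical <- function(cfg = sim_config(), seed = 1L, groups,
                              patient_ids = NULL) {
  withr::with_seed(as.integer(seed), sim_clinical_impl(cfg, groups, patient_ids))
}

#' Simulate a complete cohort
#'
#' Generates everything the pipeline consumes end-to-end: the methylation
#' matrices with planted clusters, an outcome for every tumor sample from
#' the logistic model progress probability = plogis(alpha + sum w_c z_c)
#' on the latent cluster labels z_c, follow-up times (events within 60
#' months for progressors, censoring beyond 60 months otherwise unless a
#' censoring rate is set), clinical variables conditioned on the realized
#' outcome, and a planted "previously identified CpG" list drawn from the
#' cluster member probes.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param max_attempts Outcome redraws allowed before a degenerate (single
#'   class) configuration is an error.
#' @return List with `tumors`, `tumor_free`, `annotation`, `clinical`
#'   (including `progress_event` and `followup_months`), `pi_cpg_ids` and
#'   `truth` (planted partitions, latent labels, outcome probabilities,
#'   outlier IDs).
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1L, max_attempts = 25L) {
  withr::with_seed(as.integer(seed), {
    meth <- sim_methylation_impl(cfg)
    z <- meth$truth$sample_labels
    eta <- cfg$alpha + as.numeric(z %*% cfg$cluster_weights)
    p <- plogis(eta)
    progress <- NULL
    for (attempt in seq_len(max_attempts)) {
      cand <- runif(length(p)) < p
      if (length(unique(cand)) == 2) { progress <- cand; break }
    }
    if (is.null(progress)) {
      abort("Outcome model produced a single class in every attempt; adjust `alpha`.")
    }
    n <- length(progress)
    followup <- numeric(n)
    event <- logical(n)
    followup[progress] <- runif(sum(progress), 6, 59)
    event[progress] <- TRUE
    followup[!progress] <- 60 + rexp(sum(!progress), rate = 1 / 36)
    if (cfg$censoring_rate > 0) {
      cens <- !progress & runif(n) < cfg$censoring_rate
      followup[cens] <- runif(sum(cens), 1, 59)
    }
    clinical <- sim_clinical_impl(cfg, progress,
                                  patient_ids = beta_sample_ids(meth$tumors))
    clinical$progress_event <- event
    clinical$followup_months <- followup
    member_probes <- meth$truth$probe_cluster$probe_id[meth$truth$probe_cluster$cluster > 0]
    pi_cpg_ids <- sample(member_probes, min(cfg$n_pi_cpgs, length(member_probes)))
    meth$truth$outcome_probability <- p
    meth$truth$progress <- progress
    list(
      tumors = meth$tumors, tumor_free = meth$tumor_free,
      annotation = meth$annotation, clinical = clinical,
      pi_cpg_ids = pi_cpg_ids, truth = meth$truth
    )
  })
}
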