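#' Filter array probes
#'
#' Applies the standard 450K-style probe exclusions: sex-chromosome probes,
#' probes aligning to multiple loci, probes within 3 bp of a known SNP,
#' probes absent from the EPIC array, probes with a detection p-value above
#' 0.05 or fewer than 3 beads in any sample, probes outside the promoter
#' region (TSS1500, TSS200, 5'UTR, 1stExon; toggleable), and probes in
#' supplied mQTL catalogues. A probe is retained only if it passes every
#' rule; the report attributes each exclusion to the first failing rule in
#' the order listed, so the counts are reproducible bookkeeping while the
#' retained set itself is order-independent.
#'
#' @param betas Probes-by-samples beta tibble.
#' @param ann Probe annotation (see [read_probe_annotation()]); every probe
#'   in `betas` must be annotated.
#' @param cfg A [pipeline_config()]; `restrict_promoter` toggles the
#'   promoter-region rule.
#' @param detection_p Optional probes-by-samples tibble of detection
#'   p-values (same layout as `betas`). When `NULL` the rule passes, with a
#'   message.
#' @param nbeads Optional probes-by-samples tibble of bead counts. When
#'   `NULL` the rule passes, with a message. Probes with exactly 3 beads are
#'   retained (the exclusion is "fewer than 3").
#' @param mqtl_ids Character vector of mQTL probe IDs to exclude, in
#'   addition to any `flag_mqtl` column in the annotation.
#' @param detection_p_max Detection p-value ceiling (default 0.05).
#' @param nbeads_min Minimum bead count (default 3).
#' @return A list with `betas` (the retained probes) and `report`, a tibble
#'   of per-rule exclusion counts plus the retained count.
#' @export
filter_probes <- function(betas, ann, cfg = pipeline_config(),
                          detection_p = NULL, nbeads = NULL,
                          mqtl_ids = character(),
                          detection_p_max = 0.05, nbeads_min = 3) {
  validate_beta_tbl(betas)
  ann <- validate_annotation(ann)
  probes <- betas$probe_id
  unann <- setdiff(probes, ann$probe_id)
  if (length(unann) > 0) {
    abort(sprintf("Probe(s) missing from annotation: %s%s",
                  paste(head(unann, 5), collapse = ", "),
                  if (length(unann) > 5) ", ..." else ""))
  }
  ann <- ann[match(probes, ann$probe_id), ]

  fail_detp <- rep(FALSE, length(probes))
  if (is.null(detection_p)) {
    inform("No detection p-values supplied; detection-p rule passes for all probes.")
  } else {
    dp <- beta_like_aligned(detection_p, probes, "detection_p")
    fail_detp <- apply(dp, 1, function(r) any(!is.na(r) & r > detection_p_max))
  }
  fail_beads <- rep(FALSE, length(probes))
  if (is.null(nbeads)) {
    inform("No bead counts supplied; bead-count rule passes for all probes.")
  } else {
    nb <- beta_like_aligned(nbeads, probes, "nbeads")
    fail_beads <- apply(nb, 1, function(r) any(!is.na(r) & r < nbeads_min))
  }

  promoter_regions <- c("TSS1500", "TSS200", "5'UTR", "1stExon")
  rules <- list(
    sex_chromosome   = ann$chromosome %in% c("X", "Y"),
    multi_loci       = ann$flag_multi_loci,
    snp_within_3bp   = ann$flag_snp_within_3bp,
    absent_on_epic   = ann$flag_absent_on_epic,
    detection_p      = fail_detp,
    low_bead_count   = fail_beads,
    non_promoter     = if (isTRUE(cfg$restrict_promoter)) {
      !(ann$region_label %in% promoter_regions)
    } else rep(FALSE, length(probes)),
    mqtl             = ann$flag_mqtl | probes %in% mqtl_ids
  )

  excluded_by <- rep(NA_character_, length(probes))
  for (rule in names(rules)) {
    hit <- rules[[rule]] & is.na(excluded_by)
    excluded_by[hit] <- rule
  }
  keep <- is.na(excluded_by)
  report <- tibble::tibble(
    rule = c(names(rules), "retained"),
    n = c(unname(vapply(names(rules),
                        function(r) sum(excluded_by == r, na.rm = TRUE), integer(1))),
          sum(keep))
  )
  list(betas = betas[keep, , drop = FALSE], report = report)
}

beta_like_aligned <- function(tbl, probes, what) {
  if (!is.data.frame(tbl) || !"probe_id" %in% names(tbl)) {
    abort(sprintf("`%s` must be a probes-by-samples tibble with a `probe_id` column.", what))
  }
  if (!all(probes %in% tbl$probe_id)) {
    abort(sprintf("`%s` does not cover every probe in the beta matrix.", what))
  }
  m <- as.matrix(tbl[match(probes, tbl$probe_id), setdiff(names(tbl), "probe_id")])
  storage.mode(m) <- "double"
  rownames(m) <- probes
  m
}

#' Call differentially methylated CpGs against tumor-free reference
#'
#' For each tumor sample and probe, computes delta-beta = beta(tumor) -
#' mean(beta over the tumor-free reference samples) and flags the cell as
#' hypermethylated when delta >= `threshold`, hypomethylated when
#' delta <= -`threshold` (boundaries inclusive: the call is
#' |delta-beta| >= threshold), and unflagged otherwise.
#'
#' @param tumors Probes-by-samples beta tibble for tumor samples.
#' @param tumor_free Probes-by-samples beta tibble for tumor-free reference
#'   samples; probe sets must be identical.
#' @param threshold Absolute delta-beta at or above which a cell is a
#'   differentially methylated CpG (default 0.20).
#' @return A list of class `dm_calls` with `delta` (probes-by-samples tibble
#'   of delta-beta), `flags` (same layout, values `"hyper"`, `"hypo"`,
#'   `"none"`), `tf_mean` (per-probe reference mean) and `threshold`.
#' @export
call_dm_cpgs <- function(tumors, tumor_free, threshold = 0.20) {
  validate_beta_tbl(tumors, "tumors")
  validate_beta_tbl(tumor_free, "tumor_free")
  if (!setequal(tumors$probe_id, tumor_free$probe_id)) {
    abort("Tumor and tumor-free matrices must cover identical probe sets.")
  }
  if (length(beta_sample_ids(tumor_free)) < 1) abort("Need at least one tumor-free sample.")
  tf <- beta_values(tumor_free)[tumors$probe_id, , drop = FALSE]
  tf_mean <- rowMeans(tf, na.rm = TRUE)
  tm <- beta_values(tumors)
  delta <- tm - tf_mean
  # the |delta| >= threshold comparison carries a float tolerance so exact
  # boundary differences (e.g. 0.40 - 0.60) are called; zero deltas never are
  tol <- 1e-12
  is_dm <- !is.na(delta) & abs(delta) >= threshold - tol & delta != 0
  flags <- matrix("none", nrow(delta), ncol(delta), dimnames = dimnames(delta))
  flags[is_dm & delta > 0] <- "hyper"
  flags[is_dm & delta < 0] <- "hypo"
  flags[is.na(delta)] <- NA_character_
  structure(
    list(
      delta = matrix_to_beta_tbl(delta),
      flags = dplyr::bind_cols(tibble::tibble(probe_id = rownames(flags)),
                               tibble::as_tibble(flags, .name_repair = "minimal")),
      tf_mean = tibble::tibble(probe_id = names(tf_mean), tf_mean = unname(tf_mean)),
      threshold = threshold
    ),
    class = "dm_calls"
  )
}

#' Flag global hypomethylation outlier samples
#'
#' Samples with an extreme number of hypomethylated CpGs (delta-beta at or
#' below minus the threshold) destabilize the binarization step of the
#' directed cluster analysis and are excluded from fitting, then reinstated
#' when the consensus variables are computed. The default rule flags a
#' sample whose hypomethylated-CpG count exceeds
#' median + `outlier_multiplier` * IQR of all samples' counts; an absolute
#' count threshold is available instead.
#'
#' @param dm A `dm_calls` object from [call_dm_cpgs()].
#' @param cfg A [pipeline_config()]; fields `outlier_rule`,
#'   `outlier_multiplier`, `outlier_count` control the rule.
#' @return A tibble with `sample_id`, `n_hypo` and logical `outlier`.
#' @export
flag_hypomethylation_outliers <- function(dm, cfg = pipeline_config()) {
  if (!inherits(dm, "dm_calls")) abort("`dm` must come from call_dm_cpgs().")
  fl <- as.matrix(dm$flags[setdiff(names(dm$flags), "probe_id")])
  if (nrow(fl) == 0 || ncol(fl) == 0) abort("Empty delta-beta matrix.")
  n_hypo <- colSums(fl == "hypo", na.rm = TRUE)
  if (cfg$outlier_rule == "absolute") {
    if (is.null(cfg$outlier_count)) abort("`outlier_count` must be set for the absolute rule.")
    cut <- cfg$outlier_count
  } else {
    # the IQR is floored at 1 count so cohorts whose typical samples have
    # near-identical (often zero) hypomethylation counts do not degenerate
    # into flagging every sample with a single chance call
    cut <- median(n_hypo) + cfg$outlier_multiplier * max(stats::IQR(n_hypo), 1)
  }
  tibble::tibble(
    sample_id = colnames(fl),
    n_hypo = as.integer(n_hypo),
    outlier = n_hypo > cut
  )
}

#' Impute missing clinical values by the mean
#'
#' Continuous clinical variables with missing entries are filled with the
#' training-cohort mean, or with externally supplied reference means (as
#' when scoring a new patient with a previously fitted model, whose stored
#' means travel with it).
#'
#' @param tbl Clinical tibble.
#' @param reference_means Optional named numeric vector of per-variable
#'   means; defaults to the column means of `tbl`.
#' @param variables Variables eligible for imputation; defaults to the
#'   continuous clinical features.
#' @return The clinical tibble with missing continuous entries filled; an
#'   `imputed` attribute records a tibble of patient/variable pairs that
#'   were filled.
#' @export
impute_clinical_means <- function(tbl, reference_means = NULL,
                                  variables = NULL) {
  kinds <- clinical_feature_kinds()
  if (is.null(variables)) {
    variables <- names(kinds)[kinds == "continuous"]
  }
  variables <- intersect(variables, names(tbl))
  filled <- list()
  for (v in variables) {
    x <- tbl[[v]]
    if (!anyNA(x)) next
    mu <- if (!is.null(reference_means) && v %in% names(reference_means)) {
      reference_means[[v]]
    } else if (any(!is.na(x))) {
      mean(x, na.rm = TRUE)
    } else {
      abort(sprintf("`%s` is entirely missing and no reference mean was supplied.", v))
    }
    idx <- which(is.na(x))
    filled[[v]] <- tibble::tibble(patient_id = tbl$patient_id[idx], variable = v)
    x[idx] <- mu
    tbl[[v]] <- x
  }
  attr(tbl, "imputed") <- if (length(filled)) dplyr::bind_rows(filled) else
    tibble::tibble(patient_id = character(), variable = character())
  tbl
}
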