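#' Read a beta-value matrix
#'
#' Reads a delimited text file of methylation beta values (fraction
#' methylated, in \[0, 1\]) into the package's canonical layout: a tibble
#' with a `probe_id` column followed by one numeric column per sample.
#' Files may store probes as rows (canonical) or samples as rows; the
#' `orientation` flag declares which, and the result is always
#' probes-by-samples.
#'
#' Empty cells and the token `NA` are read as missing. Any non-missing value
#' outside \[0, 1\] and any duplicated probe or sample identifier is a
#' validation error naming the offending cell or identifier.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param orientation `"probes_by_samples"` (rows are probes; default) or
#'   `"samples_by_probes"` (rows are samples).
#' @param delim Field delimiter, tab by default.
#' @return A tibble: `probe_id` plus one column per sample.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_beta_matrix(
#'   tibble::tibble(probe_id = c("cg01", "cg02"), S1 = c(0.1, 0.9), S2 = c(0.5, 0.2)), f
#' )
#' read_beta_matrix(f)
#' @export
read_beta_matrix <- function(path,
                             orientation = c("probes_by_samples", "samples_by_probes"),
                             delim = "\t") {
  orientation <- match.arg(orientation)
  raw <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                           show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2) abort("Beta matrix file needs an ID column plus at least one value column.")
  ids <- as.character(raw[[1]])
  vals <- as.matrix(raw[-1])
  storage.mode(vals) <- "double"
  if (orientation == "samples_by_probes") {
    vals <- t(vals)
    tbl <- tibble::tibble(probe_id = colnames(raw)[-1])
    tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(vals, .name_repair = "minimal"))
    names(tbl)[-1] <- ids
  } else {
    tbl <- dplyr::bind_cols(tibble::tibble(probe_id = ids),
                            tibble::as_tibble(vals, .name_repair = "minimal"))
  }
  validate_beta_tbl(tbl)
  tbl
}

#' Write a beta-value matrix
#'
#' @param betas A probes-by-samples beta tibble as returned by
#'   [read_beta_matrix()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(betas, path, delim = "\t") {
  validate_beta_tbl(betas)
  readr::write_delim(betas, path, delim = delim, na = "NA")
  invisible(path)
}

validate_beta_tbl <- function(tbl, arg = "betas") {
  if (!is.data.frame(tbl) || !"probe_id" %in% names(tbl)) {
    abort(sprintf("`%s` must be a data frame with a `probe_id` column.", arg))
  }
  probes <- tbl$probe_id
  samples <- setdiff(names(tbl), "probe_id")
  if (anyDuplicated(probes)) {
    abort(sprintf("Duplicated probe IDs: %s",
                  paste(unique(probes[duplicated(probes)]), collapse = ", ")))
  }
  if (anyDuplicated(samples)) {
    abort(sprintf("Duplicated sample IDs: %s",
                  paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  m <- beta_values(tbl)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Beta value out of [0, 1] at probe %s, sample %s (value %g).",
      probes[bad[1, 1]], samples[bad[1, 2]], m[bad[1, 1], bad[1, 2]]
    ))
  }
  invisible(tbl)
}

# probes x samples numeric matrix with dimnames
beta_values <- function(tbl) {
  m <- as.matrix(tbl[setdiff(names(tbl), "probe_id")])
  storage.mode(m) <- "double"
  rownames(m) <- tbl$probe_id
  m
}

beta_sample_ids <- function(tbl) setdiff(names(tbl), "probe_id")

matrix_to_beta_tbl <- function(m) {
  dplyr::bind_cols(tibble::tibble(probe_id = rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

#' Column dictionary for clinical files
#'
#' Maps the package's internal clinical field names to the column headers
#' expected in a clinical file. The dictionary shipped here is this package's
#' own convention (internal name == file header); pass a modified copy to
#' [read_clinical_table()] to adapt to other exports.
#'
#' @return A named character vector: names are internal fields, values are
#'   file headers.
#' @export
clinical_column_dictionary <- function() {
  fields <- c(
    "patient_id", "gender", "age", "morphological_grade", "tnm_stage",
    "t_stage", "n_stage", "necrosis", "tumor_diameter", "albumin",
    "alkaline_phosphatase", "calcium", "creatinine", "ggt", "hemoglobin",
    "thrombocyte_count", "m_stage_at_dx", "progress_event", "followup_months"
  )
  setNames(fields, fields)
}

#' The twelve clinicopathological variables
#'
#' Field names of the clinical variables used as classifier features, with
#' their measurement kind (`"continuous"` vs `"ordinal"`, the latter covering
#' categorical codes that are mean-centered but not rescaled).
#'
#' @return A named character vector mapping field name to kind.
#' @export
clinical_feature_kinds <- function() {
  c(
    gender = "ordinal", age = "continuous", morphological_grade = "ordinal",
    tnm_stage = "ordinal", albumin = "continuous",
    alkaline_phosphatase = "continuous", calcium = "continuous",
    creatinine = "continuous", ggt = "continuous", hemoglobin = "continuous",
    thrombocyte_count = "continuous", tumor_diameter = "continuous"
  )
}

mandatory_clinical <- c("patient_id", "m_stage_at_dx", "progress_event", "followup_months")

#' Read a clinical table
#'
#' Reads a per-patient clinical/pathological table from delimited text,
#' renaming columns through a dictionary, typing each field, normalizing
#' T-stage sub-labels (T2a/T2b to T2, T3a/T3b/T3c to T3, matching the
#' T1a / T1b / T2 / T3-T4 grouping used for Mayo scoring), and rejecting
#' unknown categorical levels.
#'
#' @param path Path to a delimited file with a header row.
#' @param col_map Named character vector mapping internal field names to the
#'   file's headers; defaults to [clinical_column_dictionary()]. Fields
#'   absent from the file are left missing unless mandatory.
#' @param delim Field delimiter.
#' @return A typed tibble, one row per patient.
#' @export
read_clinical_table <- function(path, col_map = clinical_column_dictionary(),
                                delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                           show_col_types = FALSE, progress = FALSE)
  present <- col_map[col_map %in% names(raw)]
  missing_mandatory <- setdiff(mandatory_clinical, names(present))
  if (length(missing_mandatory) > 0) {
    abort(sprintf("Clinical file is missing mandatory column(s): %s",
                  paste(missing_mandatory, collapse = ", ")))
  }
  tbl <- raw[unname(present)]
  names(tbl) <- names(present)
  as_clinical_table(tbl)
}

#' Coerce and validate a clinical table
#'
#' @param tbl A data frame with (a subset of) the fields of
#'   [clinical_column_dictionary()].
#' @return A validated tibble.
#' @export
as_clinical_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  if (!"patient_id" %in% names(tbl)) abort("Clinical table needs a `patient_id` column.")
  tbl$patient_id <- as.character(tbl$patient_id)
  if (anyDuplicated(tbl$patient_id)) abort("Duplicated patient IDs in clinical table.")

  chk_levels <- function(col, levels) {
    if (!col %in% names(tbl)) return()
    vals <- tbl[[col]]
    bad <- setdiff(unique(vals[!is.na(vals)]), levels)
    if (length(bad) > 0) {
      abort(sprintf("Unknown %s level(s): %s", col, paste(bad, collapse = ", ")))
    }
  }
  if ("t_stage" %in% names(tbl)) {
    tbl$t_stage <- normalize_t_stage(tbl$t_stage)
  }
  chk_levels("t_stage", c("T1a", "T1b", "T2", "T3", "T4"))
  if ("n_stage" %in% names(tbl)) {
    tbl$n_stage <- ifelse(tbl$n_stage %in% c("NX", "N0", "NX/N0"), "N0",
                          as.character(tbl$n_stage))
  }
  chk_levels("n_stage", c("N0", "N1"))
  chk_levels("gender", c("M", "F", "male", "female"))
  if ("gender" %in% names(tbl)) {
    tbl$gender <- ifelse(tbl$gender %in% c("M", "male"), "M",
                         ifelse(is.na(tbl$gender), NA, "F"))
  }
  if ("tnm_stage" %in% names(tbl)) {
    tnm <- tbl$tnm_stage
    if (!is.numeric(tnm)) {
      tnm <- match(toupper(as.character(tnm)), c("I", "II", "III", "IV"))
      if (any(is.na(tnm) & !is.na(tbl$tnm_stage))) abort("Unknown tnm_stage level.")
    }
    tbl$tnm_stage <- as.integer(tnm)
  }
  for (col in c("morphological_grade")) {
    if (col %in% names(tbl)) {
      g <- as.integer(tbl[[col]])
      if (any(!is.na(g) & (g < 1 | g > 4))) abort("morphological_grade must be in 1..4.")
      tbl[[col]] <- g
    }
  }
  for (col in c("necrosis", "progress_event")) {
    if (col %in% names(tbl)) tbl[[col]] <- as_flag(tbl[[col]], col)
  }
  chk_levels("m_stage_at_dx", c("M0", "M1"))
  num_cols <- c("age", "tumor_diameter", "albumin", "alkaline_phosphatase",
                "calcium", "creatinine", "ggt", "hemoglobin",
                "thrombocyte_count", "followup_months")
  for (col in intersect(num_cols, names(tbl))) {
    v <- as.numeric(tbl[[col]])
    if (any(!is.na(v) & v < 0)) abort(sprintf("`%s` must be non-negative.", col))
    tbl[[col]] <- v
  }
  tbl
}

normalize_t_stage <- function(x) {
  x <- as.character(x)
  x[x %in% c("T2a", "T2b")] <- "T2"
  x[x %in% c("T3a", "T3b", "T3c")] <- "T3"
  x
}

as_flag <- function(x, col) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  lx <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "yes", "present", "1")] <- TRUE
  out[lx %in% c("false", "no", "absent", "0")] <- FALSE
  if (any(is.na(out) & !is.na(x))) abort(sprintf("Unknown %s level.", col))
  out
}

#' Write a clinical table
#'
#' @param tbl Clinical tibble.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(tbl, path, delim = "\t") {
  readr::write_delim(tbl, path, delim = delim, na = "NA")
  invisible(path)
}

#' Read a probe annotation table
#'
#' Columns: `probe_id`, `chromosome` (1..22, X, Y), `region_label`
#' (TSS1500 / TSS200 / 5'UTR / 1stExon / other), and the logical exclusion
#' flags `flag_multi_loci`, `flag_snp_within_3bp`, `flag_absent_on_epic`,
#' `flag_mqtl`.
#'
#' @param path Delimited file with header.
#' @param delim Field delimiter.
#' @return A tibble, one row per probe.
#' @export
read_probe_annotation <- function(path, delim = "\t") {
  ann <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                           show_col_types = FALSE, progress = FALSE)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  ann <- tibble::as_tibble(ann)
  needed <- c("probe_id", "chromosome", "region_label")
  miss <- setdiff(needed, names(ann))
  if (length(miss) > 0) {
    abort(sprintf("Annotation is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(ann$probe_id)) abort("Duplicated probe IDs in annotation.")
  for (fl in c("flag_multi_loci", "flag_snp_within_3bp", "flag_absent_on_epic", "flag_mqtl")) {
    if (!fl %in% names(ann)) ann[[fl]] <- FALSE
    ann[[fl]] <- as_flag(ann[[fl]], fl)
    ann[[fl]][is.na(ann[[fl]])] <- FALSE
  }
  ann$chromosome <- sub("^chr", "", as.character(ann$chromosome))
  ann
}

#' Read a one-ID-per-line list
#'
#' Used for probe exclusion catalogues (mQTL, cross-reactive) and for the
#' previously identified prognostic CpG (PI-CpG) list.
#'
#' @param path Text file, one identifier per line; blank lines and lines
#'   starting with `#` are skipped.
#' @return Character vector of IDs.
#' @export
read_id_list <- function(path) {
  x <- readr::read_lines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}
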