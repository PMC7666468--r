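#' Mayo (Leibovich) progression score
#'
#' Computes the Mayo Clinic progression score for clear cell renal cell
#' carcinoma from its five components, using the point table of the
#' Leibovich 2003 scoring system: T-stage T1a = 0, T1b = 2, T2 = 3,
#' T3-T4 = 4; tumor size >= 10 cm = 1; N-stage N1 = 2 (NX/N0 = 0); Fuhrman
#' grade 1-2 = 0, grade 3 = 1, grade 4 = 3; necrosis present = 1. Risk
#' groups: low 0-2, intermediate 3-5, high >= 6. Because intermediate- and
#' high-risk patients share the same clinical follow-up scheme, the pooled
#' two-level grouping (low vs intermediate/high) is also returned; it is the
#' clinical comparator for the binary LRP/HRP classifiers.
#'
#' All arguments are vectorized; no component may be missing (the score is
#' never imputed).
#'
#' @param t_stage `"T1a"`, `"T1b"`, `"T2"`, `"T3"` or `"T4"`.
#' @param tumor_diameter Largest tumor diameter in mm.
#' @param n_stage `"N0"` (covering NX) or `"N1"`.
#' @param fuhrman_grade Integer 1-4.
#' @param necrosis Logical, tumor necrosis present.
#' @return A tibble with `score`, `risk_group` (`low` / `intermediate` /
#'   `high`) and `pooled_group` (`low` / `intermediate/high`).
#' @examples
#' mayo_score("T3", 80, "N0", 4, TRUE) # score 8, high risk
#' @export
mayo_score <- function(t_stage, tumor_diameter, n_stage, fuhrman_grade, necrosis) {
  n <- max(lengths(list(t_stage, tumor_diameter, n_stage, fuhrman_grade, necrosis)))
  args <- list(t_stage = rep_len(normalize_t_stage(t_stage), n),
               tumor_diameter = rep_len(tumor_diameter, n),
               n_stage = rep_len(as.character(n_stage), n),
               fuhrman_grade = rep_len(as.integer(fuhrman_grade), n),
               necrosis = rep_len(as.logical(necrosis), n))
  for (a in names(args)) {
    if (anyNA(args[[a]])) abort(sprintf("Mayo component `%s` has missing values.", a))
  }
  t_pts <- c(T1a = 0, T1b = 2, T2 = 3, T3 = 4, T4 = 4)
  if (!all(args$t_stage %in% names(t_pts))) {
    abort(sprintf("Unknown T-stage label: %s",
                  paste(setdiff(args$t_stage, names(t_pts)), collapse = ", ")))
  }
  args$n_stage[args$n_stage %in% c("NX", "NX/N0")] <- "N0"
  if (!all(args$n_stage %in% c("N0", "N1"))) abort("Unknown N-stage label.")
  if (!all(args$fuhrman_grade %in% 1:4)) abort("Fuhrman grade must be 1..4.")
  g_pts <- c(0, 0, 1, 3)
  score <- unname(t_pts[args$t_stage]) +
    as.integer(args$tumor_diameter >= 100) +
    2L * as.integer(args$n_stage == "N1") +
    g_pts[args$fuhrman_grade] +
    as.integer(args$necrosis)
  risk_group <- cut(score, breaks = c(-Inf, 2, 5, Inf),
                    labels = c("low", "intermediate", "high"))
  tibble::tibble(
    score = as.integer(score),
    risk_group = as.character(risk_group),
    pooled_group = ifelse(risk_group == "low", "low", "intermediate/high")
  )
}

#' Mayo classification of a cohort
#'
#' Scores every patient of a clinical table with [mayo_score()] and appends
#' the per-patient score, three-level risk group, pooled two-level group and
#' the binary high-risk call (`HRP` when pooled intermediate/high, `LRP`
#' otherwise) that is compared against the methylation classifiers.
#'
#' @param clinical Clinical tibble carrying `t_stage`, `tumor_diameter`,
#'   `n_stage`, `morphological_grade` (Fuhrman) and `necrosis` for every
#'   patient.
#' @return The clinical tibble with columns `mayo_score`, `mayo_risk_group`,
#'   `mayo_pooled_group` and `mayo_call` added.
#' @export
mayo_classify_cohort <- function(clinical) {
  needed <- c("t_stage", "tumor_diameter", "n_stage", "morphological_grade", "necrosis")
  miss <- setdiff(needed, names(clinical))
  if (length(miss) > 0) {
    abort(sprintf("Clinical table lacks Mayo component(s): %s",
                  paste(miss, collapse = ", ")))
  }
  incomplete <- !complete.cases(clinical[needed])
  if (any(incomplete)) {
    abort(sprintf("Mayo components missing for patient(s): %s",
                  paste(clinical$patient_id[incomplete], collapse = ", ")))
  }
  res <- mayo_score(clinical$t_stage, clinical$tumor_diameter, clinical$n_stage,
                    clinical$morphological_grade, clinical$necrosis)
  clinical |>
    dplyr::mutate(
      mayo_score = res$score,
      mayo_risk_group = res$risk_group,
      mayo_pooled_group = res$pooled_group,
      mayo_call = ifelse(res$pooled_group == "low", "LRP", "HRP")
    )
}
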