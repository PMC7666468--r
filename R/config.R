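#' Pipeline configuration
#'
#' Bundles every tunable constant of the analysis pipeline. The defaults are
#' the values used throughout: 40 consensus clusters, a 10% minimum minority
#' group and a 0.20 minimum between-group mean difference in the directed
#' cluster analysis, five principal components and an 85% target sensitivity
#' in the classifier, and a 0.20 absolute delta-beta threshold for calling a
#' CpG differentially methylated against tumor-free reference tissue.
#'
#' @param k Number of k-means clusters of binary CpG profiles (the number of
#'   consensus variables produced).
#' @param min_group_fraction Minimum fraction of samples allowed in the
#'   smaller of the two binarization groups; probes below it are dropped.
#' @param min_mean_diff Minimum difference between the two binarization group
#'   mean beta values; probes below it are dropped.
#' @param seed Integer seed controlling every stochastic step.
#' @param n_restarts Random restarts for the profile k-means.
#' @param n_components Number of principal components fed to the logistic
#'   risk model.
#' @param target_sensitivity Sensitivity at which the classifier cutoff is
#'   fixed, in (0, 1].
#' @param dm_threshold Absolute delta-beta at or above which a CpG is called
#'   differentially methylated.
#' @param restrict_promoter Keep only promoter-region probes (TSS1500,
#'   TSS200, 5'UTR, 1stExon) during filtering.
#' @param outlier_rule Hypomethylation-outlier rule: `"iqr"` flags samples
#'   whose hypomethylated-CpG count exceeds median + `outlier_multiplier` *
#'   IQR of all samples' counts; `"absolute"` uses `outlier_count` directly.
#' @param outlier_multiplier IQR multiplier for the `"iqr"` rule.
#' @param outlier_count Absolute count threshold for the `"absolute"` rule.
#'
#' @return A list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$k
#' @export
pipeline_config <- function(k = 40,
                            min_group_fraction = 0.10,
                            min_mean_diff = 0.20,
                            seed = 1L,
                            n_restarts = 25L,
                            n_components = 5L,
                            target_sensitivity = 0.85,
                            dm_threshold = 0.20,
                            restrict_promoter = TRUE,
                            outlier_rule = c("iqr", "absolute"),
                            outlier_multiplier = 3,
                            outlier_count = NULL) {
  outlier_rule <- match.arg(outlier_rule)
  if (!is.numeric(k) || k < 2) abort("`k` must be an integer >= 2.")
  if (min_group_fraction <= 0 || min_group_fraction >= 0.5) {
    abort("`min_group_fraction` must lie in (0, 0.5).")
  }
  if (min_mean_diff <= 0 || min_mean_diff >= 1) {
    abort("`min_mean_diff` must lie in (0, 1).")
  }
  if (target_sensitivity <= 0 || target_sensitivity > 1) {
    abort("`target_sensitivity` must lie in (0, 1].")
  }
  if (dm_threshold < 0 || dm_threshold > 1) {
    abort("`dm_threshold` must lie in [0, 1].")
  }
  structure(
    list(
      k = as.integer(k),
      min_group_fraction = min_group_fraction,
      min_mean_diff = min_mean_diff,
      seed = as.integer(seed),
      n_restarts = as.integer(n_restarts),
      n_components = as.integer(n_components),
      target_sensitivity = target_sensitivity,
      dm_threshold = dm_threshold,
      restrict_promoter = restrict_promoter,
      outlier_rule = outlier_rule,
      outlier_multiplier = outlier_multiplier,
      outlier_count = outlier_count
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  DCA: k =", x$k, "| min minority fraction", x$min_group_fraction,
      "| min mean diff", x$min_mean_diff, "\n")
  cat("  classifier:", x$n_components, "PCs at",
      sprintf("%.0f%%", 100 * x$target_sensitivity), "target sensitivity\n")
  cat("  DM threshold |delta-beta| >=", x$dm_threshold,
      "| promoter restriction:", x$restrict_promoter, "\n")
  invisible(x)
}
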