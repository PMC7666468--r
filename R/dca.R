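#' Binarize one CpG by exact 1-D 2-means
#'
#' Partitions the per-sample beta values of one probe into two groups
#' minimizing the within-group sum of squared deviations over all
#' 2-partitions. In one dimension the optimum is a split of the sorted
#' values, so the search over the n-1 sorted splits is exact and
#' deterministic — no iterative relocation and no randomness. The group with
#' the higher mean beta is labeled 1. Ties in the criterion are broken
#' toward the larger between-group mean difference, then the earlier sorted
#' split.
#'
#' @param values Numeric vector of beta values for one probe (>= 2 samples,
#'   no missing values).
#' @return `NULL` when all values are identical (degenerate, the probe is
#'   non-binarizable); otherwise a list with `labels` (0/1 per sample, in
#'   input order), `group_means` (`c(low, high)`), `mean_diff`
#'   (`high - low`, positive by construction) and `minority_fraction`.
#' @examples
#' binarize_cpg(c(0.10, 0.15, 0.12, 0.80, 0.90))
#' @export
binarize_cpg <- function(values) {
  n <- length(values)
  if (n < 2) abort("Need at least two samples to binarize.")
  if (anyNA(values)) abort("Missing beta values must be handled upstream.")
  if (max(values) == min(values)) return(NULL)
  o <- order(values)
  v <- values[o]
  cs <- cumsum(v)
  cq <- cumsum(v^2)
  tot_s <- cs[n]
  tot_q <- cq[n]
  i <- seq_len(n - 1)
  n1 <- i
  n2 <- n - i
  s1 <- cs[i]
  s2 <- tot_s - s1
  ss <- (cq[i] - s1^2 / n1) + ((tot_q - cq[i]) - s2^2 / n2)
  diff <- s2 / n2 - s1 / n1
  # min SS; ties -> larger mean difference, then earlier split
  best <- which(ss <= min(ss) + 1e-12)
  if (length(best) > 1) best <- best[order(-diff[best], best)][1]
  labels <- integer(n)
  labels[o[(best + 1):n]] <- 1L
  list(
    labels = labels,
    group_means = c(s1[best] / best, s2[best] / (n - best)),
    mean_diff = diff[best],
    minority_fraction = min(best, n - best) / n
  )
}

#' Binarize every probe of a beta matrix
#'
#' Applies [binarize_cpg()] to each probe over the fitting samples,
#' dropping non-binarizable (constant) probes, and collects the binary
#' profile vectors together with the per-probe group statistics.
#'
#' @param betas Probes-by-samples beta tibble.
#' @param samples Sample IDs to fit on; defaults to all samples. Samples
#'   excluded here (e.g. hypomethylation outliers) still receive consensus
#'   values later.
#' @return An object of class `binary_profiles`: a list with `profiles`
#'   (tibble: `probe_id`, `mean_low`, `mean_high`, `mean_diff`,
#'   `minority_fraction`), `labels` (probes-by-samples 0/1 matrix) and
#'   `dropped` (non-binarizable probe IDs).
#' @export
binarize_profiles <- function(betas, samples = NULL) {
  validate_beta_tbl(betas)
  all_samples <- beta_sample_ids(betas)
  samples <- samples %||% all_samples
  if (!all(samples %in% all_samples)) abort("Unknown sample ID in `samples`.")
  m <- beta_values(betas)[, samples, drop = FALSE]
  if (anyNA(m)) abort("Missing beta values must be handled upstream of binarization.")
  fits <- lapply(seq_len(nrow(m)), function(i) binarize_cpg(m[i, ]))
  ok <- !vapply(fits, is.null, logical(1))
  labels <- do.call(rbind, lapply(fits[ok], `[[`, "labels"))
  if (is.null(labels)) labels <- matrix(integer(0), 0, length(samples))
  dimnames(labels) <- list(rownames(m)[ok], samples)
  profiles <- tibble::tibble(
    probe_id = rownames(m)[ok],
    mean_low = vapply(fits[ok], function(f) f$group_means[1], numeric(1)),
    mean_high = vapply(fits[ok], function(f) f$group_means[2], numeric(1)),
    mean_diff = vapply(fits[ok], `[[`, numeric(1), "mean_diff"),
    minority_fraction = vapply(fits[ok], `[[`, numeric(1), "minority_fraction")
  )
  structure(
    list(profiles = profiles, labels = labels, dropped = rownames(m)[!ok]),
    class = "binary_profiles"
  )
}

#' Prefilter binary CpG profiles
#'
#' Removes probes whose smaller binarization group holds less than
#' `min_group_fraction` of the samples, and probes whose between-group mean
#' beta difference is lower than `min_mean_diff`. Boundary values are
#' retained (the removal conditions are strict "less than").
#'
#' @param bp A `binary_profiles` object.
#' @param min_group_fraction Minimum minority-group fraction (default 0.10).
#' @param min_mean_diff Minimum group mean difference (default 0.20).
#' @return A filtered `binary_profiles` object.
#' @export
prefilter_profiles <- function(bp, min_group_fraction = 0.10, min_mean_diff = 0.20) {
  stopifnot(inherits(bp, "binary_profiles"))
  keep <- bp$profiles$minority_fraction >= min_group_fraction &
    bp$profiles$mean_diff >= min_mean_diff
  if (!any(keep)) inform("Prefilter removed every probe.")
  structure(
    list(
      profiles = bp$profiles[keep, , drop = FALSE],
      labels = bp$labels[keep, , drop = FALSE],
      dropped = bp$dropped
    ),
    class = "binary_profiles"
  )
}

#' Cluster binary CpG profiles with k-means
#'
#' Runs k-means on the binary profile vectors (probes as observations,
#' samples as dimensions, squared Euclidean distance), keeping the best of
#' `n_restarts` random starts by total within-cluster sum of squares.
#' Probes with similar sample partitions land in the same cluster. The run
#' is deterministic given `seed`; cluster IDs are renumbered in order of
#' first appearance along the probe list so the labeling is stable.
#'
#' @param bp A (prefiltered) `binary_profiles` object.
#' @param k Number of clusters (default 40).
#' @param seed Integer seed.
#' @param n_restarts Random restarts (default 25).
#' @return A tibble with `probe_id` and integer `cluster` (1..k).
#' @export
cluster_profiles <- function(bp, k = 40, seed = 1L, n_restarts = 25L) {
  stopifnot(inherits(bp, "binary_profiles"))
  x <- bp$labels
  if (nrow(x) < k) {
    abort(sprintf(
      "Only %d probes remain but k = %d clusters were requested; use a smaller k.",
      nrow(x), k
    ))
  }
  n_distinct <- nrow(unique(x))
  if (n_distinct < k) {
    abort(sprintf(
      "Only %d distinct binary profiles remain but k = %d; use a smaller k.",
      n_distinct, k
    ))
  }
  km <- withr::with_seed(seed, kmeans(x, centers = k, nstart = n_restarts,
                                      iter.max = 300L))
  cluster <- match(km$cluster, unique(km$cluster))
  tibble::tibble(probe_id = rownames(x), cluster = as.integer(cluster))
}

#' Consensus methylation variables
#'
#' For each cluster and each sample, averages the beta values of the
#' cluster's member probes. The averaging makes the consensus variables
#' robust to single-CpG noise. Values are computed for every sample in
#' `betas`, including samples that were excluded from profile fitting.
#'
#' @param betas Probes-by-samples beta tibble covering (at least) the
#'   membership's probes and every sample of interest.
#' @param membership Tibble with `probe_id` and `cluster` from
#'   [cluster_profiles()].
#' @return A tibble: `sample_id` plus one `DCA_xx` column per cluster, each
#'   value the mean beta over member probes.
#' @export
consensus_variables <- function(betas, membership) {
  validate_beta_tbl(betas)
  if (!all(c("probe_id", "cluster") %in% names(membership))) {
    abort("`membership` needs `probe_id` and `cluster` columns.")
  }
  miss <- setdiff(membership$probe_id, betas$probe_id)
  if (length(miss) > 0) {
    abort(sprintf("Membership probes absent from beta matrix: %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  ks <- sort(unique(membership$cluster))
  if (length(ks) == 0) abort("Empty membership.")
  m <- beta_values(betas)
  vals <- vapply(ks, function(cl) {
    probes <- membership$probe_id[membership$cluster == cl]
    colMeans(m[probes, , drop = FALSE])
  }, numeric(ncol(m)))
  colnames(vals) <- sprintf("DCA_%02d", ks)
  dplyr::bind_cols(tibble::tibble(sample_id = colnames(m)),
                   tibble::as_tibble(vals, .name_repair = "minimal"))
}

#' Directed cluster analysis
#'
#' The full consensus-biomarker workflow: binarize each CpG by exact 1-D
#' 2-means over the fitting samples, remove probes with an unbalanced
#' binarization (< `min_group_fraction` minority) or weak separation
#' (< `min_mean_diff`), cluster the surviving binary profiles with k-means
#' (k clusters), and average beta within each cluster to obtain per-sample
#' consensus variables. Samples listed in `exclude_samples` (typically
#' global hypomethylation outliers) are left out of fitting but receive
#' consensus values.
#'
#' @param betas Filtered probes-by-samples beta tibble.
#' @param cfg A [pipeline_config()] supplying `k`, `min_group_fraction`,
#'   `min_mean_diff`, `seed` and `n_restarts`.
#' @param exclude_samples Sample IDs excluded from fitting.
#' @return An object of class `dca_fit`: list with `profiles` (retained
#'   `binary_profiles`), `membership`, `consensus` (sample-by-cluster
#'   tibble), `excluded_samples`, `provenance` (probe counts per step) and
#'   the parameters used.
#' @examples
#' sim <- simulate_methylation(sim_config(n_tumor = 40, n_clusters = 3,
#'                                        probes_per_cluster = 10,
#'                                        n_noise_probes = 30), seed = 7)
#' fit <- dca_fit(sim$tumors, pipeline_config(k = 3))
#' glance(fit)
#' @export
dca_fit <- function(betas, cfg = pipeline_config(), exclude_samples = character()) {
  validate_beta_tbl(betas)
  fit_samples <- setdiff(beta_sample_ids(betas), exclude_samples)
  bp <- binarize_profiles(betas, samples = fit_samples)
  n_binarizable <- nrow(bp$profiles)
  bp_f <- prefilter_profiles(bp, cfg$min_group_fraction, cfg$min_mean_diff)
  membership <- cluster_profiles(bp_f, k = cfg$k, seed = cfg$seed,
                                 n_restarts = cfg$n_restarts)
  consensus <- consensus_variables(betas, membership)
  structure(
    list(
      profiles = bp_f,
      membership = membership,
      consensus = consensus,
      excluded_samples = exclude_samples,
      provenance = tibble::tibble(
        step = c("input", "binarizable", "prefiltered", "clusters"),
        n = c(nrow(betas), n_binarizable, nrow(bp_f$profiles), cfg$k)
      ),
      k = cfg$k,
      min_group_fraction = cfg$min_group_fraction,
      min_mean_diff = cfg$min_mean_diff,
      seed = cfg$seed
    ),
    class = "dca_fit"
  )
}

#' @export
print.dca_fit <- function(x, ...) {
  cat("<dca_fit>\n")
  print(x$provenance)
  invisible(x)
}

#' @rdname dca_fit
#' @param x A `dca_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dca_fit <- function(x, ...) {
  cons <- as.matrix(x$consensus[-1])
  x$membership |>
    dplyr::count(.data$cluster, name = "n_probes") |>
    dplyr::mutate(
      consensus = sprintf("DCA_%02d", .data$cluster),
      mean_beta = colMeans(cons)[.data$consensus],
      sd_beta = apply(cons, 2, sd)[.data$consensus]
    )
}

#' @rdname dca_fit
#' @exportS3Method generics::glance
glance.dca_fit <- function(x, ...) {
  tibble::tibble(
    n_probes_in = x$provenance$n[1],
    n_binarizable = x$provenance$n[2],
    n_retained = x$provenance$n[3],
    k = x$k,
    n_samples = nrow(x$consensus),
    n_excluded_samples = length(x$excluded_samples)
  )
}

#' Heatmap of consensus variables
#'
#' @param object A `dca_fit` object.
#' @param ... Unused.
#' @return A ggplot: samples by consensus variables, fill = mean beta.
#' @exportS3Method ggplot2::autoplot
autoplot.dca_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$consensus, -"sample_id",
                              names_to = "consensus", values_to = "beta")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$consensus, y = .data$sample_id,
                                     fill = .data$beta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#ffffcc", high = "#253494",
                                 limits = c(0, 1), name = "mean beta") +
    ggplot2::labs(x = "consensus variable", y = "sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5),
                   axis.text.y = ggplot2::element_blank())
}
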