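#' Confusion metrics for binary risk calls
#'
#' Cross-tabulates high/low-risk calls against true progression labels and
#' returns sensitivity = TP/(TP+FN) and specificity = TN/(TN+FP).
#'
#' @param calls Character vector of `"HRP"`/`"LRP"` calls, or a logical
#'   vector (`TRUE` = high risk).
#' @param truth Logical vector of true progression labels.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_metrics <- function(calls, truth) {
  if (length(calls) != length(truth)) abort("`calls` and `truth` lengths differ.")
  if (is.character(calls) || is.factor(calls)) {
    calls <- as.character(calls)
    bad <- setdiff(unique(calls), c("HRP", "LRP"))
    if (length(bad) > 0) abort(sprintf("Unknown call label(s): %s", paste(bad, collapse = ", ")))
    calls <- calls == "HRP"
  }
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2) abort("Both outcome classes must be present in `truth`.")
  tp <- sum(calls & truth); fn <- sum(!calls & truth)
  tn <- sum(!calls & !truth); fp <- sum(calls & !truth)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp)
  )
}

#' Chi-square test of independence
#'
#' Pearson chi-square on a contingency table. In `"auto"` mode the Yates
#' continuity correction is applied to 2x2 tables and omitted for larger
#' tables, matching the convention of standard statistical software.
#'
#' @param table Integer matrix of counts (at least 2x2).
#' @param correct `"auto"`, `TRUE` or `FALSE`.
#' @return One-row tibble with `statistic`, `df`, `p_value`, `method`.
#' @export
chi_square_test <- function(table, correct = "auto") {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) abort("Need at least a 2x2 table.")
  if (any(table < 0)) abort("Counts must be non-negative.")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("Zero row or column margin.")
  }
  use_correction <- if (identical(correct, "auto")) {
    nrow(table) == 2 && ncol(table) == 2
  } else {
    isTRUE(correct)
  }
  res <- suppressWarnings(chisq.test(table, correct = use_correction))
  tibble::tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value),
    method = if (use_correction) "chi-square (Yates)" else "chi-square"
  )
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test for a difference between two continuous samples.
#' For tie-free samples with at most 20 observations per group the exact
#' distribution of U is used; otherwise the normal approximation with tie
#' correction (and continuity correction) applies.
#'
#' @param x,y Numeric samples.
#' @return One-row tibble with `statistic` (U for `x`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("Both samples must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 20 && length(y) <= 20
  res <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble::tibble(
    statistic = unname(res$statistic),
    p_value = unname(res$p.value),
    method = if (exact) "Mann-Whitney U (exact)" else
      "Mann-Whitney U (normal approximation, tie-corrected)"
  )
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), where p_o is
#' the observed agreement fraction and p_e the expected agreement from the
#' marginal products.
#'
#' @param table Square contingency table of the two raters' categories
#'   (typically 2x2: e.g. Mayo pooled group vs classifier call).
#' @return List with `kappa`, `agreement_fraction` and the input `table`.
#' @examples
#' cohens_kappa(matrix(c(26, 14, 6, 32), 2)) # ~0.49
#' @export
cohens_kappa <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table)) abort("Agreement table must be square.")
  n <- sum(table)
  if (n == 0) abort("Empty table.")
  p_o <- sum(diag(table)) / n
  p_e <- sum(rowSums(table) * colSums(table)) / n^2
  kappa <- if (p_e >= 1) {
    if (p_o == 1) 1 else abort("Degenerate margins (expected agreement 1) with disagreement.")
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  list(kappa = kappa, agreement_fraction = p_o, table = table)
}

#' Fraction of identically classified patients
#'
#' @param calls_a,calls_b Aligned call vectors.
#' @return Fraction in \[0, 1\].
#' @export
agreement_fraction <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) abort("Call vectors differ in length.")
  mean(calls_a == calls_b)
}

#' Hierarchical clustering of classifier outputs
#'
#' Clusters classifiers by the similarity of their binary call vectors
#' using Euclidean distance and average linkage. Equal-height merges follow
#' the lowest-index-first convention of [stats::hclust()], so the dendrogram
#' is deterministic.
#'
#' @param calls A tibble/data frame with one column per classifier
#'   (`"HRP"`/`"LRP"` or 0/1 calls) and one row per patient; a `patient_id`
#'   column is ignored.
#' @return An [stats::hclust] object over the classifiers.
#' @export
cluster_classifiers <- function(calls) {
  calls <- calls[setdiff(names(calls), "patient_id")]
  m <- vapply(calls, function(col) {
    if (is.character(col) || is.factor(col)) as.numeric(as.character(col) == "HRP")
    else as.numeric(col)
  }, numeric(nrow(calls)))
  hclust(dist(t(m), method = "euclidean"), method = "average")
}

#' ROC area under the curve
#'
#' AUC via the Mann-Whitney identity (ties count one half), computed with
#' the \pkg{pROC} package with the score orientation fixed so that higher
#' scores indicate the positive class.
#'
#' @param scores Numeric scores.
#' @param labels Logical labels (TRUE = positive); both classes required.
#' @return AUC as a plain number.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) abort("Both classes must be present.")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' DeLong comparison of two paired ROC curves
#'
#' Two-sided test for a difference in AUC between two classifiers scored on
#' the same patients, using DeLong's paired structural-component variance
#' estimator. Identical score vectors compare with p = 1 by convention.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Logical labels.
#' @return One-row tibble with `auc_a`, `auc_b`, `statistic`, `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels)) {
    abort("Paired scores and labels must align.")
  }
  if (length(unique(labels)) < 2) abort("Both classes must be present.")
  ra <- pROC::roc(response = labels, predictor = scores_a,
                  levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  rb <- pROC::roc(response = labels, predictor = scores_b,
                  levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  if (isTRUE(all.equal(scores_a, scores_b))) {
    return(tibble::tibble(auc_a = as.numeric(pROC::auc(ra)),
                          auc_b = as.numeric(pROC::auc(rb)),
                          statistic = 0, p_value = 1))
  }
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  tibble::tibble(
    auc_a = as.numeric(pROC::auc(ra)),
    auc_b = as.numeric(pROC::auc(rb)),
    statistic = unname(tst$statistic),
    p_value = unname(tst$p.value)
  )
}

#' Kaplan-Meier cumulative incidence of progression
#'
#' Estimates the survival curve by the product-limit method and reports the
#' cumulative incidence of progression within the horizon, pCIP(t) = 1 -
#' S(t), overall or by risk group; with groups, the log-rank test compares
#' the survival distributions.
#'
#' @param data Data frame with one row per patient.
#' @param time Column of follow-up times in months (tidy-eval).
#' @param event Column of logical progression indicators (tidy-eval);
#'   patients without an event are censored at their last follow-up.
#' @param group Optional grouping column (tidy-eval), e.g. the risk call.
#' @param horizon Horizon in months (default 60, i.e. five years).
#' @return An object of class `km_cip`: list with `fit` (the
#'   [survival::survfit] object), `summary` (tibble per group: `n`,
#'   `events`, `pcip`), `horizon` and, with groups, `logrank_p`.
#' @examples
#' km_cip(tibble::tibble(t = c(12, 24, 36, 60), e = c(TRUE, FALSE, TRUE, FALSE)), t, e)
#' @export
km_cip <- function(data, time, event, group = NULL, horizon = 60) {
  t <- eval_tidy(enquo(time), data)
  e <- as.logical(eval_tidy(enquo(event), data))
  gq <- enquo(group)
  g <- if (quo_is_null(gq)) NULL else as.character(eval_tidy(gq, data))
  if (any(t < 0)) abort("Negative follow-up time.")
  df <- data.frame(t = t, e = as.integer(e))
  if (is.null(g)) {
    fit <- survival::survfit(survival::Surv(t, e) ~ 1, data = df)
    s <- summary(fit, times = horizon, extend = TRUE)
    smry <- tibble::tibble(group = "all", n = length(t), events = sum(e),
                           pcip = 1 - s$surv)
    logrank_p <- NULL
  } else {
    df$g <- g
    fit <- survival::survfit(survival::Surv(t, e) ~ g, data = df)
    s <- summary(fit, times = horizon, extend = TRUE)
    grp <- sub("^g=", "", as.character(s$strata))
    smry <- tibble::tibble(
      group = grp,
      n = as.integer(table(g)[grp]),
      events = as.integer(tapply(e, g, sum)[grp]),
      pcip = 1 - s$surv
    )
    sd <- survival::survdiff(survival::Surv(t, e) ~ g, data = df)
    logrank_p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  }
  structure(list(fit = fit, summary = smry, horizon = horizon,
                 logrank_p = logrank_p),
            class = "km_cip")
}

#' @export
print.km_cip <- function(x, ...) {
  cat(sprintf("<km_cip> cumulative incidence of progression by %d months\n", x$horizon))
  print(x$summary)
  if (!is.null(x$logrank_p)) cat(sprintf("log-rank p = %.4g\n", x$logrank_p))
  invisible(x)
}

#' @rdname km_cip
#' @param x A `km_cip` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.km_cip <- function(x, ...) x$summary

#' Survival curves for a `km_cip` object
#'
#' @param object A `km_cip` object.
#' @param ... Unused.
#' @return A ggplot of the cumulative incidence curves 1 - S(t).
#' @exportS3Method ggplot2::autoplot
autoplot.km_cip <- function(object, ...) {
  f <- object$fit
  strata <- if (is.null(f$strata)) rep("all", length(f$time)) else
    rep(sub("^g=", "", names(f$strata)), f$strata)
  d <- dplyr::bind_rows(
    tibble::tibble(time = 0, cip = 0, group = unique(strata)),
    tibble::tibble(time = f$time, cip = 1 - f$surv, group = strata)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$cip,
                                  color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$horizon, linetype = "dotted") +
    ggplot2::labs(x = "months since diagnosis",
                  y = "cumulative incidence of progression") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Log-rank test
#'
#' @param data Data frame with one row per patient.
#' @param time,event,group Columns (tidy-eval): follow-up months, logical
#'   event, group label.
#' @return One-row tibble with `statistic`, `df`, `p_value`, `method`.
#' @export
logrank_test <- function(data, time, event, group) {
  t <- eval_tidy(enquo(time), data)
  e <- as.integer(as.logical(eval_tidy(enquo(event), data)))
  g <- as.character(eval_tidy(enquo(group), data))
  if (any(t < 0)) abort("Negative follow-up time.")
  df <- data.frame(t = t, e = e, g = g)
  sd <- survival::survdiff(survival::Surv(t, e) ~ g, data = df)
  df_ <- length(sd$n) - 1
  tibble::tibble(
    statistic = sd$chisq,
    df = df_,
    p_value = stats::pchisq(sd$chisq, df = df_, lower.tail = FALSE),
    method = "log-rank"
  )
}

#' Chance-level specificity at fixed sensitivity
#'
#' What specificity does a non-informative classifier achieve once its
#' cutoff is fixed at the target sensitivity? Under the
#' `"order_statistic"` convention, scores for both classes are i.i.d.
#' continuous; the cutoff lands on the k-th largest positive score
#' (k = ceiling(target * n_pos)), a uniform order statistic, giving the
#' closed form E\[specificity\] = (n_pos + 1 - k) / (n_pos + 1) — about 19%
#' for 20 positives at 85% sensitivity. The `"refit"` convention instead
#' fits the full 5-component logistic model to random Gaussian features
#' in-sample before fixing the cutoff; overfitting makes its expected
#' specificity exceed the closed form, and no closed form is reported.
#'
#' @param n_pos,n_neg Class sizes.
#' @param target_sensitivity Target sensitivity (default 0.85).
#' @param reps Monte-Carlo replicates.
#' @param seed Integer seed.
#' @param convention `"order_statistic"` or `"refit"`.
#' @param n_features Number of random features for `"refit"` (default 5).
#' @return One-row tibble with `convention`, `k`, `expected_specificity`
#'   (Monte-Carlo mean), `mc_se`, and `closed_form` (NA for `"refit"`).
#' @export
chance_specificity <- function(n_pos, n_neg, target_sensitivity = 0.85,
                               reps = 10000, seed = 1L,
                               convention = c("order_statistic", "refit"),
                               n_features = 5) {
  convention <- match.arg(convention)
  if (n_pos < 1 || n_neg < 1 || reps < 1) abort("`n_pos`, `n_neg`, `reps` must be >= 1.")
  labels <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
  k <- ceiling(target_sensitivity * n_pos)
  specs <- withr::with_seed(seed, vapply(seq_len(reps), function(i) {
    scores <- if (convention == "order_statistic") {
      runif(n_pos + n_neg)
    } else {
      x <- matrix(rnorm((n_pos + n_neg) * n_features), ncol = n_features)
      fit <- suppressWarnings(glm(labels ~ x, family = binomial()))
      fitted(fit)
    }
    choose_cutoff(scores, labels, target_sensitivity)$specificity
  }, numeric(1)))
  tibble::tibble(
    convention = convention,
    n_pos = n_pos, n_neg = n_neg, k = k,
    expected_specificity = mean(specs),
    mc_se = sd(specs) / sqrt(reps),
    closed_form = if (convention == "order_statistic") (n_pos + 1 - k) / (n_pos + 1)
      else NA_real_
  )
}
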