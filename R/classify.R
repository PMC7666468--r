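#' Assemble a classifier feature set
#'
#' Builds the patients-by-features matrix for one of the six feature sets:
#' the 12 clinicopathological variables (`"clinical"`), the previously
#' identified prognostic CpGs (`"pi"`), the consensus variables from
#' directed cluster analysis (`"dca"`), and their combinations
#' (`"clinical+pi"`, `"clinical+dca"`, `"triple"` =
#' clinical + PI-CpGs + DCA). Combined sets are column concatenations. The
#' patient order of `clinical` is the master ordering; methylation
#' components must cover every patient.
#'
#' @param clinical Clinical tibble (already restricted to the modeling
#'   cohort, e.g. non-metastatic patients with at least five years of
#'   follow-up, and mean-imputed).
#' @param pi_betas Probes-by-samples beta tibble of the PI-CpGs (needed for
#'   sets containing `pi`).
#' @param consensus Sample-by-cluster consensus tibble from [dca_fit()]
#'   (needed for sets containing `dca`).
#' @param set_name One of `"clinical"`, `"pi"`, `"dca"`, `"clinical+pi"`,
#'   `"clinical+dca"`, `"triple"`.
#' @param pi_cpg_ids Optional probe IDs restricting/validating `pi_betas`;
#'   probes absent from the matrix are an error listing them.
#' @return A tibble `patient_id` + feature columns, with a `kinds`
#'   attribute (named character, `"continuous"` or `"ordinal"`) recording
#'   the scaling treatment each column receives.
#' @export
assemble_features <- function(clinical, pi_betas = NULL, consensus = NULL,
                              set_name = "triple", pi_cpg_ids = NULL) {
  set_name <- normalize_set_name(set_name)
  parts <- strsplit(set_name, "+", fixed = TRUE)[[1]]
  ids <- clinical$patient_id
  blocks <- list()
  kinds <- character()

  if ("clinical" %in% parts) {
    ck <- clinical_feature_kinds()
    miss <- setdiff(names(ck), names(clinical))
    if (length(miss) > 0) {
      abort(sprintf("Clinical table lacks feature(s): %s", paste(miss, collapse = ", ")))
    }
    blk <- clinical[names(ck)]
    blk$gender <- as.numeric(blk$gender == "M")
    blk <- dplyr::mutate(blk, dplyr::across(dplyr::everything(), as.numeric))
    blocks <- c(blocks, list(blk))
    kinds <- c(kinds, ck)
  }
  if ("pi" %in% parts) {
    if (is.null(pi_betas)) abort("`pi_betas` is required for this feature set.")
    validate_beta_tbl(pi_betas, "pi_betas")
    if (!is.null(pi_cpg_ids)) {
      absent <- setdiff(pi_cpg_ids, pi_betas$probe_id)
      if (length(absent) > 0) {
        abort(sprintf("PI-CpG(s) absent from beta matrix: %s",
                      paste(absent, collapse = ", ")))
      }
      pi_betas <- pi_betas[match(pi_cpg_ids, pi_betas$probe_id), , drop = FALSE]
    }
    m <- beta_values(pi_betas)
    miss <- setdiff(ids, colnames(m))
    if (length(miss) > 0) {
      abort(sprintf("PI-CpG matrix lacks patient(s): %s", paste(head(miss, 5), collapse = ", ")))
    }
    blk <- tibble::as_tibble(t(m[, ids, drop = FALSE]), .name_repair = "minimal")
    blocks <- c(blocks, list(blk))
    kinds <- c(kinds, setNames(rep("continuous", ncol(blk)), names(blk)))
  }
  if ("dca" %in% parts) {
    if (is.null(consensus)) abort("`consensus` is required for this feature set.")
    miss <- setdiff(ids, consensus$sample_id)
    if (length(miss) > 0) {
      abort(sprintf("Consensus table lacks patient(s): %s", paste(head(miss, 5), collapse = ", ")))
    }
    blk <- consensus[match(ids, consensus$sample_id), setdiff(names(consensus), "sample_id")]
    blocks <- c(blocks, list(blk))
    kinds <- c(kinds, setNames(rep("continuous", ncol(blk)), names(blk)))
  }
  out <- dplyr::bind_cols(tibble::tibble(patient_id = ids), blocks)
  if (anyDuplicated(names(out))) abort("Duplicated feature names across blocks.")
  attr(out, "kinds") <- kinds
  attr(out, "set_name") <- set_name
  out
}

normalize_set_name <- function(set_name) {
  key <- gsub("[ _]", "", tolower(set_name))
  key <- gsub("pi-cpgs|picpgs", "pi", key)
  map <- c(
    "clinical" = "clinical", "pi" = "pi", "dca" = "dca",
    "clinical+pi" = "clinical+pi", "clinical+dca" = "clinical+dca",
    "triple" = "clinical+pi+dca", "clinical+pi+dca" = "clinical+pi+dca"
  )
  if (!key %in% names(map)) {
    abort(sprintf("Unknown feature set `%s`; expected one of %s.",
                  set_name, paste(names(map), collapse = ", ")))
  }
  unname(map[key])
}

#' Principal components with mixed scaling
#'
#' Computes the PCA transform used by the risk models: continuous columns
#' are standardized (mean 0, sd 1), while categorical/ordinal columns are
#' mean-centered only. Components are ordered by decreasing explained
#' variance, and each loading vector's sign is fixed so that its
#' largest-magnitude element is positive, making the transform
#' reproducible.
#'
#' @param features Feature tibble from [assemble_features()].
#' @param n_components Number of components retained (default 5).
#' @param kinds Named character vector of column kinds; defaults to the
#'   tibble's `kinds` attribute.
#' @return A list with `center`, `scale`, `rotation` (features x
#'   components), `sdev` (all components), `scores` (training component
#'   scores) and `kinds`.
#' @export
fit_pca <- function(features, n_components = 5, kinds = NULL) {
  kinds <- kinds %||% attr(features, "kinds")
  x <- as.matrix(features[setdiff(names(features), "patient_id")])
  storage.mode(x) <- "double"
  if (is.null(kinds)) kinds <- setNames(rep("continuous", ncol(x)), colnames(x))
  if (anyNA(x)) abort("Features contain missing values; impute upstream.")
  if (ncol(x) < n_components) {
    abort(sprintf("Need at least %d feature columns, got %d.", n_components, ncol(x)))
  }
  center <- colMeans(x)
  sds <- apply(x, 2, sd)
  scale_ <- ifelse(kinds[colnames(x)] == "continuous", sds, 1)
  zero_var <- colnames(x)[kinds[colnames(x)] == "continuous" & sds == 0]
  if (length(zero_var) > 0) {
    abort(sprintf("Zero-variance continuous feature(s): %s",
                  paste(zero_var, collapse = ", ")))
  }
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- xs %*% rot
  list(center = center, scale = scale_, rotation = rot, sdev = pc$sdev,
       scores = scores, kinds = kinds[colnames(x)])
}

#' Fix the posterior cutoff at a target sensitivity
#'
#' Chooses the largest posterior-probability threshold at which the
#' classifier (call high-risk iff posterior >= cutoff) still reaches the
#' target sensitivity: the cutoff is the k-th largest posterior among the
#' positives, with k = ceiling(target * n_pos), so exactly
#' ceiling(target * n_pos) positives (more under ties) are called
#' high-risk. Specificity is then the fraction of negatives below the
#' cutoff; no threshold meeting the target does better.
#'
#' @param posteriors Numeric scores (posterior probabilities).
#' @param labels Logical (or 0/1) true outcome; both classes required.
#' @param target_sensitivity Target sensitivity in (0, 1] (default 0.85).
#' @return List with `cutoff`, `sensitivity`, `specificity` and `n_tp`.
#' @examples
#' choose_cutoff(c(0.9, 0.8, 0.7, 0.2, 0.75, 0.5, 0.1),
#'               c(1, 1, 1, 1, 0, 0, 0), target_sensitivity = 0.75)
#' @export
choose_cutoff <- function(posteriors, labels, target_sensitivity = 0.85) {
  if (target_sensitivity <= 0 || target_sensitivity > 1) {
    abort("`target_sensitivity` must lie in (0, 1].")
  }
  labels <- as.logical(labels)
  if (length(posteriors) != length(labels)) abort("Length mismatch.")
  pos <- posteriors[labels]
  neg <- posteriors[!labels]
  if (length(pos) == 0 || length(neg) == 0) abort("Both classes must be present.")
  k <- ceiling(target_sensitivity * length(pos))
  cutoff <- sort(pos, decreasing = TRUE)[k]
  list(
    cutoff = cutoff,
    sensitivity = mean(pos >= cutoff),
    specificity = mean(neg < cutoff),
    n_tp = sum(pos >= cutoff)
  )
}

#' Fit a fixed-sensitivity risk model
#'
#' Fits the progression classifier: a PCA transform of the feature set
#' (mixed scaling, see [fit_pca()]), maximum-likelihood logistic regression
#' of the 5-year progression labels on the first `n_components` component
#' scores, and a posterior cutoff fixed at the target sensitivity with
#' [choose_cutoff()]. If the logistic fit fails to converge or separates
#' perfectly, a ridge-penalized fit (penalty 1e-6) is used instead and
#' flagged in the metadata. Evaluation is in-sample (resubstitution) unless
#' the caller splits the cohort.
#'
#' @param features Feature tibble from [assemble_features()].
#' @param labels Logical vector, progression within five years, aligned
#'   with `features`.
#' @param cfg A [pipeline_config()] (`n_components`, `target_sensitivity`).
#' @param dca_membership Optional probe-to-cluster membership tibble stored
#'   with the model so new cohorts can be scored without refitting the
#'   cluster analysis.
#' @return An object of class `risk_model`.
#' @export
fit_risk_model <- function(features, labels, cfg = pipeline_config(),
                           dca_membership = NULL) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) abort("Both outcome classes must be present.")
  if (nrow(features) != length(labels)) abort("`features` and `labels` lengths differ.")
  pca <- fit_pca(features, n_components = cfg$n_components)
  df <- data.frame(y = labels, pca$scores)
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  fallback <- !fit$converged || any(abs(coef(fit)) > 50)
  # the ridge solver needs at least two observations per class; with fewer
  # the unpenalized fit is kept (still flagged)
  if (fallback && min(table(labels)) >= 2) {
    rf <- suppressWarnings(
      glmnet::glmnet(pca$scores, labels, family = "binomial", alpha = 0,
                     lambda = 1e-6, standardize = FALSE, thresh = 1e-12)
    )
    intercept <- as.numeric(rf$a0)
    beta <- as.numeric(rf$beta)
  } else {
    intercept <- unname(coef(fit)[1])
    beta <- unname(coef(fit)[-1])
  }
  eta <- intercept + as.numeric(pca$scores %*% beta)
  posterior <- plogis(eta)
  cut <- choose_cutoff(posterior, labels, cfg$target_sensitivity)
  x <- as.matrix(features[setdiff(names(features), "patient_id")])
  model <- structure(
    list(
      version = "methprog_risk_model/1",
      feature_names = colnames(x),
      kinds = pca$kinds,
      feature_means = colMeans(x),
      center = pca$center,
      scale = pca$scale,
      rotation = pca$rotation,
      intercept = intercept,
      coefficients = setNames(beta, colnames(pca$rotation)),
      cutoff = cut$cutoff,
      sensitivity = cut$sensitivity,
      specificity = cut$specificity,
      metadata = list(
        set_name = attr(features, "set_name") %||% NA_character_,
        target_sensitivity = cfg$target_sensitivity,
        n_components = cfg$n_components,
        n_patients = nrow(features),
        n_positive = sum(labels),
        ridge_fallback = fallback
      ),
      dca_membership = dca_membership,
      training = tibble::tibble(
        patient_id = features$patient_id,
        posterior = posterior,
        label = labels,
        call = ifelse(posterior >= cut$cutoff, "HRP", "LRP")
      )
    ),
    class = "risk_model"
  )
  model
}

#' Predict risk for new patients
#'
#' Applies a fitted [fit_risk_model()] model to new patients without any
#' refitting: missing feature values are imputed with the model's stored
#' training means, then the stored scaling, loadings, logistic coefficients
#' and cutoff produce a posterior probability of progression within five
#' years and the binary call (`HRP` iff posterior >= cutoff).
#'
#' @param object A `risk_model`.
#' @param new_features Feature tibble whose columns match the model's
#'   feature names (order-free); unknown columns are an error.
#' @param ... Unused.
#' @return Tibble with `patient_id`, `posterior`, `call`.
#' @export
predict.risk_model <- function(object, new_features, ...) {
  cols <- setdiff(names(new_features), "patient_id")
  unknown <- setdiff(cols, object$feature_names)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown feature(s): %s", paste(unknown, collapse = ", ")))
  }
  missing_cols <- setdiff(object$feature_names, cols)
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing feature(s): %s", paste(head(missing_cols, 5), collapse = ", ")))
  }
  x <- as.matrix(new_features[object$feature_names])
  storage.mode(x) <- "double"
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- object$feature_means[j]
  }
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  eta <- object$intercept + as.numeric(xs %*% object$rotation %*% object$coefficients)
  posterior <- plogis(eta)
  tibble::tibble(
    patient_id = as.character(new_features$patient_id %||% seq_len(nrow(x))),
    posterior = posterior,
    call = ifelse(posterior >= object$cutoff, "HRP", "LRP")
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model>", x$metadata$set_name, "\n")
  cat(sprintf("  %d features -> %d PCs; cutoff %.4f (sensitivity %.2f, specificity %.2f)\n",
              length(x$feature_names), length(x$coefficients),
              x$cutoff, x$sensitivity, x$specificity))
  if (isTRUE(x$metadata$ridge_fallback)) cat("  note: ridge fallback used\n")
  invisible(x)
}

#' @rdname fit_risk_model
#' @param x A `risk_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.risk_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @rdname fit_risk_model
#' @exportS3Method generics::glance
glance.risk_model <- function(x, ...) {
  tibble::tibble(
    set_name = x$metadata$set_name,
    n = x$metadata$n_patients,
    n_positive = x$metadata$n_positive,
    cutoff = x$cutoff,
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    auc = roc_auc(x$training$posterior, x$training$label),
    ridge_fallback = x$metadata$ridge_fallback
  )
}

#' Posterior distribution plot for a risk model
#'
#' @param object A `risk_model`.
#' @param ... Unused.
#' @return A ggplot showing training posteriors by true outcome with the
#'   fixed-sensitivity cutoff.
#' @exportS3Method ggplot2::autoplot
autoplot.risk_model <- function(object, ...) {
  d <- object$training |>
    dplyr::mutate(outcome = ifelse(.data$label, "progression", "progression-free"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$posterior, fill = .data$outcome)) +
    ggplot2::geom_histogram(bins = 20, position = "identity", alpha = 0.6,
                            boundary = 0) +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(x = "posterior probability of 5-year progression",
                  y = "patients",
                  title = sprintf("%s classifier (cutoff %.3f)",
                                  object$metadata$set_name, object$cutoff)) +
    ggplot2::theme_minimal()
}
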