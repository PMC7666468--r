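#' Serialize a fitted risk model to structured text
#'
#' Writes a versioned JSON document carrying everything needed to score new
#' patients without refitting: feature names and kinds, imputation means,
#' scaling parameters, PCA loadings, logistic coefficients, the
#' fixed-sensitivity cutoff, and (when present) the DCA probe-to-cluster
#' membership. Numbers are written at full double precision, so a model
#' round-trips without loss and identical fits serialize to identical text.
#'
#' @param model A `risk_model` from [fit_risk_model()].
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
serialize_model <- function(model, path = NULL) {
  if (!inherits(model, "risk_model")) abort("`model` must be a risk_model.")
  doc <- list(
    version = model$version,
    feature_names = model$feature_names,
    kinds = as.list(model$kinds),
    feature_means = as.list(model$feature_means),
    center = as.list(model$center),
    scale = as.list(model$scale),
    rotation = list(
      rows = rownames(model$rotation),
      cols = colnames(model$rotation),
      values = lapply(seq_len(nrow(model$rotation)),
                      function(i) unname(model$rotation[i, ]))
    ),
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    cutoff = model$cutoff,
    sensitivity = model$sensitivity,
    specificity = model$specificity,
    metadata = model$metadata,
    dca_membership = if (is.null(model$dca_membership)) NULL else
      as.list(model$dca_membership)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), null = "null",
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Deserialize a risk model
#'
#' Inverse of [serialize_model()]. A document whose version tag does not
#' match the current format, or that cannot be parsed, is an error.
#'
#' @param input Path to a serialized model file, or the JSON string itself.
#' @return A `risk_model` that predicts identically to the serialized fit.
#' @export
deserialize_model <- function(input) {
  txt <- if (length(input) == 1 && file.exists(input)) {
    paste(readLines(input, warn = FALSE), collapse = "\n")
  } else {
    paste(input, collapse = "\n")
  }
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
                  error = function(e) abort(sprintf("Cannot parse model document: %s",
                                                    conditionMessage(e))))
  if (!identical(doc$version, "methprog_risk_model/1")) {
    abort(sprintf("Unsupported model version tag: %s",
                  doc$version %||% "<missing>"))
  }
  rot <- doc$rotation$values
  if (!is.matrix(rot)) rot <- do.call(rbind, rot)
  dimnames(rot) <- list(doc$rotation$rows, doc$rotation$cols)
  membership <- if (!is.null(doc$dca_membership)) {
    tibble::tibble(probe_id = doc$dca_membership$probe_id,
                   cluster = as.integer(doc$dca_membership$cluster))
  }
  structure(
    list(
      version = doc$version,
      feature_names = doc$feature_names,
      kinds = unlist(doc$kinds),
      feature_means = unlist(doc$feature_means),
      center = unlist(doc$center),
      scale = unlist(doc$scale),
      rotation = rot,
      intercept = doc$intercept,
      coefficients = unlist(doc$coefficients),
      cutoff = doc$cutoff,
      sensitivity = doc$sensitivity,
      specificity = doc$specificity,
      metadata = doc$metadata,
      dca_membership = membership,
      training = NULL
    ),
    class = "risk_model"
  )
}
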