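#' Proportional-odds staging model
#'
#' Parameter object for the cumulative-logit (proportional-odds) staging
#' model. With linear predictor `bx = sum(slopes * features)`, the
#' cumulative probabilities are `P(stage <= j) = plogis(alpha_j - bx)` for
#' ordered thresholds `alpha_1 < alpha_2 < alpha_3`; larger `bx` therefore
#' means a more mature stage.
#'
#' @param slopes Named numeric vector of per-feature log-odds slopes; names
#'   must be `"age"` or entries of [cvm_feature_names].
#' @param thresholds Strictly increasing numeric vector of stage
#'   thresholds (length J-1 for J stages; 3 for the four-stage model).
#' @param scale `"raw"` (slopes apply to raw measurements, the default) or
#'   `"zscored"` (features are standardised with `center`/`scale` first).
#' @param center,scale_values Named per-feature means/SDs, required when
#'   `scale = "zscored"`.
#' @return Object of class `cvm_ordinal_model`.
#' @seealso [cvm_primary_model()] for the packaged published model.
#' @export
cvm_ordinal_model <- function(slopes, thresholds, scale = c("raw", "zscored"),
                              center = NULL, scale_values = NULL) {
  scale <- match.arg(scale)
  slopes <- unlist(slopes)
  check_slope_names(names(slopes))
  thresholds <- as.numeric(unlist(thresholds))
  if (length(thresholds) < 1 || any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  if (scale == "zscored" && (is.null(center) || is.null(scale_values))) {
    stop("zscored models need per-feature center and scale_values",
         call. = FALSE)
  }
  structure(list(slopes = slopes, thresholds = thresholds, scale = scale,
                 center = center, scale_values = scale_values),
            class = "cvm_ordinal_model")
}

#' Binary correction model for the iCS3/iCS4 decision
#'
#' Parameter object for the binary logistic disambiguator applied after
#' the primary model when it predicts one of the two most mature stages.
#' `P(iCS = 3) = plogis(threshold - bx)`: probability mass below the
#' single cutpoint, with the same link convention as the ordinal model.
#'
#' @param slopes Named numeric vector of log-odds slopes.
#' @param threshold Single cutpoint alpha.
#' @param cut Probability cut for the binary decision (default 0.5):
#'   `P(iCS = 3) >= cut` decides stage 3, otherwise stage 4.
#' @return Object of class `cvm_binary_model`.
#' @seealso [cvm_correction_model()] for the packaged published model.
#' @export
cvm_binary_model <- function(slopes, threshold, cut = 0.5) {
  slopes <- unlist(slopes)
  check_slope_names(names(slopes))
  threshold <- as.numeric(threshold)
  stopifnot(length(threshold) == 1, is.finite(threshold),
            cut > 0, cut < 1)
  structure(list(slopes = slopes, threshold = threshold, cut = cut),
            class = "cvm_binary_model")
}

check_slope_names <- function(nm) {
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("slopes must be a named vector", call. = FALSE)
  }
  bad <- setdiff(nm, c("age", cvm_feature_names))
  if (length(bad)) {
    stop("unknown feature name(s) in slopes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(nm)
}

#' Packaged primary staging model
#'
#' The published four-stage proportional-odds model: slopes 3.172 (age,
#' years), 28.642 (D3:AH3 ratio), 0.727 (antero-superior angle of C4,
#' degrees) and 0.453 (C3lp-C4up distance, mm), with stage thresholds
#' 32.921, 45.460 and 62.065. Coefficients apply to raw measurement
#' values.
#'
#' @return A `cvm_ordinal_model`.
#' @export
cvm_primary_model <- function() {
  cvm_ordinal_model(
    slopes = c(age = 3.172, D3_AH3 = 28.642, ang4 = 0.727,
               C3lp_C4up = 0.453),
    thresholds = c(32.921, 45.460, 62.065)
  )
}

#' Packaged iCS3/iCS4 correction model
#'
#' The published binary logistic disambiguator for separating the third
#' and fourth stages: slopes 2.139 (age, years), 0.313 (antero-superior
#' angle of C4, degrees) and 1.444 (posterior height of C4, mm), with
#' cutpoint 51.828 and decision cut 0.5.
#'
#' @return A `cvm_binary_model`.
#' @export
cvm_correction_model <- function() {
  cvm_binary_model(
    slopes = c(age = 2.139, ang4 = 0.313, PH4 = 1.444),
    threshold = 51.828
  )
}

#' Load a packaged model by name
#'
#' @param name `"primary-2024"` or `"correction-2024"`.
#' @return The corresponding model object.
#' @export
cvm_published_model <- function(name) {
  switch(name,
    "primary-2024" = cvm_primary_model(),
    "correction-2024" = cvm_correction_model(),
    stop("unknown packaged model name: ", name, call. = FALSE)
  )
}

model_features <- function(model) names(model$slopes)

feature_matrix <- function(model, features) {
  nm <- model_features(model)
  if (is.numeric(features) && !is.null(names(features))) {
    features <- as.data.frame(as.list(features))
  }
  mis <- setdiff(nm, names(features))
  if (length(mis)) {
    stop("missing model feature(s): ", paste(mis, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(as.data.frame(features)[, nm, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("NA feature values supplied to the model",
                     call. = FALSE)
  if (identical(model$scale, "zscored")) {
    X <- sweep(sweep(X, 2, model$center[nm]), 2, model$scale_values[nm], "/")
  }
  X
}

#' Linear predictor of a staging model
#'
#' `bx = sum_k slope_k * feature_k` on the model's measurement scale.
#'
#' @param model A `cvm_ordinal_model` or `cvm_binary_model`.
#' @param features Named numeric vector, or data frame with one column per
#'   model feature (extra columns ignored).
#' @return Numeric vector of linear predictors, one per row.
#' @export
linear_predictor <- function(model, features) {
  X <- feature_matrix(model, features)
  drop(X %*% model$slopes[colnames(X)])
}

#' Stage probabilities from a linear predictor
#'
#' Cumulative probabilities `gamma_j = P(stage <= j) =
#' plogis(alpha_j - bx)` (with `gamma_0 = 0`, `gamma_J = 1`) are
#' differenced into per-stage probabilities. The logistic is evaluated in
#' its numerically stable form; no overflow occurs for `|bx|` up to 1e4
#' and beyond.
#'
#' @param model A `cvm_ordinal_model`.
#' @param bx Numeric vector of linear predictors.
#' @return Matrix with one row per `bx` value and one column per stage
#'   (`P1` ... `P4`); rows sum to 1.
#' @export
stage_probabilities <- function(model, bx) {
  stopifnot(inherits(model, "cvm_ordinal_model"))
  J <- length(model$thresholds) + 1
  gam <- vapply(model$thresholds, function(a) plogis(a - bx),
                numeric(length(bx)))
  gam <- matrix(gam, nrow = length(bx))
  p <- cbind(gam, 1) - cbind(0, gam)
  colnames(p) <- paste0("P", seq_len(J))
  rownames(p) <- NULL
  p
}

# argmax with ties broken toward the more mature stage
argmax_stage <- function(p) {
  apply(p, 1, function(r) max(which(r == max(r))))
}

#' Predict stages with the primary ordinal model
#'
#' Composes [linear_predictor()] and [stage_probabilities()]; the
#' predicted stage is the probability argmax, with ties broken toward the
#' more mature stage (mirroring the convention that in-between morphology
#' is assigned to the more mature stage).
#'
#' @param object A `cvm_ordinal_model`.
#' @param newdata Feature data frame (or named vector).
#' @param ... Unused.
#' @return Data frame of class `cvm_prediction`: `subject_id` (if
#'   present in `newdata`), `bx_primary`, `P1`..`P4`, `stage_primary`.
#' @export
predict.cvm_ordinal_model <- function(object, newdata, ...) {
  bx <- linear_predictor(object, newdata)
  p <- stage_probabilities(object, bx)
  out <- data.frame(bx_primary = bx, p,
                    stage_primary = as.integer(argmax_stage(p)))
  if (is.data.frame(newdata) && "subject_id" %in% names(newdata)) {
    out <- cbind(subject_id = newdata$subject_id, out)
  }
  structure(out, class = c("cvm_prediction", "data.frame"))
}

#' Probability that a borderline subject is in stage 3
#'
#' `P(iCS = 3) = plogis(threshold - bx)` under the binary correction
#' model: the probability mass below the single cutpoint, with the same
#' link convention as the ordinal model.
#'
#' @param model A `cvm_binary_model`.
#' @param features Feature data frame or named vector.
#' @return Numeric vector of probabilities.
#' @export
correction_probability <- function(model, features) {
  stopifnot(inherits(model, "cvm_binary_model"))
  bx <- linear_predictor(model, features)
  plogis(model$threshold - bx)
}

#' @rdname correction_probability
#' @param object A `cvm_binary_model`.
#' @param newdata Feature data frame.
#' @param ... Unused.
#' @export
predict.cvm_binary_model <- function(object, newdata, ...) {
  p3 <- correction_probability(object, newdata)
  data.frame(bx_correction = linear_predictor(object, newdata),
             P_iCS3 = p3,
             stage = ifelse(p3 >= object$cut, 3L, 4L))
}

#' Cascade staging: primary model plus iCS3/iCS4 correction
#'
#' Runs the primary ordinal model; whenever the primary prediction is one
#' of the trigger stages (default 3 and 4, the two classes the correction
#' model separates), the binary correction model re-decides between
#' stages 3 and 4: final stage 3 when `P(iCS = 3) >= cut`, else 4.
#' Primary predictions of stage 1 or 2 are never altered.
#'
#' @param features Feature data frame (or named vector) containing the
#'   union of both models' features.
#' @param primary A `cvm_ordinal_model` (default: the packaged published
#'   model).
#' @param correction A `cvm_binary_model` (default: the packaged
#'   published correction model).
#' @param trigger Primary stages that trigger the correction
#'   (default `c(3, 4)`).
#' @param cut Probability cut for the binary decision; defaults to the
#'   correction model's own `cut`.
#' @return Data frame of class `cvm_prediction`: `subject_id` (if
#'   present), `bx_primary`, `P1`..`P4`, `stage_primary`,
#'   `bx_correction`, `P_iCS3`, `stage_final`, `correction_applied`.
#' @export
predict_cascade <- function(features, primary = cvm_primary_model(),
                            correction = cvm_correction_model(),
                            trigger = c(3, 4), cut = correction$cut) {
  out <- predict(primary, features)
  # the cascade needs the union of both models' features up front
  Xc <- feature_matrix(correction, features)
  out$bx_correction <- NA_real_
  out$P_iCS3 <- NA_real_
  out$stage_final <- out$stage_primary
  out$correction_applied <- out$stage_primary %in% trigger
  if (any(out$correction_applied)) {
    idx <- which(out$correction_applied)
    bxc <- drop(Xc[idx, , drop = FALSE] %*% correction$slopes[colnames(Xc)])
    p3 <- plogis(correction$threshold - bxc)
    out$bx_correction[idx] <- bxc
    out$P_iCS3[idx] <- p3
    out$stage_final[idx] <- ifelse(p3 >= cut, 3L, 4L)
  }
  structure(out, class = c("cvm_prediction", "data.frame"))
}

#' @export
print.cvm_ordinal_model <- function(x, ...) {
  cat("Proportional-odds CVM staging model (", length(x$thresholds) + 1,
      " stages, ", x$scale, " scale)\n", sep = "")
  cat("  slopes:\n")
  for (nm in names(x$slopes)) {
    cat(sprintf("    %-10s %8.3f\n", nm, x$slopes[[nm]]))
  }
  cat("  thresholds:", paste(sprintf("%.3f", x$thresholds),
                             collapse = " < "), "\n")
  invisible(x)
}

#' @export
print.cvm_binary_model <- function(x, ...) {
  cat("Binary iCS3/iCS4 correction model (decision cut ",
      format(x$cut), ")\n", sep = "")
  cat("  slopes:\n")
  for (nm in names(x$slopes)) {
    cat(sprintf("    %-10s %8.3f\n", nm, x$slopes[[nm]]))
  }
  cat("  cutpoint:", sprintf("%.3f", x$threshold), "\n")
  invisible(x)
}

#' @export
coef.cvm_ordinal_model <- function(object, ...) {
  c(object$slopes,
    setNames(object$thresholds,
             paste0("threshold", seq_along(object$thresholds))))
}

#' @export
coef.cvm_binary_model <- function(object, ...) {
  c(object$slopes, threshold = object$threshold)
}

#' @export
print.cvm_prediction <- function(x, ...) {
  cat("CVM stage predictions for", nrow(x), "subject(s)\n")
  stg <- if ("stage_final" %in% names(x)) x$stage_final else x$stage_primary
  cat("  predicted stages:", paste(sprintf("iCS%d: %d", 1:4,
      tabulate(stg, 4)), collapse = ", "), "\n")
  if ("correction_applied" %in% names(x)) {
    cat("  correction applied to", sum(x$correction_applied),
        "subject(s)\n")
  }
  NextMethod()
}

#' Save / load staging models as JSON
#'
#' Models round-trip through a small JSON schema
#' (`{"kind": "ordinal"|"binary", "slopes": {...}, "thresholds": [...],
#' "scale": "raw", ...}`) with full double precision.
#'
#' @param model A `cvm_ordinal_model` or `cvm_binary_model`.
#' @param path JSON file path.
#' @return `save_model`: `path`, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "cvm_ordinal_model")) {
    obj <- list(kind = "ordinal", slopes = as.list(model$slopes),
                thresholds = model$thresholds, scale = model$scale)
    if (identical(model$scale, "zscored")) {
      obj$center <- as.list(model$center)
      obj$scale_values <- as.list(model$scale_values)
    }
  } else if (inherits(model, "cvm_binary_model")) {
    obj <- list(kind = "binary", slopes = as.list(model$slopes),
                thresholds = model$threshold, cut = model$cut)
  } else {
    stop("not a staging model object", call. = FALSE)
  }
  # 17 significant digits: doubles survive the round-trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$kind)) stop("model JSON missing 'kind'", call. = FALSE)
  slopes <- unlist(obj$slopes)
  if (identical(obj$kind, "ordinal")) {
    cvm_ordinal_model(slopes, obj$thresholds,
                      scale = if (is.null(obj$scale)) "raw" else obj$scale,
                      center = if (!is.null(obj$center)) unlist(obj$center),
                      scale_values = if (!is.null(obj$scale_values))
                        unlist(obj$scale_values))
  } else if (identical(obj$kind, "binary")) {
    cvm_binary_model(slopes, obj$thresholds,
                     cut = if (is.null(obj$cut)) 0.5 else obj$cut)
  } else {
    stop("unknown model kind: ", obj$kind, call. = FALSE)
  }
}
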