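#' Run the full model-development pipeline on a cohort
#'
#' Reproduces the staging-model development procedure on any cohort:
#'
#' 1. extract the morphometric features (if given landmarks),
#' 2. univariate Spearman screen of age + all 24 features against the
#'    true stage; candidates are features with `p < alpha_screen`,
#' 3. multivariable proportional-odds fit on the candidates,
#' 4. backward elimination: iteratively refit after dropping the feature
#'    with the largest non-significant Wald p-value (`>= alpha_retain`)
#'    until every retained feature is significant,
#' 5. diagnostics on the final fit: Brant proportional-odds test and
#'    variance inflation factors.
#'
#' @param cohort A [cvm_cohort] with `true_stage` set, or a
#'   `cvm_features` data frame containing `true_stage`.
#' @param alpha_screen Univariate screening level (default 0.05; no
#'   multiple-testing correction, matching the original pipeline).
#' @param alpha_retain Wald significance level for retaining a feature in
#'   the multivariable model (default 0.05).
#' @param diagnostics Run Brant/VIF diagnostics on the final fit.
#' @return Object of class `cvm_development`: list with `screening`
#'   (a `cvm_screen`), `fit` (the final `cvm_fit`), `retained`
#'   (character), `dropped` (character, in drop order), `brant`, `vif`.
#' @export
develop_model <- function(cohort, alpha_screen = 0.05,
                          alpha_retain = 0.05, diagnostics = TRUE) {
  feats <- if (inherits(cohort, "cvm_cohort")) {
    extract_features(cohort)
  } else {
    as.data.frame(cohort)
  }
  if (!"true_stage" %in% names(feats) || all(is.na(feats$true_stage))) {
    stop("development needs true_stage labels", call. = FALSE)
  }
  keep <- !is.na(feats$true_stage)
  feats <- feats[keep, , drop = FALSE]
  stage <- as.integer(feats$true_stage)

  candidates <- intersect(c("age", cvm_feature_names), names(feats))
  if (!length(candidates)) stop("no candidate feature columns found",
                                call. = FALSE)
  screening <- spearman_screen(feats[, candidates, drop = FALSE], stage,
                               alpha = alpha_screen)
  retained <- screening$feature[screening$pass]
  if (!length(retained)) {
    stop("no feature passed the univariate screen at alpha = ",
         alpha_screen, call. = FALSE)
  }

  dat <- cbind(stage = stage, feats[, candidates, drop = FALSE])
  dropped <- character(0)
  fit <- NULL
  repeat {
    fit <- fit_proportional_odds(
      stats::reformulate(retained, response = "stage"), dat)
    ct <- fit$coefficients
    ct <- ct[!grepl("^threshold", ct$term), ]
    worst <- which.max(ct$p_value)
    if (ct$p_value[worst] < alpha_retain) break
    dropped <- c(dropped, ct$term[worst])
    retained <- setdiff(retained, ct$term[worst])
    if (!length(retained)) {
      stop("backward elimination removed every feature; ",
           "no significant multivariable model exists at alpha = ",
           alpha_retain, call. = FALSE)
    }
  }

  brant <- NULL
  vifs <- NULL
  if (diagnostics) {
    brant <- if (fit$J >= 3 && length(retained) >= 1) {
      tryCatch(brant_test(fit), error = function(e) {
        warning("Brant test failed: ", conditionMessage(e), call. = FALSE)
        NULL
      })
    }
    vifs <- if (length(retained) >= 2) {
      vif(feats[, retained, drop = FALSE])
    }
  }

  structure(
    list(screening = screening, fit = fit, retained = retained,
         dropped = dropped, brant = brant, vif = vifs,
         n = nrow(feats)),
    class = "cvm_development"
  )
}

#' @export
print.cvm_development <- function(x, ...) {
  cat("CVM model development on", x$n, "subjects\n")
  cat("  screened:", nrow(x$screening), "features;",
      sum(x$screening$pass), "passed univariate screen\n")
  if (length(x$dropped)) {
    cat("  dropped in backward elimination:",
        paste(x$dropped, collapse = ", "), "\n")
  }
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  print(summary(x$fit))
  if (!is.null(x$brant)) {
    cat("Brant proportional-odds test:\n")
    print(as.data.frame(x$brant), digits = 4, row.names = FALSE)
  }
  if (!is.null(x$vif)) {
    cat("Variance inflation factors:\n")
    print(x$vif, digits = 4, row.names = FALSE)
  }
  invisible(x)
}
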