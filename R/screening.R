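#' Z-score standardisation of a feature table
#'
#' Centres and scales every numeric feature column to mean 0, SD 1, and
#' stores the centring constants so the transform can be inverted with
#' [unzscore()].
#'
#' @param x Numeric data frame or matrix (n >= 2 rows).
#' @return Standardised data frame with attributes `center` and `scale`.
#' @export
zscore <- function(x) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, TRUE)
  if (!all(num)) {
    stop("zscore() expects numeric columns; offending: ",
         paste(names(x)[!num], collapse = ", "), call. = FALSE)
  }
  if (nrow(x) < 2) stop("need at least 2 rows to standardise",
                        call. = FALSE)
  ctr <- vapply(x, mean, 0)
  scl <- vapply(x, stats::sd, 0)
  if (any(scl == 0)) {
    stop("zero-variance column(s): ",
         paste(names(x)[scl == 0], collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(mapply(function(col, m, s) (col - m) / s,
                              x, ctr, scl, SIMPLIFY = FALSE))
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' @rdname zscore
#' @param z Output of [zscore()].
#' @export
unzscore <- function(z) {
  ctr <- attr(z, "center")
  scl <- attr(z, "scale")
  if (is.null(ctr) || is.null(scl)) {
    stop("not a zscore() result: center/scale attributes missing",
         call. = FALSE)
  }
  out <- as.data.frame(mapply(function(col, m, s) col * s + m,
                              as.data.frame(z), ctr, scl,
                              SIMPLIFY = FALSE))
  attr(out, "center") <- NULL
  attr(out, "scale") <- NULL
  out
}

# Spearman rho with average ranks for ties, p via the t-approximation
spearman_rho_p <- function(x, y) {
  n <- length(x)
  rho <- suppressWarnings(stats::cor(rank(x), rank(y)))
  if (is.na(rho)) return(c(rho = NA_real_, p = NA_real_))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2))
}

#' Univariate Spearman screening of features against stage
#'
#' For every feature, the Spearman rank correlation with the maturation
#' stage (average ranks for ties) and a two-sided p-value from the
#' t-approximation; features with `p < alpha` pass the screen. No
#' multiple-testing correction is applied (matching the original
#' development pipeline); this is noted in the report.
#'
#' @param features Numeric data frame of candidate features.
#' @param stages Integer stage vector (same length as rows of `features`).
#' @param alpha Significance level (default 0.05).
#' @return Data frame of class `cvm_screen`: `feature`, `rho`,
#'   `p_value`, `pass`.
#' @export
spearman_screen <- function(features, stages, alpha = 0.05) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(stages))
  res <- t(vapply(features, spearman_rho_p, c(rho = 0, p = 0), y = stages))
  out <- data.frame(feature = rownames(res), rho = res[, "rho"],
                    p_value = res[, "p"],
                    pass = res[, "p"] < alpha, row.names = NULL)
  attr(out, "alpha") <- alpha
  attr(out, "note") <- "univariate screen; no multiple-testing correction"
  structure(out, class = c("cvm_screen", "data.frame"))
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` from the ordinary least-squares regression of
#' feature k on all other features; `tolerance = 1/VIF`. Features with
#' `VIF >= 5` (tolerance < 0.2) are flagged as collinear.
#'
#' @param features Numeric data frame with at least two columns.
#' @param included Optional character vector restricting the columns.
#' @return Data frame: `feature`, `r_squared`, `vif`, `tolerance`,
#'   `flag` (TRUE when VIF >= 5).
#' @export
vif <- function(features, included = NULL) {
  features <- as.data.frame(features)
  if (!is.null(included)) {
    mis <- setdiff(included, names(features))
    if (length(mis)) stop("unknown feature(s): ",
                          paste(mis, collapse = ", "), call. = FALSE)
    features <- features[, included, drop = FALSE]
  }
  if (ncol(features) < 2) {
    stop("VIF needs at least two features", call. = FALSE)
  }
  out <- do.call(rbind, lapply(names(features), function(nm) {
    fit <- lm(stats::reformulate(setdiff(names(features), nm),
                                 response = nm), data = features)
    r2 <- suppressWarnings(summary(fit)$r.squared)
    v <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    data.frame(feature = nm, r_squared = r2, vif = v,
               tolerance = 1 / v, flag = v >= 5)
  }))
  rownames(out) <- NULL
  out
}

#' Brant test of the proportional-odds assumption
#'
#' Fits the J-1 separate binary logistic models for the indicators
#' `y > j` and compares their slope vectors: under proportional odds the
#' slopes are equal across cutpoints. The Wald chi-square uses the
#' classical cross-model covariance estimate built from the fitted
#' cutpoint probabilities. Reports the omnibus statistic
#' (df = (J-2) * k) and a per-variable statistic (df = J-2) for each
#' slope.
#'
#' @param fit A `cvm_fit` from [fit_proportional_odds()] (J >= 3), or
#'   `NULL` if `X` and `y` are given directly.
#' @param X Optional feature matrix (overrides the one stored in `fit`).
#' @param y Optional integer stage vector.
#' @return Data frame of class `cvm_brant`: `term` ("omnibus" plus each
#'   feature), `chi_square`, `df`, `p_value`.
#' @references Brant, R. (1990) Assessing proportionality in the
#'   proportional odds model for ordinal logistic regression.
#'   *Biometrics* 46, 1171--1178.
#' @export
brant_test <- function(fit = NULL, X = NULL, y = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "cvm_fit"))
    if (is.null(X)) X <- fit$X
    if (is.null(y)) y <- fit$y
  }
  X <- as.matrix(X)
  y <- as.integer(y)
  J <- max(y)
  k <- ncol(X)
  if (J < 3) {
    stop("the Brant test needs at least 3 ordered classes ",
         "(slope equality across cutpoints is undefined for J = 2)",
         call. = FALSE)
  }
  n <- nrow(X)
  X1 <- cbind(`(Intercept)` = 1, X)

  betas <- matrix(NA_real_, k, J - 1)
  pis <- matrix(NA_real_, n, J - 1)
  for (j in seq_len(J - 1)) {
    z <- as.integer(y > j)
    g <- suppressWarnings(glm.fit(X1, z, family = binomial()))
    betas[, j] <- g$coefficients[-1]
    pis[, j] <- g$fitted.values
  }

  # cross-model covariance blocks (slopes only)
  inv_info <- lapply(seq_len(J - 1), function(j) {
    w <- pis[, j] * (1 - pis[, j])
    solve(crossprod(X1, X1 * w))
  })
  idx <- 2:(k + 1)
  V <- matrix(0, (J - 1) * k, (J - 1) * k)
  for (j in seq_len(J - 1)) {
    for (l in j:(J - 1)) {
      w_jl <- pis[, l] - pis[, j] * pis[, l]   # l >= j: pi_l <= pi_j
      blk <- inv_info[[j]] %*% crossprod(X1, X1 * w_jl) %*% inv_info[[l]]
      blk <- blk[idx, idx, drop = FALSE]
      rj <- (j - 1) * k + seq_len(k)
      rl <- (l - 1) * k + seq_len(k)
      V[rj, rl] <- blk
      if (l != j) V[rl, rj] <- t(blk)
    }
  }
  beta_vec <- as.vector(betas)

  wald <- function(D) {
    delta <- D %*% beta_vec
    chi <- drop(t(delta) %*% solve(D %*% V %*% t(D)) %*% delta)
    c(chi = chi, df = nrow(D))
  }

  D_omni <- matrix(0, (J - 2) * k, (J - 1) * k)
  for (j in seq_len(J - 2)) {
    rows <- (j - 1) * k + seq_len(k)
    D_omni[cbind(rows, (j - 1) * k + seq_len(k))] <- 1
    D_omni[cbind(rows, j * k + seq_len(k))] <- -1
  }
  omni <- wald(D_omni)

  per_var <- t(vapply(seq_len(k), function(m) {
    Dm <- matrix(0, J - 2, (J - 1) * k)
    for (j in seq_len(J - 2)) {
      Dm[j, (j - 1) * k + m] <- 1
      Dm[j, j * k + m] <- -1
    }
    wald(Dm)
  }, c(chi = 0, df = 0)))

  out <- data.frame(
    term = c("omnibus", colnames(X)),
    chi_square = c(omni["chi"], per_var[, "chi"]),
    df = as.integer(c(omni["df"], per_var[, "df"])),
    row.names = NULL
  )
  out$p_value <- pchisq(out$chi_square, out$df, lower.tail = FALSE)
  structure(out, class = c("cvm_brant", "data.frame"))
}
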