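# Maximum-likelihood fitting of the cumulative-logit (proportional-odds)
# model P(y <= j) = plogis(alpha_j - x'beta), by damped Newton iteration
# with analytic gradient and Hessian. Thresholds are optimised in the
# order-enforcing parameterisation (a1, a1 + e^{d2}, a1 + e^{d2} + e^{d3},
# ...). The binary logistic fit is the J = 2 special case of the same
# engine.

# log-likelihood, gradient and Hessian in the natural (alpha, beta)
# parameterisation; X is n x k, y integer in 1..J
po_loglik_parts <- function(alpha, beta, X, y, J, want_hessian = TRUE) {
  n <- nrow(X)
  k <- ncol(X)
  eta <- if (k) drop(X %*% beta) else numeric(n)
  a_hi <- c(alpha, Inf)[y]
  a_lo <- c(-Inf, alpha)[y]
  s_hi <- plogis(a_hi - eta)
  s_lo <- plogis(a_lo - eta)
  p <- pmax(s_hi - s_lo, 1e-300)
  ll <- sum(log(p))

  u_hi <- s_hi * (1 - s_hi)   # logistic density at the upper cutpoint
  u_lo <- s_lo * (1 - s_lo)   # ... and at the lower cutpoint (0 at +/-Inf)
  ga <- numeric(J - 1)
  hi_term <- u_hi / p
  lo_term <- u_lo / p
  for (j in seq_len(J - 1)) {
    ga[j] <- sum(hi_term[y == j]) - sum(lo_term[y == j + 1])
  }
  g_eta <- (u_lo - u_hi) / p
  gb <- if (k) drop(crossprod(X, g_eta)) else numeric(0)
  grad <- c(ga, gb)
  if (!want_hessian) {
    return(list(loglik = ll, grad = grad))
  }

  # second derivatives
  dh <- u_hi * (1 - 2 * s_hi)  # d u_hi / d a_hi
  dl <- u_lo * (1 - 2 * s_lo)
  Haa <- matrix(0, J - 1, J - 1)
  Hab <- matrix(0, J - 1, max(k, 1))[, seq_len(k), drop = FALSE]
  c_hi <- -dh / p + u_hi * (u_hi - u_lo) / p^2   # d2 logp / d a_hi d eta
  c_lo <- dl / p - u_lo * (u_hi - u_lo) / p^2    # d2 logp / d a_lo d eta
  for (j in seq_len(J - 1)) {
    sel_hi <- y == j       # obs for which alpha_j is the upper cutpoint
    sel_lo <- y == j + 1   # ... the lower cutpoint
    Haa[j, j] <- sum((dh / p - hi_term^2)[sel_hi]) +
      sum((-dl / p - lo_term^2)[sel_lo])
    if (j < J - 1) {
      # obs with y == j+1 touch both alpha_{j+1} (upper) and alpha_j (lower)
      v <- sum((u_hi * u_lo / p^2)[sel_lo])
      Haa[j, j + 1] <- Haa[j, j + 1] + v
      Haa[j + 1, j] <- Haa[j + 1, j] + v
    }
    if (k) {
      Hab[j, ] <- drop(crossprod(X[sel_hi, , drop = FALSE], c_hi[sel_hi])) +
        drop(crossprod(X[sel_lo, , drop = FALSE], c_lo[sel_lo]))
    }
  }
  h_eta <- (dh - dl) / p - ((u_hi - u_lo) / p)^2
  Hbb <- if (k) crossprod(X, X * h_eta) else
    matrix(0, 0, 0)
  H <- rbind(cbind(Haa, Hab), cbind(t(Hab), Hbb))
  list(loglik = ll, grad = grad, hessian = H)
}

# alpha from the transformed threshold parameters (a1, d2, ..., d_{J-1})
theta_to_alpha <- function(th) {
  if (length(th) == 1) return(th)
  cumsum(c(th[1], exp(th[-1])))
}

po_fit_engine <- function(X, y, J, max_iter = 200, tol = 1e-6) {
  n <- nrow(X)
  k <- ncol(X)
  # optimise on the standardised feature scale for conditioning
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) {
    stop("zero-variance feature(s): ",
         paste(colnames(X)[scl == 0], collapse = ", "), call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  prop <- cumsum(tabulate(y, J) / n)[seq_len(J - 1)]
  alpha0 <- qlogis(pmin(pmax(prop, 1e-6), 1 - 1e-6))
  th <- c(alpha0[1],
          if (J > 2) log(pmax(diff(alpha0), 1e-3)))
  beta <- numeric(k)

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  parts <- NULL
  repeat {
    iter <- iter + 1
    alpha <- theta_to_alpha(th)
    parts <- po_loglik_parts(alpha, beta, Z, y, J)
    trace <- c(trace, parts$loglik)

    # chain rule into the transformed threshold space
    Tm <- diag(1, J - 1)
    if (J > 2) {
      for (m in 2:(J - 1)) Tm[m:(J - 1), m] <- exp(th[m])
    }
    Tm[, 1] <- 1
    Jac <- rbind(cbind(Tm, matrix(0, J - 1, k)),
                 cbind(matrix(0, k, J - 1), diag(1, k)))
    g_t <- drop(crossprod(Jac, parts$grad))
    H_t <- crossprod(Jac, parts$hessian %*% Jac)
    if (J > 2) {
      for (m in 2:(J - 1)) {
        H_t[m, m] <- H_t[m, m] + sum(parts$grad[m:(J - 1)]) * exp(th[m])
      }
    }

    if (max(abs(g_t)) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break

    # damped Newton ascent step; ridge the Hessian if it is not
    # negative-definite, fall back to steepest ascent if needed
    step <- NULL
    lambda <- 0
    for (try in 1:8) {
      A <- -H_t + diag(lambda, nrow(H_t))
      step <- tryCatch(solve(A, g_t), error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step)) &&
          sum(step * g_t) > 0) break
      lambda <- if (lambda == 0) 1e-4 * max(1, abs(diag(H_t))) else
        lambda * 10
      step <- NULL
    }
    if (is.null(step)) step <- g_t / max(1, sqrt(sum(g_t^2)))

    # line search: never let the log-likelihood decrease
    ll_old <- parts$loglik
    fac <- 1
    repeat {
      th_new <- th + fac * step[seq_len(J - 1)]
      beta_new <- beta + fac * step[-seq_len(J - 1)]
      ll_new <- po_loglik_parts(theta_to_alpha(th_new), beta_new, Z, y, J,
                                want_hessian = FALSE)$loglik
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-10) {
        th_new <- th
        beta_new <- beta
        break
      }
    }
    th <- th_new
    beta <- beta_new
  }

  alpha <- theta_to_alpha(th)
  final <- po_loglik_parts(alpha, beta, Z, y, J)
  vcov_std <- tryCatch(solve(-final$hessian), error = function(e) {
    matrix(NA_real_, J - 1 + k, J - 1 + k)
  })

  # map estimates and covariance back to the raw feature scale
  beta_raw <- beta / scl
  alpha_raw <- alpha + sum(beta_raw * ctr)
  A <- diag(1, J - 1 + k)
  if (k) {
    for (j in seq_len(J - 1)) A[j, J - 1 + seq_len(k)] <- ctr / scl
    for (m in seq_len(k)) A[J - 1 + m, J - 1 + m] <- 1 / scl[m]
  }
  vcov_raw <- A %*% vcov_std %*% t(A)
  par_names <- c(paste0("threshold", seq_len(J - 1)), colnames(X))
  dimnames(vcov_raw) <- list(par_names, par_names)

  list(alpha = alpha_raw, beta = setNames(beta_raw, colnames(X)),
       beta_std = setNames(beta, colnames(X)),
       vcov = vcov_raw, loglik = final$loglik, loglik_trace = trace,
       converged = converged, iterations = iter,
       grad_norm = max(abs(final$grad)))
}

parse_fit_formula <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  list(y = y, X = X)
}

make_coef_table <- function(est, se, level = 0.95) {
  zq <- qnorm(1 - (1 - level) / 2)
  wald <- (est / se)^2
  data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    wald = unname(wald),
    p_value = unname(pchisq(wald, df = 1, lower.tail = FALSE)),
    ci_lower = unname(est - zq * se),
    ci_upper = unname(est + zq * se),
    row.names = NULL
  )
}

#' Fit a proportional-odds staging model by maximum likelihood
#'
#' Fits the cumulative-logit model `P(y <= j) = plogis(alpha_j - x'beta)`
#' with strictly ordered thresholds, by damped Newton iteration on the
#' analytic gradient and Hessian (thresholds parameterised as
#' `alpha_1, alpha_1 + e^{d_2}, ...` to enforce ordering; features are
#' standardised internally for conditioning and results mapped back to
#' the raw scale). Convergence is declared when the gradient
#' infinity-norm falls below `tol`; after `max_iter` iterations the fit
#' is returned with `converged = FALSE`.
#'
#' Standard errors come from the inverse observed information at the
#' maximum; the reported Wald statistic is `(estimate/SE)^2` with a
#' 1-df chi-square p-value, and confidence intervals are
#' `estimate +/- z * SE`, matching the reporting convention of ordinal
#' regression tables in the field.
#'
#' @param formula Model formula, e.g.
#'   `stage ~ age + D3_AH3 + ang4 + C3lp_C4up`. The response must be an
#'   integer (or ordered factor) stage with every level represented.
#' @param data Data frame containing the response and features.
#' @param max_iter,tol Newton iteration controls.
#' @return Object of class `cvm_fit` with elements `model` (a
#'   [cvm_ordinal_model]), `coefficients` (slopes then thresholds:
#'   estimate, SE, Wald, p, CI), `vcov`, `logLik`, `loglik_trace`,
#'   `converged`, `n`, `J`.
#' @examples
#' sim <- simulate_features_from_model(cvm_primary_model(), n = 400,
#'                                     seed = 1)
#' fit <- fit_proportional_odds(stage ~ age + D3_AH3 + ang4 + C3lp_C4up,
#'                              data = sim$features)
#' summary(fit)
#' @export
fit_proportional_odds <- function(formula, data, max_iter = 200,
                                  tol = 1e-6) {
  pf <- parse_fit_formula(formula, data)
  y <- pf$y
  if (is.factor(y)) y <- as.integer(y)
  if (!all(y == round(y)) || min(y) < 1) {
    stop("stages must be positive integers (or an ordered factor)",
         call. = FALSE)
  }
  y <- as.integer(y)
  J <- max(y)
  if (J < 2 || !all(seq_len(J) %in% y)) {
    stop("every stage 1..", J, " must be represented in the data",
         call. = FALSE)
  }
  res <- po_fit_engine(pf$X, y, J, max_iter = max_iter, tol = tol)
  if (any(abs(res$beta_std) > 50)) {
    warning("possible complete separation: |standardized slope| > 50 for ",
            paste(names(res$beta_std)[abs(res$beta_std) > 50],
                  collapse = ", "), call. = FALSE)
  }
  model <- cvm_ordinal_model_internal(res$beta, res$alpha)
  est <- c(res$beta, setNames(res$alpha,
                              paste0("threshold", seq_len(J - 1))))
  se <- sqrt(diag(res$vcov))[c(colnames(pf$X),
                               paste0("threshold", seq_len(J - 1)))]
  structure(
    list(kind = "ordinal", model = model,
         coefficients = make_coef_table(est, se),
         vcov = res$vcov, logLik = res$loglik,
         loglik_trace = res$loglik_trace, converged = res$converged,
         iterations = res$iterations, grad_norm = res$grad_norm,
         n = length(y), J = J, X = pf$X, y = y,
         call = match.call(), formula = formula),
    class = "cvm_fit"
  )
}

# constructor bypassing the canonical-feature-name check (fits on
# arbitrary covariate names, e.g. in simulations, are legitimate)
cvm_ordinal_model_internal <- function(slopes, thresholds) {
  if (length(thresholds) > 1 && any(diff(thresholds) <= 0)) {
    stop("fitted thresholds are not ordered", call. = FALSE)
  }
  structure(list(slopes = slopes, thresholds = as.numeric(thresholds),
                 scale = "raw", center = NULL, scale_values = NULL),
            class = "cvm_ordinal_model")
}

cvm_binary_model_internal <- function(slopes, threshold, cut = 0.5) {
  structure(list(slopes = slopes, threshold = as.numeric(threshold),
                 cut = cut),
            class = "cvm_binary_model")
}

#' Fit a binary logistic disambiguation model
#'
#' Binary logistic maximum likelihood in the same `alpha - x'beta`
#' parameterisation as the correction model: the response `TRUE`/1 is the
#' *lower* (less mature) class, so `P(positive) = plogis(alpha - x'beta)`.
#' This is exactly the two-stage special case of
#' [fit_proportional_odds()] and uses the same Newton engine.
#'
#' @param formula Formula whose response is logical or 0/1 (1 = lower
#'   class, e.g. "is stage 3").
#' @param data Data frame.
#' @param cut Decision probability cut stored in the resulting model.
#' @param max_iter,tol Newton iteration controls.
#' @return Object of class `cvm_fit` with `model` a [cvm_binary_model].
#' @export
fit_binary_logistic <- function(formula, data, cut = 0.5, max_iter = 200,
                                tol = 1e-6) {
  pf <- parse_fit_formula(formula, data)
  y <- pf$y
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) {
    stop("binary response must be logical or 0/1", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("both classes must be represented", call. = FALSE)
  }
  y_ord <- ifelse(y == 1, 1L, 2L)  # positive class is the lower category
  res <- po_fit_engine(pf$X, y_ord, 2L, max_iter = max_iter, tol = tol)
  if (any(abs(res$beta_std) > 50)) {
    warning("possible complete separation: |standardized slope| > 50 for ",
            paste(names(res$beta_std)[abs(res$beta_std) > 50],
                  collapse = ", "), call. = FALSE)
  }
  model <- cvm_binary_model_internal(res$beta, res$alpha, cut = cut)
  est <- c(res$beta, threshold1 = unname(res$alpha))
  se <- sqrt(diag(res$vcov))[c(colnames(pf$X), "threshold1")]
  structure(
    list(kind = "binary", model = model,
         coefficients = make_coef_table(est, se),
         vcov = res$vcov, logLik = res$loglik,
         loglik_trace = res$loglik_trace, converged = res$converged,
         iterations = res$iterations, grad_norm = res$grad_norm,
         n = length(y), J = 2L, X = pf$X, y = y_ord,
         call = match.call(), formula = formula),
    class = "cvm_fit"
  )
}

#' @export
print.cvm_fit <- function(x, ...) {
  cat(if (x$kind == "ordinal") "Proportional-odds" else "Binary logistic",
      "fit:", x$n, "subjects,", x$J, "classes\n")
  cat("  log-likelihood:", sprintf("%.3f", x$logLik),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
summary.cvm_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.cvm_fit")
}

#' @export
print.summary.cvm_fit <- function(x, ...) {
  fit <- x$fit
  ct <- fit$coefficients
  is_thr <- grepl("^threshold", ct$term)
  cat(if (fit$kind == "ordinal") {
    "Multivariate associations determined by ordinal logistic regression\n"
  } else {
    "Multivariate associations determined by binary logistic regression\n"
  })
  fmt <- function(df) {
    data.frame(
      term = df$term,
      B = sprintf("%.3f", df$estimate),
      `SE(B)` = sprintf("%.3f", df$se),
      Wald = sprintf("%.3f", df$wald),
      Sig = sprintf("%.3f", df$p_value),
      CI_lower = sprintf("%.3f", df$ci_lower),
      CI_upper = sprintf("%.3f", df$ci_upper),
      check.names = FALSE
    )
  }
  cat("Thresholds:\n")
  print(fmt(ct[is_thr, ]), row.names = FALSE)
  cat("Location:\n")
  print(fmt(ct[!is_thr, ]), row.names = FALSE)
  cat(sprintf("log-likelihood %.3f; n = %d; %s\n", fit$logLik, fit$n,
              if (fit$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.cvm_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
vcov.cvm_fit <- function(object, ...) object$vcov

#' @export
logLik.cvm_fit <- function(object, ...) {
  structure(object$logLik,
            df = nrow(object$coefficients), class = "logLik")
}

#' @export
predict.cvm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- as.data.frame(object$X)
  predict(object$model, newdata, ...)
}

#' Simulate stage labels from a fitted model
#'
#' Draws stage labels at the fit's own covariate values from the fitted
#' per-stage probabilities.
#'
#' @param object A `cvm_fit` (ordinal).
#' @param nsim Number of simulated label vectors.
#' @param seed RNG seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated stages.
#' @export
simulate.cvm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$kind != "ordinal") {
    stop("simulate() is implemented for ordinal fits", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  bx <- linear_predictor(object$model, as.data.frame(object$X))
  p <- stage_probabilities(object$model, bx)
  out <- as.data.frame(replicate(nsim, apply(p, 1, function(pr) {
    sample.int(length(pr), 1, prob = pr)
  })))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
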