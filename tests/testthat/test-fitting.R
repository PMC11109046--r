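test_that("z-scoring standardises and inverts exactly", {
  set.seed(30)
  x <- data.frame(a = rnorm(50, 10, 3), b = runif(50))
  z <- zscore(x)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(vapply(z, sd, 0)), c(1, 1), tolerance = 1e-9)
  expect_equal(unzscore(z), x, tolerance = 1e-12)
  already <- data.frame(a = as.numeric(scale(x$a)))
  expect_equal(zscore(already)$a, already$a, tolerance = 1e-9)
  expect_error(zscore(data.frame(a = rep(1, 10), b = 1:10)), "a")
})

test_that("Spearman screening flags monotone associations", {
  stages <- rep(1:4, each = 30)
  exact <- data.frame(same = stages, mono = exp(stages),
                      anti = -stages^3)
  rep <- spearman_screen(exact, stages)
  expect_equal(rep$rho[rep$feature == "same"], 1)
  expect_equal(rep$rho[rep$feature == "mono"], 1)   # monotone transform
  expect_equal(rep$rho[rep$feature == "anti"], -1)
  expect_true(all(rep$pass))
})

test_that("Spearman screening holds its false-positive rate under the null", {
  set.seed(31)
  stages <- rep(1:4, each = 120)
  hits <- replicate(1000, {
    p <- spearman_screen(data.frame(noise = rnorm(480)), stages)$p_value
    p < 0.05
  })
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})

test_that("proportional-odds fit matches the 2x2 contingency closed form", {
  # binary feature, 2 stages: alpha = log-odds in x = 0 group,
  # alpha - beta = log-odds in x = 1 group
  counts <- c(n10 = 30, n20 = 10, n11 = 20, n21 = 40)
  d <- data.frame(
    stage = rep(c(1, 2, 1, 2), counts),
    x = rep(c(0, 0, 1, 1), counts)
  )
  fit <- fit_proportional_odds(stage ~ x, d)
  alpha_hat <- coef(fit)[["threshold1"]]
  beta_hat <- coef(fit)[["x"]]
  expect_equal(alpha_hat, log(30 / 10), tolerance = 1e-6)
  expect_equal(alpha_hat - beta_hat, log(20 / 40), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("the fit agrees with an independent ordinal MLE implementation", {
  skip_if_not_installed("MASS")
  sim <- simulate_features_from_model(cvm_primary_model(), n = 1500,
                                      seed = 33)
  d <- sim$features
  form <- stage ~ age + D3_AH3 + ang4 + C3lp_C4up
  fit <- fit_proportional_odds(form, d)
  ref <- MASS::polr(ordered(stage) ~ age + D3_AH3 + ang4 + C3lp_C4up,
                    data = d, Hess = TRUE,
                    control = list(reltol = 1e-14, maxit = 500))
  est <- coef(fit)
  expect_equal(est[names(coef(ref))], coef(ref), tolerance = 1e-4)
  expect_equal(unname(est[paste0("threshold", 1:3)]), unname(ref$zeta),
               tolerance = 1e-4)
  # same optimum (the Newton fit may be marginally tighter than polr's)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-7)
  expect_gte(fit$logLik, as.numeric(logLik(ref)) - 1e-8)
  # Wald machinery: SEs from the observed information
  se_ref <- sqrt(diag(vcov(ref)))
  ct <- fit$coefficients
  expect_equal(ct$se[match(names(coef(ref)), ct$term)],
               unname(se_ref[names(coef(ref))]), tolerance = 1e-3)
})

test_that("coefficient table is internally consistent", {
  sim <- simulate_features_from_model(cvm_primary_model(), n = 800,
                                      seed = 34)
  fit <- fit_proportional_odds(stage ~ age + ang4, sim$features)
  ct <- fit$coefficients
  expect_equal(ct$wald, (ct$estimate / ct$se)^2, tolerance = 1e-6)
  expect_equal(ct$ci_lower, ct$estimate - qnorm(0.975) * ct$se,
               tolerance = 1e-9)
  expect_equal(ct$ci_upper, ct$estimate + qnorm(0.975) * ct$se,
               tolerance = 1e-9)
  # log-likelihood never decreases across Newton iterations
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # fitted thresholds are ordered
  thr <- fit$model$thresholds
  expect_true(all(diff(thr) > 0))
})

test_that("binary logistic fit matches glm and the collapsed ordinal fit", {
  sim <- simulate_features_from_model(cvm_primary_model(), n = 1200,
                                      seed = 35)
  d <- sim$features
  d$low <- as.integer(d$stage <= 2)
  fit <- fit_binary_logistic(low ~ age + ang4, d)
  g <- glm(low ~ age + ang4, data = d, family = binomial)
  # P(low) = plogis(alpha - bx) maps to glm's intercept = alpha,
  # slopes = -beta
  expect_equal(coef(fit)[["threshold1"]], unname(coef(g)[1]),
               tolerance = 1e-5)
  expect_equal(coef(fit)[c("age", "ang4")],
               -coef(g)[c("age", "ang4")], ignore_attr = TRUE,
               tolerance = 1e-5)
  se_g <- sqrt(diag(vcov(g)))
  expect_equal(fit$coefficients$se[match(c("age", "ang4"),
                                         fit$coefficients$term)],
               unname(se_g[c("age", "ang4")]), tolerance = 1e-3)

  # collapsing stages {1,2} vs {3,4} and fitting binary equals the
  # two-class ordinal fit exactly (same engine, same likelihood)
  d$coll <- ifelse(d$stage <= 2, 1L, 2L)
  of <- fit_proportional_odds(coll ~ age + ang4, d)
  expect_equal(coef(fit), coef(of), tolerance = 1e-8)
})

test_that("a 2x2 table binary fit recovers the log odds ratio", {
  counts <- c(a = 25, b = 15, c = 10, d = 50)
  dd <- data.frame(
    pos = rep(c(1, 0, 1, 0), counts),
    x = rep(c(0, 0, 1, 1), counts)
  )
  fit <- fit_binary_logistic(pos ~ x, dd)
  expect_equal(coef(fit)[["threshold1"]], log(25 / 15), tolerance = 1e-6)
  expect_equal(coef(fit)[["x"]],
               log(25 / 15) - log(10 / 50), tolerance = 1e-6)
})

test_that("balanced label-independent data gives near-zero slopes", {
  set.seed(36)
  d <- data.frame(pos = rep(0:1, each = 300), x1 = rnorm(600),
                  x2 = rnorm(600))
  fit <- fit_binary_logistic(pos ~ x1 + x2, d)
  ct <- fit$coefficients
  sl <- ct[ct$term %in% c("x1", "x2"), ]
  expect_true(all(abs(sl$estimate) < 3 * sl$se))
})

test_that("parameter recovery: slopes within 3 SE at n = 5000", {
  sim <- simulate_features_from_model(cvm_primary_model(), n = 5000,
                                      seed = 37)
  fit <- fit_proportional_odds(stage ~ age + D3_AH3 + ang4 + C3lp_C4up,
                               sim$features)
  truth <- cvm_primary_model()$slopes
  ct <- fit$coefficients
  for (nm in names(truth)) {
    row <- ct[ct$term == nm, ]
    expect_lt(abs(row$estimate - truth[[nm]]), 3 * row$se)
  }
  expect_true(fit$converged)
})

test_that("degenerate fitting inputs raise informative errors", {
  d <- data.frame(stage = rep(1:4, each = 10), x = rnorm(40))
  d$flat <- 1
  expect_error(fit_proportional_odds(stage ~ flat, d), "zero-variance")
  expect_error(fit_proportional_odds(stage ~ x, transform(d, stage = 5)),
               "represented")
  expect_error(fit_binary_logistic(stage ~ x, d), "0/1")
  # complete separation is flagged, not silently returned
  set.seed(44)
  sep <- data.frame(stage = rep(1:2, each = 20),
                    xs = c(runif(20, 0, 1), runif(20, 1.0001, 2)))
  expect_warning(fit_proportional_odds(stage ~ xs, sep), "separation")
})

test_that("VIF matches its closed form and flags collinearity", {
  set.seed(38)
  n <- 4000
  a <- rnorm(n)
  b <- rnorm(n)
  ortho <- vif(data.frame(a = a, b = b))
  expect_equal(ortho$vif, c(1, 1), tolerance = 0.01)
  expect_equal(ortho$tolerance, 1 / ortho$vif)

  r <- 0.8
  x2 <- r * a + sqrt(1 - r^2) * b
  two <- vif(data.frame(a = a, x2 = x2))
  r_emp <- cor(a, x2)
  expect_equal(two$vif, rep(1 / (1 - r_emp^2), 2), tolerance = 1e-6)
  expect_false(any(two$flag))

  dup <- vif(data.frame(a = a, b = b, a2 = a))
  expect_true(all(is.infinite(dup$vif[dup$feature %in% c("a", "a2")])))
  expect_true(all(dup$flag[dup$feature %in% c("a", "a2")]))
  expect_error(vif(data.frame(a = a)), "two features")
})

test_that("Brant test is calibrated under proportional odds and detects violations", {
  gen_po <- function(n) {
    x1 <- rnorm(n); x2 <- rnorm(n)
    m <- cvm_ordinal_model(c(age = 1.2, D3 = 0.8), c(-1, 0.5, 2))
    p <- stage_probabilities(m, 1.2 * x1 + 0.8 * x2)
    y <- apply(p, 1, function(pr) sample.int(4, 1, prob = pr))
    list(X = cbind(x1 = x1, x2 = x2), y = y)
  }
  set.seed(39)
  rej <- replicate(120, {
    g <- gen_po(400)
    brant_test(X = g$X, y = g$y)$p_value[1] < 0.05
  })
  expect_lt(mean(rej), 0.12)   # quick check; full calibration in acceptance

  # strongly cutpoint-varying slopes: high power at n = 1000
  set.seed(40)
  pow <- replicate(40, {
    n <- 1000
    x <- rnorm(n)
    g1 <- plogis(-1 - 2.0 * x)
    g2 <- pmax(plogis(0.5 - 0.8 * x), plogis(-1 - 2.0 * x))
    g3 <- pmax(plogis(2 - 0.2 * x), g2)
    u <- runif(n)
    y <- 1L + (u > g1) + (u > g2) + (u > g3)
    if (length(unique(y)) < 4) return(NA)
    brant_test(X = cbind(x = x), y = y)$p_value[1] < 0.05
  })
  expect_gt(mean(pow, na.rm = TRUE), 0.9)

  g <- gen_po(200)
  expect_error(brant_test(X = g$X, y = ifelse(g$y <= 2, 1, 2)),
               "3 ordered classes")
})

test_that("the development pipeline retains the informative features", {
  sim <- simulate_features_from_model(cvm_primary_model(), n = 2000,
                                      seed = 41, extra_features = "all",
                                      latent_loadings = "published")
  dev <- develop_model(sim$features)
  expect_setequal(dev$retained,
                  c("age", "D3_AH3", "ang4", "C3lp_C4up"))
  expect_true(dev$fit$converged)
  expect_s3_class(dev$screening, "cvm_screen")
  expect_true(all(c("age", "D3_AH3", "ang4", "C3lp_C4up") %in%
                  dev$screening$feature[dev$screening$pass]))
  expect_false(is.null(dev$brant))
  expect_false(is.null(dev$vif))
  expect_true(all(dev$vif$vif >= 1))

  # single informative feature is retained
  sim1 <- simulate_features_from_model(
    cvm_ordinal_model(c(age = 2), c(15, 23, 31)), n = 800, seed = 42)
  dev1 <- develop_model(sim1$features)
  expect_true("age" %in% dev1$retained)

  # screen that passes nothing is an explicit error
  set.seed(43)
  null_feats <- data.frame(
    subject_id = as.character(1:200),
    age = rnorm(200, 11, 3), D3 = rnorm(200, 1, 0.5),
    true_stage = rep(1:4, each = 50)
  )
  null_feats$age <- rnorm(200, 11, 3)  # independent of stage
  expect_error(develop_model(null_feats, alpha_screen = 1e-12),
               "screen")
})
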