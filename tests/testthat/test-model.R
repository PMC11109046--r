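pooled_means <- c(age = 11.50, D3_AH3 = 0.11, ang4 = 7.74,
                  C3lp_C4up = 3.62, PH4 = 10.22)

test_that("linear predictor reproduces hand-evaluated sums", {
  expect_equal(linear_predictor(cvm_primary_model(),
                                c(age = 0, D3_AH3 = 0, ang4 = 0,
                                  C3lp_C4up = 0)), 0)
  # independent hand evaluation, term by term
  by_hand <- 3.172 * 11.50 + 28.642 * 0.11 + 0.727 * 7.74 + 0.453 * 3.62
  expect_equal(linear_predictor(cvm_primary_model(), pooled_means),
               by_hand, tolerance = 1e-12)
  expect_equal(by_hand, 46.89546, tolerance = 1e-10)

  bxc <- 2.139 * 15.7 + 0.313 * 15.0 + 1.444 * 12.5
  expect_equal(linear_predictor(cvm_correction_model(),
                                c(age = 15.7, ang4 = 15.0, PH4 = 12.5)),
               bxc, tolerance = 1e-12)
  expect_equal(bxc, 56.3273, tolerance = 1e-10)

  expect_error(linear_predictor(cvm_primary_model(),
                                c(age = 10, D3_AH3 = 0.1, ang4 = 5)),
               "C3lp_C4up")
})

test_that("stage probabilities match scalar logistic evaluations", {
  m <- cvm_primary_model()
  bx <- linear_predictor(m, pooled_means)
  p <- stage_probabilities(m, bx)
  gam <- plogis(c(32.921, 45.460, 62.065) - bx)   # independent route
  expect_equal(unname(p[1, ]), diff(c(0, gam, 1)), tolerance = 1e-12)
  expect_equal(which.max(p[1, ]), 3, ignore_attr = TRUE)
  expect_gt(p[1, 3], 0.8)
  expect_lt(p[1, 1], 1e-5)
})

test_that("cumulative logistics saturate without overflow", {
  m <- cvm_primary_model()
  expect_equal(unname(stage_probabilities(m, -1000)[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(stage_probabilities(m, 1000)[1, ]), c(0, 0, 0, 1))
  p <- stage_probabilities(m, c(-1e4, -1, 50, 1e4))
  expect_true(all(is.finite(p)))
  expect_equal(unname(rowSums(p)), rep(1, 4), tolerance = 1e-12)
})

test_that("stage probabilities sum to one over random linear predictors", {
  m <- cvm_primary_model()
  set.seed(20)
  bx <- runif(10000, -200, 200)
  p <- stage_probabilities(m, bx)
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("predicted stage is monotone in the linear predictor and ties go up", {
  m <- cvm_primary_model()
  bx <- seq(-50, 150, by = 0.05)
  stg <- apply(stage_probabilities(m, bx), 1,
               function(p) max(which(p == max(p))))
  expect_true(all(diff(stg) >= 0))
  expect_setequal(unique(stg), 1:4)

  # near-tie P(2) ~ P(3) with thresholds symmetric about bx = 0
  sym <- cvm_ordinal_model(c(age = 1), c(-5, 0, 5))
  ptie <- stage_probabilities(sym, 0)[1, ]
  expect_equal(ptie[["P2"]], ptie[["P3"]], tolerance = 1e-12)
  # exact ties resolve toward the more mature stage
  tied <- matrix(c(0.3, 0.3, 0.3, 0.1), 1)
  expect_equal(cvmstage:::argmax_stage(tied), 3)
  expect_equal(cvmstage:::argmax_stage(matrix(0.25, 1, 4)), 4)
})

test_that("raising any positive-slope feature never lowers the stage", {
  m <- cvm_primary_model()
  set.seed(21)
  base <- data.frame(age = runif(50, 6, 19), D3_AH3 = runif(50, 0, 0.25),
                     ang4 = runif(50, 0, 25), C3lp_C4up = runif(50, 1, 7))
  s0 <- predict(m, base)$stage_primary
  for (nm in names(m$slopes)) {
    up <- base
    up[[nm]] <- up[[nm]] + 1
    expect_true(all(predict(m, up)$stage_primary >= s0), info = nm)
  }
})

test_that("correction probability follows the published link", {
  cm <- cvm_correction_model()
  # at the cutpoint the decision is exactly even
  at_cut <- c(age = 0, ang4 = 0, PH4 = 51.828 / 1.444)
  expect_equal(correction_probability(cm, at_cut), 0.5, tolerance = 1e-12)
  # iCS4-typical subject: bx = 56.3273, sigma(51.828 - 56.3273) ~ 0.011
  p4 <- correction_probability(cm, c(age = 15.7, ang4 = 15.0, PH4 = 12.5))
  expect_equal(p4, plogis(51.828 - 56.3273), tolerance = 1e-9)
  expect_lt(p4, 0.5)
  # iCS3-typical subject: bx = 43.489, sigma(8.339) ~ 0.99976
  p3 <- correction_probability(cm,
                               c(age = 12.3, ang4 = 7.74, PH4 = 10.22))
  expect_equal(p3, plogis(51.828 - (2.139 * 12.3 + 0.313 * 7.74 +
                                    1.444 * 10.22)), tolerance = 1e-9)
  expect_gt(p3, 0.999)
})

test_that("the cascade only ever revises stages 3 and 4", {
  young <- data.frame(age = 7.6, D3_AH3 = 0.02, ang4 = 2, C3lp_C4up = 4.5,
                      PH4 = 8)
  out <- predict_cascade(young)
  expect_equal(out$stage_primary, 1L)
  expect_equal(out$stage_final, 1L)
  expect_false(out$correction_applied)
  expect_true(is.na(out$P_iCS3))

  pooled <- as.data.frame(as.list(pooled_means))
  out3 <- predict_cascade(pooled)
  expect_equal(out3$stage_primary, 3L)
  expect_true(out3$correction_applied)
  expect_equal(out3$stage_final, 3L)

  mature <- data.frame(age = 15.7, D3_AH3 = 0.17, ang4 = 15, C3lp_C4up = 3.5,
                       PH4 = 12.5)
  out4 <- predict_cascade(mature)
  expect_true(out4$stage_primary %in% 3:4)
  expect_equal(out4$stage_final, 4L)
  expect_true(out4$correction_applied)

  # property: primary 1/2 predictions are never altered
  set.seed(22)
  grid <- data.frame(age = runif(500, 6, 19),
                     D3_AH3 = runif(500, 0, 0.3),
                     ang4 = runif(500, 0, 25),
                     C3lp_C4up = runif(500, 1, 7),
                     PH4 = runif(500, 6, 15))
  res <- predict_cascade(grid)
  low <- res$stage_primary %in% 1:2
  expect_true(all(res$stage_final[low] == res$stage_primary[low]))
  expect_true(all(res$correction_applied == (res$stage_primary %in% 3:4)))
  expect_true(all(res$stage_final[!low] %in% 3:4))

  # the cascade needs the correction features even if nothing triggers
  expect_error(predict_cascade(young[, setdiff(names(young), "PH4")]),
               "PH4")
})

test_that("models round-trip exactly through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  m <- cvm_primary_model()
  save_model(m, path)
  expect_equal(load_model(path), m)
  cm <- cvm_correction_model()
  save_model(cm, path)
  expect_equal(load_model(path), cm)

  odd <- cvm_ordinal_model(c(age = 1 / 3, D3 = pi), c(-1.23456789012345,
                                                      2.5, 7))
  save_model(odd, path)
  expect_identical(load_model(path)$slopes, odd$slopes)
  expect_identical(load_model(path)$thresholds, odd$thresholds)
})

test_that("model constructors and loaders reject invalid inputs", {
  expect_error(cvm_ordinal_model(c(bogus = 1), c(1, 2, 3)), "bogus")
  expect_error(cvm_ordinal_model(c(age = 1), c(2, 2, 3)),
               "strictly increasing")
  expect_error(cvm_published_model("primary-1999"), "unknown")
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(kind = "ordinal",
                            slopes = list(notafeature = 1),
                            thresholds = c(1, 2, 3)),
                       path, auto_unbox = TRUE)
  expect_error(load_model(path), "notafeature")
  jsonlite::write_json(list(kind = "ordinal", slopes = list(age = 1),
                            thresholds = c(3, 2, 1)),
                       path, auto_unbox = TRUE)
  expect_error(load_model(path), "strictly increasing")
})
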