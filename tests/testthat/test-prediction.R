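make_clinical <- function(df, types) {
  attr(df, "item_types") <- types
  class(df) <- c("trc_clinical", "data.frame")
  df
}

test_that("median imputation respects item types", {
  tab <- make_clinical(
    data.frame(patient_id = paste0("p", 1:4),
               num = c(1, NA, 3, 10),
               dich = c(0, 0, 1, NA),
               cat = c(2, 2, 5, NA)),
    c(num = "N", dich = "D", cat = "C")
  )
  imp <- impute_median(tab)
  expect_equal(imp$num[2], 3)          # median of 1, 3, 10
  expect_equal(imp$dich[4], 0)         # majority 0
  expect_equal(imp$cat[4], 2)          # mode

  tie <- make_clinical(data.frame(patient_id = "a", d = NA_real_),
                       c(d = "D"))
  expect_error(impute_median(tie), "fully missing")

  no_na <- make_clinical(data.frame(patient_id = paste0("p", 1:3),
                                    x = c(1, 2, 3)), c(x = "N"))
  expect_identical(impute_median(no_na)$x, c(1, 2, 3))

  half <- make_clinical(
    data.frame(patient_id = paste0("p", 1:5),
               d = c(0, 0, 1, 1, NA)), c(d = "D"))
  expect_equal(impute_median(half)$d[5], 0)   # tied median 0.5 rounds down
})

test_that("early partial response uses the 25% week-2 boundary inclusively", {
  s <- function(b, w2) {
    regularize_grid(rating_series("p", 0:2, c(b, NA, w2)))
  }
  expect_true(early_partial_response(s(20, 15)))    # exactly 25%
  expect_false(early_partial_response(s(20, 16)))   # 20%
  expect_true(early_partial_response(s(14, 7)))     # 50%
})

test_that("feature assembly produces the documented model dimensions", {
  spec <- synthetic_spec(40, clinical_missing_rate = 0)
  gen <- generate_cohort(spec, 33)
  coh <- regularize_cohort(gen$cohort)
  clin <- impute_median(generate_clinical(gen$labels, spec, seed = 2))
  d <- vapply(0:3, function(m) ncol(assemble_features(clin, coh, m)),
              integer(1))
  expect_identical(d, c(50L, 71L, 51L, 72L))

  f0 <- assemble_features(clin, coh, 0)
  f2 <- assemble_features(clin, coh, 2)
  expect_identical(setdiff(names(f2), names(f0)), "HD_2WE")
  expect_true(all(f2$HD_2WE %in% c(0, 1)))
  expect_error(assemble_features(clin, coh, 9), "unknown model_id")
})

test_that("mtry follows floor(sqrt(D)) and the forest finds real signal", {
  set.seed(44)
  n <- 200
  feats <- as.data.frame(matrix(rnorm(n * 50), n, 50))
  names(feats) <- paste0("x", 1:50)
  y <- feats$x1 + rnorm(n, 0, 0.05)
  fit <- rf_fit_evaluate(feats, y, trees = 300, n_perm_model = 0, seed = 3)
  expect_identical(fit$mtry, 7)        # floor(sqrt(50))
  expect_gt(fit$r2_adj, 0.5)
  expect_lte(fit$r2_adj, 1)
  expect_error(rf_fit_evaluate(feats, rep(1, n)), "constant target")
})

test_that("permutation importance p-values respect the estimator floor", {
  set.seed(45)
  n <- 120
  feats <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  names(feats) <- paste0("x", 1:5)
  y <- 2 * feats$x1 + rnorm(n, 0, 0.2)
  imp <- permutation_importance(feats, y, n_perm = 30, seed = 6, trees = 100)
  expect_true(all(imp$permutation_p >= 1 / 31))
  expect_equal(imp$permutation_p[imp$feature == "x1"], 1 / 31)
  expect_error(permutation_importance(feats, y, n_perm = 0), "n_perm")
})

test_that("per-class accuracy applies the one-vs-rest formula", {
  expect_true(all(per_class_accuracy(1:7, 1:7) == 1))

  true7 <- rep(1:7, each = 10)
  pred1 <- rep(1L, 70)
  acc <- per_class_accuracy(true7, pred1)
  expect_equal(unname(acc["C1"]), 1 / 7, tolerance = 1e-12)
  expect_equal(unname(acc["C3"]), 6 / 7, tolerance = 1e-12)

  # TP = 5, TN = 80, FP = 10, FN = 5 -> 0.85
  truth <- c(rep(1, 10), rep(2, 90))
  pred <- c(rep(1, 5), rep(2, 5), rep(1, 10), rep(2, 80))
  expect_equal(unname(per_class_accuracy(truth, pred)["C1"]), 0.85,
               tolerance = 1e-12)
})

test_that("Fisher-Z comparison matches its closed form and is symmetric", {
  eq <- compare_r2(0.2, 0.2, 100, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)

  p <- compare_r2(0.13, 0.08, 1017, 1017)
  expect_lt(abs(p$p_value - 0.050), 0.005)

  ab <- compare_r2(0.3, 0.1, 200, 150)
  ba <- compare_r2(0.1, 0.3, 150, 200)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
  expect_error(compare_r2(0.2, 0.1, 3, 100), "exceed 3")
  expect_error(compare_r2(1, 0.1, 100, 100), "r2")
})

test_that("slope-to-class mapping picks the nearest component", {
  m <- sort_components(mixture_model(c(3, 3, 3), c(-0.3, -0.15, -0.02),
                                     c(0.2, 0.2, 0.2), c(1, 1, 1) / 3))
  expect_identical(map_slope_to_class(-0.15, m), 2L)
  expect_identical(map_slope_to_class(-0.225, m), 1L)  # midpoint tie: lower
  set.seed(50)
  s <- runif(100, -0.5, 0.1)
  brute <- vapply(s, function(si) {
    which.min(abs(si - m$components$slope))
  }, integer(1))
  expect_identical(map_slope_to_class(s, m), brute)
})
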