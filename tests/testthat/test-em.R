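test_that("component log-likelihood matches direct Gaussian evaluation", {
  s1 <- ln_series("p1", 0L, 2.0, 0)        # single point y = 2 at t = 0
  comp <- list(intercept = 2.0, slope = 0, residual_sd = 1)
  expect_equal(component_loglik(s1, comp), -0.9189, tolerance = 1e-4)

  s2 <- ln_series("p2", 0:1, 2.0, 0)
  expect_equal(component_loglik(s2, comp), -1.8379, tolerance = 1e-4)

  set.seed(7)
  s4 <- ln_series("p4", c(0, 2, 3, 5), 2.8, -0.1, sigma = 0.3)
  comp2 <- list(intercept = 2.6, slope = -0.07, residual_sd = 0.21)
  expect_equal(component_loglik(s4, comp2),
               oracle_series_loglik(s4, 2.6, -0.07, 0.21),
               tolerance = 1e-10)
})

test_that("E-step posteriors match brute-force density ratios", {
  set.seed(3)
  coh <- two_line_cohort(n_per = 3, sigma = 0.2, seed = 3)

  # degenerate one-component mixture
  m1 <- mixture_model(3.0, -0.1, 0.2, 1)
  expect_true(all(e_step(m1, coh)$posteriors == 1))

  # symmetric components around a flat patient
  flat <- cohort(list(ln_series("f", 0:4, 2.5, 0)), "MARS")
  msym <- mixture_model(c(2.4, 2.6), c(0, 0), c(0.3, 0.3), c(0.5, 0.5))
  expect_equal(unname(e_step(msym, flat)$posteriors[1, ]), c(0.5, 0.5),
               tolerance = 1e-10)

  # arbitrary 6-patient, 2-component instance vs oracle
  m2 <- mixture_model(c(3.05, 2.9), c(-0.25, -0.05), c(0.25, 0.15),
                      c(0.4, 0.6))
  es <- e_step(m2, coh)
  expect_equal(unname(es$posteriors), oracle_posteriors(coh, m2),
               tolerance = 1e-10)
  expect_equal(es$loglik, oracle_total_loglik(coh, m2), tolerance = 1e-10)
})

test_that("M-step equals weighted least squares on normal equations", {
  coh <- two_line_cohort(n_per = 3, sigma = 0, seed = 1)
  n <- length(coh)

  # all mass on one component, noise-free line: exact recovery
  z1 <- matrix(1, 3, 1)
  one <- cohort(coh$series[1:3], "MARS")
  ms <- m_step(one, z1)
  expect_equal(ms$model$components$intercept, 3.0, tolerance = 1e-8)
  expect_equal(ms$model$components$slope, -0.3, tolerance = 1e-8)
  expect_equal(ms$model$components$residual_sd, 1e-4)  # floored

  # uniform posteriors: both components equal the pooled OLS fit
  zu <- matrix(0.5, n, 2)
  msu <- m_step(coh, zu)
  pooled <- stats::lm(lnval ~ week, data = as.data.frame(coh))
  expect_equal(msu$model$components$intercept,
               rep(unname(coef(pooled)[1]), 2), tolerance = 1e-10)
  expect_equal(msu$model$components$slope,
               rep(unname(coef(pooled)[2]), 2), tolerance = 1e-10)

  # random posteriors vs lm(weights=) oracle
  set.seed(9)
  coh2 <- two_line_cohort(n_per = 3, sigma = 0.25, seed = 5)
  z <- matrix(stats::runif(6 * 2), 6, 2)
  z <- z / rowSums(z)
  got <- m_step(coh2, z)$model$components
  want <- oracle_wls(coh2, z)
  expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
  expect_equal(got$slope, want$slope, tolerance = 1e-10)
  expect_equal(got$residual_sd, want$residual_sd, tolerance = 1e-9)
  expect_equal(got$weight, want$weight, tolerance = 1e-12)
})

test_that("single-component EM equals the pooled Gaussian MLE", {
  coh <- two_line_cohort(n_per = 4, sigma = 0.2, seed = 11)
  f <- fit_em(coh, 1, seed = 1)
  df <- as.data.frame(coh)
  ols <- stats::lm(lnval ~ week, data = df)
  sig <- sqrt(mean(resid(ols)^2))
  ll <- sum(stats::dnorm(df$lnval, fitted(ols), sig, log = TRUE))
  expect_equal(f$model$components$intercept, unname(coef(ols)[1]),
               tolerance = 1e-8)
  expect_equal(f$model$components$slope, unname(coef(ols)[2]),
               tolerance = 1e-8)
  expect_equal(f$diagnostics$loglik, ll, tolerance = 1e-8)
})

test_that("EM recovers a clean two-class partition and is monotone", {
  coh <- two_line_cohort(n_per = 10, sigma = 0.02, seed = 2)
  truth <- rep(1:2, each = 10)
  f <- fit_em(coh, 2, seed = 4)
  expect_true(f$diagnostics$converged)
  expect_identical(f$assignment$label, truth)
  expect_true(all(diff(f$diagnostics$loglik_trace) >= -1e-9))
})

test_that("restart search is deterministic and reduces to fit_em", {
  coh <- two_line_cohort(n_per = 6, sigma = 0.15, seed = 6)
  r1 <- fit_restarts(coh, 2, n_restarts = 1, seed = 42)
  single <- fit_em(coh, 2, seed = 42)
  expect_identical(r1$fit$model, single$model)

  ra <- fit_restarts(coh, 2, n_restarts = 10, seed = 42)
  rb <- fit_restarts(coh, 2, n_restarts = 10, seed = 42)
  expect_identical(ra$fit$model, rb$fit$model)
  expect_identical(ra$fit$diagnostics$loglik, rb$fit$diagnostics$loglik)
})

test_that("overambitious class counts are reported as failed restarts", {
  # 12 tightly clustered patients cannot support 10 components
  coh <- two_line_cohort(n_per = 6, sigma = 0.01, seed = 8)
  r <- fit_restarts(coh, 10, n_restarts = 10, seed = 1)
  expect_gt(r$n_failed, 0)
})

test_that("information criteria satisfy their defining identities", {
  coh <- two_line_cohort(n_per = 5, sigma = 0.05, seed = 3)
  f <- fit_em(coh, 2, seed = 1)
  d <- f$diagnostics
  expect_equal(d$icl, d$bic + 2 * d$entropy, tolerance = 1e-10)
  expect_gte(d$entropy, 0)
  expect_equal(d$n_params, 3 * 2 + 1)

  # hard posteriors: ICL reduces to BIC
  z_hard <- f$assignment$posteriors
  z_hard[] <- 0
  z_hard[cbind(seq_along(f$assignment$label), f$assignment$label)] <- 1
  f_hard <- f
  f_hard$assignment$posteriors <- z_hard
  d_hard <- information_criteria(f_hard)
  expect_equal(d_hard$entropy, 0)
  expect_equal(d_hard$icl, d_hard$bic)

  # 2 patients, k = 2, uniform posteriors: ENT = 2 ln 2
  f2 <- f
  f2$assignment$posteriors <- matrix(0.5, 2, 2)
  d2 <- information_criteria(f2)
  expect_equal(d2$entropy, 2 * log(2), tolerance = 1e-12)
  expect_equal(d2$icl - d2$bic, 2.7726, tolerance = 1e-4)

  # BIC formula on a toy: loglik -100, k = 2, N = 50, p = 3k + (k - 1) = 7
  f3 <- f
  f3$diagnostics$loglik <- -100
  f3$assignment$posteriors <- matrix(0.5, 50, 2)
  expect_equal(information_criteria(f3)$bic, 200 + 7 * log(50),
               tolerance = 1e-10)
})

test_that("select_k handles trivial ranges and keeps a consistent profile", {
  coh <- two_line_cohort(n_per = 8, sigma = 0.1, seed = 13)
  sel <- select_k(coh, k_range = 2, n_restarts = 5, seed = 3)
  expect_identical(sel$best_k, 2L)
  sel2 <- select_k(coh, k_range = 1:3, n_restarts = 5, seed = 3)
  ok <- !is.na(sel2$profile$icl)
  expect_equal(sel2$profile$icl[ok],
               sel2$profile$bic[ok] + 2 * sel2$profile$entropy[ok],
               tolerance = 1e-10)
})

test_that("component sorting orders by slope with intercept tie-break", {
  m <- mixture_model(c(3.0, 2.8, 3.1), c(-0.1, -0.3, 0.0),
                     c(0.2, 0.2, 0.2), c(0.3, 0.3, 0.4))
  s <- sort_components(m)
  expect_equal(s$components$slope, c(-0.3, -0.1, 0.0))
  expect_identical(sort_components(s)$components, s$components)

  mt <- mixture_model(c(3.0, 2.5), c(-0.1, -0.1), c(0.2, 0.2), c(0.5, 0.5))
  st <- sort_components(mt)
  expect_equal(st$components$intercept, c(2.5, 3.0))
})

test_that("sorting is invariant to prior component permutation", {
  coh <- two_line_cohort(n_per = 5, sigma = 0.1, seed = 17)
  f <- fit_em(coh, 2, seed = 5)
  m <- f$model
  perm <- m
  perm$components <- m$components[2:1, ]
  rownames(perm$components) <- NULL
  expect_equal(sort_components(perm)$components,
               sort_components(m)$components)
})
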