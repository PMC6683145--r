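# Brute-force oracles and small fixture builders.  The oracles use naive
# loops and base fitting functions only, independent of the package's EM
# code path.

# Gaussian log-likelihood of one series under a single line, by direct loop.
oracle_series_loglik <- function(series, intercept, slope, sigma) {
  ll <- 0
  for (j in seq_along(series$weeks)) {
    if (is.na(series$lnvals[j])) next
    ll <- ll + stats::dnorm(series$lnvals[j],
                            intercept + slope * series$weeks[j],
                            sigma, log = TRUE)
  }
  ll
}

# Posterior responsibilities by direct unnormalized-density ratios.
oracle_posteriors <- function(x, model) {
  K <- model$k
  z <- matrix(NA_real_, length(x$series), K)
  for (i in seq_along(x$series)) {
    dens <- numeric(K)
    for (k in seq_len(K)) {
      dens[k] <- model$components$weight[k] *
        exp(oracle_series_loglik(x$series[[i]],
                                 model$components$intercept[k],
                                 model$components$slope[k],
                                 model$components$residual_sd[k]))
    }
    z[i, ] <- dens / sum(dens)
  }
  z
}

# Observed-data log-likelihood by direct summation.
oracle_total_loglik <- function(x, model) {
  tot <- 0
  for (i in seq_along(x$series)) {
    dens <- 0
    for (k in seq_len(model$k)) {
      dens <- dens + model$components$weight[k] *
        exp(oracle_series_loglik(x$series[[i]],
                                 model$components$intercept[k],
                                 model$components$slope[k],
                                 model$components$residual_sd[k]))
    }
    tot <- tot + log(dens)
  }
  tot
}

# Weighted least squares per component via lm(weights = ...).
oracle_wls <- function(x, z) {
  df <- as.data.frame(x)
  pid <- match(df$patient_id, patient_ids(x))
  K <- ncol(z)
  out <- data.frame(intercept = numeric(K), slope = numeric(K),
                    residual_sd = numeric(K), weight = numeric(K))
  for (k in seq_len(K)) {
    w <- z[pid, k]
    fit <- stats::lm(lnval ~ week, data = df, weights = w)
    out$intercept[k] <- unname(coef(fit)[1])
    out$slope[k] <- unname(coef(fit)[2])
    out$residual_sd[k] <- sqrt(sum(w * resid(fit)^2) / sum(w))
    out$weight[k] <- mean(z[, k])
  }
  out
}

# Pearson chi-square statistic from textbook expected counts.
oracle_chisq <- function(a, b) {
  tab <- cbind(a, b)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Series whose ln values are exactly intercept + slope * week (+ noise):
# raw = exp(y) - 0.5 inverts the ln transform without rounding.
ln_series <- function(id, weeks, intercept, slope, sigma = 0) {
  y <- intercept + slope * weeks +
    (if (sigma > 0) stats::rnorm(length(weeks), 0, sigma) else 0)
  rating_series(id, weeks, pmax(exp(y) - 0.5, 0))
}

# Small two-line cohort with exact ln-scale values.
two_line_cohort <- function(n_per = 5, weeks = 0:6,
                            a = c(3.0, 3.0), b = c(-0.3, -0.02),
                            sigma = 0, seed = 1) {
  set.seed(seed)
  series <- c(
    lapply(seq_len(n_per), function(i)
      ln_series(sprintf("A%02d", i), weeks, a[1], b[1], sigma)),
    lapply(seq_len(n_per), function(i)
      ln_series(sprintf("B%02d", i), weeks, a[2], b[2], sigma))
  )
  cohort(series, "MARS")
}

# Well-separated generating specs used in the recovery checks: slope spacing
# at least three times the per-patient slope standard error implied by the
# residual SD and each class's observation window.
separated_spec <- function(k_true, n = 800) {
  comps <- switch(as.character(k_true),
    "3" = list(
      generating_component(0.40, 3.0, -0.30, 0.12),
      generating_component(0.35, 3.1, -0.12, 0.12),
      generating_component(0.25, 3.2, -0.01, 0.12)),
    "5" = list(
      generating_component(0.25, 3.1, -0.35, 0.08),
      generating_component(0.20, 3.1, -0.22, 0.08),
      generating_component(0.20, 3.1, -0.13, 0.08),
      generating_component(0.20, 3.1, -0.06, 0.08),
      generating_component(0.15, 3.1, -0.01, 0.08)),
    "7" = list(
      generating_component(0.15, 3.1, -0.40, 0.08),
      generating_component(0.15, 3.1, -0.30, 0.08),
      generating_component(0.15, 3.1, -0.21, 0.08),
      generating_component(0.15, 3.1, -0.14, 0.08),
      generating_component(0.15, 3.1, -0.08, 0.08),
      generating_component(0.15, 3.1, -0.04, 0.08),
      generating_component(0.10, 3.1, -0.01, 0.08)),
    stop("unsupported k_true")
  )
  synthetic_spec(n, components = comps)
}
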