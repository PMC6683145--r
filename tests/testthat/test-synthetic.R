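test_that("zero-noise trajectories lie exactly on the component line", {
  spec <- synthetic_spec(
    20,
    components = list(generating_component(1, 3.0, -0.05, 0)),
    missing_rate = 0
  )
  gen <- generate_cohort(spec, 11)
  for (s in gen$cohort$series) {
    y <- 3.0 - 0.05 * s$weeks
    # rounding to integer scores perturbs by at most half a score point
    expect_equal(s$raw, pmin(pmax(round(exp(y) - 0.5), 0), 63))
  }
})

test_that("every emitted patient satisfies the baseline >= 14 eligibility", {
  for (seed in 1:3) {
    spec <- synthetic_spec(300, design = if (seed == 2) "GENDEP" else "MARS")
    gen <- generate_cohort(spec, seed)
    base <- vapply(gen$cohort$series, function(s) s$raw[1], numeric(1))
    expect_true(all(base >= 14))
  }
})

test_that("label frequencies follow the mixing weights", {
  spec <- synthetic_spec(20000, components = list(
    generating_component(0.3, 3.0, -0.2, 0.1),
    generating_component(0.7, 3.1, -0.05, 0.1)
  ))
  gen <- generate_cohort(spec, 5)
  freq <- tabulate(gen$labels, 2) / 20000
  expect_lt(abs(freq[1] - 0.3), 0.02)
  expect_lt(abs(freq[2] - 0.7), 0.02)
})

test_that("missingness hits interior visits at the requested rate", {
  spec <- synthetic_spec(2000, missing_rate = 0)
  gen <- generate_cohort(spec, 21)
  expect_identical(apply_missingness(gen$cohort, 0), gen$cohort)

  miss <- apply_missingness(gen$cohort, 0.071, seed = 4)
  at_risk <- 0L; hit <- 0L
  for (s in miss$series) {
    idx <- which(s$weeks >= 1 & s$weeks <= 6 &
                   seq_along(s$weeks) < length(s$weeks))
    at_risk <- at_risk + length(idx)
    hit <- hit + sum(is.na(s$raw[idx]))
    expect_false(is.na(s$raw[1]))                  # baseline never missing
    expect_false(is.na(s$raw[length(s$raw)]))      # discharge visit kept
  }
  expect_lt(abs(hit / at_risk - 0.071), 0.01)
  expect_error(apply_missingness(gen$cohort, 1.2), "rate")
})

test_that("slower generating slopes produce later discharge", {
  spec <- synthetic_spec(1500)
  gen <- generate_cohort(spec, 31)
  coh <- regularize_cohort(gen$cohort)
  mk <- cohort_markers(coh)
  mean_disch <- tapply(mk$weeks_to_discharge, gen$labels, mean)
  slopes <- vapply(spec$components, `[[`, numeric(1), "slope")
  expect_gt(cor(slopes, mean_disch, method = "spearman"), 0)
  # fastest class leaves early, resistant class stays the full window
  expect_lt(mean_disch[1], 6)
  expect_gt(mean_disch[7], 15)
})

test_that("clinical generator calibrates Cohen's f and rejects unknown items", {
  spec <- synthetic_spec(50000, clinical_missing_rate = 0)
  gen_labels <- sample.int(7, 50000, replace = TRUE,
                           prob = vapply(spec$components, `[[`, numeric(1),
                                         "weight"))
  names(gen_labels) <- sprintf("P%05d", seq_along(gen_labels))
  clin <- generate_clinical(gen_labels, spec, seed = 8)
  f_neu <- anova_f(clin$epq_neu, gen_labels)$cohens_f
  expect_lt(abs(f_neu - 0.355), 0.02)
  f_ha <- anova_f(clin$tpq_ha, gen_labels)$cohens_f
  expect_lt(abs(f_ha - 0.341), 0.02)
  # extraversion decreases from fast to slow classes
  m_ext <- tapply(clin$epq_ext, gen_labels, mean)
  expect_lt(m_ext[7], m_ext[1])

  bad <- synthetic_spec(10, covariate_effects = list(not_an_item = rep(0, 7)))
  expect_error(generate_clinical(rep(1L, 10), bad), "unknown item")
})

test_that("clinical missingness and null effects behave as configured", {
  spec <- synthetic_spec(10000, clinical_missing_rate = 0.1)
  labels <- sample.int(7, 10000, replace = TRUE)
  clin <- generate_clinical(labels, spec, seed = 3)
  cells <- as.matrix(clin[, -1])
  expect_lt(abs(mean(is.na(cells)) - 0.1), 0.01)

  null_spec <- synthetic_spec(
    600,
    covariate_effects = list(epq_neu = rep(0, 7)),
    clinical_missing_rate = 0
  )
  labels6 <- sample.int(7, 600, replace = TRUE)
  clin0 <- generate_clinical(labels6, null_spec, seed = 9)
  p <- anova_f(clin0$epq_neu, labels6)$p_value
  expect_gt(p, 1e-4)  # no simulated effect: no extreme significance
})

test_that("spec validation names the offending field", {
  expect_error(synthetic_spec(0), "n_patients")
  expect_error(synthetic_spec(10, missing_rate = 1), "missing_rate")
  expect_error(synthetic_spec(10, components = list(
    generating_component(0.5, 3, -0.1, 0.1))), "sum to 1")
  expect_error(generating_component(0.5, 3, -0.1, -0.1), "residual_sd")
})
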