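# Synthetic-cohort generator.  Emulates the data structure the clustering
# pipeline assumes: mixture-structured linear decline on the ln(HAM-D + 0.5)
# scale over an inpatient (MARS-like) or trial (GENDEP-like) visit grid,
# baseline eligibility (raw >= 14), accidental missingness in the first six
# weeks, discharge censoring, and cluster-coupled clinical baseline items.

#' Generating component of a synthetic cohort
#'
#' @param weight Mixing probability in (0, 1].
#' @param intercept ln-scale score at week 0.
#' @param slope ln-scale change per week (negative = improvement).
#' @param residual_sd Within-patient ln-scale noise SD (>= 0).
#' @param random_intercept_sd Between-patient ln-scale intercept SD
#'   (default 0: all patients of a class share the class line).
#' @return A `generating_component` object.
#' @export
generating_component <- function(weight, intercept, slope, residual_sd,
                                 random_intercept_sd = 0) {
  if (!(weight > 0 && weight <= 1)) {
    stop("generating_component(): weight must be in (0, 1]")
  }
  if (residual_sd < 0) stop("generating_component(): residual_sd must be >= 0")
  if (random_intercept_sd < 0) {
    stop("generating_component(): random_intercept_sd must be >= 0")
  }
  structure(list(weight = weight, intercept = intercept, slope = slope,
                 residual_sd = residual_sd,
                 random_intercept_sd = random_intercept_sd),
            class = "generating_component")
}

#' Default seven-class generating mixture
#'
#' Seven components spanning fast, essentially complete response (steep
#' negative ln-scale slope, discharge around week 5) to treatment resistance
#' (near-zero slope, full 16-week stay), with intercepts near ln(22)
#' (moderate-to-severe baselines) and a common within-patient noise SD of
#' 0.15 ln-units.  Components are ordered by slope, fastest first.
#'
#' @return List of seven [generating_component()] objects.
#' @export
default_components <- function() {
  slopes <- c(-0.30, -0.22, -0.15, -0.10, -0.06, -0.03, -0.005)
  icepts <- c(3.00, 3.05, 3.10, 3.00, 3.10, 3.15, 3.20)
  wts    <- c(0.16, 0.18, 0.16, 0.10, 0.15, 0.14, 0.11)
  Map(function(w, a, b) generating_component(w, a, b, residual_sd = 0.15),
      wts, icepts, slopes)
}

#' Specification of a synthetic cohort
#'
#' @param n_patients Number of patients (>= 1).
#' @param components List of [generating_component()]; weights must sum to 1.
#' @param design `"MARS"` or `"GENDEP"` visit design.
#' @param missing_rate Fraction of week 1--6 interior visits set missing
#'   completely at random (default 0.071, the accidental-missingness rate of
#'   weekly inpatient ratings).
#' @param covariate_effects Named list: clinical item name -> per-class
#'   standardized mean shifts (length = number of components).  Defaults to
#'   [default_covariate_effects()].
#' @param n_noise_items Number of additional pure-noise covariates.
#' @param clinical_missing_rate Fraction of clinical-table cells set missing.
#' @param seed Default seed used when the generating functions are called
#'   without one.
#' @return A validated `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_patients,
                           components = default_components(),
                           design = "MARS",
                           missing_rate = 0.071,
                           covariate_effects = NULL,
                           n_noise_items = 0L,
                           clinical_missing_rate = 0.05,
                           seed = 1L) {
  spec <- structure(
    list(n_patients = as.integer(n_patients), components = components,
         design = match_design(design), missing_rate = missing_rate,
         covariate_effects = covariate_effects,
         n_noise_items = as.integer(n_noise_items),
         clinical_missing_rate = clinical_missing_rate,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  if (is.na(spec$n_patients) || spec$n_patients < 1L) {
    stop("synthetic_spec: field n_patients must be >= 1")
  }
  if (!(spec$missing_rate >= 0 && spec$missing_rate < 1)) {
    stop("synthetic_spec: field missing_rate must be in [0, 1)")
  }
  if (!(spec$clinical_missing_rate >= 0 && spec$clinical_missing_rate < 1)) {
    stop("synthetic_spec: field clinical_missing_rate must be in [0, 1)")
  }
  if (length(spec$components) < 1L) {
    stop("synthetic_spec: field components must be non-empty")
  }
  ok <- vapply(spec$components, inherits, logical(1), "generating_component")
  if (!all(ok)) {
    stop("synthetic_spec: field components must hold generating_component objects")
  }
  w <- vapply(spec$components, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-12) {
    stop("synthetic_spec: field components: weights must sum to 1 (got ",
         format(sum(w), digits = 15), ")")
  }
  invisible(spec)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d patients, %d components, %s design\n",
              x$n_patients, length(x$components), x$design))
  invisible(x)
}

component_params <- function(components) {
  list(
    weight = vapply(components, `[[`, numeric(1), "weight"),
    intercept = vapply(components, `[[`, numeric(1), "intercept"),
    slope = vapply(components, `[[`, numeric(1), "slope"),
    residual_sd = vapply(components, `[[`, numeric(1), "residual_sd"),
    ri_sd = vapply(components, `[[`, numeric(1), "random_intercept_sd")
  )
}

# ---- trajectory generation ---------------------------------------------

#' Generate a synthetic cohort with known class labels
#'
#' For each patient a component is drawn from the mixing weights, a
#' per-patient intercept offset from `random_intercept_sd`, and ln-scale
#' values `intercept + offset + slope * t + noise` are emitted at the design's
#' scheduled weeks.  Raw scores are the exact inverse transform
#' `round(exp(y) - 0.5)` clipped to the design's score range.  Eligibility
#' (baseline raw >= 14) is enforced by redrawing the patient's noise (the
#' drawn component is kept, so label frequencies match the weights).
#' Discharge is the first scheduled week >= 2 at which the raw score is below
#' 10 on two consecutive scheduled visits; the series is truncated there.
#' Accidental missingness is then applied via [apply_missingness()].
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @param id_prefix Prefix of the generated patient ids (default `"P"`);
#'   distinct prefixes keep pooled cohorts free of id collisions.
#' @return List with `cohort` (a `trc_cohort` of scheduled-visit series),
#'   `labels` (named integer vector of true components), and `truth`
#'   (generating parameters and seed, suitable for JSON serialization).
#' @export
generate_cohort <- function(spec, seed = spec$seed, id_prefix = "P") {
  validate_spec(spec)
  set.seed(seed)
  pars <- component_params(spec$components)
  K <- length(pars$weight)
  weeks <- design_weeks(spec$design)
  max_score <- design_max_score(spec$design)
  n <- spec$n_patients

  labels <- sample.int(K, n, replace = TRUE, prob = pars$weight)
  series <- vector("list", n)
  for (i in seq_len(n)) {
    k <- labels[i]
    for (try in seq_len(1000L)) {
      offset <- if (pars$ri_sd[k] > 0) stats::rnorm(1, 0, pars$ri_sd[k]) else 0
      y <- pars$intercept[k] + offset + pars$slope[k] * weeks +
        stats::rnorm(length(weeks), 0, pars$residual_sd[k])
      raw <- pmin(pmax(inverse_transform_score(y), 0), max_score)
      if (raw[1] >= 14) break
      if (try == 1000L) {
        stop("generate_cohort(): could not draw an eligible baseline for ",
             "component ", k, "; intercept too far below ln(14.5)")
      }
    }
    keep <- seq_along(weeks)
    below <- raw < 10
    dis <- which(below & c(FALSE, below[-length(below)]) & weeks >= 2L)
    if (length(dis) > 0L) keep <- seq_len(dis[1])
    series[[i]] <- rating_series(sprintf("%s%04d", id_prefix, i),
                                 weeks[keep], raw[keep])
  }
  coh <- cohort(series, spec$design)
  names(labels) <- patient_ids(coh)
  if (spec$missing_rate > 0) {
    coh <- apply_missingness(coh, spec$missing_rate,
                             seed = derive_seed(seed, 1L))
  }
  list(
    cohort = coh,
    labels = labels,
    truth = list(
      seed = seed, design = spec$design,
      components = lapply(spec$components, unclass),
      labels = as.integer(labels), patient_id = names(labels)
    )
  )
}

# Small deterministic seed derivation that stays inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

#' Mark interior visits missing completely at random
#'
#' Candidate visits are the scheduled weeks 1--6, excluding the baseline and
#' each patient's final (discharge) visit; each candidate is set missing
#' independently with probability `rate`.
#'
#' @param x A `trc_cohort` of scheduled-visit series.
#' @param rate Missingness probability in [0, 1).
#' @param seed Integer seed.
#' @return The cohort with the selected raw scores set to `NA`.
#' @export
apply_missingness <- function(x, rate, seed = 1L) {
  stopifnot(inherits(x, "trc_cohort"))
  if (!(rate >= 0 && rate < 1)) {
    stop("apply_missingness(): rate must be in [0, 1)")
  }
  if (rate == 0) return(x)
  set.seed(seed)
  series <- lapply(x$series, function(s) {
    idx <- which(s$weeks >= 1L & s$weeks <= 6L &
                   seq_along(s$weeks) < length(s$weeks))
    if (length(idx) > 0L) {
      hit <- idx[stats::runif(length(idx)) < rate]
      s$raw[hit] <- NA_real_
      s$lnvals[hit] <- NA_real_
    }
    s
  })
  cohort(series, x$design)
}

# ---- clinical covariates -----------------------------------------------

#' Baseline clinical item schema
#'
#' The 50-item baseline catalogue (sociodemographics, diagnosis, disease
#' history, family history, current episode, basic medical/laboratory values,
#' life events, SCL-90R psychopathology scales, and EPQ/TPQ personality
#' scales) plus the 21 baseline HAM-D single items.  Types: `N` numerical,
#' `D` dichotomous, `C` categorical.
#'
#' @return data.frame with columns `name`, `type`, `baseline_item` (logical:
#'   part of the 50-item baseline model).
#' @export
table1_schema <- function() {
  base <- data.frame(
    name = c(
      "age", "sex", "spouse", "education", "training_retirement",
      "employment", "ICD10", "age_on", "prev_epi", "s_history",
      "psychot_history", "fam_history", "fam_F20_F25", "fam_F31",
      "fam_F32_F34", "fam_X60", "index_d", "ATRQ_score", "s_current",
      "psychot_current", "height", "weight", "BMI", "HR", "RRsys", "RRdia",
      "cort_basal", "TSH", "fT3", "fT4", "CRP", "HbA1C", "L_Event",
      "wL_Event", "scl_som", "scl_comp", "scl_uncert", "scl_dep", "scl_anx",
      "scl_agg", "scl_pho", "scl_par", "scl_psy", "epq_neu", "epq_psy",
      "epq_ext", "tpq_ha", "tpq_ns", "tpq_rd", "tpq_rd2"
    ),
    type = c(
      "N", "D", "D", "N", "D",
      "N", "C", "N", "N", "D",
      "D", "D", "N", "N",
      "N", "N", "N", "N", "D",
      "D", "N", "N", "N", "N", "N", "N",
      "N", "N", "N", "N", "N", "N", "N",
      "N", "N", "N", "N", "N", "N",
      "N", "N", "N", "N", "N", "N",
      "N", "N", "N", "N", "N"
    ),
    stringsAsFactors = FALSE
  )
  hamd <- data.frame(name = sprintf("HAMD0_%02d", 1:21), type = "N",
                     stringsAsFactors = FALSE)
  out <- rbind(base, hamd)
  out$baseline_item <- c(rep(TRUE, nrow(base)), rep(FALSE, nrow(hamd)))
  out
}

# Per-class mean patterns of the informative items, on the items' natural
# scales; each is rescaled so the one-way ANOVA Cohen's f at large n hits the
# calibrated target.  Directions: episode duration, SCL uncertainty /
# psychoticism / phobic anxiety, neuroticism, harm avoidance and weighted
# life events increase from fast to slow classes; extraversion decreases;
# EPQ psychoticism is weak and non-monotone.
informative_patterns <- function() {
  list(
    index_d    = list(f = 0.153, pattern = c(22.27, 28.46, 43.35, 17.23, 38.67, 30.97, 43.46)),
    scl_uncert = list(f = 0.233, pattern = c(1.04, 1.19, 1.41, 1.02, 1.48, 1.27, 1.53)),
    scl_psy    = list(f = 0.234, pattern = c(0.63, 0.74, 0.84, 0.67, 0.93, 0.86, 1.03)),
    scl_pho    = list(f = 0.227, pattern = c(0.64, 0.79, 0.94, 0.63, 1.02, 0.94, 1.18)),
    epq_neu    = list(f = 0.355, pattern = c(5.17, 6.59, 7.43, 5.92, 7.47, 7.00, 7.74)),
    epq_ext    = list(f = 0.243, pattern = c(6.42, 5.65, 4.95, 5.56, 4.52, 4.76, 4.26)),
    epq_psy    = list(f = 0.081, pattern = c(1.91, 1.94, 2.00, 2.35, 1.94, 2.10, 1.87)),
    tpq_ha     = list(f = 0.341, pattern = c(17.18, 19.81, 21.51, 18.15, 21.92, 21.29, 22.81)),
    wL_Event   = list(f = 0.196, pattern = c(69.82, 77.92, 87.15, 29.00, 86.46, 90.72, 94.96))
  )
}

cohens_f_of_shifts <- function(d, w) {
  w <- w / sum(w)
  m <- sum(w * d)
  sqrt(sum(w * (d - m)^2))
}

#' Default cluster-coupled covariate effects
#'
#' Per-class standardized mean shifts for the nine informative baseline items,
#' each calibrated so the population one-way ANOVA Cohen's f equals its
#' target (e.g. 0.355 for neuroticism, 0.341 for harm avoidance, 0.153 for
#' episode duration) under the spec's mixing weights.  Patterns defined for
#' seven classes are linearly interpolated for other class counts.
#'
#' @param components List of [generating_component()] (supplies K and weights).
#' @return Named list of length-K shift vectors.
#' @export
default_covariate_effects <- function(components = default_components()) {
  w <- vapply(components, `[[`, numeric(1), "weight")
  K <- length(w)
  lapply(informative_patterns(), function(it) {
    p <- it$pattern
    if (K != length(p)) {
      p <- stats::approx(seq_along(p), p, n = K)$y
    }
    d <- p - mean(p)
    f0 <- cohens_f_of_shifts(d, w)
    if (f0 == 0) rep(0, K) else d * (it$f / f0)
  })
}

#' Generate a cluster-coupled clinical baseline table
#'
#' Emits the 71-item schema of [table1_schema()] on standardized scales:
#' items named in `covariate_effects` receive per-class standardized mean
#' shifts on a unit-variance Gaussian; all other items are noise.
#' Dichotomous and categorical items are produced by thresholding the latent
#' Gaussian at 0 and coded as 0/1 integers; the `employment` ordinal is cut
#' into 0/1/2; the 21 baseline HAM-D single items are integers 0--4 from a
#' discretized latent Gaussian (uninformative, as single baseline items carry
#' no class signal beyond the summary psychopathology scales).  A fraction of
#' cells is set missing completely at random.
#'
#' @param labels Integer class labels (1..K), one per patient, named by
#'   patient id.
#' @param spec The [synthetic_spec()] the labels were drawn from.
#' @param seed Integer seed.
#' @return A `trc_clinical` data.frame (first column `patient_id`) with an
#'   `item_types` attribute naming each item's type.
#' @export
generate_clinical <- function(labels, spec, seed = spec$seed) {
  validate_spec(spec)
  K <- length(spec$components)
  if (any(labels < 1L | labels > K)) {
    stop("generate_clinical(): labels outside 1..K")
  }
  eff <- spec$covariate_effects
  if (is.null(eff)) eff <- default_covariate_effects(spec$components)
  schema <- table1_schema()
  unknown <- setdiff(names(eff), schema$name)
  if (length(unknown) > 0L) {
    stop("generate_clinical(): unknown item name(s) in covariate_effects: ",
         paste(unknown, collapse = ", "))
  }
  bad_len <- names(eff)[vapply(eff, length, integer(1)) != K]
  if (length(bad_len) > 0L) {
    stop("generate_clinical(): covariate_effects entries must have length K: ",
         paste(bad_len, collapse = ", "))
  }
  set.seed(seed)
  n <- length(labels)
  cols <- list()
  types <- character(0)
  for (j in seq_len(nrow(schema))) {
    nm <- schema$name[j]
    ty <- schema$type[j]
    latent <- stats::rnorm(n)
    if (nm %in% names(eff)) latent <- latent + eff[[nm]][labels]
    cols[[nm]] <- if (grepl("^HAMD0_", nm)) {
      pmin(pmax(round(latent + 2), 0), 4)
    } else if (ty == "N" && nm == "employment") {
      as.numeric(cut(latent, c(-Inf, -0.43, 0.43, Inf), labels = FALSE)) - 1
    } else if (ty %in% c("D", "C")) {
      as.numeric(latent > 0)
    } else {
      latent
    }
    types[nm] <- ty
  }
  if (spec$n_noise_items > 0L) {
    for (j in seq_len(spec$n_noise_items)) {
      nm <- sprintf("noise_%02d", j)
      cols[[nm]] <- stats::rnorm(n)
      types[nm] <- "N"
    }
  }
  tab <- as.data.frame(cols, stringsAsFactors = FALSE)
  if (spec$clinical_missing_rate > 0) {
    m <- matrix(stats::runif(n * ncol(tab)) < spec$clinical_missing_rate,
                nrow = n)
    for (j in seq_len(ncol(tab))) tab[m[, j], j] <- NA
  }
  ids <- names(labels)
  if (is.null(ids)) ids <- sprintf("P%04d", seq_len(n))
  out <- cbind(data.frame(patient_id = ids, stringsAsFactors = FALSE), tab)
  attr(out, "item_types") <- types
  class(out) <- c("trc_clinical", "data.frame")
  out
}
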