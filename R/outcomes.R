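# Conventional response markers and the cluster-validation statistics:
# response/remission at discharge, individual ln-scale slopes, slope
# correlates, one-way ANOVA with Cohen's f, and univariate likelihood-ratio
# tests of clinical items against the classes.

#' Conventional response markers of one trajectory
#'
#' Evaluated at the last observed week (discharge, or the design end for
#' patients never discharged): response is a relative raw-score decrease of
#' at least 50% from baseline, remission a raw score below 10.
#'
#' @param series A regularized `trc_series`.
#' @return One-row data.frame: `patient_id`, `baseline_raw`,
#'   `discharge_raw`, `weeks_to_discharge`, `response`, `remission`,
#'   `individual_slope`, `episode_mean_raw`.
#' @export
response_markers <- function(series) {
  stopifnot(inherits(series, "trc_series"))
  baseline <- series$raw[series$weeks == 0L]
  dis <- series$raw[length(series$raw)]
  data.frame(
    patient_id = series$patient_id,
    baseline_raw = baseline,
    discharge_raw = dis,
    weeks_to_discharge = series$last_week,
    response = (baseline - dis) / baseline >= 0.5,
    remission = dis < 10,
    individual_slope = individual_slope(series),
    episode_mean_raw = mean(series$raw, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Response markers for every patient of a cohort
#'
#' @param x A regularized `trc_cohort`.
#' @return data.frame, one row per patient (see [response_markers()]).
#' @export
cohort_markers <- function(x) {
  stopifnot(inherits(x, "trc_cohort"))
  out <- do.call(rbind, lapply(unname(x$series), response_markers))
  rownames(out) <- NULL
  out
}

#' Individual treatment-response slope
#'
#' Ordinary least-squares slope of the ln-transformed values on the week
#' index; undefined (`NA`) with fewer than two observed timepoints.
#'
#' @param series A `trc_series`.
#' @return Scalar slope in ln-units per week.
#' @export
individual_slope <- function(series) {
  ok <- !is.na(series$lnvals)
  if (sum(ok) < 2L) return(NA_real_)
  t <- series$weeks[ok]
  y <- series$lnvals[ok]
  tc <- t - mean(t)
  sum(tc * (y - mean(y))) / sum(tc * tc)
}

#' Correlates of the cluster-derived slope
#'
#' Pearson correlations (with two-sided p-values) of per-patient
#' cluster-derived slopes with the baseline raw score and with the average
#' raw score of the episode.
#'
#' @param x A regularized `trc_cohort`.
#' @param assign A `trc_assignment` (or `trc_projection`) over the same
#'   patients.
#' @return data.frame with columns `variable`, `r`, `p_value` (`NA` when a
#'   variable is degenerate).
#' @export
slope_correlates <- function(x, assign) {
  if (inherits(assign, "trc_projection")) assign <- assign$assignment
  mk <- cohort_markers(x)
  slopes <- assign$cluster_slope[match(mk$patient_id, assign$patient_id)]
  one <- function(v, nm) {
    if (stats::sd(slopes) == 0 || stats::sd(v) == 0) {
      return(data.frame(variable = nm, r = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(slopes, v)
    data.frame(variable = nm, r = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  }
  rbind(one(mk$baseline_raw, "baseline_raw"),
        one(mk$episode_mean_raw, "episode_mean_raw"))
}

#' One-way ANOVA across classes with Cohen's f
#'
#' Cohen's f is `sqrt(eta2 / (1 - eta2))` with `eta2 = SS_between /
#' SS_total`; effect labels: f <= 0.10 negligible, < 0.25 small, < 0.40
#' medium, >= 0.40 large.  A zero within-class sum of squares yields an
#' infinite f, reported as `large` with `degenerate = TRUE`.
#'
#' @param values Numeric outcome per patient.
#' @param labels Class label per patient; empty classes are dropped.
#' @return List with `f_stat`, `p_value`, `cohens_f`, `effect_label`,
#'   `df_between`, `df_within`, `degenerate`.
#' @export
anova_f <- function(values, labels) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]
  labels <- factor(labels[ok])
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("anova_f(): fewer than 2 occupied classes")
  if (length(values) - nlevels(labels) < 1L) {
    stop("anova_f(): insufficient residual degrees of freedom")
  }
  tab <- summary(stats::aov(values ~ labels))[[1]]
  ssb <- tab[1, "Sum Sq"]
  ssw <- tab[2, "Sum Sq"]
  eta2 <- ssb / (ssb + ssw)
  degenerate <- ssw <= (ssb + ssw) * 1e-12
  f <- if (degenerate) Inf else sqrt(eta2 / (1 - eta2))
  list(
    f_stat = if (degenerate) Inf else tab[1, "F value"],
    p_value = if (degenerate) 0 else tab[1, "Pr(>F)"],
    cohens_f = f,
    effect_label = effect_label(f),
    df_between = tab[1, "Df"],
    df_within = tab[2, "Df"],
    degenerate = degenerate
  )
}

effect_label <- function(f) {
  if (f <= 0.10) "negligible"
  else if (f < 0.25) "small"
  else if (f < 0.40) "medium"
  else "large"
}

#' Univariate likelihood-ratio test of an item against the classes
#'
#' Likelihood-ratio test of the Gaussian linear model `item ~ class` against
#' the intercept-only model, referred to a chi-square distribution with
#' K - 1 degrees of freedom.
#'
#' @param item Numeric values per patient.
#' @param labels Class label per patient.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
univariate_lrt <- function(item, labels) {
  ok <- !is.na(item) & !is.na(labels)
  item <- item[ok]
  labels <- droplevels(factor(labels[ok]))
  if (nlevels(labels) < 2L) {
    stop("univariate_lrt(): fewer than 2 occupied classes")
  }
  m0 <- stats::glm(item ~ 1)
  m1 <- stats::glm(item ~ labels)
  lt <- lmtest::lrtest(m0, m1)
  list(statistic = lt$Chisq[2], df = as.integer(lt$Df[2]),
       p_value = lt$`Pr(>Chisq)`[2])
}
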