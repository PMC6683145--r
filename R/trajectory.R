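# ---- visit designs -----------------------------------------------------

#' Scheduled visit weeks of a study design
#'
#' Two visit designs are supported: `"MARS"` (inpatient design: weekly ratings
#' from baseline to week 6, then bi-weekly to week 16; 21-item HAM-D, maximum
#' total 63) and `"GENDEP"` (trial design: weekly ratings from baseline to
#' week 12; 17-item HAM-D, maximum total 52).  Weeks are 0-based with baseline
#' at week 0 throughout the package.
#'
#' @param design `"MARS"` or `"GENDEP"`.
#' @return Integer vector of scheduled visit weeks.
#' @export
design_weeks <- function(design) {
  design <- match_design(design)
  if (design == "MARS") c(0:6, seq(8L, 16L, 2L)) else 0:12
}

#' @rdname design_weeks
#' @return `design_max_week()`: last scheduled week (16 or 12).
#' @export
design_max_week <- function(design) {
  if (match_design(design) == "MARS") 16L else 12L
}

#' @rdname design_weeks
#' @return `design_max_score()`: maximum raw HAM-D total (63 or 52).
#' @export
design_max_score <- function(design) {
  if (match_design(design) == "MARS") 63L else 52L
}

match_design <- function(design) {
  match.arg(toupper(as.character(design)[1]), c("MARS", "GENDEP"))
}

# ---- score transform ---------------------------------------------------

#' Natural-log transform of a HAM-D total score
#'
#' Scores are analysed on the scale `ln(raw + 0.5)`; the +0.5 offset keeps a
#' raw score of 0 finite.  `inverse_transform_score()` is the exact inverse on
#' integers: `round(exp(y) - 0.5)`.
#'
#' @param raw Non-negative numeric score(s); `NA` passes through.
#' @param y ln-scale value(s).
#' @return Transformed value(s).
#' @examples
#' transform_score(14)               # ~2.674
#' inverse_transform_score(transform_score(14))
#' @export
transform_score <- function(raw) {
  if (any(raw < 0, na.rm = TRUE)) {
    stop("transform_score(): raw scores must be non-negative")
  }
  log(raw + 0.5)
}

#' @rdname transform_score
#' @export
inverse_transform_score <- function(y) {
  round(exp(y) - 0.5)
}

# ---- rating series -----------------------------------------------------

#' Construct a single patient's rating series
#'
#' @param patient_id Identifier (coerced to character).
#' @param weeks Strictly increasing integer visit weeks, first element 0.
#' @param raw Integer HAM-D totals at those weeks; `NA` marks a missing visit.
#' @return A `trc_series` object with fields `patient_id`, `weeks`, `raw`,
#'   `lnvals` (`ln(raw + 0.5)` where observed), `last_week`, and flags
#'   `regularized` and `usable`.
#' @export
rating_series <- function(patient_id, weeks, raw) {
  weeks <- as.integer(weeks)
  raw <- as.numeric(raw)
  if (length(weeks) != length(raw)) {
    stop("rating_series(): weeks and raw must have equal length")
  }
  if (length(weeks) == 0L) stop("rating_series(): empty series")
  if (weeks[1] != 0L) stop("rating_series(): first visit must be week 0")
  if (any(diff(weeks) <= 0L)) {
    stop("rating_series(): weeks must be strictly increasing")
  }
  if (any(raw < 0, na.rm = TRUE)) {
    stop("rating_series(): negative raw score")
  }
  structure(
    list(
      patient_id = as.character(patient_id)[1],
      weeks = weeks,
      raw = raw,
      lnvals = transform_score(raw),
      last_week = max(weeks[!is.na(raw)], 0L),
      regularized = FALSE,
      usable = sum(!is.na(raw)) >= 2L
    ),
    class = "trc_series"
  )
}

#' @export
print.trc_series <- function(x, ...) {
  cat(sprintf(
    "<trc_series> patient %s: %d visits, weeks 0-%d%s\n",
    x$patient_id, length(x$weeks), x$last_week,
    if (x$regularized) " (regularized weekly grid)" else ""
  ))
  invisible(x)
}

#' Construct a cohort of rating series
#'
#' @param series List of [rating_series()] objects.
#' @param design `"MARS"` or `"GENDEP"`.
#' @return A `trc_cohort` object; patient ids must be unique.
#' @export
cohort <- function(series, design = "MARS") {
  ids <- vapply(series, function(s) s$patient_id, character(1))
  if (anyDuplicated(ids)) {
    stop("cohort(): duplicated patient ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(series) <- ids
  structure(list(series = series, design = match_design(design)),
            class = "trc_cohort")
}

#' @export
print.trc_cohort <- function(x, ...) {
  cat(sprintf("<trc_cohort> %d patients, %s design\n",
              length(x$series), x$design))
  invisible(x)
}

#' @export
length.trc_cohort <- function(x) length(x$series)

#' Patient ids of a cohort
#' @param x A `trc_cohort`.
#' @return Character vector of patient ids.
#' @export
patient_ids <- function(x) {
  unname(vapply(x$series, function(s) s$patient_id, character(1)))
}

# ---- eligibility filter ------------------------------------------------

#' Filter a cohort to baseline-eligible patients
#'
#' Retains patients with an observed baseline (week 0) raw score of at least
#' `min_baseline`; patients below the threshold or without a baseline record
#' are excluded and listed in the report.
#'
#' @param x A `trc_cohort`.
#' @param min_baseline Minimum baseline raw score (default 14).
#' @return A list with `cohort` (the filtered cohort) and `excluded`, a
#'   data.frame of `patient_id` and `reason`.
#' @export
filter_eligible <- function(x, min_baseline = 14) {
  stopifnot(inherits(x, "trc_cohort"))
  reasons <- vapply(x$series, function(s) {
    b <- s$raw[s$weeks == 0L]
    if (length(b) == 0L || is.na(b)) {
      "no baseline"
    } else if (b < min_baseline) {
      sprintf("baseline %g < %g", b, min_baseline)
    } else {
      ""
    }
  }, character(1))
  keep <- reasons == ""
  list(
    cohort = cohort(x$series[keep], x$design),
    excluded = data.frame(
      patient_id = patient_ids(x)[!keep],
      reason = unname(reasons[!keep]),
      stringsAsFactors = FALSE
    )
  )
}

# ---- grid regularization -----------------------------------------------

#' Regularize a rating series onto a complete weekly grid
#'
#' Accidentally missing visits and the bi-weekly gaps of the MARS design are
#' filled by linear interpolation between the nearest observed neighbours, on
#' the raw scale, before the ln transform (interpolating on the ln scale would
#' systematically differ by Jensen's inequality and is available via
#' `scale = "ln"`).  No extrapolation is performed: a trailing run of missing
#' values truncates the series at the last observed week.  A series with a
#' single observed visit is kept but flagged unusable for slope estimation.
#'
#' @param series A `trc_series`.
#' @param scale Interpolation scale, `"raw"` (default) or `"ln"`.
#' @return The series with values at every integer week `0..last_week`,
#'   `regularized = TRUE`.
#' @export
regularize_grid <- function(series, scale = c("raw", "ln")) {
  stopifnot(inherits(series, "trc_series"))
  scale <- match.arg(scale)
  obs <- !is.na(series$raw)
  if (!obs[1]) stop("regularize_grid(): baseline (week 0) not observed")
  last_week <- max(series$weeks[obs])
  grid <- 0:last_week
  if (sum(obs) == 1L) {
    out <- series
    out$weeks <- 0L
    out$raw <- series$raw[1]
    out$lnvals <- transform_score(series$raw[1])
    out$last_week <- 0L
    out$regularized <- TRUE
    out$usable <- FALSE
    return(out)
  }
  if (scale == "raw") {
    vals <- stats::approx(series$weeks[obs], series$raw[obs], xout = grid,
                          method = "linear", rule = 1)$y
    lnvals <- transform_score(vals)
  } else {
    lnobs <- transform_score(series$raw[obs])
    lnvals <- stats::approx(series$weeks[obs], lnobs, xout = grid,
                            method = "linear", rule = 1)$y
    vals <- exp(lnvals) - 0.5
  }
  out <- series
  out$weeks <- grid
  out$raw <- vals
  out$lnvals <- lnvals
  out$last_week <- last_week
  out$regularized <- TRUE
  out$usable <- TRUE
  out
}

#' Regularize every series of a cohort
#'
#' @param x A `trc_cohort`.
#' @param scale Passed to [regularize_grid()].
#' @return The cohort with all series on complete weekly grids.
#' @export
regularize_cohort <- function(x, scale = c("raw", "ln")) {
  stopifnot(inherits(x, "trc_cohort"))
  scale <- match.arg(scale)
  cohort(lapply(x$series, regularize_grid, scale = scale), x$design)
}

#' Tidy long-format view of a cohort
#'
#' @param x A `trc_cohort`.
#' @return data.frame with columns `patient_id`, `week`, `raw`, `lnval`.
#' @export
as.data.frame.trc_cohort <- function(x, ...) {
  do.call(rbind, lapply(unname(x$series), function(s) {
    data.frame(patient_id = s$patient_id, week = s$weeks,
               raw = s$raw, lnval = s$lnvals, stringsAsFactors = FALSE)
  }))
}

# Stack a regularized cohort into flat vectors for the EM machinery.
# Patients with no usable ln value are rejected upstream.
stack_cohort <- function(x) {
  stopifnot(inherits(x, "trc_cohort"))
  n <- length(x$series)
  lens <- vapply(x$series, function(s) length(s$weeks), integer(1))
  list(
    y = unlist(lapply(x$series, function(s) s$lnvals), use.names = FALSE),
    t = as.numeric(unlist(lapply(x$series, function(s) s$weeks),
                          use.names = FALSE)),
    pid = rep.int(seq_len(n), lens),
    n = n,
    ids = patient_ids(x)
  )
}
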