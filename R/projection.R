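# Classification of new cohorts under a fixed, previously fitted mixture:
# one E-step with frozen coefficients, cohort-level fit statistics, class
# proportion comparison, and stability under shortened observation windows.

#' Assign a cohort under a fixed mixture model
#'
#' Performs a single E-step with frozen parameters (no refitting): posterior
#' responsibilities, hard labels (ties to the lower class index), and
#' cohort-level log-likelihood, classification log-likelihood, entropy and
#' ICL under the projected model.
#'
#' @param model A sorted `trc_model` (e.g. from a discovery-sample fit).
#' @param x A regularized `trc_cohort`.
#' @return A `trc_projection`: list with `assignment` (a `trc_assignment`),
#'   `loglik`, `class_loglik`, `entropy`, `icl`, `n`, `n_params`.
#' @export
assign_fixed <- function(model, x) {
  stopifnot(inherits(model, "trc_model"), inherits(x, "trc_cohort"))
  es <- e_step(model, x)
  assign <- make_assignment(es$posteriors, model)
  n <- nrow(es$posteriors)
  p <- 3L * model$k + (model$k - 1L)
  ent <- posterior_entropy(es$posteriors)
  # classification log-likelihood: complete-data loglik at the hard labels
  st <- stack_em(x)
  L <- loglik_matrix(st, model$components)
  lab <- assign$label
  class_ll <- sum(log(model$components$weight[lab]) +
                    L[cbind(seq_len(n), lab)])
  structure(
    list(assignment = assign, loglik = es$loglik, class_loglik = class_ll,
         entropy = ent, icl = -2 * es$loglik + p * log(n) + 2 * ent,
         n = n, n_params = p),
    class = "trc_projection"
  )
}

#' @export
print.trc_projection <- function(x, ...) {
  cat(sprintf(
    "<trc_projection> %d patients | loglik %.4f | class loglik %.4f | ICL %.4f\n",
    x$n, x$loglik, x$class_loglik, x$icl))
  print(table(class = paste0("C", x$assignment$label)))
  invisible(x)
}

#' Chi-square comparison of class proportions between two samples
#'
#' Pearson chi-square test of homogeneity on the K-by-2 contingency table of
#' per-class counts (df = K - 1); classes empty in both samples are dropped
#' with a warning.
#'
#' @param counts_a,counts_b Per-class counts (equal length, totals > 0).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
proportion_test <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b)) {
    stop("proportion_test(): count vectors must have equal length")
  }
  if (sum(counts_a) == 0 || sum(counts_b) == 0) {
    stop("proportion_test(): all-zero count vector")
  }
  both0 <- counts_a == 0 & counts_b == 0
  if (any(both0)) {
    warning("proportion_test(): dropping ", sum(both0),
            " class(es) empty in both samples")
    counts_a <- counts_a[!both0]
    counts_b <- counts_b[!both0]
  }
  ct <- suppressWarnings(
    stats::chisq.test(cbind(counts_a, counts_b), correct = FALSE)
  )
  list(statistic = unname(ct$statistic),
       df = as.integer(unname(ct$parameter)),
       p_value = unname(ct$p.value))
}

#' Class counts of an assignment
#'
#' @param assign A `trc_assignment` (or `trc_projection`).
#' @param k Number of classes (defaults to the posterior width).
#' @return Integer vector of per-class counts, length k.
#' @export
class_counts <- function(assign, k = NULL) {
  if (inherits(assign, "trc_projection")) assign <- assign$assignment
  if (is.null(k)) k <- ncol(assign$posteriors)
  tabulate(assign$label, nbins = k)
}

# ---- reduced observation windows ---------------------------------------

truncate_cohort <- function(x, m) {
  cohort(lapply(x$series, function(s) {
    keep <- seq_len(min(m, length(s$weeks)))
    s$weeks <- s$weeks[keep]
    s$raw <- s$raw[keep]
    s$lnvals <- s$lnvals[keep]
    s$last_week <- max(s$weeks)
    s
  }), x$design)
}

#' Assign a cohort using only the first m observations per patient
#'
#' Identical to [assign_fixed()] except that each patient's likelihood uses
#' only their first `min(m, available)` weekly values.
#'
#' @param model A sorted `trc_model`.
#' @param x A regularized `trc_cohort`.
#' @param m Number of leading weekly observations to use (>= 1).
#' @return A `trc_projection`.
#' @export
truncate_and_assign <- function(model, x, m) {
  if (m < 1) stop("truncate_and_assign(): m must be >= 1")
  assign_fixed(model, truncate_cohort(x, m))
}

#' Classification stability under shortened observation windows
#'
#' For each window length m from 1 to the design's full weekly grid, patients
#' are reassigned using only their first m values and the Pearson correlation
#' between the cluster-derived slopes of the truncated and the full-window
#' assignment is computed.  At the full window the correlation is exactly 1;
#' degenerate windows (all patients in one class) yield `NA` with a warning.
#'
#' @param model A sorted `trc_model`.
#' @param x A regularized `trc_cohort`.
#' @param m_max Largest window (default: the design's full grid length).
#' @return data.frame with columns `m`, `r`, `n_effective`.
#' @export
truncation_curve <- function(model, x, m_max = NULL) {
  if (is.null(m_max)) m_max <- design_max_week(x$design) + 1L
  full <- assign_fixed(model, x)$assignment$cluster_slope
  res <- lapply(seq_len(m_max), function(m) {
    trunc <- truncate_and_assign(model, x, m)$assignment$cluster_slope
    r <- if (stats::sd(full) == 0 || stats::sd(trunc) == 0) {
      warning("truncation_curve(): degenerate slope variance at m = ", m,
              "; correlation undefined")
      NA_real_
    } else {
      stats::cor(trunc, full)
    }
    data.frame(m = m, r = r, n_effective = length(full))
  })
  do.call(rbind, res)
}
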