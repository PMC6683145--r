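# Finite mixture of linear models for grouped trajectories, fitted by EM.
#
# Each class k is a line on the ln(HAM-D + 0.5) scale with intercept a_k,
# slope b_k per week and residual SD sigma_k; a patient contributes all their
# timepoints to a single posterior responsibility z_ik, so whole trajectories
# (not visits) are the units being clustered.

SIGMA_FLOOR <- 1e-4

new_model <- function(intercept, slope, residual_sd, weight, sorted = FALSE) {
  structure(
    list(
      k = length(intercept),
      components = data.frame(intercept = intercept, slope = slope,
                              residual_sd = residual_sd, weight = weight),
      sorted = sorted
    ),
    class = "trc_model"
  )
}

#' @export
print.trc_model <- function(x, ...) {
  cat(sprintf("<trc_model> %d components%s\n", x$k,
              if (isTRUE(x$sorted)) " (sorted by slope, C1 fastest)" else ""))
  comp <- x$components
  rownames(comp) <- paste0("C", seq_len(nrow(comp)))
  print(round(comp, 4))
  invisible(x)
}

#' Build a mixture model from explicit component parameters
#'
#' @param intercept,slope ln-scale intercepts (week 0) and per-week slopes.
#' @param residual_sd Positive residual SDs.
#' @param weight Mixing weights, summing to 1 within 1e-10.
#' @return A `trc_model`.
#' @export
mixture_model <- function(intercept, slope, residual_sd, weight) {
  stopifnot(length(intercept) == length(slope),
            length(slope) == length(residual_sd),
            length(residual_sd) == length(weight))
  if (any(residual_sd <= 0)) stop("mixture_model(): residual_sd must be > 0")
  if (any(weight <= 0 | weight > 1)) {
    stop("mixture_model(): weights must be in (0, 1]")
  }
  if (abs(sum(weight) - 1) > 1e-10) {
    stop("mixture_model(): weights must sum to 1")
  }
  new_model(intercept, slope, residual_sd, weight)
}

#' Mixture model with the generating parameters of a synthetic spec
#'
#' @param spec A [synthetic_spec()].
#' @return A sorted `trc_model` with the spec's component lines and weights.
#' @export
generating_model <- function(spec) {
  pars <- component_params(spec$components)
  sort_components(mixture_model(pars$intercept, pars$slope,
                                pmax(pars$residual_sd, SIGMA_FLOOR),
                                pars$weight))
}

# ---- likelihood --------------------------------------------------------

#' Per-patient log-likelihood under one component
#'
#' Sum over the patient's available weeks of the Gaussian log-density
#' `N(y_t; intercept + slope * t, residual_sd^2)`.
#'
#' @param series A `trc_series` (missing values are skipped).
#' @param comp List with `intercept`, `slope`, `residual_sd`.
#' @return Scalar log-density.
#' @export
component_loglik <- function(series, comp) {
  ok <- !is.na(series$lnvals)
  if (!any(ok)) stop("component_loglik(): series has no observed values")
  sum(stats::dnorm(series$lnvals[ok],
                   comp$intercept + comp$slope * series$weeks[ok],
                   comp$residual_sd, log = TRUE))
}

# n-by-K matrix of per-patient component log-likelihoods on stacked data.
loglik_matrix <- function(st, comp) {
  K <- length(comp$weight)
  MU <- outer(st$t, comp$slope) +
    matrix(comp$intercept, length(st$t), K, byrow = TRUE)
  R <- (st$y - MU) / matrix(comp$residual_sd, length(st$t), K, byrow = TRUE)
  LD <- -0.5 * log(2 * pi) -
    matrix(log(comp$residual_sd), length(st$t), K, byrow = TRUE) - 0.5 * R * R
  rowsum(LD, st$pid, reorder = TRUE)
}

# Log-space posterior normalization; returns z (n x K) and total loglik.
posterior_from_ll <- function(L, weight) {
  logz <- sweep(L, 2, log(weight), `+`)
  jmax <- max.col(logz, ties.method = "first")
  rM <- logz[cbind(seq_len(nrow(logz)), jmax)]
  bad <- !is.finite(rM)
  if (any(bad)) {
    warning(sum(bad), " patient(s) with fully underflowed densities; ",
            "uniform posterior assigned")
    logz[bad, ] <- 0
    rM[bad] <- 0
  }
  S <- rM + log(rowSums(exp(logz - rM)))
  list(z = exp(logz - S), loglik = sum(S))
}

#' E-step: posterior responsibilities under a mixture model
#'
#' `z_ik` is proportional to `weight_k * exp(component_loglik(i, k))`,
#' normalized per patient in log space (exact when no underflow occurs).
#'
#' @param model A `trc_model`.
#' @param x A regularized `trc_cohort`.
#' @return List with `posteriors` (n-by-K matrix, rownames = patient ids) and
#'   `loglik`, the observed-data log-likelihood.
#' @export
e_step <- function(model, x) {
  st <- stack_em(x)
  L <- loglik_matrix(st, model$components)
  post <- posterior_from_ll(L, model$components$weight)
  rownames(post$z) <- st$ids
  list(posteriors = post$z, loglik = post$loglik)
}

stack_em <- function(x) {
  st <- stack_cohort(x)
  ok <- !is.na(st$y)
  if (!all(ok)) {
    st$y <- st$y[ok]; st$t <- st$t[ok]; st$pid <- st$pid[ok]
  }
  if (!all(seq_len(st$n) %in% unique(st$pid))) {
    stop("cohort contains patients with zero usable visits")
  }
  st
}

# ---- M-step ------------------------------------------------------------

m_step_stacked <- function(st, z, weight_floor = 1) {
  W <- z[st$pid, , drop = FALSE]
  t <- st$t; y <- st$y
  Sw <- colSums(W)
  Swt <- colSums(W * t)
  Swtt <- colSums(W * t * t)
  Swy <- colSums(W * y)
  Swty <- colSums(W * t * y)
  Swyy <- colSums(W * y * y)
  det <- Sw * Swtt - Swt^2
  slope <- (Sw * Swty - Swt * Swy) / det
  intercept <- (Swy - slope * Swt) / Sw
  rss <- Swyy - 2 * intercept * Swy - 2 * slope * Swty +
    intercept^2 * Sw + 2 * intercept * slope * Swt + slope^2 * Swtt
  sigma <- sqrt(pmax(rss / Sw, SIGMA_FLOOR^2))
  wts <- colSums(z) / nrow(z)
  degenerate <- any(colSums(z) < weight_floor) || any(det <= 0) ||
    any(!is.finite(c(intercept, slope, sigma)))
  list(model = new_model(intercept, slope, sigma, wts),
       degenerate = degenerate)
}

#' M-step: weighted least-squares update of component parameters
#'
#' Each component's line is the weighted least-squares fit of the ln values
#' on week, every row of patient i weighted by that patient's responsibility
#' `z_ik`; `sigma_k^2` is the weighted mean squared residual (floored at
#' 1e-4) and `weight_k` the mean responsibility over patients.
#'
#' @param x A regularized `trc_cohort`.
#' @param posteriors n-by-K responsibility matrix.
#' @param weight_floor Minimum effective number of patients per component;
#'   below it the update is flagged degenerate.
#' @return List with `model` (a `trc_model`) and `degenerate` flag.
#' @export
m_step <- function(x, posteriors, weight_floor = 1) {
  m_step_stacked(stack_em(x), posteriors, weight_floor)
}

# ---- EM driver ---------------------------------------------------------

#' Fit a k-component mixture of linear models by EM
#'
#' Starts from a seeded random hard partition of patients, alternates E and
#' M steps until the relative change in observed-data log-likelihood falls
#' below `tol` or `max_iter` is reached.  Runs hitting a degeneracy guard
#' (component effective weight below one patient, or collapsed residual
#' variance) are flagged non-converged.  The returned model is sorted by
#' slope (fastest improvement first).
#'
#' @param x A regularized `trc_cohort`.
#' @param k Number of components (1 <= k <= number of patients).
#' @param seed Integer seed for the initial partition.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500).
#' @param init_labels Optional explicit initial hard labels (overrides seed).
#' @return A `trc_fit`: list with `model`, `assignment` (a `trc_assignment`),
#'   and `diagnostics` (loglik, BIC, entropy, ICL, iteration trace,
#'   convergence flag).
#' @export
fit_em <- function(x, k, seed = 1L, tol = 1e-8, max_iter = 500L,
                   init_labels = NULL) {
  stopifnot(inherits(x, "trc_cohort"))
  st <- stack_em(x)
  fit_em_stats(patient_stats(st), st$ids, k, seed, tol, max_iter, init_labels)
}

# Six sufficient statistics per patient: n_i, St, Stt, Sy, Sty, Syy.
patient_stats <- function(st) {
  unname(rowsum(cbind(1, st$t, st$t^2, st$y, st$t * st$y, st$y^2), st$pid))
}

fit_em_stats <- function(stats, ids, k, seed = 1L, tol = 1e-8,
                         max_iter = 500L, init_labels = NULL) {
  n <- nrow(stats)
  k <- as.integer(k)
  if (k < 1L) stop("fit_em(): k must be >= 1")
  if (k > n) stop("fit_em(): k exceeds the number of patients")
  if (is.null(init_labels)) {
    set.seed(seed)
    init_labels <- sample(rep_len(seq_len(k), n))
  }
  res <- em_core(stats, k, as.integer(init_labels) - 1L, tol,
                 as.integer(max_iter), SIGMA_FLOOR, 1)
  if (res$n_underflow > 0L) {
    warning("fit_em(): ", res$n_underflow,
            " posterior row(s) fully underflowed; uniform posterior assigned")
  }
  model <- new_model(res$intercept, res$slope, res$residual_sd, res$weight)
  z <- res$z
  rownames(z) <- ids
  diag <- make_diagnostics(res$loglik, k, n, z,
                           n_iter = res$n_iter,
                           converged = res$converged && !res$degenerate,
                           trace = res$trace)
  fit <- structure(
    list(model = model,
         assignment = make_assignment(z, model),
         diagnostics = diag,
         meta = list(seed = seed, tol = tol, max_iter = max_iter)),
    class = "trc_fit"
  )
  sort_components(fit)
}

make_diagnostics <- function(loglik, k, n, z, n_iter, converged, trace,
                             n_restarts_failed = 0L) {
  ent <- posterior_entropy(z)
  p <- 3L * k + (k - 1L)
  bic <- -2 * loglik + p * log(n)
  structure(
    list(loglik = loglik, n_params = p, n = n, bic = bic, entropy = ent,
         icl = bic + 2 * ent, n_iter = n_iter, converged = converged,
         loglik_trace = trace, n_restarts_failed = n_restarts_failed),
    class = "trc_diagnostics"
  )
}

#' @export
print.trc_diagnostics <- function(x, ...) {
  cat(sprintf(
    "<trc_diagnostics> loglik %.4f | BIC %.4f | entropy %.4f | ICL %.4f\n",
    x$loglik, x$bic, x$entropy, x$icl))
  cat(sprintf("  %d iterations, converged: %s, failed restarts: %d\n",
              x$n_iter, x$converged, x$n_restarts_failed))
  invisible(x)
}

posterior_entropy <- function(z) {
  zl <- z * log(z)
  zl[z == 0] <- 0
  -sum(zl)
}

make_assignment <- function(z, model) {
  label <- max.col(z, ties.method = "first")
  structure(
    list(patient_id = rownames(z), posteriors = z, label = label,
         cluster_slope = model$components$slope[label]),
    class = "trc_assignment"
  )
}

#' @export
print.trc_assignment <- function(x, ...) {
  cat(sprintf("<trc_assignment> %d patients, %d classes\n",
              length(x$label), ncol(x$posteriors)))
  print(table(class = paste0("C", x$label)))
  invisible(x)
}

#' @export
print.trc_fit <- function(x, ...) {
  cat("<trc_fit>\n")
  print(x$model)
  print(x$diagnostics)
  invisible(x)
}

#' Information criteria of a fitted mixture
#'
#' Free parameter count `p = 3k + (k - 1)` (intercept, slope, residual SD per
#' component plus k - 1 free weights); `BIC = -2 loglik + p ln(N)` with N the
#' number of patients (trajectories are the exchangeable units, switchable to
#' observation count via `n_unit`); `ENT = -sum z ln z`; `ICL = BIC + 2 ENT`.
#'
#' @param fit A `trc_fit`.
#' @param n_unit `"patients"` (default) or `"observations"`; the latter needs
#'   `n_obs`.
#' @param n_obs Total observation count when `n_unit = "observations"`.
#' @return A `trc_diagnostics`.
#' @export
information_criteria <- function(fit, n_unit = c("patients", "observations"),
                                 n_obs = NULL) {
  n_unit <- match.arg(n_unit)
  z <- fit$assignment$posteriors
  n <- if (n_unit == "patients") nrow(z) else {
    if (is.null(n_obs)) stop("information_criteria(): n_obs required")
    n_obs
  }
  make_diagnostics(fit$diagnostics$loglik, fit$model$k, n, z,
                   n_iter = fit$diagnostics$n_iter,
                   converged = fit$diagnostics$converged,
                   trace = fit$diagnostics$loglik_trace,
                   n_restarts_failed = fit$diagnostics$n_restarts_failed)
}

# ---- restarts and model selection --------------------------------------

#' Best-of-restarts EM fit
#'
#' Runs [fit_em()] from `n_restarts` distinct seeded initial partitions and
#' returns the converged fit with the highest log-likelihood; degenerate or
#' non-converged runs are counted as failures.  With zero converged restarts
#' an explicit no-solution result (`fit = NULL`) is returned, mirroring the
#' non-convergence observed at extreme class counts.
#'
#' @param x A regularized `trc_cohort`.
#' @param k Number of components.
#' @param n_restarts Number of random restarts (>= 1).
#' @param seed Integer master seed; restart sub-seeds are drawn from it.
#' @param ... Passed to [fit_em()] (`tol`, `max_iter`).
#' @return A `trc_restart`: list with `fit` (best `trc_fit` or `NULL`), `k`,
#'   `n_restarts`, `n_converged`, `n_failed`.
#' @export
fit_restarts <- function(x, k, n_restarts = 200L, seed = 1L, ...) {
  if (n_restarts < 1L) stop("fit_restarts(): n_restarts must be >= 1")
  st <- if (inherits(x, "trc_cohort")) stack_em(x) else x
  stats <- patient_stats(st)
  set.seed(seed)
  sub_seeds <- c(seed, sample.int(.Machine$integer.max - 1L, n_restarts - 1L))
  best <- NULL
  n_conv <- 0L
  for (s in sub_seeds) {
    f <- fit_em_stats(stats, st$ids, k, seed = s, ...)
    if (!f$diagnostics$converged) next
    n_conv <- n_conv + 1L
    if (is.null(best) || f$diagnostics$loglik > best$diagnostics$loglik) {
      best <- f
    }
  }
  if (!is.null(best)) {
    best$diagnostics$n_restarts_failed <- n_restarts - n_conv
  }
  structure(
    list(fit = best, k = as.integer(k), n_restarts = as.integer(n_restarts),
         n_converged = n_conv, n_failed = n_restarts - n_conv, seed = seed),
    class = "trc_restart"
  )
}

#' @export
print.trc_restart <- function(x, ...) {
  cat(sprintf("<trc_restart> k = %d: %d/%d restarts converged\n",
              x$k, x$n_converged, x$n_restarts))
  if (is.null(x$fit)) cat("  no converged solution\n") else print(x$fit)
  invisible(x)
}

#' Select the number of classes by the ICL criterion
#'
#' Fits each candidate k with [fit_restarts()] and chooses the k minimizing
#' the integrated completed likelihood among the k's with a converged
#' solution; the full ICL-vs-k profile is returned for inspection.
#'
#' @param x A regularized `trc_cohort`.
#' @param k_range Candidate class counts (default 4:10).
#' @param n_restarts Restarts per k (default 200).
#' @param seed Integer master seed; each k gets a derived sub-seed.
#' @param ... Passed to [fit_em()].
#' @return A `trc_selection`: list with `profile` (data.frame of k, loglik,
#'   bic, entropy, icl, n_converged), `best_k` (NA when nothing converged),
#'   `fit` (best `trc_fit`), and `fits` (per-k `trc_restart` objects).
#' @export
select_k <- function(x, k_range = 4:10, n_restarts = 200L, seed = 1L, ...) {
  if (length(k_range) < 1L) stop("select_k(): empty k_range")
  st <- stack_em(x)
  fits <- lapply(seq_along(k_range), function(j) {
    fit_restarts(st, k_range[j], n_restarts = n_restarts,
                 seed = derive_seed(seed, k_range[j]), ...)
  })
  names(fits) <- paste0("k", k_range)
  prof <- do.call(rbind, lapply(fits, function(r) {
    if (is.null(r$fit)) {
      data.frame(k = r$k, loglik = NA_real_, bic = NA_real_,
                 entropy = NA_real_, icl = NA_real_,
                 n_converged = r$n_converged)
    } else {
      d <- r$fit$diagnostics
      data.frame(k = r$k, loglik = d$loglik, bic = d$bic,
                 entropy = d$entropy, icl = d$icl,
                 n_converged = r$n_converged)
    }
  }))
  rownames(prof) <- NULL
  best_k <- NA_integer_
  best_fit <- NULL
  if (any(!is.na(prof$icl))) {
    best_k <- prof$k[which.min(prof$icl)]
    best_fit <- fits[[paste0("k", best_k)]]$fit
  }
  structure(list(profile = prof, best_k = best_k, fit = best_fit,
                 fits = fits, seed = seed),
            class = "trc_selection")
}

#' @export
print.trc_selection <- function(x, ...) {
  cat("<trc_selection> ICL profile:\n")
  print(transform(x$profile, icl = round(icl, 2), bic = round(bic, 2),
                  loglik = round(loglik, 2), entropy = round(entropy, 2)))
  cat(sprintf("chosen k (ICL minimum): %s\n", x$best_k))
  invisible(x)
}

# ---- component sorting -------------------------------------------------

#' Sort components by slope, fastest improvement first
#'
#' Components are reordered ascending by slope (most negative slope becomes
#' C1), ties broken ascending by intercept; posterior columns and hard labels
#' of an attached assignment are relabelled consistently.
#'
#' @param x A `trc_model` or `trc_fit`.
#' @return The sorted object (same class as the input).
#' @export
sort_components <- function(x) {
  if (inherits(x, "trc_fit")) {
    ord <- component_order(x$model)
    x$model <- reorder_model(x$model, ord)
    x$assignment <- reorder_assignment(x$assignment, ord, x$model)
    return(x)
  }
  if (inherits(x, "trc_model")) {
    return(reorder_model(x, component_order(x)))
  }
  stop("sort_components(): expected a trc_model or trc_fit")
}

component_order <- function(model) {
  order(model$components$slope, model$components$intercept)
}

reorder_model <- function(model, ord) {
  comp <- model$components[ord, , drop = FALSE]
  rownames(comp) <- NULL
  model$components <- comp
  model$sorted <- TRUE
  model
}

reorder_assignment <- function(assign, ord, sorted_model) {
  z <- assign$posteriors[, ord, drop = FALSE]
  make_assignment(z, sorted_model)
}
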