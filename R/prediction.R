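# Clinical prediction layer: median imputation, the four feature-set models
# (0-3) over the baseline item catalogue, random-forest regression of
# individual and cluster-derived response slopes, Altmann-style permutation
# importance, one-vs-rest class accuracies and Fisher-Z model comparison.

#' Median-impute a clinical table
#'
#' Numeric items get the column median of the observed values; dichotomous
#' items the median rounded to 0/1 (ties to 0); categorical items the mode
#' (ties to the smallest value).
#'
#' @param table A `trc_clinical` (data.frame with an `item_types` attribute;
#'   a plain data.frame is treated as all-numeric).
#' @return The table with no missing cells.
#' @export
impute_median <- function(table) {
  types <- attr(table, "item_types")
  items <- setdiff(names(table), "patient_id")
  for (nm in items) {
    v <- table[[nm]]
    if (!anyNA(v)) next
    obs <- v[!is.na(v)]
    if (length(obs) == 0L) stop("impute_median(): column '", nm,
                                "' is fully missing")
    ty <- if (is.null(types)) "N" else types[[nm]]
    fill <- switch(ty,
      D = { m <- stats::median(obs); if (m == 0.5) 0 else round(m) },
      C = { tab <- table(obs); as.numeric(names(tab)[which.max(tab)]) },
      stats::median(obs)
    )
    v[is.na(v)] <- fill
    table[[nm]] <- v
  }
  table
}

#' Early partial response flag
#'
#' TRUE when the raw score dropped by at least 25% from baseline by week 2
#' (interpolated week-2 values are permitted).
#'
#' @param series A regularized `trc_series` reaching at least week 2.
#' @return Logical flag (`NA` when week 2 is not covered).
#' @export
early_partial_response <- function(series) {
  stopifnot(inherits(series, "trc_series"))
  b <- series$raw[series$weeks == 0L]
  w2 <- series$raw[series$weeks == 2L]
  if (length(w2) == 0L || is.na(w2) || is.na(b)) return(NA)
  if (b == 0) stop("early_partial_response(): zero baseline score")
  (b - w2) / b >= 0.25
}

#' Assemble the feature matrix of one prediction model
#'
#' Model 0: the 50 baseline items; model 1: model 0 plus the 21 baseline
#' HAM-D single items (71 columns); model 2: model 0 plus the early partial
#' response flag `HD_2WE` (51); model 3: both expansions (72).  Categorical
#' items keep their integer coding.
#'
#' @param table An imputed `trc_clinical`.
#' @param x A regularized `trc_cohort` covering the table's patients (used
#'   for `HD_2WE`; may be `NULL` for models 0 and 1).
#' @param model_id 0, 1, 2 or 3.
#' @return Numeric data.frame of features, rows aligned with `table`,
#'   with a `patient_id` attribute.
#' @export
assemble_features <- function(table, x = NULL, model_id = 0L) {
  if (!model_id %in% 0:3) {
    stop("assemble_features(): unknown model_id '", model_id,
         "' (must be 0, 1, 2 or 3)")
  }
  schema <- table1_schema()
  want <- schema$name[schema$baseline_item]
  if (model_id %in% c(1L, 3L)) want <- c(want, schema$name[!schema$baseline_item])
  missing_cols <- setdiff(want, names(table))
  if (length(missing_cols) > 0L) {
    stop("assemble_features(): table lacks item(s): ",
         paste(missing_cols, collapse = ", "))
  }
  feats <- table[, want, drop = FALSE]
  if (model_id %in% c(2L, 3L)) {
    if (is.null(x)) {
      stop("assemble_features(): a cohort is required for HD_2WE (models 2, 3)")
    }
    epr <- vapply(table$patient_id, function(id) {
      s <- x$series[[id]]
      if (is.null(s)) NA else as.numeric(early_partial_response(s))
    }, numeric(1))
    if (anyNA(epr)) {
      # week 2 not covered (or patient absent): impute the dichotomous median
      m <- stats::median(epr, na.rm = TRUE)
      epr[is.na(epr)] <- if (is.na(m)) 0 else if (m == 0.5) 0 else round(m)
    }
    feats$HD_2WE <- epr
  }
  feats <- as.data.frame(lapply(feats, as.numeric))
  attr(feats, "patient_id") <- table$patient_id
  class(feats) <- "data.frame"
  feats
}

# ---- random forest -----------------------------------------------------

#' Fit and evaluate a random-forest slope model
#'
#' Random-forest regression of a per-patient response slope on the clinical
#' features, with `mtry = floor(sqrt(D))` and out-of-bag predictions defining
#' the explained variance: `R2` is the squared correlation between OOB
#' predictions and the target, adjusted as
#' `1 - (1 - R2)(n - 1)/(n - D - 1)`.  An optional overall-model p-value is
#' computed from a seeded target-permutation null of `R2`.  When a mixture
#' model and true labels are supplied, predicted slopes are mapped to the
#' nearest component slope and a confusion matrix with one-vs-rest class
#' accuracies is attached.
#'
#' @param features Numeric feature data.frame (no missing cells).
#' @param target Numeric per-patient slope.
#' @param trees Number of trees (default 2000).
#' @param n_perm_model Target permutations for the model p-value (default
#'   1000; 0 skips it).
#' @param seed Integer seed.
#' @param model Optional sorted `trc_model` for slope-to-class mapping.
#' @param true_labels Optional integer class labels for the confusion matrix.
#' @return A `trc_prediction`: list with `r2`, `r2_adj`, `model_p`, `mtry`,
#'   `n`, `D`, `oob_pred`, and (when applicable) `confusion`,
#'   `per_class_accuracy`, `predicted_class`.
#' @export
rf_fit_evaluate <- function(features, target, trees = 2000L,
                            n_perm_model = 1000L, seed = 1L,
                            model = NULL, true_labels = NULL) {
  if (anyNA(features)) stop("rf_fit_evaluate(): features contain missing cells")
  if (stats::sd(target) == 0) stop("rf_fit_evaluate(): constant target")
  n <- nrow(features)
  D <- ncol(features)
  if (n <= D + 1L) {
    stop("rf_fit_evaluate(): n must exceed D + 1 for the R2 adjustment")
  }
  mtry <- floor(sqrt(D))
  rf <- ranger::ranger(x = features, y = target, num.trees = trees,
                       mtry = mtry, seed = seed, num.threads = 1)
  oob <- rf$predictions
  r2 <- oob_r2(oob, target)
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - D - 1)
  model_p <- NA_real_
  if (n_perm_model > 0L) {
    set.seed(derive_seed(seed, 17L))
    null_r2 <- vapply(seq_len(n_perm_model), function(b) {
      yb <- sample(target)
      rb <- ranger::ranger(x = features, y = yb, num.trees = trees,
                           mtry = mtry, seed = derive_seed(seed, b),
                           num.threads = 1)
      oob_r2(rb$predictions, yb)
    }, numeric(1))
    model_p <- (1 + sum(null_r2 >= r2)) / (1 + n_perm_model)
  }
  out <- list(r2 = r2, r2_adj = r2_adj, model_p = model_p, mtry = mtry,
              n = n, D = D, trees = trees, seed = seed, oob_pred = oob)
  if (!is.null(model)) {
    out$predicted_class <- map_slope_to_class(oob, model)
    if (!is.null(true_labels)) {
      out$confusion <- confusion_matrix(true_labels, out$predicted_class,
                                        k = model$k)
      out$per_class_accuracy <- per_class_accuracy(true_labels,
                                                   out$predicted_class)
    }
  }
  structure(out, class = "trc_prediction")
}

oob_r2 <- function(oob, target) {
  ok <- !is.na(oob)
  stats::cor(oob[ok], target[ok])^2
}

#' @export
print.trc_prediction <- function(x, ...) {
  cat(sprintf(
    "<trc_prediction> n = %d, D = %d, mtry = %d | R2 = %.4f, adj R2 = %.4f",
    x$n, x$D, x$mtry, x$r2, x$r2_adj))
  if (!is.na(x$model_p)) cat(sprintf(", model p = %.4g", x$model_p))
  cat("\n")
  invisible(x)
}

#' Altmann-style permutation importance
#'
#' The forest's within-tree permutation importance is recomputed on
#' `n_perm` target-permuted refits; each feature's p-value is
#' `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param features Numeric feature data.frame (no missing cells).
#' @param target Numeric per-patient target.
#' @param n_perm Number of target permutations (>= 1; 10000 in a full run).
#' @param seed Integer seed.
#' @param trees Trees per forest (default 2000).
#' @return data.frame with columns `feature`, `importance`, `permutation_p`.
#' @export
permutation_importance <- function(features, target, n_perm = 10000L,
                                   seed = 1L, trees = 2000L) {
  if (n_perm < 1L) stop("permutation_importance(): n_perm must be >= 1")
  mtry <- floor(sqrt(ncol(features)))
  rf <- ranger::ranger(x = features, y = target, num.trees = trees,
                       mtry = mtry, importance = "permutation",
                       seed = seed, num.threads = 1)
  obs <- rf$variable.importance
  set.seed(derive_seed(seed, 29L))
  exceed <- numeric(length(obs))
  for (b in seq_len(n_perm)) {
    yb <- sample(target)
    rb <- ranger::ranger(x = features, y = yb, num.trees = trees,
                         mtry = mtry, importance = "permutation",
                         seed = derive_seed(seed, 1000L + b),
                         num.threads = 1)
    exceed <- exceed + (rb$variable.importance >= obs)
  }
  data.frame(
    feature = names(obs),
    importance = unname(obs),
    permutation_p = unname((1 + exceed) / (1 + n_perm)),
    stringsAsFactors = FALSE
  )
}

#' One-vs-rest classification accuracy per class
#'
#' For each class the labels are binarized (class of interest vs all others)
#' and the accuracy `(TP + TN) / (TP + FP + TN + FN)` computed.
#'
#' @param true_labels,predicted_labels Equal-length class label vectors.
#' @return Named numeric vector of per-class accuracies.
#' @export
per_class_accuracy <- function(true_labels, predicted_labels) {
  if (length(true_labels) == 0L) stop("per_class_accuracy(): empty inputs")
  if (length(true_labels) != length(predicted_labels)) {
    stop("per_class_accuracy(): length mismatch")
  }
  classes <- sort(unique(c(true_labels, predicted_labels)))
  acc <- vapply(classes, function(cl) {
    mean((true_labels == cl) == (predicted_labels == cl))
  }, numeric(1))
  names(acc) <- paste0("C", classes)
  acc
}

#' Confusion matrix of true vs predicted classes
#'
#' @param true_labels,predicted_labels Integer class labels.
#' @param k Number of classes.
#' @return k-by-k integer matrix (rows = true, columns = predicted).
#' @export
confusion_matrix <- function(true_labels, predicted_labels, k) {
  m <- table(factor(true_labels, levels = seq_len(k)),
             factor(predicted_labels, levels = seq_len(k)))
  mat <- matrix(as.integer(m), k, k,
                dimnames = list(true = paste0("C", seq_len(k)),
                                predicted = paste0("C", seq_len(k))))
  mat
}

#' Compare two explained-variance estimates after Fisher-Z transformation
#'
#' The R2 values are converted to correlations `r = sqrt(R2)`;
#' `Z = (atanh(r_a) - atanh(r_b)) / sqrt(1/(n_a - 3) + 1/(n_b - 3))` with a
#' two-sided standard-normal p-value (the samples are treated as
#' independent).
#'
#' @param r2_a,r2_b R2 values in [0, 1).
#' @param n_a,n_b Sample sizes (> 3).
#' @return List with `z` and `p_value`.
#' @export
compare_r2 <- function(r2_a, r2_b, n_a, n_b) {
  if (n_a <= 3 || n_b <= 3) stop("compare_r2(): sample sizes must exceed 3")
  if (any(c(r2_a, r2_b) < 0) || any(c(r2_a, r2_b) >= 1)) {
    stop("compare_r2(): r2 values must lie in [0, 1)")
  }
  z <- (atanh(sqrt(r2_a)) - atanh(sqrt(r2_b))) /
    sqrt(1 / (n_a - 3) + 1 / (n_b - 3))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Map predicted slopes to the nearest component class
#'
#' Each predicted slope is assigned the class whose component slope is
#' nearest in absolute difference; ties go to the lower class index.
#'
#' @param predicted_slope Numeric slope(s).
#' @param model A sorted `trc_model`.
#' @return Integer class label(s).
#' @export
map_slope_to_class <- function(predicted_slope, model) {
  stopifnot(inherits(model, "trc_model"))
  slopes <- model$components$slope
  vapply(predicted_slope, function(s) which.min(abs(s - slopes)),
         integer(1))
}
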