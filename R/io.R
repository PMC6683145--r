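# Readers and writers for the pipeline's tabular formats and the mixture
# model JSON.  One CSV dialect throughout: comma-separated, UTF-8, "NA" as
# the sole missing marker, weeks 0-based with baseline = week 0.

MODEL_SCHEMA_VERSION <- "1.0"

#' Read a long-format ratings CSV into a cohort
#'
#' Expected columns: `patient_id`, `week` (integer >= 0, 0 = baseline),
#' `score` (integer HAM-D total or `NA`).  Malformed rows are reported with
#' their line numbers; duplicated (patient, week) pairs are a hard error.
#'
#' @param path CSV file path.
#' @param design `"MARS"` or `"GENDEP"`.
#' @return A `trc_cohort`.
#' @export
read_ratings <- function(path, design = "MARS") {
  if (!file.exists(path)) stop("read_ratings(): no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "numeric", "numeric"))
  need <- c("patient_id", "week", "score")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop("read_ratings(): header must be 'patient_id,week,score' (got '",
         paste(names(df), collapse = ","), "')")
  }
  if (nrow(df) == 0L) return(cohort(list(), design))
  rowno <- seq_len(nrow(df)) + 1L  # file line numbers, counting the header
  bad_week <- is.na(df$week) | df$week < 0 | df$week != floor(df$week)
  if (any(bad_week)) {
    stop("read_ratings(): invalid week on line(s) ",
         paste(utils::head(rowno[bad_week], 5), collapse = ", "))
  }
  bad_score <- !is.na(df$score) & (df$score < 0 | df$score != floor(df$score))
  if (any(bad_score)) {
    stop("read_ratings(): non-integer or negative score on line(s) ",
         paste(utils::head(rowno[bad_score], 5), collapse = ", "))
  }
  key <- paste(df$patient_id, df$week)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("read_ratings(): duplicated (patient_id, week) on line ", rowno[d],
         ": ", key[d])
  }
  wk_max <- design_max_week(design)
  if (any(df$week > wk_max)) {
    stop("read_ratings(): week beyond the ", design, " design end (",
         wk_max, ")")
  }
  series <- lapply(split(df, factor(df$patient_id,
                                    levels = unique(df$patient_id))),
                   function(g) {
                     g <- g[order(g$week), ]
                     rating_series(g$patient_id[1], g$week, g$score)
                   })
  cohort(unname(series), design)
}

#' Write a cohort as a long-format ratings CSV
#'
#' @param x A `trc_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(x, path) {
  df <- as.data.frame(x)
  out <- data.frame(patient_id = df$patient_id, week = df$week,
                    score = df$raw)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a clinical baseline table CSV
#'
#' Item types are re-attached from the item schema on read; unknown columns
#' are treated as numerical.
#'
#' @param path CSV path.
#' @param table A `trc_clinical`.
#' @return `read_clinical()`: a `trc_clinical`; `write_clinical()`: `path`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("read_clinical(): no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (names(df)[1] != "patient_id") {
    stop("read_clinical(): first column must be patient_id")
  }
  schema <- table1_schema()
  types <- stats::setNames(rep("N", ncol(df) - 1L), names(df)[-1])
  known <- intersect(names(types), schema$name)
  types[known] <- schema$type[match(known, schema$name)]
  attr(df, "item_types") <- types
  class(df) <- c("trc_clinical", "data.frame")
  df
}

#' @rdname read_clinical
#' @export
write_clinical <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE, na = "NA")
  invisible(path)
}

#' Serialize a fitted mixture model to JSON
#'
#' Floats are written with 17 significant digits, so a write/read round trip
#' reproduces every parameter bit-exactly.
#'
#' @param fit A `trc_fit` (model + diagnostics) or a bare `trc_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(fit, path) {
  if (inherits(fit, "trc_fit")) {
    model <- fit$model
    diag <- fit$diagnostics
    meta <- fit$meta
  } else if (inherits(fit, "trc_model")) {
    model <- fit
    diag <- NULL
    meta <- NULL
  } else {
    stop("write_model(): expected a trc_fit or trc_model")
  }
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    k = model$k,
    sorted = isTRUE(model$sorted),
    components = list(
      intercept = model$components$intercept,
      slope = model$components$slope,
      residual_sd = model$components$residual_sd,
      weight = model$components$weight
    ),
    diagnostics = if (is.null(diag)) NULL else {
      list(loglik = diag$loglik, n_params = diag$n_params, n = diag$n,
           bic = diag$bic, entropy = diag$entropy, icl = diag$icl,
           n_iter = diag$n_iter, converged = diag$converged,
           n_restarts_failed = diag$n_restarts_failed)
    },
    meta = meta
  )
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              null = "null", pretty = TRUE), path)
  invisible(path)
}

#' Read a mixture model JSON written by [write_model()]
#'
#' @param path JSON path.
#' @return A `trc_fit` when diagnostics were stored, else a `trc_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("read_model(): no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version) ||
      doc$schema_version != MODEL_SCHEMA_VERSION) {
    stop("read_model(): schema version mismatch (expected ",
         MODEL_SCHEMA_VERSION, ", got ",
         if (is.null(doc$schema_version)) "none" else doc$schema_version, ")")
  }
  k <- doc$k
  if (is.null(k) || k < 1L) stop("read_model(): invalid component count k")
  comp <- doc$components
  lens <- vapply(comp[c("intercept", "slope", "residual_sd", "weight")],
                 length, integer(1))
  if (any(lens != k)) {
    stop("read_model(): component arrays do not match k = ", k)
  }
  model <- mixture_model(comp$intercept, comp$slope, comp$residual_sd,
                         comp$weight)
  model$sorted <- isTRUE(doc$sorted)
  if (is.null(doc$diagnostics)) return(model)
  d <- doc$diagnostics
  diag <- structure(
    list(loglik = d$loglik, n_params = d$n_params, n = d$n, bic = d$bic,
         entropy = d$entropy, icl = d$icl, n_iter = d$n_iter,
         converged = d$converged, loglik_trace = NULL,
         n_restarts_failed = d$n_restarts_failed),
    class = "trc_diagnostics"
  )
  structure(list(model = model, assignment = NULL, diagnostics = diag,
                 meta = doc$meta),
            class = "trc_fit")
}

#' Write a projection report
#'
#' CSV with one row per patient (`patient_id`, `label`, `max_posterior`,
#' `cluster_slope`) plus a JSON diagnostics sidecar at `paste0(path,
#' ".json")`.
#'
#' @param proj A `trc_projection`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_projection <- function(proj, path) {
  a <- proj$assignment
  df <- data.frame(
    patient_id = a$patient_id,
    label = a$label,
    max_posterior = a$posteriors[cbind(seq_along(a$label), a$label)],
    cluster_slope = a$cluster_slope
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  diag <- list(loglik = proj$loglik, class_loglik = proj$class_loglik,
               entropy = proj$entropy, icl = proj$icl, n = proj$n,
               n_params = proj$n_params)
  writeLines(jsonlite::toJSON(diag, digits = I(17), auto_unbox = TRUE),
             paste0(path, ".json"))
  invisible(path)
}
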