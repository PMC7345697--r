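# Prediction for new compounds, the extrapolation and relative-error
# filters, and the evaluation statistics (best-fit line, r-squared, median
# error, tolerance bands, t-tests).

#' Predict retention times for new compounds
#'
#' Replays the trained pipeline on a compound table: descriptors are
#' computed from SMILES (or taken from user-supplied columns, which win on
#' name collisions), residual missing cells are imputed with the training
#' medians, features are standardized with the training statistics,
#' restricted to the model's selected descriptors and passed to the learner.
#'
#' Each prediction carries an `extrapolation` flag, set when the predicted
#' retention time falls outside the training set's observed range — a model
#' extrapolating beyond the retention times it saw is unreliable. (When
#' evaluating against measured values, use [exclude_extrapolated()], which
#' applies the observed-time rule instead.)
#'
#' Compounds whose SMILES cannot be parsed are reported in the `failures`
#' attribute and skipped, not fatal.
#'
#' @param object a `qsrr_model` (from [fit_final()] or a loaded bundle).
#' @param table a [compound_table()] of compounds to predict, or a
#'   precomputed descriptor matrix with named columns.
#' @param ... unused.
#' @return A data frame with columns `name`, `predicted_rt` (minutes) and
#'   `extrapolation` (logical); attribute `"failures"` lists per-compound
#'   descriptor errors.
#' @export
predict.qsrr_model <- function(object, table, ...) {
  if (inherits(table, "compound_table")) {
    desc <- compute_descriptors(table)
    x <- desc$values
    failures <- desc$failures
  } else {
    x <- as_descriptor_matrix(table)
    failures <- character(0)
  }
  missing_cols <- setdiff(object$selected_features, colnames(x))
  if (length(missing_cols)) {
    qsrr_abort(sprintf("input lacks descriptor(s) required by the model: %s",
                       paste(missing_cols, collapse = ", ")),
               "qsrr_contract_error")
  }
  pipe <- list(medians = object$imputation, scaler = object$scaler,
               search = list(learner_kind = object$learner_kind),
               fit = object$fit)
  pred <- predict_pipeline(pipe, x)
  out <- data.frame(
    name = if (is.null(rownames(x))) as.character(seq_along(pred)) else rownames(x),
    predicted_rt = pred,
    extrapolation = pred < object$train_rt_min | pred > object$train_rt_max,
    stringsAsFactors = FALSE
  )
  attr(out, "failures") <- failures
  out
}

#' Exclude test compounds outside the training retention-time range
#'
#' When scoring predictions against measured values, any test compound whose
#' observed retention time is later than the latest, or earlier than the
#' earliest, observed retention time in the training set is discarded:
#' extrapolation beyond the training range easily produces inaccurate
#' predictions. Boundary-equal values are kept.
#'
#' @param observed_rt numeric vector of observed retention times (minutes).
#' @param train_rt_min,train_rt_max training-set retention-time range, or a
#'   `qsrr_model` passed as `train_rt_min`.
#' @return A list with logical vector `keep`, and counts `n_kept`,
#'   `n_excluded` (`n_kept + n_excluded` equals the input length).
#' @export
exclude_extrapolated <- function(observed_rt, train_rt_min, train_rt_max = NULL) {
  if (inherits(train_rt_min, "qsrr_model")) {
    m <- train_rt_min
    train_rt_min <- m$train_rt_min
    train_rt_max <- m$train_rt_max
  }
  if (anyNA(observed_rt)) {
    qsrr_abort("all observed retention times must be present", "qsrr_validation_error")
  }
  keep <- observed_rt >= train_rt_min & observed_rt <= train_rt_max
  list(keep = keep, n_kept = sum(keep), n_excluded = sum(!keep))
}

#' Relative-error validity filter
#'
#' Drops any prediction whose relative error versus the observed retention
#' time is strictly greater than `max_pct` percent (default 35). A
#' prediction exactly at the boundary is kept.
#'
#' @param predicted,observed numeric vectors (minutes); `observed` must be
#'   positive.
#' @param max_pct maximum allowed percent error.
#' @return A list with logical `keep`, `pct_error` (signed percent errors)
#'   and counts `n_kept`, `n_dropped`.
#' @export
filter_relative_error <- function(predicted, observed, max_pct = 35) {
  if (length(predicted) != length(observed)) {
    qsrr_abort("predicted and observed must have equal length", "qsrr_validation_error")
  }
  bad <- which(is.na(observed) | observed <= 0)
  if (length(bad)) {
    qsrr_abort(sprintf("observed retention times must be > 0; offending entries: %s",
                       paste(bad, collapse = ", ")), "qsrr_validation_error")
  }
  pct <- 100 * (predicted - observed) / observed
  keep <- abs(pct) <= max_pct
  list(keep = keep, pct_error = pct, n_kept = sum(keep), n_dropped = sum(!keep))
}

#' Evaluation statistics for a set of predictions
#'
#' Computes the statistics used to judge a retention-time model: the
#' ordinary-least-squares best-fit line of predicted (ordinate) on measured
#' (abscissa) — an ideal model gives y = x — the squared Pearson correlation
#' r-squared, the median signed error and median signed percent error, and
#' the fraction of predictions within each tolerance band (default 1 and 2
#' minutes of the true value).
#'
#' @param predicted,observed numeric vectors (minutes), at least 3 pairs.
#' @param tolerances_min tolerance bands in minutes.
#' @param n_excluded optional count of compounds removed beforehand (e.g.,
#'   by [exclude_extrapolated()]), recorded in the report.
#' @return An `evaluation_report`: `slope`, `intercept`, `r_squared`,
#'   `median_error`, `median_pct_error`, `within` (named fractions),
#'   `n_used`, `n_excluded`.
#' @export
evaluate_predictions <- function(predicted, observed, tolerances_min = c(1, 2),
                                 n_excluded = 0L) {
  if (length(predicted) != length(observed)) {
    qsrr_abort("predicted and observed must have equal length", "qsrr_validation_error")
  }
  if (length(observed) < 3L) {
    qsrr_abort("evaluation needs at least 3 prediction/observation pairs",
               "qsrr_validation_error")
  }
  if (stats::sd(observed) == 0) {
    qsrr_abort("observed retention times have zero variance; fit undefined",
               "qsrr_degenerate_target_error")
  }
  fit <- stats::lm(predicted ~ observed)
  err <- predicted - observed
  within <- vapply(tolerances_min, function(tol) mean(abs(err) <= tol), 0)
  names(within) <- sprintf("within_%g_min", tolerances_min)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = suppressWarnings(stats::cor(predicted, observed))^2,
         median_error = stats::median(err),
         median_pct_error = stats::median(100 * err / observed),
         within = within,
         n_used = length(observed),
         n_excluded = as.integer(n_excluded)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d (%d excluded for extrapolation)\n",
              x$n_used, x$n_excluded))
  cat(sprintf("  best fit: y = %.4fx + %.4f, r2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  median error %.3f min | median %% error %.2f%%\n",
              x$median_error, x$median_pct_error))
  for (nm in names(x$within)) {
    cat(sprintf("  %s: %.1f%%\n", sub("_", " ", nm), 100 * x$within[[nm]]))
  }
  invisible(x)
}

#' Compare two prediction sets with a t-test
#'
#' Standard Student t-test on two vectors of predictions (or predictions
#' versus measured values): paired when every compound appears in both
#' vectors, unpaired otherwise. Two-sided p-value.
#'
#' @param a,b numeric vectors; equal length (>= 3) for the paired test,
#'   each of length >= 3 for the unpaired test.
#' @param paired use the paired test (default `TRUE`).
#' @return A list with `t`, `p_value` and `df`.
#' @export
paired_t_test <- function(a, b, paired = TRUE) {
  if (paired && length(a) != length(b)) {
    qsrr_abort("paired t-test requires equal-length vectors", "qsrr_validation_error")
  }
  if (length(a) < 3L || length(b) < 3L) {
    qsrr_abort("t-test requires at least 3 values per vector", "qsrr_validation_error")
  }
  if (paired && stats::sd(a - b) == 0) {
    if (all(a == b)) return(list(t = 0, p_value = 1, df = length(a) - 1L))
    qsrr_abort("paired differences have zero variance; t statistic undefined",
               "qsrr_degenerate_target_error")
  }
  ht <- stats::t.test(a, b, paired = paired, var.equal = FALSE)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Write predictions to CSV
#'
#' @param predictions data frame from [predict.qsrr_model()].
#' @param table the predicted `compound_table` (for the SMILES column).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, table, path) {
  smiles <- table$compounds$smiles[match(predictions$name, table$compounds$name)]
  out <- data.frame(name = predictions$name, smiles = smiles,
                    predicted_rt_minutes = predictions$predicted_rt,
                    extrapolation = predictions$extrapolation,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
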