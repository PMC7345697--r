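# The experimental protocol around the learner: randomized 75/25
# train/test splits, replicate models per split, extrapolation exclusion,
# evaluation, and feature-usage consistency across all models.

#' Split plan
#'
#' @param n_splits number of independent randomized train/test splits
#'   (default 5).
#' @param train_fraction fraction of compounds in the training set (default
#'   0.75; the first `ceiling(train_fraction * n)` compounds of each
#'   randomized order). Ignored when `train_n` is set.
#' @param train_n absolute training-set size (e.g., 60, 120, 180 for a
#'   training-set-size series); the remaining compounds all become test
#'   compounds, so smaller training sets yield more predictions.
#' @param replicates_per_split models fitted per split (default 3); they
#'   share the split's test set and differ only through seed-derived
#'   randomness.
#' @param base_seed integer; per-split and per-replicate seeds are derived
#'   as `base_seed + split * 1000 + replicate` for full reproducibility.
#' @return A list of class `split_plan`.
#' @export
split_plan <- function(n_splits = 5L, train_fraction = 0.75, train_n = NULL,
                       replicates_per_split = 3L, base_seed = 1L) {
  if (!is_count(n_splits) || n_splits < 1) {
    qsrr_abort("n_splits must be a positive integer", "qsrr_validation_error")
  }
  if (is.null(train_n)) {
    if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
      qsrr_abort("train_fraction must lie in (0, 1)", "qsrr_validation_error")
    }
  } else if (!is_count(train_n) || train_n < 1) {
    qsrr_abort("train_n must be a positive integer", "qsrr_validation_error")
  }
  if (!is_count(replicates_per_split) || replicates_per_split < 1) {
    qsrr_abort("replicates_per_split must be a positive integer", "qsrr_validation_error")
  }
  structure(list(n_splits = as.integer(n_splits),
                 train_fraction = train_fraction,
                 train_n = if (is.null(train_n)) NULL else as.integer(train_n),
                 replicates_per_split = as.integer(replicates_per_split),
                 base_seed = as.integer(base_seed)),
            class = "split_plan")
}

#' Build the randomized train/test splits
#'
#' Each split shuffles the rows with its own derived seed and assigns the
#' first `ceiling(train_fraction * n)` rows (or exactly `train_n` rows) to
#' the training set and the remainder to the test set. Splits are
#' independent shuffles; within a split, train and test partition the data.
#'
#' @param n number of compounds, or a `compound_table`.
#' @param plan a [split_plan()].
#' @return A list of length `n_splits`; each element has integer index
#'   vectors `train` and `test`.
#' @export
make_splits <- function(n, plan = split_plan()) {
  if (inherits(n, "compound_table")) {
    if (anyNA(n$compounds$rt)) {
      qsrr_abort("all compounds need a retention time to build splits",
                 "qsrr_validation_error")
    }
    n <- nrow(n$compounds)
  }
  n_train <- if (is.null(plan$train_n)) ceiling(plan$train_fraction * n) else plan$train_n
  if (n_train < 1 || n_train >= n) {
    qsrr_abort(sprintf("split leaves an empty train or test set (n = %d, train = %d)",
                       n, n_train), "qsrr_validation_error")
  }
  lapply(seq_len(plan$n_splits), function(s) {
    perm <- with_seed(derive_seed(plan$base_seed, s), sample.int(n))
    list(train = perm[seq_len(n_train)], test = perm[-seq_len(n_train)])
  })
}

#' Run the full split/replicate study protocol
#'
#' For every split and replicate: randomize the training rows (replicate
#' seed), fit the full pipeline on the training set, discard test compounds
#' whose observed retention time lies outside the training range, predict
#' the remaining test compounds and evaluate. Feature usage is aggregated
#' across all `n_splits * replicates_per_split` models: a descriptor used
#' by most or all models is likely critical to retention on that column,
#' while one appearing in one or two models is a quirk of the random splits.
#'
#' @param x filtered descriptor matrix for all compounds (filters are
#'   re-applied per training set to avoid leakage; pass the raw computed
#'   matrix).
#' @param y retention times (minutes) for all compounds.
#' @param plan a [split_plan()].
#' @param config a [search_config()]; its seed is replaced by the derived
#'   per-replicate seed.
#' @param filter_cfg a [filter_config()] applied to each training set.
#' @return A `protocol_result`: `models` (data frame with one row per
#'   split x replicate: learner, n_features, test MAE, r-squared, median
#'   error, n kept/excluded), `reports` (list of `evaluation_report`),
#'   `feature_usage` (named integer vector: models containing each
#'   descriptor), `errors` (per-model prediction error vectors, minutes),
#'   `n_models`.
#' @export
run_protocol <- function(x, y, plan = split_plan(), config = search_config(),
                         filter_cfg = filter_config()) {
  x <- as_descriptor_matrix(x)
  if (length(y) != nrow(x)) qsrr_abort("y must match rows of x", "qsrr_validation_error")
  splits <- make_splits(nrow(x), plan)

  rows <- list()
  reports <- list()
  errors <- list()
  usage <- integer(0)
  failed <- character(0)
  for (s in seq_along(splits)) {
    tr_idx <- splits[[s]]$train
    te_idx <- splits[[s]]$test
    for (r in seq_len(plan$replicates_per_split)) {
      tag <- sprintf("split%d_rep%d", s, r)
      res <- tryCatch({
        seed_sr <- derive_seed(plan$base_seed, s, r)
        cfg <- config
        cfg$seed <- seed_sr
        x_tr <- x[tr_idx, , drop = FALSE]
        y_tr <- y[tr_idx]
        filt <- apply_filters(x_tr, filter_cfg)
        ord <- with_seed(seed_sr, sample.int(length(tr_idx)))
        model <- fit_final(filt$values[ord, , drop = FALSE], y_tr[ord], cfg)

        excl <- exclude_extrapolated(y[te_idx], model)
        kept <- te_idx[excl$keep]
        pred <- stats::predict(model, x[kept, colnames(filt$values), drop = FALSE])
        rep_eval <- evaluate_predictions(pred$predicted_rt, y[kept],
                                         n_excluded = excl$n_excluded)
        list(model = model, eval = rep_eval,
             err = pred$predicted_rt - y[kept])
      }, qsrr_error = function(e) e)
      if (inherits(res, "qsrr_error")) {
        failed <- c(failed, stats::setNames(conditionMessage(res), tag))
        next
      }
      for (f in res$model$selected_features) {
        usage[f] <- (if (is.na(usage[f])) 0L else usage[f]) + 1L
      }
      rows[[tag]] <- data.frame(
        split = s, replicate = r, learner = res$model$learner_kind,
        n_features = length(res$model$selected_features),
        test_mae = mean(abs(res$err)), r_squared = res$eval$r_squared,
        median_error = res$eval$median_error,
        n_used = res$eval$n_used, n_excluded = res$eval$n_excluded,
        stringsAsFactors = FALSE
      )
      reports[[tag]] <- res$eval
      errors[[tag]] <- res$err
    }
  }
  structure(
    list(models = do.call(rbind, rows), reports = reports,
         feature_usage = usage[order(-usage, names(usage))],
         errors = errors, failed = failed,
         n_models = length(reports)),
    class = "protocol_result"
  )
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %d models (%d failed)\n",
              x$n_models, length(x$failed)))
  if (!is.null(x$models)) {
    cat(sprintf("  mean test MAE %.3f min | mean r2 %.3f\n",
                mean(x$models$test_mae), mean(x$models$r_squared)))
    core <- sum(x$feature_usage == x$n_models)
    cat(sprintf("  %d descriptors used by every model; %d used by any\n",
                core, length(x$feature_usage)))
  }
  invisible(x)
}

#' Export protocol results as CSV
#'
#' @param result a `protocol_result`.
#' @param models_path,usage_path output CSV paths (either may be `NULL`).
#' @return invisibly, `NULL`.
#' @export
export_protocol <- function(result, models_path = NULL, usage_path = NULL) {
  if (!is.null(models_path)) {
    utils::write.csv(result$models, models_path, row.names = FALSE)
  }
  if (!is.null(usage_path)) {
    utils::write.csv(data.frame(descriptor = names(result$feature_usage),
                                n_models = as.integer(result$feature_usage)),
                     usage_path, row.names = FALSE)
  }
  invisible(NULL)
}
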