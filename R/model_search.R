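# The automated learner: data-order randomization, standardization,
# recursive feature elimination with a random-forest regressor (RFECV),
# nested cross-validated model/hyperparameter selection, outer-CV reporting
# and the final fit on all data.
#
# Candidate learners mirror published QSRR practice: multiple linear
# regression, random forest (500 trees) and RBF-kernel support vector
# regression with C and gamma tuned over [0.001, 1000].

#' Search configuration
#'
#' @param method which learner to fit: `"auto"` tries linear, random forest
#'   and SVR and keeps the best by inner-CV score; a specific value
#'   restricts the search to that learner (SVR is still grid-searched).
#' @param outer_folds folds of the outer cross-validation (default 5).
#' @param inner_folds folds of the inner cross-validations used for feature
#'   selection and the hyperparameter grid search (default 5).
#' @param rf_trees trees per random forest, both for feature-selection
#'   importance and the candidate learner (default 500).
#' @param svr_c_bounds,svr_gamma_bounds closed intervals searched for the
#'   SVR penalty C and RBF width gamma (default `c(0.001, 1000)`), covered
#'   by a 7-point log-spaced grid each.
#' @param forced_n_features when set, recursive elimination runs to exactly
#'   this many features instead of letting the inner CV choose the count.
#' @param seed integer seed; together with the data and configuration it
#'   fully determines the fitted model.
#' @return A list of class `search_config`.
#' @export
search_config <- function(method = c("auto", "linear", "random_forest", "svr"),
                          outer_folds = 5L, inner_folds = 5L, rf_trees = 500L,
                          svr_c_bounds = c(0.001, 1000),
                          svr_gamma_bounds = c(0.001, 1000),
                          forced_n_features = NULL, seed = 1L) {
  method <- match.arg(method)
  if (!is_count(outer_folds) || outer_folds < 2) {
    qsrr_abort("outer_folds must be an integer >= 2", "qsrr_validation_error")
  }
  if (!is_count(inner_folds) || inner_folds < 2) {
    qsrr_abort("inner_folds must be an integer >= 2", "qsrr_validation_error")
  }
  if (!is_count(rf_trees) || rf_trees < 1) {
    qsrr_abort("rf_trees must be a positive integer", "qsrr_validation_error")
  }
  for (b in list(svr_c_bounds, svr_gamma_bounds)) {
    if (length(b) != 2L || any(b <= 0) || b[1] > b[2]) {
      qsrr_abort("SVR bounds must be positive with low <= high", "qsrr_validation_error")
    }
  }
  if (!is.null(forced_n_features) &&
      (!is_count(forced_n_features) || forced_n_features < 1)) {
    qsrr_abort("forced_n_features must be a positive integer", "qsrr_validation_error")
  }
  structure(list(method = method,
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 rf_trees = as.integer(rf_trees),
                 svr_c_bounds = as.numeric(svr_c_bounds),
                 svr_gamma_bounds = as.numeric(svr_gamma_bounds),
                 forced_n_features = if (is.null(forced_n_features)) NULL else
                   as.integer(forced_n_features),
                 seed = as.integer(seed)),
            class = "search_config")
}

MIN_TRAIN_ROWS <- 10L

#' Randomize compound order
#'
#' Applies a seeded permutation to the rows of a compound table or matrix.
#' The same seed always produces the same permutation.
#'
#' @param x a `compound_table`, matrix or data frame.
#' @param seed integer seed.
#' @return `x` with rows permuted.
#' @export
randomize_order <- function(x, seed) {
  n <- if (inherits(x, "compound_table")) nrow(x$compounds) else nrow(x)
  perm <- with_seed(seed, sample.int(n))
  if (inherits(x, "compound_table")) x[perm] else x[perm, , drop = FALSE]
}

## ---- internal: scaling ----------------------------------------------------

fit_scaler <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  keep <- s > 0
  list(mean = m[keep], sd = s[keep], dropped_constant = colnames(x)[!keep])
}

apply_scaler <- function(scaler, x) {
  x <- x[, names(scaler$mean), drop = FALSE]
  sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

## ---- internal: learners ---------------------------------------------------

fit_learner <- function(kind, x, y, hyper, cfg) {
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(x)))  # syntactically safe names
  df$.y <- y
  switch(kind,
    linear = stats::lm(.y ~ ., data = df),
    random_forest = ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = cfg$rf_trees, seed = cfg$seed, num.threads = 1L
    ),
    svr = e1071::svm(.y ~ ., data = df, type = "eps-regression",
                     kernel = "radial", cost = hyper$C, gamma = hyper$gamma,
                     scale = FALSE),
    qsrr_abort(sprintf("unknown learner '%s'", kind), "qsrr_internal_error")
  )
}

predict_learner <- function(kind, fit, x) {
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(x)))
  if (kind == "random_forest") {
    as.numeric(stats::predict(fit, data = df, num.threads = 1L)$predictions)
  } else {
    # rank-deficient linear fits (p ~ n) warn but still predict
    as.numeric(suppressWarnings(stats::predict(fit, newdata = df)))
  }
}

# coefficient of determination on held-out data (can be negative)
score_r2 <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / ss_tot
}

# contiguous fold assignment over an already randomized row order
fold_ids <- function(n, k) {
  if (n < k) qsrr_abort("fewer rows than folds", "qsrr_validation_error")
  sort(rep_len(seq_len(k), n))
}

cv_score <- function(kind, hyper, x, y, folds, cfg) {
  k <- max(folds)
  r2 <- mae <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_learner(kind, x[tr, , drop = FALSE], y[tr], hyper, cfg)
    pred <- predict_learner(kind, fit, x[!tr, , drop = FALSE])
    r2[f] <- score_r2(y[!tr], pred)
    mae[f] <- mean(abs(pred - y[!tr]))
  }
  c(r2 = mean(r2), mae = mean(mae))
}

## ---- feature selection (RFECV) -------------------------------------------

# elimination schedule: drop 10% of the remaining features (at least one)
# per round, down to a single feature
rfe_schedule <- function(p, stop_at = 1L) {
  sizes <- p
  while (p > stop_at) {
    p <- max(stop_at, p - max(1L, floor(0.1 * p)))
    sizes <- c(sizes, p)
  }
  sizes
}

# one RFE pass: returns the kept feature names at each schedule size and,
# when scoring rows are given, the held-out MAE of the RF fitted at each
# size. A single forest per step serves both the importance ranking and the
# held-out score.
rfe_path <- function(x, y, sizes, cfg, x_test = NULL, y_test = NULL) {
  current <- colnames(x)
  kept_at <- vector("list", length(sizes))
  mae_at <- rep(NA_real_, length(sizes))
  i <- 1L
  repeat {
    df <- as.data.frame(x[, current, drop = FALSE])
    names(df) <- current
    df$.y <- y
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = cfg$rf_trees, importance = "impurity",
                          seed = cfg$seed, num.threads = 1L)
    at_size <- length(current) == sizes[i]
    if (at_size) {
      kept_at[[i]] <- current
      if (!is.null(x_test)) {
        dft <- as.data.frame(x_test[, current, drop = FALSE])
        names(dft) <- current
        pred <- stats::predict(fit, data = dft, num.threads = 1L)$predictions
        mae_at[i] <- mean(abs(pred - y_test))
      }
      if (i == length(sizes)) break
      i <- i + 1L
    }
    # drop the least-important features toward the next target size
    n_drop <- min(length(current) - sizes[i],
                  max(1L, floor(0.1 * length(current))))
    imp <- fit$variable.importance[current]  # keep canonical order for ties
    ranked <- current[order(-imp)]           # stable: ties keep earlier column
    current <- current[current %in% ranked[seq_len(length(current) - n_drop)]]
  }
  list(kept = kept_at, mae = mae_at)
}

#' Select descriptors by recursive feature elimination
#'
#' Recursive feature elimination driven by random-forest impurity importance
#' (`rf_trees` trees): each round drops the least-important 10% of the
#' remaining descriptors. The subset size is chosen by an `inner_folds`-fold
#' cross-validation minimizing held-out mean absolute error (ties favour the
#' smaller subset); with `forced_n_features` set, elimination instead runs
#' to exactly that count on the full data.
#'
#' @param x fully imputed, filtered numeric descriptor matrix (>= 10 rows).
#' @param y retention times (minutes), one per row of `x`.
#' @param config a [search_config()].
#' @return Character vector of selected descriptor names (non-empty).
#' @export
select_features <- function(x, y, config = search_config()) {
  x <- as_descriptor_matrix(x)
  if (anyNA(x)) qsrr_abort("descriptor matrix must be imputed first", "qsrr_contract_error")
  if (nrow(x) < MIN_TRAIN_ROWS) {
    qsrr_abort(sprintf("feature selection needs at least %d rows, got %d",
                       MIN_TRAIN_ROWS, nrow(x)), "qsrr_insufficient_data_error")
  }
  if (length(y) != nrow(x)) qsrr_abort("y must match rows of x", "qsrr_validation_error")
  p <- ncol(x)
  if (p == 1L) return(colnames(x))

  if (!is.null(config$forced_n_features)) {
    target <- min(config$forced_n_features, p)
    path <- rfe_path(x, y, sizes = target, cfg = config)
    return(path$kept[[1]])
  }

  sizes <- rfe_schedule(p)
  folds <- fold_ids(nrow(x), config$inner_folds)
  mae_mat <- matrix(NA_real_, nrow = length(sizes), ncol = config$inner_folds)
  for (f in seq_len(config$inner_folds)) {
    tr <- folds != f
    path <- rfe_path(x[tr, , drop = FALSE], y[tr], sizes, config,
                     x_test = x[!tr, , drop = FALSE], y_test = y[!tr])
    mae_mat[, f] <- path$mae
  }
  mean_mae <- rowMeans(mae_mat)
  # ties favour the smaller subset (later schedule entry)
  best <- length(sizes) + 1L - which.min(rev(mean_mae))
  final <- rfe_path(x, y, sizes = sizes[best], cfg = config)
  final$kept[[1]]
}

## ---- model / hyperparameter search ---------------------------------------

log_grid <- function(bounds, n = 7L) {
  exp(seq(log(bounds[1]), log(bounds[2]), length.out = n))
}

SIMPLICITY_ORDER <- c(linear = 1L, svr = 2L, random_forest = 3L)

#' Choose the learner and hyperparameters by inner cross-validation
#'
#' With `method = "auto"` the candidates are: linear regression (no
#' hyperparameters), random forest (`rf_trees` trees) and RBF-kernel SVR
#' over a 7 x 7 log-spaced grid of C and gamma spanning the configured
#' bounds. Every candidate is scored by `inner_folds`-fold cross-validation;
#' the winner has the best mean held-out r-squared, with ties broken by
#' lower mean held-out MAE and then by simplicity
#' (linear < svr < random forest). A fixed `method` restricts the candidate
#' set (SVR is still grid-searched).
#'
#' @param x scaled, imputed, feature-selected matrix (selection must have
#'   happened within the calling fold only — no leakage).
#' @param y retention times.
#' @param config a [search_config()].
#' @return A list: `learner_kind`, `hyperparameters` (list, possibly empty),
#'   `score` (named vector `r2`, `mae` of the winner), `candidates` (data
#'   frame of every candidate's mean inner-CV scores).
#' @export
search_model <- function(x, y, config = search_config()) {
  x <- as_descriptor_matrix(x)
  if (stats::sd(y) == 0) {
    qsrr_abort("retention times are constant; nothing to model", "qsrr_degenerate_target_error")
  }
  folds <- fold_ids(nrow(x), config$inner_folds)

  cand <- list()
  if (config$method %in% c("auto", "linear")) {
    cand[[length(cand) + 1L]] <- list(kind = "linear", hyper = list())
  }
  if (config$method %in% c("auto", "svr")) {
    for (C in log_grid(config$svr_c_bounds)) {
      for (g in log_grid(config$svr_gamma_bounds)) {
        cand[[length(cand) + 1L]] <- list(kind = "svr", hyper = list(C = C, gamma = g))
      }
    }
  }
  if (config$method %in% c("auto", "random_forest")) {
    cand[[length(cand) + 1L]] <- list(kind = "random_forest", hyper = list())
  }

  scores <- t(vapply(cand, function(cn) cv_score(cn$kind, cn$hyper, x, y, folds, config),
                     c(r2 = 0, mae = 0)))
  tab <- data.frame(
    kind = vapply(cand, `[[`, "", "kind"),
    C = vapply(cand, function(cn) cn$hyper$C %||% NA_real_, 0),
    gamma = vapply(cand, function(cn) cn$hyper$gamma %||% NA_real_, 0),
    r2 = scores[, "r2"], mae = scores[, "mae"]
  )
  ord <- order(-tab$r2, tab$mae, SIMPLICITY_ORDER[tab$kind])
  best <- ord[1]
  list(learner_kind = tab$kind[best],
       hyperparameters = cand[[best]]$hyper,
       score = c(r2 = tab$r2[best], mae = tab$mae[best]),
       candidates = tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- pipeline: impute -> scale -> select -> search -> fit -----------------

fit_pipeline <- function(x, y, config) {
  medians <- fit_imputer(x)
  x_imp <- apply_imputer(medians, x)
  scaler <- fit_scaler(x_imp)
  x_sc <- apply_scaler(scaler, x_imp)
  selected <- select_features(x_sc, y, config)
  x_sel <- x_sc[, selected, drop = FALSE]
  search <- search_model(x_sel, y, config)
  fit <- fit_learner(search$learner_kind, x_sel, y, search$hyperparameters, config)
  list(
    medians = medians[selected],
    scaler = list(mean = scaler$mean[selected], sd = scaler$sd[selected]),
    selected = selected,
    search = search,
    fit = fit
  )
}

predict_pipeline <- function(pipe, x) {
  x <- apply_imputer(pipe$medians, x)
  x <- sweep(sweep(x, 2, pipe$scaler$mean, "-"), 2, pipe$scaler$sd, "/")
  predict_learner(pipe$search$learner_kind, pipe$fit, x)
}

#' Outer cross-validation of the full pipeline
#'
#' Splits the rows into `outer_folds` contiguous blocks (the caller is
#' expected to have randomized the row order with [randomize_order()]) and,
#' for each fold, fits the entire pipeline — imputation, standardization,
#' RFECV feature selection, model/hyperparameter search, learner fit — on
#' the training block only, then scores the held-out block. This estimates
#' how well a final model built by the same recipe will predict new
#' compounds.
#'
#' @param x filtered descriptor matrix (may contain missing cells).
#' @param y retention times (minutes).
#' @param config a [search_config()].
#' @return A `cv_report`: data frame `folds` (per-fold r2, mae, learner,
#'   n_features) plus aggregate fields `mean_r2`, `median_r2`, `mean_mae`,
#'   `sd_mae`.
#' @export
outer_cv <- function(x, y, config = search_config()) {
  x <- as_descriptor_matrix(x)
  if (length(y) != nrow(x)) qsrr_abort("y must match rows of x", "qsrr_validation_error")
  folds <- fold_ids(nrow(x), config$outer_folds)
  per <- data.frame(fold = seq_len(config$outer_folds), r2 = NA_real_,
                    mae = NA_real_, learner = NA_character_, n_features = NA_integer_)
  for (f in seq_len(config$outer_folds)) {
    tr <- folds != f
    pipe <- fit_pipeline(x[tr, , drop = FALSE], y[tr], config)
    pred <- predict_pipeline(pipe, x[!tr, , drop = FALSE])
    per$r2[f] <- score_r2(y[!tr], pred)
    per$mae[f] <- mean(abs(pred - y[!tr]))
    per$learner[f] <- pipe$search$learner_kind
    per$n_features[f] <- length(pipe$selected)
  }
  structure(
    list(folds = per,
         mean_r2 = mean(per$r2), median_r2 = stats::median(per$r2),
         mean_mae = mean(per$mae), sd_mae = stats::sd(per$mae)),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> outer cross-validation\n")
  print(x$folds, row.names = FALSE)
  cat(sprintf("  mean r2 %.4f | median r2 %.4f | mean MAE %.3f min (sd %.3f)\n",
              x$mean_r2, x$median_r2, x$mean_mae, x$sd_mae))
  invisible(x)
}

#' Fit the final model on all data
#'
#' Refits the full pipeline on every row (the inner cross-validations for
#' feature selection and model search still run) and packages everything
#' needed for standalone prediction: imputation medians, scaler statistics,
#' selected descriptor names, the fitted learner with its hyperparameters,
#' and the training retention-time range used for extrapolation flagging.
#'
#' @inheritParams outer_cv
#' @param cv_report optionally, a `cv_report` from [outer_cv()] to embed.
#' @return A `qsrr_model`.
#' @export
fit_final <- function(x, y, config = search_config(), cv_report = NULL) {
  x <- as_descriptor_matrix(x)
  if (length(y) != nrow(x)) qsrr_abort("y must match rows of x", "qsrr_validation_error")
  if (nrow(x) < MIN_TRAIN_ROWS) {
    qsrr_abort(sprintf("training needs at least %d rows, got %d",
                       MIN_TRAIN_ROWS, nrow(x)), "qsrr_insufficient_data_error")
  }
  pipe <- fit_pipeline(x, y, config)
  structure(
    list(learner_kind = pipe$search$learner_kind,
         hyperparameters = pipe$search$hyperparameters,
         fit = pipe$fit,
         scaler = pipe$scaler,
         imputation = pipe$medians,
         selected_features = pipe$selected,
         search_score = pipe$search$score,
         train_rt_min = min(y), train_rt_max = max(y),
         n_train = nrow(x),
         seed = config$seed,
         config = config,
         cv_report = cv_report),
    class = "qsrr_model"
  )
}

#' @export
print.qsrr_model <- function(x, ...) {
  cat(sprintf("<qsrr_model> %s, %d selected descriptors, trained on %d compounds\n",
              x$learner_kind, length(x$selected_features), x$n_train))
  if (length(x$hyperparameters)) {
    cat(sprintf("  hyperparameters: %s\n",
                paste(sprintf("%s = %.4g", names(x$hyperparameters),
                              unlist(x$hyperparameters)), collapse = ", ")))
  }
  cat(sprintf("  training RT range: [%.3f, %.3f] min\n", x$train_rt_min, x$train_rt_max))
  invisible(x)
}
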