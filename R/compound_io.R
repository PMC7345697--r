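#' Compound tables
#'
#' A compound table holds one row per compound: a unique `name`, a SMILES
#' structure string and, for training data, a measured retention time in
#' minutes. Any further numeric columns in the input file are carried along
#' as user-supplied descriptors and take precedence over computed descriptors
#' of the same name.
#'
#' @param name character vector of unique compound identifiers.
#' @param smiles character vector of SMILES strings.
#' @param rt numeric vector of retention times in minutes, or `NULL` for
#'   prediction inputs. When present, values must be finite and positive.
#' @param extra_descriptors optional data frame (one row per compound, in the
#'   same order) of user-supplied numeric descriptors.
#' @return An object of class `compound_table`: a list with elements
#'   `compounds` (data frame with columns `name`, `smiles`, `rt`) and
#'   `extra_descriptors` (data frame or `NULL`).
#' @export
compound_table <- function(name, smiles, rt = NULL, extra_descriptors = NULL) {
  name <- as.character(name)
  smiles <- as.character(smiles)
  if (length(name) != length(smiles)) {
    qsrr_abort("name and smiles must have equal length", "qsrr_validation_error")
  }
  if (any(!nzchar(trimws(name))) || anyNA(name)) {
    qsrr_abort("compound names must be non-empty", "qsrr_validation_error")
  }
  if (anyDuplicated(name)) {
    dups <- unique(name[duplicated(name)])
    qsrr_abort(
      sprintf("duplicate compound name(s): %s", paste(dups, collapse = ", ")),
      "qsrr_validation_error"
    )
  }
  if (!is.null(rt)) {
    rt <- as.numeric(rt)
    if (length(rt) != length(name)) {
      qsrr_abort("rt must match the number of compounds", "qsrr_validation_error")
    }
    bad <- which(!is.na(rt) & (!is.finite(rt) | rt <= 0))
    if (length(bad)) {
      qsrr_abort(
        sprintf("retention times must be finite and > 0 minutes; offending rows: %s",
                paste(bad, collapse = ", ")),
        "qsrr_validation_error"
      )
    }
  } else {
    rt <- rep(NA_real_, length(name))
  }
  if (!is.null(extra_descriptors)) {
    extra_descriptors <- as.data.frame(extra_descriptors)
    if (nrow(extra_descriptors) != length(name)) {
      qsrr_abort("extra_descriptors must have one row per compound", "qsrr_validation_error")
    }
    rownames(extra_descriptors) <- name
  }
  structure(
    list(
      compounds = data.frame(name = name, smiles = smiles, rt = rt,
                             stringsAsFactors = FALSE),
      extra_descriptors = extra_descriptors
    ),
    class = "compound_table"
  )
}

#' @export
print.compound_table <- function(x, ...) {
  n <- nrow(x$compounds)
  n_rt <- sum(!is.na(x$compounds$rt))
  cat(sprintf("<compound_table> %d compounds (%d with retention times)\n", n, n_rt))
  if (!is.null(x$extra_descriptors)) {
    cat(sprintf("  user descriptors: %s\n",
                paste(names(x$extra_descriptors), collapse = ", ")))
  }
  invisible(x)
}

#' Subset a compound table by row index
#'
#' @param x a `compound_table`.
#' @param i integer or logical row index.
#' @param ... unused.
#' @return A `compound_table` with the selected compounds (and the matching
#'   rows of `extra_descriptors`, when present).
#' @export
`[.compound_table` <- function(x, i, ...) {
  compound_table(
    name = x$compounds$name[i],
    smiles = x$compounds$smiles[i],
    rt = if (all(is.na(x$compounds$rt))) NULL else x$compounds$rt[i],
    extra_descriptors = if (is.null(x$extra_descriptors)) NULL else
      x$extra_descriptors[i, , drop = FALSE]
  )
}

TEMPLATE_NAME_COL <- "name"
TEMPLATE_SMILES_COL <- "smiles"
TEMPLATE_RT_COL <- "rt_minutes"

#' Write an empty input template
#'
#' Writes a CSV with the expected header (`name`, `smiles` and, for training
#' input, `rt_minutes`) and no data rows, to make the input file easier to
#' create.
#'
#' @param path output file path.
#' @param include_rt include the retention-time column (use `FALSE` for a
#'   prediction-input template).
#' @return `path`, invisibly.
#' @export
write_template <- function(path, include_rt = TRUE) {
  cols <- c(TEMPLATE_NAME_COL, TEMPLATE_SMILES_COL,
            if (include_rt) TEMPLATE_RT_COL)
  ok <- tryCatch({
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste(cols, collapse = ","), con)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    qsrr_abort(sprintf("cannot write template to '%s'", path), "qsrr_io_error")
  }
  invisible(path)
}

normalize_header <- function(x) tolower(trimws(x))

#' Read a compound table from CSV
#'
#' The file must carry the template header (`name`, `smiles`, optionally
#' `rt_minutes`; header names are matched case-insensitively after whitespace
#' stripping). Columns beyond the template columns are captured as
#' user-supplied descriptors; non-numeric extra columns are dropped with a
#' note in the parse report.
#'
#' @param path CSV file path.
#' @param require_rt require a retention time for every row (training input).
#' @return A `compound_table`. The parse report (rows read / rejected and
#'   why) is attached as attribute `"parse_report"`.
#' @export
read_table <- function(path, require_rt = TRUE) {
  if (!file.exists(path)) {
    qsrr_abort(sprintf("file not found: '%s'", path), "qsrr_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  hdr <- normalize_header(names(raw))
  i_name <- match(TEMPLATE_NAME_COL, hdr)
  i_smiles <- match(TEMPLATE_SMILES_COL, hdr)
  i_rt <- match(TEMPLATE_RT_COL, hdr)
  if (is.na(i_name) || is.na(i_smiles)) {
    qsrr_abort(
      sprintf("missing mandatory column(s): %s",
              paste(c("name", "smiles")[c(is.na(i_name), is.na(i_smiles))],
                    collapse = ", ")),
      "qsrr_format_error"
    )
  }
  if (require_rt && is.na(i_rt)) {
    qsrr_abort(sprintf("missing mandatory column: %s", TEMPLATE_RT_COL),
               "qsrr_format_error")
  }

  name <- as.character(raw[[i_name]])
  smiles <- as.character(raw[[i_smiles]])
  if (anyDuplicated(name)) {
    dups <- unique(name[duplicated(name)])
    qsrr_abort(sprintf("duplicate compound name(s): %s", paste(dups, collapse = ", ")),
               "qsrr_validation_error")
  }

  rt <- NULL
  if (!is.na(i_rt)) {
    rt_raw <- raw[[i_rt]]
    rt <- suppressWarnings(as.numeric(rt_raw))
    if (require_rt) {
      bad <- which(is.na(rt) | !is.finite(rt) | rt <= 0)
      if (length(bad)) {
        qsrr_abort(
          sprintf("missing or invalid retention time in row(s): %s",
                  paste(bad, collapse = ", ")),
          "qsrr_validation_error"
        )
      }
    }
  }

  extra_idx <- setdiff(seq_along(raw), c(i_name, i_smiles, i_rt[!is.na(i_rt)]))
  extra <- NULL
  dropped_cols <- character(0)
  if (length(extra_idx)) {
    extra <- raw[extra_idx]
    numeric_ok <- vapply(extra, is.numeric, logical(1))
    dropped_cols <- names(extra)[!numeric_ok]
    extra <- extra[numeric_ok]
    if (!ncol(extra)) extra <- NULL
  }

  tbl <- compound_table(name, smiles, rt, extra)
  attr(tbl, "parse_report") <- list(
    rows_read = nrow(raw),
    rows_rejected = 0L,
    rejected_reasons = character(0),
    non_numeric_columns_dropped = dropped_cols
  )
  tbl
}

#' Write a compound table to CSV
#'
#' Inverse of [read_table()]: records (and user descriptors, when present)
#' round-trip exactly.
#'
#' @param table a `compound_table`.
#' @param path output CSV path.
#' @param include_rt write the retention-time column.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, include_rt = any(!is.na(table$compounds$rt))) {
  stopifnot(inherits(table, "compound_table"))
  out <- data.frame(name = table$compounds$name, smiles = table$compounds$smiles,
                    stringsAsFactors = FALSE)
  if (include_rt) out[[TEMPLATE_RT_COL]] <- table$compounds$rt
  if (!is.null(table$extra_descriptors)) out <- cbind(out, table$extra_descriptors)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) qsrr_abort(sprintf("cannot write table to '%s'", path), "qsrr_io_error")
  invisible(path)
}

BUNDLE_FORMAT_VERSION <- 1L

#' Persist and reload trained models
#'
#' A model bundle is a self-describing archive holding the trained model with
#' its full preprocessing state (imputation medians, scaler statistics,
#' selected descriptors, training retention-time range), a format version and
#' creation metadata, so that prediction is reproducible without the training
#' data. Saving then loading a bundle yields bit-identical predictions.
#'
#' @param model a `qsrr_model` from [fit_final()].
#' @param path file path for the bundle.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the bundle, a list with elements `model`, `format_version`, `created`,
#'   `seed` and `config`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "qsrr_model"))
  bundle <- list(
    model = model,
    format_version = BUNDLE_FORMAT_VERSION,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = model$seed,
    config = model$config,
    package_version = as.character(utils::packageVersion("qsrrflow"))
  )
  ok <- tryCatch({ saveRDS(bundle, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) qsrr_abort(sprintf("cannot write model bundle to '%s'", path), "qsrr_io_error")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    qsrr_abort(sprintf("model bundle not found: '%s'", path), "qsrr_io_error")
  }
  bundle <- tryCatch(readRDS(path), error = function(e) {
    qsrr_abort(sprintf("model bundle '%s' is corrupted or not a bundle: %s",
                       path, conditionMessage(e)), "qsrr_corrupt_bundle_error")
  })
  if (!is.list(bundle) || is.null(bundle$format_version) || is.null(bundle$model)) {
    qsrr_abort(sprintf("'%s' is not a model bundle", path), "qsrr_corrupt_bundle_error")
  }
  if (bundle$format_version > BUNDLE_FORMAT_VERSION) {
    qsrr_abort(
      sprintf("bundle format version %d is newer than supported version %d",
              bundle$format_version, BUNDLE_FORMAT_VERSION),
      "qsrr_version_error"
    )
  }
  if (!inherits(bundle$model, "qsrr_model")) {
    qsrr_abort(sprintf("'%s' does not contain a trained model", path),
               "qsrr_corrupt_bundle_error")
  }
  bundle
}
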