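# Descriptor calculation and the three descriptor-hygiene filters.
#
# Descriptors are deliberately 2-D only (constitutional counts, functional
# groups, rings, hydrogen-bonding capacity, polar surface area, molar
# refractivity, Wildman-Crippen SLogP): retention on both reverse-phase and
# HILIC columns is driven largely by hydrophobicity and polarity, which these
# capture without any conformer generation.

#' Compute 2-D molecular descriptors from SMILES
#'
#' Parses each compound's SMILES with OpenBabel (via ChemmineR/ChemmineOB)
#' and assembles a numeric descriptor matrix: physicochemical properties
#' (SLogP, molar refractivity MR, molecular weight, topological polar
#' surface area TPSA, hydrogen-bond donor/acceptor counts), element counts,
#' ring and aromatic-ring counts, and functional-group counts. User-supplied
#' descriptor columns from the table are merged in and take precedence on a
#' name collision. Non-finite backend outputs become missing values.
#'
#' Compounds whose SMILES cannot be parsed are excluded from the matrix and
#' listed in the result's `failures`; if every compound fails, this is an
#' error.
#'
#' @param table a [compound_table()].
#' @return A list of class `descriptor_result`: `values` (numeric matrix,
#'   compounds x descriptors, `NA` = missing), `failures` (named character
#'   vector of per-compound parse errors), `rt` (retention times aligned to
#'   the matrix rows).
#' @export
compute_descriptors <- function(table) {
  stopifnot(inherits(table, "compound_table"))
  name <- table$compounds$name
  smiles <- table$compounds$smiles
  n <- length(name)
  if (!n) qsrr_abort("empty compound table", "qsrr_validation_error")

  # convert one SMILES at a time: a batch conversion aborts at the first
  # invalid structure and silently loses every compound after it
  mols <- lapply(seq_len(n), function(i) {
    one <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles[i], name[i]))),
      error = function(e) NULL
    )
    if (is.null(one) || !isTRUE(tryCatch(ChemmineR::validSDF(one),
                                         error = function(e) FALSE))) NULL
    else one@SDF[[1]]
  })
  valid <- !vapply(mols, is.null, logical(1))
  failures <- character(0)
  if (any(!valid)) {
    failures <- stats::setNames(rep("unparseable SMILES", sum(!valid)), name[!valid])
  }
  if (!any(valid)) {
    qsrr_abort("no compound has a parseable SMILES string", "qsrr_descriptor_error")
  }
  kept_names <- name[valid]
  sdf <- methods::new("SDFset", SDF = mols[valid], ID = kept_names)

  prop <- ChemmineR::propOB(sdf)
  phys <- cbind(
    SLogP = as.numeric(prop$logP),
    MR = as.numeric(prop$MR),
    MW = as.numeric(prop$MW),
    TPSA = as.numeric(prop$TPSA),
    HBD = as.numeric(prop$HBD),
    HBA = as.numeric(prop$HBA2),
    nF_OB = as.numeric(prop$nF)
  )

  one_row <- function(m) {
    # ChemmineR returns a bare vector for a single molecule
    if (is.null(dim(m))) matrix(m, nrow = 1, dimnames = list(NULL, names(m))) else m
  }
  atoms <- one_row(ChemmineR::atomcountMA(sdf, addH = TRUE))
  colnames(atoms) <- paste0("n", colnames(atoms))
  ring <- one_row(ChemmineR::rings(sdf, type = "count", arom = TRUE))
  colnames(ring) <- c("nRings", "nAromRings")
  grp <- as.matrix(one_row(ChemmineR::groups(sdf, groups = "fctgroup")))
  colnames(grp) <- paste0("grp_", colnames(grp))

  x <- cbind(phys, atoms, ring, grp)
  storage.mode(x) <- "double"
  # simple derived constitutional descriptors
  nH <- if ("nH" %in% colnames(x)) x[, "nH"] else rep(0, nrow(x))
  heavy <- rowSums(x[, grepl("^n[A-Z]", colnames(x)), drop = FALSE]) - nH
  hetero <- heavy - (if ("nC" %in% colnames(x)) x[, "nC"] else 0)
  x <- cbind(x, nHeavyAtoms = heavy, nHeteroAtoms = hetero,
             MWperHeavy = ifelse(heavy > 0, x[, "MW"] / heavy, NA_real_))
  x[!is.finite(x)] <- NA_real_
  rownames(x) <- kept_names

  # merge user-supplied descriptors; user columns win on name collision
  if (!is.null(table$extra_descriptors)) {
    extra <- as.matrix(table$extra_descriptors[kept_names, , drop = FALSE])
    storage.mode(extra) <- "double"
    extra[!is.finite(extra)] <- NA_real_
    x <- x[, setdiff(colnames(x), colnames(extra)), drop = FALSE]
    x <- cbind(extra, x)
  }
  if (anyDuplicated(colnames(x))) {
    qsrr_abort("duplicate descriptor names after merge", "qsrr_internal_error")
  }

  structure(
    list(values = x,
         failures = failures,
         rt = stats::setNames(table$compounds$rt[valid], kept_names)),
    class = "descriptor_result"
  )
}

#' @export
print.descriptor_result <- function(x, ...) {
  cat(sprintf("<descriptor_result> %d compounds x %d descriptors (%d SMILES failures)\n",
              nrow(x$values), ncol(x$values), length(x$failures)))
  invisible(x)
}

#' Descriptor-filter configuration
#'
#' Thresholds for the three descriptor-hygiene filters. All are inclusive:
#' a descriptor is dropped when its statistic reaches the threshold.
#'
#' @param dup_fraction drop a descriptor when its modal value covers at least
#'   this fraction of compounds (default 0.90).
#' @param missing_fraction drop a descriptor when at least this fraction of
#'   its cells is missing (default 0.75).
#' @param corr_threshold drop a descriptor when its absolute Pearson
#'   correlation with an already-kept descriptor reaches this value
#'   (default 0.90).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(dup_fraction = 0.90, missing_fraction = 0.75,
                          corr_threshold = 0.90) {
  for (v in c(dup_fraction, missing_fraction, corr_threshold)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1) {
      qsrr_abort("filter thresholds must lie in (0, 1]", "qsrr_validation_error")
    }
  }
  structure(list(dup_fraction = dup_fraction,
                 missing_fraction = missing_fraction,
                 corr_threshold = corr_threshold),
            class = "filter_config")
}

as_descriptor_matrix <- function(x) {
  if (inherits(x, "descriptor_result")) x <- x$values
  if (!is.matrix(x) || !is.numeric(x)) {
    qsrr_abort("descriptor table must be a numeric matrix", "qsrr_validation_error")
  }
  if (is.null(colnames(x))) {
    qsrr_abort("descriptor matrix must have column names", "qsrr_validation_error")
  }
  if (!nrow(x) || !ncol(x)) qsrr_abort("empty descriptor matrix", "qsrr_validation_error")
  x
}

#' Drop near-constant descriptors
#'
#' A descriptor is dropped when its modal value (among non-missing entries)
#' occurs in at least `dup_fraction` of the compounds. The boundary is
#' inclusive: with 20 compounds and `dup_fraction = 0.9`, 18 identical
#' values drop the column.
#'
#' @param x numeric descriptor matrix (compounds x descriptors) or a
#'   `descriptor_result`.
#' @param dup_fraction threshold in (0, 1].
#' @return A list with `values` (the filtered matrix) and `dropped`
#'   (character vector of removed descriptor names).
#' @export
drop_near_constant <- function(x, dup_fraction = 0.90) {
  x <- as_descriptor_matrix(x)
  n <- nrow(x)
  modal_count <- apply(x, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) 0L else max(tabulate(match(col, unique(col))))
  })
  drop <- modal_count / n >= dup_fraction
  list(values = x[, !drop, drop = FALSE], dropped = colnames(x)[drop])
}

#' Drop descriptors with too many missing values
#'
#' A descriptor is dropped when the fraction of missing cells is at least
#' `missing_fraction` (inclusive boundary).
#'
#' @inheritParams drop_near_constant
#' @param missing_fraction threshold in (0, 1].
#' @return As [drop_near_constant()].
#' @export
drop_high_missing <- function(x, missing_fraction = 0.75) {
  x <- as_descriptor_matrix(x)
  miss <- colMeans(is.na(x))
  drop <- miss >= missing_fraction
  list(values = x[, !drop, drop = FALSE], dropped = colnames(x)[drop])
}

#' Drop highly correlated descriptors
#'
#' Greedy scan in input column order: each candidate descriptor is compared
#' against the already-kept set and dropped (recording the first offending
#' partner) when the absolute Pearson correlation, computed on
#' pairwise-complete observations with at least 3 shared points, reaches
#' `corr_threshold`. The kept set therefore contains no pair at or above the
#' threshold, and ties always keep the earlier column.
#'
#' @inheritParams drop_near_constant
#' @param corr_threshold threshold in (0, 1].
#' @return A list with `values` (filtered matrix) and `dropped` (named
#'   character vector: names are the dropped descriptors, values their
#'   retained partners).
#' @export
drop_correlated <- function(x, corr_threshold = 0.90) {
  x <- as_descriptor_matrix(x)
  p <- ncol(x)
  kept <- integer(0)
  dropped <- character(0)
  partners <- character(0)
  for (j in seq_len(p)) {
    partner <- NA_character_
    for (k in kept) {
      ok <- !is.na(x[, j]) & !is.na(x[, k])
      if (sum(ok) < 3L) next
      r <- suppressWarnings(stats::cor(x[ok, j], x[ok, k]))
      if (!is.na(r) && abs(r) >= corr_threshold) {
        partner <- colnames(x)[k]
        break
      }
    }
    if (is.na(partner)) {
      kept <- c(kept, j)
    } else {
      dropped <- c(dropped, colnames(x)[j])
      partners <- c(partners, partner)
    }
  }
  list(values = x[, kept, drop = FALSE],
       dropped = stats::setNames(partners, dropped))
}

#' Apply the full descriptor-filter stack
#'
#' Applies, in order: the high-missing filter, the near-constant filter and
#' the correlation filter. The order matters only for attribution (a fully
#' missing column is also "constant"); correlation is computed last so that
#' it sees the most complete, informative columns. The stack is idempotent.
#'
#' @inheritParams drop_near_constant
#' @param config a [filter_config()].
#' @return A list with `values` (the filtered matrix) and `report`, a
#'   `filter_report`: `dropped` (named character vector mapping descriptor
#'   -> reason, one of `high_missing`, `near_constant`,
#'   `correlated(<partner>)`) and `kept_count`.
#' @export
apply_filters <- function(x, config = filter_config()) {
  x <- as_descriptor_matrix(x)
  stopifnot(inherits(config, "filter_config"))
  input_count <- ncol(x)

  no_survivors <- function() {
    qsrr_abort("no descriptors survive filtering; model search is impossible",
               "qsrr_filter_error")
  }
  s1 <- drop_high_missing(x, config$missing_fraction)
  if (!ncol(s1$values)) no_survivors()
  s2 <- drop_near_constant(s1$values, config$dup_fraction)
  if (!ncol(s2$values)) no_survivors()
  s3 <- drop_correlated(s2$values, config$corr_threshold)
  if (!ncol(s3$values)) no_survivors()
  reasons <- c(
    stats::setNames(rep("high_missing", length(s1$dropped)), s1$dropped),
    stats::setNames(rep("near_constant", length(s2$dropped)), s2$dropped),
    stats::setNames(sprintf("correlated(%s)", s3$dropped), names(s3$dropped))
  )
  stopifnot(length(reasons) + ncol(s3$values) == input_count)
  report <- structure(
    list(dropped = reasons, kept_count = ncol(s3$values),
         input_count = input_count),
    class = "filter_report"
  )
  list(values = s3$values, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  tab <- table(sub("\\(.*", "", x$dropped))
  cat(sprintf("<filter_report> kept %d of %d descriptors\n", x$kept_count, x$input_count))
  for (r in names(tab)) cat(sprintf("  dropped %d (%s)\n", tab[[r]], r))
  invisible(x)
}

#' Median imputation of residual missing cells
#'
#' After filtering, a descriptor column can still contain sporadic missing
#' values. `fit_imputer()` records each column's median over the training
#' rows; `apply_imputer()` replaces missing cells with those medians. Fit
#' only on training rows so that no information leaks from held-out data.
#'
#' @param x numeric descriptor matrix of training rows.
#' @return `fit_imputer()`: named numeric vector of training medians.
#' @export
fit_imputer <- function(x) {
  x <- as_descriptor_matrix(x)
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  if (anyNA(med)) {
    qsrr_abort("imputer fit on a column with no observed values (filters should have removed it)",
               "qsrr_internal_error")
  }
  med
}

#' @rdname fit_imputer
#' @param medians result of `fit_imputer()`.
#' @return `apply_imputer()`: matrix with zero missing cells, columns
#'   restricted to (and ordered as) the imputer's columns.
#' @export
apply_imputer <- function(medians, x) {
  x <- as_descriptor_matrix(x)
  unknown <- setdiff(names(medians), colnames(x))
  if (length(unknown)) {
    qsrr_abort(sprintf("descriptor column(s) unseen by the imputer are required: %s",
                       paste(unknown, collapse = ", ")),
               "qsrr_contract_error")
  }
  x <- x[, names(medians), drop = FALSE]
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- medians[[j]]
  }
  x
}

#' Export a filtered descriptor table and its filter report as CSV
#'
#' @param values descriptor matrix.
#' @param report a `filter_report` from [apply_filters()].
#' @param values_path,report_path output CSV paths (either may be `NULL`).
#' @return invisibly, `NULL`.
#' @export
export_filtered <- function(values, report, values_path = NULL, report_path = NULL) {
  if (!is.null(values_path)) {
    utils::write.csv(data.frame(name = rownames(values), values,
                                check.names = FALSE), values_path, row.names = FALSE)
  }
  if (!is.null(report_path)) {
    utils::write.csv(data.frame(descriptor = names(report$dropped),
                                reason = unname(report$dropped)),
                     report_path, row.names = FALSE)
  }
  invisible(NULL)
}
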