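# Seeded synthetic-data generators. They emulate the statistical structure
# the pipeline assumes — a compounds x descriptors matrix with a handful of
# informative columns among noise, plus the pathologies the filters must
# catch — and homologous chemical series with retention linear in chain
# length, so every stage is testable without any real LC-MS data.

#' Specification of a synthetic descriptor matrix
#'
#' @param n_compounds number of compounds (rows).
#' @param n_noise_features i.i.d. standard-normal noise descriptors.
#' @param informative list of `(index, coefficient)` pairs — noise-feature
#'   indices that actually drive retention — given as a named numeric
#'   vector: names are feature indices, values coefficients.
#' @param corr_blocks list of `list(source, copies, jitter_sd)`: each adds
#'   `copies` affine copies of noise feature `source` with Gaussian jitter,
#'   which the correlation filter should remove.
#' @param n_near_constant columns whose modal value covers 95% of compounds.
#' @param n_high_missing columns with 80% missing cells.
#' @param rt_mechanism `"linear"` (rt = offset + sum coef * feature) or
#'   `"rbf_nonlinear"` (offset plus a smooth sinusoidal function of the
#'   informative features).
#' @param noise_sd Gaussian noise on retention time, minutes. Default 0.1:
#'   replicate retention-time standard deviations on real columns mostly
#'   fall in 0.005-0.2 min.
#' @param rt_offset baseline retention time, minutes (default 16, well clear
#'   of zero relative to the planted-signal spread).
#' @param seed integer seed.
#' @return A list of class `matrix_spec`.
#' @export
matrix_spec <- function(n_compounds = 200L, n_noise_features = 50L,
                        informative = c("1" = 2, "2" = -2, "3" = 2),
                        corr_blocks = list(),
                        n_near_constant = 0L, n_high_missing = 0L,
                        rt_mechanism = c("linear", "rbf_nonlinear"),
                        noise_sd = 0.1, rt_offset = 16, seed = 1L) {
  rt_mechanism <- match.arg(rt_mechanism)
  stopifnot(n_compounds > 0, n_noise_features >= length(informative),
            n_near_constant >= 0, n_high_missing >= 0, noise_sd >= 0)
  structure(
    list(n_compounds = as.integer(n_compounds),
         n_noise_features = as.integer(n_noise_features),
         informative = informative,
         corr_blocks = corr_blocks,
         n_near_constant = as.integer(n_near_constant),
         n_high_missing = as.integer(n_high_missing),
         rt_mechanism = rt_mechanism,
         noise_sd = noise_sd, rt_offset = rt_offset, seed = as.integer(seed)),
    class = "matrix_spec"
  )
}

#' Generate a synthetic descriptor matrix with planted signal
#'
#' Noise descriptors are i.i.d. standard normal; the informative subset
#' drives retention either linearly or through a smooth nonlinear
#' (sinusoidal) response that an RBF-kernel learner can fit but a linear
#' model cannot. Correlated blocks, near-constant columns and high-missing
#' columns are constructed to cross the default filter thresholds, and the
#' ground truth (informative descriptor names and coefficients, plus which
#' planted columns each filter should drop) is returned alongside.
#'
#' @param spec a [matrix_spec()].
#' @return A list: `x` (descriptor matrix with planted pathologies), `rt`
#'   (positive retention times, minutes), `truth` (list with
#'   `informative_features`, `coefficients`, `planted_constant`,
#'   `planted_missing`, `planted_correlated`).
#' @export
gen_matrix <- function(spec) {
  stopifnot(inherits(spec, "matrix_spec"))
  with_seed(spec$seed, {
    n <- spec$n_compounds
    p <- spec$n_noise_features
    x <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(sprintf("cmpd_%03d", seq_len(n)),
                                sprintf("f%03d", seq_len(p))))
    idx <- as.integer(names(spec$informative))
    coef <- as.numeric(spec$informative)
    inf_names <- colnames(x)[idx]

    signal <- switch(spec$rt_mechanism,
      linear = as.numeric(x[, idx, drop = FALSE] %*% coef),
      rbf_nonlinear = rowSums(vapply(seq_along(idx), function(i) {
        coef[i] * sin(2 * x[, idx[i]])
      }, numeric(n)))
    )
    rt <- spec$rt_offset + signal + stats::rnorm(n, 0, spec$noise_sd)
    if (any(rt <= 0)) {
      qsrr_abort("spec produced non-positive retention times; raise rt_offset",
                 "qsrr_validation_error")
    }

    extra <- list()
    corr_names <- character(0)
    for (blk in spec$corr_blocks) {
      src <- colnames(x)[blk$source]
      for (c_i in seq_len(blk$copies)) {
        nm <- sprintf("%s_copy%d", src, c_i)
        extra[[nm]] <- 2 * x[, src] + 1 + stats::rnorm(n, 0, blk$jitter_sd %||% 0)
        corr_names <- c(corr_names, nm)
      }
    }
    const_names <- sprintf("const_%02d", seq_len(spec$n_near_constant))
    for (nm in const_names) {
      col <- rep(1, n)
      n_vary <- floor(0.05 * n)          # modal value covers >= 95% of rows
      if (n_vary > 0) col[sample.int(n, n_vary)] <- stats::rnorm(n_vary)
      extra[[nm]] <- col
    }
    miss_names <- sprintf("miss_%02d", seq_len(spec$n_high_missing))
    for (nm in miss_names) {
      col <- stats::rnorm(n)
      col[sample.int(n, ceiling(0.8 * n))] <- NA_real_  # 80% missing >= 75% default
      extra[[nm]] <- col
    }
    if (length(extra)) x <- cbind(x, do.call(cbind, extra))

    list(x = x, rt = rt,
         truth = list(informative_features = inf_names,
                      coefficients = stats::setNames(coef, inf_names),
                      planted_constant = const_names,
                      planted_missing = miss_names,
                      planted_correlated = corr_names))
  })
}

#' Specification of a homologous chemical series
#'
#' @param family `"n_alkanols"` (linear-chain alcohols) or
#'   `"n_fatty_acids"` (linear-chain carboxylic acids).
#' @param chain_lengths integer vector of carbon chain lengths (>= 2).
#' @param rt_intercept,rt_slope retention model: rt = intercept +
#'   slope * chain_length, minutes; slope must be positive (longer chains
#'   are more hydrophobic and elute later on reverse phase).
#' @param noise_sd Gaussian noise on rt, minutes.
#' @param seed integer seed.
#' @return A list of class `series_spec`.
#' @export
series_spec <- function(family = c("n_alkanols", "n_fatty_acids"),
                        chain_lengths = 2:41, rt_intercept = 1,
                        rt_slope = 0.35, noise_sd = 0.1, seed = 1L) {
  family <- match.arg(family)
  stopifnot(all(chain_lengths >= 2), rt_slope > 0, noise_sd >= 0)
  structure(list(family = family, chain_lengths = as.integer(chain_lengths),
                 rt_intercept = rt_intercept, rt_slope = rt_slope,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "series_spec")
}

#' Generate a homologous series with programmed retention
#'
#' Builds real, parseable SMILES for a homologous series (n-alkanols or
#' n-fatty acids) whose retention time is linear in chain length plus
#' Gaussian noise — the idealized reverse-phase behaviour of a lipid-like
#' family sharing a backbone, where hydrophobicity (SLogP) is the monotone
#' driver of retention.
#'
#' @param spec a [series_spec()].
#' @return A [compound_table()] with retention times.
#' @export
gen_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  chains <- spec$chain_lengths
  smiles <- switch(spec$family,
    n_alkanols = paste0(strrep("C", chains), "O"),
    n_fatty_acids = paste0(strrep("C", chains - 1), "C(=O)O")
  )
  name <- sprintf("%s_C%d", sub("^n_", "", spec$family), chains)
  rt <- with_seed(spec$seed,
    spec$rt_intercept + spec$rt_slope * chains +
      stats::rnorm(length(chains), 0, spec$noise_sd))
  if (any(rt <= 0)) {
    qsrr_abort("series spec produced non-positive retention times",
               "qsrr_validation_error")
  }
  compound_table(name, smiles, rt)
}
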