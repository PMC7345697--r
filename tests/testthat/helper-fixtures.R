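# Shared fixtures and independent oracles used across test files.

# Write a small compound CSV and return its path.
write_fixture_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

three_compound_csv <- function() {
  write_fixture_csv(c(
    "name,smiles,rt_minutes",
    "ethanol,CCO,1.5",
    "propanol,CCCO,2.1",
    "butanol,CCCCO,2.8"
  ))
}

# Textbook Pearson correlation on pairwise-complete observations --
# independent of stats::cor, used as the oracle for the correlation filter.
pearson_oracle <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  if (den == 0) NA_real_ else num / den
}

# Brute-force reference for the full filter stack: explicit enumeration,
# no shared code with apply_filters beyond the threshold conventions.
filter_oracle <- function(x, dup = 0.9, miss = 0.75, corr = 0.9) {
  n <- nrow(x)
  keep <- colnames(x)
  # high-missing (inclusive)
  keep <- keep[vapply(keep, function(j) sum(is.na(x[, j])) / n < miss, TRUE)]
  # near-constant (inclusive, modal count over total compounds)
  keep <- keep[vapply(keep, function(j) {
    v <- x[, j][!is.na(x[, j])]
    if (!length(v)) return(TRUE)
    max(table(v)) / n < dup
  }, TRUE)]
  # greedy correlation scan in column order
  kept <- character(0)
  for (j in keep) {
    clash <- FALSE
    for (k in kept) {
      r <- pearson_oracle(x[, j], x[, k])
      if (!is.na(r) && abs(r) >= corr) { clash <- TRUE; break }
    }
    if (!clash) kept <- c(kept, j)
  }
  kept
}

# A random matrix with planted constant / missing / duplicate pathologies,
# for the filter-equivalence checks.
random_pathology_matrix <- function(seed, n = 20, p = 15) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("c%02d", 1:p)))
  x[, 3] <- 1                                   # constant
  x[, 5][sample(n, ceiling(0.8 * n))] <- NA     # high missing
  x[, 9] <- x[, 2]                              # exact duplicate
  if (p >= 12) x[, 12] <- round(x[, 12])        # discretized: near-constant-ish
  x
}

# Small imputed linear-signal matrix for model-search unit tests.
linear_toy <- function(n = 60, p = 6, seed = 1, noise = 0) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%d", 1:p)))
  y <- 3 * x[, 1] - x[, 2] + 0.5 + rnorm(n, 0, noise)
  list(x = x, y = y)
}
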