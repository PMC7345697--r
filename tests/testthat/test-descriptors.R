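test_that("computed descriptors match reference values for ethanol", {
  tbl <- compound_table(c("ethanol", "butanol"), c("CCO", "CCCCO"),
                        rt = c(1.5, 2.8))
  d <- compute_descriptors(tbl)
  expect_identical(rownames(d$values), c("ethanol", "butanol"))
  # pinned from a reference Wildman-Crippen / TPSA calculation
  expect_equal(d$values["ethanol", "SLogP"], -0.0014, tolerance = 1e-3)
  expect_equal(d$values["ethanol", "MW"], 46.069, tolerance = 1e-3)
  expect_equal(d$values["ethanol", "TPSA"], 20.23, tolerance = 1e-2)
  expect_equal(unname(d$values[, "HBD"]), c(1, 1))
  expect_equal(unname(d$values[, "nC"]), c(2, 4))
  expect_true(all(is.finite(d$values[, c("MW", "MR", "nHeavyAtoms")])))
})

test_that("unparseable SMILES are reported per compound, not fatal", {
  tbl <- compound_table(c("ok", "broken"), c("CCO", "C("), rt = c(1, 2))
  d <- compute_descriptors(tbl)
  expect_identical(rownames(d$values), "ok")
  expect_named(d$failures, "broken")

  all_bad <- compound_table("broken", "C(", rt = 1)
  expect_error(compute_descriptors(all_bad), class = "qsrr_descriptor_error")
})

test_that("SLogP increases strictly with alkanol chain length", {
  tbl <- gen_series(series_spec(chain_lengths = 2:10, noise_sd = 0))
  d <- compute_descriptors(tbl)
  expect_true(all(diff(d$values[, "SLogP"]) > 0))
})

test_that("user-supplied descriptors are merged and win name collisions", {
  tbl <- compound_table(c("a", "b"), c("CCO", "CCCO"), rt = c(1, 2),
                        extra_descriptors = data.frame(SLogP = c(99, 98),
                                                       custom = c(1, 2)))
  d <- compute_descriptors(tbl)
  expect_equal(unname(d$values[, "SLogP"]), c(99, 98))
  expect_equal(unname(d$values[, "custom"]), c(1, 2))
  expect_false(anyDuplicated(colnames(d$values)) > 0)
})

test_that("near-constant filter drops at the inclusive boundary", {
  x <- cbind(boundary = c(rep(1, 18), 2, 3),  # 18/20 = 0.90 exactly
             constant = rep(7, 20),
             distinct = 1:20)
  res <- drop_near_constant(x, 0.90)
  expect_setequal(res$dropped, c("boundary", "constant"))
  expect_identical(colnames(res$values), "distinct")
})

test_that("high-missing filter drops at the inclusive boundary", {
  x <- cbind(boundary = c(rep(NA_real_, 15), 1:5),  # 15/20 = 0.75 exactly
             observed = rnorm(20),
             all_missing = rep(NA_real_, 20))
  res <- drop_high_missing(x, 0.75)
  expect_setequal(res$dropped, c("boundary", "all_missing"))
})

test_that("correlation filter drops later columns, recording the partner", {
  set.seed(4)
  x <- cbind(x1 = rnorm(30), x2 = rnorm(30))
  x <- cbind(x, affine = 2 * x[, "x1"] + 1, dup = x[, "x2"])
  res <- drop_correlated(x, 0.90)
  expect_identical(colnames(res$values), c("x1", "x2"))
  expect_identical(unname(res$dropped["affine"]), "x1")
  expect_identical(unname(res$dropped["dup"]), "x2")

  # independent standard-normal columns stay (oracle-confirmed below 0.9)
  set.seed(7)
  z <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  expect_lt(abs(pearson_oracle(z[, 1], z[, 2])), 0.9)
  expect_identical(drop_correlated(z, 0.90)$dropped, setNames(character(0), character(0)))
})

test_that("apply_filters attributes one reason per drop and is idempotent", {
  set.seed(11)
  x <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(NULL, paste0("clean", 1:4)))
  x <- cbind(x, missing_col = rep(NA_real_, 20), const_col = rep(1, 20),
             dup_col = x[, "clean2"])
  res <- apply_filters(x, filter_config())
  expect_identical(res$report$kept_count, 4L)
  reasons <- res$report$dropped
  expect_identical(unname(reasons["missing_col"]), "high_missing")
  expect_identical(unname(reasons["const_col"]), "near_constant")
  expect_identical(unname(reasons["dup_col"]), "correlated(clean2)")

  again <- apply_filters(res$values, filter_config())
  expect_length(again$report$dropped, 0)
  expect_identical(again$values, res$values)

  # a matrix with nothing to drop passes through
  clean <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("c", 1:5)))
  expect_length(apply_filters(clean)$report$dropped, 0)
})

test_that("filter outcomes are invariant to compound (row) order", {
  x <- random_pathology_matrix(21)
  res1 <- apply_filters(x)
  res2 <- apply_filters(x[rev(seq_len(nrow(x))), ])
  expect_identical(colnames(res1$values), colnames(res2$values))
  expect_identical(res1$report$dropped[order(names(res1$report$dropped))],
                   res2$report$dropped[order(names(res2$report$dropped))])
})

test_that("all descriptors dropped is a hard error", {
  x <- cbind(a = rep(1, 10), b = rep(NA_real_, 10))
  expect_error(apply_filters(x), class = "qsrr_filter_error")
})

test_that("median imputation fills missing cells from training columns only", {
  x <- cbind(a = c(1, 2, NA, 4), b = c(5, 6, 7, 8))
  med <- fit_imputer(x)
  expect_equal(unname(med["a"]), 2)  # median of {1, 2, 4}
  out <- apply_imputer(med, x)
  expect_equal(unname(out[3, "a"]), 2)
  expect_false(anyNA(out))

  # no missing cells -> identity
  expect_identical(apply_imputer(fit_imputer(x[, "b", drop = FALSE]),
                                 x[, "b", drop = FALSE]),
                   x[, "b", drop = FALSE])

  # unknown column demanded by the imputer -> contract error
  expect_error(apply_imputer(c(zz = 1), x), class = "qsrr_contract_error")
})
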