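test_that("templates carry the expected header and no data rows", {
  p <- tempfile(fileext = ".csv")
  write_template(p, include_rt = TRUE)
  df <- read.csv(p)
  expect_identical(names(df), c("name", "smiles", "rt_minutes"))
  expect_identical(nrow(df), 0L)

  write_template(p, include_rt = FALSE)
  expect_identical(names(read.csv(p)), c("name", "smiles"))

  expect_error(write_template(file.path(tempfile(), "nope", "t.csv")),
               class = "qsrr_io_error")
})

test_that("read_table parses well-formed files and validates structure", {
  tbl <- read_table(three_compound_csv())
  expect_s3_class(tbl, "compound_table")
  expect_identical(tbl$compounds$name, c("ethanol", "propanol", "butanol"))
  expect_equal(tbl$compounds$rt, c(1.5, 2.1, 2.8))
  rep <- attr(tbl, "parse_report")
  expect_identical(rep$rows_read, 3L)
  expect_identical(rep$rows_rejected, 0L)

  # header matching is case-insensitive after whitespace stripping
  p <- write_fixture_csv(c(" Name , SMILES , RT_Minutes", "glycine,C(C(=O)O)N,4.2"))
  expect_identical(read_table(p)$compounds$name, "glycine")

  expect_error(read_table(write_fixture_csv(c("name,rt_minutes", "a,1"))),
               class = "qsrr_format_error")
  expect_error(
    read_table(write_fixture_csv(c("name,smiles,rt_minutes",
                                   "glycine,NCC(=O)O,4.2",
                                   "glycine,NCC(=O)O,4.3"))),
    regexp = "glycine", class = "qsrr_validation_error")
  expect_error(
    read_table(write_fixture_csv(c("name,smiles,rt_minutes", "a,CCO,oops"))),
    class = "qsrr_validation_error")
  expect_error(
    read_table(write_fixture_csv(c("name,smiles,rt_minutes", "a,CCO,-2"))),
    class = "qsrr_validation_error")
  # missing rt tolerated for prediction input
  expect_silent(tbl2 <- read_table(
    write_fixture_csv(c("name,smiles", "a,CCO")), require_rt = FALSE))
  expect_true(is.na(tbl2$compounds$rt))
})

test_that("extra numeric columns pass through as user descriptors", {
  p <- write_fixture_csv(c("name,smiles,rt_minutes,SLogP,note",
                           "a,CCO,1.5,0.2,hello",
                           "b,CCCO,2.0,0.6,world"))
  tbl <- read_table(p)
  expect_identical(names(tbl$extra_descriptors), "SLogP")
  expect_equal(tbl$extra_descriptors$SLogP, c(0.2, 0.6))
  expect_identical(attr(tbl, "parse_report")$non_numeric_columns_dropped, "note")
})

test_that("write_table / read_table round-trips records and user descriptors", {
  tbl <- compound_table(c("a", "b", "c"), c("CCO", "CCCO", "CCCCO"),
                        rt = c(1.1, 2.2, 3.3),
                        extra_descriptors = data.frame(SLogP = c(0.1, 0.4, 0.8)))
  p <- tempfile(fileext = ".csv")
  write_table(tbl, p)
  back <- read_table(p)
  expect_identical(back$compounds$name, tbl$compounds$name)
  expect_identical(back$compounds$smiles, tbl$compounds$smiles)
  expect_equal(back$compounds$rt, tbl$compounds$rt)
  expect_equal(back$extra_descriptors$SLogP, tbl$extra_descriptors$SLogP)
})

test_that("model bundles round-trip and reject corruption and future versions", {
  gm <- gen_matrix(matrix_spec(n_compounds = 40, n_noise_features = 6,
                               informative = c("1" = 2), seed = 42))
  model <- fit_final(gm$x, gm$rt, search_config(method = "linear", seed = 42))
  path <- tempfile(fileext = ".qsrr")
  save_model(model, path)
  bundle <- load_model(path)
  expect_identical(bundle$format_version, 1L)
  newx <- gen_matrix(matrix_spec(n_compounds = 15, n_noise_features = 6,
                                 informative = c("1" = 2), seed = 43))$x
  expect_identical(predict(bundle$model, newx)$predicted_rt,
                   predict(model, newx)$predicted_rt)

  # truncated file -> corruption error
  trunc <- tempfile(fileext = ".qsrr")
  raw <- readBin(path, "raw", file.info(path)$size)
  writeBin(raw[seq_len(20)], trunc)
  expect_error(load_model(trunc), class = "qsrr_corrupt_bundle_error")

  # future format version -> explicit incompatibility
  fut <- readRDS(path)
  fut$format_version <- 999L
  futp <- tempfile(fileext = ".qsrr")
  saveRDS(fut, futp)
  expect_error(load_model(futp), class = "qsrr_version_error")
})
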