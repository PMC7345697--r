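make_small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gm <- gen_matrix(matrix_spec(n_compounds = 50, n_noise_features = 6,
                                   informative = c("1" = 2, "2" = -1), seed = 31))
      cache <<- list(gm = gm,
                     model = fit_final(gm$x, gm$rt,
                                       search_config(method = "linear", seed = 31)))
    }
    cache
  }
})

test_that("prediction replays the pipeline and flags extrapolation", {
  ms <- make_small_model()
  pred <- predict(ms$model, ms$gm$x)
  expect_identical(nrow(pred), 50L)
  expect_true(all(is.finite(pred$predicted_rt)))
  expect_identical(pred$extrapolation,
                   pred$predicted_rt < ms$model$train_rt_min |
                     pred$predicted_rt > ms$model$train_rt_max)

  # save/load round trip predicts bit-identically
  p <- tempfile(fileext = ".qsrr")
  save_model(ms$model, p)
  pred2 <- predict(load_model(p)$model, ms$gm$x)
  expect_identical(pred$predicted_rt, pred2$predicted_rt)

  # required descriptor absent from the input -> contract error
  expect_error(predict(ms$model, ms$gm$x[, 4:6, drop = FALSE]),
               class = "qsrr_contract_error")
})

test_that("unparseable SMILES at prediction time are skipped with a report", {
  tbl <- gen_series(series_spec(chain_lengths = 2:16, seed = 6))
  d <- compute_descriptors(tbl)
  filt <- apply_filters(d$values)
  model <- fit_final(filt$values, d$rt, search_config(method = "linear", seed = 6))
  mixed <- compound_table(c("good", "bad"), c("CCCCCO", "X(("))
  pred <- predict(model, mixed)
  expect_identical(pred$name, "good")
  expect_named(attr(pred, "failures"), "bad")
})

test_that("extrapolation exclusion keeps boundary-equal observations", {
  obs <- c(0.5, 1.0, 8.2, 16.0, 16.5)
  res <- exclude_extrapolated(obs, 1.0, 16.0)
  expect_identical(res$keep, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(res$n_kept + res$n_excluded, length(obs))
  expect_identical(exclude_extrapolated(c(2, 3), 1, 16)$n_excluded, 0L)
})

test_that("the relative-error filter drops strictly above the threshold", {
  res <- filter_relative_error(c(13.6, 13.5, 10.0), c(10, 10, 10), max_pct = 35)
  expect_identical(res$keep, c(FALSE, TRUE, TRUE))  # 36% out, 35% boundary in
  expect_equal(res$pct_error, c(36, 35, 0))
  expect_identical(res$n_kept + res$n_dropped, 3L)
  expect_error(filter_relative_error(1, 0), class = "qsrr_validation_error")
})

test_that("evaluation statistics match hand-computed least squares", {
  perfect <- evaluate_predictions(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$intercept, 0)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$median_error, 0)
  expect_equal(unname(perfect$within), c(1, 1))

  # pairs (1,1.5),(2,2.5),(3,3.5): unit slope, offset 0.5
  off <- evaluate_predictions(c(1.5, 2.5, 3.5), c(1, 2, 3))
  expect_equal(off$slope, 1)
  expect_equal(off$intercept, 0.5)
  expect_equal(off$r_squared, 1)
  expect_equal(off$median_error, 0.5)
  expect_equal(unname(off$within["within_1_min"]), 1)

  # counting the tolerance band
  band <- evaluate_predictions(c(1, 2, 3, 4) + c(-0.5, 0, 0.5, 1.5),
                               c(1, 2, 3, 4))
  expect_equal(unname(band$within["within_1_min"]), 0.75)

  expect_error(evaluate_predictions(c(1, 2), c(1, 2)),
               class = "qsrr_validation_error")
  expect_error(evaluate_predictions(c(1, 2, 3), c(2, 2, 2)),
               class = "qsrr_degenerate_target_error")
})

test_that("evaluation is translation-consistent", {
  set.seed(13)
  obs <- runif(25, 1, 15)
  pred <- obs + rnorm(25, 0, 0.4)
  base <- evaluate_predictions(pred, obs)
  shift <- evaluate_predictions(pred + 0.7, obs)
  expect_equal(shift$slope, base$slope)
  expect_equal(shift$r_squared, base$r_squared)
  expect_equal(shift$intercept, base$intercept + 0.7)
  expect_equal(shift$median_error, base$median_error + 0.7)
})

test_that("t-tests agree with the textbook formula", {
  a <- c(2, 4, 6); b <- c(1, 2, 3)   # differences {1, 2, 3}
  res <- paired_t_test(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(3))       # = 2 / (1 / sqrt(3))
  expect_equal(res$t, t_hand)
  expect_equal(res$t, 3.464102, tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df = 2))

  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$t, 0)
  expect_identical(same$p_value, 1)

  expect_error(paired_t_test(1:4, 1:3), class = "qsrr_validation_error")
  expect_error(paired_t_test(c(1, 2, 3), c(2, 3, 4)),
               class = "qsrr_degenerate_target_error")

  # random-vector agreement with the reference implementation
  set.seed(17)
  for (i in 1:20) {
    u <- rnorm(12); v <- rnorm(12)
    ours <- paired_t_test(u, v)
    ref <- t.test(u, v, paired = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
    un <- paired_t_test(u, v, paired = FALSE)
    ref2 <- t.test(u, v, paired = FALSE)
    expect_equal(un$t, unname(ref2$statistic), tolerance = 1e-6)
    expect_equal(un$p_value, ref2$p.value, tolerance = 1e-6)
  }
})
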