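# A model that predicts the constant c for any epoch: zero weights, zero
# biases, degenerate target normalization.
constant_model <- function(c_value, n_in = 300) {
  m <- init_model(c(n_in, 2, 1), seed = 1)
  for (l in seq_along(m$weights)) { m$weights[[l]][] <- 0; m$biases[[l]][] <- 0 }
  m$input_norm <- list(min = rep(0, n_in), range = rep(100, n_in))
  m$target_norm <- list(min = c_value, range = 0)
  m
}

test_that("night estimation averages per-epoch predictions", {
  rec <- spo2_record(rep(96, 1800), fs = 0.5)
  expect_equal(estimate_night(constant_model(7.5), rec), 7.5)

  one_epoch <- spo2_record(rep(96, 300), fs = 0.5)
  expect_equal(estimate_night(constant_model(3), one_epoch), 3)

  # recomputation identity against an externally computed epoch mean
  m <- init_model(c(300, 5, 1), seed = 2)
  norms <- fit_normalization(matrix(runif(3000, 80, 100), 10, 300),
                             runif(10, 0, 90))
  m$input_norm <- norms$input_norm
  m$target_norm <- norms$target_norm
  withr::with_seed(3, x <- round(runif(1800, 88, 99)))
  rec2 <- spo2_record(x, fs = 0.5)
  es <- epoch_signal(downsample(rec2, 0.5))
  manual <- mean(predict(m, es$epochs[es$valid_mask, , drop = FALSE]))
  expect_equal(estimate_night(m, rec2), manual, tolerance = 1e-12)

  expect_error(estimate_night(constant_model(1), spo2_record(rep(NA_real_, 300), fs = 0.5)),
               "valid")
})

test_that("error statistics follow their definitions", {
  em <- error_metrics(tibble::tibble(reference = c(5, 12), estimate = c(5, 10)))
  expect_equal(em$mean_abs_error, 1)
  expect_equal(em$median_abs_error, 1)
  expect_equal(em$min_error, 0)
  expect_equal(em$max_error, 2)

  perfect <- error_metrics(tibble::tibble(reference = 1:4, estimate = 1:4))
  expect_true(all(unlist(perfect[, c("mean_abs_error", "median_abs_error",
                                     "min_error", "max_error")]) == 0))

  pct <- error_metrics(tibble::tibble(reference = 5, estimate = 6))
  expect_equal(pct$median_pct_error, 20)

  # zero-reference patients are excluded from the percentage median only
  mixed <- error_metrics(tibble::tibble(reference = c(0, 5), estimate = c(2, 6)))
  expect_equal(mixed$median_pct_error, 20)
  expect_equal(mixed$n_pct_basis, 1)
  expect_equal(mixed$max_error, 2)

  expect_error(error_metrics(tibble::tibble(reference = numeric(),
                                            estimate = numeric())), "empty")
})

test_that("classification metrics enumerate the toy cohort correctly", {
  est <- tibble::tibble(reference = c(4, 10, 20, 40),
                        estimate = c(4.5, 16, 20, 40))
  cm <- classification_metrics(est)
  expect_equal(cm$accuracy, 0.75)
  expect_equal(cm$n_misclassified, 1)
  expect_equal(cm$confusion["mild", "moderate"], 1)
  expect_equal(sum(cm$confusion), 4)
  expect_equal(sum(diag(cm$confusion)), 3)
  expect_equal(cm$accuracy, 1 - cm$n_misclassified / 4)
  expect_equal(cm$misclassified_errors$mean_abs_error, 6)

  all_right <- classification_metrics(tibble::tibble(reference = c(2, 20),
                                                     estimate = c(3, 22)))
  expect_equal(all_right$accuracy, 1)
  expect_null(all_right$misclassified_errors)
})

test_that("ICC(2,1) matches an independent ANOVA-table computation", {
  x <- c(9, 6, 8, 7, 10, 6)
  y <- c(2, 1, 4, 1, 5, 2)
  got <- icc_agreement(x, y)

  # oracle: mean squares from aov() on the long-format two-way layout
  long <- data.frame(
    score = c(x, y),
    subject = factor(rep(1:6, 2)),
    rater = factor(rep(c("ref", "est"), each = 6))
  )
  ms <- summary(aov(score ~ subject + rater, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 6; k <- 2
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(got$icc, icc_oracle, tolerance = 1e-12)
  expect_true(got$ci_lower < got$icc && got$icc < got$ci_upper)

  # perfect agreement on a non-constant vector
  expect_equal(icc_agreement(c(1, 3, 5, 7), c(1, 3, 5, 7))$icc, 1)

  expect_error(icc_agreement(1:5, 1:4), "length")
  expect_error(icc_agreement(1:2, 1:2), "3")
})

test_that("ICC of permuted values is near zero", {
  withr::with_seed(17, {
    x <- runif(500, 0, 100)
    y <- sample(x)
  })
  expect_lt(abs(icc_agreement(x, y)$icc), 0.12)
})

test_that("the evaluation report is internally consistent", {
  withr::with_seed(19, {
    ref <- runif(40, 0, 80)
    est <- pmax(ref + rnorm(40, 0, 4), 0)
  })
  ev <- evaluate_estimates(tibble::tibble(reference = ref, estimate = est),
                           index = "ahi")
  expect_s3_class(ev, "osa_evaluation")
  expect_equal(sum(ev$confusion), 40)
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / 40)
  expect_equal(ev$n_misclassified, 40 - sum(diag(ev$confusion)))
  g <- glance(ev)
  expect_equal(g$icc, ev$icc$icc)
  td <- tidy(ev)
  expect_equal(td$value[td$metric == "accuracy"], ev$accuracy)
})
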