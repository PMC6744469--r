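#' Estimate a full-night index from an SpO2 record
#'
#' Preprocesses the record exactly as in training (downsample to the network
#' rate, overlapping 10-minute epochs), predicts every valid epoch, and
#' returns the arithmetic mean of the epoch predictions (each clamped at
#' zero).
#'
#' @param model A fitted `mlp_model`.
#' @param record An [spo2_record()] of at least one window's duration.
#' @param target_fs,window_s,overlap,invalid_threshold Preprocessing
#'   parameters; keep identical to the values used in training.
#' @return A single index estimate in events/hour.
#' @export
estimate_night <- function(model, record, target_fs = 0.5, window_s = 600,
                           overlap = 0.98, invalid_threshold = 0.1) {
  es <- prepare_record(record, target_fs = target_fs, window_s = window_s,
                       overlap = overlap, invalid_threshold = invalid_threshold)
  if (!any(es$valid_mask)) {
    abort("No valid epochs in the record; cannot estimate an index.")
  }
  preds <- predict(model, es$epochs[es$valid_mask, , drop = FALSE])
  mean(preds)
}

#' Per-patient error statistics
#'
#' Absolute errors `|estimate - reference|` per patient, summarised by mean,
#' median, minimum and maximum; the median percentage error
#' `100 |est - ref| / ref` is computed over patients with a non-zero
#' reference only (it is undefined at zero), while such patients remain in
#' the absolute-error statistics.
#'
#' @param estimates A data frame with columns `reference` and `estimate`
#'   (events/hour), one row per patient.
#' @return A one-row tibble: `n`, `mean_abs_error`, `median_abs_error`,
#'   `min_error`, `max_error`, `median_pct_error`, `n_pct_basis`.
#' @examples
#' error_metrics(tibble::tibble(reference = c(5, 12), estimate = c(5, 10)))
#' @export
error_metrics <- function(estimates) {
  check_estimates(estimates)
  abs_err <- abs(estimates$estimate - estimates$reference)
  pos <- estimates$reference > 0
  tibble::tibble(
    n = nrow(estimates),
    mean_abs_error = mean(abs_err),
    median_abs_error = median(abs_err),
    min_error = min(abs_err),
    max_error = max(abs_err),
    median_pct_error = if (any(pos)) {
      median(100 * abs_err[pos] / estimates$reference[pos])
    } else {
      NA_real_
    },
    n_pct_basis = sum(pos)
  )
}

check_estimates <- function(estimates) {
  if (!is.data.frame(estimates) || nrow(estimates) == 0L) {
    abort("`estimates` must be a non-empty data frame.")
  }
  if (!all(c("reference", "estimate") %in% names(estimates))) {
    abort("`estimates` needs columns `reference` and `estimate`.")
  }
  invisible(estimates)
}

#' Severity confusion matrix, accuracy and misclassification errors
#'
#' Classifies reference and estimated indices with [classify_severity()],
#' tabulates the 4x4 confusion matrix (reference in rows, estimate in
#' columns), and recomputes the error statistics restricted to the
#' misclassified (off-diagonal) patients.
#'
#' @inheritParams error_metrics
#' @return A list: `confusion` (4x4 labelled matrix), `accuracy`,
#'   `n_misclassified`, `misclassified_errors` (one-row tibble or `NULL`).
#' @export
classification_metrics <- function(estimates) {
  check_estimates(estimates)
  ref_class <- classify_severity(estimates$reference)
  est_class <- classify_severity(estimates$estimate)
  confusion <- table(reference = ref_class, estimate = est_class)
  confusion <- unclass(confusion)
  wrong <- ref_class != est_class
  list(
    confusion = confusion,
    accuracy = sum(diag(confusion)) / sum(confusion),
    n_misclassified = sum(wrong),
    misclassified_errors = if (any(wrong)) {
      error_metrics(estimates[wrong, , drop = FALSE])
    } else {
      NULL
    }
  )
}

#' Intraclass correlation between reference and estimated indices
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC — ICC(2,1) —
#' treating the manual reference and the network as two raters scoring the
#' same subjects: `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` from
#' the two-way ANOVA mean squares of the `n x 2` table. The 95% confidence
#' interval uses the standard F-distribution bounds with Satterthwaite
#' degrees of freedom (McGraw & Wong).
#'
#' @param x Reference values (one per subject, length >= 3).
#' @param y Estimated values, same length.
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble: `icc`, `ci_lower`, `ci_upper`, `n`.
#' @examples
#' icc_agreement(c(1, 3, 5, 7, 9, 11), c(2, 3, 4, 8, 9, 10))
#' @export
icc_agreement <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) abort("`x` and `y` must have the same length.")
  n <- length(x)
  if (n < 3L) abort("ICC needs at least 3 paired observations.")
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((dat - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  if (mse == 0 && msc == msr) {  # degenerate: perfect agreement
    return(tibble::tibble(icc = icc, ci_lower = icc, ci_upper = icc, n = n))
  }
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  tibble::tibble(icc = icc, ci_lower = lower, ci_upper = upper, n = n)
}

#' Full evaluation report for one index
#'
#' Bundles the error statistics, severity classification metrics and ICC for
#' a cohort of per-patient reference/estimate pairs into the package's report
#' object.
#'
#' @param estimates Data frame with columns `patient_id` (optional),
#'   `reference`, `estimate`.
#' @param index Label for the index being evaluated (`"ahi"` or `"odi"`).
#' @return An `osa_evaluation` object.
#' @export
evaluate_estimates <- function(estimates, index = c("ahi", "odi")) {
  index <- match.arg(index)
  check_estimates(estimates)
  estimates <- tibble::as_tibble(estimates)
  if (!"patient_id" %in% names(estimates)) {
    estimates$patient_id <- sprintf("P%04d", seq_len(nrow(estimates)))
  }
  estimates$ref_class <- classify_severity(estimates$reference)
  estimates$est_class <- classify_severity(estimates$estimate)
  cls <- classification_metrics(estimates)
  structure(
    list(
      index = index,
      estimates = estimates,
      errors = error_metrics(estimates),
      confusion = cls$confusion,
      accuracy = cls$accuracy,
      n_misclassified = cls$n_misclassified,
      misclassified_errors = cls$misclassified_errors,
      icc = icc_agreement(estimates$reference, estimates$estimate)
    ),
    class = "osa_evaluation"
  )
}

#' @export
print.osa_evaluation <- function(x, ...) {
  cat(format_evaluation_text(x), sep = "\n")
  invisible(x)
}

format_evaluation_text <- function(x) {
  e <- x$errors
  m <- x$misclassified_errors
  lines <- c(
    sprintf("Evaluation of estimated %s (N = %d)", toupper(x$index), e$n),
    sprintf("  mean absolute error (events/hour)    %8.2f", e$mean_abs_error),
    sprintf("  median absolute error (events/hour)  %8.2f", e$median_abs_error),
    sprintf("  min error (events/hour)              %8.2f", e$min_error),
    sprintf("  max error (events/hour)              %8.2f", e$max_error),
    sprintf("  median %% error                       %8.1f", e$median_pct_error),
    sprintf("  severity accuracy                    %8.1f%% (%d/%d misclassified)",
            100 * x$accuracy, x$n_misclassified, e$n),
    sprintf("  ICC (95%% CI)                         %8.3f (%.3f-%.3f)",
            x$icc$icc, x$icc$ci_lower, x$icc$ci_upper)
  )
  if (!is.null(m)) {
    lines <- c(
      lines,
      sprintf("  misclassified: mean absolute error   %8.2f", m$mean_abs_error),
      sprintf("  misclassified: median absolute error %8.2f", m$median_abs_error),
      sprintf("  misclassified: median %% error        %8.1f", m$median_pct_error)
    )
  }
  conf <- x$confusion
  lines <- c(lines, "  confusion (rows = reference, cols = estimate):",
             utils::capture.output(print(conf)))
  lines
}
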