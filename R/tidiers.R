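#' Tidy a training history
#'
#' @param x An `scg_history` from [scg_train()].
#' @param ... Unused.
#' @return A tibble with one row per iteration: `iteration`, `train_mse`,
#'   `val_mse`, `lambda`, `step_accepted`.
#' @export
tidy.scg_history <- function(x, ...) x$iterations

#' @rdname tidy.scg_history
#' @return For `glance()`: a one-row summary with the iteration count, stop
#'   reason and best validation MSE.
#' @export
glance.scg_history <- function(x, ...) {
  tibble::tibble(
    n_iterations = nrow(x$iterations),
    best_iteration = x$best_iteration,
    best_val_mse = x$best_val_mse,
    final_train_mse = tail(x$iterations$train_mse, 1),
    stop_reason = x$stop_reason
  )
}

#' @export
glance.mlp_model <- function(x, ...) {
  tibble::tibble(
    architecture = paste(x$layer_sizes, collapse = "-"),
    n_parameters = n_params(x),
    output_activation = x$output_activation,
    normalized = !is.null(x$input_norm)
  )
}

#' Tidy an evaluation report
#'
#' @param x An `osa_evaluation` from [evaluate_estimates()].
#' @param ... Unused.
#' @return `tidy()` returns the error statistics in long form (`metric`,
#'   `value`); `glance()` a one-row cohort summary; `augment()` the
#'   per-patient estimate table.
#' @export
tidy.osa_evaluation <- function(x, ...) {
  e <- x$errors
  tibble::tibble(
    metric = c("mean_abs_error", "median_abs_error", "min_error", "max_error",
               "median_pct_error", "accuracy", "icc"),
    value = c(e$mean_abs_error, e$median_abs_error, e$min_error, e$max_error,
              e$median_pct_error, x$accuracy, x$icc$icc)
  )
}

#' @rdname tidy.osa_evaluation
#' @export
glance.osa_evaluation <- function(x, ...) {
  tibble::tibble(
    index = x$index,
    n = x$errors$n,
    median_abs_error = x$errors$median_abs_error,
    mean_abs_error = x$errors$mean_abs_error,
    accuracy = x$accuracy,
    n_misclassified = x$n_misclassified,
    icc = x$icc$icc,
    icc_ci_lower = x$icc$ci_lower,
    icc_ci_upper = x$icc$ci_upper
  )
}

#' @rdname tidy.osa_evaluation
#' @export
augment.osa_evaluation <- function(x, ...) x$estimates

#' @export
glance.osa_experiment <- function(x, ...) {
  dplyr::bind_rows(glance(x$evaluation$ahi), glance(x$evaluation$odi))
}
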