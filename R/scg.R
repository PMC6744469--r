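#' Training configuration
#'
#' @param max_iterations Hard iteration cap.
#' @param max_val_failures Consecutive iterations with validation MSE above
#'   its running best before training stops (early stopping; default 100).
#' @param sigma Scale of the finite-difference second-order estimate along
#'   the search direction (Moller's sigma, default 5e-5).
#' @param lambda0 Initial Levenberg-style scaling parameter (default 5e-7).
#' @param val_check_every Validate every this many iterations.
#' @param seed Seed (recorded for provenance; the optimizer itself is
#'   deterministic given the initial weights).
#' @return A `training_config` list.
#' @export
training_config <- function(max_iterations = 800L,
                            max_val_failures = 100L,
                            sigma = 5e-5,
                            lambda0 = 5e-7,
                            val_check_every = 1L,
                            seed = 1L) {
  stopifnot(max_iterations >= 1, max_val_failures >= 1,
            sigma > 0, lambda0 > 0, val_check_every >= 1)
  structure(
    list(max_iterations = as.integer(max_iterations),
         max_val_failures = as.integer(max_val_failures),
         sigma = sigma, lambda0 = lambda0,
         val_check_every = as.integer(val_check_every),
         seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Train a network by scaled conjugate gradient with early stopping
#'
#' Full-batch implementation of Moller's scaled conjugate gradient (SCG):
#' conjugate search directions, a second-order curvature estimate from a
#' finite difference of the gradient along the direction (scale `sigma`),
#' Levenberg-style adaptation of the scaling parameter `lambda`, and step
#' acceptance by the comparison parameter. After every iteration the
#' validation MSE is evaluated; when it has exceeded its running best for
#' `max_val_failures` consecutive checks, training stops and the parameters
#' with the best validation MSE seen are returned.
#'
#' @param model An `mlp_model` with fitted normalization (see
#'   [fit_normalization()]); its current weights are the starting point.
#' @param train_inputs,train_targets Training epochs (matrix) and index
#'   targets (events/hour).
#' @param val_inputs,val_targets Validation set in the same units.
#' @param config A [training_config()].
#' @return A list with `model` (best-validation parameters) and `history`
#'   (`scg_history`): per-iteration train/validation MSE, `lambda`, step
#'   success, plus `best_iteration` and `stop_reason`.
#' @export
scg_train <- function(model, train_inputs, train_targets,
                      val_inputs, val_targets,
                      config = training_config()) {
  stopifnot(inherits(model, "mlp_model"))
  if (is.null(model$input_norm) || is.null(model$target_norm)) {
    abort("Fit normalization before training (see fit_normalization()).")
  }
  if (!is.matrix(train_inputs) || nrow(train_inputs) == 0L ||
      !is.matrix(val_inputs) || nrow(val_inputs) == 0L) {
    abort("Training and validation sets must be non-empty matrices.")
  }

  Xn <- apply_norm(train_inputs, model$input_norm)
  tn <- matrix(apply_norm(train_targets, model$target_norm), ncol = 1L)
  Xv <- apply_norm(val_inputs, model$input_norm)
  tv <- matrix(apply_norm(val_targets, model$target_norm), ncol = 1L)

  obj <- function(w) {
    m <- unflatten_params(model, w)
    grad_normalized(m, Xn, tn)
  }
  val_mse <- function(w) {
    m <- unflatten_params(model, w)
    acts <- mlp_forward_cache(m, Xv)
    mean((acts[[length(acts)]] - tv)^2)
  }

  w <- flatten_params(model)
  N <- length(w)
  ev <- obj(w)
  E_w <- ev$loss
  g <- flatten_grad(ev$grad)
  r <- -g
  p <- r
  lambda <- config$lambda0
  lambda_bar <- 0
  success <- TRUE
  delta_base <- 0
  norm_p2 <- sum(p^2)

  best_val <- Inf
  best_w <- w
  best_iter <- 0L
  fails <- 0L
  stop_reason <- "max_iterations"

  hist_iter <- integer(0)
  hist_train <- hist_val <- hist_lambda <- numeric(0)
  hist_success <- logical(0)

  k <- 1L
  while (k <= config$max_iterations) {
    if (success) {
      norm_p2 <- sum(p^2)
      norm_p <- sqrt(norm_p2)
      if (norm_p < 1e-14) { stop_reason <- "converged"; break }
      sigma_k <- config$sigma / norm_p
      ev_s <- obj(w + sigma_k * p)
      s <- (flatten_grad(ev_s$grad) - g) / sigma_k
      delta_base <- sum(p * s)
    }
    delta <- delta_base + (lambda - lambda_bar) * norm_p2
    if (delta <= 0) {
      lambda_bar <- 2 * (lambda - delta / norm_p2)
      delta <- -delta + lambda * norm_p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    ev_new <- obj(w + alpha * p)
    if (!is.finite(ev_new$loss)) {
      abort(sprintf("Non-finite training loss at iteration %d.", k))
    }
    Delta <- 2 * delta * (E_w - ev_new$loss) / mu^2

    if (Delta >= 0) {
      w <- w + alpha * p
      E_w <- ev_new$loss
      g_new <- flatten_grad(ev_new$grad)
      r_new <- -g_new
      lambda_bar <- 0
      success <- TRUE
      if (k %% N == 0L) {
        p <- r_new
      } else {
        beta <- (sum(r_new^2) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      g <- g_new
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta * (1 - Delta) / norm_p2
    lambda <- min(lambda, 1e100)

    v <- if (k %% config$val_check_every == 0L) val_mse(w) else NA_real_
    if (!is.na(v) && !is.finite(v)) {
      abort(sprintf("Non-finite validation loss at iteration %d.", k))
    }
    hist_iter <- c(hist_iter, k)
    hist_train <- c(hist_train, E_w)
    hist_val <- c(hist_val, v)
    hist_lambda <- c(hist_lambda, lambda)
    hist_success <- c(hist_success, Delta >= 0)

    if (!is.na(v)) {
      if (v < best_val) {
        best_val <- v
        best_w <- w
        best_iter <- k
        fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails >= config$max_val_failures) {
          stop_reason <- "early_stopping"
          k <- k + 1L
          break
        }
      }
    }
    if (sum(r^2) < 1e-20) { stop_reason <- "converged"; k <- k + 1L; break }
    k <- k + 1L
  }

  if (!is.finite(best_val)) {  # no validation check ever ran
    best_w <- w
    best_iter <- length(hist_iter)
  }
  history <- structure(
    list(
      iterations = tibble::tibble(
        iteration = hist_iter,
        train_mse = hist_train,
        val_mse = hist_val,
        lambda = hist_lambda,
        step_accepted = hist_success
      ),
      best_iteration = best_iter,
      best_val_mse = best_val,
      stop_reason = stop_reason,
      config = config
    ),
    class = "scg_history"
  )
  list(model = unflatten_params(model, best_w), history = history)
}

#' @export
print.scg_history <- function(x, ...) {
  n <- nrow(x$iterations)
  cat(sprintf(
    "<scg_history> %d iterations, stopped by %s; best validation MSE %.4g at iteration %d\n",
    n, x$stop_reason, x$best_val_mse, x$best_iteration
  ))
  invisible(x)
}
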