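#' Initialize a feedforward regression network
#'
#' Builds the multilayer perceptron used for epoch-wise index regression:
#' the default architecture takes a 300-sample epoch through hidden layers of
#' 60, 15 and 5 units to a single output. Hidden layers use the symmetric
#' sigmoid `2 / (1 + exp(-2 z)) - 1` (identical to `tanh`); the output layer
#' is linear by default (regression convention), with a symmetric-sigmoid
#' alternative available. Weights are drawn uniformly on
#' `+/- sqrt(6 / (fan_in + fan_out))`, biases start at zero.
#'
#' @param layer_sizes Integer vector of layer widths, input first, output
#'   last; default `c(300, 60, 15, 5, 1)`.
#' @param seed Integer seed for the weight draw.
#' @param output_activation `"identity"` (default) or `"tanh"`.
#' @return An `mlp_model`: layer sizes, weight matrices (`out x in`), bias
#'   vectors, activation spec, and (once fitted) input/target normalization.
#' @examples
#' m <- init_model(c(4, 3, 1), seed = 1)
#' vapply(m$weights, dim, integer(2))
#' @export
init_model <- function(layer_sizes = c(300, 60, 15, 5, 1), seed = 1L,
                       output_activation = c("identity", "tanh")) {
  output_activation <- match.arg(output_activation)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1)) {
    abort("`layer_sizes` needs at least an input and an output size, all positive.")
  }
  layer_sizes <- as.integer(layer_sizes)
  n_layers <- length(layer_sizes) - 1L
  withr::with_seed(as.integer(seed), {
    weights <- vector("list", n_layers)
    biases <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      fan_in <- layer_sizes[l]
      fan_out <- layer_sizes[l + 1L]
      r <- sqrt(6 / (fan_in + fan_out))
      weights[[l]] <- matrix(runif(fan_out * fan_in, -r, r),
                             nrow = fan_out, ncol = fan_in)
      biases[[l]] <- numeric(fan_out)
    }
    structure(
      list(
        layer_sizes = layer_sizes,
        weights = weights,
        biases = biases,
        hidden_activation = "symmetric_sigmoid",
        output_activation = output_activation,
        input_norm = NULL,
        target_norm = NULL
      ),
      class = "mlp_model"
    )
  })
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf(
    "<mlp_model> %s, %d parameters, output: %s, normalization: %s\n",
    paste(x$layer_sizes, collapse = "-"),
    n_params(x),
    x$output_activation,
    if (is.null(x$input_norm)) "unfitted" else "fitted"
  ))
  invisible(x)
}

n_params <- function(model) {
  sum(vapply(model$weights, length, integer(1))) +
    sum(vapply(model$biases, length, integer(1)))
}

sym_sigmoid <- function(z) tanh(z)  # 2 / (1 + exp(-2 z)) - 1 == tanh(z)

#' Fit min-max normalization from training data
#'
#' Per-feature affine maps onto `[-1, 1]`, computed on training data only.
#' A constant feature (zero range) maps to 0 everywhere.
#'
#' @param train_inputs Numeric matrix, one row per epoch.
#' @param train_targets Numeric vector of per-epoch index targets.
#' @return A list with `input_norm` and `target_norm`, each holding `min` and
#'   `range` vectors.
#' @export
fit_normalization <- function(train_inputs, train_targets) {
  if (!is.matrix(train_inputs) || nrow(train_inputs) == 0L) {
    abort("`train_inputs` must be a non-empty matrix.")
  }
  if (length(train_targets) != nrow(train_inputs)) {
    abort("Row count of inputs and length of targets differ.")
  }
  lo <- apply(train_inputs, 2, min)
  hi <- apply(train_inputs, 2, max)
  t_lo <- min(train_targets)
  t_hi <- max(train_targets)
  list(
    input_norm = list(min = lo, range = hi - lo),
    target_norm = list(min = t_lo, range = t_hi - t_lo)
  )
}

apply_norm <- function(x, norm) {
  rng <- norm$range
  if (is.matrix(x)) {
    out <- sweep(x, 2, norm$min)
    out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
    out <- 2 * out - 1
    if (any(rng == 0)) out[, rng == 0] <- 0
    out
  } else {
    if (all(rng == 0)) return(rep(0, length(x)))
    2 * (x - norm$min) / rng - 1
  }
}

invert_norm <- function(xn, norm) {
  if (all(norm$range == 0)) return(rep(norm$min, length(xn)))
  (xn + 1) / 2 * norm$range + norm$min
}

# Forward pass on a normalized input matrix; returns activations per layer.
mlp_forward_cache <- function(model, Xn) {
  n_layers <- length(model$weights)
  acts <- vector("list", n_layers + 1L)
  acts[[1L]] <- Xn
  for (l in seq_len(n_layers)) {
    z <- tcrossprod(acts[[l]], model$weights[[l]])
    z <- sweep(z, 2, model$biases[[l]], "+")
    acts[[l + 1L]] <- if (l < n_layers || model$output_activation == "tanh") {
      sym_sigmoid(z)
    } else {
      z
    }
  }
  acts
}

#' Predict per-epoch indices
#'
#' Runs the forward pass `y = denorm(W4 s(W3 s(W2 s(W1 x + b1) + b2) + b3)
#' + b4)` on min-max-normalized epochs and maps the output back to
#' events/hour. Negative outputs are clamped to zero at prediction time — an
#' event index cannot be negative.
#'
#' @param object A fitted `mlp_model` (normalization present).
#' @param newdata Matrix of epochs (rows) or a single epoch vector, in raw
#'   saturation percent.
#' @param clamp Clamp negative predictions to zero (default `TRUE`).
#' @param ... Unused.
#' @return Numeric vector of index estimates, events/hour.
#' @export
predict.mlp_model <- function(object, newdata, clamp = TRUE, ...) {
  if (is.null(object$input_norm)) {
    abort("Model has no fitted normalization; train it or attach one first.")
  }
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != object$layer_sizes[1L]) {
    abort(sprintf("Epoch length %d does not match the network input size %d.",
                  ncol(newdata), object$layer_sizes[1L]))
  }
  Xn <- apply_norm(newdata, object$input_norm)
  acts <- mlp_forward_cache(object, Xn)
  yn <- drop(acts[[length(acts)]])
  y <- invert_norm(yn, object$target_norm)
  if (clamp) y <- pmax(y, 0)
  y
}

#' Mean squared error of a model on a batch
#'
#' Computed in normalized target space (the space the optimizer sees).
#'
#' @param model A fitted `mlp_model`.
#' @param inputs Epoch matrix in raw saturation percent.
#' @param targets Index targets in events/hour.
#' @return Scalar MSE.
#' @export
mse_loss <- function(model, inputs, targets) {
  if (!is.matrix(inputs)) inputs <- matrix(inputs, nrow = 1L)
  if (nrow(inputs) == 0L) abort("Empty batch.")
  if (nrow(inputs) != length(targets)) abort("Input/target row mismatch.")
  Xn <- apply_norm(inputs, model$input_norm)
  tn <- apply_norm(targets, model$target_norm)
  acts <- mlp_forward_cache(model, Xn)
  yn <- drop(acts[[length(acts)]])
  mean((yn - tn)^2)
}

#' Exact MSE gradient by reverse-mode backpropagation
#'
#' @inheritParams mse_loss
#' @return List with `weights` and `biases`: gradients matching the model's
#'   parameter shapes, in normalized space.
#' @export
backprop_gradient <- function(model, inputs, targets) {
  if (!is.matrix(inputs)) inputs <- matrix(inputs, nrow = 1L)
  if (nrow(inputs) == 0L) abort("Empty batch.")
  if (nrow(inputs) != length(targets)) abort("Input/target row mismatch.")
  Xn <- apply_norm(inputs, model$input_norm)
  tn <- apply_norm(targets, model$target_norm)
  grad_normalized(model, Xn, tn)$grad
}

# Core gradient in normalized space; returns loss and gradient lists.
grad_normalized <- function(model, Xn, tn) {
  n <- nrow(Xn)
  n_layers <- length(model$weights)
  acts <- mlp_forward_cache(model, Xn)
  yn <- acts[[n_layers + 1L]]
  err <- yn - tn            # n x 1
  loss <- mean(err^2)
  delta <- 2 * err / n      # dE/dy for linear output
  if (model$output_activation == "tanh") {
    delta <- delta * (1 - yn^2)
  }
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    gW[[l]] <- crossprod(delta, acts[[l]])     # out x in
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% model$weights[[l]]) * (1 - acts[[l]]^2)
    }
  }
  list(loss = loss, grad = list(weights = gW, biases = gb))
}

# Identity normalization: network inputs/outputs equal raw values. Used for
# small algebraic test problems where scaling would only obscure the algebra.
attach_identity_norm <- function(model) {
  p <- model$layer_sizes[1L]
  model$input_norm <- list(min = rep(-1, p), range = rep(2, p))
  model$target_norm <- list(min = -1, range = 2)
  model
}

# --- flat parameter vector helpers (optimizer interface) -------------------

flatten_params <- function(model) {
  unlist(c(purrr::map(model$weights, as.numeric),
           purrr::map(model$biases, as.numeric)), use.names = FALSE)
}

unflatten_params <- function(model, w) {
  pos <- 0L
  for (l in seq_along(model$weights)) {
    k <- length(model$weights[[l]])
    model$weights[[l]][] <- w[pos + seq_len(k)]
    pos <- pos + k
  }
  for (l in seq_along(model$biases)) {
    k <- length(model$biases[[l]])
    model$biases[[l]] <- w[pos + seq_len(k)]
    pos <- pos + k
  }
  model
}

flatten_grad <- function(g) {
  unlist(c(purrr::map(g$weights, as.numeric),
           purrr::map(g$biases, as.numeric)), use.names = FALSE)
}

# --- serialization ---------------------------------------------------------

#' Save / load a network as portable JSON
#'
#' The container is a versioned JSON document: layout, activations and
#' normalization in the header, parameters as base64-encoded little-endian
#' doubles so that a save/load round trip is bit-exact.
#'
#' @param model A fitted or unfitted `mlp_model`.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the `mlp_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  enc <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = 8, endian = "little"))
  doc <- list(
    schema = "oxinet-mlp/1",
    layer_sizes = model$layer_sizes,
    hidden_activation = model$hidden_activation,
    output_activation = model$output_activation,
    weights = purrr::map(model$weights, enc),
    biases = purrr::map(model$biases, enc),
    input_norm = if (!is.null(model$input_norm)) {
      list(min = enc(model$input_norm$min), range = enc(model$input_norm$range))
    },
    target_norm = if (!is.null(model$target_norm)) {
      list(min = enc(model$target_norm$min),
           range = enc(model$target_norm$range))
    }
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "oxinet-mlp/1")) {
    abort(sprintf("Unsupported model schema: %s", doc$schema %||% "<none>"))
  }
  dec <- function(s) readBin(jsonlite::base64_dec(s), "numeric",
                             n = 1e7, size = 8, endian = "little")
  sizes <- as.integer(doc$layer_sizes)
  n_layers <- length(sizes) - 1L
  weights <- vector("list", n_layers)
  biases <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    weights[[l]] <- matrix(dec(doc$weights[[l]]),
                           nrow = sizes[l + 1L], ncol = sizes[l])
    biases[[l]] <- dec(doc$biases[[l]])
  }
  norm_or_null <- function(nd) {
    if (is.null(nd)) NULL else list(min = dec(nd$min), range = dec(nd$range))
  }
  structure(
    list(
      layer_sizes = sizes,
      weights = weights,
      biases = biases,
      hidden_activation = doc$hidden_activation,
      output_activation = doc$output_activation,
      input_norm = norm_or_null(doc$input_norm),
      target_norm = norm_or_null(doc$target_norm)
    ),
    class = "mlp_model"
  )
}
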