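test_that("initialization is reproducible and correctly shaped", {
  a <- init_model(c(300, 60, 15, 5, 1), seed = 1)
  b <- init_model(c(300, 60, 15, 5, 1), seed = 1)
  c <- init_model(c(300, 60, 15, 5, 1), seed = 2)
  expect_identical(a$weights, b$weights)
  expect_false(identical(a$weights, c$weights))
  expect_equal(
    lapply(a$weights, dim),
    list(c(60L, 300L), c(15L, 60L), c(5L, 15L), c(1L, 5L))
  )
  expect_true(all(vapply(a$biases, function(x) all(x == 0), logical(1))))
  # bounded scaled-uniform draw
  r <- sqrt(6 / (300 + 60))
  expect_true(all(abs(a$weights[[1]]) <= r))
  expect_error(init_model(integer(0)), "layer")
})

test_that("the forward pass is linear-consistent and deterministic", {
  m <- oxinet:::attach_identity_norm(init_model(c(4, 3, 1), seed = 1))
  for (l in seq_along(m$weights)) m$weights[[l]][] <- 0
  expect_equal(predict(m, matrix(rnorm(8), 2, 4), clamp = FALSE), c(0, 0))

  m2 <- oxinet:::attach_identity_norm(init_model(c(6, 4, 1), seed = 3))
  X <- matrix(rnorm(30), 5, 6)
  batch <- predict(m2, X, clamp = FALSE)
  single <- vapply(1:5, function(i) predict(m2, X[i, ], clamp = FALSE),
                   numeric(1))
  expect_equal(batch, single)
  expect_error(predict(m2, matrix(0, 1, 5)), "input size")
})

test_that("mse_loss matches an independent recomputation from predictions", {
  m <- oxinet:::attach_identity_norm(init_model(c(3, 5, 1), seed = 2))
  X <- matrix(rnorm(21), 7, 3)
  t <- rnorm(7)
  preds <- predict(m, X, clamp = FALSE)
  expect_equal(mse_loss(m, X, t), mean((preds - t)^2), tolerance = 1e-12)

  # zero error and the single-sample case
  expect_equal(mse_loss(m, X, preds), 0)
  z <- m
  for (l in seq_along(z$weights)) { z$weights[[l]][] <- 0; z$biases[[l]][] <- 0 }
  expect_equal(mse_loss(z, matrix(0, 1, 3), 2), 4)   # error 2 -> squared 4
  expect_error(mse_loss(m, X[0, , drop = FALSE], numeric(0)), "Empty")
})

test_that("backprop gradients match central finite differences", {
  withr::with_seed(31, {
    for (i in 1:5) {
      sizes <- c(sample(3:6, 1), sample(2:5, 1), sample(2:4, 1), 1)
      m <- oxinet:::attach_identity_norm(init_model(sizes, seed = i))
      X <- matrix(rnorm(8 * sizes[1]), 8, sizes[1])
      t <- rnorm(8)
      g <- oxinet:::flatten_grad(backprop_gradient(m, X, t))
      expect_lt(max_rel_err(g, fd_gradient(m, X, t)), 1e-6)
    }
  })
})

test_that("a linear single-layer gradient equals the normal-equation form", {
  m <- oxinet:::attach_identity_norm(init_model(c(4, 1), seed = 5))
  X <- matrix(rnorm(40), 10, 4)
  t <- rnorm(10)
  g <- backprop_gradient(m, X, t)
  w <- drop(m$weights[[1]])
  resid <- drop(X %*% w) + m$biases[[1]] - t
  expect_equal(drop(g$weights[[1]]), drop(2 * crossprod(X, resid) / 10),
               tolerance = 1e-12)
  expect_equal(g$biases[[1]], 2 * mean(resid), tolerance = 1e-12)

  # zero-error batch sits at a stationary point
  t_exact <- drop(X %*% w) + m$biases[[1]]
  g0 <- oxinet:::flatten_grad(backprop_gradient(m, X, t_exact))
  expect_true(all(abs(g0) < 1e-14))
})

test_that("min-max normalization maps to [-1, 1] and inverts exactly", {
  X <- cbind(runif(20, 80, 100), rep(97, 20))
  t <- runif(20, 0, 150)
  norms <- fit_normalization(X, t)
  Xn <- oxinet:::apply_norm(X, norms$input_norm)
  expect_true(all(Xn >= -1 & Xn <= 1))
  expect_true(all(Xn[, 2] == 0))               # constant feature -> 0
  expect_equal(oxinet:::apply_norm(90, list(min = 80, range = 20)), 0)
  tn <- oxinet:::apply_norm(t, norms$target_norm)
  expect_equal(oxinet:::invert_norm(tn, norms$target_norm), t,
               tolerance = 1e-12)
  expect_error(fit_normalization(X[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("SCG reaches the least-squares solution of a linear problem", {
  withr::with_seed(7, {
    X <- matrix(rnorm(200 * 6), 200, 6)
    beta <- rnorm(6)
    y <- drop(X %*% beta) + 0.05 * rnorm(200)
  })
  m <- oxinet:::attach_identity_norm(init_model(c(6, 1), seed = 1))
  fit <- scg_train(m, X, y, X, y, training_config(max_iterations = 200))
  ls <- qr.solve(cbind(1, X), y)
  got <- c(fit$model$biases[[1]], drop(fit$model$weights[[1]]))
  expect_lt(max(abs(got - ls)), 1e-6)
})

test_that("best-so-far training MSE is monotone when validating on the train set", {
  withr::with_seed(12, {
    teacher <- oxinet:::attach_identity_norm(init_model(c(2, 3, 1), seed = 99))
    X <- matrix(rnorm(100 * 2), 100, 2)
    y <- predict(teacher, X, clamp = FALSE)
  })
  m <- oxinet:::attach_identity_norm(init_model(c(2, 6, 1), seed = 4))
  fit <- scg_train(m, X, y, X, y, training_config(max_iterations = 150))
  best_so_far <- cummin(fit$history$iterations$train_mse)
  expect_true(all(diff(best_so_far) <= 0))
  # with val == train, the returned model minimizes the training MSE seen
  expect_equal(mse_loss(fit$model, X, y), min(fit$history$iterations$val_mse),
               tolerance = 1e-10)
})

test_that("early stopping returns exactly the best-validation iterate", {
  # small noisy training set, clean wider validation set: validation MSE
  # turns upward once the network starts fitting noise
  withr::with_seed(13, {
    teacher <- oxinet:::attach_identity_norm(init_model(c(3, 4, 1), seed = 50))
    Xtr <- matrix(rnorm(25 * 3), 25, 3)
    ytr <- predict(teacher, Xtr, clamp = FALSE) + rnorm(25, 0, 0.3)
    Xv <- matrix(rnorm(200 * 3), 200, 3)
    yv <- predict(teacher, Xv, clamp = FALSE)
  })
  m <- oxinet:::attach_identity_norm(init_model(c(3, 20, 1), seed = 6))
  cfg <- training_config(max_iterations = 3000, max_val_failures = 40)
  fit <- scg_train(m, Xtr, ytr, Xv, yv, cfg)
  h <- fit$history
  expect_equal(h$stop_reason, "early_stopping")
  expect_equal(nrow(h$iterations), h$best_iteration + 40)
  expect_equal(h$best_iteration, which.min(h$iterations$val_mse))
  expect_equal(mse_loss(fit$model, Xv, yv), min(h$iterations$val_mse),
               tolerance = 1e-12)
})

test_that("model serialization round-trips bit-exactly", {
  m <- init_model(c(10, 4, 1), seed = 8)
  norms <- fit_normalization(matrix(runif(50, 80, 100), 5, 10), runif(5, 0, 60))
  m$input_norm <- norms$input_norm
  m$target_norm <- norms$target_norm
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(oxinet:::flatten_params(m), oxinet:::flatten_params(m2))
  expect_identical(m$input_norm$min, m2$input_norm$min)
  expect_identical(m$target_norm$range, m2$target_norm$range)
  X <- matrix(runif(30, 80, 100), 3, 10)
  expect_identical(predict(m, X), predict(m2, X))
})
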