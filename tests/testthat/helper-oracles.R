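# Independent oracles used across the suite. These deliberately re-derive
# results by the most naive route available (exhaustive scans, finite
# differences, explicit ANOVA tables) and never call the code paths they
# check.

# Naive desaturation scan: walks the trace sample by sample, recomputing the
# trailing-window baseline by an explicit scan at every step, and applies the
# open/nadir/close/backtrack definition literally.
oracle_detect <- function(x, fs, min_drop = 4, baseline_window_s = 120,
                          recovery_margin = 1, timeout_s = 300) {
  n <- length(x)
  w <- round(baseline_window_s * fs)
  timeout_n <- round(timeout_s * fs)
  out <- data.frame(onset_s = numeric(), nadir_s = numeric(),
                    depth = numeric(), duration_s = numeric())
  i <- 1
  while (i <= n) {
    b <- NA_real_
    if (i > 1) {
      win <- x[max(1, i - w):(i - 1)]
      if (!all(is.na(win))) b <- max(win, na.rm = TRUE)
    }
    if (is.na(x[i]) || is.na(b) || x[i] > b - min_drop) {
      i <- i + 1
      next
    }
    open_i <- i
    nadir_i <- i
    nadir_v <- x[i]
    j <- i + 1
    while (j <= n) {
      if (is.na(x[j]) || (j - open_i) >= timeout_n) break
      if (x[j] >= b - recovery_margin) break
      if (x[j] < nadir_v) {
        nadir_v <- x[j]
        nadir_i <- j
      }
      j <- j + 1
    }
    depth <- b - nadir_v
    if (depth >= min_drop) {
      k <- open_i
      while (k > 1 && !is.na(x[k - 1]) && x[k - 1] < b - recovery_margin) {
        k <- k - 1
      }
      onset_i <- if (k > 1 && !is.na(x[k - 1])) k - 1 else k
      out <- rbind(out, data.frame(
        onset_s = (onset_i - 1) / fs,
        nadir_s = (nadir_i - 1) / fs,
        depth = depth,
        duration_s = (min(j, n) - 1) / fs - (onset_i - 1) / fs
      ))
    }
    i <- max(j, i + 1)
  }
  # merge overlapping spans, keeping the deepest nadir
  if (nrow(out) >= 2) {
    keep <- rep(TRUE, nrow(out))
    for (i in 2:nrow(out)) {
      prev <- max(which(keep[1:(i - 1)]))
      if (out$onset_s[i] < out$onset_s[prev] + out$duration_s[prev]) {
        end_i <- out$onset_s[i] + out$duration_s[i]
        out$duration_s[prev] <- max(out$onset_s[prev] + out$duration_s[prev],
                                    end_i) - out$onset_s[prev]
        if (out$depth[i] > out$depth[prev]) {
          out$depth[prev] <- out$depth[i]
          out$nadir_s[prev] <- out$nadir_s[i]
        }
        keep[i] <- FALSE
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  out
}

# Random oximetry-like short trace: noisy plateau with a few planted plunges
# and occasional dropouts, integer-quantized like a real oximeter.
random_trace <- function(len_s = 240, fs = 1) {
  n <- len_s * fs
  base <- sample(92:98, 1)
  x <- base + cumsum(rnorm(n, 0, 0.3)) * 0.2
  for (d in seq_len(sample(0:3, 1))) {
    at <- sample(seq_len(n - 20), 1)
    depth <- runif(1, 2, 9)
    width <- sample(8:30, 1)
    idx <- at:min(n, at + width)
    shape <- sin(seq(0, pi, length.out = length(idx)))
    x[idx] <- x[idx] - depth * shape
  }
  x <- round(pmin(pmax(x, 1), 100))
  if (runif(1) < 0.3) {
    at <- sample(n, 1)
    x[at:min(n, at + sample(3:10, 1))] <- NA
  }
  x
}

# Central finite-difference gradient of the model's MSE in normalized space.
fd_gradient <- function(model, X, t, h = 1e-6) {
  w <- oxinet:::flatten_params(model)
  f <- function(wv) mse_loss(oxinet:::unflatten_params(model, wv), X, t)
  vapply(seq_along(w), function(i) {
    e <- numeric(length(w))
    e[i] <- h
    (f(w + e) - f(w - e)) / (2 * h)
  }, numeric(1))
}

max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b) / pmax(abs(a), abs(b), floor))
}

# Greedy one-to-one onset matching within a tolerance; returns the count of
# matched pairs.
match_onsets <- function(truth, detected, tol_s = 10) {
  used <- rep(FALSE, length(detected))
  matched <- 0L
  for (t0 in truth) {
    d <- abs(detected - t0)
    d[used] <- Inf
    if (length(d) && min(d) <= tol_s) {
      used[which.min(d)] <- TRUE
      matched <- matched + 1L
    }
  }
  matched
}

# Profile constructor for hand-built simulation scenarios.
test_profile <- function(target_ahi = 20, recording_duration_s = 3600,
                         noise_sd = 0.4, artifact_rate = 0.5,
                         desat_yield = 0.9, apnea_fraction = 0.2,
                         baseline_spo2 = 96.5, desat_depth_mean = 6,
                         desat_depth_sd = 1.5,
                         event_duration_s = min(45, max(12.5, 0.5 * 3600 / max(target_ahi, 1))),
                         resat_duration_s = 20, record_seed = 1L) {
  tibble::tibble(
    patient_id = "T0001",
    target_ahi = target_ahi,
    apnea_fraction = apnea_fraction,
    desat_yield = desat_yield,
    baseline_spo2 = baseline_spo2,
    desat_depth_mean = desat_depth_mean,
    desat_depth_sd = desat_depth_sd,
    event_duration_s = event_duration_s,
    resat_duration_s = resat_duration_s,
    noise_sd = noise_sd,
    artifact_rate = artifact_rate,
    recording_duration_s = recording_duration_s,
    record_seed = record_seed
  )
}

# Micro experiment config for pipeline/reproducibility tests.
micro_config <- function(seed = 11L, max_iterations = 25L) {
  experiment_config(
    n_train = 6L, n_val = 2L, n_test = 3L,
    recording_duration_s = 1200,
    train_thin = 6L,
    training = training_config(max_iterations = max_iterations,
                               max_val_failures = 100L, seed = seed),
    seed = seed
  )
}
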