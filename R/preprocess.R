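#' Downsample an SpO2 record by block averaging
#'
#' Decimates the trace from `record$fs` to `target_fs` by taking the mean of
#' each consecutive block of `fs / target_fs` samples. Block averaging doubles
#' as the anti-alias step and smooths oximeter quantization noise. Any block
#' containing an invalid sample is itself invalid (`NA`): artifacts propagate
#' rather than silently averaging away.
#'
#' @param record An [spo2_record()].
#' @param target_fs Target sampling frequency in Hz; `record$fs` must be an
#'   integer multiple of it.
#' @return An [spo2_record()] at `target_fs`.
#' @examples
#' rec <- spo2_record(rep(97, 2400), fs = 4)
#' downsample(rec, 0.5)
#' @export
downsample <- function(record, target_fs = 0.5) {
  stopifnot(inherits(record, "spo2_record"))
  ratio <- record$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort(sprintf(
      "Cannot decimate %g Hz to %g Hz: the ratio %.6g is not an integer.",
      record$fs, target_fs, ratio
    ))
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(record)
  n_out <- length(record$samples) %/% ratio
  x <- record$samples[seq_len(n_out * ratio)]
  m <- matrix(x, nrow = ratio)
  out <- colMeans(m)  # NA block -> NA output, by design
  spo2_record(out, fs = target_fs)
}

#' Split a record into overlapping fixed-length epochs
#'
#' Tiles the record from `t = 0` with windows of `window_s` seconds advancing
#' by `window_s * (1 - overlap)` (the stride; 12 s for the default 10-minute
#' window with 98% overlap). A trailing partial window is discarded so every
#' epoch has exactly `window_s * fs` samples — the fixed input dimension the
#' network requires. Epochs whose invalid-sample fraction exceeds
#' `invalid_threshold` are flagged invalid; invalid samples inside valid
#' epochs are filled by linear interpolation so that the matrix is complete.
#'
#' @param record An [spo2_record()] (typically already downsampled to 0.5 Hz).
#' @param window_s Epoch length in seconds.
#' @param overlap Fractional overlap between consecutive epochs, in `[0, 1)`.
#' @param invalid_threshold Maximum tolerated invalid-sample fraction per
#'   epoch before the epoch is dropped from the valid mask.
#' @return An `epoch_set`: list with `epochs` (matrix, one row per epoch),
#'   `epoch_start_s`, `valid_mask`, `fs`, `window_s`, `stride_s`,
#'   and optional `target_ahi` / `target_odi` filled by
#'   [compute_epoch_targets()].
#' @examples
#' rec <- spo2_record(rep(96, 1800), fs = 0.5)   # one hour at 0.5 Hz
#' es <- epoch_signal(rec)
#' nrow(es$epochs)   # floor((3600 - 600) / 12) + 1 = 251
#' @export
epoch_signal <- function(record, window_s = 600, overlap = 0.98,
                         invalid_threshold = 0.1) {
  stopifnot(inherits(record, "spo2_record"))
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1).")
  stride_s <- window_s * (1 - overlap)
  n_win <- round(window_s * record$fs)
  n_stride <- stride_s * record$fs
  if (abs(n_stride - round(n_stride)) > 1e-9) {
    abort("Stride is not a whole number of samples at this sampling rate.")
  }
  n_stride <- as.integer(round(n_stride))
  if (record$duration_s < window_s) {
    abort(sprintf(
      "Record of %.0f s is shorter than one %.0f s window.",
      record$duration_s, window_s
    ))
  }
  n_epochs <- floor((record$duration_s - window_s) / stride_s + 1e-9) + 1
  starts <- (seq_len(n_epochs) - 1L) * n_stride
  idx <- outer(starts, seq_len(n_win), `+`)
  epochs <- matrix(record$samples[idx], nrow = n_epochs)
  invalid_frac <- rowMeans(is.na(epochs))
  valid_mask <- invalid_frac <= invalid_threshold
  if (anyNA(epochs)) {
    for (i in which(valid_mask & invalid_frac > 0)) {
      epochs[i, ] <- zoo::na.approx(epochs[i, ], na.rm = FALSE, rule = 2)
    }
  }
  structure(
    list(
      epochs = epochs,
      epoch_start_s = starts / record$fs,
      valid_mask = valid_mask,
      fs = record$fs,
      window_s = window_s,
      stride_s = stride_s,
      target_ahi = NULL,
      target_odi = NULL,
      record_id = NULL
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d epochs x %d samples (window %g s, stride %g s, fs %g Hz), %d invalid\n",
    nrow(x$epochs), ncol(x$epochs), x$window_s, x$stride_s, x$fs,
    sum(!x$valid_mask)
  ))
  if (!is.null(x$target_ahi)) cat("  per-epoch AHI targets attached\n")
  if (!is.null(x$target_odi)) cat("  per-epoch ODI targets attached\n")
  invisible(x)
}

#' Attach per-epoch AHI/ODI targets from an annotation
#'
#' The target of an epoch is `6 x` the number of relevant event onsets falling
#' in `[start, start + window_s)`, i.e. the count scaled to events/hour for a
#' 10-minute window. An event whose onset lies inside several overlapping
#' windows contributes to each of them. AHI targets count apneas and
#' hypopneas; ODI targets count desaturations.
#'
#' @param epoch_set An `epoch_set` from [epoch_signal()].
#' @param events Annotation tibble (`kind`, `onset_s`, `duration_s`).
#' @param kind `"ahi"` or `"odi"`.
#' @return The `epoch_set` with `target_ahi` or `target_odi` filled.
#' @export
compute_epoch_targets <- function(epoch_set, events, kind = c("ahi", "odi")) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  kind <- match.arg(kind)
  events <- validate_annotation(events)
  relevant <- if (kind == "ahi") {
    events$onset_s[events$kind %in% c("apnea", "hypopnea")]
  } else {
    events$onset_s[events$kind == "desaturation"]
  }
  starts <- epoch_set$epoch_start_s
  win <- epoch_set$window_s
  per_hour <- 3600 / win
  counts <- vapply(starts, function(s) {
    sum(relevant >= s & relevant < s + win)
  }, numeric(1))
  epoch_set[[paste0("target_", kind)]] <- counts * per_hour
  epoch_set
}

#' Pool epoch sets from several records into one training set
#'
#' Concatenates per-record epoch sets, keeping record provenance, dropping
#' invalid epochs, and optionally thinning the 98%-overlap windows (keeping
#' every `thin`-th epoch) to control the size of the pooled design matrix —
#' neighbouring 12 s-strided windows are nearly identical, so thinning costs
#' little information.
#'
#' @param epoch_sets List of `epoch_set` objects with targets attached.
#' @param record_ids Character vector of record identifiers (same length).
#' @param thin Keep every `thin`-th valid epoch of each record (1 = keep all).
#' @return A list with `inputs` (matrix), `target_ahi`, `target_odi`,
#'   `record_id`, `epoch_start_s`.
#' @export
pool_training_epochs <- function(epoch_sets, record_ids = NULL, thin = 1L) {
  if (!length(epoch_sets)) abort("No epoch sets to pool.")
  if (is.null(record_ids)) record_ids <- as.character(seq_along(epoch_sets))
  if (length(record_ids) != length(epoch_sets)) {
    abort(sprintf("%d epoch sets but %d record ids.",
                  length(epoch_sets), length(record_ids)))
  }
  thin <- max(1L, as.integer(thin))
  pieces <- purrr::map2(epoch_sets, record_ids, function(es, id) {
    stopifnot(inherits(es, "epoch_set"))
    keep <- which(es$valid_mask)
    keep <- keep[seq(1L, length(keep), by = thin)]
    list(
      inputs = es$epochs[keep, , drop = FALSE],
      target_ahi = if (!is.null(es$target_ahi)) es$target_ahi[keep],
      target_odi = if (!is.null(es$target_odi)) es$target_odi[keep],
      record_id = rep(id, length(keep)),
      epoch_start_s = es$epoch_start_s[keep]
    )
  })
  list(
    inputs = do.call(rbind, purrr::map(pieces, "inputs")),
    target_ahi = unlist(purrr::map(pieces, "target_ahi"), use.names = FALSE),
    target_odi = unlist(purrr::map(pieces, "target_odi"), use.names = FALSE),
    record_id = unlist(purrr::map(pieces, "record_id"), use.names = FALSE),
    epoch_start_s = unlist(purrr::map(pieces, "epoch_start_s"),
                           use.names = FALSE)
  )
}

# Record -> ready epoch_set at the network's input rate, with both targets.
prepare_record <- function(record, events = NULL, target_fs = 0.5,
                           window_s = 600, overlap = 0.98,
                           invalid_threshold = 0.1) {
  ds <- if (record$fs == target_fs) record else downsample(record, target_fs)
  es <- epoch_signal(ds, window_s = window_s, overlap = overlap,
                     invalid_threshold = invalid_threshold)
  if (!is.null(events)) {
    es <- compute_epoch_targets(es, events, "ahi")
    es <- compute_epoch_targets(es, events, "odi")
  }
  es
}
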