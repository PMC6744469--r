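#' Detect oxygen desaturation events
#'
#' Sliding-baseline detector in the spirit of the AASM 2007 4% rule: the
#' baseline at each sample is the maximum valid saturation over the preceding
#' `baseline_window_s` seconds; a candidate event opens when the signal falls
#' at least `min_drop` percentage points below baseline, its nadir is the
#' minimum before recovery, and it closes when the signal returns to within
#' `recovery_margin` points of the opening baseline or after `timeout_s`
#' seconds. The reported onset is backtracked from the threshold crossing to
#' the last sample within `recovery_margin` of baseline, i.e. the shoulder
#' where the decline began. Invalid (`NA`) samples terminate a candidate;
#' candidates whose depth never reaches `min_drop` are discarded.
#'
#' The 4 means four percentage points of saturation (absolute), not a 4%
#' relative drop. Setting `min_drop = 3` gives the AASM 2012 variant.
#'
#' @param record An [spo2_record()].
#' @param min_drop Minimum depth below baseline, percentage points.
#' @param baseline_window_s Length of the trailing baseline window, seconds.
#' @param recovery_margin Closing criterion: within this many points of the
#'   baseline, percentage points.
#' @param timeout_s Maximum event duration before forced closure, seconds.
#' @return A tibble of events: `onset_s`, `nadir_s`, `depth`, `duration_s`.
#' @examples
#' x <- rep(97, 600); x[200:230] <- 92
#' detect_desaturations(spo2_record(x, fs = 1))
#' @export
detect_desaturations <- function(record, min_drop = 4,
                                 baseline_window_s = 120,
                                 recovery_margin = 1,
                                 timeout_s = 300) {
  stopifnot(inherits(record, "spo2_record"), min_drop > 0)
  x <- record$samples
  fs <- record$fs
  if (all(is.na(x))) abort("Record contains no valid samples.")
  n <- length(x)
  w <- as.integer(round(baseline_window_s * fs))
  timeout_n <- as.integer(round(timeout_s * fs))

  # baseline[i] = max valid sample over the w samples strictly before i
  lagged <- c(NA_real_, x[-n])
  baseline <- zoo::rollapplyr(
    lagged, width = w,
    FUN = function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE),
    partial = TRUE, fill = NA
  )

  events <- list()
  i <- 1L
  while (i <= n) {
    b <- baseline[i]
    if (is.na(x[i]) || is.na(b) || x[i] > b - min_drop) {
      i <- i + 1L
      next
    }
    # candidate opens at i against frozen baseline b
    open_i <- i
    nadir_i <- i
    nadir_v <- x[i]
    j <- i + 1L
    closed <- FALSE
    while (j <= n) {
      if (is.na(x[j]) || (j - open_i) >= timeout_n) { closed <- TRUE; break }
      if (x[j] >= b - recovery_margin) { closed <- TRUE; break }
      if (x[j] < nadir_v) { nadir_v <- x[j]; nadir_i <- j }
      j <- j + 1L
    }
    depth <- b - nadir_v
    if (depth >= min_drop) {
      # backtrack onset to the shoulder: last sample near baseline before open
      k <- open_i
      while (k > 1L && !is.na(x[k - 1L]) && x[k - 1L] < b - recovery_margin) {
        k <- k - 1L
      }
      onset_i <- if (k > 1L && !is.na(x[k - 1L])) k - 1L else k
      events[[length(events) + 1L]] <- c(
        onset = (onset_i - 1L) / fs,
        nadir = (nadir_i - 1L) / fs,
        depth = depth,
        end = (min(j, n) - 1L) / fs
      )
    }
    i <- max(j, i + 1L)
  }

  if (!length(events)) {
    return(tibble::tibble(onset_s = numeric(), nadir_s = numeric(),
                          depth = numeric(), duration_s = numeric()))
  }
  m <- do.call(rbind, events)
  out <- tibble::tibble(
    onset_s = unname(m[, "onset"]),
    nadir_s = unname(m[, "nadir"]),
    depth = unname(m[, "depth"]),
    duration_s = unname(m[, "end"] - m[, "onset"])
  )
  # merge candidates whose spans overlap (can arise from backtracked onsets)
  merge_overlapping_events(out)
}

merge_overlapping_events <- function(ev) {
  if (nrow(ev) < 2L) return(ev)
  keep <- rep(TRUE, nrow(ev))
  for (i in 2:nrow(ev)) {
    prev <- max(which(keep[1:(i - 1)]))
    if (ev$onset_s[i] < ev$onset_s[prev] + ev$duration_s[prev]) {
      # absorb into previous: extend span, keep deepest nadir
      end_i <- ev$onset_s[i] + ev$duration_s[i]
      ev$duration_s[prev] <- max(ev$onset_s[prev] + ev$duration_s[prev],
                                 end_i) - ev$onset_s[prev]
      if (ev$depth[i] > ev$depth[prev]) {
        ev$depth[prev] <- ev$depth[i]
        ev$nadir_s[prev] <- ev$nadir_s[i]
      }
      keep[i] <- FALSE
    }
  }
  ev[keep, , drop = FALSE]
}

#' Events-per-hour index
#'
#' @param events Number of events (count).
#' @param duration_s Recording duration in seconds (> 0).
#' @return `3600 * events / duration_s`, in events/hour.
#' @examples
#' compute_index(240, 28800)   # 30 events/hour
#' @export
compute_index <- function(events, duration_s) {
  if (any(duration_s <= 0)) abort("`duration_s` must be > 0.")
  if (any(events < 0)) abort("`events` must be a non-negative count.")
  3600 * events / duration_s
}

#' OSA severity from an AHI or ODI value
#'
#' Standard four-class scheme with left-closed intervals: no OSA below 5,
#' mild in `[5, 15)`, moderate in `[15, 30)`, severe at 30 events/hour and
#' above. Boundary values belong to the higher class.
#'
#' @param index AHI or ODI in events/hour (vectorized, each >= 0).
#' @return Ordered factor with levels `no_osa < mild < moderate < severe`.
#' @examples
#' classify_severity(c(0, 4.999, 5, 14.999, 15, 29.999, 30, 80))
#' @export
classify_severity <- function(index) {
  if (any(is.na(index)) || any(index < 0)) {
    abort("Severity is undefined for negative or missing index values.")
  }
  cut(index, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
      labels = severity_levels(), ordered_result = TRUE)
}
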