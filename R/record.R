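#' SpO2 record constructor
#'
#' A uniformly sampled pulse-oximetry trace. Saturation values are percentages
#' in `[1, 100]`; samples flagged invalid (oximeter dropouts, motion artifact)
#' are carried as `NA` so that downstream code is forced to handle them
#' explicitly rather than treating a sentinel number as physiology.
#'
#' @param samples Numeric vector of saturation values (% SpO2). `NA` marks an
#'   invalid sample.
#' @param fs Sampling frequency in Hz (nominally 4 for ambulatory oximeters).
#' @return An object of class `spo2_record`: a list with `samples`, `fs` and
#'   `duration_s` (= `length(samples) / fs`).
#' @examples
#' rec <- spo2_record(rep(97, 2400), fs = 4)
#' rec$duration_s
#' @export
spo2_record <- function(samples, fs = 4) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  samples <- as.numeric(samples)
  bad <- !is.na(samples) & (samples < 1 | samples > 100)
  if (any(bad)) {
    abort(sprintf(
      "%d sample(s) outside the valid saturation range [1, 100]; flag invalid samples as NA.",
      sum(bad)
    ))
  }
  structure(
    list(samples = samples, fs = fs, duration_s = length(samples) / fs),
    class = "spo2_record"
  )
}

#' @export
print.spo2_record <- function(x, ...) {
  n_bad <- sum(is.na(x$samples))
  cat(sprintf(
    "<spo2_record> %d samples @ %g Hz (%.1f min), %d invalid (%.2f%%)\n",
    length(x$samples), x$fs, x$duration_s / 60,
    n_bad, 100 * n_bad / max(1L, length(x$samples))
  ))
  invisible(x)
}

#' Coerce an SpO2 record to a tibble
#'
#' @param x An [spo2_record()].
#' @param ... Unused.
#' @return A tibble with columns `time_s` and `spo2` (`NA` = invalid sample).
#' @export
spo2_tbl <- function(x, ...) {
  stopifnot(inherits(x, "spo2_record"))
  tibble::tibble(
    time_s = (seq_along(x$samples) - 1) / x$fs,
    spo2 = x$samples
  )
}

new_annotation <- function(kind = character(), onset_s = numeric(),
                           duration_s = numeric()) {
  tibble::tibble(
    kind = as.character(kind),
    onset_s = as.numeric(onset_s),
    duration_s = as.numeric(duration_s)
  )
}

validate_annotation <- function(events, recording_duration_s = NULL) {
  stopifnot(is.data.frame(events))
  req <- c("kind", "onset_s", "duration_s")
  if (!all(req %in% names(events))) {
    abort("An event annotation needs columns kind, onset_s, duration_s.")
  }
  ok_kind <- events$kind %in% c("apnea", "hypopnea", "desaturation")
  if (!all(ok_kind)) {
    abort(sprintf("Unknown event kind(s): %s",
                  paste(unique(events$kind[!ok_kind]), collapse = ", ")))
  }
  if (any(events$onset_s < 0) || any(events$duration_s <= 0)) {
    abort("Event onsets must be >= 0 and durations > 0.")
  }
  if (is.unsorted(events$onset_s)) {
    events <- events[order(events$onset_s), , drop = FALSE]
  }
  if (!is.null(recording_duration_s) &&
      any(events$onset_s + events$duration_s > recording_duration_s + 1e-9)) {
    abort("Events must end within the recording.")
  }
  events
}

#' Ground-truth indices of an event annotation
#'
#' The reference AHI counts apneas plus hypopneas per hour of recording; the
#' reference ODI counts desaturation events per hour. The denominator is total
#' recording time, the home-sleep-apnea-test convention (no sleep staging is
#' available from an oximeter alone).
#'
#' @param events Annotation tibble with columns `kind`, `onset_s`,
#'   `duration_s` (kinds: `apnea`, `hypopnea`, `desaturation`).
#' @param duration_s Recording duration in seconds.
#' @return A one-row tibble with columns `ahi` and `odi`, both in events/hour.
#' @examples
#' ev <- tibble::tibble(kind = c("apnea", "desaturation"),
#'                      onset_s = c(100, 115), duration_s = c(20, 30))
#' annotation_indices(ev, duration_s = 3600)
#' @export
annotation_indices <- function(events, duration_s) {
  events <- validate_annotation(events)
  n_resp <- sum(events$kind %in% c("apnea", "hypopnea"))
  n_desat <- sum(events$kind == "desaturation")
  tibble::tibble(
    ahi = compute_index(n_resp, duration_s),
    odi = compute_index(n_desat, duration_s)
  )
}
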