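#' Sample a synthetic patient cohort
#'
#' Draws per-patient profiles for the oximetry simulator, stratified over the
#' four OSA severity classes. Each profile fixes the event rate (target AHI),
#' event morphology, oximeter noise and artifact load of one synthetic night.
#' Default parameter distributions emulate a suspected-OSA clinic population:
#' roughly half of patients below the diagnostic threshold, a long right tail
#' of severe patients reaching an AHI of about 150 events/hour, apneas forming
#' a minority (~15%) of obstructive events, and slightly fewer desaturations
#' than respiratory events so that cohort ODI sits just below cohort AHI.
#'
#' @param n Number of patients (>= 1).
#' @param severity_mix Proportions of the four severity classes
#'   (no OSA, mild, moderate, severe); must sum to 1. The default mirrors a
#'   clinical referral population (48.6/25.4/12.9/13.1%).
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @param recording_duration_s Nominal recording length in seconds
#'   (default 8 h).
#' @return A tibble with one row per patient: `patient_id`, `severity`,
#'   `target_ahi`, `apnea_fraction`, `desat_yield`, `baseline_spo2`,
#'   `desat_depth_mean`, `desat_depth_sd`, `event_duration_s`,
#'   `resat_duration_s`, `noise_sd`, `artifact_rate`, `recording_duration_s`,
#'   `record_seed`.
#' @examples
#' cohort <- sample_cohort(10, seed = 1)
#' table(cohort$severity)
#' @export
sample_cohort <- function(n,
                          severity_mix = c(0.486, 0.254, 0.129, 0.131),
                          seed = 1L,
                          recording_duration_s = 28800) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    abort("`n` must be a single integer >= 1.")
  }
  n <- as.integer(n)
  if (length(severity_mix) != 4L || any(severity_mix < 0)) {
    abort("`severity_mix` must be 4 non-negative proportions (no OSA, mild, moderate, severe).")
  }
  if (abs(sum(severity_mix) - 1) > 1e-9) {
    abort(sprintf(
      "`severity_mix` must sum to 1 (got %.10f); normalize the proportions first.",
      sum(severity_mix)
    ))
  }
  if (recording_duration_s <= 0) abort("`recording_duration_s` must be > 0.")

  withr::with_seed(as.integer(seed), {
    severity <- sample(severity_levels(), n, replace = TRUE, prob = severity_mix)
    target_ahi <- vapply(severity, draw_target_ahi, numeric(1))
    # Events must fit the night: at high event rates the inter-event cycle
    # (3600/AHI seconds) bounds how long a single obstruction can last.
    max_dur <- ifelse(target_ahi > 0,
                      pmin(45, pmax(12.5, 0.6 * 3600 / target_ahi)), 45)
    profiles <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      severity = factor(severity, levels = severity_levels(), ordered = TRUE),
      target_ahi = target_ahi,
      apnea_fraction = rbeta(n, 1.5, 7),
      desat_yield = rbeta(n, 18, 1.5),
      baseline_spo2 = truncnorm(n, 96.5, 1, 92, 99),
      desat_depth_mean = runif(n, 5, 9),
      desat_depth_sd = rep(1.5, n),
      event_duration_s = runif(n, 12, max_dur),
      resat_duration_s = rep(20, n),
      noise_sd = runif(n, 0.2, 0.8),
      artifact_rate = runif(n, 0, 1),
      recording_duration_s = rep(as.numeric(recording_duration_s), n),
      record_seed = sample.int(.Machine$integer.max - 1L, n)
    )
    profiles
  })
}

severity_levels <- function() c("no_osa", "mild", "moderate", "severe")

draw_target_ahi <- function(severity) {
  switch(severity,
    no_osa   = runif(1, 0, 5),
    mild     = runif(1, 5, 15),
    moderate = runif(1, 15, 30),
    severe   = min(30 + rexp(1, rate = 1 / 25), 150)
  )
}

truncnorm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

# One-sided truncation by redraw; depth >= lo (and < hi when given).
trunc_draw <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  for (i in seq_len(200)) {
    bad <- x < lo | x >= hi
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi - 1e-6)
}

#' Simulate one annotated oximetry night
#'
#' Plants respiratory events by a homogeneous Poisson process (non-overlap
#' enforced by a spacing construction), attaches a desaturation to each event
#' with probability `desat_yield`, renders the SpO2 waveform (baseline plateau,
#' linear fall to the nadir, exponential resaturation), adds Gaussian oximeter
#' noise, quantizes to integer percent, and inserts invalid-run artifacts.
#' Desaturation onset lags the respiratory-event onset by a circulation delay
#' (default 15 s). Desaturating events have depth drawn from
#' `Normal(desat_depth_mean, desat_depth_sd)` truncated to `>= 4` percentage
#' points; non-desaturating events produce a sub-threshold dip (< 4 points).
#'
#' @param profile A one-row tibble/list as produced by [sample_cohort()].
#' @param seed Integer seed. Defaults to the profile's own `record_seed`.
#' @param fs Output sampling frequency in Hz.
#' @param desat_lag_s Circulation delay between event onset and the start of
#'   the desaturation, in seconds.
#' @return A list with elements `record` ([spo2_record()]), `events`
#'   (annotation tibble: `kind`, `onset_s`, `duration_s`, sorted by onset) and
#'   `reference` (one-row tibble: ground-truth `ahi`, `odi`).
#' @examples
#' prof <- sample_cohort(1, seed = 3, recording_duration_s = 3600)
#' night <- simulate_record(prof)
#' night$reference
#' @export
simulate_record <- function(profile, seed = NULL, fs = 4, desat_lag_s = 15) {
  profile <- as.list(tibble::as_tibble(profile)[1, ])
  check_profile(profile)
  seed <- as.integer(seed %||% profile$record_seed %||% 1L)
  dur <- profile$recording_duration_s

  withr::with_seed(seed, {
    ev <- place_events(profile, dur)
    n_ev <- nrow(ev)
    samples <- render_spo2(profile, ev, dur, fs, desat_lag_s)
    samples <- insert_artifacts(samples, profile$artifact_rate, dur, fs)

    resp <- new_annotation(
      kind = ev$kind, onset_s = ev$onset_s, duration_s = ev$duration_s
    )
    desat_rows <- ev[ev$desaturating, , drop = FALSE]
    desat_onset <- desat_rows$onset_s + desat_lag_s
    desat <- new_annotation(
      kind = rep("desaturation", nrow(desat_rows)),
      onset_s = desat_onset,
      duration_s = pmin(desat_rows$duration_s + profile$resat_duration_s,
                        dur - desat_onset)
    )
    desat <- desat[desat$duration_s > 0, , drop = FALSE]
    events <- dplyr::arrange(dplyr::bind_rows(resp, desat), .data$onset_s)
    events <- validate_annotation(events, dur)
    list(
      record = spo2_record(samples, fs = fs),
      events = events,
      reference = annotation_indices(events, dur)
    )
  })
}

check_profile <- function(p) {
  need <- c("target_ahi", "apnea_fraction", "desat_yield", "baseline_spo2",
            "desat_depth_mean", "desat_depth_sd", "event_duration_s",
            "resat_duration_s", "noise_sd", "artifact_rate",
            "recording_duration_s")
  miss <- setdiff(need, names(p))
  if (length(miss)) abort(paste0("Profile is missing fields: ",
                                 paste(miss, collapse = ", ")))
  stopifnot(
    p$target_ahi >= 0, p$target_ahi <= 150,
    p$apnea_fraction >= 0, p$apnea_fraction <= 1,
    p$desat_yield >= 0, p$desat_yield <= 1,
    p$baseline_spo2 >= 88, p$baseline_spo2 <= 99,
    p$desat_depth_mean >= 4, p$desat_depth_sd >= 0,
    p$event_duration_s >= 10, p$event_duration_s <= 120,
    p$resat_duration_s > 0, p$noise_sd >= 0, p$artifact_rate >= 0,
    p$recording_duration_s > 0
  )
  invisible(p)
}

# Poisson-count events placed uniformly subject to a hard-core (non-overlap)
# constraint: draw sorted uniforms on the free interval left after reserving
# each event's duration plus a 2 s guard gap, then re-insert the reserved
# lengths. Equivalent to uniform placement conditioned on no overlap.
place_events <- function(profile, dur, guard_s = 2) {
  rate <- profile$target_ahi
  ev_len <- profile$event_duration_s + guard_s
  expected_occupancy <- rate * dur / 3600 * ev_len / dur
  if (expected_occupancy > 0.9) {
    abort(sprintf(
      "Event rate %.1f/hour with %.0f s events cannot fit a %.0f s recording without overlap.",
      rate, profile$event_duration_s, dur
    ))
  }
  n <- rpois(1, rate * dur / 3600)
  n_max <- floor(dur / ev_len)
  n <- min(n, n_max)  # Poisson tail beyond hard capacity truncated (rare)
  if (n == 0) {
    return(tibble::tibble(kind = character(), onset_s = numeric(),
                          duration_s = numeric(), desaturating = logical(),
                          depth = numeric()))
  }
  free <- dur - n * ev_len
  u <- sort(runif(n, 0, free))
  onset <- u + (seq_len(n) - 1) * ev_len
  desaturating <- runif(n) < profile$desat_yield
  depth <- numeric(n)
  if (any(desaturating)) {
    depth[desaturating] <- trunc_draw(sum(desaturating),
                                      profile$desat_depth_mean,
                                      profile$desat_depth_sd, lo = 4)
  }
  if (any(!desaturating)) {
    depth[!desaturating] <- trunc_draw(sum(!desaturating),
                                       min(3, profile$desat_depth_mean - 2),
                                       profile$desat_depth_sd, lo = 1, hi = 4)
  }
  tibble::tibble(
    kind = ifelse(runif(n) < profile$apnea_fraction, "apnea", "hypopnea"),
    onset_s = onset,
    duration_s = rep(profile$event_duration_s, n),
    desaturating = desaturating,
    depth = depth
  )
}

# Waveform: baseline minus, at each instant, the deepest active dip. A dip
# falls linearly from desaturation onset to the nadir over at most
# `desat_fall_s` seconds (typical desaturation slopes are a few tenths of a
# percentage point per second), holds the nadir while the obstruction
# persists, then recovers exponentially (time constant resat_duration_s / 4,
# i.e. ~98% recovered at resat_duration_s). Overlapping recoveries take the
# pointwise maximum deficit, which truncates an unfinished recovery when the
# next event begins -- the morphology of closely spaced severe-OSA
# desaturations.
render_spo2 <- function(profile, ev, dur, fs, desat_lag_s, desat_fall_s = 15) {
  n_samp <- round(fs * dur)
  t <- (seq_len(n_samp) - 1) / fs
  deficit <- numeric(n_samp)
  if (nrow(ev)) {
    tau <- profile$resat_duration_s / 4
    for (i in seq_len(nrow(ev))) {
      d0 <- ev$onset_s[i] + desat_lag_s
      nadir_t <- d0 + ev$duration_s[i]
      fall_t <- min(d0 + desat_fall_s, nadir_t)
      end_t <- min(nadir_t + 6 * tau, dur)
      idx <- which(t >= d0 & t <= end_t)
      if (!length(idx)) next
      ti <- t[idx]
      shape <- ifelse(
        ti <= fall_t, (ti - d0) / (fall_t - d0),
        ifelse(ti <= nadir_t, 1, exp(-(ti - nadir_t) / tau))
      )
      dip <- ev$depth[i] * shape
      deficit[idx] <- pmax(deficit[idx], dip)
    }
  }
  x <- profile$baseline_spo2 - deficit
  if (profile$noise_sd > 0) x <- x + rnorm(n_samp, 0, profile$noise_sd)
  x <- round(x)            # oximeter reports integer percent
  pmin(pmax(x, 1), 100)
}

insert_artifacts <- function(samples, rate_per_hour, dur, fs) {
  if (rate_per_hour <= 0) return(samples)
  n_art <- rpois(1, rate_per_hour * dur / 3600)
  if (n_art == 0) return(samples)
  for (i in seq_len(n_art)) {
    len_s <- runif(1, 5, 30)
    start_s <- runif(1, 0, max(0, dur - len_s))
    idx <- seq(floor(start_s * fs) + 1, min(length(samples),
                                            ceiling((start_s + len_s) * fs)))
    samples[idx] <- NA_real_
  }
  samples
}
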