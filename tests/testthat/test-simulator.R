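test_that("cohort sampling stratifies severity as requested", {
  # degenerate mix: everyone below the diagnostic threshold
  cohort <- sample_cohort(100, severity_mix = c(1, 0, 0, 0), seed = 1)
  expect_equal(nrow(cohort), 100)
  expect_true(all(cohort$target_ahi < 5))

  # clinic-like mix: class counts near-binomial around the expected shares
  mix <- c(0.486, 0.254, 0.129, 0.131)
  cohort <- sample_cohort(1000, severity_mix = mix, seed = 7)
  counts <- as.integer(table(classify_severity(cohort$target_ahi)))
  lo <- qbinom(0.005, 1000, mix)
  hi <- qbinom(0.995, 1000, mix)
  expect_true(all(counts >= lo & counts <= hi))

  # profiles respect their documented ranges
  expect_true(all(cohort$target_ahi >= 0 & cohort$target_ahi <= 150))
  expect_true(all(cohort$baseline_spo2 >= 92 & cohort$baseline_spo2 <= 99))
  expect_true(all(cohort$desat_yield >= 0 & cohort$desat_yield <= 1))
  expect_true(all(cohort$event_duration_s >= 10 & cohort$event_duration_s <= 120))
})

test_that("cohort sampling rejects bad inputs", {
  expect_error(sample_cohort(0), "n")
  expect_error(sample_cohort(10, severity_mix = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(sample_cohort(10, severity_mix = c(1, 0, 0)), "4")
})

test_that("identical (profile, seed) pairs yield bit-identical records", {
  prof <- sample_cohort(1, seed = 3, recording_duration_s = 1800)
  a <- simulate_record(prof, seed = 42)
  b <- simulate_record(prof, seed = 42)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$events, b$events)
  c <- simulate_record(prof, seed = 43)
  expect_false(identical(a$record$samples, c$record$samples))
})

test_that("a zero-rate profile produces an empty, zero-index night", {
  prof <- test_profile(target_ahi = 0, recording_duration_s = 1800,
                       artifact_rate = 0)
  night <- simulate_record(prof, seed = 5)
  expect_equal(nrow(night$events), 0)
  expect_equal(night$reference$ahi, 0)
  expect_equal(night$reference$odi, 0)
})

test_that("planted event counts follow Poisson moments", {
  # rate 30/hour over 8 h: counts ~ Poisson(240), sd ~ 15.5
  prof <- as.list(test_profile(target_ahi = 30, recording_duration_s = 28800,
                               event_duration_s = 30))
  counts <- withr::with_seed(99, {
    vapply(1:200, function(i) nrow(oxinet:::place_events(prof, 28800)),
           numeric(1))
  })
  expect_lt(abs(mean(counts) - 240), 3 * 15.5 / sqrt(200))
  expect_gt(sd(counts), 11)
  expect_lt(sd(counts), 20)
})

test_that("reference AHI converges to the profile's target rate over seeds", {
  prof <- test_profile(target_ahi = 24, recording_duration_s = 3600)
  ahis <- vapply(1:40, function(s) {
    simulate_record(prof, seed = s)$reference$ahi
  }, numeric(1))
  se <- sd(ahis) / sqrt(length(ahis))
  expect_lt(abs(mean(ahis) - 24), 3 * se)
})

test_that("ODI never exceeds AHI when the desaturation yield is below 1", {
  cohort <- sample_cohort(15, seed = 8, recording_duration_s = 1800)
  for (i in seq_len(nrow(cohort))) {
    ref <- simulate_record(cohort[i, ])$reference
    expect_lte(ref$odi, ref$ahi)
  }
})

test_that("infeasible event loads are rejected with the rate named", {
  prof <- test_profile(target_ahi = 150, event_duration_s = 120,
                       recording_duration_s = 3600)
  expect_error(simulate_record(prof, seed = 1), "150")
})

test_that("clean records contain exactly the planted desaturation dips", {
  prof <- test_profile(target_ahi = 18, noise_sd = 0, artifact_rate = 0,
                       desat_yield = 1, recording_duration_s = 3600)
  night <- simulate_record(prof, seed = 7)
  planted <- night$events[night$events$kind == "desaturation", ]
  det <- detect_desaturations(night$record)
  expect_equal(nrow(det), nrow(planted))
  expect_equal(match_onsets(planted$onset_s, det$onset_s, tol_s = 10),
               nrow(planted))
})

test_that("artifacts appear as flagged invalid runs at the configured rate", {
  prof <- test_profile(target_ahi = 5, artifact_rate = 6,
                       recording_duration_s = 7200)
  night <- simulate_record(prof, seed = 2)
  expect_gt(sum(is.na(night$record$samples)), 0)
  # valid samples stay inside the physical range
  v <- night$record$samples[!is.na(night$record$samples)]
  expect_true(all(v >= 1 & v <= 100))
  expect_true(all(v == round(v)))  # oximeter quantization
})
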