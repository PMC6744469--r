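test_that("block-mean downsampling preserves constants and decimates exactly", {
  rec <- spo2_record(rep(97, 2400), fs = 4)
  out <- downsample(rec, 0.5)
  expect_equal(out$fs, 0.5)
  expect_equal(length(out$samples), 300)        # 2400 / 8
  expect_true(all(out$samples == 97))

  # block means, not subsampling
  rec2 <- spo2_record(rep(c(96, 98), 400), fs = 4)
  expect_true(all(downsample(rec2, 0.5)$samples == 97))

  expect_error(downsample(rec, 0.3), "0.3")
})

test_that("invalid samples poison their downsampling block only", {
  x <- rep(95, 80)
  x[10] <- NA
  out <- downsample(spo2_record(x, fs = 4), 0.5)
  expect_true(is.na(out$samples[2]))            # block containing sample 10
  expect_equal(sum(is.na(out$samples)), 1)
})

test_that("epoch count follows the stride arithmetic for any duration", {
  rec <- spo2_record(rep(96, 1800), fs = 0.5)
  expect_equal(nrow(epoch_signal(rec)$epochs), 251)

  one <- epoch_signal(spo2_record(rep(96, 300), fs = 0.5))
  expect_equal(nrow(one$epochs), 1)
  expect_equal(one$epoch_start_s, 0)

  expect_error(epoch_signal(spo2_record(rep(96, 299), fs = 0.5)), "window")

  # property: n_epochs = floor((T - 600) / 12) + 1 across random durations
  withr::with_seed(4, {
    for (dur in sample(600:5000, 25)) {
      dur <- 2 * (dur %/% 2)  # whole samples at 0.5 Hz
      es <- epoch_signal(spo2_record(rep(95, dur / 2), fs = 0.5))
      expect_equal(nrow(es$epochs), floor((dur - 600) / 12) + 1)
      expect_equal(unique(round(diff(es$epoch_start_s), 9)), 12)
    }
  })
})

test_that("epochs read back the exact source samples (no resampling drift)", {
  withr::with_seed(5, x <- round(runif(900, 85, 99)))
  rec <- spo2_record(x, fs = 0.5)
  es <- epoch_signal(rec)
  for (i in c(1, 7, nrow(es$epochs))) {
    start_idx <- es$epoch_start_s[i] * 0.5 + 1
    expect_identical(es$epochs[i, ], x[start_idx:(start_idx + 299)])
  }
})

test_that("per-epoch targets are 6x the onset count in the window", {
  rec <- spo2_record(rep(96, 600), fs = 0.5)   # 1200 s -> 51 epochs
  ev <- tibble::tibble(
    kind = c("apnea", "hypopnea", "apnea", "desaturation"),
    onset_s = c(10, 50, 590, 60),
    duration_s = c(20, 20, 20, 30)
  )
  es <- compute_epoch_targets(epoch_signal(rec), ev, "ahi")
  es <- compute_epoch_targets(es, ev, "odi")
  # first window [0, 600) holds 3 respiratory onsets -> 18 events/hour
  expect_equal(es$target_ahi[1], 18)
  expect_equal(es$target_odi[1], 6)
  # an onset at 590 s sits in every window starting at <= 590: counted in each
  in_window <- es$epoch_start_s <= 590 & es$epoch_start_s + 600 > 590
  expect_true(all(es$target_ahi[in_window] >= 6))
  # beyond the last containing window the count drops out
  expect_true(all(es$target_ahi[es$epoch_start_s > 590] == 0))

  empty <- compute_epoch_targets(epoch_signal(rec), ev[0, ], "ahi")
  expect_true(all(empty$target_ahi == 0))
})

test_that("epoch-target average approaches the record's reference index", {
  # one event every 120 s for two hours: AHI 30 by construction
  dur <- 7200
  onsets <- seq(30, dur - 60, by = 120)
  ev <- tibble::tibble(kind = "hypopnea", onset_s = onsets, duration_s = 20)
  es <- compute_epoch_targets(epoch_signal(spo2_record(rep(95, dur / 2), fs = 0.5)),
                              ev, "ahi")
  ref <- annotation_indices(ev, dur)$ahi
  expect_lt(abs(mean(es$target_ahi) - ref), 1)
})

test_that("pooling concatenates valid epochs with provenance and thinning", {
  rec <- spo2_record(rep(96, 1800), fs = 0.5)
  ev <- tibble::tibble(kind = "apnea", onset_s = 100, duration_s = 20)
  es1 <- compute_epoch_targets(epoch_signal(rec), ev, "ahi")
  es2 <- es1
  es2$valid_mask[1:11] <- FALSE
  pool <- pool_training_epochs(list(es1, es2), record_ids = c("a", "b"))
  expect_equal(nrow(pool$inputs), 251 + 240)
  expect_equal(unique(pool$record_id), c("a", "b"))
  expect_equal(length(pool$target_ahi), nrow(pool$inputs))

  thinned <- pool_training_epochs(list(es1), record_ids = "a", thin = 10)
  expect_equal(nrow(thinned$inputs), length(seq(1, 251, by = 10)))

  expect_error(pool_training_epochs(list(es1, es2), record_ids = "a"),
               "record ids")
  expect_error(pool_training_epochs(list()), "No epoch sets")
})

test_that("epochs crossing the invalid threshold are masked out", {
  x <- rep(95, 900)
  x[1:45] <- NA                                # 15% of the first epoch
  es <- epoch_signal(spo2_record(x, fs = 0.5))
  expect_false(es$valid_mask[1])
  expect_true(all(es$valid_mask[es$epoch_start_s > 90]))
  # valid epochs carry no NA after interpolation
  expect_false(anyNA(es$epochs[es$valid_mask, ]))
})
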