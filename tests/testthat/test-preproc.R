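test_that("band-pass + resample yields the expected rate, length, and DC removal", {
  set.seed(1)
  n <- 500 * 30
  rec <- eeg_recording(matrix(rnorm(n * 2, 0, 5) + 20, ncol = 2), fs = 500)
  out <- bandpass_resample(rec)
  expect_identical(out$fs, 128)
  expect_identical(nrow(out$data), 30L * 128L)
  # constant offset removed by the 0.1 Hz high-pass (steady state)
  mid <- (5 * 128):(25 * 128)
  expect_lt(abs(mean(out$data[mid, 1])), 0.5)
  expect_error(bandpass_resample(eeg_recording(matrix(0, 100, 1),
                                               fs = 100)), "Nyquist")
  expect_error(bandpass_resample(rec, target_fs = 600), "exceeds")
})

test_that("a stop-band tone is strongly attenuated", {
  fs <- 500
  t <- seq_len(fs * 20) / fs
  tone80 <- sin(2 * pi * 80 * t) * 10
  tone10 <- sin(2 * pi * 10 * t) * 10
  rec <- eeg_recording(cbind(tone80, tone10), fs = fs)
  out <- bandpass_resample(rec)
  mid <- (2 * 128):(18 * 128)
  amp80 <- sqrt(mean(out$data[mid, 1]^2))
  amp10 <- sqrt(mean(out$data[mid, 2]^2))
  expect_gt(amp10, 6)          # pass-band essentially preserved
  expect_lt(amp80, 0.1 * amp10)  # 80 Hz well into the stop band
})

test_that("segmentation uses floor division and warns on too-short input", {
  rec <- white_recording(n_s = 300, k = 2, seed = 2)
  expect_length(segment_recording(rec)$segments, 30L)
  rec305 <- white_recording(n_s = 305, k = 2, seed = 2)
  expect_message(s <- segment_recording(rec305), "dropped")
  expect_length(s$segments, 30L)
  rec9 <- white_recording(n_s = 9, k = 2, seed = 2)
  expect_warning(s9 <- segment_recording(rec9), "shorter")
  expect_length(s9$segments, 0L)
})

test_that("each rejection criterion detects its targeted artifact", {
  clean <- white_recording(n_s = 40, k = 2, sd_uv = 5, seed = 3)
  base <- segment_recording(clean)
  expect_length(reject_artifacts(base)$rejected, 0L)

  # gradient: consecutive-sample jump of 100 uV at 128 Hz = 12.8 uV/ms > 10
  spec <- data.frame(type = "step", channel = 1, at_s = 15,
                     duration_s = NA, amplitude_uv = 100)
  r <- reject_artifacts(segment_recording(inject_artifacts(clean, spec)))
  expect_true(2L %in% r$rejected)
  expect_true("gradient" %in% r$log$criterion[r$log$segment == 2])

  # amplitude: +-200 uV spike exceeds the +-150 uV bounds
  spec <- data.frame(type = "spike", channel = 2, at_s = 25,
                     duration_s = NA, amplitude_uv = -200)
  r <- reject_artifacts(segment_recording(inject_artifacts(clean, spec)))
  expect_true(3L %in% r$rejected)
  expect_true("amplitude" %in% r$log$criterion[r$log$segment == 3])

  # low activity: a 200 ms flatline stays under 0.5 uV over 100 ms
  spec <- data.frame(type = "flatline", channel = 1, at_s = 5,
                     duration_s = 0.2, amplitude_uv = 0)
  r <- reject_artifacts(segment_recording(inject_artifacts(clean, spec)))
  expect_true(1L %in% r$rejected)
  expect_true("low_activity" %in% r$log$criterion[r$log$segment == 1])

  # min-max: a 120 uV swing inside 200 ms without a steep gradient
  slow <- clean
  idx <- (10 * 128):(10 * 128 + 20)
  bumpy <- 120 * sin(seq(0, pi, length.out = length(idx)))
  slow$data[idx, 1] <- slow$data[idx, 1] + bumpy
  r <- reject_artifacts(segment_recording(slow))
  expect_true("minmax" %in% r$log$criterion)
  expect_true(2L %in% r$rejected)
})

test_that("an all-zero segment fails the low-activity criterion", {
  rec <- eeg_recording(matrix(0, 10 * 128, 1), fs = 128)
  r <- reject_artifacts(segment_recording(rec))
  expect_identical(r$rejected, 1L)
  expect_true(all(r$log$criterion == "low_activity"))
})

test_that("rejection is idempotent on the kept set", {
  clean <- white_recording(n_s = 60, k = 3, sd_uv = 5, seed = 8)
  spec <- data.frame(type = "spike", channel = 1, at_s = 33,
                     duration_s = NA, amplitude_uv = 300)
  r1 <- reject_artifacts(segment_recording(inject_artifacts(clean, spec)))
  r2 <- reject_artifacts(r1$kept)
  expect_length(r2$rejected, 0L)
  expect_identical(length(r2$kept$segments), length(r1$kept$segments))
})

test_that("montage averaging, normalization, and permutation invariance", {
  set.seed(9)
  a <- rnorm(1000); b <- rnorm(1000)
  rec <- eeg_recording(cbind(A1 = a, A2 = b, B1 = a), fs = 100)
  mon <- list(front = c("A1", "A2"), back = "B1")
  out <- apply_montage(rec, mon)
  expect_identical(out$channels, c("front", "back"))
  expect_equal(drop(stats::cor(out$data[, 1], (a + b) / 2)), 1)
  expect_equal(unname(colMeans(out$data)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(out$data, 2, stats::sd)), c(1, 1))
  # permuting channels within a region does not change the result
  out2 <- apply_montage(rec, list(front = c("A2", "A1"), back = "B1"))
  expect_equal(out$data, out2$data)
  # identical member channels reduce to the normalized common signal
  rec2 <- eeg_recording(cbind(C1 = a, C2 = a), fs = 100)
  o <- apply_montage(rec2, list(r = c("C1", "C2")))
  expect_equal(drop(o$data[, 1]), drop(scale(a)), ignore_attr = TRUE)
  expect_error(apply_montage(rec, list(front = c("A1", "ZZ"))), "ZZ")
  expect_error(apply_montage(rec, list(f = "A1", g = "A1")),
               "more than one")
})

test_that("segmented montage pools normalization across segments", {
  rec <- white_recording(n_s = 40, k = 8, seed = 10)
  segs <- segment_recording(rec)
  roi <- apply_montage(segs, identity_montage())
  all <- do.call(rbind, roi$segments)
  expect_equal(unname(colMeans(all)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(all, 2, stats::sd)), rep(1, 8))
})

test_that("common average reference zeroes the instantaneous channel mean", {
  rec <- white_recording(n_s = 2, k = 4, seed = 11)
  out <- common_average_reference(rec)
  expect_lt(max(abs(rowMeans(out$data))), 1e-12)
})

test_that("default montage covers the eight regions disjointly", {
  mon <- default_montage()
  expect_identical(names(mon), roi_labels())
  expect_false(anyDuplicated(unlist(mon)) > 0)
})
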