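test_that("cohort draws respect bounds and are reproducible", {
  ch <- sample_cohort(28, seed = 4)
  expect_identical(nrow(ch), 28L)
  expect_true(all(ch$lsbq >= 5.05 & ch$lsbq <= 14.05))
  expect_true(all(ch$age >= 18 & ch$age <= 57))
  expect_true(all(ch$l2_aoa >= 0 & ch$l2_aoa <= 20))
  expect_true(all(ch$education %in% 1:4))
  expect_identical(sample_cohort(28, seed = 4), ch)
  expect_false(identical(sample_cohort(28, seed = 5)$lsbq, ch$lsbq))
  expect_error(sample_cohort(0), ">= 1")
})

test_that("cohort moments converge to the analytic truncated-normal values", {
  # closed-form truncated normal moments as the oracle
  trunc_moments <- function(mu, sigma, lo, hi) {
    a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
    Z <- pnorm(b) - pnorm(a)
    m <- mu + sigma * (dnorm(a) - dnorm(b)) / Z
    v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                      ((dnorm(a) - dnorm(b)) / Z)^2)
    c(mean = m, sd = sqrt(v))
  }
  ch <- sample_cohort(10000, seed = 11)
  mo <- trunc_moments(9.01, 2.69, 5.05, 14.05)
  expect_equal(mean(ch$lsbq), unname(mo["mean"]), tolerance = 0.01)
  expect_equal(sd(ch$lsbq), unname(mo["sd"]), tolerance = 0.03)
  moa <- trunc_moments(33.11, 9.57, 18, 57)
  expect_equal(mean(ch$age), unname(moa["mean"]), tolerance = 0.01)
  expect_equal(mean(ch$gender == "F"), 21 / 28, tolerance = 0.03)
})

test_that("a degenerate zero-variance config yields exactly the mean profile", {
  cfg <- cohort_config()
  cfg$lsbq$sd <- 0; cfg$age$sd <- 0; cfg$l2_aoa$sd <- 0
  cfg$education$prob <- c(0, 0, 1, 0)
  cfg$gender$prob <- c(1, 0)
  cfg$handedness$prob <- c(1, 0)
  cfg$task_order$prob <- c(1, rep(0, 5))
  ch <- sample_cohort(1, seed = 1, config = cfg)
  expect_identical(ch$lsbq, 9.01)
  expect_identical(ch$age, 33.11)
  expect_identical(ch$gender, "F")
  expect_identical(ch$education_label, "Degree")
})

test_that("zero-noise zero-effect behavior is constant; defaults hit the learning target", {
  ses <- build_session(seed = 1)
  prof <- sample_cohort(4, seed = 2)
  flat <- behavior_params(block_slope_ms = 0, lsbq_rt_offset = 0,
                          lsbq_slope_flattening = 0,
                          class_effect_ambiguous = 0,
                          class_effect_disambiguated = 0, noise_sigma = 0)
  resp <- simulate_behavior(prof, ses, flat, seed = 1)
  expect_true(all(resp$rt_ms == flat$baseline_rt_ms))

  prof28 <- sample_cohort(28, seed = 3)
  resp <- simulate_behavior(prof28, ses, behavior_params(), seed = 2)
  # configured change: block_slope * 7 blocks = -84 ms, up to noise
  expect_equal(rt_block_change(resp), -84, tolerance = 5)
  expect_equal(mean(resp$correct), 0.97, tolerance = 0.01)
  expect_error(simulate_behavior(prof28, list(trials = data.frame(a = 1)),
                                 behavior_params()), "annotations")
})

test_that("simulated learning slopes have the configured sign at every level", {
  ses <- build_session(seed = 1)
  prof <- sample_cohort(28, seed = 5)
  resp <- simulate_behavior(prof, ses, behavior_params(), seed = 3)
  d <- resp[resp$block > 0, ]
  for (L in 0:4) {
    cls <- d[[paste0("class_at_level_", L)]]
    dl <- d[cls %in% c("ambiguous", "disambiguated", "unambiguous"), ]
    co <- stats::coef(stats::lm(rt_ms ~ block, data = dl))
    expect_lt(co["block"], 0)
  }
})

test_that("VAR recordings are seeded, stationary, and refuse explosive truths", {
  truth <- connectivity_truth()
  prof <- data.frame(id = 1, lsbq = 9)
  a <- simulate_rest_recording(prof, truth, duration_s = 5, fs = 128,
                               seed = 9)
  b <- simulate_rest_recording(prof, truth, duration_s = 5, fs = 128,
                               seed = 9)
  expect_identical(a$data, b$data)
  expect_identical(dim(a$data), c(5L * 128L, 8L))

  Abad <- array(0, c(1, 8, 8)); diag(Abad[1, , ]) <- 1.05
  bad <- connectivity_truth(coef = Abad)
  expect_error(simulate_rest_recording(prof, bad, duration_s = 5,
                                       fs = 128),
               "spectral radius")
})

test_that("empirical lag-1 autocovariance matches the Yule-Walker value", {
  A <- array(0, c(1, 2, 2))
  A[1, 1, 1] <- 0.3; A[1, 2, 2] <- 0.5; A[1, 2, 1] <- 0.4
  truth <- connectivity_truth(coef = A, innovation_sd = 1,
                              labels = c("x", "y"))
  rec <- simulate_rest_recording(data.frame(id = 1, lsbq = 9), truth,
                                 duration_s = 3000, fs = 128, seed = 2)
  G <- var_stationary_autocov(A, diag(2), lags = 1)
  n <- nrow(rec$data)
  emp <- stats::cov(rec$data[-1, ], rec$data[-n, ])
  expect_equal(unname(emp), G[[2]], tolerance = 0.02)
})

test_that("with zero cross-coefficients the channels are independent", {
  truth <- connectivity_truth()
  rec <- simulate_rest_recording(data.frame(id = 1, lsbq = 9), truth,
                                 duration_s = 120, fs = 128, seed = 3)
  cc <- stats::cor(rec$data)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  gc <- granger_pair(rec$data[, 1], rec$data[, 2], order = 1)
  expect_lt(gc, 4 / nrow(rec$data))   # below the small-sample bias bound
})

test_that("modulators move the injected edge with the score", {
  truth <- connectivity_truth(modulators = list(
    list(from = "left_central", to = "right_parietal",
         fun = lsbq_bump(center = 10, width = 1.5, height = 0.4))))
  A10 <- fibconn:::truth_coef_at(truth, 10)
  A5 <- fibconn:::truth_coef_at(truth, 5)
  i <- match("right_parietal", roi_labels())
  j <- match("left_central", roi_labels())
  expect_equal(A10[1, i, j], 0.4)
  expect_lt(A5[1, i, j], 0.01)
})

test_that("artifact injection places known artifacts and leaves the rest untouched", {
  rec <- white_recording(n_s = 20, seed = 4)
  spec <- data.frame(type = c("spike", "flatline"),
                     channel = c("medial_frontal", "left_central"),
                     at_s = c(5, 12), duration_s = c(NA, 0.2),
                     amplitude_uv = c(200, 0))
  out <- inject_artifacts(rec, spec)
  log <- attr(out, "artifact_log")
  expect_identical(nrow(log), 2L)
  i_spike <- log$sample[1]
  expect_equal(out$data[i_spike, 1], rec$data[i_spike, 1] + 200)
  flat_idx <- log$sample[2] + 0:(round(0.2 * 128) - 1)
  expect_true(all(out$data[flat_idx, 2] == 0))
  expect_identical(out$data[, 3:8], rec$data[, 3:8])
  expect_identical(out$data[-i_spike, 1], rec$data[-i_spike, 1])
  expect_identical(out$data[-flat_idx, 2], rec$data[-flat_idx, 2])
  expect_identical(inject_artifacts(rec, spec[0, ]), rec)
  bad <- data.frame(type = "spike", channel = 1, at_s = 100,
                    duration_s = NA, amplitude_uv = 10)
  expect_error(inject_artifacts(rec, bad), "outside")
})

test_that("recordings round-trip through TSV + JSON sidecar", {
  rec <- white_recording(n_s = 2, k = 3, seed = 6)
  prefix <- withr::local_tempfile()
  write_recording(rec, prefix)
  back <- read_recording(prefix)
  expect_equal(back$data, rec$data, ignore_attr = TRUE)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$channels, rec$channels)
  expect_identical(back$condition, "pre")
})
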