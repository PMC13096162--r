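test_that("the design has one constrained 14-column block per connection", {
  cohort <- sample_cohort(28, seed = 1)
  et <- make_edge_table(cohort[cohort$id %in% 1:28, ])
  des <- build_design(et[et$participant_id <= 28, ])
  sm <- Filter(function(b) b$type == "smooth", des$blocks)
  expect_length(sm, 56L)
  expect_identical(sum(vapply(sm, function(b) length(b$cols), 0L)), 784L)
  expect_identical(ncol(des$Z), 14L)
  # sum-to-zero: each smooth's fitted values sum to ~0 over observed lsbq
  fit <- fit_penalized(des)
  sums <- vapply(sm[1:5], function(b)
    sum(des$X[, b$cols] %*% fit$coefficients[b$cols]), 0)
  expect_lt(max(abs(sums)), 1e-8)
})

test_that("missing covariates are reported with offending rows", {
  cohort <- sample_cohort(5, seed = 2)
  et <- make_edge_table(cohort)
  et$age[3] <- NA
  expect_error(build_design(et), "rows: 3")
  expect_error(build_design(et[, setdiff(names(et), "lsbq")]),
               "missing columns")
})

test_that("zero penalty reduces to the unpenalized basis regression", {
  cohort <- sample_cohort(20, seed = 3)
  et <- make_edge_table(cohort, effect = function(cn, l) 0.1 * l)
  spec0 <- fs_model_spec(penalty = 0, ridge = 1e-8,
                         covariates = character(0),
                         random = character(0))
  des <- build_design(et, spec0)
  fit <- fit_penalized(des)
  # unpenalized least squares on the same columns (ridge ~ 0)
  beta_ls <- qr.coef(qr(des$X), des$y)
  beta_ls[is.na(beta_ls)] <- 0
  expect_equal(drop(des$X %*% beta_ls), fit$fitted, tolerance = 1e-6)
})

test_that("effective degrees of freedom shrink monotonically in the penalty", {
  cohort <- sample_cohort(20, seed = 4)
  et <- make_edge_table(cohort)
  edfs <- vapply(c(1e-6, 0.02, 1, 100), function(lam) {
    des <- build_design(et, fs_model_spec(penalty = lam))
    fit <- fit_penalized(des)
    unname(fit$edf[et$connection[1]])
  }, 0)
  expect_true(all(diff(edfs) < 0))
  expect_lt(edfs[4], 3)      # heavy penalty collapses toward the null
  expect_gt(edfs[1], 12)     # light penalty approaches basis capacity
})

test_that("doubled data and duplicate weights give identical estimates", {
  cohort <- sample_cohort(12, seed = 5)
  et <- make_edge_table(cohort, effect = function(cn, l) 0.02 * l)
  des1 <- build_design(et)
  fit_w <- fit_penalized(des1, weights = rep(2, nrow(et)))
  et2 <- rbind(et, et)
  des2 <- build_design(et2)
  fit_d <- fit_penalized(des2)
  expect_equal(fit_w$coefficients, fit_d$coefficients, tolerance = 1e-8)
})

test_that("smooth tests are calibrated under a global null and detect a bump", {
  cohort <- sample_cohort(28, seed = 6)
  et <- make_edge_table(cohort)
  des <- build_design(et)
  fit <- fit_penalized(des)
  set.seed(7)
  rates <- vapply(1:60, function(i) {
    f <- fs_refit(fit, rnorm(nrow(et)))
    mean(test_smooths(f)$p_value < 0.05)
  }, 0)
  expect_gt(mean(rates), 0.03)
  expect_lt(mean(rates), 0.075)

  # a bump on one connection is detected and localized
  target <- et$connection[1]
  et2 <- make_edge_table(cohort, effect = function(cn, l)
    if (cn == target) 0.2 * exp(-(l - 10)^2 / (2 * 1.5^2)) else 0,
    noise_sd = 0.02, seed = 8)
  fit2 <- fs_refit(fit, et2$gc)
  ts <- test_smooths(fit2)
  fd <- fdr_correct(ts$p_value)
  expect_true(fd$significant[ts$connection == target])
  sm <- evaluate_smooth(fit2, target)
  expect_lt(abs(sm$x[which.max(sm$s)] - 10), 1)
})

test_that("pure-noise responses keep all smooths flat", {
  cohort <- sample_cohort(28, seed = 9)
  et <- make_edge_table(cohort, noise_sd = 1, seed = 10)
  fit <- fit_penalized(build_design(et))
  ts <- test_smooths(fit)
  expect_true(all(ts$p_value > 1e-4))
  expect_false(any(fdr_correct(ts$p_value)$significant))
})

test_that("the factor-smooth fit agrees with an independent GAM fit", {
  skip_if_not_installed("mgcv")
  cohort <- sample_cohort(28, seed = 11)
  target <- "left_central->right_parietal"
  et <- make_edge_table(cohort, effect = function(cn, l)
    if (cn == target) 0.15 * exp(-(l - 10)^2 / 4.5) else 0.01,
    noise_sd = 0.02, seed = 12)
  et <- et[et$connection %in% c(target, "medial_frontal->left_central"), ]
  et$conn_f <- factor(et$connection)
  fit <- fit_penalized(build_design(
    et, fs_model_spec(covariates = character(0), random = character(0))))
  g <- mgcv::gam(gc ~ conn_f + s(lsbq, by = conn_f, k = 15, bs = "cr"),
                 data = et)
  grid <- seq(min(et$lsbq) + 0.1, max(et$lsbq) - 0.1, length.out = 50)
  ours <- evaluate_smooth(fit, target, grid)$s
  nd <- data.frame(lsbq = grid, conn_f = factor(target,
                                                levels = levels(et$conn_f)))
  theirs <- mgcv::predict.gam(g, nd, type = "terms")
  theirs <- theirs[, grep("s\\(lsbq\\)", colnames(theirs))]
  theirs <- rowSums(as.matrix(theirs))
  # same shape up to smoothing differences: high correlation, same peak
  expect_gt(stats::cor(ours, theirs), 0.98)
  expect_lt(abs(grid[which.max(ours)] - grid[which.max(theirs)]), 0.75)
})

test_that("BH adjustment matches the brute-force step-up formula", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
    out <- numeric(m); out[o] <- pmin(adj, 1)
    out
  }
  p <- c(0.001, 0.01, 0.02, 0.2)
  fd <- fdr_correct(p)
  expect_equal(fd$p_fdr, c(0.004, 0.02, 1 / 37.5, 0.2))
  expect_equal(fd$p_fdr, bh_oracle(p))
  set.seed(13)
  for (i in 1:20) {
    p <- runif(56)^2
    fd <- fdr_correct(p)
    expect_equal(fd$p_fdr, bh_oracle(p))
    expect_true(all(fd$p_fdr >= fd$p_raw))
  }
  expect_equal(fdr_correct(rep(0.3, 5))$p_fdr, rep(0.3, 5))
  expect_identical(nrow(fdr_correct(numeric(0))), 0L)
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("model comparison prefers the truth and errors on non-nested fits", {
  cohort <- sample_cohort(28, seed = 14)
  et <- make_edge_table(cohort, noise_sd = 0.05, seed = 15)
  et$gc <- et$gc + 0.04 * et$age / 10     # age really drives the response
  # no participant intercepts here: age is constant within participant and
  # would otherwise be absorbed by the random-effect block
  sp_red <- fs_model_spec(covariates = c("l2_aoa"), random = character(0))
  sp_full <- fs_model_spec(covariates = c("l2_aoa", "age"),
                           random = character(0))
  f_red <- fit_penalized(build_design(et, sp_red))
  f_full <- fit_penalized(build_design(et, sp_full))
  cmp <- compare_models(f_red, f_full)
  expect_identical(cmp$preferred, "full")
  expect_lt(cmp$p_value, 0.01)
  # identical models: zero deltas
  cmp0 <- compare_models(f_full, f_full)
  expect_equal(cmp0$chisq, 0)
  expect_equal(cmp0$aic_full, cmp0$aic_reduced)
  expect_error(compare_models(f_full, f_red), "nested")

  # a pure-noise covariate is usually rejected by AIC
  set.seed(16)
  wins <- vapply(1:10, function(i) {
    et$noisecov <- rnorm(nrow(et))
    et$gc <- make_edge_table(cohort, noise_sd = 0.05, seed = 100 + i)$gc
    fr <- fit_penalized(build_design(et, fs_model_spec(
      covariates = c("age"))))
    ff <- fit_penalized(build_design(et, fs_model_spec(
      covariates = c("age", "noisecov"))))
    compare_models(fr, ff)$preferred == "reduced"
  }, TRUE)
  expect_gt(mean(wins), 0.5)
})

test_that("the IQR screen flags far points and respects affine invariance", {
  v <- c(1:10, 100)
  fl <- iqr_outlier_screen(v)
  expect_identical(which(fl), 11L)
  expect_identical(iqr_outlier_screen(v * 3 - 2), fl)
  expect_false(any(iqr_outlier_screen(rnorm(50, 0, 1e-6) + 5)))
  expect_error(iqr_outlier_screen(1:3), "at least 4")
  # the kind of screen used for cohort scores: a wild value is caught
  lsbq <- c(sample_cohort(27, seed = 17)$lsbq, 18.33)
  expect_true(iqr_outlier_screen(lsbq)[28])
})
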