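#' Default region-of-interest labels
#'
#' Eight scalp regions used throughout: medial frontal, left/right central,
#' left/right temporal, left/right parietal, medial occipital.
#'
#' @return character vector of length 8.
#' @export
roi_labels <- function() {
  c("medial_frontal", "left_central", "right_central",
    "left_temporal", "right_temporal", "left_parietal", "right_parietal",
    "medial_occipital")
}

#' Gaussian-bump modulator of an edge coefficient
#'
#' Returns `baseline + height * exp(-(lsbq - center)^2 / (2 width^2))`, a
#' shape able to emulate both "peak at mid experience" and, with a large
#' center, "peak at high experience" profiles.
#'
#' @param center score at which the bump peaks.
#' @param width Gaussian width in score units.
#' @param height coefficient increment at the peak.
#' @param baseline coefficient away from the bump.
#' @return function of the bilingualism score.
#' @export
lsbq_bump <- function(center = 10, width = 1.5, height = 0.4, baseline = 0) {
  force(center); force(width); force(height); force(baseline)
  function(lsbq) baseline + height * exp(-(lsbq - center)^2 / (2 * width^2))
}

#' Directed-connectivity ground truth
#'
#' A stationary VAR(p) process over the 8 region-of-interest signals whose
#' directed lag-1 coefficients may depend on the participant's bilingualism
#' score through edge modulators.
#'
#' @param coef array `[lag, to, from]` of base VAR coefficients; default a
#'   diagonal AR(1) with coefficient 0.4 and no cross-edges.
#' @param innovation_sd innovation standard deviation per channel, in
#'   microvolts (scalar or length-8).
#' @param modulators list of `list(from =, to =, fun =)` entries; `fun` is
#'   a function of the score added to the lag-1 coefficient `from -> to`.
#' @param labels channel labels.
#' @param condition `"pre"` or `"post"`.
#' @return object of class `connectivity_truth`.
#' @examples
#' truth <- connectivity_truth(
#'   modulators = list(list(from = "left_central", to = "right_parietal",
#'                          fun = lsbq_bump(center = 10))))
#' @export
connectivity_truth <- function(coef = NULL, innovation_sd = 5,
                               modulators = list(), labels = roi_labels(),
                               condition = "pre") {
  k <- length(labels)
  if (is.null(coef)) {
    coef <- array(0, c(1, k, k))
    for (i in seq_len(k)) coef[1, i, i] <- 0.4
  }
  stopifnot(length(dim(coef)) == 3, dim(coef)[2] == k, dim(coef)[3] == k)
  if (length(innovation_sd) == 1L) innovation_sd <- rep(innovation_sd, k)
  for (m in modulators) {
    if (!all(c(m$from, m$to) %in% labels))
      stop("modulator names an unknown channel")
    if (!is.function(m$fun)) stop("modulator fun must be a function")
  }
  structure(list(coef = coef, innovation_sd = innovation_sd,
                 modulators = modulators, labels = labels,
                 condition = condition),
            class = "connectivity_truth")
}

#' @export
print.connectivity_truth <- function(x, ...) {
  cat("connectivity_truth: VAR(", dim(x$coef)[1], ") over ",
      length(x$labels), " channels, ", length(x$modulators),
      " modulated edge(s), condition ", x$condition, "\n", sep = "")
  invisible(x)
}

# Coefficient array with modulators evaluated at a given score.
truth_coef_at <- function(truth, lsbq) {
  A <- truth$coef
  for (m in truth$modulators) {
    i <- match(m$to, truth$labels)
    j <- match(m$from, truth$labels)
    A[1, i, j] <- A[1, i, j] + m$fun(lsbq)
  }
  A
}

#' Companion-matrix spectral radius of a VAR coefficient array
#'
#' @param coef array `[lag, to, from]`.
#' @return largest eigenvalue modulus of the companion matrix; the process
#'   is stationary iff this is < 1.
#' @export
var_spectral_radius <- function(coef) {
  p <- dim(coef)[1]; k <- dim(coef)[2]
  comp <- matrix(0, k * p, k * p)
  for (l in seq_len(p))
    comp[seq_len(k), (l - 1) * k + seq_len(k)] <- coef[l, , ]
  if (p > 1)
    comp[k + seq_len(k * (p - 1)), seq_len(k * (p - 1))] <-
      diag(k * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Stationary autocovariance of a VAR process
#'
#' Solves the discrete Lyapunov equation of the companion form for the
#' lag-0 covariance and propagates it through the Yule-Walker recursion
#' for higher lags.
#'
#' @param coef array `[lag, to, from]`.
#' @param sigma innovation covariance matrix.
#' @param lags maximum lag.
#' @return list of `lags + 1` covariance matrices; element `l + 1` is
#'   `Cov(x_t, x_{t-l})`.
#' @export
var_stationary_autocov <- function(coef, sigma, lags = 1L) {
  p <- dim(coef)[1]; k <- dim(coef)[2]
  kp <- k * p
  comp <- matrix(0, kp, kp)
  for (l in seq_len(p))
    comp[seq_len(k), (l - 1) * k + seq_len(k)] <- coef[l, , ]
  if (p > 1)
    comp[k + seq_len(k * (p - 1)), seq_len(k * (p - 1))] <- diag(k * (p - 1))
  Q <- matrix(0, kp, kp)
  Q[seq_len(k), seq_len(k)] <- sigma
  vecP <- solve(diag(kp^2) - kronecker(comp, comp), as.vector(Q))
  P <- matrix(vecP, kp, kp)          # companion lag-0 covariance
  G <- vector("list", lags + 1L)
  G[[1]] <- P[seq_len(k), seq_len(k)]
  Pl <- P
  for (l in seq_len(lags)) {
    Pl <- comp %*% Pl
    G[[l + 1L]] <- Pl[seq_len(k), seq_len(k)]
  }
  G
}

#' Simulate a resting recording from the connectivity ground truth
#'
#' Draws one realization of the participant-specific VAR process (the base
#' coefficients with every modulated edge evaluated at the participant's
#' score), discards a burn-in, and returns the series in microvolts.  The
#' default length and rate mirror a five-minute resting recording at the
#' working rate of 128 Hz.
#'
#' @param profile one cohort row (needs `lsbq` and `id`).
#' @param truth a [connectivity_truth()].
#' @param duration_s recording length in seconds (default 300).
#' @param fs sampling rate in Hz (default 128).
#' @param seed RNG seed.
#' @param burn_in burn-in samples discarded before the recording starts.
#' @return an [eeg_recording()].
#' @export
simulate_rest_recording <- function(profile, truth, duration_s = 300,
                                    fs = 128, seed = 1L, burn_in = 500L) {
  A <- truth_coef_at(truth, profile$lsbq)
  p <- dim(A)[1]; k <- dim(A)[2]
  n <- round(duration_s * fs)
  if (n < 10 * p) stop("recording too short for the VAR order")
  sr <- var_spectral_radius(A)
  if (sr >= 1)
    stop(sprintf("non-stationary ground truth: spectral radius %.3f >= 1",
                 sr))
  set.seed(seed)
  total <- n + burn_in
  E <- matrix(stats::rnorm(total * k), total, k) %*%
    diag(truth$innovation_sd, k)
  X <- matrix(0, total, k)
  Al <- lapply(seq_len(p), function(l) t(A[l, , ]))   # x_{t-l} %*% t(A_l)
  for (t in (p + 1):total) {
    acc <- E[t, ]
    for (l in seq_len(p)) acc <- acc + drop(X[t - l, ] %*% Al[[l]])
    X[t, ] <- acc
  }
  eeg_recording(X[(burn_in + 1):total, , drop = FALSE], fs = fs,
                channels = truth$labels, units = "uV",
                participant_id = profile$id, condition = truth$condition)
}

#' Inject known artifacts into a recording
#'
#' Test-fixture generator for the rejection criteria: contaminates a clean
#' recording with artifacts at known sample positions and attaches the
#' ground-truth log as the `"artifact_log"` attribute.
#'
#' @param rec an [eeg_recording()].
#' @param artifact_spec data frame with columns `type` (one of `"step"`,
#'   `"spike"`, `"flatline"`, `"drift"`), `channel` (label or index),
#'   `at_s` (onset, seconds), `duration_s` (ignored for `spike`/`step`),
#'   `amplitude_uv`.
#' @return the contaminated recording.
#' @export
inject_artifacts <- function(rec, artifact_spec) {
  if (nrow(artifact_spec) == 0) return(rec)
  dat <- rec$data
  n <- nrow(dat)
  log <- artifact_spec
  log$sample <- NA_integer_
  for (r in seq_len(nrow(artifact_spec))) {
    a <- artifact_spec[r, ]
    ch <- if (is.numeric(a$channel)) a$channel else
      match(a$channel, rec$channels)
    if (is.na(ch)) stop("unknown channel in artifact_spec row ", r)
    i0 <- floor(a$at_s * rec$fs) + 1L
    dur <- if (is.null(a$duration_s) || is.na(a$duration_s)) 0 else
      a$duration_s
    i1 <- min(n, i0 + max(0L, round(dur * rec$fs) - 1L))
    if (i0 < 1L || i0 > n)
      stop("artifact outside recording in artifact_spec row ", r)
    seg <- i0:i1
    dat[, ch] <- switch(
      a$type,
      spike = { dat[i0, ch] <- dat[i0, ch] + a$amplitude_uv; dat[, ch] },
      step = { dat[i0:n, ch] <- dat[i0:n, ch] + a$amplitude_uv; dat[, ch] },
      flatline = { dat[seg, ch] <- a$amplitude_uv; dat[, ch] },
      drift = { dat[seg, ch] <- dat[seg, ch] +
        seq(0, a$amplitude_uv, length.out = length(seg)); dat[, ch] },
      stop("unknown artifact type: ", a$type))
    log$sample[r] <- i0
  }
  out <- eeg_recording(dat, rec$fs, rec$channels, rec$units,
                       rec$participant_id, rec$condition)
  attr(out, "artifact_log") <- log
  out
}
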