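#' Artifact rejection criteria
#'
#' The four automatic criteria applied to every channel of every segment:
#' a gradient criterion (change of more than 10 microvolts per millisecond
#' between consecutive samples), a min-max criterion (amplitude range above
#' 100 microvolts within any 200 ms window), an absolute amplitude
#' criterion (any sample below -150 or above +150 microvolts), and a low
#' activity criterion (amplitude range below 0.5 microvolts within any
#' 100 ms window).
#'
#' @param gradient_uv_per_ms,minmax_uv,minmax_window_ms,amp_min_uv,amp_max_uv,low_activity_uv,low_activity_window_ms
#'   thresholds; defaults as stated above.
#' @return list of class `rejection_criteria`.
#' @export
rejection_criteria <- function(gradient_uv_per_ms = 10,
                               minmax_uv = 100, minmax_window_ms = 200,
                               amp_min_uv = -150, amp_max_uv = 150,
                               low_activity_uv = 0.5,
                               low_activity_window_ms = 100) {
  stopifnot(gradient_uv_per_ms > 0, minmax_uv > 0, minmax_window_ms > 0,
            low_activity_uv > 0, low_activity_window_ms > 0,
            amp_min_uv < amp_max_uv)
  structure(as.list(environment()), class = "rejection_criteria")
}

#' Zero-phase band-pass filter and resample
#'
#' Applies zero-phase (forward-backward) Butterworth high- and low-pass
#' filters at the cut-offs, then polyphase-resamples to the target rate.
#' With the defaults a recording is band-limited to 0.1-64 Hz and brought
#' to 128 Hz.
#'
#' @param rec an [eeg_recording()].
#' @param low_hz,high_hz band edges; `high_hz = NULL` skips the low-pass
#'   (for signals already band-limited by construction — note that any
#'   low-pass or resampling step mixes samples in time and can induce
#'   small spurious reverse Granger dependencies downstream).
#' @param target_fs output sampling rate.
#' @param order Butterworth order of each (high/low) section.
#' @return filtered, resampled [eeg_recording()].
#' @export
bandpass_resample <- function(rec, low_hz = 0.1, high_hz = 64,
                              target_fs = 128, order = 4L) {
  fs <- rec$fs
  if (!is.null(high_hz)) {
    if (high_hz >= fs / 2)
      stop("high cut-off must be below the input Nyquist frequency (",
           fs / 2, " Hz)")
    if (fs < 2 * high_hz) stop("input rate below twice the high cut-off")
  }
  if (target_fs > fs) stop("target_fs exceeds the input rate")
  hp <- signal::butter(order, low_hz / (fs / 2), type = "high")
  lp <- if (!is.null(high_hz))
    signal::butter(order, high_hz / (fs / 2), type = "low")
  dat <- apply(rec$data, 2, function(x) {
    y <- signal::filtfilt(hp, x)
    if (is.null(lp)) y else signal::filtfilt(lp, y)
  })
  if (target_fs != fs) {
    gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
    p <- round(target_fs * 1000); q <- round(fs * 1000)
    g <- gcd(p, q)
    dat <- apply(dat, 2, function(x) signal::resample(x, p / g, q / g))
  }
  eeg_recording(dat, fs = target_fs, channels = rec$channels,
                units = rec$units, participant_id = rec$participant_id,
                condition = rec$condition)
}

#' Cut a recording into fixed-length non-overlapping segments
#'
#' @param rec an [eeg_recording()].
#' @param seg_s segment length, seconds (default 10).
#' @return list of class `segment_list`: `segments` (list of sample
#'   matrices), `fs`, `channels`, and provenance; a trailing remainder
#'   shorter than one segment is dropped.  A recording shorter than one
#'   segment yields an empty list with a warning.
#' @export
segment_recording <- function(rec, seg_s = 10) {
  w <- round(seg_s * rec$fs)
  n <- nrow(rec$data)
  k <- n %/% w
  if (k == 0) {
    warning("recording shorter than one segment; no segments produced")
    segs <- list()
  } else {
    segs <- lapply(seq_len(k), function(i)
      rec$data[((i - 1) * w + 1):(i * w), , drop = FALSE])
    dropped <- n - k * w
    if (dropped > 0)
      message(sprintf("dropped trailing %.2f s (%d samples)",
                      dropped / rec$fs, dropped))
  }
  structure(list(segments = segs, fs = rec$fs, channels = rec$channels,
                 participant_id = rec$participant_id,
                 condition = rec$condition, seg_s = seg_s),
            class = "segment_list")
}

#' @export
print.segment_list <- function(x, ...) {
  cat("segment_list:", length(x$segments), "segment(s) of", x$seg_s,
      "s @", x$fs, "Hz,", length(x$channels), "channel(s)\n")
  invisible(x)
}

# Rolling range (max - min) over every window of w samples.
roll_range <- function(x, w) {
  n <- length(x)
  if (n < w) return(numeric(0))
  hi <- x[seq_len(n - w + 1L)]
  lo <- hi
  for (o in seq_len(w - 1L)) {
    xo <- x[(1L + o):(n - w + 1L + o)]
    hi <- pmax(hi, xo)
    lo <- pmin(lo, xo)
  }
  hi - lo
}

#' Reject segments violating any artifact criterion
#'
#' A segment is rejected when any channel violates any of the four
#' criteria; the log records every violation with its segment, channel,
#' criterion, first offending 0-based sample index, and the offending
#' value.  The gradient criterion compares consecutive samples scaled by
#' the inter-sample interval to microvolts per millisecond.
#'
#' @param segs a [segment_recording()] result.
#' @param criteria a [rejection_criteria()] list.
#' @return list: `kept` (a `segment_list` of retained segments),
#'   `rejected` (indices), `log` (data frame).
#' @export
reject_artifacts <- function(segs, criteria = rejection_criteria()) {
  fs <- segs$fs
  dt_ms <- 1000 / fs
  w_minmax <- max(2L, round(criteria$minmax_window_ms * fs / 1000))
  w_low <- max(2L, round(criteria$low_activity_window_ms * fs / 1000))
  log <- list()
  bad <- logical(length(segs$segments))
  for (si in seq_along(segs$segments)) {
    seg <- segs$segments[[si]]
    for (ci in seq_len(ncol(seg))) {
      x <- seg[, ci]
      grad <- abs(diff(x)) / dt_ms
      viol <- function(criterion, idx, value) {
        bad[si] <<- TRUE
        data.frame(segment = si, channel = segs$channels[ci],
                   criterion = criterion, sample_index = idx - 1L,
                   value = value)
      }
      if (any(grad > criteria$gradient_uv_per_ms)) {
        i <- which.max(grad > criteria$gradient_uv_per_ms)
        log[[length(log) + 1L]] <- viol("gradient", i, grad[i])
      }
      rr <- roll_range(x, w_minmax)
      if (any(rr > criteria$minmax_uv)) {
        i <- which.max(rr > criteria$minmax_uv)
        log[[length(log) + 1L]] <- viol("minmax", i, rr[i])
      }
      if (any(x < criteria$amp_min_uv | x > criteria$amp_max_uv)) {
        i <- which.max(x < criteria$amp_min_uv | x > criteria$amp_max_uv)
        log[[length(log) + 1L]] <- viol("amplitude", i, x[i])
      }
      rl <- roll_range(x, w_low)
      if (any(rl < criteria$low_activity_uv)) {
        i <- which.max(rl < criteria$low_activity_uv)
        log[[length(log) + 1L]] <- viol("low_activity", i, rl[i])
      }
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(segment = integer(0), channel = character(0),
               criterion = character(0), sample_index = integer(0),
               value = numeric(0))
  kept <- segs
  kept$segments <- segs$segments[!bad]
  list(kept = kept, rejected = which(bad), log = log)
}

#' Default electrode-to-region montage
#'
#' A configurable grouping of a 32-electrode 10-20 layout into the eight
#' scalp regions of [roi_labels()].  This is a documented, editable default
#' rather than a claim about any particular published electrode map.
#'
#' @return named list mapping each region to its electrode labels.
#' @export
default_montage <- function() {
  list(
    medial_frontal = c("Fp1", "Fp2", "Fz"),
    left_central = c("F3", "FC1", "FC5", "C3"),
    right_central = c("F4", "FC2", "FC6", "C4"),
    left_temporal = c("F7", "T7", "FT9", "TP9"),
    right_temporal = c("F8", "T8", "FT10", "TP10"),
    left_parietal = c("CP1", "CP5", "P3", "P7"),
    right_parietal = c("CP2", "CP6", "P4", "P8"),
    medial_occipital = c("O1", "O2", "Oz")
  )
}

#' Average channels into region-of-interest series and normalize
#'
#' Per region, member channels are averaged sample-wise and the resulting
#' series z-normalized (mean 0, SD 1) over the whole recording.  For
#' segmented input the normalization statistics pool all segments of the
#' recording so that segments stay mutually comparable.
#'
#' @param x an [eeg_recording()] or [segment_recording()] output.
#' @param montage named list region -> electrode labels; electrodes must
#'   be disjoint across regions and present in the input.
#' @return same class as the input, with one channel per region.
#' @export
apply_montage <- function(x, montage = default_montage()) {
  elecs <- unlist(montage)
  if (anyDuplicated(elecs))
    stop("montage assigns an electrode to more than one region")
  if (any(vapply(montage, length, 1L) == 0))
    stop("montage contains an empty region")
  chans <- if (inherits(x, "eeg_recording")) x$channels else x$channels
  missing <- setdiff(elecs, chans)
  if (length(missing))
    stop("electrode(s) missing from the recording: ",
         paste(missing, collapse = ", "))
  region_means <- function(dat)
    vapply(montage, function(e)
      rowMeans(dat[, e, drop = FALSE]), numeric(nrow(dat)))
  if (inherits(x, "eeg_recording")) {
    m <- region_means(x$data)
    m <- scale(m)
    attr(m, "scaled:center") <- NULL; attr(m, "scaled:scale") <- NULL
    return(eeg_recording(m, x$fs, names(montage), "z",
                         x$participant_id, x$condition))
  }
  if (inherits(x, "segment_list")) {
    ms <- lapply(x$segments, region_means)
    all <- do.call(rbind, ms)
    ctr <- colMeans(all)
    sdv <- apply(all, 2, stats::sd)
    out <- x
    out$segments <- lapply(ms, function(m)
      sweep(sweep(m, 2, ctr), 2, sdv, "/"))
    out$channels <- names(montage)
    return(out)
  }
  stop("x must be an eeg_recording or a segment_list")
}

#' Optional common-average re-reference
#'
#' Subtracts the instantaneous mean across all channels from every
#' channel.
#'
#' @param rec an [eeg_recording()].
#' @return re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  dat <- rec$data - rowMeans(rec$data)
  eeg_recording(dat, rec$fs, rec$channels, rec$units,
                rec$participant_id, rec$condition)
}
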