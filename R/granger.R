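# Build a within-segment lagged regression of channel series.
# segments: list of sample x channel matrices.  Returns the stacked
# response rows (t = p+1 .. L per segment) and lagged predictor matrix
# with columns ordered channel-major (ch1 lag1..p, ch2 lag1..p, ...).
build_lagged <- function(segments, p) {
  ys <- list(); xs <- list()
  for (seg in segments) {
    L <- nrow(seg)
    if (L <= p) next
    idx <- (p + 1):L
    ys[[length(ys) + 1L]] <- seg[idx, , drop = FALSE]
    lagcols <- lapply(seq_len(ncol(seg)), function(ci)
      vapply(seq_len(p), function(l) seg[idx - l, ci], numeric(length(idx))))
    xs[[length(xs) + 1L]] <- do.call(cbind, lagcols)
  }
  if (!length(ys)) stop("all segments shorter than the lag order")
  list(Y = do.call(rbind, ys), X = do.call(rbind, xs))
}

rss_ols <- function(X, y) {
  fit <- stats::lm.fit(cbind(1, X), y)
  sum(fit$residuals^2)
}

#' Pairwise time-domain Granger causality
#'
#' `GC(x -> y)` is the log ratio of the residual variance of an AR(p)
#' model of `y` on its own past to that of a model also including the past
#' of `x`; it is non-negative up to estimation noise and invariant to
#' rescaling either series.  Models are fitted by least squares; when the
#' input is segmented, lagged regressors are built within segments only so
#' that gaps never create spurious transitions.
#'
#' @param x,y numeric vectors (or matrices with one column) of equal
#'   length, or lists of equal-length segment pairs.
#' @param order lag order `p` (default 1).
#' @return the estimated GC value for `x -> y`.
#' @examples
#' set.seed(1)
#' x <- rnorm(2000); y <- stats::filter(0.4 * c(0, x[-2000]), 0.5,
#'   "recursive") + rnorm(2000)
#' granger_pair(x, as.numeric(y), order = 1)
#' @export
granger_pair <- function(x, y, order = 1L) {
  p <- as.integer(order)
  if (p < 1) stop("order must be >= 1")
  segs <- if (is.list(x)) {
    stopifnot(is.list(y), length(x) == length(y))
    mapply(function(a, b) cbind(y = a, x = b), y, x, SIMPLIFY = FALSE)
  } else {
    if (length(x) != length(y)) stop("series lengths differ")
    list(cbind(y = as.numeric(y), x = as.numeric(x)))
  }
  ntot <- sum(vapply(segs, nrow, 1L))
  if (ntot < 10 * p)
    stop("series too short for order ", p, " (need >= ", 10 * p,
         " samples)")
  lag <- build_lagged(segs, p)
  yy <- lag$Y[, 1]
  Xy <- lag$X[, seq_len(p), drop = FALSE]             # past of y
  Xxy <- lag$X                                         # past of y and x
  rss_r <- rss_ols(Xy, yy)
  rss_f <- rss_ols(Xxy, yy)
  if (rss_f <= 0) stop("singular full model (zero residual variance)")
  log(rss_r / rss_f)
}

#' Select a shared VAR order by BIC
#'
#' Fits the full multichannel VAR by least squares for each candidate
#' order on a common sample and returns the order minimizing the Bayesian
#' information criterion.
#'
#' @param segs a `segment_list` (or list of sample x channel matrices).
#' @param pmax largest order tried (default 20).
#' @return integer order.
#' @export
select_var_order <- function(segs, pmax = 20L) {
  segments <- if (inherits(segs, "segment_list")) segs$segments else segs
  k <- ncol(segments[[1]])
  best <- 1L; best_bic <- Inf
  lag_full <- build_lagged(segments, pmax)
  N <- nrow(lag_full$Y)
  for (p in seq_len(pmax)) {
    cols <- as.vector(outer(seq_len(p), (seq_len(k) - 1) * pmax, "+"))
    X <- cbind(1, lag_full$X[, cols, drop = FALSE])
    fit <- stats::lm.fit(X, lag_full$Y)
    Sigma <- crossprod(as.matrix(fit$residuals)) / N
    bic <- determinant(Sigma, logarithm = TRUE)$modulus +
      log(N) * (k^2 * p) / N
    if (bic < best_bic) { best_bic <- bic; best <- p }
  }
  best
}

#' Directed connectivity matrix over region-of-interest series
#'
#' Computes [granger_pair()] for all ordered channel pairs of a segmented
#' multichannel recording, producing a square matrix with an undefined
#' (missing) diagonal.
#'
#' @param segs a `segment_list` of region series (e.g. from
#'   [apply_montage()]), or an [eeg_recording()] treated as one segment.
#' @param order_policy `"bic"` (shared order by [select_var_order()]) or
#'   `"fixed"`.
#' @param order the fixed order (required for `"fixed"`).
#' @param pmax BIC cap.
#' @return object of class `gc_matrix`: a `k x k` numeric matrix with `NA`
#'   diagonal and attributes `participant_id`, `condition`, `order`.
#' @export
granger_matrix <- function(segs, order_policy = c("bic", "fixed"),
                           order = NULL, pmax = 20L) {
  order_policy <- match.arg(order_policy)
  if (inherits(segs, "eeg_recording"))
    segs <- structure(list(segments = list(segs$data), fs = segs$fs,
                           channels = segs$channels,
                           participant_id = segs$participant_id,
                           condition = segs$condition, seg_s = NA),
                      class = "segment_list")
  k <- length(segs$channels)
  if (k < 2) stop("need at least 2 channels")
  p <- if (order_policy == "fixed") {
    if (is.null(order)) stop("order_policy 'fixed' needs order")
    as.integer(order)
  } else select_var_order(segs, pmax = pmax)
  lag <- build_lagged(segs$segments, p)
  M <- matrix(NA_real_, k, k, dimnames = list(from = segs$channels,
                                              to = segs$channels))
  rss_restricted <- numeric(k)
  for (j in seq_len(k)) {
    Xy <- lag$X[, (j - 1) * p + seq_len(p), drop = FALSE]
    rss_restricted[j] <- rss_ols(Xy, lag$Y[, j])
  }
  for (j in seq_len(k)) {
    yy <- lag$Y[, j]
    for (i in seq_len(k)) {
      if (i == j) next
      cols <- c((j - 1) * p + seq_len(p), (i - 1) * p + seq_len(p))
      rss_f <- rss_ols(lag$X[, cols, drop = FALSE], yy)
      M[i, j] <- log(rss_restricted[j] / rss_f)
    }
  }
  structure(M, class = c("gc_matrix", "matrix"),
            participant_id = segs$participant_id,
            condition = segs$condition, order = p,
            n_samples = nrow(lag$Y))
}

#' @export
print.gc_matrix <- function(x, ...) {
  cat("gc_matrix: ", nrow(x), "x", ncol(x), " directed GC (VAR order ",
      attr(x, "order"), "), participant ", attr(x, "participant_id"),
      ", condition ", attr(x, "condition"), "\n", sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Convert connectivity matrices to a covariate-joined edge list
#'
#' One row per participant, condition and ordered region pair (56 rows per
#' 8-region matrix), joined with the cohort covariates.
#'
#' @param matrices list of `gc_matrix` objects (one per participant and
#'   condition; duplicates are an error).
#' @param cohort cohort data frame from [sample_cohort()].
#' @return long-form data frame with columns `participant_id`,
#'   `condition`, `from_roi`, `to_roi`, `connection` ("from->to"), `gc`,
#'   and the cohort covariates.
#' @export
to_edge_list <- function(matrices, cohort) {
  keys <- vapply(matrices, function(m)
    paste(attr(m, "participant_id"), attr(m, "condition")), "")
  if (anyDuplicated(keys))
    stop("duplicate participant/condition: ", keys[duplicated(keys)][1])
  rows <- lapply(matrices, function(m) {
    labs <- rownames(m)
    idx <- which(!is.na(m), arr.ind = TRUE)
    data.frame(participant_id = attr(m, "participant_id"),
               condition = attr(m, "condition"),
               from_roi = labs[idx[, 1]], to_roi = labs[idx[, 2]],
               gc = m[idx], stringsAsFactors = FALSE)
  })
  el <- do.call(rbind, rows)
  el$connection <- paste0(el$from_roi, "->", el$to_roi)
  cov_cols <- intersect(c("lsbq", "age", "l2_aoa", "education", "gender",
                          "handedness", "task_order"), names(cohort))
  el <- merge(el, cohort[, c("id", cov_cols)], by.x = "participant_id",
              by.y = "id", sort = FALSE)
  el <- el[order(el$participant_id, el$condition, el$from_roi, el$to_roi), ]
  rownames(el) <- NULL
  el
}

#' Write / read a connectivity matrix as CSV
#'
#' Square CSV with region labels as header row and first column; the
#' diagonal is left empty.
#'
#' @param m a `gc_matrix`.
#' @param path file path.
#' @return `path` invisibly; `read_gc_matrix` returns a `gc_matrix`
#'   (provenance attributes restored from optional columns is not
#'   attempted — pass them explicitly if needed).
#' @export
write_gc_matrix <- function(m, path) {
  d <- as.data.frame(unclass(m))
  d <- cbind(from = rownames(m), d)
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_gc_matrix
#' @param participant_id,condition provenance restored onto the object.
#' @export
read_gc_matrix <- function(path, participant_id = NA,
                           condition = NA_character_) {
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d$from
  structure(m, class = c("gc_matrix", "matrix"),
            participant_id = participant_id, condition = condition)
}
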