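#' Multichannel recording container
#'
#' A thin container for a continuous multichannel time series: a numeric
#' matrix (rows = samples, columns = channels) plus the metadata needed to
#' interpret it (sampling rate, channel labels, units, provenance).
#'
#' @param data numeric matrix, samples by channels.
#' @param fs sampling rate in Hz.
#' @param channels channel labels (defaults to the matrix column names).
#' @param units amplitude units (default microvolts).
#' @param participant_id,condition optional provenance fields; `condition`
#'   is `"pre"` or `"post"` for task-driven resting-state designs.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels = colnames(data),
                          units = "uV", participant_id = NA,
                          condition = NA_character_) {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(data)))
  stopifnot(length(channels) == ncol(data), fs > 0)
  colnames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels, units = units,
                 participant_id = participant_id, condition = condition),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("eeg_recording: ", ncol(x$data), " channel(s) x ", nrow(x$data),
      " samples @ ", x$fs, " Hz (", round(nrow(x$data) / x$fs, 2), " s, ",
      x$units, ")\n", sep = "")
  if (!is.na(x$participant_id))
    cat("  participant ", x$participant_id,
        if (!is.na(x$condition)) paste0(", condition ", x$condition), "\n",
        sep = "")
  invisible(x)
}

#' Write / read a recording as delimited matrix plus JSON sidecar
#'
#' The sample matrix is written as a tab-separated file
#' (`<prefix>.tsv`, one row per sample, one column per channel) and the
#' metadata as `<prefix>.json` with fields `channel_labels`, `fs_hz`,
#' `units`, `participant_id`, `condition`.
#'
#' @param rec an [eeg_recording()].
#' @param prefix output path prefix (without extension).
#' @return the prefix, invisibly (`write_recording`); an `eeg_recording`
#'   (`read_recording`).
#' @export
write_recording <- function(rec, prefix) {
  utils::write.table(rec$data, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = rec$channels)
  meta <- list(channel_labels = rec$channels, fs_hz = rec$fs,
               units = rec$units, participant_id = rec$participant_id,
               condition = rec$condition)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dat <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t",
                                     header = TRUE, check.names = FALSE))
  pid <- meta$participant_id
  eeg_recording(dat, fs = as.numeric(meta$fs_hz),
                channels = meta$channel_labels,
                units = meta$units,
                participant_id = if (is.null(pid)) NA else pid,
                condition = if (is.null(meta$condition)) NA_character_
                            else meta$condition)
}
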