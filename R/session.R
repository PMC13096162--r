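#' Build the pseudo-random ungrammatical training block
#'
#' The training sequence has 50 items with (up to rounding) the same symbol
#' frequencies as a grammatical block (89/144 ones, here 31 ones and 19
#' zeros), shuffled and re-drawn until it is *not* a possible output of the
#' grammar: it must contain at least one "00" and at least one "111"
#' subsequence.
#'
#' @param seed RNG seed; the same seed always yields the same block.
#' @param length_out block length (default 50).
#' @return character vector of symbols.
#' @export
build_training_block <- function(seed = 1L, length_out = 50L) {
  n1 <- round(length_out * 89 / 144)   # 31 for the default length
  n0 <- length_out - n1
  set.seed(seed)
  repeat {
    s <- sample(c(rep("0", n0), rep("1", n1)))
    txt <- paste(s, collapse = "")
    if (grepl("00", txt, fixed = TRUE) && grepl("111", txt, fixed = TRUE))
      return(s)
  }
}

#' Build a full serial reaction-time session
#'
#' Eight blocks: block 0 is the ungrammatical training sequence; blocks
#' 1 to 7 each present a full generation 11 of the grammar (144 symbols,
#' 1008 experimental trials).  Stimuli map 0 to a red circle answered with
#' 'M' and 1 to a blue circle answered with 'Z'; every stimulus is followed
#' by a 500 ms inter-stimulus interval.  Each experimental block is
#' annotated independently with ambiguity levels (no cross-block context).
#'
#' @param seed RNG seed (affects only the training-block order).
#' @param generation grammar generation per experimental block.
#' @param n_blocks_exp number of experimental blocks.
#' @param max_level annotation depth passed to [assign_ambiguity_levels()].
#' @return list of class `session_spec` with `trials` (one row per trial)
#'   and `seed`.  Trial columns: `block`, `trial_in_block` (0-based),
#'   `symbol`, `color`, `expected_key`, `isi_ms`, plus annotation columns
#'   (`NA` for the training block).
#' @examples
#' ses <- build_session(seed = 1)
#' table(ses$trials$block)
#' @export
build_session <- function(seed = 1L, generation = 11L, n_blocks_exp = 7L,
                          max_level = 5L) {
  train <- build_training_block(seed)
  g <- fib_generate(generation)
  ann <- assign_ambiguity_levels(g, max_level = max_level)
  ann_cols <- setdiff(names(ann), c("position", "symbol"))

  block_df <- function(block, sym, ann = NULL) {
    d <- data.frame(block = block,
                    trial_in_block = seq_along(sym) - 1L,
                    symbol = sym,
                    color = ifelse(sym == "0", "red", "blue"),
                    expected_key = ifelse(sym == "0", "M", "Z"),
                    isi_ms = 500L,
                    stringsAsFactors = FALSE)
    if (is.null(ann)) {
      for (cc in ann_cols) d[[cc]] <- NA
    } else {
      for (cc in ann_cols) d[[cc]] <- ann[[cc]]
    }
    d
  }

  trials <- block_df(0L, train)
  for (b in seq_len(n_blocks_exp))
    trials <- rbind(trials, block_df(b, g$symbols, ann))
  rownames(trials) <- NULL
  structure(list(trials = trials, seed = seed, generation = generation),
            class = "session_spec")
}

#' @export
print.session_spec <- function(x, ...) {
  nb <- length(unique(x$trials$block))
  cat("session_spec:", nrow(x$trials), "trials in", nb, "blocks",
      "(training block 0 +", nb - 1L, "experimental)\n")
  invisible(x)
}

#' Export / read a session trial list
#'
#' One CSV row per trial with all stimulus fields and annotation columns;
#' training rows have empty ambiguity columns.  Reading the file back
#' reproduces the trial table.
#'
#' @param session a `session_spec`.
#' @param path output CSV path.
#' @param participant_id optional id recorded in a leading column.
#' @return `path` invisibly (`export_trial_list`); a trial data frame
#'   (`read_trial_list`).
#' @export
export_trial_list <- function(session, path, participant_id = NA) {
  d <- session$trials
  d <- cbind(participant_id = participant_id, d)
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname export_trial_list
#' @export
read_trial_list <- function(path) {
  d <- utils::read.csv(path, na.strings = "",
                       colClasses = c(symbol = "character"))
  d
}
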