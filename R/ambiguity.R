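#' Surface-level (level-0) transition labels
#'
#' The grammar's two deterministic regularities classify every transition:
#' a 0 is always followed by a 1, and two 1s are always followed by a 0, so
#' a position whose prefix ends in '0' or in "11" is *unambiguous*; a
#' position whose prefix ends in exactly one '1' is *ambiguous* (a 1 can be
#' followed by either symbol).  The first position has no preceding context.
#'
#' @param s grammatical string (string, symbol vector, or `fib_string`).
#' @return character vector, one label per position, values
#'   `"no_context"`, `"unambiguous"`, `"ambiguous"`.
#' @examples
#' annotate_level0("10101101")
#' @export
annotate_level0 <- function(s) {
  sym <- as_symbols(s)
  v <- fib_validate(sym)
  if (!v$valid)
    stop("ungrammatical string (0-based position ", v$violations$position[1],
         ")")
  n <- length(sym)
  if (n < 2) stop("need at least 2 symbols")
  lab <- character(n)
  lab[1] <- "no_context"
  for (i in 2:n) {
    prev <- sym[i - 1L]
    if (prev == "0") {
      lab[i] <- "unambiguous"
    } else if (i >= 3 && sym[i - 2L] == "1") {
      lab[i] <- "unambiguous"            # prefix ends "11"
    } else {
      lab[i] <- "ambiguous"              # prefix ends a single '1'
    }
  }
  lab
}

#' Constituent-chunk hierarchy of a grammar string
#'
#' Repeatedly inverse-parses the string ([fib_parse_down()]), keeping track
#' of which surface span each constituent covers.  Level 0 is the surface
#' string itself (single-position spans); the labels of level `k` spans,
#' concatenated, equal the string's generation minus `k`.
#'
#' @param s grammatical string.
#' @param max_level number of chunked levels to build (level 0 is free).
#'   When this exceeds what the string supports, the hierarchy is truncated
#'   with a warning.
#' @return object of class `chunk_hierarchy`: a list with `levels`, where
#'   element `k + 1` is a data frame of half-open 0-based surface spans
#'   `start`, `end` and their `label` at level `k`.
#' @examples
#' h <- build_chunk_hierarchy("01101", 1)
#' h$levels[[2]]
#' @export
build_chunk_hierarchy <- function(s, max_level) {
  sym <- as_symbols(s)
  v <- fib_validate(sym)
  if (!v$valid)
    stop("ungrammatical string (0-based position ", v$violations$position[1],
         ")")
  levels <- list(data.frame(start = seq_along(sym) - 1L,
                            end = seq_along(sym), label = sym))
  cur <- sym
  k <- 0L
  while (k < max_level) {
    if (length(cur) < 2L) {
      warning("hierarchy truncated at level ", k,
              ": string too short to chunk further")
      break
    }
    prev_spans <- levels[[k + 1L]]
    starts <- integer(0); ends <- integer(0); labs <- character(0)
    i <- 1L
    n <- length(cur)
    j <- 1L   # index into prev_spans
    while (i <= n) {
      if (cur[i] == "0") {
        starts <- c(starts, prev_spans$start[j])
        ends <- c(ends, prev_spans$end[j + 1L])
        labs <- c(labs, "1")
        i <- i + 2L; j <- j + 2L
      } else {
        starts <- c(starts, prev_spans$start[j])
        ends <- c(ends, prev_spans$end[j])
        labs <- c(labs, "0")
        i <- i + 1L; j <- j + 1L
      }
    }
    k <- k + 1L
    levels[[k + 1L]] <- data.frame(start = starts, end = ends, label = labs)
    cur <- labs
  }
  structure(list(levels = levels, n = length(sym)), class = "chunk_hierarchy")
}

#' @export
print.chunk_hierarchy <- function(x, ...) {
  cat("chunk_hierarchy:", x$n, "surface symbols,",
      length(x$levels) - 1L, "chunked level(s)\n")
  for (k in seq_along(x$levels))
    cat("  level", k - 1L, ":", nrow(x$levels[[k]]), "constituents\n")
  invisible(x)
}

# Classify the transition into position j (1-based) of a label vector by
# the grammar's order-2 determinism rules.  Returns "det", "amb" or "none".
classify_transition <- function(labels, j) {
  if (j <= 1L) return("none")
  if (labels[j - 1L] == "0") return("det")
  if (j >= 3L && labels[j - 2L] == "1") return("det")
  "amb"
}

#' Assign a hierarchical ambiguity level to every position
#'
#' A position's ambiguity level is the minimal chunking level at which its
#' identity becomes deterministically predictable from the preceding
#' constituents.  Level 0 means the surface transition itself is
#' deterministic (prefix ends '0' or "11").  A surface-ambiguous position
#' always starts a new constituent at the next level, so the ambiguous
#' transition lifts to the transition between adjacent constituents there,
#' classified by the same two rules on the level's label string; the
#' recursion stops when the lifted transition is deterministic (the level
#' reached is the ambiguity level), or when the position runs out of
#' preceding context or `max_level` is exceeded (`"unresolved"`).
#'
#' @param s grammatical string.
#' @param max_level deepest chunked level consulted (default 5).
#' @return data frame of class `annotation_table`: `position` (0-based),
#'   `symbol`, `ambiguity_level` (integer, `NA` when not resolved),
#'   `status` (`"resolved"`, `"unresolved"`, `"no_context"`) and
#'   `class_at_level_0 ..  class_at_level_{max_level - 1}`.
#' @param pool_below when `TRUE`, a point resolved strictly below the class
#'   level L counts as "disambiguated" at L; by default it is reported as
#'   `"resolved_below"` so exactly-at-L and below-L points stay separable.
#' @examples
#' ann <- assign_ambiguity_levels(fib_generate(6))
#' table(ann$ambiguity_level, useNA = "ifany")
#' @export
assign_ambiguity_levels <- function(s, max_level = 5L, pool_below = FALSE) {
  sym <- as_symbols(s)
  h <- suppressWarnings(build_chunk_hierarchy(sym, max_level))
  built <- length(h$levels) - 1L
  # surface start position (0-based) of each constituent, per level
  starts <- lapply(h$levels, function(d) d$start)
  labels <- lapply(h$levels, function(d) d$label)
  n <- length(sym)
  lev <- rep(NA_integer_, n)
  status <- rep("resolved", n)
  for (i in seq_len(n)) {
    if (i == 1L) { status[i] <- "no_context"; next }
    k <- 0L
    repeat {
      j <- match(i - 1L, starts[[k + 1L]])   # position of i in level-k labels
      cls <- classify_transition(labels[[k + 1L]], j)
      if (cls == "det") { lev[i] <- k; break }
      if (cls == "none") { status[i] <- "unresolved"; break }
      if (k >= built) { status[i] <- "unresolved"; break }
      k <- k + 1L
    }
  }
  ann <- data.frame(position = seq_len(n) - 1L, symbol = sym,
                    ambiguity_level = lev, status = status,
                    stringsAsFactors = FALSE)
  for (L in 0:(max_level - 1L))
    ann[[paste0("class_at_level_", L)]] <-
      class_at_level(lev, status, L, pool_below)
  class(ann) <- c("annotation_table", "data.frame")
  ann
}

# Per-level point class given minimal resolving levels.
class_at_level <- function(lev, status, L, pool_below = FALSE) {
  cls <- character(length(lev))
  for (i in seq_along(lev)) {
    cls[i] <- if (status[i] == "no_context") "no_context"
    else if (status[i] == "unresolved") "ambiguous"
    else if (lev[i] == 0L) "unambiguous"
    else if (lev[i] > L) "ambiguous"
    else if (lev[i] == L) "disambiguated"
    else if (pool_below) "disambiguated" else "resolved_below"
  }
  cls
}

#' Brute-force minimal resolving level by context matching
#'
#' Verification oracle, independent of the rule-based classifier in
#' [assign_ambiguity_levels()]: at each level the two constituent labels
#' preceding the (lifted) transition are looked up in a long reference
#' generation; the level resolves the point if every occurrence of that
#' context in the reference is followed by the same symbol.
#'
#' @param s grammatical string.
#' @param i 0-based position.
#' @param ref_generation generation index of the reference string whose
#'   level-`k` labels supply the matching population (default 15).
#' @param max_level deepest level tried.
#' @return integer level, or `"no_context"` / `"unresolved"`.
#' @export
oracle_min_resolving_level <- function(s, i, ref_generation = 15L,
                                       max_level = 5L) {
  sym <- as_symbols(s)
  if (i == 0L) return("no_context")
  h <- suppressWarnings(build_chunk_hierarchy(sym, max_level))
  built <- length(h$levels) - 1L
  starts <- lapply(h$levels, function(d) d$start)
  labels <- lapply(h$levels, function(d) d$label)
  for (k in 0:min(max_level, built)) {
    j <- match(i, starts[[k + 1L]])
    if (is.null(j) || is.na(j))
      stop("position ", i, " is not a constituent start at level ", k)
    labs <- labels[[k + 1L]]
    if (j == 1L) return("unresolved")        # context exhausted at this level
    ctx <- labs[max(1L, j - 2L):(j - 1L)]    # up to two preceding labels
    ref <- fib_generate(ref_generation - k)$symbols
    m <- length(ctx)
    cand <- integer(0)
    for (pos in (m + 1L):length(ref))
      if (all(ref[(pos - m):(pos - 1L)] == ctx))
        cand <- c(cand, pos)
    nxt <- unique(ref[cand])
    if (length(nxt) == 1L) return(k)
  }
  "unresolved"
}

#' Write an annotation table as CSV
#'
#' Columns: `position` (0-based), `symbol`, `ambiguity_level`, `status`,
#' and `class_at_level_0` onward.
#'
#' @param ann an `annotation_table` from [assign_ambiguity_levels()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  utils::write.csv(as.data.frame(ann), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
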