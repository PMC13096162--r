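#' Fibonacci grammar rewriting system
#'
#' The Fibonacci grammar is a two-symbol Lindenmayer system: all symbols are
#' rewritten simultaneously at each generation, with no terminal symbols and
#' no rule-ordering convention.  The default system uses the rules
#' `0 -> 1` and `1 -> 01` with axiom `0`; under this convention
#' generation 11 has 144 symbols.
#'
#' @param rules named character vector mapping each symbol to its
#'   replacement string.
#' @param axiom single-character starting string.
#' @return an object of class `rewrite_system`.
#' @examples
#' sys <- fib_system()
#' fib_generate(3, sys)
#' @export
fib_system <- function(rules = c("0" = "1", "1" = "01"), axiom = "0") {
  alphabet <- names(rules)
  if (is.null(alphabet) || any(alphabet == ""))
    stop("every alphabet symbol needs a named rule")
  if (anyDuplicated(alphabet))
    stop("each symbol must have exactly one rule")
  repl_syms <- unique(unlist(strsplit(unname(rules), "", fixed = TRUE)))
  if (!all(repl_syms %in% alphabet))
    stop("replacement strings must use only alphabet symbols")
  if (nchar(axiom) != 1L || !axiom %in% alphabet)
    stop("axiom must be a single alphabet symbol")
  structure(list(alphabet = alphabet, rules = rules, axiom = axiom),
            class = "rewrite_system")
}

#' @export
print.rewrite_system <- function(x, ...) {
  cat("L-system over {", paste(x$alphabet, collapse = ","), "}, axiom '",
      x$axiom, "'\n", sep = "")
  for (s in x$alphabet)
    cat("  ", s, " -> ", x$rules[[s]], "\n", sep = "")
  invisible(x)
}

fib_string <- function(symbols, generation = NA_integer_) {
  structure(list(symbols = symbols, generation = generation),
            class = "fib_string")
}

#' @export
print.fib_string <- function(x, ...) {
  gen <- if (is.na(x$generation)) "unknown" else x$generation
  cat("fib_string, generation ", gen, ", length ", length(x$symbols),
      "\n", sep = "")
  s <- paste(x$symbols, collapse = "")
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 60), "...")
  cat(" ", s, "\n")
  invisible(x)
}

# Accept "0110", c("0","1","1","0") or a fib_string; return character vector
# of single symbols.
as_symbols <- function(s) {
  if (inherits(s, "fib_string")) return(s$symbols)
  if (is.character(s) && length(s) == 1L && nchar(s) > 1L)
    return(strsplit(s, "", fixed = TRUE)[[1]])
  as.character(s)
}

#' Generate a grammar string
#'
#' Applies `n` simultaneous rewriting passes of the system's rules to the
#' axiom.  For the default Fibonacci system the length of generation `n` is
#' the Fibonacci number `F(n)` with `F(0) = F(1) = 1`, and for `n >= 2` the
#' string equals the concatenation of generations `n - 2` and `n - 1`.
#'
#' @param n non-negative integer number of rewriting passes.
#' @param system a [fib_system()] object.
#' @return a `fib_string` carrying the generation index.
#' @examples
#' fib_generate(0)            # the axiom
#' fib_generate(3)            # "101"
#' length(fib_generate(11)$symbols)  # 144
#' @export
fib_generate <- function(n, system = fib_system()) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != floor(n))
    stop("n must be a single non-negative integer")
  s <- system$axiom
  if (n > 0) {
    for (i in seq_len(n))
      s <- paste(system$rules[strsplit(s, "", fixed = TRUE)[[1]]],
                 collapse = "")
  }
  fib_string(strsplit(s, "", fixed = TRUE)[[1]], generation = as.integer(n))
}

#' Check a symbol sequence for grammaticality
#'
#' A string over \{0, 1\} can be an output of the Fibonacci grammar only if it
#' contains neither "00" nor "111": a 0 is always followed by a 1, and two
#' 1s are always followed by a 0.
#'
#' @param s a string, character vector of symbols, or `fib_string`.
#' @return list with `valid` (logical) and `violations`, a data frame of
#'   0-based start positions and the forbidden substring found there.
#' @examples
#' fib_validate("01101")$valid   # TRUE
#' fib_validate("001")$violations
#' @export
fib_validate <- function(s) {
  sym <- as_symbols(s)
  if (!all(sym %in% c("0", "1")))
    stop("symbols outside alphabet {0,1}: ",
         paste(unique(setdiff(sym, c("0", "1"))), collapse = ", "))
  n <- length(sym)
  pos <- integer(0); what <- character(0)
  if (n >= 2) {
    i00 <- which(sym[-n] == "0" & sym[-1] == "0")
    pos <- c(pos, i00); what <- c(what, rep("00", length(i00)))
  }
  if (n >= 3) {
    i111 <- which(sym[seq_len(n - 2)] == "1" & sym[seq(2, n - 1)] == "1" &
                    sym[seq(3, n)] == "1")
    pos <- c(pos, i111); what <- c(what, rep("111", length(i111)))
  }
  o <- order(pos)
  list(valid = length(pos) == 0L,
       violations = data.frame(position = pos[o] - 1L, substring = what[o]))
}

#' Inverse-parse a grammar string one generation down
#'
#' The self-similarity of the grammar makes inverse rewriting deterministic:
#' scanning left to right, each "01" chunk maps to '1' and each remaining
#' lone '1' maps to '0'.  The result is the previous generation of the
#' grammar.
#'
#' @param s a grammatical string (see [fib_validate()]).
#' @param system a [fib_system()] (only the default rules are invertible
#'   this way).
#' @return a `fib_string` with generation index one less (when known).
#' @examples
#' fib_parse_down("01101")   # "101"
#' @export
fib_parse_down <- function(s, system = fib_system()) {
  sym <- as_symbols(s)
  v <- fib_validate(sym)
  if (!v$valid)
    stop("ungrammatical input at 0-based position ",
         v$violations$position[1], " ('", v$violations$substring[1], "')")
  n <- length(sym)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    if (sym[i] == "0") {
      if (i == n || sym[i + 1L] != "1")
        stop("ungrammatical input: unpaired '0' at 0-based position ", i - 1L)
      out <- c(out, "1")
      i <- i + 2L
    } else {
      out <- c(out, "0")
      i <- i + 1L
    }
  }
  gen <- if (inherits(s, "fib_string") && !is.na(s$generation))
    s$generation - 1L else NA_integer_
  fib_string(out, generation = gen)
}

#' Write / read a grammar string
#'
#' Strings are serialized as plain text ("0"/"1" characters) or as a
#' one-column CSV with a 0-based position index.
#'
#' @param s string to write.
#' @param path file path.
#' @param format `"txt"` (single line) or `"csv"` (position, symbol).
#' @return `path`, invisibly.
#' @export
write_fib_string <- function(s, path, format = c("txt", "csv")) {
  format <- match.arg(format)
  sym <- as_symbols(s)
  if (format == "txt") {
    writeLines(paste(sym, collapse = ""), path)
  } else {
    utils::write.csv(
      data.frame(position = seq_along(sym) - 1L, symbol = sym),
      path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_fib_string
#' @export
read_fib_string <- function(path, format = c("txt", "csv")) {
  format <- match.arg(format)
  if (format == "txt") {
    fib_string(as_symbols(readLines(path, n = 1L)))
  } else {
    d <- utils::read.csv(path, colClasses = c(symbol = "character"))
    fib_string(d$symbol)
  }
}
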