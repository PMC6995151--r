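#' Two-line dot-bracket encoding of tetrad pairings
#'
#' A tetrad's four pairs form a 4-cycle, which no single dot-bracket line
#' can express, so the encoding uses two bracket lines over one sequence
#' line: each tetrad contributes pairs (A,B) and (C,D) to line 1 and (B,C)
#' and (D,A) to line 2.  Within a line, crossing pairs receive distinct
#' bracket levels by greedy interval-graph colouring in order of 5'
#' endpoints; levels use the alphabet `()`, `[]`, `{}`, `<>`, then `Aa`
#' through `Zz`.  Unpaired positions are dots and chain breaks appear as
#' `-` in all three lines.  Parsing the two lines back recovers exactly the
#' encoded pair set.
#'
#' @param tetrads list of oriented `tetrad` objects (e.g. all tetrads of an
#'   analysis, quadruplex members and lone tetrads alike).
#' @param graph an [annotation_graph()].
#' @return An object of class `two_line_dot_bracket`: list with `sequence`,
#'   `line1`, `line2` (equal-length strings) and `columns` (residue row ->
#'   string column).
#' @export
encode_dot_bracket <- function(tetrads, graph) {
  ord <- order(global_index(graph))      # residue rows in 5'->3' order
  chains <- graph$residues$chain[ord]
  n <- length(ord)
  # assign string columns, inserting one '-' between consecutive chains
  cols <- integer(n)
  col <- 0L
  seq_chars <- character(0)
  for (k in seq_len(n)) {
    if (k > 1L && chains[k] != chains[k - 1L]) {
      col <- col + 1L
      seq_chars <- c(seq_chars, "-")
    }
    col <- col + 1L
    cols[k] <- col
    seq_chars <- c(seq_chars, graph$residues$base[ord[k]])
  }
  col_of <- integer(nrow(graph$residues))
  col_of[ord] <- cols
  width <- col

  pairs1 <- NULL; pairs2 <- NULL
  for (t in tetrads) {
    ab <- sort(col_of[t$abcd[c(1L, 2L)]])
    cd <- sort(col_of[t$abcd[c(3L, 4L)]])
    bc <- sort(col_of[t$abcd[c(2L, 3L)]])
    da <- sort(col_of[t$abcd[c(4L, 1L)]])
    pairs1 <- rbind(pairs1, ab, cd)
    pairs2 <- rbind(pairs2, bc, da)
  }
  line1 <- render_bracket_line(pairs1, width, seq_chars == "-")
  line2 <- render_bracket_line(pairs2, width, seq_chars == "-")
  structure(list(sequence = paste(seq_chars, collapse = ""),
                 line1 = line1, line2 = line2, columns = col_of),
            class = "two_line_dot_bracket")
}

BRACKET_LEVELS <- c("()", "[]", "{}", "<>",
                    paste0(LETTERS, letters))

render_bracket_line <- function(pairs, width, is_break) {
  chars <- rep(".", width)
  chars[is_break] <- "-"
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(paste(chars, collapse = ""))
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  np <- nrow(pairs)
  level <- integer(np)
  for (k in seq_len(np)) {
    lv <- 1L
    repeat {
      prior <- which(level == lv)
      crossing <- any(vapply(prior, function(m) {
        i <- pairs[m, 1L]; j <- pairs[m, 2L]
        a <- pairs[k, 1L]; b <- pairs[k, 2L]
        (i < a & a < j & j < b) | (a < i & i < b & b < j)
      }, logical(1)))
      if (!crossing) break
      lv <- lv + 1L
      if (lv > length(BRACKET_LEVELS))
        stop("more than ", length(BRACKET_LEVELS),
             " bracket levels required")
    }
    level[k] <- lv
  }
  for (k in seq_len(np)) {
    sym <- BRACKET_LEVELS[level[k]]
    chars[pairs[k, 1L]] <- substr(sym, 1L, 1L)
    chars[pairs[k, 2L]] <- substr(sym, 2L, 2L)
  }
  paste(chars, collapse = "")
}

#' Parse a dot-bracket line (or a two-line encoding) back into pairs
#'
#' Stack-based matching per bracket level.  For a `two_line_dot_bracket`
#' object both lines are parsed and the union returned.
#'
#' @param x a bracket line string, or a `two_line_dot_bracket`.
#' @return integer matrix with columns `open`, `close` (string columns,
#'   sorted), zero rows when nothing is paired.
#' @export
parse_dot_bracket <- function(x) {
  if (inherits(x, "two_line_dot_bracket")) {
    out <- rbind(parse_dot_bracket(x$line1), parse_dot_bracket(x$line2))
    return(out[order(out[, 1L], out[, 2L]), , drop = FALSE])
  }
  chars <- strsplit(x, "")[[1L]]
  out <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("open", "close")))
  for (sym in BRACKET_LEVELS) {
    op <- substr(sym, 1L, 1L); cl <- substr(sym, 2L, 2L)
    stack <- integer(0)
    for (k in seq_along(chars)) {
      if (chars[k] == op) stack <- c(stack, k)
      else if (chars[k] == cl) {
        if (length(stack) == 0L) stop("unbalanced '", cl, "' at column ", k)
        out <- rbind(out, c(stack[length(stack)], k))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack) > 0L)
      stop("unbalanced '", op, "' at column ", stack[1L])
  }
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

#' @export
print.two_line_dot_bracket <- function(x, ...) {
  cat(x$sequence, x$line1, x$line2, sep = "\n")
  invisible(x)
}
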