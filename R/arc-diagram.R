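#' Default arc-diagram palette
#'
#' Class O is blue, N green, Z orange; positive subclasses take the dark
#' shade and negative the light shade.  Unclassified tetrad arcs are grey;
#' canonical pairs outside the motif (shown with `complete_2d`) are black.
#'
#' @return named character vector of hex colours.
#' @export
default_palette <- function() {
  c("O+" = "#003366", "O-" = "#99CCFF",
    "N+" = "#006400", "N-" = "#90EE90",
    "Z+" = "#CC6600", "Z-" = "#FFCC66",
    unclassified = "#808080", canonical = "#000000")
}

#' Read a palette configuration file
#'
#' INI-style `key = value` lines (a `[palette]` section header is allowed
#' and ignored), e.g. `O+ = #112233`.  Unknown keys are rejected; missing
#' keys keep their defaults.
#'
#' @param path configuration file.
#' @return named character vector like [default_palette()].
#' @export
read_palette_config <- function(path) {
  pal <- default_palette()
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "[")]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("cannot parse palette line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(pal)) stop("unknown palette key: ", key)
    pal[[key]] <- val
  }
  pal
}

# arcs to draw: one row per pair, with colour class resolved
arc_table <- function(qa, complete_2d = FALSE) {
  graph <- qa$graph
  gidx <- global_index(graph)
  col_of <- qa$dot_bracket$columns
  out <- NULL
  tetrad_pairs_key <- character(0)
  all_tetrads <- c(unlist(lapply(qa$quadruplexes, `[[`, "tetrads"),
                          recursive = FALSE), qa$lone_tetrads)
  for (t in all_tetrads) {
    cls <- if (is.na(t$onz)) "unclassified" else t$onz
    for (k in 1:4) {
      a <- t$abcd[k]; b <- t$abcd[if (k == 4L) 1L else k + 1L]
      out <- rbind(out, data.frame(
        x1 = col_of[min(a, b)], x2 = col_of[max(a, b)], class = cls,
        stringsAsFactors = FALSE))
      tetrad_pairs_key <- c(tetrad_pairs_key,
                            paste(min(a, b), max(a, b)))
    }
  }
  if (complete_2d) {
    p <- graph$pairs
    canon <- p[p$canonical & !paste(p$i, p$j) %in% tetrad_pairs_key, ,
               drop = FALSE]
    if (nrow(canon) > 0L)
      out <- rbind(out, data.frame(x1 = col_of[canon$i], x2 = col_of[canon$j],
                                   class = "canonical",
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(x1 = integer(), x2 = integer(), class = character())
  # fix x1 < x2 then deterministic draw order
  sw <- out$x1 > out$x2
  tmp <- out$x1[sw]; out$x1[sw] <- out$x2[sw]; out$x2[sw] <- tmp
  out[order(out$x1, out$x2, out$class), , drop = FALSE]
}

#' Render the arc diagram as SVG
#'
#' Residues are laid out on a horizontal axis in the committed chain order
#' (chain breaks marked by gaps in the sequence line); every tetrad pair is
#' drawn as a semicircular arc coloured by the tetrad's ONZ class, with
#' grey arcs for unclassified tetrads.  With `complete_2d`, canonical pairs
#' outside the quadruplexes are added as black arcs.  The output is plain
#' SVG text with fixed number formatting and no timestamps, so identical
#' input yields byte-identical files.
#'
#' @param qa a `quadruplex_analysis`.
#' @param path output SVG path.
#' @param complete_2d include canonical pairs outside the motif.
#' @param palette named colour vector as in [default_palette()].
#' @return `path`, invisibly.
#' @export
render_arc_svg <- function(qa, path, complete_2d = FALSE,
                           palette = default_palette()) {
  arcs <- arc_table(qa, complete_2d)
  seq_chars <- strsplit(qa$dot_bracket$sequence, "")[[1L]]
  n <- length(seq_chars)
  step <- 14; margin <- 20
  xpos <- function(col) margin + (col - 1) * step
  width <- 2 * margin + (n - 1) * step
  max_r <- if (nrow(arcs)) max((arcs$x2 - arcs$x1) * step / 2) else 0
  top <- max_r + 10
  height <- top + 40
  lines <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            ceiling(width), ceiling(height), ceiling(width), ceiling(height)),
    sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#CCCCCC"/>',
            xpos(1), top, xpos(n), top)
  )
  for (k in seq_len(nrow(arcs))) {
    x1 <- xpos(arcs$x1[k]); x2 <- xpos(arcs$x2[k])
    r <- (x2 - x1) / 2
    col <- unname(palette[[arcs$class[k]]])
    lines <- c(lines, sprintf(
      '<path d="M %.1f %.1f A %.1f %.1f 0 0 1 %.1f %.1f" stroke="%s" fill="none" stroke-width="1.5"/>',
      x1, top, r, r, x2, top, col))
  }
  for (k in seq_len(n)) {
    if (seq_chars[k] == "-") next
    lines <- c(lines, sprintf(
      '<text x="%.1f" y="%.1f" font-family="monospace" font-size="10" text-anchor="middle">%s</text>',
      xpos(k), top + 14, seq_chars[k]))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}

#' Plot an arc diagram
#'
#' Base-graphics rendering of the same diagram [render_arc_svg()] writes.
#'
#' @param x a `quadruplex_analysis`.
#' @param complete_2d include canonical pairs outside the motif.
#' @param palette named colour vector as in [default_palette()].
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.quadruplex_analysis <- function(x, complete_2d = FALSE,
                                     palette = default_palette(), ...) {
  arcs <- arc_table(x, complete_2d)
  seq_chars <- strsplit(x$dot_bracket$sequence, "")[[1L]]
  n <- length(seq_chars)
  max_r <- if (nrow(arcs)) max((arcs$x2 - arcs$x1) / 2) else 1
  graphics::plot(NULL, xlim = c(0, n + 1), ylim = c(-1.5, max_r + 1),
                 axes = FALSE, xlab = "", ylab = "", asp = 1)
  graphics::segments(1, 0, n, 0, col = "grey80")
  th <- seq(0, pi, length.out = 60)
  for (k in seq_len(nrow(arcs))) {
    cx <- (arcs$x1[k] + arcs$x2[k]) / 2
    r <- (arcs$x2[k] - arcs$x1[k]) / 2
    graphics::lines(cx + r * cos(th), r * sin(th),
                    col = unname(palette[[arcs$class[k]]]), lwd = 2)
  }
  keep <- seq_chars != "-"
  graphics::text(seq_len(n)[keep], -0.8, seq_chars[keep], cex = 0.7,
                 family = "mono")
  invisible(x)
}
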