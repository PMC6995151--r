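#' Build an annotation graph
#'
#' The annotation graph is the uniform container every other function in the
#' package consumes: the ordered residue list of one structure model, the set
#' of base pairs with Leontis-Westhof edge/orientation labels, and the set of
#' base-stacking contacts.  It can be built directly (e.g. by the fixture
#' generators), read from a DSSR-style JSON annotation with
#' [read_dssr_json()], or derived from atomic coordinates with
#' [annotate_geometry()].
#'
#' Residues are stored in file order and identified internally by their row
#' number (a stable id).  The 5'->3' global index of a residue is *derived*
#' from the committed `chain_order` (see [global_index()]); re-ordering chains
#' never rewrites the residue table.
#'
#' @param residues data frame with columns `chain` (character), `number`
#'   (integer author residue number), `icode` (character insertion code, `""`
#'   if none), `base` (one-letter base code; `"?"` for unknown).
#' @param pairs data frame with columns `i`, `j` (residue row numbers,
#'   `i < j`), `orientation` (`"cis"`, `"trans"` or `NA`), `edge_i`, `edge_j`
#'   (`"W"`, `"H"`, `"S"` or `NA`: the Leontis-Westhof edge each endpoint
#'   uses).  A pair is stored once; [pair_edge_for()] answers queries from
#'   either side.
#' @param stacks data frame with columns `i`, `j` (residue row numbers,
#'   `i < j`): symmetric base-stacking contacts.
#' @param chain_order character vector of chain ids, each exactly once;
#'   defaults to order of first appearance in `residues`.
#' @return An object of class `annotation_graph`.
#' @export
annotation_graph <- function(residues, pairs = NULL, stacks = NULL,
                             chain_order = NULL) {
  stopifnot(is.data.frame(residues),
            all(c("chain", "number", "base") %in% names(residues)))
  residues <- data.frame(
    chain  = as.character(residues$chain),
    number = as.integer(residues$number),
    icode  = if ("icode" %in% names(residues))
               as.character(residues$icode) else rep("", nrow(residues)),
    base   = as.character(residues$base),
    stringsAsFactors = FALSE
  )
  key <- paste(residues$chain, residues$number, residues$icode)
  if (anyDuplicated(key))
    stop("duplicate residue identifier: ", key[duplicated(key)][1L])

  pairs  <- normalize_pairs(pairs, nrow(residues), residues)
  stacks <- normalize_stacks(stacks, nrow(residues))

  if (is.null(chain_order)) chain_order <- unique(residues$chain)
  chain_order <- as.character(chain_order)
  if (anyDuplicated(chain_order) || !setequal(chain_order, unique(residues$chain)))
    stop("chain_order must list each chain exactly once")

  structure(
    list(residues = residues, pairs = pairs, stacks = stacks,
         chain_order = chain_order),
    class = "annotation_graph"
  )
}

empty_pairs_df <- function() {
  data.frame(i = integer(), j = integer(),
             orientation = character(), edge_i = character(),
             edge_j = character(), canonical = logical(),
             stringsAsFactors = FALSE)
}

normalize_pairs <- function(pairs, n, residues) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty_pairs_df())
  stopifnot(all(c("i", "j") %in% names(pairs)))
  i <- as.integer(pairs$i); j <- as.integer(pairs$j)
  orientation <- if ("orientation" %in% names(pairs))
    as.character(pairs$orientation) else rep(NA_character_, length(i))
  edge_i <- if ("edge_i" %in% names(pairs))
    as.character(pairs$edge_i) else rep(NA_character_, length(i))
  edge_j <- if ("edge_j" %in% names(pairs))
    as.character(pairs$edge_j) else rep(NA_character_, length(i))
  # store once with i < j, swapping edge labels when flipped
  flip <- i > j
  tmp <- i[flip]; i[flip] <- j[flip]; j[flip] <- tmp
  tmp <- edge_i[flip]; edge_i[flip] <- edge_j[flip]; edge_j[flip] <- tmp
  if (any(i == j)) stop("self-pair not allowed")
  if (any(i < 1L | j > n)) stop("pair endpoint outside residue list")
  bad_or <- !is.na(orientation) & !orientation %in% c("cis", "trans")
  if (any(bad_or)) stop("orientation must be 'cis', 'trans' or NA")
  bad_e <- function(e) !is.na(e) & !e %in% c("W", "H", "S")
  if (any(bad_e(edge_i)) || any(bad_e(edge_j)))
    stop("edges must be 'W', 'H', 'S' or NA")
  df <- data.frame(i = i, j = j, orientation = orientation,
                   edge_i = edge_i, edge_j = edge_j,
                   stringsAsFactors = FALSE)
  dup <- duplicated(df[, c("i", "j")])
  df <- df[!dup, , drop = FALSE]
  df$canonical <- is_canonical_pair(df, residues)
  rownames(df) <- NULL
  df
}

normalize_stacks <- function(stacks, n) {
  if (is.null(stacks) || nrow(stacks) == 0L)
    return(data.frame(i = integer(), j = integer()))
  i <- as.integer(stacks$i); j <- as.integer(stacks$j)
  flip <- i > j
  tmp <- i[flip]; i[flip] <- j[flip]; j[flip] <- tmp
  if (any(i == j)) stop("self-stacking not allowed")
  if (any(i < 1L | j > n)) stop("stack endpoint outside residue list")
  df <- unique(data.frame(i = i, j = j))
  rownames(df) <- NULL
  df
}

# canonical = cis Watson-Crick/Watson-Crick A:U(T), G:C or G:U wobble
is_canonical_pair <- function(pairs, residues) {
  if (nrow(pairs) == 0L) return(logical(0))
  b1 <- toupper(residues$base[pairs$i])
  b2 <- toupper(residues$base[pairs$j])
  b1[b1 == "T"] <- "U"; b2[b2 == "T"] <- "U"
  combo <- paste(pmin(b1, b2), pmax(b1, b2))
  ok_combo <- combo %in% c("A U", "C G", "G U")
  !is.na(pairs$orientation) & pairs$orientation == "cis" &
    !is.na(pairs$edge_i) & pairs$edge_i == "W" &
    !is.na(pairs$edge_j) & pairs$edge_j == "W" & ok_combo
}

#' 5'->3' global index of every residue under a chain order
#'
#' Residues are ranked by the position of their chain in `chain_order`, then
#' by file order within the chain (assumed 5'->3').  The result is 0-based: a
#' bijection onto `0..N-1`.
#'
#' @param graph an [annotation_graph()].
#' @param chain_order chain permutation to use; defaults to the graph's
#'   committed order.
#' @return integer vector, one entry per residue row.
#' @export
global_index <- function(graph, chain_order = graph$chain_order) {
  chain_rank <- match(graph$residues$chain, chain_order)
  if (anyNA(chain_rank)) stop("chain_order is missing a chain present in residues")
  order(order(chain_rank, seq_len(nrow(graph$residues)))) - 1L
}

#' Query a stored pair from either direction
#'
#' Returns the pair record oriented as seen from residue `x` toward residue
#' `y`: `edge_x` is the Leontis-Westhof edge residue `x` uses.  Pairs are
#' stored once; querying `(y, x)` returns the same pair with edges swapped.
#'
#' @param graph an [annotation_graph()].
#' @param x,y residue row numbers.
#' @return A one-row data frame (`x`, `y`, `orientation`, `edge_x`, `edge_y`,
#'   `canonical`), or `NULL` when the residues are not paired.
#' @export
pair_edge_for <- function(graph, x, y) {
  p <- graph$pairs
  hit <- which((p$i == x & p$j == y) | (p$i == y & p$j == x))
  if (length(hit) == 0L) return(NULL)
  hit <- hit[1L]
  if (p$i[hit] == x) {
    data.frame(x = x, y = y, orientation = p$orientation[hit],
               edge_x = p$edge_i[hit], edge_y = p$edge_j[hit],
               canonical = p$canonical[hit], stringsAsFactors = FALSE)
  } else {
    data.frame(x = x, y = y, orientation = p$orientation[hit],
               edge_x = p$edge_j[hit], edge_y = p$edge_i[hit],
               canonical = p$canonical[hit], stringsAsFactors = FALSE)
  }
}

#' @export
print.annotation_graph <- function(x, ...) {
  cat("annotation graph:", nrow(x$residues), "residues,",
      nrow(x$pairs), "pairs,", nrow(x$stacks), "stacking contacts\n")
  cat("chains (committed order):", paste(x$chain_order, collapse = " "), "\n")
  invisible(x)
}

#' Write / read the internal annotation JSON dialect
#'
#' A plain JSON serialization of an annotation graph: `residues` (chain,
#' number, icode, base in file order), `pairs` and `stacks` referencing
#' residues by 1-based position, and `chain_order`.  Round-trips exactly.
#'
#' @param graph an [annotation_graph()].
#' @param path file path.
#' @return `write_annotation_json` returns `path` invisibly;
#'   `read_annotation_json` returns an [annotation_graph()].
#' @export
write_annotation_json <- function(graph, path) {
  obj <- list(
    residues = graph$residues,
    pairs = graph$pairs[, c("i", "j", "orientation", "edge_i", "edge_j")],
    stacks = graph$stacks,
    chain_order = graph$chain_order
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, na = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_annotation_json
#' @export
read_annotation_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$residues)) stop("not an annotation JSON: no 'residues'")
  res <- as.data.frame(obj$residues, stringsAsFactors = FALSE)
  if (is.null(res$icode)) res$icode <- ""
  res$icode[is.na(res$icode)] <- ""
  pairs <- if (!is.null(obj$pairs) && length(obj$pairs))
    as.data.frame(obj$pairs, stringsAsFactors = FALSE) else NULL
  stacks <- if (!is.null(obj$stacks) && length(obj$stacks))
    as.data.frame(obj$stacks, stringsAsFactors = FALSE) else NULL
  annotation_graph(res, pairs, stacks, chain_order = obj$chain_order)
}
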