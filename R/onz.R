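#' Classify a tetrad in the ONZ taxonomy
#'
#' With the tetrad oriented so that A is its 5'-most residue and pairs run
#' (A,B), (B,C), (C,D), (D,A), the class is read off the 5'->3' arrangement
#' of the remaining residues:
#'
#' \describe{
#'   \item{O+}{5'-A-B-C-D-3'}
#'   \item{O-}{5'-A-D-C-B-3'}
#'   \item{N+}{5'-A-B-D-C-3'}
#'   \item{N-}{5'-A-C-D-B-3'}
#'   \item{Z+}{5'-A-C-B-D-3'}
#'   \item{Z-}{5'-A-D-B-C-3'}
#' }
#'
#' The six permutations of B, C, D are exhaustive and mutually exclusive, so
#' every oriented tetrad receives exactly one label.  The letter names the
#' O-, N- or Z-shaped track the pairings trace in a secondary-structure
#' diagram; the sign records the cycle direction relative to the sequence
#' direction.
#'
#' @param tetrad a `tetrad` from [find_tetrads()] / [orient_tetrad()].
#' @param graph an [annotation_graph()].
#' @param gidx global index vector (defaults to the committed chain order).
#' @return The tetrad with `onz` set to one of `"O+"`, `"O-"`, `"N+"`,
#'   `"N-"`, `"Z+"`, `"Z-"`.
#' @export
classify_tetrad <- function(tetrad, graph, gidx = global_index(graph)) {
  stopifnot(inherits(tetrad, "tetrad"))
  idx <- gidx[tetrad$abcd]
  if (anyDuplicated(idx)) stop("tetrad residues must have distinct indices")
  if (which.min(idx) != 1L)
    stop("tetrad not oriented: A must be the 5'-most residue")
  pattern <- paste(c("B", "C", "D")[order(idx[2:4])], collapse = "")
  tetrad$onz <- switch(pattern,
    BCD = "O+", DCB = "O-", BDC = "N+", CDB = "N-", CBD = "Z+", DBC = "Z-")
  tetrad
}

#' Orient and classify a set of tetrads under a chain order
#'
#' Re-orients every cycle and assigns ONZ classes under the given chain
#' order.  Tetrads spanning more than one chain are classified only when
#' `classify_multichain` is `TRUE` (i.e. under a committed chain order from
#' the reordering step, or when reordering is accepted); otherwise their
#' class is left `NA`.
#'
#' @param tetrads list of `tetrad` objects.
#' @param graph an [annotation_graph()].
#' @param chain_order chain permutation to classify under.
#' @param classify_multichain logical.
#' @return list of classified `tetrad` objects, sorted by A's index.
#' @export
classify_tetrads <- function(tetrads, graph,
                             chain_order = graph$chain_order,
                             classify_multichain = TRUE) {
  gidx <- global_index(graph, chain_order)
  out <- lapply(tetrads, function(t) {
    t <- orient_tetrad(t$cycle, graph, gidx)
    multi <- length(tetrad_chains(t, graph)) > 1L
    if (!multi || classify_multichain) t <- classify_tetrad(t, graph, gidx)
    t
  })
  a_idx <- vapply(out, function(t) gidx[t$abcd[1L]], integer(1))
  out[order(a_idx)]
}
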