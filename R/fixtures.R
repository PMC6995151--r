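#' Synthetic tetrad fixture with known ground truth
#'
#' Builds an annotation graph containing one tetrad whose ONZ class is known
#' by construction: the four residues are laid out 5'->3' in the arrangement
#' defining the requested class, and the cycle pairs (A,B), (B,C), (C,D),
#' (D,A) are cis Watson-Crick/Hoogsteen with the first residue of each pair
#' on its Watson-Crick edge.  Optional unpaired spacer residues (seeded) are
#' interleaved; they cannot change the class, which depends only on the
#' relative order of the tetrad residues.
#'
#' For `chains > 1` the residues are distributed over several strands and
#' the file chain order is adversarial: under the input order the tetrad is
#' multimeric (left unclassified when reordering is disabled), and the
#' returned `expected$reordered` is the class the chain-reordering
#' optimization provably commits to.  With 2 chains the split is chosen so
#' that the reordering objective (maximum O, then N, then earliest chain
#' order) recovers exactly the requested class.  With 4 chains (one residue
#' per strand) every cycle admits an O-yielding permutation, so the
#' reordering outcome is always O with the requested sign; the requested
#' class is realized under the identity arrangement only.
#'
#' @param onz requested class: `"O+"`, `"O-"`, `"N+"`, `"N-"`, `"Z+"`,
#'   `"Z-"`.
#' @param chains 1, 2 or 4 strands.
#' @param seed optional integer; seeds spacer placement.
#' @return list with `graph` (an [annotation_graph()]), `members` (residue
#'   rows of A, B, C, D), and `expected` (`identity`: class under the file
#'   chain order; `reordered`: class after chain reordering; `no_reorder`:
#'   class with reordering disabled, `NA` for multimeric tetrads).
#' @export
make_tetrad_graph <- function(onz = c("O+", "O-", "N+", "N-", "Z+", "Z-"),
                              chains = 1L, seed = NULL) {
  onz <- match.arg(onz)
  chains <- as.integer(chains)
  if (!chains %in% c(1L, 2L, 4L)) stop("chains must be 1, 2 or 4")
  if (!is.null(seed)) set.seed(seed)

  # member letters in 5'->3' sequence order for each class
  seq_pattern <- list(
    "O+" = c("A", "B", "C", "D"), "O-" = c("A", "D", "C", "B"),
    "N+" = c("A", "B", "D", "C"), "N-" = c("A", "C", "D", "B"),
    "Z+" = c("A", "C", "B", "D"), "Z-" = c("A", "D", "B", "C"))[[onz]]

  if (chains == 1L) {
    chain_of <- rep("A", 4L)
    file_chain_order <- "A"
    expected <- list(identity = onz, reordered = onz, no_reorder = onz)
  } else if (chains == 2L) {
    # block split (positions in target order) making the reordering
    # objective recover the requested class; see the derivations in the
    # methods vignette
    k <- c("O+" = 2L, "O-" = 2L, "N+" = 2L, "N-" = 2L,
           "Z+" = 1L, "Z-" = 3L)[[onz]]
    chain_of <- c(rep("A", k), rep("B", 4L - k))
    file_chain_order <- c("B", "A")        # adversarial input order
    swapped_class <- c("O+" = "O+", "O-" = "O-", "N+" = "Z-",
                       "N-" = "Z+", "Z+" = "Z-", "Z-" = "Z+")[[onz]]
    expected <- list(identity = swapped_class, reordered = onz,
                     no_reorder = NA_character_)
  } else {
    # one residue per strand; strand ids follow the cycle (sign +) or the
    # reversed cycle (sign -) so the earliest O permutation has the
    # requested sign
    sign <- substr(onz, 2L, 2L)
    ids_by_member <- if (sign == "+")
      c(A = "A", B = "B", C = "C", D = "D")
    else
      c(A = "A", B = "D", C = "C", D = "B")
    chain_of <- unname(ids_by_member[seq_pattern])
    file_chain_order <- c("D", "C", "B", "A")  # adversarial input order
    expected <- list(identity = if (sign == "+") "O-" else "O+",
                     reordered = paste0("O", sign),
                     no_reorder = NA_character_)
  }

  # lay residues chain by chain in file_chain_order, keeping the target
  # arrangement within the concatenation of sorted chain ids
  member_letter <- seq_pattern          # position k holds this member
  rows <- data.frame(chain = chain_of, letter = member_letter,
                     pos = seq_len(4L), stringsAsFactors = FALSE)
  res <- NULL; member_row <- integer(0)
  for (ch in file_chain_order) {
    idx <- which(rows$chain == ch)
    for (k in idx) {
      n_spacer <- if (is.null(seed)) 0L else sample(0:2, 1L)
      if (n_spacer > 0L)
        res <- rbind(res, data.frame(chain = ch, base = sample(c("A", "C", "U"),
                     n_spacer, replace = TRUE), letter = NA, stringsAsFactors = FALSE))
      res <- rbind(res, data.frame(chain = ch, base = "G",
                                   letter = rows$letter[k],
                                   stringsAsFactors = FALSE))
    }
  }
  res$number <- stats::ave(seq_len(nrow(res)), res$chain, FUN = seq_along)
  residues <- data.frame(chain = res$chain, number = res$number, icode = "",
                         base = res$base, stringsAsFactors = FALSE)
  member_row <- vapply(c("A", "B", "C", "D"),
                       function(L) which(!is.na(res$letter) & res$letter == L),
                       integer(1))
  pairs <- cycle_pairs(member_row[c("A", "B", "C", "D")])
  graph <- annotation_graph(residues, pairs, chain_order = file_chain_order)
  list(graph = graph, members = member_row, expected = expected)
}

# directed 4-cycle as cis W->H pairs: (m1,m2),(m2,m3),(m3,m4),(m4,m1)
cycle_pairs <- function(m) {
  data.frame(i = m, j = m[c(2L, 3L, 4L, 1L)],
             orientation = "cis", edge_i = "W", edge_j = "H",
             stringsAsFactors = FALSE)
}

# directed cycle over the four tract columns for each tetrad class: entry k
# is the column holding cycle member k (A, B, C, D)
CYCLE_COLUMNS <- list(
  "O+" = c(1L, 2L, 3L, 4L), "O-" = c(1L, 4L, 3L, 2L),
  "N+" = c(1L, 2L, 4L, 3L), "N-" = c(1L, 4L, 2L, 3L),
  "Z+" = c(1L, 3L, 2L, 4L), "Z-" = c(1L, 3L, 4L, 2L))

#' Synthetic quadruplex fixture with known ground truth
#'
#' Builds a single-strand annotation graph of `n_tetrads` fully stacked
#' tetrads arranged in four tract blocks, realizing a requested ONZM class:
#' the tetrad letter (O, N, Z, or M for a mix of letters), the strand
#' progression (p/a/h via per-tract ascending or descending layout) and the
#' subtype sign (+, -, or * via per-tetrad cycle direction).  Consecutive
#' tetrads share 4/4 stacking contacts by default; `contacts_per_step`
#' lowers that (e.g. 2 to emulate imperfect stacking tolerated only at
#' stacking-mismatch 2).
#'
#' @param letter `"O"`, `"N"`, `"Z"` or `"M"`.
#' @param direction `"p"`, `"a"` or `"h"`.
#' @param sign `"+"`, `"-"` or `"*"`.
#' @param n_tetrads number of stacked tetrads (default 3; `"*"` and `"M"`
#'   require at least 2).
#' @param seed optional integer; seeds loop lengths between tract blocks.
#' @param contacts_per_step stacking contacts between consecutive tetrads
#'   (0 to 4, default 4).
#' @return list with `graph`, `columns` (list of 4 residue-row vectors, one
#'   per tract block in stack order), `expected` (list: `onzm`, `tetrads` =
#'   per-tetrad ONZ classes in stack order).
#' @export
make_quadruplex_graph <- function(letter = c("O", "N", "Z", "M"),
                                  direction = c("p", "a", "h"),
                                  sign = c("+", "-", "*"),
                                  n_tetrads = 3L, seed = NULL,
                                  contacts_per_step = 4L) {
  letter <- match.arg(letter); direction <- match.arg(direction)
  sign <- match.arg(sign)
  n <- as.integer(n_tetrads)
  if (n < 2L) stop("a quadruplex needs at least 2 tetrads")
  if (!is.null(seed)) set.seed(seed)

  letters_per <- switch(letter,
    M = rep(c("O", "Z"), length.out = n),
    rep(letter, n))
  signs_per <- switch(sign,
    "+" = rep("+", n), "-" = rep("-", n),
    "*" = c("-", rep("+", n - 1L)))
  onz_per <- paste0(letters_per, signs_per)

  desc_cols <- switch(direction, p = integer(0), a = c(2L, 4L), h = 4L)

  # column blocks along the chain with short loops between them
  loop_len <- function() if (is.null(seed)) 2L else sample(1:3, 1L)
  res <- NULL
  col_rows <- vector("list", 4L)
  for (col in 1:4) {
    if (col > 1L) {
      nl <- loop_len()
      loop_bases <- if (is.null(seed)) rep("U", nl)
                    else sample(c("A", "C", "U"), nl, replace = TRUE)
      res <- rbind(res, data.frame(base = loop_bases, col = NA, slot = NA))
    }
    res <- rbind(res, data.frame(base = "G", col = col, slot = seq_len(n)))
  }
  rownames(res) <- NULL
  for (col in 1:4) {
    rows_here <- which(!is.na(res$col) & res$col == col)
    # slot s of column col = residue of tetrad s; descending columns host
    # tetrad s at the opposite end of the block
    if (col %in% desc_cols) rows_here <- rev(rows_here)
    col_rows[[col]] <- rows_here
  }

  residues <- data.frame(chain = "A", number = seq_len(nrow(res)), icode = "",
                         base = res$base, stringsAsFactors = FALSE)
  pairs <- NULL; stacks <- NULL
  for (s in seq_len(n)) {
    cyc_cols <- CYCLE_COLUMNS[[onz_per[s]]]
    members <- vapply(cyc_cols, function(cc) col_rows[[cc]][s], integer(1))
    pairs <- rbind(pairs, cycle_pairs(members))
    if (s < n) {
      cols_with_contact <- seq_len(min(4L, max(0L, contacts_per_step)))
      for (cc in cols_with_contact)
        stacks <- rbind(stacks, data.frame(i = col_rows[[cc]][s],
                                           j = col_rows[[cc]][s + 1L]))
    }
  }
  graph <- annotation_graph(residues, pairs, stacks)
  list(graph = graph, columns = col_rows,
       expected = list(onzm = paste0(letter, direction, sign),
                       tetrads = onz_per))
}

#' Synthetic multimeric stack of quadruplexes (eight strands)
#'
#' A synthetic analogue of a tetramolecular DNA/RNA hybrid assembly: two
#' independent quadruplexes, each built from four strands contributing one
#' tract apiece, with a chosen number of tetrads and per-tetrad signs.
#' Under the (adversarial) file chain order all tetrads are multimeric and
#' unclassifiable without reordering; the reordering optimization commits
#' the sorted chain order, under which every tetrad is O-class with the
#' requested sign and each quadruplex is a parallel O (Op) motif.
#'
#' @param signs list of character vectors, one per quadruplex, giving each
#'   tetrad's sign (`"+"` or `"-"`) in stack order.
#' @param file_order chain order of the input file; defaults to a fixed
#'   scramble so that the identity order is adversarial.
#' @return list with `graph` and `expected` (`n_tetrads`, `onz` per tetrad
#'   after reordering, `onzm` per quadruplex, `chain_order` the reordering
#'   commits).
#' @export
make_multimer_graph <- function(signs = list(c("+", "+", "+", "+", "-"),
                                             c("+", "+", "-", "+", "-")),
                                file_order = NULL) {
  n_quad <- length(signs)
  chain_ids <- LETTERS[seq_len(4L * n_quad)]
  if (is.null(file_order)) {
    file_order <- unlist(lapply(seq_len(n_quad), function(q)
      chain_ids[4L * (q - 1L) + c(2L, 4L, 1L, 3L)]))
  }
  n_per <- vapply(signs, length, integer(1))
  # residue rows laid out chain by chain in file order
  chain_len <- stats::setNames(rep(n_per, each = 4L), chain_ids)
  residues <- do.call(rbind, lapply(file_order, function(ch)
    data.frame(chain = ch, number = seq_len(chain_len[[ch]]), icode = "",
               base = "G", stringsAsFactors = FALSE)))
  row_of <- function(ch, k) which(residues$chain == ch)[k]

  pairs <- NULL; stacks <- NULL
  onz_expected <- character(0)
  for (q in seq_len(n_quad)) {
    qchains <- chain_ids[4L * (q - 1L) + 1:4]
    for (s in seq_along(signs[[q]])) {
      cols <- if (signs[[q]][s] == "+") 1:4 else c(1L, 4L, 3L, 2L)
      members <- vapply(cols, function(cc) row_of(qchains[cc], s), integer(1))
      pairs <- rbind(pairs, cycle_pairs(members))
      onz_expected <- c(onz_expected, paste0("O", signs[[q]][s]))
      if (s < length(signs[[q]]))
        for (cc in 1:4)
          stacks <- rbind(stacks, data.frame(i = row_of(qchains[cc], s),
                                             j = row_of(qchains[cc], s + 1L)))
    }
  }
  graph <- annotation_graph(residues, pairs, stacks, chain_order = file_order)
  list(graph = graph,
       expected = list(n_tetrads = sum(n_per),
                       onz = onz_expected,
                       onzm = vapply(signs, function(sg)
                         paste0("Op", if (all(sg == "+")) "+"
                                else if (all(sg == "-")) "-" else "*"),
                         character(1)),
                       chain_order = chain_ids))
}

#' Random base-pair graph for oracle testing
#'
#' Seeded Erdos-Renyi-style pair graph over a single chain, with random
#' cis/trans orientations and edge labels.  Intended for comparing the
#' tetrad finder against brute-force enumeration on small cases.
#'
#' @param n_residues number of residues (default 10).
#' @param n_edges number of base pairs drawn without replacement.
#' @param seed integer seed.
#' @return An [annotation_graph()].
#' @export
make_random_pair_graph <- function(n_residues = 10L, n_edges = 12L, seed = 1L) {
  set.seed(seed)
  all_pairs <- utils::combn(n_residues, 2L)
  pick <- sample(ncol(all_pairs), min(n_edges, ncol(all_pairs)))
  edges <- all_pairs[, pick, drop = FALSE]
  pairs <- data.frame(
    i = edges[1L, ], j = edges[2L, ],
    orientation = sample(c("cis", "trans"), length(pick), replace = TRUE),
    edge_i = sample(c("W", "H", "S"), length(pick), replace = TRUE),
    edge_j = sample(c("W", "H", "S"), length(pick), replace = TRUE),
    stringsAsFactors = FALSE)
  residues <- data.frame(chain = "A", number = seq_len(n_residues),
                         icode = "", base = "G", stringsAsFactors = FALSE)
  annotation_graph(residues, pairs)
}
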