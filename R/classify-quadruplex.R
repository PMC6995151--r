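#' Classify a quadruplex in the ONZM taxonomy
#'
#' The class combines three ingredients.  The *letter* is the common ONZ
#' letter of the component tetrads (O, N or Z) for regular motifs, or M
#' (mixed) when the tetrad letters differ; a quadruplex containing any
#' unclassified tetrad falls into class R.  The *direction* comes from the
#' four N-tracts: each tract's residue indices read along the tetrad stack
#' are either ascending or descending, and all four agreeing gives a
#' parallel (p) motif, a 2-vs-2 split antiparallel (a), and a 1-vs-3 split
#' hybrid (h).  The *sign* is `+` when all tetrads are positive, `-` when
#' all are negative, and `*` for a mixture.
#'
#' A tract whose indices are not strictly monotone leaves the direction
#' undetermined (`"?"`, with a warning); the letter and sign are still
#' reported.
#'
#' @param q a `quadruplex` from [build_quadruplexes()].
#' @param graph an [annotation_graph()].
#' @param gidx global index vector under the committed chain order.
#' @return The quadruplex with `onzm` (e.g. `"Op+"`, `"Mh*"`, `"R"`),
#'   `direction` and `sign` filled in.
#' @export
classify_quadruplex <- function(q, graph, gidx = global_index(graph)) {
  stopifnot(inherits(q, "quadruplex"))
  onz <- vapply(q$tetrads, function(t) t$onz, character(1))
  if (anyNA(onz)) {
    q$onzm <- "R"; q$direction <- NA_character_; q$sign <- NA_character_
    return(q)
  }
  letters_ <- substr(onz, 1L, 1L)
  signs <- substr(onz, 2L, 2L)
  letter <- if (length(unique(letters_)) == 1L) letters_[1L] else "M"
  sign <- if (all(signs == "+")) "+" else if (all(signs == "-")) "-" else "*"

  dirs <- vapply(q$tracts, function(tr) {
    idx <- gidx[tr]
    d <- diff(idx)
    if (all(d > 0L)) "asc" else if (all(d < 0L)) "desc" else NA_character_
  }, character(1))
  if (anyNA(dirs)) {
    warning("non-monotone tract: quadruplex direction undetermined")
    direction <- "?"
  } else {
    n_desc <- sum(dirs == "desc")
    direction <- if (n_desc %in% c(0L, 4L)) "p"
                 else if (n_desc == 2L) "a" else "h"
  }
  q$onzm <- paste0(letter, direction, sign)
  q$direction <- direction
  q$sign <- sign
  q
}

#' Optimize the chain processing order of a multimeric motif
#'
#' The ONZ classification follows the 5'->3' direction, so for motifs built
#' from several strands the chain order decides the class.  All permutations
#' of the chains participating in tetrads are examined (non-participating
#' chains keep their relative order and are placed after), tetrads are
#' re-oriented and re-classified under each, and the permutation maximizing
#' the number of O-class tetrads is committed (ties: more N tetrads, then
#' the lexicographically earliest chain order).  In structures observed so
#' far O-type tetrads dominate, which motivates the objective.
#'
#' With more than `max_chains` participating chains the exhaustive search is
#' refused and the identity order kept, with a warning.
#'
#' @param graph an [annotation_graph()].
#' @param tetrads list of `tetrad` objects.
#' @param max_chains refuse exhaustive search beyond this many participating
#'   chains (default 8).
#' @return list with `chain_order` (the committed full order), `tetrads`
#'   (re-classified under it) and `identity_o` / `best_o` (O-tetrad counts
#'   under the identity and committed orders).
#' @export
reorder_chains <- function(graph, tetrads, max_chains = 8L) {
  participating <- unique(unlist(lapply(tetrads, tetrad_chains, graph = graph)))
  participating <- graph$chain_order[graph$chain_order %in% participating]
  rest <- setdiff(graph$chain_order, participating)

  pre <- lapply(tetrads, precompute_orientation, graph = graph)
  count_on <- function(chain_order) {
    gidx <- global_index(graph, chain_order)
    onz <- vapply(pre, fast_classify_onz, character(1), gidx = gidx)
    c(o = sum(substr(onz, 1L, 1L) == "O"),
      n = sum(substr(onz, 1L, 1L) == "N"))
  }
  identity_order <- c(participating, rest)
  id_counts <- count_on(identity_order)

  if (length(participating) < 2L) {
    cl <- classify_tetrads(tetrads, graph, graph$chain_order)
    return(list(chain_order = graph$chain_order, tetrads = cl,
                identity_o = unname(id_counts["o"]),
                best_o = unname(id_counts["o"])))
  }
  if (length(participating) > max_chains) {
    warning("more than ", max_chains,
            " participating chains: exhaustive reordering refused, keeping input order")
    cl <- classify_tetrads(tetrads, graph, graph$chain_order)
    return(list(chain_order = graph$chain_order, tetrads = cl,
                identity_o = unname(id_counts["o"]),
                best_o = unname(id_counts["o"])))
  }

  perms <- permutations_of(sort(participating))
  best_order <- NULL; best_score <- c(-1L, -1L)
  for (r in seq_len(nrow(perms))) {
    ord <- c(perms[r, ], rest)
    sc <- count_on(ord)
    if (sc["o"] > best_score[1L] ||
        (sc["o"] == best_score[1L] && sc["n"] > best_score[2L])) {
      best_score <- unname(sc); best_order <- ord
    }
    # ties keep the earlier permutation: perms are generated in
    # lexicographic order of chain ids
  }
  cl <- classify_tetrads(tetrads, graph, best_order)
  list(chain_order = best_order, tetrads = cl,
       identity_o = unname(id_counts["o"]), best_o = best_score[1L])
}

# chain-order-independent orientation facts for one tetrad: for each cycle
# position, does that residue present its Watson-Crick edge (and the
# neighbour a non-WC edge) toward the next / previous cycle position?
precompute_orientation <- function(tetrad, graph) {
  cycle <- tetrad$cycle
  wc_to <- function(a, nb) {
    pr <- pair_edge_for(graph, a, nb)
    !is.null(pr) && !is.na(pr$edge_x) && pr$edge_x == "W" &&
      !is.na(pr$edge_y) && pr$edge_y != "W"
  }
  nxt_of <- c(2L, 3L, 4L, 1L); prv_of <- c(4L, 1L, 2L, 3L)
  list(cycle = cycle,
       wc_next = vapply(1:4, function(k) wc_to(cycle[k], cycle[nxt_of[k]]), logical(1)),
       wc_prev = vapply(1:4, function(k) wc_to(cycle[k], cycle[prv_of[k]]), logical(1)))
}

# integer-only orient + classify used inside the permutation search; must
# agree with orient_tetrad() + classify_tetrad()
fast_classify_onz <- function(pre, gidx) {
  idx <- gidx[pre$cycle]
  a_pos <- which.min(idx)
  nxt <- (a_pos %% 4L) + 1L
  prv <- ((a_pos + 2L) %% 4L) + 1L
  forward <- if (pre$wc_next[a_pos] && !pre$wc_prev[a_pos]) TRUE
             else if (pre$wc_prev[a_pos] && !pre$wc_next[a_pos]) FALSE
             else idx[nxt] <= idx[prv]
  pos <- if (forward) ((a_pos - 1L + 0:3) %% 4L) + 1L
         else ((a_pos - 1L - 0:3) %% 4L) + 1L
  bcd <- idx[pos[2:4]]
  pattern <- paste(c("B", "C", "D")[order(bcd)], collapse = "")
  switch(pattern,
    BCD = "O+", DCB = "O-", BDC = "N+", CDB = "N-", CBD = "Z+", DBC = "Z-")
}

# all permutations of a character vector, rows in lexicographic order
permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L, 1L))
  out <- NULL
  for (k in seq_len(n)) {
    sub <- permutations_of(x[-k])
    out <- rbind(out, cbind(x[k], sub, deparse.level = 0))
  }
  out
}
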