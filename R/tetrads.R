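#' Find tetrads in an annotation graph
#'
#' A tetrad is four residues forming a single 4-cycle in the base-pair
#' graph, each residue pairing with exactly its two cycle neighbours.  In
#' strict mode only cis pairs joining a Watson-Crick edge to a Hoogsteen
#' edge are traversable (the pairing chemistry of a canonical G-tetrad); by
#' default any base pair is traversable, which admits tetrads linked by
#' pairs of other types.
#'
#' Candidate 4-cycles may share residues; a maximum-cardinality
#' vertex-disjoint subset is selected, preferring (at equal cardinality)
#' subsets with more cis Watson-Crick/Hoogsteen pairs, then cycles earlier
#' in the 5'->3' order.  Each selected cycle is oriented with
#' [orient_tetrad()] and the list is returned sorted by the global index of
#' residue A.
#'
#' @param graph an [annotation_graph()].
#' @param strict logical; restrict traversable pairs to cis WC/Hoogsteen.
#' @return list of `tetrad` objects (fields `cycle`: residue rows in cycle
#'   adjacency order; `abcd`: rows ordered A,B,C,D; `n_cwh`: number of cis
#'   WC/Hoogsteen pairs among the 4 cycle pairs; `onz`: class label, filled
#'   by [classify_tetrad()], initially `NA`).
#' @export
find_tetrads <- function(graph, strict = FALSE) {
  gidx <- global_index(graph)
  cand <- candidate_cycles(graph, strict)
  if (length(cand) == 0L) return(list())
  chosen <- select_disjoint_cycles(cand, gidx)
  tetrads <- lapply(chosen, function(cy) orient_tetrad(cy, graph, gidx))
  a_idx <- vapply(tetrads, function(t) gidx[t$abcd[1L]], integer(1))
  tetrads[order(a_idx)]
}

# enumerate all simple 4-cycles among traversable pairs; a candidate is a
# list(cycle = 4 residue rows in adjacency order, n_cwh, key)
candidate_cycles <- function(graph, strict = FALSE) {
  p <- graph$pairs
  if (nrow(p) == 0L) return(list())
  if (strict) {
    keep <- !is.na(p$orientation) & p$orientation == "cis" &
      !is.na(p$edge_i) & !is.na(p$edge_j) &
      ((p$edge_i == "W" & p$edge_j == "H") |
       (p$edge_i == "H" & p$edge_j == "W"))
    p <- p[keep, , drop = FALSE]
  }
  if (nrow(p) == 0L) return(list())
  n <- nrow(graph$residues)
  adj <- vector("list", n)
  for (k in seq_len(nrow(p))) {
    adj[[p$i[k]]] <- c(adj[[p$i[k]]], p$j[k])
    adj[[p$j[k]]] <- c(adj[[p$j[k]]], p$i[k])
  }
  seen <- new.env(parent = emptyenv())
  out <- list()
  verts <- sort(unique(c(p$i, p$j)))
  # a 4-cycle u-v-w-x is determined by its two diagonals {u,w}, {v,x}:
  # v and x are common neighbours of u and w
  for (u in verts) for (w in verts) {
    if (w <= u) next
    common <- intersect(adj[[u]], adj[[w]])
    common <- common[common != u & common != w]
    if (length(common) < 2L) next
    common <- sort(common)
    for (a in seq_len(length(common) - 1L)) for (b in seq((a + 1L), length(common))) {
      v <- common[a]; x <- common[b]
      key <- cycle_key(u, w, v, x)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      cy <- c(u, v, w, x)
      out[[length(out) + 1L]] <- list(
        cycle = cy,
        n_cwh = count_cwh(graph, cy),
        key = key
      )
    }
  }
  out
}

# canonical identifier of a 4-cycle from its two diagonals {u,w}, {v,x}:
# the diagonal containing the smallest residue comes first, each sorted
cycle_key <- function(u, w, v, x) {
  d1 <- c(min(u, w), max(u, w)); d2 <- c(min(v, x), max(v, x))
  if (d2[1L] < d1[1L]) { tmp <- d1; d1 <- d2; d2 <- tmp }
  paste(d1[1L], d1[2L], d2[1L], d2[2L], sep = ".")
}

# number of cycle pairs that are cis Watson-Crick/Hoogsteen
count_cwh <- function(graph, cycle) {
  s <- 0L
  for (k in 1:4) {
    pr <- pair_edge_for(graph, cycle[k], cycle[if (k == 4L) 1L else k + 1L])
    if (is.null(pr)) next
    if (!is.na(pr$orientation) && pr$orientation == "cis" &&
        !is.na(pr$edge_x) && !is.na(pr$edge_y) &&
        setequal(c(pr$edge_x, pr$edge_y), c("W", "H")))
      s <- s + 1L
  }
  s
}

# choose a vertex-disjoint subset of candidate cycles maximizing, in order:
# cardinality, total cis-WC/H pair count, then earliest cycles (smallest
# sorted vector of per-cycle minimum global indices, then canonical key).
# Exact branch-and-bound over candidates in preference order; falls back to
# greedy beyond 32 candidates.
select_disjoint_cycles <- function(cand, gidx) {
  min_idx <- vapply(cand, function(c) min(gidx[c$cycle]), integer(1))
  cwh <- vapply(cand, function(c) c$n_cwh, integer(1))
  keys <- vapply(cand, function(c) c$key, character(1))
  ord <- order(-cwh, min_idx, keys)
  cand <- cand[ord]; min_idx <- min_idx[ord]; cwh <- cwh[ord]

  if (length(cand) > 32L) {
    warning("more than 32 candidate 4-cycles; using greedy disjoint selection")
    used <- integer(0); sel <- list()
    for (k in seq_along(cand)) {
      if (!any(cand[[k]]$cycle %in% used)) {
        sel[[length(sel) + 1L]] <- cand[[k]]
        used <- c(used, cand[[k]]$cycle)
      }
    }
    return(lapply(sel, `[[`, "cycle"))
  }

  best <- NULL
  score_of <- function(sel) {
    list(n = length(sel),
         cwh = sum(vapply(sel, function(k) cwh[k], integer(1))),
         mins = sort(min_idx[unlist(sel)]),
         keys = sort(vapply(sel, function(k) cand[[k]]$key, character(1))))
  }
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$n != b$n) return(a$n > b$n)
    if (a$cwh != b$cwh) return(a$cwh > b$cwh)
    cm <- compare_int_vec(a$mins, b$mins)
    if (cm != 0L) return(cm < 0L)
    compare_chr_vec(a$keys, b$keys) < 0L
  }
  n_cand <- length(cand)
  recurse <- function(k, sel, used) {
    if (k > n_cand) {
      sc <- score_of(sel)
      if (better(sc, best)) best <<- sc
      return(invisible())
    }
    # bound: even taking every remaining candidate cannot beat best count
    if (!is.null(best) && length(sel) + (n_cand - k + 1L) < best$n)
      return(invisible())
    cy <- cand[[k]]$cycle
    if (!any(cy %in% used)) recurse(k + 1L, c(sel, k), c(used, cy))
    recurse(k + 1L, sel, used)
  }
  recurse(1L, list(), integer(0))
  sel_idx <- which(vapply(seq_len(n_cand), function(k)
    cand[[k]]$key %in% best$keys, logical(1)))
  lapply(cand[sel_idx], `[[`, "cycle")
}

compare_int_vec <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0L) for (k in seq_len(n)) {
    if (a[k] < b[k]) return(-1L)
    if (a[k] > b[k]) return(1L)
  }
  sign(length(a) - length(b))
}

compare_chr_vec <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0L) for (k in seq_len(n)) {
    if (a[k] < b[k]) return(-1L)
    if (a[k] > b[k]) return(1L)
  }
  sign(length(a) - length(b))
}

#' Orient a 4-cycle into a canonical tetrad (A, B, C, D)
#'
#' A is the 5'-most residue of the cycle.  The traversal direction is chosen
#' so that in pair (A, B) residue A binds along its Watson-Crick edge (the
#' tetrad pairing convention: each first residue uses its Watson-Crick edge,
#' each second its Hoogsteen edge).  When A's edges are symmetric or
#' unknown, the direction runs toward the cycle neighbour of A with the
#' smaller global index.
#'
#' @param cycle integer vector of 4 residue rows in cycle adjacency order,
#'   or a `tetrad` object.
#' @param graph an [annotation_graph()].
#' @param gidx global index vector (defaults to the graph's committed order).
#' @return A `tetrad` object with `abcd` filled in.
#' @export
orient_tetrad <- function(cycle, graph, gidx = global_index(graph)) {
  if (inherits(cycle, "tetrad")) cycle <- cycle$cycle
  stopifnot(length(cycle) == 4L)
  a_pos <- which.min(gidx[cycle])
  a <- cycle[a_pos]
  nxt <- cycle[if (a_pos == 4L) 1L else a_pos + 1L]
  prv <- cycle[if (a_pos == 1L) 4L else a_pos - 1L]
  wc_to <- function(nb) {
    pr <- pair_edge_for(graph, a, nb)
    !is.null(pr) && !is.na(pr$edge_x) && pr$edge_x == "W" &&
      !is.na(pr$edge_y) && pr$edge_y != "W"
  }
  w_nxt <- wc_to(nxt); w_prv <- wc_to(prv)
  b <- if (w_nxt && !w_prv) nxt
       else if (w_prv && !w_nxt) prv
       else if (gidx[nxt] <= gidx[prv]) nxt else prv
  # walk the cycle from a toward b
  if (b == nxt) {
    abcd <- cycle[((a_pos - 1L + 0:3) %% 4L) + 1L]
  } else {
    abcd <- cycle[((a_pos - 1L - 0:3) %% 4L) + 1L]
  }
  structure(list(cycle = cycle, abcd = abcd,
                 n_cwh = count_cwh(graph, cycle),
                 onz = NA_character_),
            class = "tetrad")
}

#' @export
print.tetrad <- function(x, ...) {
  cat("tetrad (A,B,C,D) rows:", paste(x$abcd, collapse = ","),
      " class:", ifelse(is.na(x$onz), "unclassified", x$onz), "\n")
  invisible(x)
}

# chains touched by a tetrad
tetrad_chains <- function(t, graph) unique(graph$residues$chain[t$abcd])
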