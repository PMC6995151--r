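#' Stacking parameters for quadruplex assembly
#'
#' @param mismatch integer 0, 1 or 2 (default 2): how many of the four
#'   residue-residue stacking contacts between two consecutive tetrads may
#'   be missing.  0 enforces ideal geometry (all 4 aligned residues
#'   stacked); 2 leaves room for imperfect stacking.
#' @param relaxed_stem logical; when `TRUE`, sequentially neighbouring
#'   tetrads join the same quadruplex regardless of their mutual stacking.
#' @return list of class `stacking_params`.
#' @export
stacking_params <- function(mismatch = 2L, relaxed_stem = FALSE) {
  mismatch <- as.integer(mismatch)
  if (!mismatch %in% 0:2) stop("mismatch must be 0, 1 or 2")
  structure(list(mismatch = mismatch, relaxed_stem = isTRUE(relaxed_stem)),
            class = "stacking_params")
}

# 4x4 logical contact matrix between the residues of two tetrads
stack_matrix <- function(t1, t2, graph) {
  s <- graph$stacks
  m <- matrix(FALSE, 4L, 4L)
  if (nrow(s) == 0L) return(m)
  key <- paste(s$i, s$j)
  for (a in 1:4) for (b in 1:4) {
    r1 <- t1$abcd[a]; r2 <- t2$abcd[b]
    m[a, b] <- paste(min(r1, r2), max(r1, r2)) %in% key
  }
  m
}

ALL_PERMS4 <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
ALL_PERMS4 <- ALL_PERMS4[apply(ALL_PERMS4, 1L, function(p) length(unique(p)) == 4L), ]
ALL_PERMS4 <- ALL_PERMS4[do.call(order, as.data.frame(ALL_PERMS4)), ]

# best one-to-one assignment t1 -> t2 maximizing matched stacking contacts;
# exact over all 4! permutations, ties broken by lexicographically smallest
# permutation.  Returns list(count, perm).
best_stack_matching <- function(t1, t2, graph) {
  m <- stack_matrix(t1, t2, graph)
  best_n <- -1L; best_p <- NULL
  for (r in seq_len(nrow(ALL_PERMS4))) {
    p <- ALL_PERMS4[r, ]
    n <- sum(m[cbind(1:4, p)])
    if (n > best_n) { best_n <- n; best_p <- p }
  }
  list(count = best_n, perm = unname(best_p))
}

#' Are two tetrads stacked?
#'
#' Two tetrads stack when a one-to-one matching of their residues exists
#' with at least `4 - mismatch` matched residue pairs present in the
#' stacking-contact set.  The maximum matching is computed exactly over all
#' 4! assignments.
#'
#' @param t1,t2 `tetrad` objects from the same graph.
#' @param graph an [annotation_graph()].
#' @param params a [stacking_params()].
#' @return logical.
#' @export
tetrads_stacked <- function(t1, t2, graph, params = stacking_params()) {
  best_stack_matching(t1, t2, graph)$count >= 4L - params$mismatch
}

# sequential adjacency for relaxed-stem mode: the tetrads share >=1 chain
# and, on every shared chain, the gap between their index ranges contains
# no residue belonging to a third tetrad
sequentially_adjacent <- function(t1, t2, graph, all_tetrads, gidx) {
  ch1 <- graph$residues$chain[t1$abcd]
  ch2 <- graph$residues$chain[t2$abcd]
  shared <- intersect(ch1, ch2)
  if (length(shared) == 0L) return(FALSE)
  other_res <- setdiff(unlist(lapply(all_tetrads, `[[`, "abcd")),
                       c(t1$abcd, t2$abcd))
  between <- gidx[other_res]
  for (ch in shared) {
    i1 <- gidx[t1$abcd[ch1 == ch]]
    i2 <- gidx[t2$abcd[ch2 == ch]]
    overlap <- min(i1) <= max(i2) && min(i2) <= max(i1)
    if (overlap) next
    gap_lo <- min(max(i1), max(i2))
    gap_hi <- max(min(i1), min(i2))
    if (any(between > gap_lo & between < gap_hi)) return(FALSE)
  }
  TRUE
}

#' Group tetrads into quadruplexes
#'
#' Builds the tetrad graph whose edges join stacked tetrads (per
#' [tetrads_stacked()]), plus sequence-adjacency edges in relaxed-stem mode,
#' and takes connected components.  A component of at least two tetrads is a
#' quadruplex: its tetrads are ordered along a stacking path starting from
#' the tetrad holding the 5'-most residue, and its four tracts are built by
#' chaining the per-step stacking matchings from (A,B,C,D) of the first
#' tetrad.  Single-tetrad components are reported separately as lone
#' tetrads.
#'
#' @param tetrads list of (classified) `tetrad` objects, mutually disjoint.
#' @param graph an [annotation_graph()].
#' @param params a [stacking_params()].
#' @return list with `quadruplexes` (list of `quadruplex` objects) and
#'   `lone_tetrads` (list of `tetrad`).
#' @export
build_quadruplexes <- function(tetrads, graph, params = stacking_params()) {
  n <- length(tetrads)
  if (n == 0L) return(list(quadruplexes = list(), lone_tetrads = list()))
  gidx <- global_index(graph)
  adj <- matrix(FALSE, n, n)
  if (n > 1L) for (a in seq_len(n - 1L)) for (b in seq((a + 1L), n)) {
    e <- tetrads_stacked(tetrads[[a]], tetrads[[b]], graph, params)
    if (!e && params$relaxed_stem)
      e <- sequentially_adjacent(tetrads[[a]], tetrads[[b]], graph, tetrads, gidx)
    adj[a, b] <- adj[b, a] <- e
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  quadruplexes <- list(); lone <- list()
  for (cid in sort(unique(comp))) {
    members <- which(comp == cid)
    if (length(members) == 1L) {
      lone[[length(lone) + 1L]] <- tetrads[[members]]
      next
    }
    ordered <- order_component(members, tetrads, adj, gidx)
    quadruplexes[[length(quadruplexes) + 1L]] <-
      make_quadruplex(tetrads[ordered], graph, gidx)
  }
  # deterministic order: by 5'-most residue of each motif
  if (length(quadruplexes) > 1L) {
    first <- vapply(quadruplexes, function(q)
      min(gidx[unlist(lapply(q$tetrads, `[[`, "abcd"))]), integer(1))
    quadruplexes <- quadruplexes[order(first)]
  }
  if (length(lone) > 1L) {
    first <- vapply(lone, function(t) min(gidx[t$abcd]), integer(1))
    lone <- lone[order(first)]
  }
  list(quadruplexes = quadruplexes, lone_tetrads = lone)
}

# order the tetrads of a component along a Hamiltonian path in the stacking
# graph starting at the tetrad with the 5'-most residue; neighbours visited
# by ascending minimum index.  Falls back to plain index order (warning).
order_component <- function(members, tetrads, adj, gidx) {
  min_idx <- vapply(members, function(k) min(gidx[tetrads[[k]]$abcd]), integer(1))
  start <- members[which.min(min_idx)]
  n <- length(members)
  found <- NULL
  dfs <- function(path) {
    if (!is.null(found)) return(invisible())
    if (length(path) == n) { found <<- path; return(invisible()) }
    last <- path[length(path)]
    nbrs <- members[adj[last, members] & !(members %in% path)]
    if (length(nbrs) > 1L)
      nbrs <- nbrs[order(min_idx[match(nbrs, members)])]
    for (nb in nbrs) dfs(c(path, nb))
  }
  dfs(start)
  if (is.null(found)) {
    warning("no complete stacking path through component; ordering tetrads by sequence")
    return(members[order(min_idx)])
  }
  found
}

# assignment between consecutive tetrads when they have no stacking contact
# (relaxed adjacency): minimize total |index difference|, ties by
# lexicographically smallest permutation
closest_sequence_matching <- function(t1, t2, gidx) {
  best <- NULL; best_cost <- Inf
  for (r in seq_len(nrow(ALL_PERMS4))) {
    p <- ALL_PERMS4[r, ]
    cost <- sum(abs(gidx[t1$abcd] - gidx[t2$abcd[p]]))
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  unname(best)
}

make_quadruplex <- function(tetrads_ordered, graph, gidx) {
  k <- length(tetrads_ordered)
  tracts <- lapply(1:4, function(h) tetrads_ordered[[1L]]$abcd[h])
  cur <- tetrads_ordered[[1L]]$abcd
  for (step in seq_len(k - 1L)) {
    t1 <- tetrads_ordered[[step]]; t2 <- tetrads_ordered[[step + 1L]]
    mm <- best_stack_matching(t1, t2, graph)
    perm <- if (mm$count > 0L) mm$perm else closest_sequence_matching(t1, t2, gidx)
    # map current tract heads (residues of t1) to residues of t2
    nxt <- integer(4)
    for (h in 1:4) {
      pos_in_t1 <- match(cur[h], t1$abcd)
      nxt[h] <- t2$abcd[perm[pos_in_t1]]
    }
    for (h in 1:4) tracts[[h]] <- c(tracts[[h]], nxt[h])
    cur <- nxt
  }
  chains <- lapply(tetrads_ordered, function(t) unique(graph$residues$chain[t$abcd]))
  n4 <- any(vapply(seq_len(k), function(a) any(vapply(seq_len(k), function(b)
    length(intersect(chains[[a]], chains[[b]])) == 0L, logical(1))), logical(1)))
  structure(list(tetrads = tetrads_ordered, tracts = tracts,
                 n4_helix = n4, onzm = NA_character_,
                 direction = NA_character_, sign = NA_character_),
            class = "quadruplex")
}

#' @export
print.quadruplex <- function(x, ...) {
  cat("quadruplex:", length(x$tetrads), "tetrads, class",
      ifelse(is.na(x$onzm), "(unset)", x$onzm),
      if (isTRUE(x$n4_helix)) "[N4-helix]" else "", "\n")
  invisible(x)
}
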