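# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code path with the package internals they
# verify: cycles are found by testing every 4-subset, subset selection by
# complete enumeration, and matchings by recursive permutation generation.

# all 4-cycles in the traversable pair graph, as canonical diagonal keys
# "a.b.c.d" (diagonal holding the smallest residue first, each sorted)
oracle_cycles <- function(graph, strict = FALSE) {
  p <- graph$pairs
  if (strict) {
    keep <- !is.na(p$orientation) & p$orientation == "cis" &
      !is.na(p$edge_i) & !is.na(p$edge_j) &
      ((p$edge_i == "W" & p$edge_j == "H") |
       (p$edge_i == "H" & p$edge_j == "W"))
    p <- p[keep, , drop = FALSE]
  }
  has_edge <- function(a, b)
    any((p$i == min(a, b)) & (p$j == max(a, b)))
  n <- nrow(graph$residues)
  out <- character(0)
  if (n < 4L) return(out)
  subsets <- utils::combn(n, 4L)
  for (s in seq_len(ncol(subsets))) {
    q <- subsets[, s]   # sorted a < b < c < d
    a <- q[1L]; b <- q[2L]; c_ <- q[3L]; d <- q[4L]
    # three pairings by choice of a's diagonal partner
    trials <- list(c(b, c_, d), c(c_, b, d), c(d, b, c_))
    for (tr in trials) {
      diag2 <- sort(tr[2:3])
      # cycle: a - diag2[1] - tr[1] - diag2[2]
      if (has_edge(a, diag2[1L]) && has_edge(diag2[1L], tr[1L]) &&
          has_edge(tr[1L], diag2[2L]) && has_edge(diag2[2L], a)) {
        out <- c(out, paste(a, tr[1L], diag2[1L], diag2[2L], sep = "."))
      }
    }
  }
  unique(out)
}

key_vertices <- function(key) as.integer(strsplit(key, ".", fixed = TRUE)[[1L]])

# count of cis W/H pairs among a cycle's 4 edges, straight off the pair table
oracle_cwh_count <- function(graph, key) {
  v <- key_vertices(key)
  # key is (d1a, d1b, d2a, d2b): cycle order d1a-d2a-d1b-d2b
  cyc <- v[c(1L, 3L, 2L, 4L)]
  p <- graph$pairs
  s <- 0L
  for (k in 1:4) {
    a <- cyc[k]; b <- cyc[if (k == 4L) 1L else k + 1L]
    row <- which(p$i == min(a, b) & p$j == max(a, b))[1L]
    if (is.na(row)) next
    ok <- !is.na(p$orientation[row]) && p$orientation[row] == "cis" &&
      !is.na(p$edge_i[row]) && !is.na(p$edge_j[row]) &&
      setequal(c(p$edge_i[row], p$edge_j[row]), c("W", "H"))
    if (ok) s <- s + 1L
  }
  s
}

# best vertex-disjoint subset of cycles by complete enumeration, under the
# declared preference: most cycles, then most cis-W/H pairs, then smallest
# sorted vector of per-cycle minimum indices, then smallest sorted key list
oracle_select <- function(graph, keys, gidx) {
  m <- length(keys)
  if (m == 0L) return(character(0))
  verts <- lapply(keys, key_vertices)
  cwh <- vapply(keys, oracle_cwh_count, integer(1), graph = graph)
  mins <- vapply(verts, function(v) min(gidx[v]), integer(1))
  best <- NULL; best_sc <- NULL
  for (mask in 0:(2^m - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
    vv <- unlist(verts[sel])
    if (anyDuplicated(vv)) next
    sc <- list(n = length(sel), cwh = sum(cwh[sel]),
               mins = sort(mins[sel]), keys = sort(keys[sel]))
    if (is.null(best_sc) || oracle_score_better(sc, best_sc)) {
      best <- sel; best_sc <- sc
    }
  }
  sort(keys[best])
}

oracle_score_better <- function(a, b) {
  if (a$n != b$n) return(a$n > b$n)
  if (a$cwh != b$cwh) return(a$cwh > b$cwh)
  av <- paste(sprintf("%06d", a$mins), collapse = ","); bv <- paste(sprintf("%06d", b$mins), collapse = ",")
  if (av != bv) return(av < bv)
  paste(a$keys, collapse = "|") < paste(b$keys, collapse = "|")
}

# maximum bipartite matching count by recursive permutation enumeration
oracle_max_matching <- function(m) {
  stopifnot(nrow(m) == ncol(m))
  n <- nrow(m)
  best <- 0L
  recurse <- function(row, used, count) {
    if (row > n) { best <<- max(best, count); return(invisible()) }
    for (col in seq_len(n)) {
      if (col %in% used) next
      recurse(row + 1L, c(used, col), count + as.integer(m[row, col]))
    }
  }
  recurse(1L, integer(0), 0L)
  best
}

# canonical key of a tetrad object, for comparing against oracle keys
tetrad_key <- function(t) {
  cy <- t$cycle
  quadtet:::cycle_key(cy[1L], cy[3L], cy[2L], cy[4L])
}
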