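# shared in-code fixtures for the test suite

residues4 <- function(chains = rep("A", 4L)) {
  data.frame(chain = chains,
             number = stats::ave(seq_along(chains), chains, FUN = seq_along),
             icode = "", base = "G", stringsAsFactors = FALSE)
}

# directed cis W->H 4-cycle over residue rows m
cycle_pairs_df <- function(m) {
  data.frame(i = m, j = m[c(2:4, 1L)], orientation = "cis",
             edge_i = "W", edge_j = "H", stringsAsFactors = FALSE)
}

# the pair columns every tetrad of an analysis should contribute to the
# two-line dot-bracket, sorted; used as the parse-back reference
expected_pair_columns <- function(qa) {
  out <- NULL
  for (t in qa$tetrads) {
    ab <- t$abcd
    for (k in 1:4) {
      a <- qa$dot_bracket$columns[ab[k]]
      b <- qa$dot_bracket$columns[ab[if (k == 4L) 1L else k + 1L]]
      out <- rbind(out, sort(c(a, b)))
    }
  }
  unname(out[order(out[, 1L], out[, 2L]), , drop = FALSE])
}

# graph holding a single oriented tetrad whose members sit at the given
# sequence positions (named A, B, C, D); extra unpaired residues pad to n
tetrad_at_positions <- function(posA, posB, posC, posD, n = NULL) {
  pos <- c(A = posA, B = posB, C = posC, D = posD)
  if (is.null(n)) n <- max(pos)
  res <- data.frame(chain = "A", number = seq_len(n), icode = "", base = "G",
                    stringsAsFactors = FALSE)
  annotation_graph(res, cycle_pairs_df(unname(pos)))
}
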