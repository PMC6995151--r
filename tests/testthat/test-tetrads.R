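test_that("a minimal 4-cycle gives one tetrad; chords do not add tetrads", {
  g <- annotation_graph(residues4(), cycle_pairs_df(1:4))
  tt <- find_tetrads(g)
  expect_length(tt, 1L)
  expect_identical(sort(tt[[1L]]$cycle), 1:4)

  # add chord 1-3: still exactly one tetrad on the same 4-cycle
  pairs <- rbind(cycle_pairs_df(1:4),
                 data.frame(i = 1L, j = 3L, orientation = "cis",
                            edge_i = "W", edge_j = "W"))
  g2 <- annotation_graph(residues4(), pairs)
  tt2 <- find_tetrads(g2)
  expect_length(tt2, 1L)
  expect_identical(tetrad_key(tt2[[1L]]), tetrad_key(tt[[1L]]))
})

test_that("overlapping candidate cycles resolve to a disjoint subset", {
  # cycles {1,2,3,4} and {2,3,4,5} share residues: only one survives
  res <- data.frame(chain = "A", number = 1:5, icode = "", base = "G",
                    stringsAsFactors = FALSE)
  pairs <- rbind(cycle_pairs_df(1:4), cycle_pairs_df(2:5))
  pairs <- pairs[!duplicated(t(apply(pairs[, 1:2], 1L, sort))), ]
  g <- annotation_graph(res, pairs)
  tt <- find_tetrads(g)
  expect_length(tt, 1L)
  # no residue in two reported tetrads (trivially true here), and the
  # choice matches the brute-force oracle
  keys <- oracle_select(g, oracle_cycles(g), global_index(g))
  expect_identical(sort(vapply(tt, tetrad_key, character(1))), keys)
})

test_that("strict mode traverses only cis Watson-Crick/Hoogsteen pairs", {
  pairs <- cycle_pairs_df(1:4)
  pairs$orientation[2L] <- "trans"
  g <- annotation_graph(residues4(), pairs)
  expect_length(find_tetrads(g, strict = TRUE), 0L)
  expect_length(find_tetrads(g, strict = FALSE), 1L)
})

test_that("tetrad finding equals brute-force enumeration on random graphs", {
  for (seed in 1:200) {
    n <- 9L + (seed %% 4L)
    g <- make_random_pair_graph(n_residues = n, n_edges = n + 3L, seed = seed)
    gidx <- global_index(g)
    got <- suppressWarnings(find_tetrads(g))
    expect_identical(sort(vapply(got, tetrad_key, character(1))),
                     oracle_select(g, oracle_cycles(g), gidx),
                     info = paste("seed", seed))
    # strict mode against the strict oracle every 10th trial
    if (seed %% 10L == 0L) {
      got_s <- suppressWarnings(find_tetrads(g, strict = TRUE))
      expect_identical(sort(vapply(got_s, tetrad_key, character(1))),
                       oracle_select(g, oracle_cycles(g, strict = TRUE), gidx),
                       info = paste("strict seed", seed))
    }
  }
})

test_that("orientation follows A's Watson-Crick edge, with index tie-break", {
  # cycle 1-2-3-4 with directed W->H pairs: A=1 presents W toward 2
  g <- annotation_graph(residues4(), cycle_pairs_df(1:4))
  t1 <- orient_tetrad(c(1L, 2L, 3L, 4L), g)
  expect_identical(t1$abcd, c(1L, 2L, 3L, 4L))

  # reversing every pair direction swaps B and D
  rev_pairs <- cycle_pairs_df(c(1L, 4L, 3L, 2L))
  g2 <- annotation_graph(residues4(), rev_pairs)
  t2 <- orient_tetrad(c(1L, 2L, 3L, 4L), g2)
  expect_identical(t2$abcd, c(1L, 4L, 3L, 2L))

  # all edges unknown: direction runs toward A's smaller-index neighbour
  unk <- cycle_pairs_df(1:4)
  unk$edge_i <- NA; unk$edge_j <- NA
  g3 <- annotation_graph(residues4(), unk)
  t3 <- orient_tetrad(c(2L, 3L, 4L, 1L), g3)   # same cycle, rotated input
  expect_identical(t3$abcd[1L], 1L)
  expect_identical(t3$abcd[2L], 2L)            # neighbours of 1 are 2 and 4
})

test_that("orientation is a pure function of the cycle, not input rotation", {
  g <- annotation_graph(residues4(), cycle_pairs_df(1:4))
  rotations <- list(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 1L),
                    c(3L, 4L, 1L, 2L), c(4L, 1L, 2L, 3L))
  outs <- lapply(rotations, function(cy) orient_tetrad(cy, g)$abcd)
  for (o in outs) expect_identical(o, outs[[1L]])
})
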