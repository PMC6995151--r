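test_that("graph construction enforces its invariants", {
  g <- annotation_graph(residues4(), cycle_pairs_df(1:4))
  expect_s3_class(g, "annotation_graph")
  expect_identical(g$chain_order, "A")
  expect_identical(global_index(g), 0:3)

  dup <- residues4(); dup$number <- c(1L, 1L, 2L, 3L)
  expect_error(annotation_graph(dup), "duplicate residue")
  expect_error(annotation_graph(residues4(), data.frame(i = 1L, j = 5L)),
               "outside")
  expect_error(annotation_graph(residues4(), data.frame(i = 2L, j = 2L)),
               "self-pair")
  expect_error(annotation_graph(residues4(), chain_order = c("A", "B")),
               "chain_order")
})

test_that("pairs are stored once and queried symmetrically from both sides", {
  pairs <- data.frame(i = 3L, j = 1L, orientation = "trans",
                      edge_i = "H", edge_j = "W")
  g <- annotation_graph(residues4(), pairs)
  expect_equal(nrow(g$pairs), 1L)
  expect_true(g$pairs$i < g$pairs$j)
  fwd <- pair_edge_for(g, 1L, 3L)
  rev <- pair_edge_for(g, 3L, 1L)
  expect_identical(fwd$edge_x, rev$edge_y)
  expect_identical(fwd$edge_y, rev$edge_x)
  expect_identical(fwd$orientation, "trans")
  expect_null(pair_edge_for(g, 1L, 2L))
})

test_that("global_index follows chain order then intra-chain file order", {
  res <- data.frame(chain = c("B", "B", "A", "A"), number = c(1L, 2L, 1L, 2L),
                    icode = "", base = "G", stringsAsFactors = FALSE)
  g <- annotation_graph(res)
  expect_identical(g$chain_order, c("B", "A"))          # file order
  expect_identical(global_index(g), c(0L, 1L, 2L, 3L))
  expect_identical(global_index(g, c("A", "B")), c(2L, 3L, 0L, 1L))
  expect_identical(sort(global_index(g)), 0:3)           # bijection
})

test_that("canonical flag marks cis W/W A:U, G:C and G:U only", {
  res <- data.frame(chain = "A", number = 1:6, icode = "",
                    base = c("G", "C", "A", "U", "G", "G"),
                    stringsAsFactors = FALSE)
  pairs <- data.frame(i = c(1L, 3L, 5L, 1L),
                      j = c(2L, 4L, 6L, 4L),
                      orientation = c("cis", "cis", "cis", "trans"),
                      edge_i = c("W", "W", "W", "W"),
                      edge_j = c("W", "W", "H", "W"))
  g <- annotation_graph(res, pairs)
  expect_identical(g$pairs$canonical, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("annotation JSON dialect round-trips a graph exactly", {
  fx <- make_quadruplex_graph("N", "a", "*", 3, seed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  write_annotation_json(fx$graph, path)
  g2 <- read_annotation_json(path)
  expect_identical(g2$residues, fx$graph$residues)
  expect_identical(g2$pairs, fx$graph$pairs)
  expect_identical(g2$stacks, fx$graph$stacks)
  expect_identical(g2$chain_order, fx$graph$chain_order)
})
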