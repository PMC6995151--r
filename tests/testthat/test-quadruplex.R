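two_tetrad_graph <- function(n_contacts = 4L) {
  make_quadruplex_graph("O", "p", "+", n_tetrads = 2L,
                        contacts_per_step = n_contacts)
}

test_that("stacking decision follows the 4 - mismatch contact threshold", {
  for (nc in 0:4) {
    fx <- two_tetrad_graph(nc)
    tt <- classify_tetrads(find_tetrads(fx$graph), fx$graph)
    for (mm in 0:2) {
      got <- tetrads_stacked(tt[[1L]], tt[[2L]], fx$graph,
                             stacking_params(mismatch = mm))
      expect_identical(got, nc >= 4L - mm,
                       info = paste("contacts", nc, "mismatch", mm))
    }
  }
})

test_that("maximum stacking matching equals exhaustive enumeration", {
  for (seed in 1:200) {
    set.seed(seed)
    m <- matrix(stats::runif(16) < 0.4, 4L, 4L)
    fx <- two_tetrad_graph(0L)
    g <- fx$graph
    tt <- classify_tetrads(find_tetrads(g), g)
    # install the random contact matrix between the two tetrads
    idx <- which(m, arr.ind = TRUE)
    g$stacks <- if (nrow(idx)) {
      data.frame(i = pmin(tt[[1L]]$abcd[idx[, 1L]], tt[[2L]]$abcd[idx[, 2L]]),
                 j = pmax(tt[[1L]]$abcd[idx[, 1L]], tt[[2L]]$abcd[idx[, 2L]]))
    } else data.frame(i = integer(), j = integer())
    got <- quadtet:::best_stack_matching(tt[[1L]], tt[[2L]], g)$count
    expect_identical(got, oracle_max_matching(m), info = paste("seed", seed))
  }
})

test_that("two stacked tetrads form one quadruplex; a lone tetrad does not", {
  fx <- two_tetrad_graph()
  tt <- classify_tetrads(find_tetrads(fx$graph), fx$graph)
  qs <- build_quadruplexes(tt, fx$graph)
  expect_length(qs$quadruplexes, 1L)
  expect_length(qs$lone_tetrads, 0L)

  lone <- make_tetrad_graph("O+")
  tl <- classify_tetrads(find_tetrads(lone$graph), lone$graph)
  ql <- build_quadruplexes(tl, lone$graph)
  expect_length(ql$quadruplexes, 0L)
  expect_length(ql$lone_tetrads, 1L)
})

test_that("tracts chain the stacking matchings through a 3-tetrad stack", {
  fx <- make_quadruplex_graph("O", "p", "+", n_tetrads = 3L)
  tt <- classify_tetrads(find_tetrads(fx$graph), fx$graph)
  qs <- build_quadruplexes(tt, fx$graph)
  q <- qs$quadruplexes[[1L]]
  expect_length(q$tetrads, 3L)
  # tract k must equal column k of the generator layout
  for (k in 1:4)
    expect_identical(q$tracts[[k]], fx$columns[[k]])
  # tract consistency: row s across tracts reconstructs tetrad s
  for (s in 1:3)
    expect_setequal(vapply(q$tracts, `[`, integer(1), s),
                    q$tetrads[[s]]$abcd)
})

test_that("stacked-pair relation is monotone in the mismatch parameter", {
  for (seed in 1:25) {
    set.seed(seed)
    nc <- sample(0:4, 1L)
    fx <- two_tetrad_graph(nc)
    tt <- classify_tetrads(find_tetrads(fx$graph), fx$graph)
    prev <- FALSE
    for (mm in 0:2) {
      cur <- tetrads_stacked(tt[[1L]], tt[[2L]], fx$graph,
                             stacking_params(mismatch = mm))
      expect_true(!prev || cur)   # once stacked, stays stacked as mm grows
      prev <- cur
    }
  }
})

test_that("every tetrad lands in exactly one quadruplex or the lone list", {
  fx1 <- make_quadruplex_graph("O", "p", "+", 3L, seed = 3)
  fx2 <- make_tetrad_graph("Z+", seed = 4)
  # merge the two graphs into one (disjoint residue blocks)
  off <- nrow(fx1$graph$residues)
  res <- rbind(fx1$graph$residues,
               transform(fx2$graph$residues, chain = "B"))
  pairs <- rbind(fx1$graph$pairs,
                 transform(fx2$graph$pairs, i = i + off, j = j + off))
  g <- annotation_graph(res, pairs, fx1$graph$stacks)
  tt <- classify_tetrads(find_tetrads(g), g)
  qs <- build_quadruplexes(tt, g)
  placed <- c(unlist(lapply(qs$quadruplexes, function(q)
    lapply(q$tetrads, tetrad_key))),
    vapply(qs$lone_tetrads, tetrad_key, character(1)))
  expect_setequal(placed, vapply(tt, tetrad_key, character(1)))
  expect_length(placed, length(tt))
})

test_that("relaxed-stem mode joins sequential neighbours without stacking", {
  fx <- two_tetrad_graph(0L)    # no stacking contacts at all
  tt <- classify_tetrads(find_tetrads(fx$graph), fx$graph)
  strict_qs <- build_quadruplexes(tt, fx$graph, stacking_params(2L, FALSE))
  expect_length(strict_qs$quadruplexes, 0L)
  relaxed_qs <- build_quadruplexes(tt, fx$graph, stacking_params(2L, TRUE))
  expect_length(relaxed_qs$quadruplexes, 1L)
})
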