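pipeline_onzm <- function(fx) {
  qa <- quadruplex_analysis(fx$graph)
  expect_length(qa$quadruplexes, 1L)
  qa$quadruplexes[[1L]]$onzm
}

test_that("regular quadruplexes combine letter, tract direction and sign", {
  expect_identical(pipeline_onzm(make_quadruplex_graph("O", "p", "+", 3)), "Op+")
  expect_identical(pipeline_onzm(make_quadruplex_graph("O", "a", "+", 3)), "Oa+")
  expect_identical(pipeline_onzm(make_quadruplex_graph("O", "h", "-", 3)), "Oh-")
  expect_identical(pipeline_onzm(make_quadruplex_graph("Z", "a", "+", 2)), "Za+")
  # mixture of signs gives the * subtype, mixture of letters gives M
  expect_identical(pipeline_onzm(make_quadruplex_graph("O", "p", "*", 3)), "Op*")
  expect_identical(pipeline_onzm(make_quadruplex_graph("M", "p", "*", 2)), "Mp*")
  expect_identical(pipeline_onzm(make_quadruplex_graph("M", "h", "+", 3)), "Mh+")
})

test_that("a quadruplex with any unclassified tetrad falls into class R", {
  fx <- make_quadruplex_graph("O", "p", "+", 2)
  tt <- classify_tetrads(find_tetrads(fx$graph), fx$graph)
  tt[[1L]]$onz <- NA_character_
  qs <- build_quadruplexes(tt, fx$graph)
  q <- classify_quadruplex(qs$quadruplexes[[1L]], fx$graph)
  expect_identical(q$onzm, "R")
})

test_that("classification is invariant under reversing the stack order", {
  for (d in c("p", "a", "h")) {
    fx <- make_quadruplex_graph("O", d, "+", 3)
    tt <- classify_tetrads(find_tetrads(fx$graph), fx$graph)
    qs <- build_quadruplexes(tt, fx$graph)
    q <- qs$quadruplexes[[1L]]
    q_rev <- q
    q_rev$tetrads <- rev(q$tetrads)
    q_rev$tracts <- lapply(q$tracts, rev)
    expect_identical(classify_quadruplex(q, fx$graph)$onzm,
                     classify_quadruplex(q_rev, fx$graph)$onzm)
  }
})

test_that("exactly one direction and one sign are assigned", {
  for (L in c("O", "N", "Z", "M")) for (d in c("p", "a", "h"))
    for (s in c("+", "-", "*")) {
      fx <- make_quadruplex_graph(L, d, s, 3)
      qa <- quadruplex_analysis(fx$graph)
      q <- qa$quadruplexes[[1L]]
      expect_true(q$direction %in% c("p", "a", "h", "?"))
      expect_true(q$sign %in% c("+", "-", "*"))
      expect_identical(q$direction, d)
      expect_identical(q$sign, s)
    }
})

test_that("reordering never loses O tetrads and ties keep the earliest order", {
  for (seed in 1:100) {
    cls <- c("O+", "O-", "N+", "N-", "Z+", "Z-")[1L + (seed %% 6L)]
    nch <- if (seed %% 2L == 0L) 2L else 4L
    fx <- make_tetrad_graph(cls, chains = nch, seed = seed)
    tt <- find_tetrads(fx$graph)
    ro <- reorder_chains(fx$graph, tt)
    expect_gte(ro$best_o, ro$identity_o)
    expect_identical(ro$tetrads[[1L]]$onz, fx$expected$reordered,
                     info = paste(cls, nch, "seed", seed))
  }
})

test_that("two chain orders with equal objective keep the lexicographically earlier", {
  # Z- on two chains: both orders yield Z-family (zero O, zero N) classes,
  # so the sorted order must win
  fx <- make_tetrad_graph("Z-", chains = 2L)
  tt <- find_tetrads(fx$graph)
  ro <- reorder_chains(fx$graph, tt)
  expect_identical(ro$chain_order[1:2], c("A", "B"))
  expect_identical(ro$tetrads[[1L]]$onz, "Z-")
})

test_that("unimolecular structures keep the identity order and classes", {
  fx <- make_quadruplex_graph("N", "h", "+", 3, seed = 2)
  qa <- quadruplex_analysis(fx$graph)
  expect_identical(qa$chain_order, "A")
  expect_null(qa$reorder)
  expect_identical(qa$quadruplexes[[1L]]$onzm, "Nh+")
})

test_that("too many participating chains refuse exhaustive reordering", {
  fx <- make_multimer_graph(signs = rep(list(c("+", "+")), 3L))  # 12 chains
  tt <- find_tetrads(fx$graph)
  expect_warning(ro <- reorder_chains(fx$graph, tt, max_chains = 8L),
                 "refused")
  expect_identical(ro$chain_order, fx$graph$chain_order)
})
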