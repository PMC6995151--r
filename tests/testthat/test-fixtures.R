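test_that("tetrad generator is sound for every class and chain count", {
  for (cl in c("O+", "O-", "N+", "N-", "Z+", "Z-")) {
    for (nch in c(1L, 2L, 4L)) {
      fx <- make_tetrad_graph(cl, chains = nch, seed = 1L)
      qa <- quadruplex_analysis(fx$graph)
      expect_length(qa$tetrads, 1L)
      expect_identical(qa$tetrads[[1L]]$onz, fx$expected$reordered,
                       info = paste(cl, nch))
      qan <- quadruplex_analysis(fx$graph, no_reorder = TRUE)
      expect_identical(qan$tetrads[[1L]]$onz, fx$expected$no_reorder,
                       info = paste(cl, nch, "no-reorder"))
    }
  }
})

test_that("generated classes are distinct across the six-class taxonomy", {
  got <- vapply(c("O+", "O-", "N+", "N-", "Z+", "Z-"), function(cl) {
    fx <- make_tetrad_graph(cl)
    quadruplex_analysis(fx$graph)$tetrads[[1L]]$onz
  }, character(1))
  expect_length(unique(got), 6L)
})

test_that("quadruplex generator realizes every reachable class combination", {
  for (L in c("O", "N", "Z", "M")) for (d in c("p", "a", "h"))
    for (s in c("+", "-", "*")) {
      fx <- make_quadruplex_graph(L, d, s, n_tetrads = 3L, seed = 9L)
      qa <- quadruplex_analysis(fx$graph)
      expect_length(qa$quadruplexes, 1L)
      expect_identical(qa$quadruplexes[[1L]]$onzm, fx$expected$onzm,
                       info = paste(L, d, s))
      expect_identical(vapply(qa$quadruplexes[[1L]]$tetrads,
                              function(t) t$onz, character(1)),
                       fx$expected$tetrads, info = paste(L, d, s))
    }
})

test_that("impossible generator requests fail loudly", {
  expect_error(make_quadruplex_graph("O", "p", "*", n_tetrads = 1L),
               "at least 2")
  expect_error(make_tetrad_graph("O+", chains = 3L), "chains")
})

test_that("generator output is reproducible under a fixed seed", {
  a <- make_quadruplex_graph("O", "a", "*", 3, seed = 42)
  b <- make_quadruplex_graph("O", "a", "*", 3, seed = 42)
  expect_identical(a$graph$residues, b$graph$residues)
  expect_identical(a$graph$pairs, b$graph$pairs)
})

test_that("coordinate fixtures annotate to their designed ground truth", {
  # the generated tetrad's pair cycle covers residues 1-4 exactly
  g <- annotate_geometry(fixture_gtetrad())
  expect_identical(sort(unique(c(g$pairs$i, g$pairs$j))), 1:4)
  tt <- find_tetrads(g)
  expect_length(tt, 1L)
  # stacked layers are stacked, 4 contacts
  g2 <- annotate_geometry(fixture_gtetrad(n_layers = 2L))
  expect_equal(nrow(g2$stacks), 4L)
})
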