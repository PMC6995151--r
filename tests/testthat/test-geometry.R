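test_that("a G:G Watson-Crick/Hoogsteen fixture is annotated cis W/H", {
  g <- annotate_geometry(fixture_gg_cwh())
  expect_equal(nrow(g$pairs), 1L)
  expect_identical(g$pairs$orientation, "cis")
  expect_setequal(c(g$pairs$edge_i, g$pairs$edge_j), c("W", "H"))
  expect_false(g$pairs$canonical)
})

test_that("distant bases yield no pair", {
  g <- annotate_geometry(fixture_distant_pair(30))
  expect_equal(nrow(g$pairs), 0L)
})

test_that("a Watson-Crick G:C pair and a B-form step are canonical", {
  g <- annotate_geometry(fixture_gc_wc())
  expect_equal(nrow(g$pairs), 1L)
  expect_true(g$pairs$canonical)
  expect_identical(g$pairs$orientation, "cis")
  expect_identical(c(g$pairs$edge_i, g$pairs$edge_j), c("W", "W"))

  step <- annotate_geometry(fixture_gc_step())
  expect_equal(nrow(step$pairs), 2L)
  expect_true(all(step$pairs$canonical))
  expect_gte(nrow(step$stacks), 1L)
})

test_that("stacking respects distance, planarity angle and ring overlap", {
  expect_equal(nrow(detect_stacking(fixture_stacked_bases(rise = 3.3))), 1L)
  # coplanar side-by-side bases never stack
  expect_equal(nrow(detect_stacking(
    fixture_stacked_bases(rise = 0, lateral = 8))), 0L)
  # close but tilted 60 degrees: fails the 30-degree planarity threshold
  expect_equal(nrow(detect_stacking(fixture_stacked_bases(tilt = 60))), 0L)
  # past the 4.5 A centroid threshold
  expect_equal(nrow(detect_stacking(fixture_stacked_bases(rise = 5))), 0L)
  # laterally displaced until the rings no longer overlap in projection
  # (centroids still within 4.5 A and planes parallel)
  expect_equal(nrow(detect_stacking(
    fixture_stacked_bases(rise = 1.0, lateral = 4.3))), 0L)
})

test_that("annotation detects the full G-tetrad pair cycle", {
  g <- annotate_geometry(fixture_gtetrad())
  expect_equal(nrow(g$pairs), 4L)
  expect_true(all(g$pairs$orientation == "cis"))
  # every pair joins a Watson-Crick edge to a Hoogsteen edge
  expect_true(all((g$pairs$edge_i == "W" & g$pairs$edge_j == "H") |
                  (g$pairs$edge_i == "H" & g$pairs$edge_j == "W")))
  tt <- find_tetrads(g)
  expect_length(tt, 1L)
})

test_that("stacked tetrad layers assemble into a quadruplex from coordinates", {
  qa <- quadruplex_analysis(fixture_gtetrad(n_layers = 2L))
  expect_length(qa$tetrads, 2L)
  expect_length(qa$quadruplexes, 1L)
  expect_length(qa$quadruplexes[[1L]]$tetrads, 2L)
})

test_that("annotation is invariant under rigid motion of all coordinates", {
  m <- fixture_gtetrad(n_layers = 2L)
  rot <- quadtet:::rot_z(73) %*% quadtet:::rot_x(31)
  m2 <- m
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(rot)
  m2$atoms$x <- xyz[, 1L] + 12.3
  m2$atoms$y <- xyz[, 2L] - 4.5
  m2$atoms$z <- xyz[, 3L] + 101
  g1 <- annotate_geometry(m)
  g2 <- annotate_geometry(m2)
  expect_identical(g1$pairs, g2$pairs)
  expect_identical(g1$stacks, g2$stacks)
})
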