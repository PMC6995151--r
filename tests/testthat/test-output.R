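test_that("tetrad arcs take their class colour; rendering is byte-stable", {
  fx <- make_quadruplex_graph("O", "p", "+", 2)
  qa <- quadruplex_analysis(fx$graph)
  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  render_arc_svg(qa, p1)
  render_arc_svg(qa, p2)
  svg <- readLines(p1)
  expect_identical(svg, readLines(p2))
  expect_equal(sum(grepl("#003366", svg)), 8L)   # 2 tetrads x 4 arcs, O+ dark blue
  expect_false(any(grepl("#99CCFF", svg)))
})

test_that("positive and negative tetrads use dark and light shades", {
  fx <- make_quadruplex_graph("O", "p", "*", 3)   # one O-, two O+
  qa <- quadruplex_analysis(fx$graph)
  path <- withr::local_tempfile(fileext = ".svg")
  render_arc_svg(qa, path)
  svg <- readLines(path)
  expect_equal(sum(grepl("#003366", svg)), 8L)    # O+ arcs
  expect_equal(sum(grepl("#99CCFF", svg)), 4L)    # O- arcs
})

test_that("unclassified tetrads are drawn grey", {
  fx <- make_tetrad_graph("O+", chains = 2L)
  qa <- quadruplex_analysis(fx$graph, no_reorder = TRUE)
  expect_true(is.na(qa$tetrads[[1L]]$onz))
  path <- withr::local_tempfile(fileext = ".svg")
  render_arc_svg(qa, path)
  expect_equal(sum(grepl("#808080", readLines(path))), 4L)
})

test_that("complete_2d adds black arcs for canonical pairs outside the motif", {
  fx <- make_quadruplex_graph("O", "p", "+", 2)
  g <- fx$graph
  # append a short canonical duplex stem after the motif
  n0 <- nrow(g$residues)
  extra <- data.frame(chain = "A", number = n0 + 1:4, icode = "",
                      base = c("G", "G", "C", "C"), stringsAsFactors = FALSE)
  stem <- data.frame(i = n0 + c(1L, 2L), j = n0 + c(4L, 3L),
                     orientation = "cis", edge_i = "W", edge_j = "W")
  core <- g$pairs[, c("i", "j", "orientation", "edge_i", "edge_j")]
  g2 <- annotation_graph(rbind(g$residues, extra), rbind(core, stem),
                         g$stacks)
  qa <- quadruplex_analysis(g2)
  with_black <- withr::local_tempfile(fileext = ".svg")
  without <- withr::local_tempfile(fileext = ".svg")
  render_arc_svg(qa, with_black, complete_2d = TRUE)
  render_arc_svg(qa, without, complete_2d = FALSE)
  expect_equal(sum(grepl("#000000", readLines(with_black))), 2L)
  expect_equal(sum(grepl("#000000", readLines(without))), 0L)
})

test_that("palette configuration overrides colours and rejects unknown keys", {
  cfg <- withr::local_tempfile(fileext = ".ini")
  writeLines(c("[palette]", "# custom shades", "O+ = #112233"), cfg)
  pal <- read_palette_config(cfg)
  expect_identical(unname(pal["O+"]), "#112233")
  expect_identical(unname(pal["N+"]), unname(default_palette()["N+"]))
  bad <- withr::local_tempfile(fileext = ".ini")
  writeLines("Q+ = #000000", bad)
  expect_error(read_palette_config(bad), "unknown palette key")
})

test_that("text and JSON reports carry classes, residues and dot-bracket", {
  fx <- make_quadruplex_graph("Z", "a", "+", 2)
  qa <- quadruplex_analysis(fx$graph)
  txt <- report_text(qa)
  expect_true(any(grepl("class Za\\+", txt)))
  expect_true(any(grepl("A\\.G1", txt)))
  jp <- withr::local_tempfile(fileext = ".json")
  report_json(qa, jp)
  obj <- jsonlite::fromJSON(jp, simplifyVector = FALSE)
  expect_identical(obj$quadruplexes[[1L]]$onzm, "Za+")
  expect_length(obj$tetrads, 2L)
  expect_identical(obj$dot_bracket$sequence, qa$dot_bracket$sequence)
})
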