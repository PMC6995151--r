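#' Identify and classify tetrads and quadruplexes
#'
#' The package's main entry point.  Takes a structure (PDB/mmCIF path), a
#' pre-computed annotation (DSSR-style JSON path or an
#' [annotation_graph()]), or both, and runs the full pipeline: tetrad
#' finding in the base-pair graph, ONZ classification (with chain
#' reordering for multimeric motifs unless disabled), quadruplex assembly
#' from inter-tetrad stacking, ONZM classification, and the two-line
#' dot-bracket encoding.
#'
#' When both a structure file and an annotation are given, the annotation's
#' base pairs and stacking take precedence and the coordinates are kept
#' only for reference.  When only a structure file is given the built-in
#' geometric annotator derives pairs and stacking from the coordinates.
#'
#' @param x input: an [annotation_graph()], a `coord_model`, or a file path
#'   (`.json` is read as a DSSR-style or internal annotation, anything else
#'   as a structure file).
#' @param structure optional structure file path accompanying a JSON
#'   annotation.
#' @param strict only cis Watson-Crick/Hoogsteen pairs form tetrads.
#' @param stacking_mismatch 0, 1 or 2 (default): tolerated missing contacts
#'   between stacked tetrads.
#' @param relaxed_stem sequentially neighbouring tetrads share a quadruplex
#'   regardless of stacking.
#' @param no_reorder keep the input chain order; multimeric tetrads then
#'   stay unclassified.
#' @param model model number for multi-model structure files.
#' @return An object of class `quadruplex_analysis`: list with `graph`,
#'   `chain_order` (committed), `tetrads` (all, classified where possible),
#'   `quadruplexes`, `lone_tetrads`, `dot_bracket`, and `params`.
#' @examples
#' fx <- make_quadruplex_graph("O", "p", "+", n_tetrads = 3)
#' qa <- quadruplex_analysis(fx$graph)
#' print(qa)
#' @export
quadruplex_analysis <- function(x, structure = NULL, strict = FALSE,
                                stacking_mismatch = 2L, relaxed_stem = FALSE,
                                no_reorder = FALSE, model = 1L) {
  graph <- resolve_input(x, structure, model)
  params <- stacking_params(stacking_mismatch, relaxed_stem)

  tetrads <- find_tetrads(graph, strict = strict)
  reorder_info <- NULL
  if (length(tetrads) > 0L) {
    multi <- vapply(tetrads, function(t)
      length(tetrad_chains(t, graph)) > 1L, logical(1))
    if (no_reorder || !any(multi)) {
      tetrads <- classify_tetrads(tetrads, graph, graph$chain_order,
                                  classify_multichain = !no_reorder)
    } else {
      reorder_info <- reorder_chains(graph, tetrads)
      graph$chain_order <- reorder_info$chain_order
      tetrads <- reorder_info$tetrads
    }
  }
  gidx <- global_index(graph)
  qs <- build_quadruplexes(tetrads, graph, params)
  qs$quadruplexes <- lapply(qs$quadruplexes, classify_quadruplex,
                            graph = graph, gidx = gidx)
  db <- encode_dot_bracket(tetrads, graph)

  structure(list(graph = graph, chain_order = graph$chain_order,
                 tetrads = tetrads, quadruplexes = qs$quadruplexes,
                 lone_tetrads = qs$lone_tetrads, dot_bracket = db,
                 reorder = reorder_info,
                 params = list(strict = strict,
                               stacking_mismatch = params$mismatch,
                               relaxed_stem = params$relaxed_stem,
                               no_reorder = no_reorder)),
            class = "quadruplex_analysis")
}

resolve_input <- function(x, structure = NULL, model = 1L) {
  if (inherits(x, "annotation_graph")) return(x)
  if (inherits(x, "coord_model")) return(annotate_geometry(x))
  if (is.character(x) && length(x) == 1L) {
    if (grepl("\\.json$", x, ignore.case = TRUE)) {
      graph <- tryCatch(read_annotation_json(x),
                        error = function(e) read_dssr_json(x))
      if (!is.null(structure)) {
        cm <- read_structure(structure, model = model)
        check_residue_consistency(graph, cm)
      }
      return(graph)
    }
    return(annotate_geometry(read_structure(x, model = model)))
  }
  stop("cannot interpret input of class ", paste(class(x), collapse = "/"))
}

check_residue_consistency <- function(graph, cm) {
  k1 <- paste(graph$residues$chain, graph$residues$number, graph$residues$icode)
  k2 <- paste(cm$residues$chain, cm$residues$number, cm$residues$icode)
  miss <- setdiff(k1, k2)
  if (length(miss) > 0L)
    stop("annotation and structure disagree: residue '", miss[1L],
         "' absent from the structure", call. = FALSE)
  invisible(TRUE)
}

residue_label <- function(graph, rows) {
  r <- graph$residues[rows, , drop = FALSE]
  paste0(r$chain, ".", r$base, r$number,
         ifelse(r$icode == "", "", paste0("^", r$icode)))
}

#' @export
print.quadruplex_analysis <- function(x, ...) {
  cat("quadruplex analysis\n")
  cat("  chains (committed order):", paste(x$chain_order, collapse = " "), "\n")
  cat("  tetrads:", length(x$tetrads),
      " quadruplexes:", length(x$quadruplexes),
      " lone tetrads:", length(x$lone_tetrads), "\n")
  for (q in x$quadruplexes)
    cat("  quadruplex [", q$onzm, "]: ",
        paste(vapply(q$tetrads, function(t) t$onz, character(1)),
              collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.quadruplex_analysis <- function(object, ...) {
  x <- object
  cat("Quadruplex analysis summary\n")
  cat("===========================\n")
  cat("Residues:", nrow(x$graph$residues),
      " pairs:", nrow(x$graph$pairs),
      " stacking contacts:", nrow(x$graph$stacks), "\n")
  cat("Committed chain order:", paste(x$chain_order, collapse = " "), "\n")
  if (!is.null(x$reorder))
    cat("Chain reordering: O tetrads", x$reorder$identity_o,
        "(input order) ->", x$reorder$best_o, "(committed)\n")
  onz <- vapply(x$tetrads, function(t) t$onz, character(1))
  cat("\nTetrads (", length(onz), "):\n", sep = "")
  for (t in x$tetrads)
    cat("  ", paste(residue_label(x$graph, t$abcd), collapse = " "),
        " -> ", ifelse(is.na(t$onz), "unclassified", t$onz), "\n", sep = "")
  cat("\nQuadruplexes (", length(x$quadruplexes), "):\n", sep = "")
  for (q in x$quadruplexes)
    cat("  class ", q$onzm, ": ", length(q$tetrads), " tetrads [",
        paste(vapply(q$tetrads, function(t)
          ifelse(is.na(t$onz), "?", t$onz), character(1)), collapse = " "),
        "]", if (isTRUE(q$n4_helix)) " (N4-helix)" else "", "\n", sep = "")
  if (length(x$lone_tetrads))
    cat("Lone tetrads:", length(x$lone_tetrads), "\n")
  cat("\nDot-bracket:\n")
  print(x$dot_bracket)
  invisible(x)
}

#' Plain-text and JSON reports
#'
#' `report_text()` renders the analysis as the standard text report
#' (quadruplex classes, tetrad list with ONZ labels and residue
#' identifiers, dot-bracket); `report_json()` writes the machine-readable
#' equivalent.
#'
#' @param qa a `quadruplex_analysis`.
#' @param path output file; `report_text` returns the lines invisibly when
#'   `path` is `NULL`.
#' @return `report_text`: character vector of lines; `report_json`: `path`.
#' @export
report_text <- function(qa, path = NULL) {
  lines <- c("quadruplex analysis report",
             paste("chain order:", paste(qa$chain_order, collapse = " ")),
             "")
  describe_tetrad <- function(t, indent = "  ") {
    paste0(indent, ifelse(is.na(t$onz), "unclassified", t$onz), " ",
           paste(residue_label(qa$graph, t$abcd), collapse = " "))
  }
  for (k in seq_along(qa$quadruplexes)) {
    q <- qa$quadruplexes[[k]]
    lines <- c(lines,
               paste0("quadruplex ", k, " class ", q$onzm,
                      if (isTRUE(q$n4_helix)) " (N4-helix)" else ""),
               vapply(q$tetrads, describe_tetrad, character(1)))
  }
  if (length(qa$lone_tetrads)) {
    lines <- c(lines, "lone tetrads:",
               vapply(qa$lone_tetrads, describe_tetrad, character(1)))
  }
  lines <- c(lines, "", "dot-bracket:", qa$dot_bracket$sequence,
             qa$dot_bracket$line1, qa$dot_bracket$line2)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @rdname report_text
#' @export
report_json <- function(qa, path) {
  obj <- list(
    chain_order = qa$chain_order,
    tetrads = lapply(qa$tetrads, function(t)
      list(residues = residue_label(qa$graph, t$abcd),
           onz = if (is.na(t$onz)) NULL else t$onz)),
    quadruplexes = lapply(qa$quadruplexes, function(q)
      list(onzm = q$onzm, n4_helix = q$n4_helix,
           tetrads = lapply(q$tetrads, function(t)
             list(residues = residue_label(qa$graph, t$abcd),
                  onz = if (is.na(t$onz)) NULL else t$onz)),
           tracts = lapply(q$tracts, function(tr) residue_label(qa$graph, tr)))),
    lone_tetrads = lapply(qa$lone_tetrads, function(t)
      list(residues = residue_label(qa$graph, t$abcd),
           onz = if (is.na(t$onz)) NULL else t$onz)),
    dot_bracket = list(sequence = qa$dot_bracket$sequence,
                       line1 = qa$dot_bracket$line1,
                       line2 = qa$dot_bracket$line2)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
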