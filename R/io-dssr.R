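#' Read a DSSR-style JSON annotation into an annotation graph
#'
#' Consumes the JSON produced by the DSSR annotator (`x3dna-dssr --json`):
#' the `nts` array gives the nucleotides in order, `pairs` gives base pairs
#' with a Leontis-Westhof string (`"cWH"`, `"tWW"`, ...), and `stacks` lists
#' runs of mutually stacked nucleotides (consecutive members of a run are
#' taken as stacking contacts).  Unknown LW codes such as `"c--"` keep the
#' pair with both edges marked unknown (`NA`).
#'
#' @param path path to the JSON file.
#' @return An [annotation_graph()].
#' @export
read_dssr_json <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed JSON in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(obj$nts))
    stop("no 'nts' array in '", path,
         "': re-run the annotator with JSON output enabled", call. = FALSE)
  nts <- as.data.frame(obj$nts, stringsAsFactors = FALSE)

  chain <- if (!is.null(nts$chain_name)) as.character(nts$chain_name)
           else dssr_id_field(nts$nt_id, "chain")
  number <- if (!is.null(nts$nt_resnum)) as.integer(nts$nt_resnum)
            else as.integer(dssr_id_field(nts$nt_id, "number"))
  icode <- if (!is.null(nts$nt_icode)) {
    ic <- as.character(nts$nt_icode); ic[is.na(ic)] <- ""; ic
  } else dssr_id_field(nts$nt_id, "icode")
  base <- if (!is.null(nts$nt_code)) normalize_base(nts$nt_code)
          else normalize_base(nts$nt_name)

  residues <- data.frame(chain = chain, number = number, icode = icode,
                         base = base, stringsAsFactors = FALSE)
  id_lookup <- seq_len(nrow(residues))
  names(id_lookup) <- if (!is.null(nts$nt_id)) as.character(nts$nt_id)
                      else paste0(chain, ".", base, number)

  pairs <- NULL
  if (!is.null(obj$pairs) && length(obj$pairs)) {
    pr <- as.data.frame(obj$pairs, stringsAsFactors = FALSE)
    if (is.null(pr$nt1) || is.null(pr$nt2))
      stop("'pairs' records lack nt1/nt2 in '", path, "'", call. = FALSE)
    i <- unname(id_lookup[as.character(pr$nt1)])
    j <- unname(id_lookup[as.character(pr$nt2)])
    if (anyNA(i) || anyNA(j))
      stop("pair references a nucleotide absent from 'nts'", call. = FALSE)
    lw <- decode_lw(if (!is.null(pr$LW)) pr$LW else rep(NA_character_, nrow(pr)))
    pairs <- data.frame(i = i, j = j, orientation = lw$orientation,
                        edge_i = lw$edge1, edge_j = lw$edge2,
                        stringsAsFactors = FALSE)
  }

  stacks <- NULL
  if (!is.null(obj$stacks) && length(obj$stacks)) {
    st <- as.data.frame(obj$stacks, stringsAsFactors = FALSE)
    runs <- if (!is.null(st$nts_long)) st$nts_long else st$nts
    edges <- do.call(rbind, lapply(runs, function(run) {
      ids <- unname(id_lookup[strsplit(run, ",", fixed = TRUE)[[1L]]])
      ids <- ids[!is.na(ids)]
      if (length(ids) < 2L) return(NULL)
      cbind(ids[-length(ids)], ids[-1L])
    }))
    if (!is.null(edges))
      stacks <- data.frame(i = edges[, 1L], j = edges[, 2L])
  }

  annotation_graph(residues, pairs, stacks)
}

# DSSR nt_id looks like "A.DG1" or "B.G12^A" (insertion code after ^)
dssr_id_field <- function(ids, what) {
  ids <- as.character(ids)
  chain <- sub("\\..*$", "", ids)
  rest <- sub("^[^.]*\\.", "", ids)
  icode <- ifelse(grepl("\\^", rest), sub("^.*\\^", "", rest), "")
  rest <- sub("\\^.*$", "", rest)
  number <- sub("^[A-Za-z?]+", "", rest)
  switch(what, chain = chain, number = number, icode = icode)
}

#' Decode Leontis-Westhof strings
#'
#' `"cWH"` means a cis pair where the first residue uses its Watson-Crick
#' edge and the second its Hoogsteen edge.  Dashes or unrecognized letters
#' yield `NA` for that component.
#'
#' @param lw character vector of LW codes.
#' @return list with character vectors `orientation`, `edge1`, `edge2`.
#' @export
decode_lw <- function(lw) {
  lw <- as.character(lw)
  ori <- rep(NA_character_, length(lw))
  ori[substr(lw, 1L, 1L) == "c"] <- "cis"
  ori[substr(lw, 1L, 1L) == "t"] <- "trans"
  dec <- function(ch) {
    out <- rep(NA_character_, length(ch))
    out[ch %in% c("W", "w")] <- "W"
    out[ch %in% c("H", "h")] <- "H"
    out[ch %in% c("S", "s")] <- "S"
    out
  }
  list(orientation = ori,
       edge1 = dec(substr(lw, 2L, 2L)),
       edge2 = dec(substr(lw, 3L, 3L)))
}

# map modified-nucleotide residue names to a parent one-letter code;
# unknown names give '?'
MODIFIED_BASE_PARENT <- c(
  A = "A", C = "C", G = "G", U = "U", T = "T", DA = "A", DC = "C",
  DG = "G", DT = "T", DU = "U",
  "1MA" = "A", "2MA" = "A", "6MA" = "A", "MA6" = "A", "RIA" = "A",
  "AMP" = "A", "ADP" = "A", "ATP" = "A",
  "5MC" = "C", "OMC" = "C", "4OC" = "C", "CBR" = "C", "CCC" = "C",
  "1MG" = "G", "2MG" = "G", "7MG" = "G", "M2G" = "G", "OMG" = "G",
  "YG" = "G", "GTP" = "G", "GDP" = "G", "GMP" = "G", "BGM" = "G",
  "PSU" = "U", "5MU" = "U", "OMU" = "U", "4SU" = "U", "H2U" = "U",
  "5BU" = "U", "BRU" = "U", "UMP" = "U",
  "BMT" = "T", "TLN" = "T"
)

#' Normalize residue names to one-letter base codes
#'
#' Standard and deoxy residue names map to A/C/G/U/T; common modified
#' nucleotides map to their parent base via a bundled table; anything else
#' becomes `"?"` (such residues may still take part in tetrads in the
#' default, non-strict mode).
#'
#' @param x character vector of residue names or one-letter codes.
#' @return character vector of one-letter codes.
#' @export
normalize_base <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- unname(MODIFIED_BASE_PARENT[x])
  out[is.na(out)] <- "?"
  out
}
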