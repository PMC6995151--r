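#' Read a nucleic-acid structure from PDB or mmCIF
#'
#' Parses the file with bio3d, keeps the nucleotide residues of one model
#' (amino acids, waters and ions are dropped), and returns a coordinate
#' model: the residue table in file order plus an atom table with Cartesian
#' coordinates.  A residue counts as a nucleotide when it has a C1' atom and
#' at least three base-ring atoms.  Residue names are mapped to one-letter
#' parent bases via [normalize_base()]; unmapped modified residues keep base
#' `"?"` and still take part in downstream analysis.
#'
#' @param path path to a structure file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (from the file extension;
#'   `.cif`/`.mmcif` select mmCIF).
#' @param model model number for multi-model (e.g. NMR) files; default 1.
#' @return An object of class `coord_model`: list with `residues` (chain,
#'   number, icode, base, resid) and `atoms` (res = residue row, name, x, y,
#'   z).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), model = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "mmcif")
      suppressWarnings(bio3d::read.cif(path, multi = TRUE))
    else
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE)),
    error = function(e) stop("cannot parse '", path, "' as ", format, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  atoms <- parsed$atom
  n_models <- if (is.matrix(parsed$xyz)) nrow(parsed$xyz) else 1L
  if (model < 1L || model > n_models)
    stop("model ", model, " requested but file has ", n_models, " model(s)",
         call. = FALSE)
  if (model > 1L) {
    xyz <- parsed$xyz[model, ]
    atoms$x <- xyz[seq(1L, length(xyz), 3L)]
    atoms$y <- xyz[seq(2L, length(xyz), 3L)]
    atoms$z <- xyz[seq(3L, length(xyz), 3L)]
  }
  atoms$elety <- gsub("^\"|\"$|^'|'$", "", atoms$elety)
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$chain[is.na(atoms$chain)] <- ""
  coord_model_from_atoms(atoms)
}

RING_ATOMS <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")

coord_model_from_atoms <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  groups <- split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
  keep <- vapply(groups, function(idx) {
    nm <- atoms$elety[idx]
    "C1'" %in% nm && sum(RING_ATOMS %in% nm) >= 3L
  }, logical(1))
  groups <- groups[keep]
  if (length(groups) == 0L)
    stop("no nucleotide residues found in structure", call. = FALSE)
  first <- vapply(groups, `[`, integer(1), 1L)
  residues <- data.frame(
    chain  = atoms$chain[first],
    number = as.integer(atoms$resno[first]),
    icode  = as.character(atoms$insert[first]),
    base   = normalize_base(atoms$resid[first]),
    resid  = as.character(atoms$resid[first]),
    stringsAsFactors = FALSE
  )
  at <- do.call(rbind, lapply(seq_along(groups), function(k) {
    idx <- groups[[k]]
    data.frame(res = k, name = atoms$elety[idx],
               x = atoms$x[idx], y = atoms$y[idx], z = atoms$z[idx],
               stringsAsFactors = FALSE)
  }))
  # drop hydrogens and alternate locations beyond the first occurrence
  at <- at[!grepl("^H|^\\dH", at$name), , drop = FALSE]
  at <- at[!duplicated(at[, c("res", "name")]), , drop = FALSE]
  rownames(at) <- NULL
  structure(list(residues = residues, atoms = at), class = "coord_model")
}

#' @export
print.coord_model <- function(x, ...) {
  cat("coordinate model:", nrow(x$residues), "nucleotide residues,",
      nrow(x$atoms), "heavy atoms\n")
  invisible(x)
}

#' Write a minimal mmCIF file for a coordinate model
#'
#' Emits a bare `atom_site` loop sufficient for round-tripping fixture
#' models through [read_structure()].
#'
#' @param model a `coord_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mmcif <- function(model, path) {
  res <- model$residues
  at <- model$atoms
  lines <- c(
    "data_fixture",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  elem <- substr(gsub("[^A-Za-z]", "", at$name), 1L, 1L)
  body <- sprintf(
    "ATOM %d %s \"%s\" . %s %s 1 %d %s %.3f %.3f %.3f 1.00 0.00 ? %d %s %s \"%s\" 1",
    seq_len(nrow(at)), elem, at$name,
    res$resid[at$res], res$chain[at$res], res$number[at$res],
    ifelse(res$icode[at$res] == "", "?", res$icode[at$res]),
    at$x, at$y, at$z,
    res$number[at$res], res$resid[at$res], res$chain[at$res], at$name
  )
  writeLines(c(lines, body, "#"), path)
  invisible(path)
}
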