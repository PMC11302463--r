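# Reading and writing AlphaFold-style single-chain backbone models.
#
# Structures are held as a `protein_structure`: backbone N/CA/C coordinates
# (Angstrom) plus the per-residue pLDDT confidence.  AlphaFold deposits
# pLDDT (0-100) in the B-factor column; it is normalized to [0, 1] on read
# so that the standard confidence threshold reads as 0.9.

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA_ONE_TO_THREE <- c(stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE),
                     X = "UNK")
AA_ALPHABET <- c(sort(unname(AA_THREE_TO_ONE)), "X")

#' Construct a validated protein structure
#'
#' Backbone-only representation of a single-chain protein model: N, CA and C
#' coordinates per residue plus the AlphaFold per-residue confidence (pLDDT,
#' stored on the 0-1 scale).
#'
#' @param protein_id Character scalar identifier.
#' @param residue_index Integer vector of author residue numbers, strictly
#'   increasing.
#' @param aa Character vector of one-letter amino-acid codes (non-standard
#'   residues as `"X"`).
#' @param N,CA,C Numeric matrices (n x 3) of backbone atom coordinates in
#'   Angstrom.
#' @param plddt Numeric vector of per-residue confidences in \[0, 1\].
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(protein_id, residue_index, aa, N, CA, C, plddt) {
  n <- length(residue_index)
  if (n < 1) stop("structure must contain at least one residue")
  N <- matrix(as.numeric(N), ncol = 3)
  CA <- matrix(as.numeric(CA), ncol = 3)
  C <- matrix(as.numeric(C), ncol = 3)
  stopifnot(nrow(N) == n, nrow(CA) == n, nrow(C) == n,
            length(aa) == n, length(plddt) == n)
  if (any(diff(residue_index) <= 0)) {
    stop("residue indices must be strictly increasing")
  }
  if (!all(is.finite(N)) || !all(is.finite(CA)) || !all(is.finite(C))) {
    stop("backbone coordinates must be finite")
  }
  if (any(plddt < 0 | plddt > 1)) stop("plddt must lie in [0, 1]")
  aa <- as.character(aa)
  aa[!aa %in% AA_ALPHABET] <- "X"
  structure(
    list(protein_id = as.character(protein_id),
         residue_index = as.integer(residue_index),
         aa = aa, N = N, CA = CA, C = C, plddt = as.numeric(plddt)),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure> ", x$protein_id, ": ", length(x$aa),
      " residues, mean pLDDT ", sprintf("%.3f", mean(x$plddt)), "\n", sep = "")
  invisible(x)
}

#' Number of residues in a structure
#' @param structure A `protein_structure`.
#' @return Integer residue count.
#' @export
n_residues <- function(structure) length(structure$aa)

guess_format <- function(path) {
  if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
}

#' Read a single-chain AlphaFold-style model
#'
#' Parses a PDB or mmCIF file containing exactly one polypeptide chain and
#' one model.  The B-factor column is interpreted as pLDDT (0-100) and
#' divided by 100.  HETATM records are skipped; residues with insertion
#' codes, multi-model files, and residues missing any of N/CA/C raise
#' errors.
#'
#' @param path Path to the structure file.
#' @param format `"pdb"` or `"mmcif"`; guessed from the extension by default.
#' @return A [protein_structure()].
#' @export
read_structure <- function(path, format = guess_format(path)) {
  format <- match.arg(format, c("pdb", "mmcif"))
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- if (format == "pdb") {
    if (sum(grepl("^MODEL", readLines(path, warn = FALSE))) > 1) {
      stop("multi-model file not supported: ", path)
    }
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  } else {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  }
  atoms <- pdb$atom
  if (!is.null(pdb$xyz) && is.matrix(unclass(pdb$xyz)) &&
      nrow(unclass(pdb$xyz)) > 1) {
    stop("multi-model file not supported: ", path)
  }
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0) stop("empty chain in ", path)
  if (length(unique(atoms$chain)) > 1) {
    stop("expected exactly one chain, found: ",
         paste(unique(atoms$chain), collapse = ", "))
  }
  if (any(!is.na(atoms$insert) & atoms$insert != "")) {
    stop("insertion codes are not supported")
  }
  resno <- unique(atoms$resno)
  n <- length(resno)
  get_atom <- function(elety) {
    sel <- atoms[atoms$elety == elety, , drop = FALSE]
    sel[match(resno, sel$resno), , drop = FALSE]
  }
  an <- get_atom("N"); aca <- get_atom("CA"); ac <- get_atom("C")
  for (i in seq_len(n)) {
    missing <- c("N", "CA", "C")[c(is.na(an$resno[i]), is.na(aca$resno[i]),
                                   is.na(ac$resno[i]))]
    if (length(missing)) {
      stop("residue ", resno[i], " is missing backbone atom(s): ",
           paste(missing, collapse = ", "))
    }
  }
  aa <- unname(AA_THREE_TO_ONE[aca$resid])
  aa[is.na(aa)] <- "X"
  protein_structure(
    protein_id = sub("\\.(pdb|cif)$", "", basename(path), ignore.case = TRUE),
    residue_index = resno,
    aa = aa,
    N = as.matrix(an[, c("x", "y", "z")]),
    CA = as.matrix(aca[, c("x", "y", "z")]),
    C = as.matrix(ac[, c("x", "y", "z")]),
    plddt = aca$b / 100
  )
}

#' Write a structure to PDB or mmCIF
#'
#' Coordinates are written to 3 decimals and pLDDT to the B-factor column as
#' a 0-100 value with 2 decimals, so `read_structure(write_structure(s))`
#' reproduces `s` at that precision.
#'
#' @param structure A [protein_structure()].
#' @inheritParams read_structure
#' @return The path, invisibly.
#' @export
write_structure <- function(structure, path, format = guess_format(path)) {
  format <- match.arg(format, c("pdb", "mmcif"))
  n <- n_residues(structure)
  res3 <- unname(AA_ONE_TO_THREE[structure$aa])
  lines <- character(0)
  serial <- 0L
  if (format == "pdb") {
    for (i in seq_len(n)) {
      for (atom in c("N", "CA", "C")) {
        serial <- serial + 1L
        xyz <- structure[[atom]][i, ]
        lines <- c(lines, sprintf(
          "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", atom), res3[i], "A",
          structure$residue_index[i], xyz[1], xyz[2], xyz[3],
          1.00, structure$plddt[i] * 100, substr(atom, 1, 1)))
      }
    }
    lines <- c(lines, "TER", "END")
  } else {
    lines <- c(
      paste0("data_", structure$protein_id),
      "#", "loop_",
      paste0("_atom_site.", c(
        "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
        "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
        "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
        "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
        "auth_comp_id", "auth_asym_id", "auth_atom_id",
        "pdbx_PDB_model_num")))
    for (i in seq_len(n)) {
      for (atom in c("N", "CA", "C")) {
        serial <- serial + 1L
        xyz <- structure[[atom]][i, ]
        lines <- c(lines, sprintf(
          "ATOM %d %s %s . %s A 1 %d ? %.3f %.3f %.3f 1.00 %.2f ? %d %s A %s 1",
          serial, substr(atom, 1, 1), atom, res3[i],
          structure$residue_index[i], xyz[1], xyz[2], xyz[3],
          structure$plddt[i] * 100, structure$residue_index[i],
          res3[i], atom))
      }
    }
    lines <- c(lines, "#")
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path)
  })
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
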