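## Atomic data model for binary protein-RNA complexes.
##
## A complex is stored as a flat atom table (one row per atom) plus an id.
## Each atom row records which partner (protein/rna) and which residue unit
## it belongs to, whether it is a backbone heavy atom, and whether it is a
## hydrogen. Residue units are identified by (chain, resno, insert).

#' Standard residue and nucleotide name sets
#'
#' Three-letter codes for the 20 standard amino acids and the accepted
#' spellings of the four ribonucleotides. DNA residue names are deliberately
#' not recognised: the package models protein-RNA complexes only.
#' @name residue-names
#' @keywords internal
NULL

#' Construct a protein-RNA complex from an atom table
#'
#' Low-level constructor used by [read_pdb()] and the fixture generators.
#' The atom table must contain one row per atom with columns `serial`,
#' `name`, `element`, `resname`, `chain`, `resno`, `insert`, `partner`
#' (`"protein"` or `"rna"`), and coordinates `x`, `y`, `z` in Angstrom.
#' Backbone/hydrogen flags and the per-unit key are derived here.
#'
#' @param atoms data.frame as described above.
#' @param id character label for the complex.
#' @return An object of class `rna_complex`.
#' @export
new_complex <- function(atoms, id = "complex") {
  stopifnot(is.data.frame(atoms))
  needed <- c("serial", "name", "element", "resname", "chain", "resno",
              "insert", "partner", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms$name <- normalize_atom_name(atoms$name)
  atoms$element <- trimws(atoms$element)
  atoms$is_hydrogen <- atoms$element %in% c("H", "D") |
    (atoms$element == "" & grepl("^[0-9]*H", atoms$name))
  atoms$backbone <- !atoms$is_hydrogen & ifelse(
    atoms$partner == "protein",
    atoms$name %in% PROTEIN_BACKBONE,
    atoms$name %in% RNA_BACKBONE
  )
  ## unit key: chain + residue number + insertion code, unique per unit
  atoms$unit <- paste0(atoms$partner, "/", atoms$chain, "/", atoms$resno,
                       ifelse(atoms$insert == "", "", atoms$insert))
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  if (anyDuplicated(atoms$serial)) stop("duplicate atom serial numbers")
  if (any(!nzchar(atoms$name))) stop("empty atom name")
  if (!any(atoms$partner == "protein") || !any(atoms$partner == "rna")) {
    stop("not a binary protein-RNA complex: need one protein and one RNA partner")
  }
  structure(list(id = id, atoms = atoms), class = "rna_complex")
}

#' @export
print.rna_complex <- function(x, ...) {
  a <- x$atoms
  cat("Protein-RNA complex '", x$id, "'\n", sep = "")
  cat("  protein: ", length(unique(a$unit[a$partner == "protein"])),
      " residues, ", sum(a$partner == "protein"), " atoms\n", sep = "")
  cat("  rna:     ", length(unique(a$unit[a$partner == "rna"])),
      " nucleotides, ", sum(a$partner == "rna"), " atoms\n", sep = "")
  invisible(x)
}

#' Number of residue units per partner
#' @param complex an `rna_complex`.
#' @return named integer vector with elements `protein` and `rna`.
#' @export
n_units <- function(complex) {
  a <- complex$atoms
  c(protein = length(unique(a$unit[a$partner == "protein"])),
    rna = length(unique(a$unit[a$partner == "rna"])))
}

#' Split the atom table into residue units
#'
#' @param complex an `rna_complex`.
#' @param partner `"protein"`, `"rna"` or `"both"`.
#' @return data.frame with one row per unit: `unit`, `partner`, `type`
#'   (residue/nucleotide code), `chain`, `resno`.
#' @export
unit_table <- function(complex, partner = "both") {
  a <- complex$atoms
  if (partner != "both") a <- a[a$partner == partner, , drop = FALSE]
  first <- !duplicated(a$unit)
  data.frame(unit = a$unit[first], partner = a$partner[first],
             type = ifelse(a$partner[first] == "rna",
                           unname(RNA_RESNAME_MAP[a$resname[first]]),
                           a$resname[first]),
             chain = a$chain[first], resno = a$resno[first],
             stringsAsFactors = FALSE)
}

classify_resname <- function(resname) {
  resname <- trimws(resname)
  out <- rep(NA_character_, length(resname))
  out[resname %in% PROTEIN_RESNAMES] <- "protein"
  out[resname %in% names(RNA_RESNAME_MAP)] <- "rna"
  out
}

#' Read a binary protein-RNA complex from a PDB file
#'
#' Parses ATOM records (first model only; HETATM, waters and ions are
#' ignored), resolves alternate locations to the highest-occupancy
#' conformer, and partitions residues into the protein and RNA partners by
#' residue name. Hydrogens are retained when present. Residues with
#' non-standard names (including DNA) are skipped with a warning; if more
#' than half of the residues are skipped the file is rejected.
#'
#' @param path path to a PDB file.
#' @param id label for the complex; defaults to the file name.
#' @return An `rna_complex`.
#' @export
read_pdb <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  ## alternate locations: keep the highest-occupancy conformer per atom slot
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$eleno), , drop = FALSE]

  partner <- classify_resname(at$resid)
  ukey <- paste(at$chain, at$resno, at$insert, at$resid)
  skipped <- unique(ukey[is.na(partner)])
  if (length(skipped) > 0) {
    n_total <- length(unique(ukey))
    warning("skipping ", length(skipped),
            " residue(s) with non-standard names in ", path)
    if (length(skipped) > n_total / 2) {
      stop("more than half of the residues have unrecognised names in ", path)
    }
    at <- at[!is.na(partner), , drop = FALSE]
    partner <- partner[!is.na(partner)]
  }
  if (!any(partner == "protein") || !any(partner == "rna")) {
    stop("not a binary protein-RNA complex: ", path)
  }

  atoms <- data.frame(
    serial = at$eleno, name = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     guess_element(at$elety), at$elesy),
    resname = trimws(at$resid), chain = at$chain, resno = at$resno,
    insert = at$insert, partner = partner,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE
  )
  new_complex(atoms, id = id %||% sub("\\.pdb$", "", basename(path)))
}

## Fallback element inference from the atom name (PDB v2 files without an
## element column): strip digits/primes, first letter wins except two-letter
## names are rare in standard residues.
guess_element <- function(name) {
  nm <- gsub("[0-9'*]", "", trimws(name))
  ifelse(grepl("^[0-9]*H", trimws(name)), "H", substr(nm, 1, 1))
}

#' Write a complex to a PDB file, optionally applying a pose
#'
#' The pose (a rigid transform, see [pose()]) is applied to the mobile RNA
#' partner; the protein partner is written as-is. Round-tripping through
#' [read_pdb()] preserves atom counts, names, ordering and coordinates to
#' the 3-decimal precision of the PDB format.
#'
#' @param complex an `rna_complex`.
#' @param path output file path.
#' @param pose a `pose` object or `NULL` for the identity.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(complex, path, pose = NULL) {
  stopifnot(inherits(complex, "rna_complex"))
  a <- complex$atoms
  if (!is.null(pose)) {
    xyz <- apply_pose_xyz(atom_xyz(a), pose,
                          mobile = a$partner == "rna",
                          pivot = partner_centroid(complex, "rna"))
  } else {
    xyz <- atom_xyz(a)
  }
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(xyz)),
    type = rep("ATOM", nrow(a)),
    eleno = a$serial, elety = a$name, resid = a$resname,
    chain = a$chain, resno = a$resno, insert = ifelse(a$insert == "", NA, a$insert),
    o = rep(1, nrow(a)), b = rep(0, nrow(a)), elesy = a$element
  )
  invisible(path)
}

#' Centroid (mean position) of one partner's atoms
#' @param complex an `rna_complex`.
#' @param partner `"protein"` or `"rna"`.
#' @param heavy_only use heavy atoms only (default TRUE).
#' @return numeric length-3 vector.
#' @export
partner_centroid <- function(complex, partner, heavy_only = TRUE) {
  a <- complex$atoms
  sel <- a$partner == partner
  if (heavy_only) sel <- sel & !a$is_hydrogen
  colMeans(atom_xyz(a[sel, , drop = FALSE]))
}
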