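## Shared constants: standard residue/nucleotide names, backbone atom
## sets and the environment-class labels of the statistical tables.

PROTEIN_RESNAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

## Map accepted RNA residue spellings to the canonical one-letter code.
RNA_RESNAME_MAP <- c(
  A = "A", C = "C", G = "G", U = "U",
  RA = "A", RC = "C", RG = "G", RU = "U",
  ADE = "A", CYT = "C", GUA = "G", URA = "U", URI = "U"
)

PROTEIN_BACKBONE <- c("N", "CA", "C", "O", "OXT")

## RNA backbone: phosphate group plus the ribose (sugar-ring) heavy atoms.
RNA_BACKBONE <- c(
  "P", "OP1", "OP2", "OP3", "O5'", "C5'", "C4'", "O4'",
  "C3'", "O3'", "C2'", "O2'", "C1'"
)

## Normalise atom names: star-style sugar names (O5*) to prime style (O5'),
## legacy phosphate oxygen names O1P/O2P to OP1/OP2.
normalize_atom_name <- function(name) {
  name <- gsub("*", "'", trimws(name), fixed = TRUE)
  legacy <- c("O1P" = "OP1", "O2P" = "OP2", "O3P" = "OP3")
  hit <- match(name, names(legacy))
  name[!is.na(hit)] <- legacy[hit[!is.na(hit)]]
  name
}

ALL_UNIT_TYPES <- c(PROTEIN_RESNAMES, c("A", "C", "G", "U"))
ENV_CLASSES <- c("int_bur", "int_exp", "non_bur", "non_exp")

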