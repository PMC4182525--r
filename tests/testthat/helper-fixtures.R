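## Shared test fixtures: hand-written PDB records, tiny complexes built
## directly from atom tables, and independent brute-force oracles.

## One fixed-width ATOM record (PDB v3 columns).
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1.00, alt = "", element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, occ, 0, element)
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

## Minimal 3-residue + 2-nucleotide complex as raw PDB text.
fixture_pdb_small <- function() {
  lines <- c(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_line(2, "CA", "ALA", "A", 1, 1.4, 0, 0),
    pdb_line(3, "C", "ALA", "A", 1, 2.0, 1.2, 0),
    pdb_line(4, "O", "ALA", "A", 1, 3.2, 1.3, 0, element = "O"),
    pdb_line(5, "CB", "ALA", "A", 1, 1.8, -1.2, 0.8),
    pdb_line(6, "N", "GLY", "A", 2, 1.8, 2.3, 0, element = "N"),
    pdb_line(7, "CA", "GLY", "A", 2, 2.6, 3.5, 0.2),
    pdb_line(8, "C", "GLY", "A", 2, 3.8, 3.6, 1.0),
    pdb_line(9, "O", "GLY", "A", 2, 4.9, 3.9, 0.5, element = "O"),
    pdb_line(10, "N", "SER", "A", 3, 3.7, 3.6, 2.3, element = "N"),
    pdb_line(11, "CA", "SER", "A", 3, 4.8, 3.8, 3.2),
    pdb_line(12, "C", "SER", "A", 3, 5.9, 2.8, 3.0),
    pdb_line(13, "O", "SER", "A", 3, 7.0, 3.1, 3.4, element = "O"),
    pdb_line(14, "OG", "SER", "A", 3, 5.3, 5.1, 3.0, element = "O"),
    pdb_line(15, "P", "G", "B", 1, 8.0, 0, 1.0, element = "P"),
    pdb_line(16, "OP1", "G", "B", 1, 9.0, 1.0, 1.2, element = "O"),
    pdb_line(17, "C1'", "G", "B", 1, 8.5, -1.5, 2.0),
    pdb_line(18, "N9", "G", "B", 1, 7.8, -2.7, 2.2, element = "N"),
    pdb_line(19, "C8", "G", "B", 1, 8.3, -3.9, 2.6),
    pdb_line(20, "P", "U", "B", 2, 10.5, 0, 4.0, element = "P"),
    pdb_line(21, "C1'", "U", "B", 2, 11.0, -1.5, 5.0),
    pdb_line(22, "N1", "U", "B", 2, 10.3, -2.6, 5.4, element = "N"),
    pdb_line(23, "O2", "U", "B", 2, 10.8, -3.8, 5.8, element = "O")
  )
  write_pdb_text(lines)
}

## Build an rna_complex directly from (name, resname, chain, resno, x, y, z)
## rows; element inferred from the first letter of the name.
tiny_complex <- function(rows, id = "tiny") {
  df <- data.frame(
    name = vapply(rows, function(r) as.character(r[[1]]), ""),
    resname = vapply(rows, function(r) as.character(r[[2]]), ""),
    chain = vapply(rows, function(r) as.character(r[[3]]), ""),
    resno = vapply(rows, function(r) as.integer(r[[4]]), 0L),
    x = vapply(rows, function(r) as.numeric(r[[5]]), 0),
    y = vapply(rows, function(r) as.numeric(r[[6]]), 0),
    z = vapply(rows, function(r) as.numeric(r[[7]]), 0),
    stringsAsFactors = FALSE
  )
  df$element <- ifelse(grepl("^[0-9]*H", df$name), "H",
                       substr(gsub("[0-9']", "", df$name), 1, 1))
  df$insert <- ""
  df$partner <- ifelse(df$resname %in% c("A", "C", "G", "U"), "rna", "protein")
  df$serial <- seq_len(nrow(df))
  new_complex(df, id = id)
}

atom_row <- function(name, resname, chain, resno, x, y, z) {
  list(name, resname, chain, resno, x, y, z)
}

## Independent O(n^2) concordant-pair AUC (ties count one half); positives
## are the LOW-score class under the energy convention.
oracle_auc <- function(score, label) {
  pos <- which(label); neg <- which(!label)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (score[i] < score[j]) + 0.5 * (score[i] == score[j])
  }
  tot / (length(pos) * length(neg))
}

## Random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## A mid-sized synthetic complex shared by several files.
shared_complex <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_complex(6, 4, 4, seed = 7, id = "shared")
    cache
  }
})
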