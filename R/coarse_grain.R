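## Low-resolution representation: backbone heavy atoms plus one centroid
## pseudo-atom per residue/nucleotide. The protein centroid stands for the
## side chain, the RNA centroid for the base.

#' Reduce a complex to its coarse-grained (centroid) model
#'
#' Each residue contributes its backbone heavy atoms plus one centroid: the
#' unweighted geometric centre of the side-chain heavy atoms (protein) or of
#' the base heavy atoms (RNA). Glycine, which has no side-chain heavy atom,
#' falls back to its CA position. With `mass_weighted = TRUE` the centroid is
#' the centre of mass instead (using integer atomic masses); the difference
#' is negligible for C/N/O side chains and bases.
#'
#' @param complex an `rna_complex`.
#' @param mass_weighted logical; mass-weighted centroids instead of the
#'   geometric centre. Default `FALSE`.
#' @return An object of class `centroid_model` with components:
#'   `units` (data.frame: `unit`, `partner`, `type`, `chain`, `resno`,
#'   centroid coordinates `x`, `y`, `z`) and `backbone` (data.frame of
#'   backbone heavy-atom coordinates with their `unit` and `partner`).
#' @export
reduce_complex <- function(complex, mass_weighted = FALSE) {
  stopifnot(inherits(complex, "rna_complex"))
  a <- complex$atoms
  heavy <- a[!a$is_hydrogen, , drop = FALSE]
  units <- unit_table(complex)

  masses <- c(C = 12, N = 14, O = 16, P = 31, S = 32)
  cen <- matrix(NA_real_, nrow(units), 3)
  for (i in seq_len(nrow(units))) {
    ua <- heavy[heavy$unit == units$unit[i], , drop = FALSE]
    if (nrow(ua) == 0) stop("residue with no heavy atoms: ", units$unit[i])
    side <- ua[!ua$backbone, , drop = FALSE]
    if (nrow(side) == 0) {
      ## glycine (or a backbone-only unit): fall back to CA / first backbone atom
      ca <- ua[ua$name == "CA", , drop = FALSE]
      if (nrow(ca) == 0) ca <- ua[1, , drop = FALSE]
      cen[i, ] <- as.numeric(ca[1, c("x", "y", "z")])
    } else if (mass_weighted) {
      w <- masses[side$element]
      w[is.na(w)] <- 12
      cen[i, ] <- colSums(atom_xyz(side) * w) / sum(w)
    } else {
      cen[i, ] <- colMeans(atom_xyz(side))
    }
  }
  units$x <- cen[, 1]; units$y <- cen[, 2]; units$z <- cen[, 3]

  bb <- heavy[heavy$backbone, c("unit", "partner", "name", "x", "y", "z")]
  structure(list(units = units, backbone = bb, id = complex$id),
            class = "centroid_model")
}

#' @export
print.centroid_model <- function(x, ...) {
  cat("Centroid model '", x$id, "': ",
      sum(x$units$partner == "protein"), " protein + ",
      sum(x$units$partner == "rna"), " RNA units, ",
      nrow(x$backbone), " backbone atoms\n", sep = "")
  invisible(x)
}

## Centroid coordinate matrix for one partner of a centroid model.
model_centroids <- function(model, partner) {
  u <- model$units[model$units$partner == partner, , drop = FALSE]
  cbind(u$x, u$y, u$z)
}

## Coarse atoms (backbone heavy atoms + centroids) for one partner.
model_coarse_xyz <- function(model, partner) {
  bb <- model$backbone[model$backbone$partner == partner, , drop = FALSE]
  rbind(cbind(bb$x, bb$y, bb$z), model_centroids(model, partner))
}

#' Write the coarse-grained model as a PDB file
#'
#' Backbone atoms keep their names; centroids are written as pseudo-atoms
#' named `CEN`.
#'
#' @param model a `centroid_model`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_centroid_pdb <- function(model, path) {
  bb <- model$backbone
  u <- model$units
  idx <- match(c(bb$unit, u$unit), u$unit)
  name <- c(bb$name, rep("CEN", nrow(u)))
  xyz <- rbind(cbind(bb$x, bb$y, bb$z), cbind(u$x, u$y, u$z))
  o <- order(idx, name == "CEN")
  resid <- u$type[idx]
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(xyz[o, , drop = FALSE])),
    type = rep("ATOM", length(idx)),
    eleno = seq_along(idx), elety = name[o],
    resid = resid[o], chain = u$chain[idx][o], resno = u$resno[idx][o],
    o = rep(1, length(idx)), b = rep(0, length(idx))
  )
  invisible(path)
}
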