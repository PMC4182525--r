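## All-atom (high-resolution) scoring: Lennard-Jones attractive/repulsive,
## Coulomb electrostatics with distance-dependent dielectric,
## Lazaridis-Karplus solvation, 10-12 hydrogen-bond sub-terms and the
## statistical residue-nucleotide pair term. Only inter-partner interactions
## are scored: in rigid-body docking the intra-partner energy is
## pose-invariant and cancels in ranking.

#' High-resolution term keys
#'
#' Order of the ten weighted terms of the all-atom score. `fa_dun`
#' (side-chain rotamer energy) is fixed at zero because no repacking is
#' performed for RNA docking; the slot is kept so that weight vectors stay
#' compatible with the full term inventory.
#' @export
HIGHRES_TERMS <- c("fa_atr", "fa_rep", "fa_sol", "fa_pair", "fa_dun",
                   "hack_elec", "hbond_lr_bb", "hbond_sr_bb",
                   "hbond_lr_sc", "hbond_sr_sc")

#' Atom-type parameter table
#'
#' Reads the bundled simplified element+context typing table (Lennard-Jones
#' radii and well depths, Lazaridis-Karplus solvation parameters, partial
#' charges, donor/acceptor flags). RNA atoms are mapped onto the same
#' protein-derived types by element and polarity.
#'
#' @param path optional path to an alternative table in the same format.
#' @return data.frame with one row per atom type, row names = type.
#' @export
atom_type_params <- function(path = NULL) {
  path <- path %||% system.file("extdata", "atom_types.tsv", package = "rnadock")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  rownames(tab) <- tab$type
  tab
}

#' Scoring cutoffs and constants of the all-atom terms
#'
#' @param lj_cutoff,solv_cutoff,elec_cutoff pair cutoffs in Angstrom.
#' @param elec_min_dist lower distance clamp for the Coulomb term.
#' @param coulomb_constant 332.0637 kcal*A/(mol*e^2).
#' @param hbond_range admissible donor-acceptor heavy-atom distances.
#' @param hbond_r0,hbond_eps 10-12 potential optimum distance and depth.
#' @param pair_cutoff heavy-atom contact cutoff of the atomic pair term.
#' @param rep_linearize_below fraction of r_min below which the repulsive
#'   branch is linearized.
#' @return list of class `highres_config`.
#' @export
highres_config <- function(lj_cutoff = 6, solv_cutoff = 6, elec_cutoff = 5.5,
                           elec_min_dist = 1.45, coulomb_constant = 332.0637,
                           hbond_range = c(2.2, 3.6), hbond_r0 = 2.9,
                           hbond_eps = 2.0, pair_cutoff = 5,
                           rep_linearize_below = 0.6) {
  structure(as.list(environment()), class = "highres_config")
}

## Typed atom frame of one partner, with the pose applied to the RNA.
## Returns heavy atoms (plus hydrogens separately for H-bond geometry).
typed_atoms <- function(complex, pose = NULL, params = atom_type_params()) {
  cx <- if (is.null(pose)) complex else apply_pose(complex, pose)
  a <- cx$atoms
  a$type <- assign_atom_types(a)
  bad <- is.na(a$type)
  if (any(bad)) {
    stop("untyped atoms: ", paste(unique(a$name[bad]), collapse = ", "))
  }
  idx <- match(a$type, rownames(params))
  a$lj_radius <- params$lj_radius[idx]
  a$lj_welldepth <- params$lj_welldepth[idx]
  a$lk_dgfree <- params$lk_dgfree[idx]
  a$lk_lambda <- params$lk_lambda[idx]
  a$lk_volume <- params$lk_volume[idx]
  a$charge <- params$charge[idx]
  a$donor <- params$donor[idx] == 1
  a$acceptor <- params$acceptor[idx] == 1
  a
}

#' Assign simplified atom types by element and context
#'
#' @param atoms an atom table (as in `complex$atoms`).
#' @return character vector of type names (`NA` for unassignable atoms).
#' @export
assign_atom_types <- function(atoms) {
  el <- toupper(atoms$element)
  nm <- atoms$name
  type <- rep(NA_character_, nrow(atoms))
  type[el == "H" | atoms$is_hydrogen] <- "H"
  type[el == "P"] <- "Phos"
  type[el == "S"] <- "S"
  isN <- el == "N"
  type[isN] <- ifelse(atoms$partner[isN] == "protein" & nm[isN] == "N",
                      "Nbb", "Npol")
  isO <- el == "O"
  ooc <- nm %in% c("OP1", "OP2", "OP3", "OD1", "OD2", "OE1", "OE2", "OXT")
  ohx <- nm %in% c("O2'", "OG", "OG1", "OH")
  obb <- atoms$partner == "protein" & nm == "O"
  type[isO & ooc] <- "OOC"
  type[isO & !ooc & ohx] <- "OHx"
  type[isO & !ooc & !ohx & obb] <- "OCbb"
  type[isO & is.na(type)] <- "Oacc"
  isC <- el == "C"
  type[isC & atoms$partner == "protein" & nm == "C"] <- "CObb"
  type[isC & nm == "CA"] <- "CAbb"
  type[isC & is.na(type)] <- "CH"
  type
}

## Inter-partner heavy-atom geometry shared by LJ / solvation / elec:
## typed heavy-atom frames for both partners and their distance matrix.
interaction_frame <- function(complex, pose = NULL, params = atom_type_params()) {
  a <- typed_atoms(complex, pose, params)
  heavy <- a[!a$is_hydrogen, , drop = FALSE]
  p <- heavy[heavy$partner == "protein", , drop = FALSE]
  r <- heavy[heavy$partner == "rna", , drop = FALSE]
  list(p = p, r = r, d = pair_dist(atom_xyz(p), atom_xyz(r)),
       hydro = a[a$is_hydrogen, , drop = FALSE])
}

#' Lennard-Jones attractive and repulsive terms
#'
#' Standard 12-6 potential over inter-partner heavy-atom pairs within the
#' cutoff, with `r_min = r_i + r_j` and `eps = sqrt(eps_i eps_j)`. The
#' energy is split by sign: non-positive contributions sum into `atr`,
#' positive ones into `rep`. The repulsive branch is linearized below
#' `0.6 r_min` so that deep clashes grow linearly rather than as `d^-12`.
#'
#' @param complex an `rna_complex`.
#' @param pose optional `pose` applied to the RNA partner.
#' @param params atom-type table from [atom_type_params()].
#' @param config a [highres_config()].
#' @param frame precomputed interaction frame (internal fast path).
#' @return named numeric `c(atr = ..., rep = ...)`.
#' @export
score_lj <- function(complex, pose = NULL, params = atom_type_params(),
                     config = highres_config(), frame = NULL) {
  f <- frame %||% interaction_frame(complex, pose, params)
  d <- f$d
  within <- d < config$lj_cutoff & d > 0
  if (!any(within)) return(c(atr = 0, rep = 0))
  rmin <- outer(f$p$lj_radius, f$r$lj_radius, "+")
  eps <- sqrt(outer(f$p$lj_welldepth, f$r$lj_welldepth))
  dd <- d[within]; rm <- rmin[within]; ep <- eps[within]
  lj <- function(dd, rm, ep) ep * ((rm / dd)^12 - 2 * (rm / dd)^6)
  e <- lj(dd, rm, ep)
  ## linearize below the clash wall: first-order expansion at 0.6 r_min
  lo <- dd < config$rep_linearize_below * rm
  if (any(lo)) {
    d0 <- config$rep_linearize_below * rm[lo]
    e0 <- lj(d0, rm[lo], ep[lo])
    slope <- ep[lo] * (-12 * rm[lo]^12 / d0^13 + 12 * rm[lo]^6 / d0^7)
    e[lo] <- e0 + slope * (dd[lo] - d0)
  }
  c(atr = sum(e[e <= 0]), rep = sum(e[e > 0]))
}

#' Coulomb electrostatic term
#'
#' Inter-partner sum of `q_i q_j C / (eps(d) d)` with the
#' distance-dependent dielectric `eps(d) = d`, pair distances clamped from
#' below at `elec_min_dist` and cut off at `elec_cutoff`. All atoms
#' (including hydrogens) carry a partial charge.
#'
#' @inheritParams score_lj
#' @return numeric, kcal/mol.
#' @export
score_elec <- function(complex, pose = NULL, params = atom_type_params(),
                       config = highres_config(), frame = NULL) {
  f <- frame %||% interaction_frame(complex, pose, params)
  within <- f$d < config$elec_cutoff & f$d > 0
  if (!any(within)) return(0)
  q <- outer(f$p$charge, f$r$charge)
  dc <- pmax(f$d[within], config$elec_min_dist)
  sum(config$coulomb_constant * q[within] / (dc * dc))
}

#' Lazaridis-Karplus solvation term
#'
#' Symmetric Gaussian-exclusion desolvation over inter-partner heavy-atom
#' pairs within the cutoff:
#' `-[dG_i / (2 pi^{3/2} lambda_i d^2)] exp(-x_i^2) V_j + (i <-> j)` with
#' `x_i = (d - r_i)/lambda_i`.
#'
#' @inheritParams score_lj
#' @return numeric, kcal/mol.
#' @export
score_solv <- function(complex, pose = NULL, params = atom_type_params(),
                       config = highres_config(), frame = NULL) {
  f <- frame %||% interaction_frame(complex, pose, params)
  within <- which(f$d < config$solv_cutoff & f$d > 0, arr.ind = TRUE)
  if (nrow(within) == 0) return(0)
  i <- within[, 1]; j <- within[, 2]
  d <- f$d[within]
  pre <- 2 * pi^1.5
  xi <- (d - f$p$lj_radius[i]) / f$p$lk_lambda[i]
  xj <- (d - f$r$lj_radius[j]) / f$r$lk_lambda[j]
  ei <- -(f$p$lk_dgfree[i] / (pre * f$p$lk_lambda[i] * d^2)) *
    exp(-xi^2) * f$r$lk_volume[j]
  ej <- -(f$r$lk_dgfree[j] / (pre * f$r$lk_lambda[j] * d^2)) *
    exp(-xj^2) * f$p$lk_volume[i]
  sum(ei + ej)
}

#' Hydrogen-bond 10-12 term, binned four ways
#'
#' Donor-acceptor heavy-atom pairs across the interface with distance in
#' the admissible window score
#' `E = eps_hb * (5 (r0/d)^12 - 6 (r0/d)^10) * f(theta)` where `theta` is
#' the deviation of the donor-H...acceptor geometry from linearity;
#' `f = cos^2 theta`, and 1 when no hydrogen is bonded to the donor (so
#' hydrogen-free structures remain scorable). Bonds are binned by backbone
#' (`bb`: both atoms backbone) vs side-chain/base (`sc`), and short-range
#' (same chain, sequence separation <= 4) vs long-range. Inter-partner
#' bonds, the only ones scored here, are always long-range.
#'
#' @inheritParams score_lj
#' @return named numeric `c(lr_bb, sr_bb, lr_sc, sr_sc)`, kcal/mol.
#' @export
score_hbond <- function(complex, pose = NULL, params = atom_type_params(),
                        config = highres_config(), frame = NULL) {
  f <- frame %||% interaction_frame(complex, pose, params)
  out <- c(lr_bb = 0, sr_bb = 0, lr_sc = 0, sr_sc = 0)
  pairs <- rbind(
    hb_pairs(f$p, f$r, f$d, config),                # donor in protein
    hb_pairs(f$r, f$p, t(f$d), config)              # donor in RNA
  )
  if (nrow(pairs) == 0) return(out)
  for (k in seq_len(nrow(pairs))) {
    e <- pairs$energy[k] * hb_angle_factor(pairs[k, ], f$hydro)
    bin <- if (pairs$bb[k]) "lr_bb" else "lr_sc"
    out[bin] <- out[bin] + e
  }
  out
}

## Candidate donor->acceptor pairs with the distance-dependent 10-12 energy.
hb_pairs <- function(don_frame, acc_frame, d, config) {
  don <- which(don_frame$donor)
  acc <- which(acc_frame$acceptor)
  if (length(don) == 0 || length(acc) == 0) {
    return(data.frame())
  }
  dd <- d[don, acc, drop = FALSE]
  hit <- which(dd >= config$hbond_range[1] & dd <= config$hbond_range[2],
               arr.ind = TRUE)
  if (nrow(hit) == 0) return(data.frame())
  di <- don[hit[, 1]]; ai <- acc[hit[, 2]]
  r <- dd[hit]
  ratio <- config$hbond_r0 / r
  data.frame(
    energy = config$hbond_eps * (5 * ratio^12 - 6 * ratio^10),
    bb = don_frame$backbone[di] & acc_frame$backbone[ai],
    don_unit = don_frame$unit[di],
    dx = don_frame$x[di], dy = don_frame$y[di], dz = don_frame$z[di],
    ax = acc_frame$x[ai], ay = acc_frame$y[ai], az = acc_frame$z[ai],
    stringsAsFactors = FALSE
  )
}

## cos^2 of the deviation from donor-H...acceptor linearity; 1 without H.
hb_angle_factor <- function(pair, hydro) {
  h <- hydro[hydro$unit == pair$don_unit, , drop = FALSE]
  if (nrow(h) == 0) return(1)
  dpos <- c(pair$dx, pair$dy, pair$dz)
  hd <- pair_dist(atom_xyz(h), matrix(dpos, 1))
  h <- h[hd < 1.3, , drop = FALSE]
  if (nrow(h) == 0) return(1)
  best <- 0
  apos <- c(pair$ax, pair$ay, pair$az)
  for (k in seq_len(nrow(h))) {
    hpos <- as.numeric(h[k, c("x", "y", "z")])
    v1 <- dpos - hpos; v2 <- apos - hpos
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    c_dev <- -cosang                     # 1 when perfectly linear
    best <- max(best, if (c_dev > 0) c_dev^2 else 0)
  }
  best
}

#' Atomic-contact statistical pair term
#'
#' Sum of residue-nucleotide pair-table entries over all protein-residue /
#' nucleotide pairs that share at least one inter-partner heavy-atom
#' contact below the cutoff. Reuses the table estimated by
#' [estimate_pair_params()].
#'
#' @inheritParams score_lj
#' @param pair_table symmetric type x type matrix of pair log-odds.
#' @return numeric.
#' @export
score_pair_atomic <- function(complex, pose = NULL, pair_table,
                              params = atom_type_params(),
                              config = highres_config(), frame = NULL) {
  f <- frame %||% interaction_frame(complex, pose, params)
  hit <- which(f$d < config$pair_cutoff & f$d > 0, arr.ind = TRUE)
  if (nrow(hit) == 0) return(0)
  pu <- f$p$unit[hit[, 1]]; ru <- f$r$unit[hit[, 2]]
  upairs <- unique(data.frame(pu = pu, ru = ru, stringsAsFactors = FALSE))
  pa <- f$p$resname[match(upairs$pu, f$p$unit)]
  rb <- unname(RNA_RESNAME_MAP[f$r$resname[match(upairs$ru, f$r$unit)]])
  if (any(!pa %in% rownames(pair_table)) || any(!rb %in% rownames(pair_table))) {
    stop("residue type missing from pair table")
  }
  sum(pair_table[cbind(pa, rb)])
}

#' Box-constrained weight vector for the all-atom terms
#'
#' @param values numeric of length 10 (or named, matching
#'   [HIGHRES_TERMS]); every weight must lie in `[box_min, box_max]`.
#' @param box_min,box_max weight box, default `[0, 1]`.
#' @return named numeric of class `weight_vector`.
#' @export
weight_vector <- function(values = rep(1, length(HIGHRES_TERMS)),
                          box_min = 0, box_max = 1) {
  if (is.null(names(values))) {
    stopifnot(length(values) == length(HIGHRES_TERMS))
    names(values) <- HIGHRES_TERMS
  }
  stopifnot(all(HIGHRES_TERMS %in% names(values)))
  values <- values[HIGHRES_TERMS]
  if (any(values < box_min - 1e-12) || any(values > box_max + 1e-12)) {
    stop("weights outside the [", box_min, ", ", box_max, "] box")
  }
  structure(as.numeric(values), names = HIGHRES_TERMS,
            class = "weight_vector")
}

#' All-atom score breakdown of a pose
#'
#' Computes the ten term values over inter-partner interactions and their
#' weighted sum. `fa_dun` is always 0 (no side-chain repacking is performed;
#' see [HIGHRES_TERMS]). Lower total = better pose.
#'
#' @inheritParams score_lj
#' @param weights a [weight_vector()].
#' @param pair_table residue-nucleotide pair log-odds matrix (zeros if
#'   omitted, i.e. a neutral pair term).
#' @return list of class `score_breakdown`: `terms` (named numeric of
#'   length 10) and `total`.
#' @export
score_highres <- function(complex, pose = NULL, weights = weight_vector(),
                          pair_table = NULL, params = atom_type_params(),
                          config = highres_config()) {
  weights <- weight_vector(weights)
  f <- interaction_frame(complex, pose, params)
  terms <- highres_terms_from_frame(f, complex, pose, pair_table, params, config)
  structure(list(terms = terms, total = sum(unclass(weights) * terms)),
            class = "score_breakdown")
}

## Term vector from a precomputed frame (fast path shared with decoy scoring).
highres_terms_from_frame <- function(f, complex, pose, pair_table, params,
                                     config) {
  if (is.null(pair_table)) {
    pair_table <- matrix(0, length(ALL_UNIT_TYPES), length(ALL_UNIT_TYPES),
                         dimnames = list(ALL_UNIT_TYPES, ALL_UNIT_TYPES))
  }
  lj <- score_lj(complex, pose, params, config, frame = f)
  hb <- score_hbond(complex, pose, params, config, frame = f)
  terms <- c(
    fa_atr = unname(lj["atr"]), fa_rep = unname(lj["rep"]),
    fa_sol = score_solv(complex, pose, params, config, frame = f),
    fa_pair = score_pair_atomic(complex, pose, pair_table, params, config,
                                frame = f),
    fa_dun = 0,
    hack_elec = score_elec(complex, pose, params, config, frame = f),
    hbond_lr_bb = unname(hb["lr_bb"]), hbond_sr_bb = unname(hb["sr_bb"]),
    hbond_lr_sc = unname(hb["lr_sc"]), hbond_sr_sc = unname(hb["sr_sc"])
  )
  terms[HIGHRES_TERMS]
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat("all-atom score breakdown (kcal/mol-scale, lower = better):\n")
  for (k in names(x$terms)) cat(sprintf("  %-12s %10.4f\n", k, x$terms[k]))
  cat(sprintf("  %-12s %10.4f\n", "total", x$total))
  invisible(x)
}

#' Score a set of poses into a per-decoy term matrix
#'
#' Applies each pose to the RNA partner and computes the ten-term
#' breakdown; typing is done once. This is the feature-matrix builder used
#' by the learning pipeline.
#'
#' @param complex an `rna_complex`.
#' @param poses list of `pose` objects.
#' @param pair_table optional pair log-odds matrix.
#' @param params,config as in [score_highres()].
#' @return numeric matrix, one row per pose, columns [HIGHRES_TERMS].
#' @export
score_poses <- function(complex, poses, pair_table = NULL,
                        params = atom_type_params(),
                        config = highres_config()) {
  out <- matrix(NA_real_, length(poses), length(HIGHRES_TERMS),
                dimnames = list(NULL, HIGHRES_TERMS))
  for (i in seq_along(poses)) {
    f <- interaction_frame(complex, poses[[i]], params)
    out[i, ] <- highres_terms_from_frame(f, complex, poses[[i]], pair_table,
                                         params, config)
  }
  out
}

#' Write/read a weight vector as a two-column text file
#' @param weights a [weight_vector()].
#' @param path file path.
#' @return the path (write) or a `weight_vector` (read).
#' @export
write_weights <- function(weights, path) {
  utils::write.table(
    data.frame(term = names(weights), weight = as.numeric(weights)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  weight_vector(setNames(tab$weight, tab$term))
}
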