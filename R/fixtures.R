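## Synthetic protein-RNA fixtures: idealized helical complexes in standard
## PDB nomenclature, decoy ensembles with a controllable near-native
## fraction, and feature matrices with known ground-truth weights. These
## generators are first-class, tested code: every test input of the package
## is built by them, deterministically from a seed.

#' Generate an idealized protein-RNA complex
#'
#' The protein partner is an idealized helix of N/CA/C/O backbone atoms
#' with one or two side-chain dummy atoms per residue (glycine gets none,
#' exercising the centroid fallback); residue types cycle through a fixed
#' palette. The RNA partner is an idealized single helix with the phosphate
#' and full sugar-ring backbone plus a planar base ring per nucleotide,
#' types cycling A, C, G, U. The RNA is translated along the inter-partner
#' axis until the minimum heavy-atom distance equals `interface_gap`.
#'
#' Geometry is parametric, not real A-form helical parameters: the point is
#' standard nomenclature, realistic atom densities and contact distances,
#' not structure prediction.
#'
#' @param n_protein_residues,n_nucleotides unit counts (>= 1).
#' @param interface_gap minimum inter-partner heavy-atom distance, Angstrom.
#' @param seed integer seed (small coordinate jitter, deterministic).
#' @param id complex label.
#' @param path optional file path; when given the complex is also written
#'   as a PDB file.
#' @return an `rna_complex`.
#' @export
make_complex <- function(n_protein_residues = 5, n_nucleotides = 3,
                         interface_gap = 4, seed = 1, id = "synthetic",
                         path = NULL) {
  stopifnot(n_protein_residues >= 1, n_nucleotides >= 1, interface_gap > 0)
  set.seed(seed)
  jit <- function(n) stats::rnorm(n, 0, 0.02)

  ## --- protein helix: rise 1.5 A, 100 deg/residue, radius 2.3 A
  prot_types <- rep(c("ALA", "SER", "ARG", "GLY", "LEU"),
                    length.out = n_protein_residues)
  prows <- list()
  for (i in seq_len(n_protein_residues)) {
    th <- (i - 1) * 100 * pi / 180
    ca <- c(2.3 * cos(th), 2.3 * sin(th), 1.5 * (i - 1))
    out_dir <- c(cos(th), sin(th), 0)
    atoms <- rbind(
      N = ca + c(-0.5, 0.8, -0.9), CA = ca,
      C = ca + c(0.6, -0.7, 0.8), O = ca + c(1.2, -1.2, 1.4)
    )
    if (prot_types[i] != "GLY") {
      atoms <- rbind(atoms, CB = ca + 1.5 * out_dir)
      if (prot_types[i] %in% c("ARG", "LEU")) {
        atoms <- rbind(atoms, CG = ca + 2.9 * out_dir + c(0, 0, 0.4))
      }
      if (prot_types[i] == "ARG") {
        atoms <- rbind(atoms, NH1 = ca + 4.2 * out_dir + c(0, 0, 0.8))
      }
      if (prot_types[i] == "SER") {
        atoms <- rbind(atoms, OG = ca + 2.7 * out_dir + c(0, 0, 0.3))
      }
    }
    el <- substr(rownames(atoms), 1, 1)
    prows[[i]] <- data.frame(
      name = rownames(atoms), element = el, resname = prot_types[i],
      chain = "A", resno = i, insert = "", partner = "protein",
      x = atoms[, 1] + jit(nrow(atoms)), y = atoms[, 2] + jit(nrow(atoms)),
      z = atoms[, 3] + jit(nrow(atoms)), stringsAsFactors = FALSE
    )
  }

  ## --- RNA helix: rise 2.8 A, 33 deg/nt, radius 9 A, offset in +x
  rna_types <- rep(c("A", "C", "G", "U"), length.out = n_nucleotides)
  rrows <- list()
  sugar <- c("O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'")
  for (i in seq_len(n_nucleotides)) {
    th <- (i - 1) * 33 * pi / 180
    anchor <- c(9 * cos(th), 9 * sin(th), 2.8 * (i - 1))
    inward <- -c(cos(th), sin(th), 0)    # base points toward the helix axis
    perp <- c(-sin(th), cos(th), 0)
    atoms <- rbind(
      P = anchor, OP1 = anchor + c(0.8, 1.1, 0.6),
      OP2 = anchor + c(-1.2, 0.7, -0.5)
    )
    for (k in seq_along(sugar)) {
      ang <- 2 * pi * (k - 1) / length(sugar)
      atoms <- rbind(atoms, anchor + 1.4 * inward +
                       1.2 * (cos(ang) * perp + sin(ang) * c(0, 0, 1)))
      rownames(atoms)[nrow(atoms)] <- sugar[k]
    }
    base_names <- if (rna_types[i] %in% c("A", "G")) {
      c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
    } else {
      c("N1", "C2", "O2", "N3", "C4", "C5", "C6")
    }
    base_c <- anchor + 4.2 * inward
    for (k in seq_along(base_names)) {
      ang <- 2 * pi * (k - 1) / length(base_names)
      atoms <- rbind(atoms, base_c + 1.3 * (cos(ang) * perp + sin(ang) * c(0, 0, 1)))
      rownames(atoms)[nrow(atoms)] <- base_names[k]
    }
    el <- substr(rownames(atoms), 1, 1)
    rrows[[i]] <- data.frame(
      name = rownames(atoms), element = el, resname = rna_types[i],
      chain = "B", resno = i, insert = "", partner = "rna",
      x = atoms[, 1] + jit(nrow(atoms)), y = atoms[, 2] + jit(nrow(atoms)),
      z = atoms[, 3] + jit(nrow(atoms)), stringsAsFactors = FALSE
    )
  }

  atoms <- do.call(rbind, c(prows, rrows, list(make.row.names = FALSE)))
  atoms$serial <- seq_len(nrow(atoms))

  ## shift the RNA along the axis to its closest protein atom until the
  ## minimum heavy-atom separation equals interface_gap
  prot_xyz <- as.matrix(atoms[atoms$partner == "protein", c("x", "y", "z")])
  rna_sel <- atoms$partner == "rna"
  for (iter in 1:50) {
    rna_xyz <- as.matrix(atoms[rna_sel, c("x", "y", "z")])
    d <- pair_dist(prot_xyz, rna_xyz)
    m <- min(d)
    if (abs(m - interface_gap) < 0.01) break
    hit <- which(d == m, arr.ind = TRUE)[1, ]
    dirv <- rna_xyz[hit[2], ] - prot_xyz[hit[1], ]
    dirv <- dirv / sqrt(sum(dirv^2))
    shift <- (interface_gap - m) * dirv
    atoms$x[rna_sel] <- atoms$x[rna_sel] + shift[1]
    atoms$y[rna_sel] <- atoms$y[rna_sel] + shift[2]
    atoms$z[rna_sel] <- atoms$z[rna_sel] + shift[3]
  }

  cx <- new_complex(atoms, id = id)
  if (!is.null(path)) write_pdb(cx, path)
  cx
}

#' Decoy ensemble with a controlled near-native fraction
#'
#' A test double for [generate_decoys()]: mixes low-amplitude poses (which
#' stay below the near-native Irmsd threshold) with large-amplitude poses
#' (far beyond the decoy threshold), so that the realised near-native
#' fraction tracks `target_nn_fraction`. Labels are still computed honestly
#' from the realised Irmsd.
#'
#' @param complex the native `rna_complex`.
#' @param n ensemble size.
#' @param target_nn_fraction desired near-native fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return a `labelled_decoy_set`.
#' @export
make_decoy_ensemble <- function(complex, n, target_nn_fraction = 0.3,
                                seed = 1) {
  stopifnot(target_nn_fraction >= 0, target_nn_fraction <= 1, n >= 1)
  interface <- native_interface(complex)
  nat <- interface_fit_atoms(complex, interface)
  nat_xyz <- atom_xyz(nat)
  mobile <- nat$partner == "rna"
  pivot <- partner_centroid(complex, "rna")

  near <- structure(list(name = "near", translation_mean = 0.5,
                         rotation_mean = 2, sd = 0.3),
                    class = "perturbation_setting")
  ## superposition over the joint interface absorbs part of an RNA-only
  ## displacement, so the far regime needs a large amplitude to stay
  ## safely beyond the 8 A decoy threshold
  far <- structure(list(name = "far", translation_mean = 60,
                        rotation_mean = 90, sd = 2),
                   class = "perturbation_setting")
  set.seed(seed)
  use_near <- stats::runif(n) < target_nn_fraction
  poses <- vector("list", n)
  irmsds <- numeric(n)
  for (i in seq_len(n)) {
    p <- sample_pose(if (use_near[i]) near else far)
    poses[[i]] <- p
    dec_xyz <- apply_pose_xyz(nat_xyz, p, mobile = mobile, pivot = pivot)
    irmsds[i] <- kabsch_rmsd(nat_xyz, dec_xyz)
  }
  label <- ifelse(irmsds < 5, "near_native",
                  ifelse(irmsds > 8, "decoy", "test"))
  structure(list(poses = poses, irmsd = irmsds, label = label,
                 setting = near, complex_id = complex$id,
                 nn_threshold = 5, decoy_threshold = 8),
            class = "labelled_decoy_set")
}

#' Feature matrix with known ground-truth weights
#'
#' Class-conditional Gaussian term values constructed so that the
#' Bayes-optimal linear score is exactly `true_weights`: the class-mean
#' difference is `-true_weights` (near-native rows have lower energy along
#' the informative directions) with isotropic noise of standard deviation
#' `noise_sd`. With `noise_sd = 0` the classes are perfectly separable by
#' `true_weights`; as `noise_sd` grows, the achievable AUC falls toward
#' 0.5.
#'
#' @param n_groups number of complexes (groups).
#' @param rows_per_class near-native (and decoy) rows per group.
#' @param true_weights numeric length 10 (or any length), in `[0, 1]`.
#' @param noise_sd noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return data.frame: `group`, `label` (`near_native`/`decoy`), `irmsd`
#'   (surrogate values consistent with the labels), plus one column per
#'   term in `names(true_weights)` (or [HIGHRES_TERMS]).
#' @export
make_feature_matrix <- function(n_groups = 2, rows_per_class = 30,
                                true_weights = weight_vector(),
                                noise_sd = 0.1, seed = 1) {
  stopifnot(noise_sd >= 0, n_groups >= 1, rows_per_class >= 1)
  w <- as.numeric(true_weights)
  d <- length(w)
  keys <- names(true_weights) %||% HIGHRES_TERMS[seq_len(d)]
  set.seed(seed)
  n <- 2 * rows_per_class * n_groups
  y <- rep(rep(c(1, 0), each = rows_per_class), n_groups)
  X <- matrix(stats::rnorm(n * d, 0, noise_sd), n, d)
  X <- X - outer(y, w)                    # near-native rows shift down by w
  colnames(X) <- keys
  out <- data.frame(
    group = rep(sprintf("g%03d", seq_len(n_groups)), each = 2 * rows_per_class),
    label = ifelse(y == 1, "near_native", "decoy"),
    irmsd = ifelse(y == 1, stats::runif(n, 0.5, 4.5), stats::runif(n, 9, 30)),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(X))
}
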