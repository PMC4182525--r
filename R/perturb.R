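## Rigid-body perturbation decoys around the native pose. Amplitudes follow
## a normal law with unit variance around setting-specific expectations;
## decoys are labelled by interface RMSD: near-native below 5 A, decoy above
## 8 A, the 5-8 A band held out as "test" and excluded from learning.

#' Perturbation amplitude settings
#'
#' The three regimes used when generating decoy ensembles: the expectation
#' of the translation magnitude (Angstrom) and of each rotation magnitude
#' (degrees); both are drawn with standard deviation 1.
#'
#' @param name `"small"` (1 A, 4 deg), `"regular"` (3 A, 8 deg) or
#'   `"large"` (9 A, 27 deg).
#' @return list of class `perturbation_setting`.
#' @export
perturbation_setting <- function(name = c("regular", "small", "large")) {
  name <- match.arg(name)
  p <- switch(name,
    small = c(translation_mean = 1, rotation_mean = 4),
    regular = c(translation_mean = 3, rotation_mean = 8),
    large = c(translation_mean = 9, rotation_mean = 27)
  )
  structure(list(name = name, translation_mean = p[["translation_mean"]],
                 rotation_mean = p[["rotation_mean"]], sd = 1),
            class = "perturbation_setting")
}

#' Sample a random rigid-body pose
#'
#' The translation magnitude is drawn from Normal(translation_mean, 1),
#' clamped at zero, and applied along a uniformly random direction. Each of
#' the three Euler angles has magnitude Normal(rotation_mean, 1), clamped
#' at zero, with a random sign.
#'
#' @param setting a [perturbation_setting()].
#' @return a `pose`. Uses the current RNG stream; seed with `set.seed()`
#'   or use the `seed` arguments of the higher-level generators.
#' @export
sample_pose <- function(setting = perturbation_setting("regular")) {
  mag <- max(0, stats::rnorm(1, setting$translation_mean, setting$sd))
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  ang <- pmax(0, stats::rnorm(3, setting$rotation_mean, setting$sd)) *
    sample(c(-1, 1), 3, replace = TRUE)
  pose(rotation = ang, translation = mag * dir)
}

#' Generate a labelled rigid-body decoy ensemble
#'
#' Applies `n` sampled poses to the RNA partner (protein fixed), computes
#' each decoy's interface RMSD against the native, and labels it
#' `near_native` (Irmsd < `nn_threshold`), `decoy`
#' (Irmsd > `decoy_threshold`) or `test` (in between). Deterministic for a
#' given seed.
#'
#' @param complex the native `rna_complex`.
#' @param n number of decoys (>= 1).
#' @param setting a [perturbation_setting()].
#' @param seed integer seed.
#' @param nn_threshold,decoy_threshold Irmsd label thresholds (5 and 8 A).
#' @param interface optional precomputed [native_interface()].
#' @return list of class `labelled_decoy_set`: `poses` (list), `irmsd`
#'   (numeric), `label` (character), `setting`, `complex_id`.
#' @export
generate_decoys <- function(complex, n, setting = perturbation_setting("regular"),
                            seed = 1, nn_threshold = 5, decoy_threshold = 8,
                            interface = NULL) {
  if (n < 1) stop("n must be >= 1")
  interface <- interface %||% native_interface(complex)
  ## precompute fit atoms once: poses act on the fit atoms directly
  nat <- interface_fit_atoms(complex, interface)
  nat_xyz <- atom_xyz(nat)
  mobile <- nat$partner == "rna"
  pivot <- partner_centroid(complex, "rna")

  set.seed(seed)
  poses <- vector("list", n)
  irmsds <- numeric(n)
  for (i in seq_len(n)) {
    p <- sample_pose(setting)
    poses[[i]] <- p
    dec_xyz <- apply_pose_xyz(nat_xyz, p, mobile = mobile, pivot = pivot)
    irmsds[i] <- kabsch_rmsd(nat_xyz, dec_xyz)
  }
  label <- ifelse(irmsds < nn_threshold, "near_native",
                  ifelse(irmsds > decoy_threshold, "decoy", "test"))
  structure(list(poses = poses, irmsd = irmsds, label = label,
                 setting = setting, complex_id = complex$id,
                 nn_threshold = nn_threshold,
                 decoy_threshold = decoy_threshold),
            class = "labelled_decoy_set")
}

#' @export
print.labelled_decoy_set <- function(x, ...) {
  cat(sprintf(
    "decoy set '%s' (%s setting): %d decoys | near_native %d, decoy %d, test %d\n",
    x$complex_id, x$setting$name, length(x$poses),
    sum(x$label == "near_native"), sum(x$label == "decoy"),
    sum(x$label == "test")))
  invisible(x)
}

#' Select the smallest workable perturbation setting
#'
#' Tries the small, regular and large settings in that order and returns
#' the first whose `n`-decoy ensemble contains at least `required`
#' near-native and `required` decoy conformations.
#'
#' @param complex the native `rna_complex`.
#' @param n ensemble size per trial.
#' @param required minimum count per class, default 30.
#' @param seed integer master seed (a distinct child seed per setting).
#' @return the selected `perturbation_setting`; errors with the
#'   per-setting class counts when none qualifies.
#' @export
select_setting <- function(complex, n, required = 30, seed = 1) {
  tried <- character(0)
  for (k in seq_along(c("small", "regular", "large"))) {
    nm <- c("small", "regular", "large")[k]
    setting <- perturbation_setting(nm)
    ds <- generate_decoys(complex, n, setting, seed = child_seed(seed, k))
    nn <- sum(ds$label == "near_native"); de <- sum(ds$label == "decoy")
    if (nn >= required && de >= required) return(setting)
    tried <- c(tried, sprintf("%s: %d near-native / %d decoy", nm, nn, de))
  }
  stop("no setting yields ", required, "/", required,
       " near-native/decoy conformations (", paste(tried, collapse = "; "), ")")
}

#' Assemble a balanced learning set from labelled decoy ensembles
#'
#' Uniformly samples, without replacement, `per_class` near-native and
#' `per_class` decoy conformations from each complex's ensemble. Decoys in
#' the intermediate "test" Irmsd band never enter the learning set.
#'
#' @param sets list of `labelled_decoy_set` objects.
#' @param per_class conformations per class per complex, default 30.
#' @param seed integer seed for the uniform draws.
#' @return data.frame with one row per selected conformation: `group`
#'   (complex id), `index` (position in its ensemble), `irmsd`, `label`.
#' @export
assemble_learning_set <- function(sets, per_class = 30, seed = 1) {
  set.seed(seed)
  rows <- lapply(sets, function(s) {
    nn <- which(s$label == "near_native")
    de <- which(s$label == "decoy")
    if (length(nn) < per_class || length(de) < per_class) {
      stop("complex ", s$complex_id, " has only ", length(nn),
           " near-native and ", length(de), " decoy conformations; ",
           per_class, " of each required")
    }
    idx <- c(sample(nn, per_class), sample(de, per_class))
    data.frame(group = s$complex_id, index = idx, irmsd = s$irmsd[idx],
               label = s$label[idx], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a decoy set index as delimited text
#'
#' One row per decoy: id, the six pose parameters, Irmsd, label and (when
#' given) the per-term scores.
#'
#' @param set a `labelled_decoy_set`.
#' @param path output file path.
#' @param scores optional matrix of per-decoy term values ([score_poses()]).
#' @return invisibly, `path`.
#' @export
write_decoy_index <- function(set, path, scores = NULL) {
  rot <- t(vapply(set$poses, function(p) p$rotation, numeric(3)))
  tra <- t(vapply(set$poses, function(p) p$translation, numeric(3)))
  df <- data.frame(
    decoy = seq_along(set$poses),
    rot_x = rot[, 1], rot_y = rot[, 2], rot_z = rot[, 3],
    trans_x = tra[, 1], trans_y = tra[, 2], trans_z = tra[, 3],
    irmsd = set$irmsd, label = set$label
  )
  if (!is.null(scores)) df <- cbind(df, as.data.frame(scores))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decoy_index
#' @param ... passed to `utils::read.table`.
#' @export
read_decoy_index <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, ...)
}
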