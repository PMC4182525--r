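## Assessment metrics: interface RMSD adapted to protein-RNA complexes
## (fit atoms: protein backbone N/CA/C/O and RNA backbone P), ROC/AUC with
## tie handling, top-k precision and the enrichment score.

#' Native interface definition
#'
#' Units of either partner with at least one heavy atom within `cutoff` of
#' a heavy atom of the other partner, computed on the native complex only.
#'
#' @param native an `rna_complex`.
#' @param cutoff heavy-atom distance cutoff, Angstrom (default 10, the
#'   CAPRI-style interface convention).
#' @return list of class `interface_definition`: `units` (character vector
#'   of unit keys), `cutoff`.
#' @export
native_interface <- function(native, cutoff = 10) {
  a <- native$atoms
  heavy <- a[!a$is_hydrogen, , drop = FALSE]
  p <- heavy[heavy$partner == "protein", , drop = FALSE]
  r <- heavy[heavy$partner == "rna", , drop = FALSE]
  d <- pair_dist(atom_xyz(p), atom_xyz(r))
  close_pairs <- d < cutoff
  units <- unique(c(p$unit[rowSums(close_pairs) > 0],
                    r$unit[colSums(close_pairs) > 0]))
  if (length(units) == 0) stop("empty native interface at cutoff ", cutoff)
  structure(list(units = units, cutoff = cutoff),
            class = "interface_definition")
}

## Interface fit-atom selector: protein backbone N/CA/C/O and RNA P atoms
## of interface units, in a stable order.
interface_fit_atoms <- function(complex, interface) {
  a <- complex$atoms
  sel <- a$unit %in% interface$units &
    ((a$partner == "protein" & a$name %in% c("N", "CA", "C", "O")) |
       (a$partner == "rna" & a$name == "P"))
  a[sel, , drop = FALSE]
}

## Least-squares (Kabsch) superposition of moving onto fixed (both n x 3).
## Returns the RMSD after the optimal rigid fit.
kabsch_rmsd <- function(fixed, moving) {
  stopifnot(nrow(fixed) == nrow(moving), nrow(fixed) >= 3)
  cf <- colMeans(fixed); cm <- colMeans(moving)
  A <- sweep(fixed, 2, cf); B <- sweep(moving, 2, cm)
  s <- svd(crossprod(B, A))
  dsign <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  fitted <- B %*% t(R)
  sqrt(mean(rowSums((fitted - A)^2)))
}

#' Interface RMSD of a decoy against the native complex
#'
#' The native interface (heavy-atom cutoff, default 10 A) selects the fit
#' atoms: backbone N, CA, C, O of interface protein residues and the
#' backbone P atoms of interface nucleotides. The decoy's fit atoms are
#' optimally superposed onto the native's (least-squares rotation over both
#' partners' interface backbone) and the RMSD over those atoms is returned.
#'
#' @param native the native `rna_complex`.
#' @param decoy an `rna_complex` with the same residue composition, or a
#'   `pose` to be applied to the native's RNA partner.
#' @param interface optional precomputed [native_interface()].
#' @return Irmsd in Angstrom.
#' @export
irmsd <- function(native, decoy, interface = NULL) {
  interface <- interface %||% native_interface(native)
  nat <- interface_fit_atoms(native, interface)
  nat_xyz <- atom_xyz(nat)
  if (inherits(decoy, "pose")) {
    dec_xyz <- apply_pose_xyz(nat_xyz, decoy,
                              mobile = nat$partner == "rna",
                              pivot = partner_centroid(native, "rna"))
  } else {
    dec <- interface_fit_atoms(decoy, interface)
    if (nrow(dec) != nrow(nat) ||
        !all(paste(dec$unit, dec$name) == paste(nat$unit, nat$name))) {
      stop("decoy interface atom set does not match the native")
    }
    dec_xyz <- atom_xyz(dec)
  }
  kabsch_rmsd(nat_xyz, dec_xyz)
}

## Tie-aware AUC from an orientation where HIGHER s means more positive.
## Rank-statistic form: equals counting concordant pairs with ties at 1/2.
auc_rank <- function(s, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("both classes must be present for AUC")
  r <- rank(s)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC for scored decoys
#'
#' Scores follow the energy convention (lower = better); positives are the
#' near-native decoys. The AUC is the tie-aware rank statistic (ties count
#' one half), which equals the trapezoidal area under the tie-grouped ROC
#' curve.
#'
#' @param score numeric, lower = better.
#' @param label logical or 0/1, `TRUE`/1 for near-native.
#' @return list of class `roc_result`: `auc`, `roc_points` (data.frame with
#'   `fpr`, `tpr`).
#' @export
roc_auc <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label))
  auc <- auc_rank(-score, label)
  ## tie-grouped ROC points, best (lowest) scores first
  o <- order(score)
  s <- score[o]; l <- label[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)
  pts <- data.frame(fpr = c(0, fp[last] / sum(!l)),
                    tpr = c(0, tp[last] / sum(l)))
  structure(list(auc = auc, roc_points = pts), class = "roc_result")
}

#' Enrichment score
#'
#' Overlap between the best `fraction` of decoys by energy and the best
#' `fraction` by Irmsd, normalized as
#' `ES = |E_top intersect R_top| / (fraction^2 N)`. With the default 10%
#' fraction, random scoring gives 1 in expectation and a perfect
#' score-to-Irmsd ordering gives 10.
#'
#' @param score numeric, lower = better.
#' @param irmsd_values numeric, Angstrom.
#' @param fraction top fraction, default 0.10.
#' @return numeric in `[0, 1/fraction]`.
#' @export
enrichment_score <- function(score, irmsd_values, fraction = 0.10) {
  n <- length(score)
  stopifnot(length(irmsd_values) == n)
  k <- floor(fraction * n)
  if (k < 1) stop("too few decoys for the top fraction ", fraction)
  e_top <- order(score)[seq_len(k)]
  r_top <- order(irmsd_values)[seq_len(k)]
  length(intersect(e_top, r_top)) / (fraction^2 * n)
}

#' Near-native counts among the k best-scoring decoys
#'
#' @param score numeric, lower = better; ties broken by input order
#'   (stable sort).
#' @param label logical/0-1 near-native indicator.
#' @param ks integer vector of list sizes, default `c(10, 100)`.
#' @return data.frame with `k`, `count` (near-natives in the top k) and
#'   `expected` (`k * n_near_native / N`, the chance level).
#' @export
topk_stats <- function(score, label, ks = c(10, 100)) {
  label <- as.logical(label)
  n <- length(score)
  stopifnot(max(ks) <= n)
  o <- order(score)                       # stable for ties
  data.frame(
    k = ks,
    count = vapply(ks, function(k) sum(label[o][seq_len(k)]), 0L),
    expected = ks * sum(label) / n
  )
}

#' Full evaluation report for one decoy set
#'
#' Assessment labelling (near-native: Irmsd < 5 A, non-native otherwise)
#' with ROC/AUC, enrichment score and top-10/top-100 counts, the statistics
#' reported per complex by the evaluation tables.
#'
#' @param score numeric energies, lower = better.
#' @param irmsd_values numeric Irmsd per decoy, Angstrom.
#' @param nn_threshold near-native Irmsd threshold, default 5.
#' @param fraction enrichment-score top fraction, default 0.10.
#' @return list of class `evaluation_report`: `auc`, `roc_points`, `es`,
#'   `top10_nn`, `top100_nn`, `expected_top10`, `n_near_native`, `n`.
#' @export
evaluate_decoys <- function(score, irmsd_values, nn_threshold = 5,
                            fraction = 0.10) {
  label <- irmsd_values < nn_threshold
  roc <- roc_auc(score, label)
  tk <- topk_stats(score, label, ks = c(10, 100))
  structure(list(
    auc = roc$auc, roc_points = roc$roc_points,
    es = enrichment_score(score, irmsd_values, fraction),
    top10_nn = tk$count[1], top100_nn = tk$count[2],
    expected_top10 = tk$expected[1],
    n_near_native = sum(label), n = length(score)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation: N=%d, near-native=%d | ES %.2f, top10 %d (exp %.2f), top100 %d, AUC %.2f%%\n",
    x$n, x$n_near_native, x$es, x$top10_nn, x$expected_top10,
    x$top100_nn, 100 * x$auc))
  invisible(x)
}
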