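## Rigid-body poses: three Euler angles (degrees, ZYX convention) plus a
## translation vector, applied to the mobile RNA partner about its centroid.

#' Create a rigid-body pose
#'
#' @param rotation numeric length-3, Euler angles in degrees applied in ZYX
#'   order (first a rotation about x, then y, then z).
#' @param translation numeric length-3 translation in Angstrom.
#' @return An object of class `pose`.
#' @export
pose <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3, length(translation) == 3,
            all(is.finite(rotation)), all(is.finite(translation)))
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation)),
            class = "pose")
}

#' Identity pose
#' @return A `pose` with zero rotation and zero translation.
#' @export
pose_identity <- function() pose()

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("pose: rot (%.2f, %.2f, %.2f) deg, trans (%.2f, %.2f, %.2f) A\n",
              x$rotation[1], x$rotation[2], x$rotation[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation matrix of a pose (ZYX Euler, degrees)
#' @param p a `pose`.
#' @return 3x3 rotation matrix.
#' @export
pose_rotation_matrix <- function(p) {
  r <- p$rotation * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

## Apply a pose to selected rows of an n x 3 coordinate matrix, rotating
## about `pivot` and then translating.
apply_pose_xyz <- function(xyz, p, mobile = rep(TRUE, nrow(xyz)), pivot) {
  R <- pose_rotation_matrix(p)
  m <- xyz[mobile, , drop = FALSE]
  m <- sweep(m, 2, pivot) %*% t(R)
  m <- sweep(m, 2, pivot + p$translation, "+")
  xyz[mobile, ] <- m
  xyz
}

#' Apply a pose to the mobile RNA partner of a complex
#'
#' Rotates the RNA partner about its heavy-atom centroid and translates it;
#' the protein partner is left fixed, as in rigid-body perturbation around
#' a native binding mode.
#'
#' @param complex an `rna_complex`.
#' @param p a `pose`.
#' @return A new `rna_complex` with transformed RNA coordinates.
#' @export
apply_pose <- function(complex, p) {
  stopifnot(inherits(complex, "rna_complex"), inherits(p, "pose"))
  a <- complex$atoms
  xyz <- apply_pose_xyz(atom_xyz(a), p, mobile = a$partner == "rna",
                        pivot = partner_centroid(complex, "rna"))
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  out <- complex
  out$atoms <- a
  out
}

#' Apply an arbitrary global rigid transform to a whole complex
#'
#' Utility used mainly by invariance tests: rotates all atoms of both
#' partners about the origin and translates them.
#'
#' @param complex an `rna_complex`.
#' @param R 3x3 rotation matrix.
#' @param t numeric length-3 translation.
#' @return A transformed `rna_complex`.
#' @export
transform_complex <- function(complex, R = diag(3), t = c(0, 0, 0)) {
  a <- complex$atoms
  xyz <- atom_xyz(a) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  out <- complex
  out$atoms <- a
  out
}
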