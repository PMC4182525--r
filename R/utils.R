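## Internal numerical helpers shared across modules.

## Squared Euclidean distance matrix between two coordinate matrices (n x 3,
## m x 3). Clamped at zero to guard against negative round-off.
pair_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

pair_dist <- function(a, b) sqrt(pair_dist2(a, b))

## Coordinate matrix (n x 3) from an atom table.
atom_xyz <- function(atoms) {
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}

## Derive a reproducible child seed from a master seed. Kept below 2^31.
child_seed <- function(seed, k) {
  (as.integer(seed) + 104729L * as.integer(k)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
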