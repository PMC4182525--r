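## Independent brute-force oracles: plain double loops over atom pairs,
## scalar arithmetic only, no reuse of the package's vectorized kernels.

heavy_frames <- function(cx, params = atom_type_params()) {
  a <- rnadock:::typed_atoms(cx, NULL, params)
  h <- a[!a$is_hydrogen, ]
  list(p = h[h$partner == "protein", ], r = h[h$partner == "rna", ])
}

oracle_lj <- function(cx, params = atom_type_params(), cutoff = 6,
                      lin = 0.6) {
  f <- heavy_frames(cx, params)
  atr <- 0; rep_ <- 0
  for (i in seq_len(nrow(f$p))) for (j in seq_len(nrow(f$r))) {
    d <- sqrt(sum((c(f$p$x[i], f$p$y[i], f$p$z[i]) -
                     c(f$r$x[j], f$r$y[j], f$r$z[j]))^2))
    if (d >= cutoff) next
    rm <- f$p$lj_radius[i] + f$r$lj_radius[j]
    ep <- sqrt(f$p$lj_welldepth[i] * f$r$lj_welldepth[j])
    if (d < lin * rm) {
      d0 <- lin * rm
      e0 <- ep * ((rm / d0)^12 - 2 * (rm / d0)^6)
      slope <- ep * (-12 * rm^12 / d0^13 + 12 * rm^6 / d0^7)
      e <- e0 + slope * (d - d0)
    } else {
      e <- ep * ((rm / d)^12 - 2 * (rm / d)^6)
    }
    if (e <= 0) atr <- atr + e else rep_ <- rep_ + e
  }
  c(atr = atr, rep = rep_)
}

oracle_elec <- function(cx, params = atom_type_params(), cutoff = 5.5,
                        dmin = 1.45, C = 332.0637) {
  a <- rnadock:::typed_atoms(cx, NULL, params)
  p <- a[a$partner == "protein", ]; r <- a[a$partner == "rna", ]
  e <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(nrow(r))) {
    d <- sqrt(sum((c(p$x[i], p$y[i], p$z[i]) - c(r$x[j], r$y[j], r$z[j]))^2))
    if (d >= cutoff) next
    dc <- max(d, dmin)
    e <- e + C * p$charge[i] * r$charge[j] / (dc * dc)
  }
  e
}

oracle_solv <- function(cx, params = atom_type_params(), cutoff = 6) {
  f <- heavy_frames(cx, params)
  e <- 0
  for (i in seq_len(nrow(f$p))) for (j in seq_len(nrow(f$r))) {
    d <- sqrt(sum((c(f$p$x[i], f$p$y[i], f$p$z[i]) -
                     c(f$r$x[j], f$r$y[j], f$r$z[j]))^2))
    if (d >= cutoff || d == 0) next
    xi <- (d - f$p$lj_radius[i]) / f$p$lk_lambda[i]
    xj <- (d - f$r$lj_radius[j]) / f$r$lk_lambda[j]
    e <- e - (f$p$lk_dgfree[i] / (2 * pi^1.5 * f$p$lk_lambda[i] * d^2)) *
      exp(-xi^2) * f$r$lk_volume[j]
    e <- e - (f$r$lk_dgfree[j] / (2 * pi^1.5 * f$r$lk_lambda[j] * d^2)) *
      exp(-xj^2) * f$p$lk_volume[i]
  }
  e
}

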