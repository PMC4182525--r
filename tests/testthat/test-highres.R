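## Brute-force oracle definitions live in helper-oracles.R.

test_that("Lennard-Jones matches closed forms at the minimum and the cutoff", {
  ## two CH atoms at d = r_min = 4.0: pure attraction of depth -eps
  cx <- tiny_complex(list(
    atom_row("CB", "ALA", "A", 1, 0, 0, 0),
    atom_row("C1'", "U", "B", 1, 4.0, 0, 0)
  ))
  lj <- score_lj(cx)
  eps <- atom_type_params()["CH", "lj_welldepth"]
  expect_equal(unname(lj["atr"]), -eps, tolerance = 1e-12)
  expect_equal(unname(lj["rep"]), 0)

  ## beyond the 6 A cutoff: both components vanish
  cx2 <- tiny_complex(list(
    atom_row("CB", "ALA", "A", 1, 0, 0, 0),
    atom_row("C1'", "U", "B", 1, 6.5, 0, 0)
  ))
  expect_equal(unname(score_lj(cx2)), c(0, 0))
})

test_that("all pairwise terms equal their brute-force oracles to 1e-9", {
  cx <- make_complex(3, 2, 3, seed = 13)  # close interface, ~50 atoms
  expect_equal(score_lj(cx), oracle_lj(cx), tolerance = 1e-9)
  expect_equal(score_elec(cx), oracle_elec(cx), tolerance = 1e-9)
  expect_equal(score_solv(cx), oracle_solv(cx), tolerance = 1e-9)

  ## and on a clashing fixture that exercises the linearized wall
  cx2 <- make_complex(3, 2, 1.2, seed = 14)
  expect_equal(score_lj(cx2), oracle_lj(cx2), tolerance = 1e-9)
  expect_gt(unname(score_lj(cx2)["rep"]), 0)
})

test_that("Coulomb term reproduces the printed closed form", {
  ## +1e and -1e at 2 A with eps(d) = d: 332.0637 * (-1) / 4 = -83.0159
  params <- atom_type_params()
  params["CH", "charge"] <- 1
  params["Oacc", "charge"] <- -1
  cx <- tiny_complex(list(
    atom_row("CB", "ALA", "A", 1, 0, 0, 0),
    atom_row("O4'", "U", "B", 1, 2, 0, 0)
  ))
  expect_equal(score_elec(cx, params = params), 332.0637 * (-1) / 4,
               tolerance = 1e-9)
  ## neutral pair contributes nothing
  params["Oacc", "charge"] <- 0
  params["CH", "charge"] <- 0
  expect_equal(score_elec(cx, params = params), 0)
})

test_that("solvation matches a hand evaluation of the Gaussian-exclusion form", {
  params <- atom_type_params()
  cx <- tiny_complex(list(
    atom_row("CB", "ALA", "A", 1, 0, 0, 0),
    atom_row("O4'", "U", "B", 1, 2.0, 0, 0)
  ))
  ri <- params["CH", "lj_radius"]; rj <- params["Oacc", "lj_radius"]
  gi <- params["CH", "lk_dgfree"]; gj <- params["Oacc", "lk_dgfree"]
  vi <- params["CH", "lk_volume"]; vj <- params["Oacc", "lk_volume"]
  lam <- 3.5; d <- 2.0
  manual <- -(gi / (2 * pi^1.5 * lam * d^2)) * exp(-((d - ri) / lam)^2) * vj -
    (gj / (2 * pi^1.5 * lam * d^2)) * exp(-((d - rj) / lam)^2) * vi
  expect_equal(score_solv(cx, params = params), manual, tolerance = 1e-12)

  far <- tiny_complex(list(
    atom_row("CB", "ALA", "A", 1, 0, 0, 0),
    atom_row("O4'", "U", "B", 1, 8, 0, 0)
  ))
  expect_equal(score_solv(far), 0)
})

test_that("hydrogen bonds follow the 10-12 form, window and bins", {
  ## donor (backbone N) and acceptor (RNA O4') at the optimum distance,
  ## no hydrogen present: angular factor 1, E = -eps_hb
  cx <- tiny_complex(list(
    atom_row("N", "ALA", "A", 1, 0, 0, 0),
    atom_row("O4'", "U", "B", 1, 2.9, 0, 0)
  ))
  hb <- score_hbond(cx)
  ## backbone N to sugar O4' is a backbone-backbone, inter-partner (hence
  ## long-range) bond
  expect_equal(unname(hb["lr_bb"]), -2.0, tolerance = 1e-12)
  expect_equal(sum(hb != 0), 1)

  ## outside the [2.2, 3.6] window: nothing
  cx2 <- tiny_complex(list(
    atom_row("N", "ALA", "A", 1, 0, 0, 0),
    atom_row("O4'", "U", "B", 1, 4.0, 0, 0)
  ))
  expect_equal(unname(score_hbond(cx2)), c(0, 0, 0, 0))

  ## with an explicit donor hydrogen, the cos^2 deviation factor applies:
  ## linear geometry keeps the full energy, orthogonal geometry kills it
  cx3 <- tiny_complex(list(
    atom_row("N", "ALA", "A", 1, 0, 0, 0),
    atom_row("H", "ALA", "A", 1, 1.0, 0, 0),
    atom_row("O4'", "U", "B", 1, 2.9, 0, 0)
  ))
  hb3 <- score_hbond(cx3)
  expect_equal(sum(hb3), -2.0, tolerance = 1e-9)
  cx4 <- tiny_complex(list(
    atom_row("N", "ALA", "A", 1, 0, 0, 0),
    atom_row("H", "ALA", "A", 1, 0, 1.0, 0),
    atom_row("O4'", "U", "B", 1, 2.9, 0, 0)
  ))
  ## H at 90 deg: donor-H...acceptor strongly bent, factor ~ small
  expect_gt(sum(score_hbond(cx4)), -0.3)
})

test_that("hydrogen-bond bb/sc binning separates backbone-backbone bonds", {
  ## one bb-bb bond (backbone N to RNA O5') and one sc bond (ARG NH1 to
  ## base O2): energies land in their own long-range bins
  cx <- tiny_complex(list(
    atom_row("N", "ALA", "A", 1, 0, 0, 0),
    atom_row("NH1", "ARG", "A", 2, 0, 10, 0),
    atom_row("O5'", "U", "B", 1, 2.9, 0, 0),
    atom_row("O2", "U", "B", 1, 2.9, 10, 0)
  ))
  hb <- score_hbond(cx)
  expect_lt(hb["lr_bb"], 0)
  expect_lt(hb["lr_sc"], 0)
  expect_equal(unname(hb["sr_bb"]), 0)
  expect_equal(unname(hb["sr_sc"]), 0)
  ## oracle: manual 10-12 evaluation of the two bonds
  e <- 2.0 * (5 * (2.9 / 2.9)^12 - 6 * (2.9 / 2.9)^10)
  expect_equal(unname(hb["lr_bb"]), e, tolerance = 1e-9)
  expect_equal(unname(hb["lr_sc"]), e, tolerance = 1e-9)
})

test_that("atomic pair term enumerates contacting residue-nucleotide pairs", {
  tab <- matrix(0, 24, 24, dimnames = list(rnadock:::ALL_UNIT_TYPES,
                                           rnadock:::ALL_UNIT_TYPES))
  tab["ALA", "U"] <- -0.5; tab["U", "ALA"] <- -0.5
  cx <- tiny_complex(list(
    atom_row("CB", "ALA", "A", 1, 0, 0, 0),
    atom_row("C1'", "U", "B", 1, 4.0, 0, 0)
  ))
  expect_equal(score_pair_atomic(cx, pair_table = tab), -0.5)

  ## no contact below 5 A: zero
  cx2 <- tiny_complex(list(
    atom_row("CB", "ALA", "A", 1, 0, 0, 0),
    atom_row("C1'", "U", "B", 1, 5.5, 0, 0)
  ))
  expect_equal(score_pair_atomic(cx2, pair_table = tab), 0)

  ## multi-contact fixture vs enumeration oracle
  cx3 <- make_complex(4, 3, 3, seed = 21)
  ref <- estimate_pair_params(list(cx3), lowres_params())
  f <- heavy_frames(cx3)
  seen <- character(0); manual <- 0
  for (i in seq_len(nrow(f$p))) for (j in seq_len(nrow(f$r))) {
    d <- sqrt(sum((c(f$p$x[i], f$p$y[i], f$p$z[i]) -
                     c(f$r$x[j], f$r$y[j], f$r$z[j]))^2))
    if (d < 5) {
      key <- paste(f$p$unit[i], f$r$unit[j])
      if (!key %in% seen) {
        seen <- c(seen, key)
        a <- f$p$resname[i]
        b <- rnadock:::RNA_RESNAME_MAP[[f$r$resname[j]]]
        manual <- manual + ref$pair_logodds[a, b]
      }
    }
  }
  expect_gt(length(seen), 2)
  expect_equal(score_pair_atomic(cx3, pair_table = ref$pair_logodds), manual,
               tolerance = 1e-9)
})

test_that("the total is exactly linear in the weights and fa_dun is off", {
  cx <- make_complex(4, 3, 3, seed = 31)
  sb1 <- score_highres(cx)                        # all-ones weights
  expect_equal(sb1$total, sum(sb1$terms), tolerance = 1e-12)
  expect_equal(unname(sb1$terms["fa_dun"]), 0)

  w0 <- weight_vector(rep(0, 10))
  expect_equal(score_highres(cx, weights = w0)$total, 0)

  set.seed(77)
  w <- weight_vector(runif(10))
  sbw <- score_highres(cx, weights = w)
  expect_equal(sbw$total, sum(as.numeric(w) * sb1$terms), tolerance = 1e-12)
  expect_identical(sbw$terms, sb1$terms)

  expect_error(weight_vector(c(rep(0.5, 9), 1.4)), "box")
})

test_that("all-atom terms are rigid-motion invariant and vanish at separation", {
  cx <- make_complex(4, 3, 3, seed = 41)
  set.seed(6)
  cx2 <- transform_complex(cx, random_rotation(), c(7, -2, 3))
  s1 <- score_highres(cx)
  s2 <- score_highres(cx2)
  expect_equal(s1$terms, s2$terms, tolerance = 1e-9)
  expect_lte(unname(s1$terms["fa_atr"]), 0)
  expect_gte(unname(s1$terms["fa_rep"]), 0)

  far <- apply_pose(cx, pose(translation = c(500, 0, 0)))
  expect_equal(score_highres(far)$total, 0)
})

test_that("pose-based scoring equals scoring the transformed complex", {
  cx <- make_complex(4, 3, 4, seed = 51)
  p <- pose(rotation = c(10, -5, 3), translation = c(1, 0.5, -0.7))
  via_pose <- score_highres(cx, pose = p)
  via_complex <- score_highres(apply_pose(cx, p))
  expect_equal(via_pose$terms, via_complex$terms, tolerance = 1e-12)

  mat <- score_poses(cx, list(pose_identity(), p))
  expect_equal(unname(mat[1, ]), unname(score_highres(cx)$terms),
               tolerance = 1e-12)
  expect_equal(unname(mat[2, ]), unname(via_pose$terms), tolerance = 1e-12)
})
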