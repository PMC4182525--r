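## Two single-unit partners whose centroids sit a controlled distance apart.
two_unit_model <- function(gap) {
  cx <- tiny_complex(list(
    atom_row("CA", "ALA", "A", 1, 0, 0, 0),
    atom_row("CB", "ALA", "A", 1, 0, 0, 0),
    atom_row("P", "U", "B", 1, gap, 0, 0),
    atom_row("N1", "U", "B", 1, gap, 0, 0)
  ))
  reduce_complex(cx)
}

test_that("contact count follows the 6 A centroid rule", {
  expect_equal(score_contact(two_unit_model(5)), 2)
  expect_equal(score_contact(two_unit_model(7)), 0)
  expect_error(score_contact(two_unit_model(5), cutoff = -1))
})

test_that("contact count equals a brute-force double loop on a 3x3 fixture", {
  cx <- make_complex(3, 3, 4, seed = 3)
  m <- reduce_complex(cx)
  p <- m$units[m$units$partner == "protein", ]
  r <- m$units[m$units$partner == "rna", ]
  cnt <- 0
  for (i in seq_len(nrow(p))) {
    hit <- FALSE
    for (j in seq_len(nrow(r))) {
      d <- sqrt(sum((c(p$x[i], p$y[i], p$z[i]) - c(r$x[j], r$y[j], r$z[j]))^2))
      if (d < 6) hit <- TRUE
    }
    cnt <- cnt + hit
  }
  for (j in seq_len(nrow(r))) {
    hit <- FALSE
    for (i in seq_len(nrow(p))) {
      d <- sqrt(sum((c(p$x[i], p$y[i], p$z[i]) - c(r$x[j], r$y[j], r$z[j]))^2))
      if (d < 6) hit <- TRUE
    }
    cnt <- cnt + hit
  }
  expect_equal(score_contact(m), cnt)
})

test_that("bump penalty matches closed forms and a pairwise oracle", {
  ## partners separated beyond the clash distance: zero
  expect_equal(score_bump(two_unit_model(10)), 0)
  ## one coincident pair at clash_distance/2: (c/2)^2 per clashing pair
  m <- two_unit_model(1.5)
  ## all 4 coarse-atom cross pairs (2 coarse atoms per partner, collocated)
  expect_equal(score_bump(m, clash_distance = 3), 4 * (3 - 1.5)^2)

  cx <- make_complex(4, 3, 2, seed = 9)  # tight interface, some clashes
  m2 <- reduce_complex(cx)
  a <- rnadock:::model_coarse_xyz(m2, "protein")
  b <- rnadock:::model_coarse_xyz(m2, "rna")
  acc <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((a[i, ] - b[j, ])^2))
    if (d < 3) acc <- acc + (3 - d)^2
  }
  expect_gt(acc, 0)
  expect_equal(score_bump(m2, 3), acc, tolerance = 1e-9)
})

test_that("environment table equals hand counting with add-one pseudocounts", {
  cx <- read_pdb(fixture_pdb_small())
  params <- lowres_params()
  est <- estimate_env_params(list(cx), params)
  ## independent counting
  m <- reduce_complex(cx)
  cls <- rnadock:::unit_env_classes(m, params)
  types <- m$units$type
  for (tt in c("ALA", "SER", "G", "U", "ARG")) {
    for (ee in c("int_bur", "int_exp", "non_bur", "non_exp")) {
      cnt_te <- sum(types == tt & cls == ee)
      cnt_e <- sum(cls == ee)
      expect_equal(est$env_logprob[tt, ee], -log((cnt_te + 1) / (cnt_e + 24)),
                   tolerance = 1e-12)
    }
  }
  ## pseudocounts keep unseen types finite
  expect_true(all(is.finite(est$env_logprob)))
  expect_error(estimate_env_params(list()), "empty reference")
})

test_that("environment score sums table lookups over units", {
  cx <- read_pdb(fixture_pdb_small())
  params <- estimate_env_params(list(cx), lowres_params())
  m <- reduce_complex(cx)
  cls <- rnadock:::unit_env_classes(m, params)
  manual <- sum(vapply(seq_len(nrow(m$units)), function(i) {
    params$env_logprob[m$units$type[i], cls[i]]
  }, 0))
  expect_equal(score_env(m, params), manual, tolerance = 1e-12)

  ## a uniform table makes the score independent of geometry
  uni <- lowres_params(env_logprob = matrix(
    0.7, 24, 4, dimnames = list(rnadock:::ALL_UNIT_TYPES,
                                rnadock:::ENV_CLASSES)))
  expect_equal(score_env(m, uni), 0.7 * nrow(m$units))
  far <- reduce_complex(transform_complex(cx, diag(3), c(500, 0, 0)))
  expect_equal(score_env(far, uni), 0.7 * nrow(m$units))
})

test_that("pair score equals enumeration over contacting centroid pairs", {
  cx <- make_complex(5, 3, 3, seed = 2)   # tight interface: real contacts
  params <- estimate_pair_params(list(cx), lowres_params())
  m <- reduce_complex(cx)
  ## brute-force contact enumeration + lookup
  p <- m$units[m$units$partner == "protein", ]
  r <- m$units[m$units$partner == "rna", ]
  manual <- 0; npairs <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(nrow(r))) {
    d <- sqrt(sum((c(p$x[i], p$y[i], p$z[i]) - c(r$x[j], r$y[j], r$z[j]))^2))
    if (d < 6) {
      manual <- manual + params$pair_logodds[p$type[i], r$type[j]]
      npairs <- npairs + 1
    }
  }
  expect_gt(npairs, 0)
  expect_equal(score_pair(m, params), manual, tolerance = 1e-12)
})

test_that("a single contacting (ARG, G) pair scores one table entry", {
  cx <- tiny_complex(list(
    atom_row("CA", "ARG", "A", 1, 0, 0, 0),
    atom_row("CB", "ARG", "A", 1, 0, 0, 0),
    atom_row("P", "G", "B", 1, 4, 0, 0),
    atom_row("N9", "G", "B", 1, 4, 0, 0)
  ))
  m <- reduce_complex(cx)
  params <- lowres_params()
  params$pair_logodds["ARG", "G"] <- -1.25
  params$pair_logodds["G", "ARG"] <- -1.25
  expect_equal(score_pair(m, params), -1.25)
})

test_that("uniform contacts drive pair log-odds toward zero", {
  ## synthetic complexes whose contacts sample type pairs evenly: with
  ## counts growing, P(a,b|contact) approaches P(a)P(b) restricted to
  ## inter-partner pairs, and the log-odds of observed pairs shrink
  set.seed(1)
  ref <- lapply(1:6, function(i) make_complex(8, 6, 4, seed = 20 + i))
  params <- estimate_pair_params(ref, lowres_params())
  seen <- unique(do.call(rbind, lapply(ref, function(cx) {
    rnadock:::contact_type_pairs(reduce_complex(cx), 6)
  })))
  vals <- params$pair_logodds[cbind(seen$a, seen$b)]
  expect_true(all(is.finite(vals)))
  expect_lt(stats::median(abs(vals)), 5)
})

test_that("the weighted low-resolution total behaves as a linear combination", {
  cx <- read_pdb(fixture_pdb_small())
  ref <- list(cx)
  params <- estimate_pair_params(ref, estimate_env_params(ref))
  m <- reduce_complex(cx)

  ## all-zero weights give zero total
  p0 <- params; p0$weights <- c(contact = 0, bump = 0, env = 0, pair = 0)
  expect_equal(score_lowres(m, p0)$total, 0)

  ## unit weights: total is the hand-assembled sum with contact negated
  s <- score_lowres(m, params)
  expect_equal(s$total, -s$contact + s$bump + s$env + s$pair)
  expect_gte(s$bump, 0)
  expect_true(s$contact >= 0 && s$contact == round(s$contact))

  ## with only the contact weight active, each added contact lowers the total
  p_only <- params
  p_only$weights <- c(contact = 1, bump = 0, env = 0, pair = 0)
  expect_equal(score_lowres(m, p_only)$total, -score_contact(m))
})

test_that("low-resolution terms are invariant under global rigid motion", {
  cx <- shared_complex()
  ref <- list(cx)
  params <- estimate_pair_params(ref, estimate_env_params(ref))
  set.seed(5)
  R <- random_rotation()
  cx2 <- transform_complex(cx, R, c(-4, 9, 2))
  s1 <- score_lowres(reduce_complex(cx), params)
  s2 <- score_lowres(reduce_complex(cx2), params)
  expect_equal(s1$contact, s2$contact)
  expect_equal(s1$bump, s2$bump, tolerance = 1e-9)
  expect_equal(s1$env, s2$env, tolerance = 1e-9)
  expect_equal(s1$pair, s2$pair, tolerance = 1e-9)
})

test_that("parameter tables survive a text round-trip", {
  cx <- read_pdb(fixture_pdb_small())
  params <- estimate_pair_params(list(cx), estimate_env_params(list(cx)))
  f <- tempfile(fileext = ".tsv")
  write_lowres_params(params, f)
  back <- read_lowres_params(f)
  expect_equal(back$contact_cutoff, params$contact_cutoff)
  expect_equal(back$weights, params$weights)
  expect_equal(unname(back$env_logprob), unname(params$env_logprob),
               tolerance = 1e-12)
  expect_equal(unname(back$pair_logodds), unname(params$pair_logodds),
               tolerance = 1e-12)
})
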