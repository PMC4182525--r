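test_that("Irmsd is zero for the native and for globally moved copies", {
  cx <- shared_complex()
  expect_lt(irmsd(cx, pose_identity()), 1e-9)
  expect_lt(irmsd(cx, cx), 1e-9)
  set.seed(8)
  moved <- transform_complex(cx, random_rotation(), c(12, -4, 6))
  expect_lt(irmsd(cx, moved), 1e-9)
})

test_that("Irmsd equals an independent least-squares superposition oracle", {
  cx <- shared_complex()
  p <- pose(rotation = c(8, -3, 5), translation = c(2, 1, -1))
  got <- irmsd(cx, p)
  expect_gt(got, 0)

  ## oracle: bio3d's quaternion-free lsq fit on the same fit-atom sets
  interface <- native_interface(cx)
  nat <- rnadock:::interface_fit_atoms(cx, interface)
  nat_xyz <- cbind(nat$x, nat$y, nat$z)
  dec <- rnadock:::interface_fit_atoms(apply_pose(cx, p), interface)
  dec_xyz <- cbind(dec$x, dec$y, dec$z)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(as.vector(t(nat_xyz)), as.vector(t(dec_xyz))))
  oracle <- sqrt(mean((fitted - as.vector(t(nat_xyz)))^2) * 3)
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("Irmsd on a printed 4-point toy matches the hand-computed value", {
  ## square of side 2 with two corners displaced by (1,0,0); the optimal
  ## rigid fit (translation + slight rotation) leaves rmsd 0.3562224,
  ## strictly below the translation-only bound of 0.5
  fixed <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))
  moving <- fixed
  moving[1, 1] <- moving[1, 1] + 1
  moving[2, 1] <- moving[2, 1] + 1
  expect_equal(rnadock:::kabsch_rmsd(fixed, moving), 0.3562224,
               tolerance = 1e-6)
  expect_lt(rnadock:::kabsch_rmsd(fixed, moving), 0.5)
  ## oracle via an independent superposition implementation
  fitted <- suppressWarnings(
    bio3d::fit.xyz(as.vector(t(fixed)), as.vector(t(moving))))
  expect_equal(rnadock:::kabsch_rmsd(fixed, moving),
               sqrt(mean((fitted - as.vector(t(fixed)))^2) * 3),
               tolerance = 1e-6)
})

test_that("Irmsd rejects mismatched decoys and empty interfaces", {
  cx <- shared_complex()
  other <- make_complex(5, 3, 4, seed = 99, id = "other")
  expect_error(irmsd(cx, other), "does not match")
  apart <- apply_pose(cx, pose(translation = c(200, 0, 0)))
  expect_error(native_interface(apart), "empty native interface")
})

test_that("AUC matches the concordant-pair oracle, including ties", {
  ## perfectly separated energies
  score <- c(1, 2, 3, 10, 11, 12)
  label <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(roc_auc(score, label)$auc, 1.0)
  ## all ties
  expect_equal(roc_auc(rep(5, 6), label)$auc, 0.5)
  ## mixed fixture with ties vs O(n^2) count
  s <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  l <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(roc_auc(s, l)$auc, oracle_auc(s, l), tolerance = 1e-12)
  ## random fixtures up to 200 decoys
  set.seed(11)
  for (rep_i in 1:5) {
    n <- sample(20:200, 1)
    s <- sample(1:40, n, replace = TRUE)   # plenty of ties
    l <- runif(n) < 0.3
    if (!any(l) || all(l)) next
    expect_equal(roc_auc(s, l)$auc, oracle_auc(s, l), tolerance = 1e-9)
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  s <- rnorm(150); l <- runif(150) < 0.4
  got <- roc_auc(s, l)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = l, predictor = s,
                                        direction = ">", quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("AUC is invariant under monotone transforms and flips under negation", {
  set.seed(13)
  s <- rnorm(80); l <- runif(80) < 0.5
  a0 <- roc_auc(s, l)$auc
  expect_equal(roc_auc(3 * s + 7, l)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_auc(exp(s), l)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_auc(-s, l)$auc, 1 - a0, tolerance = 1e-12)
  ## ROC points bound the unit square and end at (1,1)
  pts <- roc_auc(s, l)$roc_points
  expect_true(all(pts$fpr >= 0 & pts$fpr <= 1 & pts$tpr >= 0 & pts$tpr <= 1))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
})

test_that("enrichment score hits its anchors and bounds", {
  ## identical score and rmsd orderings: perfect overlap, ES = 10
  x <- runif(1000)
  expect_equal(enrichment_score(x, x), 10)
  ## disjoint top sets: ES = 0
  s <- 1:100
  r <- c(51:100, 1:50)  # best-score ids have the worst rmsd ranks
  expect_equal(enrichment_score(s, r, fraction = 0.10), 0)
  ## invariance under monotone transforms of either ordering
  set.seed(14)
  s2 <- rnorm(500); r2 <- rnorm(500)
  expect_equal(enrichment_score(s2, r2),
               enrichment_score(rank(s2), exp(r2)), tolerance = 1e-12)
  ## bounds over random cases
  for (i in 1:10) {
    es <- enrichment_score(rnorm(200), rnorm(200))
    expect_gte(es, 0); expect_lte(es, 10)
  }
  expect_error(enrichment_score(1:5, 1:5, fraction = 0.1), "too few")
})

test_that("top-k counts match a manual sort and the expected-count formula", {
  set.seed(15)
  s <- rnorm(20)
  l <- runif(20) < 0.4
  tk <- topk_stats(s, l, ks = c(5, 10))
  manual <- sapply(c(5, 10), function(k) sum(l[order(s)][1:k]))
  expect_equal(tk$count, as.integer(manual))
  expect_equal(tk$expected, c(5, 10) * sum(l) / 20)
  ## stable tie-breaking by input order
  s2 <- rep(1, 10); l2 <- c(TRUE, rep(FALSE, 9))
  expect_equal(topk_stats(s2, l2, ks = 1)$count, 1L)
})

test_that("the evaluation report assembles the per-complex statistics", {
  set.seed(16)
  irmsds <- c(runif(40, 0, 4.9), runif(160, 6, 40))
  score <- irmsds + rnorm(200, 0, 2)   # informative but noisy energies
  rep_ <- evaluate_decoys(score, irmsds)
  expect_equal(rep_$n_near_native, sum(irmsds < 5))
  expect_equal(rep_$expected_top10, 10 * rep_$n_near_native / 200)
  expect_gt(rep_$auc, 0.8)
  expect_gt(rep_$es, 1)
})
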