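## ROC-AUC-maximizing (mu+lambda) evolution strategy over box-constrained
## weight vectors, scored through a logistic model. The logistic link is
## monotone, so the AUC of the logistic output equals the AUC of the linear
## score; fitness therefore works directly on the (negated) weighted sum of
## energy terms.

#' Genetic-algorithm configuration
#'
#' @param mu number of parents kept each generation (default 10).
#' @param lambda offspring per generation (default 80).
#' @param budget total fitness evaluations (default 100000).
#' @param mutation_sd Gaussian mutation standard deviation (default 0.05).
#' @param crossover_rate probability an offspring is produced by uniform
#'   crossover of two parents rather than cloning one (default 0.5).
#' @param box_min,box_max weight box, default `[0, 1]`.
#' @param seed integer seed.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(mu = 10, lambda = 80, budget = 100000,
                      mutation_sd = 0.05, crossover_rate = 0.5,
                      box_min = 0, box_max = 1, seed = 1) {
  stopifnot(mu >= 1, lambda >= mu, budget >= mu + lambda,
            mutation_sd > 0, box_max > box_min)
  structure(list(mu = mu, lambda = lambda, budget = budget,
                 mutation_sd = mutation_sd, crossover_rate = crossover_rate,
                 box_min = box_min, box_max = box_max, seed = seed),
            class = "ga_config")
}

#' ROC-AUC fitness of a weight vector on a feature matrix
#'
#' Rows are decoys, columns the high-resolution term values, labels 1 for
#' near-native and 0 for decoy. The per-row score is `s = -sum(w_k f_k)`
#' (lower energy means higher near-native propensity) and the fitness is
#' the tie-aware ROC-AUC of `s` against the labels.
#'
#' @param weights numeric weight vector (length = number of feature
#'   columns).
#' @param features numeric matrix, decoys x terms.
#' @param labels 0/1 or logical, 1 = near-native.
#' @return AUC in `[0, 1]`.
#' @export
fitness <- function(weights, features, labels) {
  labels <- as.logical(labels)
  s <- -as.vector(features %*% as.numeric(weights))
  auc_rank(s, labels)
}

#' Optimize scoring weights with a (mu+lambda) evolution strategy
#'
#' Initial parents are uniform in the box. Each generation draws `lambda`
#' offspring: two tournament-selected parents are combined by uniform
#' crossover (with probability `crossover_rate`; otherwise the first parent
#' is cloned) and perturbed by Gaussian mutation, clipped to the box.
#' Survivors are the best `mu` of parents plus offspring; the best-ever
#' individual is returned once the evaluation budget is spent. A logistic
#' intercept is fitted post hoc on the linear score; it does not change the
#' AUC but calibrates reported probabilities.
#'
#' @param features numeric matrix, decoys x terms.
#' @param labels 0/1 near-native labels.
#' @param config a [ga_config()].
#' @return list of class `fitted_scorer`: `weights` (named if `features`
#'   has column names), `intercept`, `fitness` (achieved AUC),
#'   `history` (best fitness per generation), `config`.
#' @export
evolve <- function(features, labels, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  features <- as.matrix(features)
  d <- ncol(features)
  lo <- config$box_min; hi <- config$box_max

  set.seed(config$seed)
  pos <- labels
  eval_pop <- function(W) {           # W: individuals x d
    S <- -features %*% t(W)           # rows: decoys, cols: individuals
    apply(S, 2, auc_rank, positive = pos)
  }

  P <- matrix(stats::runif(config$mu * d, lo, hi), config$mu, d)
  fit <- eval_pop(P)
  evals <- config$mu
  best_i <- which.max(fit)
  best_w <- P[best_i, ]; best_f <- fit[best_i]
  history <- numeric(0)

  while (evals + config$lambda <= config$budget) {
    ## binary tournaments on the current parents
    t1 <- matrix(sample.int(config$mu, 2 * config$lambda, replace = TRUE),
                 ncol = 2)
    t2 <- matrix(sample.int(config$mu, 2 * config$lambda, replace = TRUE),
                 ncol = 2)
    p1 <- ifelse(fit[t1[, 1]] >= fit[t1[, 2]], t1[, 1], t1[, 2])
    p2 <- ifelse(fit[t2[, 1]] >= fit[t2[, 2]], t2[, 1], t2[, 2])
    cross <- stats::runif(config$lambda) < config$crossover_rate
    pick <- matrix(stats::runif(config$lambda * d) < 0.5, config$lambda, d)
    O <- P[p1, , drop = FALSE]
    O[cross & pick] <- P[p2, , drop = FALSE][cross & pick]
    O <- O + matrix(stats::rnorm(config$lambda * d, 0, config$mutation_sd),
                    config$lambda, d)
    O[O < lo] <- lo; O[O > hi] <- hi

    ofit <- eval_pop(O)
    evals <- evals + config$lambda
    all_w <- rbind(P, O)
    all_f <- c(fit, ofit)
    keep <- order(all_f, decreasing = TRUE)[seq_len(config$mu)]
    P <- all_w[keep, , drop = FALSE]
    fit <- all_f[keep]
    if (fit[1] > best_f) {
      best_f <- fit[1]; best_w <- P[1, ]
    }
    history <- c(history, best_f)
  }

  names(best_w) <- colnames(features)
  s <- -as.vector(features %*% best_w)
  intercept <- tryCatch(
    unname(stats::coef(stats::glm(labels ~ 1, offset = s,
                                  family = stats::binomial()))[1]),
    error = function(e) 0, warning = function(w) 0
  )
  structure(list(weights = best_w, intercept = intercept, fitness = best_f,
                 history = history, config = config),
            class = "fitted_scorer")
}

#' @export
print.fitted_scorer <- function(x, ...) {
  cat(sprintf("fitted scorer: ROC-AUC %.4f over %d terms\n",
              x$fitness, length(x$weights)))
  for (k in seq_along(x$weights)) {
    cat(sprintf("  %-12s %.4f\n",
                names(x$weights)[k] %||% paste0("w", k), x$weights[k]))
  }
  invisible(x)
}

#' Logistic near-native probability under a fitted scorer
#' @param scorer a `fitted_scorer`.
#' @param features matrix of term values.
#' @return numeric vector of probabilities.
#' @export
predict_scorer <- function(scorer, features) {
  s <- -as.matrix(features) %*% scorer$weights + scorer$intercept
  stats::plogis(as.vector(s))
}

#' Leave-one-pdb-out cross-validated evaluation
#'
#' For every complex (group), a balanced learning matrix is assembled from
#' the other groups' near-native/decoy rows, the weights are optimized on
#' it, and ALL of the held-out group's decoys are evaluated with the
#' assessment labelling (near-native < 5 A vs non-native >= 5 A).
#'
#' @param index data.frame with one row per decoy: `group`, `irmsd`,
#'   `label` (`near_native`/`decoy`/`test`), plus one column per term in
#'   `terms`.
#' @param terms character vector of feature column names (default
#'   [HIGHRES_TERMS]).
#' @param config a [ga_config()].
#' @param per_class learning rows per class per training group, default 30.
#' @param nn_threshold assessment near-native threshold, default 5.
#' @return list of class `loo_result`: `reports` (named list of
#'   `evaluation_report`), `scorers` (named list of `fitted_scorer`),
#'   `table` (data.frame, one row per complex).
#' @export
leave_one_pdb_out <- function(index, terms = HIGHRES_TERMS,
                              config = ga_config(), per_class = 30,
                              nn_threshold = 5) {
  groups <- unique(index$group)
  if (length(groups) < 2) stop("need at least 2 groups for leave-one-pdb-out")
  stopifnot(all(terms %in% names(index)))
  reports <- list(); scorers <- list()
  for (g in groups) {
    train <- index[index$group != g & index$label %in%
                     c("near_native", "decoy"), , drop = FALSE]
    train <- balance_training_rows(train, per_class,
                                   seed = child_seed(config$seed, match(g, groups)))
    if (any(train$group == g)) stop("leakage: held-out group in training set")
    sc <- evolve(as.matrix(train[, terms]),
                 train$label == "near_native",
                 config)
    test <- index[index$group == g, , drop = FALSE]
    score <- as.vector(as.matrix(test[, terms]) %*% sc$weights)
    reports[[g]] <- evaluate_decoys(score, test$irmsd,
                                    nn_threshold = nn_threshold)
    scorers[[g]] <- sc
  }
  tab <- do.call(rbind, lapply(groups, function(g) {
    r <- reports[[g]]
    data.frame(group = g, es = r$es, top10 = r$top10_nn,
               top100 = r$top100_nn, expected_top10 = r$expected_top10,
               n_near_native = r$n_near_native, auc = r$auc)
  }))
  structure(list(reports = reports, scorers = scorers, table = tab),
            class = "loo_result")
}

## Uniformly sample per_class rows of each label per group.
balance_training_rows <- function(rows, per_class, seed) {
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(rows)),
                              list(rows$group, rows$label), drop = TRUE),
                        function(ix) {
    if (length(ix) < per_class) {
      stop("group has fewer than ", per_class, " rows in one class")
    }
    sample(ix, per_class)
  }))
  rows[sort(keep), , drop = FALSE]
}

#' Median and quartile ROC curves across complexes
#'
#' Interpolates each report's ROC curve on a common FPR grid and returns
#' the pointwise median and quartiles, the aggregate view used for
#' cross-validated ROC summaries.
#'
#' @param loo a `loo_result`.
#' @param grid FPR grid, default 101 points.
#' @return data.frame: `fpr`, `tpr_q1`, `tpr_median`, `tpr_q3`.
#' @export
aggregate_roc <- function(loo, grid = seq(0, 1, length.out = 101)) {
  tprs <- vapply(loo$reports, function(r) {
    stats::approx(r$roc_points$fpr, r$roc_points$tpr, xout = grid,
                  ties = max, rule = 2)$y
  }, numeric(length(grid)))
  data.frame(
    fpr = grid,
    tpr_q1 = apply(tprs, 1, stats::quantile, 0.25),
    tpr_median = apply(tprs, 1, stats::median),
    tpr_q3 = apply(tprs, 1, stats::quantile, 0.75)
  )
}
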