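## Coarse-grained (low-resolution) scoring: interface contact count, steric
## bump penalty, environment log-probability term and statistical pair term.
## The environment and pair tables are counting statistics estimated from a
## reference set of complexes; the weighted sum is not optimized further.

#' Low-resolution scoring parameters
#'
#' Bundles the distance parameters, statistical tables and term weights of
#' the coarse-grained score. The environment and pair tables default to
#' zeros (neutral) until estimated from a reference set with
#' [estimate_env_params()] / [estimate_pair_params()].
#'
#' @param contact_cutoff centroid-centroid interface cutoff in Angstrom
#'   (default 6).
#' @param clash_distance distance below which coarse atom pairs are
#'   penalised quadratically, Angstrom (default 3).
#' @param burial_radius,burial_threshold a centroid is "buried" when at
#'   least `burial_threshold` same-partner centroids lie within
#'   `burial_radius` Angstrom (defaults 10 and 8).
#' @param weights named numeric: `contact`, `bump`, `env`, `pair` term
#'   weights, all 1 by default.
#' @param env_logprob matrix type x environment class, or `NULL`.
#' @param pair_logodds symmetric matrix type x type, or `NULL`.
#' @return An object of class `lowres_params`.
#' @export
lowres_params <- function(contact_cutoff = 6, clash_distance = 3,
                          burial_radius = 10, burial_threshold = 8,
                          weights = c(contact = 1, bump = 1, env = 1, pair = 1),
                          env_logprob = NULL, pair_logodds = NULL) {
  stopifnot(contact_cutoff > 0, clash_distance > 0)
  if (is.null(env_logprob)) {
    env_logprob <- matrix(0, length(ALL_UNIT_TYPES), length(ENV_CLASSES),
                          dimnames = list(ALL_UNIT_TYPES, ENV_CLASSES))
  }
  if (is.null(pair_logodds)) {
    pair_logodds <- matrix(0, length(ALL_UNIT_TYPES), length(ALL_UNIT_TYPES),
                           dimnames = list(ALL_UNIT_TYPES, ALL_UNIT_TYPES))
  }
  stopifnot(all(ALL_UNIT_TYPES %in% rownames(env_logprob)),
            all(ALL_UNIT_TYPES %in% rownames(pair_logodds)),
            all(c("contact", "bump", "env", "pair") %in% names(weights)))
  structure(list(contact_cutoff = contact_cutoff,
                 clash_distance = clash_distance,
                 burial_radius = burial_radius,
                 burial_threshold = burial_threshold,
                 weights = weights,
                 env_logprob = env_logprob,
                 pair_logodds = pair_logodds),
            class = "lowres_params")
}

#' Interface contact count
#'
#' Number of residue/nucleotide units (over both partners) whose centroid
#' lies within `cutoff` of at least one centroid of the other partner.
#'
#' @param model a `centroid_model`.
#' @param cutoff Angstrom, default 6.
#' @return integer count.
#' @export
score_contact <- function(model, cutoff = 6) {
  stopifnot(cutoff > 0)
  p <- model_centroids(model, "protein")
  r <- model_centroids(model, "rna")
  if (nrow(p) == 0 || nrow(r) == 0) stop("both partners must be non-empty")
  d <- pair_dist(p, r)
  sum(apply(d, 1, min) < cutoff) + sum(apply(d, 2, min) < cutoff)
}

#' Steric bump penalty
#'
#' Quadratic penalty over inter-partner coarse-atom pairs (backbone heavy
#' atoms plus centroids): `sum (clash_distance - d)^2` over pairs closer
#' than `clash_distance`. Zero when the partners do not clash.
#'
#' @param model a `centroid_model`.
#' @param clash_distance Angstrom, default 3.
#' @return non-negative numeric.
#' @export
score_bump <- function(model, clash_distance = 3) {
  stopifnot(clash_distance > 0)
  d <- pair_dist(model_coarse_xyz(model, "protein"),
                 model_coarse_xyz(model, "rna"))
  sum((clash_distance - d[d < clash_distance])^2)
}

## Environment class of every unit: interface (centroid < contact_cutoff of
## other partner) x buried (>= burial_threshold same-partner centroids
## within burial_radius, the unit itself excluded).
unit_env_classes <- function(model, params) {
  u <- model$units
  p <- model_centroids(model, "protein")
  r <- model_centroids(model, "rna")
  d <- pair_dist(p, r)
  int_p <- apply(d, 1, min) < params$contact_cutoff
  int_r <- apply(d, 2, min) < params$contact_cutoff
  interface <- logical(nrow(u))
  interface[u$partner == "protein"] <- int_p
  interface[u$partner == "rna"] <- int_r
  buried <- logical(nrow(u))
  for (part in c("protein", "rna")) {
    cen <- model_centroids(model, part)
    dd <- pair_dist(cen, cen)
    nb <- rowSums(dd < params$burial_radius) - 1L
    buried[u$partner == part] <- nb >= params$burial_threshold
  }
  paste0(ifelse(interface, "int_", "non_"), ifelse(buried, "bur", "exp"))
}

#' Estimate the environment table from a reference set
#'
#' For each unit type `t` and environment class `e` (interface/non-interface
#' x buried/exposed), the table entry is the negative log conditional
#' frequency with add-one pseudocounts over the `T = 24` types:
#' `-log((count(t,e) + 1) / (count(e) + T))`.
#'
#' @param reference list of `rna_complex` objects.
#' @param params a `lowres_params` providing cutoffs.
#' @return `params` with the `env_logprob` table filled in.
#' @export
estimate_env_params <- function(reference, params = lowres_params()) {
  if (length(reference) == 0) stop("empty reference set")
  counts <- matrix(0, length(ALL_UNIT_TYPES), length(ENV_CLASSES),
                   dimnames = list(ALL_UNIT_TYPES, ENV_CLASSES))
  for (cx in reference) {
    model <- reduce_complex(cx)
    cls <- unit_env_classes(model, params)
    tab <- table(factor(model$units$type, levels = ALL_UNIT_TYPES),
                 factor(cls, levels = ENV_CLASSES))
    counts <- counts + tab
  }
  Tn <- length(ALL_UNIT_TYPES)
  params$env_logprob <- -log(sweep(counts + 1, 2, colSums(counts) + Tn, "/"))
  params
}

#' Environment score of a pose
#'
#' Sum over all units of the environment table entry for the unit's type and
#' its current environment class.
#'
#' @param model a `centroid_model`.
#' @param params a `lowres_params` with an estimated `env_logprob` table.
#' @return numeric.
#' @export
score_env <- function(model, params) {
  cls <- unit_env_classes(model, params)
  types <- model$units$type
  if (any(!types %in% rownames(params$env_logprob))) {
    stop("unit type missing from environment table")
  }
  sum(params$env_logprob[cbind(types, cls)])
}

## Inter-partner centroid contact pairs (type_a from protein, type_b from
## RNA) under the contact cutoff.
contact_type_pairs <- function(model, cutoff) {
  p <- model$units[model$units$partner == "protein", , drop = FALSE]
  r <- model$units[model$units$partner == "rna", , drop = FALSE]
  d <- pair_dist(cbind(p$x, p$y, p$z), cbind(r$x, r$y, r$z))
  hit <- which(d < cutoff, arr.ind = TRUE)
  data.frame(a = p$type[hit[, 1]], b = r$type[hit[, 2]],
             stringsAsFactors = FALSE)
}

#' Estimate the statistical pair table from a reference set
#'
#' Contacts are inter-partner centroid pairs closer than the contact
#' cutoff. The table entry for types `a`, `b` is the negative log odds
#' `-log((P(a,b | contact) + eps) / (P(a) P(b) + eps))`, where `P(a)` is the
#' marginal frequency of type `a` over all units of the reference set and
#' the joint is symmetrised. Favourable (over-represented) pairs therefore
#' get negative entries, lowering the score.
#'
#' @param reference list of `rna_complex` objects.
#' @param params a `lowres_params`.
#' @param eps pseudo-probability guard, default `1e-6`.
#' @return `params` with the `pair_logodds` table filled in.
#' @export
estimate_pair_params <- function(reference, params = lowres_params(),
                                 eps = 1e-6) {
  if (length(reference) == 0) stop("empty reference set")
  Tn <- length(ALL_UNIT_TYPES)
  joint <- matrix(0, Tn, Tn, dimnames = list(ALL_UNIT_TYPES, ALL_UNIT_TYPES))
  marg <- setNames(numeric(Tn), ALL_UNIT_TYPES)
  for (cx in reference) {
    model <- reduce_complex(cx)
    pr <- contact_type_pairs(model, params$contact_cutoff)
    if (nrow(pr) > 0) {
      tab <- table(factor(pr$a, levels = ALL_UNIT_TYPES),
                   factor(pr$b, levels = ALL_UNIT_TYPES))
      joint <- joint + tab + t(tab)
    }
    marg <- marg + table(factor(model$units$type, levels = ALL_UNIT_TYPES))
  }
  pj <- if (sum(joint) > 0) joint / sum(joint) else joint
  pm <- marg / sum(marg)
  params$pair_logodds <- -log((pj + eps) / (outer(pm, pm) + eps))
  params
}

#' Statistical pair score of a pose
#'
#' Sum of pair-table entries over all inter-partner centroid contact pairs.
#'
#' @param model a `centroid_model`.
#' @param params a `lowres_params` with an estimated `pair_logodds` table.
#' @return numeric.
#' @export
score_pair <- function(model, params) {
  pr <- contact_type_pairs(model, params$contact_cutoff)
  if (nrow(pr) == 0) return(0)
  if (any(!c(pr$a, pr$b) %in% rownames(params$pair_logodds))) {
    stop("unit type missing from pair table")
  }
  sum(params$pair_logodds[cbind(pr$a, pr$b)])
}

#' Full low-resolution score
#'
#' Weighted sum of the four coarse-grained terms. The contact count enters
#' negated so that forming more interface contacts lowers (improves) the
#' score; the other terms are penalties or log-statistics where lower is
#' already better.
#'
#' @param model a `centroid_model`.
#' @param params a `lowres_params`.
#' @return A list of class `lowres_score`: `contact`, `bump`, `env`,
#'   `pair`, `total`.
#' @export
score_lowres <- function(model, params = lowres_params()) {
  contact <- score_contact(model, params$contact_cutoff)
  bump <- score_bump(model, params$clash_distance)
  env <- score_env(model, params)
  pair <- score_pair(model, params)
  w <- params$weights
  total <- w[["contact"]] * (-contact) + w[["bump"]] * bump +
    w[["env"]] * env + w[["pair"]] * pair
  structure(list(contact = contact, bump = bump, env = env, pair = pair,
                 total = total), class = "lowres_score")
}

#' @export
print.lowres_score <- function(x, ...) {
  cat(sprintf(
    "low-res score: contact %d, bump %.3f, env %.3f, pair %.3f, total %.3f\n",
    x$contact, x$bump, x$env, x$pair, x$total))
  invisible(x)
}

#' Write/read low-resolution parameter tables as delimited text
#'
#' The file holds a header with the distance parameters and weights,
#' followed by the environment and pair tables in tab-separated blocks.
#'
#' @param params a `lowres_params`.
#' @param path file path.
#' @return `write_lowres_params` returns `path` invisibly;
#'   `read_lowres_params` returns a `lowres_params`.
#' @export
write_lowres_params <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# contact_cutoff\t%g", params$contact_cutoff), con)
  writeLines(sprintf("# clash_distance\t%g", params$clash_distance), con)
  writeLines(sprintf("# burial_radius\t%g", params$burial_radius), con)
  writeLines(sprintf("# burial_threshold\t%g", params$burial_threshold), con)
  writeLines(sprintf("# weights\t%s",
                     paste(sprintf("%s=%g", names(params$weights),
                                   params$weights), collapse = ",")), con)
  writeLines("[env]", con)
  utils::write.table(params$env_logprob, con, sep = "\t", quote = FALSE)
  writeLines("[pair]", con)
  utils::write.table(params$pair_logodds, con, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_lowres_params
#' @export
read_lowres_params <- function(path) {
  lines <- readLines(path)
  getval <- function(key) {
    ln <- grep(paste0("^# ", key, "\t"), lines, value = TRUE)
    sub(".*\t", "", ln[1])
  }
  wtxt <- strsplit(strsplit(getval("weights"), ",")[[1]], "=")
  weights <- setNames(vapply(wtxt, function(z) as.numeric(z[2]), 0),
                      vapply(wtxt, `[`, "", 1))
  i_env <- which(lines == "[env]")
  i_pair <- which(lines == "[pair]")
  read_block <- function(from, to) {
    as.matrix(utils::read.table(text = paste(lines[from:to], collapse = "\n"),
                                sep = "\t", header = TRUE, check.names = FALSE))
  }
  lowres_params(
    contact_cutoff = as.numeric(getval("contact_cutoff")),
    clash_distance = as.numeric(getval("clash_distance")),
    burial_radius = as.numeric(getval("burial_radius")),
    burial_threshold = as.numeric(getval("burial_threshold")),
    weights = weights,
    env_logprob = read_block(i_env + 1, i_pair - 1),
    pair_logodds = read_block(i_pair + 1, length(lines))
  )
}
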