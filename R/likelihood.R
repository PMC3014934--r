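# Likelihood-engine interface: per-site log-likelihoods, branch-length
# optimisation, posterior-mean site rates, ML over an explicit topology set
# and the nonparametric bootstrap.
#
# There is deliberately no heuristic tree search here: the scientific
# questions this package addresses concern a handful of focal lineages, so
# maximum likelihood is taken exactly over an enumerated (or
# backbone-constrained) topology set, which removes search stochasticity.

# ---- internal encoding ----------------------------------------------------

# site-pattern compression of an alignment: residue codes (0..19, -1 for
# '-', 'X', '?'), unique patterns and their weights
make_encoding <- function(aln) {
  codes <- matrix(match(unclass(aln), aa_alphabet()) - 1L, nrow = nrow(aln))
  codes[is.na(codes)] <- -1L
  key <- apply(codes, 2, paste, collapse = ",")
  pat_index <- match(key, unique(key))
  keep <- !duplicated(key)
  list(codes = codes[, keep, drop = FALSE],
       pat_index = pat_index,
       patw = as.numeric(tabulate(pat_index, nbins = sum(keep))),
       taxa = rownames(aln),
       n_sites = ncol(aln))
}

encode_for_tree <- function(enc, tree) {
  idx <- match(tree$tip.label, enc$taxa)
  if (anyNA(idx)) {
    stop("tip without sequence: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  }
  enc$codes[idx, , drop = FALSE]
}

# flatten components x gamma categories into per-class eigen systems
model_classes <- function(model) {
  out <- list()
  for (cm in model$components) {
    for (k in seq_len(model$k)) {
      out[[length(out) + 1L]] <- list(
        V = cm$V, Vinv = cm$Vinv, lambda = cm$eigenvalues, pi = cm$freqs,
        weight = cm$weight * model$cat_weights[k],
        rate = model$cat_rates[k])
    }
  }
  out
}

class_cat_rates <- function(model) {
  rep(model$cat_rates, times = length(model$components))
}

tree_encoding <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  list(tree = tr,
       edges = tr$edge,
       lengths = tr$edge.length,
       n_tips = length(tr$tip.label),
       n_nodes = length(tr$tip.label) + tr$Nnode,
       root = length(tr$tip.label) + 1L)
}

# ---- per-site log-likelihood ----------------------------------------------

#' Per-site log-likelihoods by Felsenstein pruning
#'
#' Sums over discrete-gamma categories (and mixture components) with their
#' weights. Ambiguity characters (`-`, `X`, `?`) contribute all-ones
#' partials; a fully missing column therefore has likelihood 1 (log 0),
#' which keeps concatenated-matrix likelihoods well defined under heavy
#' missingness.
#'
#' @param aln An [aa_alignment()] containing every tree tip.
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param model An [build_model()] object.
#' @return Object of class `site_loglik`: list with `per_site` (natural-log
#'   vector, one entry per column) and `total`.
#' @export
site_loglik <- function(aln, tree, model) {
  validate_tree(tree, require_lengths = TRUE)
  enc <- make_encoding(aln)
  te <- tree_encoding(tree)
  res <- cpp_site_loglik(encode_for_tree(enc, te$tree), model_classes(model),
                         te$edges, te$lengths,
                         te$n_tips, te$n_nodes, te$root)
  per_site <- res$site_loglik[enc$pat_index]
  structure(list(per_site = per_site, total = sum(per_site)),
            class = "site_loglik")
}

#' @export
print.site_loglik <- function(x, ...) {
  cat(sprintf("Site log-likelihoods: %d sites, total lnL = %.4f\n",
              length(x$per_site), x$total))
  invisible(x)
}

# ---- branch-length optimisation -------------------------------------------

#' Optimise branch lengths on a fixed topology
#'
#' Coordinate-wise Brent optimisation over edges (with outside/inside
#' partial caching), iterated until the total log-likelihood improves by
#' less than `tol` or `max_rounds` sweeps are reached. The total lnL is
#' non-decreasing across sweeps. Lengths are clamped to
#' `[min_bl, max_bl] = [1e-8, 20]`.
#'
#' @param aln An [aa_alignment()].
#' @param tree An `ape::phylo` topology; edges without lengths start at 0.1.
#' @param model An [build_model()] object.
#' @param tol Convergence tolerance on total lnL (default 1e-6).
#' @param max_rounds Maximum sweeps (default 30).
#' @param min_bl,max_bl Branch-length clamps.
#' @return List with `tree` (lengths filled in), `loglik` (a `site_loglik`),
#'   and `rounds`.
#' @export
optimize_branch_lengths <- function(aln, tree, model, tol = 1e-6,
                                    max_rounds = 30L,
                                    min_bl = 1e-8, max_bl = 20) {
  enc <- make_encoding(aln)
  fit <- optimize_bl_enc(enc, tree, model, tol, max_rounds, min_bl, max_bl)
  per_site <- fit$site_loglik[enc$pat_index]
  if (any(!is.finite(per_site))) {
    stop("numerical error: non-finite likelihood at site ",
         which(!is.finite(per_site))[1])
  }
  list(tree = fit$tree,
       loglik = structure(list(per_site = per_site, total = sum(per_site)),
                          class = "site_loglik"),
       rounds = fit$rounds)
}

# encoding-level optimiser shared by the bootstrap fast path
optimize_bl_enc <- function(enc, tree, model, tol = 1e-6, max_rounds = 30L,
                            min_bl = 1e-8, max_bl = 20, patw = NULL) {
  te <- tree_encoding(tree)
  if (is.null(te$lengths)) te$lengths <- rep(0.1, nrow(te$edges))
  te$lengths[is.na(te$lengths)] <- 0.1
  te$lengths <- pmin(pmax(te$lengths, min_bl), max_bl)
  if (is.null(patw)) patw <- enc$patw
  res <- cpp_optimize_bl(encode_for_tree(enc, te$tree), model_classes(model),
                         te$edges, te$lengths,
                         te$n_tips, te$n_nodes, te$root,
                         patw, tol, max_rounds, min_bl, max_bl)
  tr <- te$tree
  tr$edge.length <- res$lengths
  list(tree = tr, loglik = res$loglik, site_loglik = res$site_loglik,
       class_site_loglik = res$class_site_loglik, rounds = res$rounds)
}

# ---- posterior-mean site rates --------------------------------------------

#' Posterior-mean relative site rates
#'
#' For each column, the discrete-gamma category rates averaged with weights
#' proportional to `w_k L_ik` (mixture components marginalised): the
#' standard empirical-Bayes site-rate estimate used to rank sites for
#' fast-site removal.
#'
#' @param aln An [aa_alignment()].
#' @param tree Tree with branch lengths (optimise first).
#' @param model An [build_model()] object; with a single rate category the
#'   ranking is undefined and all rates are returned as 1 with a warning.
#' @return Object of class `site_rates`: numeric vector of per-column rates.
#' @export
estimate_site_rates <- function(aln, tree, model) {
  validate_tree(tree, require_lengths = TRUE)
  if (model$k == 1L) {
    warning("single rate category: site-rate ranking undefined, returning 1s")
    return(structure(rep(1, ncol(aln)), class = "site_rates"))
  }
  enc <- make_encoding(aln)
  te <- tree_encoding(tree)
  res <- cpp_site_loglik(encode_for_tree(enc, te$tree), model_classes(model),
                         te$edges, te$lengths,
                         te$n_tips, te$n_nodes, te$root)
  rates_pat <- posterior_mean_rates(res$class_site_loglik, model)
  structure(rates_pat[enc$pat_index], class = "site_rates")
}

posterior_mean_rates <- function(class_site_loglik, model) {
  cls <- model_classes(model)
  w <- vapply(cls, `[[`, 0, "weight")
  r <- vapply(cls, `[[`, 0, "rate")
  M <- apply(class_site_loglik, 1, max)
  lik <- exp(sweep(class_site_loglik, 1, M, "-"))
  num <- as.numeric(lik %*% (w * r))
  den <- as.numeric(lik %*% w)
  num / den
}

#' @export
print.site_rates <- function(x, ...) {
  cat(sprintf("Posterior-mean site rates: %d sites, mean %.3f, range [%.3f, %.3f]\n",
              length(x), mean(x), min(x), max(x)))
  invisible(x)
}

# ---- ML over a topology set ------------------------------------------------

#' Maximum likelihood over an explicit topology set
#'
#' Each topology gets independently optimised branch lengths; the result is
#' sorted by total log-likelihood, descending, with ties broken by input
#' order.
#'
#' @param aln An [aa_alignment()].
#' @param topologies A `topology_set` or list of trees.
#' @param model An [build_model()] object.
#' @param ... Passed to [optimize_branch_lengths()] (`tol`, `max_rounds`...).
#' @return Object of class `ml_ranking`: list with `trees` (optimised, in
#'   rank order), `loglik` (vector), `order` (input indices in rank order).
#' @export
ml_over_topology_set <- function(aln, topologies, model, ...) {
  trees <- if (inherits(topologies, "topology_set")) topologies$trees else topologies
  if (length(trees) == 0L) stop("empty topology set")
  enc <- make_encoding(aln)
  fits <- lapply(trees, function(tr) optimize_bl_enc(enc, tr, model, ...))
  lnl <- vapply(fits, `[[`, 0, "loglik")
  ord <- order(-lnl)                      # stable: ties keep input order
  structure(list(trees = lapply(fits[ord], `[[`, "tree"),
                 loglik = lnl[ord], order = ord),
            class = "ml_ranking")
}

#' @export
print.ml_ranking <- function(x, ...) {
  cat("ML ranking over", length(x$trees), "topologies\n")
  for (i in seq_len(min(5, length(x$trees)))) {
    cat(sprintf("  %2d. lnL %.4f  %s\n", i, x$loglik[i],
                write_newick(x$trees[[i]])))
  }
  invisible(x)
}

# ---- nonparametric bootstrap -----------------------------------------------

# deterministic substream seed for replicate i of a master seed
derive_seed <- function(master, i) {
  x <- (as.numeric(master) %% 2147483647) * 48271 %% 2147483647
  as.integer((x + as.numeric(i) * 104729) %% 2147483647)
}

#' Nonparametric bootstrap over a topology set
#'
#' Each replicate resamples alignment columns with replacement to the
#' original length, reruns the topology-set ML, and records the best tree.
#' Bipartition support aggregates the splits of the replicate winners.
#' Replicate `b` uses the deterministic substream `(seed, b)`, so results
#' are reproducible for a fixed seed.
#'
#' @param aln An [aa_alignment()].
#' @param topologies A `topology_set` or list of trees.
#' @param model An [build_model()] object.
#' @param B Number of replicates (>= 1).
#' @param seed Master integer seed.
#' @param optim_rounds Branch-length sweeps per replicate fit (the fits are
#'   warm-started from the full-data optima, so few sweeps are needed).
#' @param optim_tol lnL convergence tolerance for replicate fits; looser
#'   than the full-data default because bootstrap support only needs the
#'   per-replicate ranking of topologies, not exact branch lengths.
#' @return Object of class `bootstrap_result`: `B`, `trees` (winner per
#'   replicate), `seed`, `bipartition_support` (named fractions), `splits`.
#' @export
bootstrap <- function(aln, topologies, model, B = 100L, seed = 1L,
                      optim_rounds = 2L, optim_tol = 0.05) {
  if (B < 1) stop("need at least one bootstrap replicate")
  trees <- if (inherits(topologies, "topology_set")) topologies$trees else topologies
  if (length(trees) == 0L) stop("empty topology set")
  enc <- make_encoding(aln)
  # full-data optima as warm starts
  base_fits <- lapply(trees, function(tr) {
    optimize_bl_enc(enc, tr, model, tol = optim_tol / 10)
  })
  winners <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, b))
    idx <- sample.int(enc$n_sites, enc$n_sites, replace = TRUE)
    patw_b <- as.numeric(tabulate(enc$pat_index[idx],
                                  nbins = length(enc$patw)))
    lnl <- numeric(length(trees))
    fit_trees <- vector("list", length(trees))
    for (i in seq_along(trees)) {
      f <- optimize_bl_enc(enc, base_fits[[i]]$tree, model,
                           tol = optim_tol, max_rounds = optim_rounds,
                           patw = patw_b)
      lnl[i] <- f$loglik
      fit_trees[[i]] <- f$tree
    }
    winners[[b]] <- fit_trees[[which.max(lnl)]]
  }
  support <- split_support_from_trees(winners)
  structure(list(B = B, trees = winners, seed = seed,
                 bipartition_support = support$fraction,
                 splits = support$splits),
            class = "bootstrap_result")
}

split_support_from_trees <- function(trees) {
  all_keys <- character(0)
  all_splits <- list()
  per_tree <- lapply(trees, function(tr) {
    bps <- bipartitions(tr)
    keys <- vapply(bps, split_key, "")
    for (i in seq_along(bps)) {
      if (!(keys[i] %in% all_keys)) {
        all_keys <<- c(all_keys, keys[i])
        all_splits[[length(all_splits) + 1L]] <<- bps[[i]]
      }
    }
    keys
  })
  frac <- vapply(all_keys, function(k) {
    mean(vapply(per_tree, function(keys) k %in% keys, NA))
  }, 0)
  names(frac) <- all_keys
  list(fraction = frac, splits = all_splits)
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Bootstrap:", x$B, "replicates (seed", x$seed, ")\n")
  sup <- sort(x$bipartition_support, decreasing = TRUE)
  for (k in utils::head(names(sup), 8)) {
    cat(sprintf("  %.2f  %s\n", sup[[k]], k))
  }
  invisible(x)
}
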