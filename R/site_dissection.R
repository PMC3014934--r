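# Progressive removal of fast-evolving sites with bootstrap monitoring of
# bipartition support: topology-averaged site rates, the removal schedule,
# rate-mass-based reduction and the resulting support curves.
#
# Fast sites are the ones most likely to be saturated; removing them in
# increasing slices and watching how support for competing splits responds
# separates genuine signal from long-branch artifacts.

#' Topology-averaged posterior-mean site rates
#'
#' Because the topology used to estimate site rates influences the ranking,
#' rates are estimated on every topology of the set (branch lengths
#' optimised per topology) and averaged per site.
#'
#' @param aln An [aa_alignment()].
#' @param topologies A `topology_set` or list of trees.
#' @param model An [build_model()] object (needs `k >= 2`).
#' @param ... Passed to [optimize_branch_lengths()].
#' @return A `site_rates` vector.
#' @export
mean_rates_over_set <- function(aln, topologies, model, ...) {
  trees <- if (inherits(topologies, "topology_set")) topologies$trees else topologies
  if (length(trees) == 0L) stop("empty topology set")
  per_tree <- lapply(trees, function(tr) {
    fit <- optimize_branch_lengths(aln, tr, model, ...)
    as.numeric(estimate_site_rates(aln, fit$tree, model))
  })
  structure(rowMeans(do.call(cbind, per_tree)), class = "site_rates")
}

#' Validate a removal schedule
#'
#' @param percentages Strictly increasing percentages in (0, 100).
#' @return An object of class `removal_schedule`.
#' @export
removal_schedule <- function(percentages) {
  p <- as.numeric(percentages)
  if (any(p <= 0) || any(p >= 100)) stop("schedule percentages must lie in (0, 100)")
  if (any(diff(p) <= 0)) stop("schedule percentages must be strictly increasing")
  structure(p, class = "removal_schedule")
}

#' The default 14-step removal schedule
#'
#' 5\% to 90\%: 10-point intervals between 10 and 50, 5-point intervals
#' between 55 and 90.
#'
#' @return A [removal_schedule()] of length 14.
#' @export
default_schedule <- function() {
  removal_schedule(c(5, seq(10, 50, by = 10), seq(55, 90, by = 5)))
}

#' Remove the fastest-evolving sites
#'
#' In `rate_mass` mode (the default), columns are sorted by rate descending
#' (ties by ascending column index) and the minimal prefix whose cumulative
#' rate reaches `pct`\% of the total rate is removed: the removal percentage
#' refers to the total rate distribution, not the site count, so removing
#' 90\% of the rate mass leaves far more than 10\% of the sites when the
#' rate distribution is long-tailed. `site_fraction` mode removes the
#' fastest `ceiling(pct\% * N)` columns instead.
#'
#' @param aln An [aa_alignment()].
#' @param rates Per-column `site_rates` (same length as the alignment).
#' @param pct Percentage in `[0, 100]`.
#' @param mode `"rate_mass"` or `"site_fraction"`.
#' @return List with `alignment` (kept columns) and `removed_columns`
#'   (original indices of the removed columns).
#' @export
reduce_alignment <- function(aln, rates, pct,
                             mode = c("rate_mass", "site_fraction")) {
  mode <- match.arg(mode)
  rates <- as.numeric(rates)
  if (length(rates) != ncol(aln)) stop("rates length must equal alignment columns")
  if (pct < 0 || pct > 100) stop("pct must be in [0, 100]")
  if (pct == 0) {
    return(list(alignment = aln, removed_columns = integer(0)))
  }
  ord <- order(-rates, seq_along(rates))   # fastest first, ties by index
  n_remove <- if (mode == "rate_mass") {
    target <- pct / 100 * sum(rates)
    which(cumsum(rates[ord]) >= target - 1e-12)[1]
  } else {
    ceiling(pct / 100 * length(rates))
  }
  removed <- sort(ord[seq_len(n_remove)])
  if (length(removed) >= ncol(aln)) stop("removal would empty the alignment")
  list(alignment = aln[, -removed, drop = FALSE], removed_columns = removed)
}

#' Bootstrap support curves along a removal schedule
#'
#' For each schedule step the alignment is reduced with
#' [reduce_alignment()], a bootstrap over the topology set is run (the
#' step's seed is derived deterministically from the master seed and the
#' step index), and the support of each monitored bipartition among the
#' replicate winners is recorded. A `pct = 0` baseline row (full data) is
#' included by default. Posterior-probability columns are emitted as `NA`
#' placeholders to keep the table shape of companion Bayesian analyses.
#'
#' @param aln An [aa_alignment()].
#' @param rates Per-column `site_rates`.
#' @param schedule A [removal_schedule()].
#' @param monitored Named list of [bipartition()]s to track.
#' @param topologies A `topology_set` or list of trees.
#' @param model An [build_model()] object.
#' @param B Bootstrap replicates per step.
#' @param seed Master seed.
#' @param mode Removal mode, see [reduce_alignment()].
#' @param min_columns Steps leaving fewer columns are skipped with a
#'   warning (default 50).
#' @param include_full Include the `pct = 0` full-data baseline.
#' @param ... Passed to [bootstrap()].
#' @return Object of class `support_curve`: a data frame with one row per
#'   step (`pct`, `columns_removed`, `columns_remaining`, one `bp_*` column
#'   per monitored split, one `pp_*` placeholder per split).
#' @export
support_curves <- function(aln, rates, schedule = default_schedule(),
                           monitored, topologies, model,
                           B = 100L, seed = 1L,
                           mode = "rate_mass", min_columns = 50L,
                           include_full = TRUE, ...) {
  if (is.null(names(monitored)) || any(!nzchar(names(monitored)))) {
    names(monitored) <- paste0("split", seq_along(monitored))
  }
  pcts <- c(if (include_full) 0, as.numeric(schedule))
  rows <- list()
  for (i in seq_along(pcts)) {
    pct <- pcts[i]
    red <- tryCatch(reduce_alignment(aln, rates, pct, mode = mode),
                    error = function(e) NULL)
    if (is.null(red)) {
      warning(sprintf("step %g%% would empty the alignment: skipped", pct))
      next
    }
    if (ncol(red$alignment) < min_columns) {
      warning(sprintf("step %g%% leaves %d columns (< %d): skipped",
                      pct, ncol(red$alignment), min_columns))
      next
    }
    bs <- bootstrap(red$alignment, topologies, model, B = B,
                    seed = derive_seed(seed, i), ...)
    bp <- vapply(monitored, function(q) support_of(q, bs$trees), 0)
    rows[[length(rows) + 1L]] <- data.frame(
      pct = pct,
      columns_removed = length(red$removed_columns),
      columns_remaining = ncol(red$alignment),
      t(stats::setNames(bp, paste0("bp_", names(monitored)))),
      t(stats::setNames(rep(NA_real_, length(monitored)),
                        paste0("pp_", names(monitored)))),
      check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("support_curve", "data.frame"),
            monitored = monitored, B = B, seed = seed)
}

#' @export
print.support_curve <- function(x, ...) {
  cat("Support curve over", nrow(x), "steps (B =", attr(x, "B"), ")\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}
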