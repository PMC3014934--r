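# Topology and model-adequacy tests: the approximately unbiased (AU) test
# via multiscale resampling of estimated site log-likelihoods (RELL), and
# cross-validation comparison of two model/topology candidates.

#' Approximately unbiased (AU) topology test
#'
#' Multiscale RELL bootstrap: at each scale `r`, `ceiling(r * n)` site
#' columns of the log-likelihood matrix are resampled with replacement
#' `b_per_scale` times and the proportion of replicates in which each
#' candidate has the highest total is recorded. For every candidate the
#' normal-quantile-transformed proportions `qnorm(1 - BP(r))` are fitted by
#' weighted least squares to `d * sqrt(r) + c / sqrt(r)`, giving a signed
#' distance `d` and curvature `c`; the p-value is `1 - pnorm(d - c)`. Only
#' differences of site log-likelihoods matter: adding a site-wise constant
#' to all candidates leaves the result unchanged.
#'
#' @param site_lnl Numeric matrix, rows = candidates (row names used as
#'   labels), columns = sites: per-site log-likelihoods.
#' @param scales Bootstrap scale factors (default `seq(0.5, 1.4, by 0.1)`).
#' @param b_per_scale Replicates per scale (default 1000).
#' @param seed Integer seed (deterministic result).
#' @return Object of class `au_result`: data frame with `p_au`, `d`, `c`
#'   and a `flag` per candidate, plus the per-scale winning proportions in
#'   `attr(, "bp")`.
#' @export
au_test <- function(site_lnl, scales = seq(0.5, 1.4, by = 0.1),
                    b_per_scale = 1000L, seed = 1L) {
  site_lnl <- as.matrix(site_lnl)
  n_cand <- nrow(site_lnl)
  n <- ncol(site_lnl)
  if (n_cand < 2L) stop("AU test needs at least 2 candidates")
  if (is.null(rownames(site_lnl))) {
    rownames(site_lnl) <- paste0("cand", seq_len(n_cand))
  }
  bp <- matrix(0, n_cand, length(scales),
               dimnames = list(rownames(site_lnl), paste0("r", scales)))
  set.seed(seed)
  for (si in seq_along(scales)) {
    m <- ceiling(scales[si] * n)
    # resampling with replacement == multinomial column counts
    counts <- stats::rmultinom(b_per_scale, m, rep(1 / n, n))
    totals <- site_lnl %*% counts               # candidates x replicates
    winner <- apply(totals, 2, which.max)       # ties -> first (stable)
    tab <- tabulate(winner, nbins = n_cand)
    bp[, si] <- tab / b_per_scale
  }

  res <- data.frame(candidate = rownames(site_lnl),
                    p_au = NA_real_, d = NA_real_, c = NA_real_,
                    flag = "", stringsAsFactors = FALSE)
  for (i in seq_len(n_cand)) {
    p <- bp[i, ]
    usable <- p > 0 & p < 1
    if (sum(p) == 0) {
      res$p_au[i] <- 0; res$flag[i] <- sprintf("never best (p < %g)", 1 / b_per_scale)
      next
    }
    if (all(p == 1)) {
      res$p_au[i] <- 1; res$flag[i] <- "always best"
      next
    }
    if (sum(usable) < 2L) {
      res$p_au[i] <- if (mean(p) > 0.5) 1 else 0
      res$flag[i] <- "degenerate fit (too few informative scales)"
      next
    }
    r <- scales[usable]
    z <- qnorm(1 - p[usable])
    w <- b_per_scale * dnorm(z)^2 / (p[usable] * (1 - p[usable]))
    X <- cbind(sqrt(r), 1 / sqrt(r))
    fit <- stats::lm.wfit(X, z, w)
    res$d[i] <- fit$coefficients[1]
    res$c[i] <- fit$coefficients[2]
    res$p_au[i] <- 1 - pnorm(res$d[i] - res$c[i])
  }
  structure(res, class = c("au_result", "data.frame"),
            bp = bp, scales = scales, b_per_scale = b_per_scale, seed = seed)
}

#' @export
print.au_result <- function(x, ...) {
  cat("AU test (", attr(x, "b_per_scale"), "replicates x",
      length(attr(x, "scales")), "scales)\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Learning/test split sizes for cross-validation
#'
#' The learning set takes `learn_frac` of the columns with half-up
#' rounding; the test set is the complement. A 90/10 split of 36,735
#' columns, for example, gives 33,062 learning and 3,673 test positions.
#'
#' @param n Total number of alignment columns.
#' @param learn_frac Learning fraction in (0, 1).
#' @return Named integer vector `c(learn = , test = )`.
#' @export
cv_split_sizes <- function(n, learn_frac = 0.9) {
  if (learn_frac <= 0 || learn_frac >= 1) stop("learn_frac must be in (0, 1)")
  n_learn <- as.integer(floor(learn_frac * n + 0.5))   # half-up rounding
  c(learn = n_learn, test = as.integer(n) - n_learn)
}

#' Cross-validation comparison of two model/topology candidates
#'
#' The alignment columns are split without replacement into a learning set
#' (`learn_frac`, half-up rounding) and a test set (the complement),
#' independently per replicate. Each candidate's branch lengths are
#' optimised on the learning set; the statistic is the test-set
#' log-likelihood difference (candidate A minus candidate B), reported as
#' mean plus/minus standard deviation over replicates. A positive mean
#' favours candidate A.
#'
#' @param aln An [aa_alignment()].
#' @param candidate_a,candidate_b Lists `list(model = <aa_model>,
#'   tree = <phylo topology>)`.
#' @param replicates Number of random splits (default 10).
#' @param learn_frac Learning fraction in (0, 1) (default 0.9).
#' @param seed Master seed; replicate `j` uses substream `(seed, j)`.
#' @param ... Passed to [optimize_branch_lengths()].
#' @return Object of class `cv_result`: `deltas`, `mean`, `sd`,
#'   `replicates`, `n_learn`, `n_test`.
#' @export
cross_validate <- function(aln, candidate_a, candidate_b, replicates = 10L,
                           learn_frac = 0.9, seed = 1L, ...) {
  if (replicates < 1) stop("need at least one replicate")
  n <- ncol(aln)
  sizes <- cv_split_sizes(n, learn_frac)
  n_learn <- sizes[["learn"]]
  n_test <- sizes[["test"]]
  if (n_test < 1L) stop("test set is empty")
  deltas <- numeric(replicates)
  for (j in seq_len(replicates)) {
    set.seed(derive_seed(seed, j))
    learn <- sort(sample.int(n, n_learn))
    test <- setdiff(seq_len(n), learn)
    test_lnl <- vapply(list(candidate_a, candidate_b), function(cand) {
      fit <- optimize_branch_lengths(aln[, learn, drop = FALSE],
                                     cand$tree, cand$model, ...)
      site_loglik(aln[, test, drop = FALSE], fit$tree, cand$model)$total
    }, 0)
    deltas[j] <- test_lnl[1] - test_lnl[2]
  }
  structure(list(deltas = deltas, mean = mean(deltas),
                 sd = stats::sd(deltas), replicates = replicates,
                 n_learn = n_learn, n_test = n_test),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "Cross-validation over %d replicates (learning %d / test %d columns)\n",
    x$replicates, x$n_learn, x$n_test))
  cat(sprintf("  delta lnL (A - B): %.1f +/- %.1f; A preferred in %d/%d\n",
              x$mean, x$sd, sum(x$deltas > 0), x$replicates))
  invisible(x)
}
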