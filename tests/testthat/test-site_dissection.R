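# site-rate averaging, removal schedule, rate-mass reduction, support curves

test_that("topology-averaged rates reduce to the single-tree estimate", {
  m <- lg4()
  tr <- balanced_5taxon_tree()
  aln <- simulate_alignment(tr, m, 120, seed = 8)
  topo_single <- list(tr)
  r1 <- mean_rates_over_set(aln, topo_single, m, tol = 1e-3, max_rounds = 8)
  fit <- optimize_branch_lengths(aln, tr, m, tol = 1e-3, max_rounds = 8)
  r_direct <- estimate_site_rates(aln, fit$tree, m)
  expect_equal(as.numeric(r1), as.numeric(r_direct), tolerance = 1e-8)

  # a duplicated topology changes nothing
  r2 <- mean_rates_over_set(aln, list(tr, tr), m, tol = 1e-3, max_rounds = 8)
  expect_equal(as.numeric(r2), as.numeric(r1), tolerance = 1e-10)
})

test_that("rates over two topologies are the hand average", {
  m <- lg4()
  t1 <- balanced_5taxon_tree()
  t2 <- parse_newick("((A:0.2,C:0.2):0.1,(B:0.2,D:0.2):0.1,E:0.2);")
  aln <- simulate_alignment(t1, m, 80, seed = 9)
  pooled <- mean_rates_over_set(aln, list(t1, t2), m, tol = 1e-4,
                                max_rounds = 12)
  per_tree <- lapply(list(t1, t2), function(tr) {
    fit <- optimize_branch_lengths(aln, tr, m, tol = 1e-4, max_rounds = 12)
    as.numeric(estimate_site_rates(aln, fit$tree, m))
  })
  expect_equal(as.numeric(pooled), (per_tree[[1]] + per_tree[[2]]) / 2,
               tolerance = 1e-10)
})

test_that("the default schedule is the documented 14-step ladder", {
  s <- default_schedule()
  expect_equal(length(s), 14)
  expect_equal(s[1], 5)
  expect_equal(s[14], 90)
  expect_equal(as.numeric(s),
               c(5, 10, 20, 30, 40, 50, 55, 60, 65, 70, 75, 80, 85, 90))
  expect_error(removal_schedule(c(10, 10, 20)), "strictly increasing")
  expect_error(removal_schedule(c(0, 50)), "in \\(0, 100\\)")
})

test_that("rate-mass reduction removes the minimal fastest prefix", {
  aln <- random_alignment(4, 4, seed = 1)
  rates <- structure(c(4, 2, 1, 1), class = "site_rates")
  out <- reduce_alignment(aln, rates, 50, mode = "rate_mass")
  expect_equal(out$removed_columns, 1L)        # total mass 8, rate-4 column
  expect_equal(ncol(out$alignment), 3)

  out0 <- reduce_alignment(aln, rates, 0)
  expect_identical(unclass(out0$alignment), unclass(aln))

  outf <- reduce_alignment(aln, rates, 50, mode = "site_fraction")
  expect_equal(outf$removed_columns, c(1L, 2L))

  expect_error(reduce_alignment(aln, rates, 100, mode = "site_fraction"),
               "empty")
  expect_error(reduce_alignment(aln, structure(1:3, class = "site_rates"), 10),
               "length")
})

test_that("rate-mass removal cuts no more sites than the site-fraction count
           when fast sites carry above-average mass", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(50:200, 1)
    rates <- rexp(n, 1)^2        # long-tailed
    aln <- random_alignment(4, n, seed = i)
    pct <- sample(c(10, 30, 50, 70), 1)
    rm_mass <- reduce_alignment(aln, structure(rates, class = "site_rates"),
                                pct, "rate_mass")$removed_columns
    rm_frac <- reduce_alignment(aln, structure(rates, class = "site_rates"),
                                pct, "site_fraction")$removed_columns
    if (all(rates[rm_mass] > mean(rates))) {
      expect_lte(length(rm_mass), length(rm_frac))
    }
  }
})

test_that("long-tailed rates leave most sites at the deepest removal step", {
  # removing 90% of the rate mass of a
  # long-tailed distribution retains far more than 10% of the sites
  set.seed(13)
  n <- 36735
  rates <- rgamma(n, shape = 0.35, rate = 0.35)
  aln_cols <- seq_len(n)
  ord <- order(-rates, aln_cols)
  n_removed <- which(cumsum(rates[ord]) >= 0.9 * sum(rates))[1]
  expect_gt((n - n_removed) / n, 0.30)
})

test_that("support curves track monitored splits and shrink monotonically", {
  m <- lg1()
  tr <- balanced_5taxon_tree(inner = 0.15, outer = 0.25)
  aln <- simulate_alignment(tr, m, 250, seed = 12)
  # a restricted candidate set: neither tree contains the A,E split, so a
  # monitored split incompatible with every candidate scores 0 throughout
  topo <- list(tr, parse_newick("((A:0.2,C:0.2):0.1,(B:0.2,D:0.2):0.1,E:0.2);"))
  rates <- structure(runif(250, 0.5, 2), class = "site_rates")
  monitored <- list(
    true_ab = bipartition(c("A", "B"), c("C", "D", "E")),
    impossible = bipartition(c("A", "E"), c("B", "C", "D")))
  sc <- support_curves(aln, rates, removal_schedule(c(30, 60)), monitored,
                       topo, m, B = 5, seed = 3, min_columns = 20)
  expect_true(all(sc$bp_impossible == 0))
  expect_equal(nrow(sc), 3)                       # full + 2 steps
  expect_true(all(diff(sc$columns_remaining) < 0))
  expect_equal(sc$columns_removed + sc$columns_remaining,
               rep(250, 3))
  expect_true(all(sc$bp_true_ab >= 0 & sc$bp_true_ab <= 1))
  expect_true(all(is.na(sc$pp_true_ab)))

  # a step leaving too few columns is skipped with a warning
  expect_warning(
    sc2 <- support_curves(aln, rates, removal_schedule(c(30, 99.9)),
                          monitored, topo, m, B = 2, seed = 3,
                          mode = "site_fraction", min_columns = 50),
    "skipped")
  expect_equal(nrow(sc2), 2)
})
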