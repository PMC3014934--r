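# likelihood engine: pruning correctness, optimisation, site rates,
# topology-set ML, bootstrap

test_that("two-taxon single-site likelihood matches the closed form", {
  m <- lg1()
  aln <- aa_alignment(c(A = "A", B = "R"))
  tr <- parse_newick("(A:0.3,B:0.2);")
  P <- transition_matrix(m, 0.5)
  pi <- m$components[[1]]$freqs
  expect_equal(site_loglik(aln, tr, m)$total, log(unname(pi[1]) * P[1, 2]),
               tolerance = 1e-10)
})

test_that("fully missing columns contribute log-likelihood zero", {
  m <- lg4()
  aln <- aa_alignment(c(A = "A?", B = "R-", C = "NX", D = "D?"))
  tr <- balanced_5taxon_tree()
  tr <- ape::drop.tip(tr, "E")
  sl <- site_loglik(aln, tr, m)
  expect_equal(sl$per_site[2], 0)
  expect_lt(sl$per_site[1], 0)
})

test_that("pruning equals brute-force enumeration on small instances", {
  cases <- expand.grid(nt = c(3, 4), k = c(1, 2), seed = 1:2)
  for (i in seq_len(nrow(cases))) {
    nt <- cases$nt[i]
    m <- build_model("LG", alpha = 0.6, k = cases$k[i])
    tr <- random_tree(nt, seed = cases$seed[i])
    tr$tip.label <- paste0("tax", seq_len(nt))
    aln <- random_alignment(nt, 3, seed = cases$seed[i] + 10,
                            missing_frac = 0.2)
    sl <- site_loglik(aln, tr, m)
    expect_equal(sl$per_site, brute_site_loglik(aln, tr, m),
                 tolerance = 1e-8)
  }
})

test_that("total likelihood is invariant to root placement (pulley)", {
  m <- lg4()
  tr <- balanced_5taxon_tree()
  aln <- simulate_alignment(tr, m, 40, seed = 5)
  ref <- site_loglik(aln, tr, m)$total
  for (tip in tr$tip.label) {
    rooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(site_loglik(aln, rooted, m)$total, ref, tolerance = 1e-9)
  }
})

test_that("branch-length optimisation improves lnL and matches a grid oracle", {
  m <- lg1()
  tr <- parse_newick("(A:0.1,B:0.1);")
  aln <- simulate_alignment(parse_newick("(A:0.15,B:0.15);"), m, 400, seed = 2)
  fit <- optimize_branch_lengths(aln, tr, m)
  expect_gte(fit$loglik$total, site_loglik(aln, tr, m)$total)
  # grid oracle over the identifiable total length
  grid <- seq(0.05, 1.2, by = 1e-4)
  lnl <- vapply(grid, function(t) {
    g <- tr; g$edge.length <- c(t / 2, t / 2)
    site_loglik(aln, g, m)$total
  }, 0)
  expect_equal(sum(fit$tree$edge.length), grid[which.max(lnl)],
               tolerance = 5e-4)

  # identical sequences drive the length to the lower clamp
  same <- aa_alignment(c(A = strrep("AR", 25), B = strrep("AR", 25)))
  fit0 <- optimize_branch_lengths(same, tr, m)
  expect_lt(sum(fit0$tree$edge.length), 1e-6)
})

test_that("optimisation never decreases the likelihood", {
  m <- lg1()
  for (seed in 1:10) {
    tr <- random_tree(5, seed = seed)
    tr$tip.label <- paste0("tax", 1:5)
    aln <- random_alignment(5, 60, seed = seed + 100, missing_frac = 0.1)
    before <- site_loglik(aln, tr, m)$total
    fit <- optimize_branch_lengths(aln, tr, m, max_rounds = 4)
    expect_gte(fit$loglik$total + 1e-9, before)
  }
})

test_that("posterior-mean site rates follow the Bayes formula", {
  m <- build_model("LG", alpha = 0.8, k = 2)
  aln <- aa_alignment(c(A = "A", B = "W"))
  tr <- parse_newick("(A:0.2,B:0.3);")
  r <- estimate_site_rates(aln, tr, m)
  # hand computation
  pi <- m$components[[1]]$freqs
  lik_k <- vapply(1:2, function(k) {
    P <- transition_matrix(m, 0.5, rate = m$cat_rates[k])
    pi[1] * P[1, match("W", aa_alphabet())]
  }, 0)
  expected <- sum(m$cat_rates * 0.5 * lik_k) / sum(0.5 * lik_k)
  expect_equal(as.numeric(r), expected, tolerance = 1e-10)

  expect_warning(estimate_site_rates(aln, tr, lg1()), "single rate category")
})

test_that("constant columns score slower than maximally variable ones", {
  m <- lg4()
  tr <- balanced_5taxon_tree()
  aln <- aa_alignment(setNames(c("AC", "AD", "AE", "AF", "AG"),
                               c("A", "B", "C", "D", "E")))
  r <- estimate_site_rates(aln, tr, m)
  expect_lt(r[1], r[2])
})

test_that("ML over a topology set ranks the generating topology first", {
  m <- lg1()
  true_tree <- balanced_5taxon_tree(inner = 0.15, outer = 0.25)
  aln <- simulate_alignment(true_tree, m, 1500, seed = 3)
  topo <- enumerate_topologies(true_tree$tip.label, rooted = FALSE)
  rank <- ml_over_topology_set(aln, topo, m, tol = 1e-3, max_rounds = 10)
  expect_true(all(diff(rank$loglik) <= 1e-9))
  expect_equal(support_of(bipartition(c("A", "B"), c("C", "D", "E")),
                          rank$trees[[1]]), 1)
  expect_equal(support_of(bipartition(c("C", "D"), c("A", "B", "E")),
                          rank$trees[[1]]), 1)
  # singleton set is returned as-is
  single <- ml_over_topology_set(aln, list(true_tree), m, max_rounds = 2)
  expect_equal(length(single$trees), 1)
  expect_error(ml_over_topology_set(aln, list(), m), "empty topology set")
})

test_that("bootstrap is deterministic and degenerate data pin support", {
  m <- lg1()
  # alignment of one repeated column: replicates are identical
  one <- aa_alignment(setNames(rep(strrep("A", 30), 5), c("A","B","C","D","E")))
  one[2, ] <- "R"; one[4, ] <- "N"
  topo <- enumerate_topologies(c("A","B","C","D","E"), rooted = FALSE)
  bs1 <- bootstrap(one, topo, m, B = 5, seed = 9)
  expect_true(all(bs1$bipartition_support %in% c(0, 1)))

  tr <- balanced_5taxon_tree()
  aln <- simulate_alignment(tr, m, 150, seed = 4)
  a <- bootstrap(aln, topo, m, B = 4, seed = 7)
  b <- bootstrap(aln, topo, m, B = 4, seed = 7)
  expect_identical(a$bipartition_support, b$bipartition_support)
  expect_identical(lapply(a$trees, write_newick), lapply(b$trees, write_newick))
  expect_equal(a$B, 4)
})
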