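# simulators: determinism, stationarity, missingness, rate classes

test_that("zero branch lengths give identical sequences", {
  m <- lg1()
  tr <- parse_newick("((A:0,B:0):0,(C:0,D:0):0,E:0);")
  aln <- simulate_alignment(tr, m, 30, seed = 1)
  for (t in c("B", "C", "D", "E")) {
    expect_identical(unclass(aln)[t, ], unclass(aln)["A", ])
  }
})

test_that("simulation is bit-reproducible under a fixed seed", {
  m <- lg4()
  tr <- balanced_5taxon_tree()
  a <- simulate_alignment(tr, m, 200, seed = 42,
                          site_class_mix = list(list(0.3, 5)))
  b <- simulate_alignment(tr, m, 200, seed = 42,
                          site_class_mix = list(list(0.3, 5)))
  expect_identical(unclass(a), unclass(b))
  expect_identical(attr(a, "site_class"), attr(b, "site_class"))
  c <- simulate_alignment(tr, m, 200, seed = 43)
  expect_false(identical(unclass(a), unclass(c)))
})

test_that("long simulations reproduce the stationary frequencies", {
  m <- lg1()
  tr <- balanced_5taxon_tree()
  aln <- simulate_alignment(tr, m, 50000, seed = 6)
  pi <- m$components[[1]]$freqs
  emp <- as.numeric(table(factor(unclass(aln), levels = aa_alphabet())))
  emp <- emp / sum(emp)
  expect_lt(0.5 * sum(abs(emp - pi)), 0.01)   # total variation
})

test_that("the LBA case wires tree, fast class and truth splits together", {
  case <- make_lba_case(lba_scenario(n_sites = 300, seed = 2))
  expect_equal(sort(case$tree$tip.label),
               sort(c("t_short_1", "t_long_1", "t_short_2", "t_long_2",
                      "t_out")))
  # long branches are non-sisters in the generating tree
  expect_equal(support_of(case$truth$lba_split, case$tree), 0)
  expect_equal(support_of(case$truth$true_split_1, case$tree), 1)
  cls <- attr(case$alignment, "site_class")
  expect_equal(length(cls), 300)
  expect_true(all(cls %in% c(0, 1)))
  expect_error(lba_scenario(fast_class_fraction = 1), "fraction")
})

test_that("fast-class sites earn higher estimated rates than background", {
  m4 <- lg4()
  case <- make_lba_case(lba_scenario(n_sites = 1200, seed = 3))
  fit <- optimize_branch_lengths(case$alignment, case$tree, m4,
                                 tol = 1e-2, max_rounds = 6)
  r <- estimate_site_rates(case$alignment, fit$tree, m4)
  cls <- attr(case$alignment, "site_class")
  expect_gt(mean(r[cls == 1]), mean(r[cls == 0]))
  w <- wilcox.test(r[cls == 1], r[cls == 0], alternative = "greater")
  expect_lt(w$p.value, 0.01)
})

test_that("gene sets honour presence probabilities and reproduce", {
  tr <- balanced_5taxon_tree()
  spec1 <- gene_set_spec(6, tr$tip.label, tr, presence_prob = 1,
                         length_range = c(20, 40), seed = 1)
  genes <- make_gene_set(spec1, model = lg1())
  sm <- concatenate(genes, tr$tip.label)
  expect_equal(sm$global_missing, 0)

  # with a dozen taxa the >= 4-taxa floor almost never binds, so the
  # global missingness tracks 1 - presence_prob
  big <- random_tree(12, seed = 4)
  spec2 <- gene_set_spec(40, big$tip.label, big, presence_prob = 0.6,
                         length_range = c(20, 40), seed = 2)
  g2 <- make_gene_set(spec2, model = lg1())
  sm2 <- concatenate(g2, big$tip.label)
  expect_lt(abs(sm2$global_missing - 0.4), 0.05)

  g2b <- make_gene_set(spec2, model = lg1())
  expect_identical(lapply(g2, unclass), lapply(g2b, unclass))
})

test_that("tandem proteins assemble with the requested insertions", {
  mono <- ubiquitin_monomer()
  expect_equal(nchar(make_tandem_protein(mono, 2)), 2 * nchar(mono))
  q <- make_tandem_protein(mono, 3, list(`1` = "S"))
  expect_equal(nchar(q), 3 * nchar(mono) + 1)
  expect_error(make_tandem_protein(mono, 3, list(`1` = "ABC")), "longer")
  expect_error(make_tandem_protein(mono, 1), "at least 2")
  expect_error(make_tandem_protein(mono, 3, list(`5` = "S")), "junction")
})
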