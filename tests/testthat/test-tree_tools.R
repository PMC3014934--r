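# topology enumeration, bipartitions, grafting, split support

test_that("enumeration counts follow the double factorials", {
  dfact <- function(n) prod(seq(n, 1, by = -2))
  for (n in 3:7) {
    tips <- paste0("t", seq_len(n))
    expect_equal(length(enumerate_topologies(tips, rooted = TRUE)),
                 dfact(2 * n - 3))
    if (n >= 4) {
      expect_equal(length(enumerate_topologies(tips, rooted = FALSE)),
                   dfact(2 * n - 5))
    }
  }
  expect_equal(length(enumerate_topologies(paste0("t", 1:5), TRUE)), 105)
  expect_equal(length(enumerate_topologies(paste0("t", 1:5), FALSE)), 15)
  expect_equal(length(enumerate_topologies(c("a", "b"), TRUE)), 1)
  expect_error(enumerate_topologies(paste0("t", 1:9)), "8 tips")
  # enumerated sets contain no duplicate topologies
  ts <- enumerate_topologies(paste0("t", 1:5), rooted = TRUE)
  keys <- vapply(ts$trees, phylodissect:::topology_key, "", rooted = TRUE)
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("bipartitions are canonical, non-trivial and n-3 in number", {
  tr <- parse_newick("((A,B),(C,D));")
  bps <- bipartitions(tr)
  expect_equal(length(bps), 1)
  expect_equal(phylodissect:::split_key(bps[[1]]), "A,B|C,D")

  star <- parse_newick("(A,B,C,D);")
  expect_error(bipartitions(star), "non-binary")

  for (n in 4:8) {
    tr <- random_tree(n, seed = n)
    expect_equal(length(bipartitions(ape::unroot(tr))), n - 3)
  }
})

test_that("bipartitions survive a newick round trip", {
  for (seed in 1:20) {
    tr <- random_tree(sample(4:8, 1), seed = seed)
    back <- parse_newick(write_newick(tr))
    k1 <- sort(vapply(bipartitions(tr), phylodissect:::split_key, ""))
    k2 <- sort(vapply(bipartitions(back), phylodissect:::split_key, ""))
    expect_identical(k1, k2)
  }
})

test_that("grafting one tip yields one topology per backbone branch", {
  bb <- parse_newick("((A,B),(C,D));")   # rooted, 6 edges
  ts <- graft_into_backbone(bb, "X")
  expect_equal(length(ts), nrow(bb$edge) + 1L)  # each edge + above root
  # every graft keeps the backbone split A,B|C,D
  expect_equal(support_of(bipartition(c("A", "B"), c("C", "D")), ts), 1)

  expect_equal(length(graft_into_backbone(bb, character(0))), 1)
})

test_that("grafting two tips matches the constrained-enumeration oracle", {
  bb <- ape::unroot(parse_newick("((A,B),(C,D));"))
  ts <- graft_into_backbone(bb, c("X", "Y"))
  # oracle: all unrooted 6-tip topologies whose restriction to A-D is bb
  all6 <- enumerate_topologies(c("A", "B", "C", "D", "X", "Y"),
                               rooted = FALSE)
  bb_key <- phylodissect:::topology_key(bb, rooted = FALSE)
  consistent <- Filter(function(tr) {
    sub <- ape::drop.tip(tr, c("X", "Y"))
    identical(phylodissect:::topology_key(sub, rooted = FALSE), bb_key)
  }, all6$trees)
  expect_equal(length(ts), length(consistent))
  k1 <- sort(vapply(ts$trees, phylodissect:::topology_key, "", rooted = FALSE))
  k2 <- sort(vapply(consistent, phylodissect:::topology_key, "",
                    rooted = FALSE))
  expect_identical(k1, k2)

  expect_error(graft_into_backbone(bb, "A"), "overlap")
})

test_that("split support counts matching trees, restricting as needed", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  q <- bipartition(c("A", "B"), c("C", "D"))
  expect_equal(support_of(q, list(t1, t1)), 1)
  expect_equal(support_of(q, list(t2, t2)), 0)
  expect_equal(support_of(q, list(t1, t2, t1, t2)), 0.5)

  # tree missing a universe taxon: query restricted to the induced set
  t3 <- parse_newick("((A,B),(C,E));")
  q5 <- bipartition(c("A", "B"), c("C", "D", "E"))
  expect_equal(support_of(q5, list(t3)), 1)
  # side empty after restriction counts as absent, with a warning
  t4 <- parse_newick("((C,D),(E,F));")
  expect_warning(s <- support_of(bipartition(c("A", "B"), c("C", "D", "E", "F")),
                                 list(t4)), "restriction")
  expect_equal(s, 0)
})
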