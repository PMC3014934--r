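# block trimming, gene filtering, concatenation, taxon removal

test_that("trimming keeps clean conserved alignments untouched", {
  aln <- aa_alignment(setNames(rep(strrep("ARNDCQEGHILKMFPSTWYV", 1), 5),
                               paste0("t", 1:5)))
  out <- trim_blocks(aln)
  expect_equal(out$kept_columns, 1:20)
  expect_identical(unclass(out$alignment), unclass(aln))
})

test_that("short non-conserved runs survive inside one flanked block", {
  # 6 taxa, 30 columns: conserved 1-8, diverged 9-13, conserved 14-16,
  # diverged 17-21, conserved 22-30. Both diverged runs are <= 12, so the
  # whole stretch stays one block bounded by highly conserved flanks; kept
  # columns are ordered, and no surviving block is shorter than 5.
  set.seed(42)
  cons <- function(n) matrix(rep(sample(aa_alphabet(), n, TRUE), each = 6), 6)
  div <- function(n) matrix(sample(aa_alphabet(), 6 * n, TRUE), 6)
  m <- cbind(cons(8), div(5), cons(3), div(5), cons(9))
  rownames(m) <- paste0("t", 1:6)
  out <- trim_blocks(aa_alignment(m))
  expect_true(all(diff(out$kept_columns) > 0))
  segs <- split(out$kept_columns, cumsum(c(1, diff(out$kept_columns) != 1)))
  expect_true(all(lengths(segs) >= 5))
})

test_that("an isolated island dies when its surrounding runs exceed 12", {
  set.seed(7)
  cons <- function(n) matrix(rep(sample(aa_alphabet(), n, TRUE), each = 6), 6)
  div <- function(n) matrix(sample(aa_alphabet(), 6 * n, TRUE), 6)
  m <- cbind(cons(8), div(13), cons(3), div(13), cons(9))
  rownames(m) <- paste0("t", 1:6)
  out <- trim_blocks(aa_alignment(m))
  # both 13-column runs are rejected outright; the 3-column island is then
  # a block shorter than 5 and is dropped; the flanking conserved blocks stay
  expect_true(all(out$kept_columns %in% c(1:8, 38:46)))
  expect_false(any(out$kept_columns %in% 22:24))
})

test_that("gap-saturated columns are removed under the half-gaps rule", {
  set.seed(3)
  base <- matrix(rep(sample(aa_alphabet(), 12, TRUE), each = 6), 6)
  base[1:4, 6] <- "-"            # 4 of 6 rows gapped > 50%
  rownames(base) <- paste0("t", 1:6)
  out <- trim_blocks(aa_alignment(base))
  expect_false(6 %in% out$kept_columns)
})

test_that("trimming is idempotent", {
  for (seed in 1:5) {
    aln <- random_alignment(6, 80, seed = seed, missing_frac = 0.25)
    t1 <- trim_blocks(aln)
    t2 <- trim_blocks(t1$alignment)
    expect_identical(unclass(t2$alignment), unclass(t1$alignment))
  }
})

test_that("gene filtering reproduces the registry arithmetic", {
  reg <- c(
    lapply(1:23, function(i) gene_record(paste0("para", i),
                                         paralogy_suspect = TRUE)),
    lapply(1:12, function(i) gene_record(paste0("nofocal", i),
                                         has_focal_taxon = FALSE)),
    lapply(1:167, function(i) gene_record(paste0("good", i)))
  )
  res <- filter_genes(reg)
  expect_equal(unname(res$report["kept"]), 167)
  expect_equal(unname(res$report["discarded_paralogy"]), 23)
  expect_equal(unname(res$report["discarded_no_focal"]), 12)

  empty <- filter_genes(list())
  expect_equal(unname(empty$report["kept"]), 0)

  both <- filter_genes(list(gene_record("g", paralogy_suspect = TRUE,
                                        has_focal_taxon = FALSE)))
  expect_equal(unname(both$report["discarded_paralogy"]), 1)
  expect_equal(unname(both$report["discarded_no_focal"]), 0)

  expect_error(filter_genes(list(gene_record("a"), gene_record("a"))),
               "duplicate gene names")
})

test_that("concatenation fills absences, tracks partitions and missingness", {
  g1 <- random_alignment(3, 10, seed = 1)
  g2 <- random_alignment(3, 20, seed = 2)
  rownames(g2) <- rownames(g1)
  g2 <- g2[c("tax1", "tax2"), ]   # tax3 absent from gene 2
  sm <- concatenate(list(g1 = g1, g2 = g2), paste0("tax", 1:3))
  expect_equal(ncol(sm$alignment), 30)
  expect_equal(sm$partitions$start, c(0, 10))
  expect_equal(sm$partitions$end, c(10, 30))
  expect_equal(unname(sm$per_taxon_missing["tax3"]), 20 / 30)

  # single complete gene: zero missingness
  sm1 <- concatenate(list(only = g1), rownames(g1))
  expect_equal(sm1$global_missing, 0)
  expect_identical(unclass(sm1$alignment), unclass(g1))
})

test_that("concatenation conserves residue count and column totals", {
  set.seed(5)
  lens <- sample(10:40, 8)
  taxa <- paste0("tax", 1:6)
  genes <- lapply(seq_along(lens), function(i) {
    g <- random_alignment(6, lens[i], seed = i, missing_frac = 0.1)
    g[sample(taxa, sample(4:6, 1)), , drop = FALSE]
  })
  names(genes) <- paste0("g", seq_along(genes))
  sm <- concatenate(genes, taxa)
  expect_equal(ncol(sm$alignment), sum(lens))
  residues_in <- sum(vapply(genes, function(g) sum(!is_missing_cell(g)), 0))
  expect_equal(sum(!is_missing_cell(sm$alignment)), residues_in)
})

test_that("a 167-gene set sized to a 36,735-column matrix concatenates exactly", {
  lens <- rep(219L, 167); lens[seq_len(36735 - sum(lens))] <- 220L
  expect_equal(sum(lens), 36735)
  taxa <- paste0("tax", 1:5)
  genes <- lapply(lens, function(L) {
    aa_alignment(matrix("A", 5, L, dimnames = list(taxa, NULL)))
  })
  names(genes) <- paste0("g", seq_along(genes))
  sm <- concatenate(genes, taxa)
  expect_equal(ncol(sm$alignment), 36735)
})

test_that("taxon removal deletes emptied columns and re-indexes partitions", {
  taxa <- paste0("tax", 1:5)
  g1 <- random_alignment(5, 10, seed = 1); rownames(g1) <- taxa
  g2 <- random_alignment(1, 6, seed = 2); rownames(g2) <- "tax5"
  sm <- concatenate(list(g1 = g1, g2 = g2), taxa)

  # dropping a taxon present nowhere alone deletes nothing
  sm_a <- remove_taxa(sm, "tax1")
  expect_equal(attr(sm_a, "deleted_columns"), 0L)

  # gene 2 exists only in tax5: dropping it deletes the whole interval
  sm_b <- remove_taxa(sm, "tax5")
  expect_equal(attr(sm_b, "deleted_columns"), 6L)
  expect_equal(sm_b$partitions$gene, "g1")
  expect_equal(sm_b$partitions$end, 10)

  # dropping nothing is the identity
  sm_c <- remove_taxa(sm, character(0))
  expect_identical(unclass(sm_c$alignment), unclass(sm$alignment))

  expect_error(remove_taxa(sm, c("tax1", "tax2")), "fewer than 4")
})

test_that("deleted-column count is invariant to gene order", {
  taxa <- paste0("tax", 1:6)
  set.seed(9)
  genes <- lapply(1:6, function(i) {
    g <- random_alignment(6, 8 + i, seed = i)
    rownames(g) <- taxa
    g[sample(taxa, sample(c(1, 4, 5), 1)), , drop = FALSE]
  })
  names(genes) <- paste0("g", 1:6)
  drop <- c("tax1", "tax2")
  counts <- vapply(1:5, function(s) {
    set.seed(s)
    perm <- sample(genes)
    sm <- concatenate(perm, taxa)
    attr(remove_taxa(sm, drop), "deleted_columns")
  }, 0L)
  expect_true(all(counts == counts[1]))
})
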