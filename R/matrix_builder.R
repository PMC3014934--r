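# Supermatrix construction: block trimming of single-gene alignments,
# gene filtering, partition-aware concatenation with missing-data
# accounting, and taxon-removal experiments.

#' Block-trimming parameters
#'
#' Parameters of the block-selection algorithm of Castresana (2000), with
#' the defaults used throughout this package: up to half of the rows may be
#' gapped in a usable column; a column is "conserved" ("highly conserved")
#' when its most frequent residue occurs in at least 50\% of the taxa plus
#' one; contiguous non-conserved runs longer than 12 columns are rejected;
#' surviving blocks must be at least 5 columns long.
#'
#' @param gap_fraction_allowed Maximum fraction of gapped rows in a usable
#'   column (default 0.5).
#' @param min_conserved Rows required to call a column conserved; `NULL`
#'   means `floor(ntaxa/2) + 1`, resolved at trim time.
#' @param min_flank Rows required for a highly conserved (flank) column;
#'   `NULL` as above.
#' @param max_nonconserved_run Longest tolerated run of contiguous
#'   non-conserved columns (default 12).
#' @param min_block_len Minimum surviving block length (default 5).
#' @return An object of class `trim_params`.
#' @export
trim_params <- function(gap_fraction_allowed = 0.5,
                        min_conserved = NULL,
                        min_flank = NULL,
                        max_nonconserved_run = 12L,
                        min_block_len = 5L) {
  if (gap_fraction_allowed < 0 || gap_fraction_allowed > 1) {
    stop("config error: gap_fraction_allowed must be in [0, 1]")
  }
  if (min_block_len < 1) stop("config error: min_block_len must be >= 1")
  if (max_nonconserved_run < 1) stop("config error: max_nonconserved_run must be >= 1")
  structure(list(gap_fraction_allowed = gap_fraction_allowed,
                 min_conserved = min_conserved,
                 min_flank = min_flank,
                 max_nonconserved_run = as.integer(max_nonconserved_run),
                 min_block_len = as.integer(min_block_len)),
            class = "trim_params")
}

# run-length positions of TRUE stretches in a logical vector
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values],
             len = r$lengths[r$values])
}

#' Remove ambiguously aligned blocks from an alignment
#'
#' Implements the block-selection algorithm: (1) classify every column as
#' non-conserved, conserved or highly conserved (columns with more gapped
#' rows than allowed are non-conserved); (2) reject contiguous non-conserved
#' runs longer than `max_nonconserved_run`; (3) trim the ends of the
#' remaining segments back to highly conserved columns; (4) reject
#' gap-saturated columns together with adjacent non-conserved columns up to
#' the nearest conserved one; (5) drop blocks shorter than `min_block_len`.
#'
#' @param aln An [aa_alignment()] with at least 4 taxa.
#' @param params A [trim_params()].
#' @return List with `alignment` (kept columns) and `kept_columns` (their
#'   original indices, in order). Trimming is idempotent.
#' @export
trim_blocks <- function(aln, params = trim_params()) {
  if (nrow(aln) < 4L) stop("need at least 4 taxa to trim")
  n <- ncol(aln)
  nt <- nrow(aln)
  minc <- params$min_conserved
  minf <- params$min_flank
  if (is.null(minc)) minc <- nt %/% 2L + 1L
  if (is.null(minf)) minf <- nt %/% 2L + 1L
  if (minc > nt || minf > nt) stop("config error: conservation thresholds exceed taxa")

  miss <- is_missing_cell(aln)
  gapped <- colSums(miss) / nt > params$gap_fraction_allowed
  topcount <- apply(unclass(aln), 2, function(col) {
    col <- col[!(col %in% missing_symbols())]
    if (length(col) == 0L) 0L else max(table(col))
  })
  status <- ifelse(gapped | topcount < minc, "non",
                   ifelse(topcount < minf, "cons", "high"))

  keep <- rep(TRUE, n)
  # (2) long non-conserved runs
  runs <- true_runs(status == "non")
  for (i in seq_len(nrow(runs))) {
    if (runs$len[i] > params$max_nonconserved_run) {
      keep[runs$start[i]:runs$end[i]] <- FALSE
    }
  }
  # (3) trim segment flanks to highly conserved columns
  segs <- true_runs(keep)
  for (i in seq_len(nrow(segs))) {
    idx <- segs$start[i]:segs$end[i]
    hi <- which(status[idx] == "high")
    if (length(hi) == 0L) { keep[idx] <- FALSE; next }
    keep[idx[seq_len(min(hi) - 1L)]] <- FALSE
    if (max(hi) < length(idx)) keep[idx[(max(hi) + 1L):length(idx)]] <- FALSE
  }
  # (4) gap-saturated columns and adjacent non-conserved stretches
  for (g in which(gapped & keep)) {
    keep[g] <- FALSE
    j <- g - 1L
    while (j >= 1L && keep[j] && status[j] == "non") { keep[j] <- FALSE; j <- j - 1L }
    j <- g + 1L
    while (j <= n && keep[j] && status[j] == "non") { keep[j] <- FALSE; j <- j + 1L }
  }
  # (5) short blocks
  segs <- true_runs(keep)
  for (i in seq_len(nrow(segs))) {
    if (segs$len[i] < params$min_block_len) {
      keep[segs$start[i]:segs$end[i]] <- FALSE
    }
  }
  kept <- which(keep)
  list(alignment = aln[, kept, drop = FALSE], kept_columns = kept)
}

#' Gene record for registry filtering
#'
#' @param name Gene name (unique within a registry).
#' @param alignment The gene's [aa_alignment()] (optional for bookkeeping
#'   use).
#' @param paralogy_suspect Curation flag: evidence of deep paralogy in the
#'   single-gene tree.
#' @param has_focal_taxon Curation flag: at least one focal-group taxon
#'   present. Both flags are curation inputs (e.g. from visual inspection of
#'   single-gene trees); they are not computed here.
#' @return An object of class `gene_record`.
#' @export
gene_record <- function(name, alignment = NULL, paralogy_suspect = FALSE,
                        has_focal_taxon = TRUE) {
  structure(list(name = name, alignment = alignment,
                 paralogy_suspect = isTRUE(paralogy_suspect),
                 has_focal_taxon = isTRUE(has_focal_taxon)),
            class = "gene_record")
}

#' Filter a gene registry on curation flags
#'
#' Discards genes flagged for deep paralogy, then genes lacking any
#' focal-group taxon. A gene carrying both flags is counted once, under
#' paralogy (paralogy takes precedence).
#'
#' @param registry List of [gene_record()]s with unique names.
#' @return List with `kept` (the surviving records) and `report`: counts
#'   `kept`, `discarded_paralogy`, `discarded_no_focal`.
#' @export
filter_genes <- function(registry) {
  nms <- vapply(registry, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("duplicate gene names: ", paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  para <- vapply(registry, `[[`, NA, "paralogy_suspect")
  focal <- vapply(registry, `[[`, NA, "has_focal_taxon")
  drop_para <- para
  drop_focal <- !para & !focal
  kept <- registry[!drop_para & !drop_focal]
  list(kept = kept,
       report = c(kept = length(kept),
                  discarded_paralogy = sum(drop_para),
                  discarded_no_focal = sum(drop_focal)))
}

#' Concatenate gene alignments into a partitioned supermatrix
#'
#' Taxa absent from a gene are filled with `?` across that gene's column
#' interval. Partitions are half-open 0-based intervals `[start, end)`.
#'
#' @param genes Named list of [aa_alignment()]s (names are gene names), or a
#'   list of `gene_record`s.
#' @param taxon_universe Labels of all taxa; each gene's taxa must be a
#'   subset.
#' @return An object of class `supermatrix`: list with `alignment`,
#'   `partitions` (data frame `gene`, `start`, `end`), `per_taxon_missing`
#'   and `global_missing` fractions.
#' @export
concatenate <- function(genes, taxon_universe) {
  if (length(genes) && inherits(genes[[1]], "gene_record")) {
    nms <- vapply(genes, `[[`, "", "name")
    genes <- stats::setNames(lapply(genes, `[[`, "alignment"), nms)
  }
  if (is.null(names(genes)) || any(!nzchar(names(genes)))) {
    stop("genes must be named")
  }
  taxon_universe <- as.character(taxon_universe)
  total <- sum(vapply(genes, ncol, 0L))
  mat <- matrix("?", length(taxon_universe), total,
                dimnames = list(taxon_universe, NULL))
  starts <- integer(length(genes)); ends <- integer(length(genes))
  at <- 0L
  for (g in seq_along(genes)) {
    aln <- genes[[g]]
    if (anyDuplicated(rownames(aln))) {
      stop("conflicting duplicate taxon rows in gene ", names(genes)[g])
    }
    extra <- setdiff(rownames(aln), taxon_universe)
    if (length(extra)) {
      stop("gene ", names(genes)[g], " has taxa outside the universe: ",
           paste(extra, collapse = ", "))
    }
    w <- ncol(aln)
    if (w > 0L) mat[rownames(aln), (at + 1L):(at + w)] <- unclass(aln)
    starts[g] <- at; ends[g] <- at + w
    at <- at + w
  }
  new_supermatrix(aa_alignment(mat),
                  data.frame(gene = names(genes), start = starts, end = ends,
                             stringsAsFactors = FALSE))
}

new_supermatrix <- function(aln, partitions) {
  miss <- is_missing_cell(aln)
  structure(list(alignment = aln,
                 partitions = partitions,
                 per_taxon_missing = rowMeans(miss),
                 global_missing = mean(miss)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix:", nrow(x$alignment), "taxa x", ncol(x$alignment),
      "positions,", nrow(x$partitions), "genes\n")
  cat(sprintf("  global missing data: %.1f%%\n", 100 * x$global_missing))
  invisible(x)
}

#' Remove taxa from a supermatrix
#'
#' Rows are dropped; columns left entirely missing are deleted and the
#' partition intervals re-indexed (genes reduced to zero width are
#' removed). The number of deleted columns is reported in
#' `attr(, "deleted_columns")`.
#'
#' @param sm A [concatenate()] supermatrix.
#' @param drop Taxon labels to remove (must leave at least 4 taxa).
#' @return A new `supermatrix`.
#' @export
remove_taxa <- function(sm, drop) {
  drop <- as.character(drop)
  bad <- setdiff(drop, rownames(sm$alignment))
  if (length(bad)) stop("taxa not in supermatrix: ", paste(bad, collapse = ", "))
  keep_taxa <- setdiff(rownames(sm$alignment), drop)
  if (length(keep_taxa) < 4L) stop("dropping would leave fewer than 4 taxa")
  aln <- sm$alignment[keep_taxa, , drop = FALSE]
  dead <- colSums(!is_missing_cell(aln)) == 0L
  part <- sm$partitions
  new_part <- part
  removed_before <- cumsum(c(0L, as.integer(dead)))  # deleted cols before position i+1
  for (g in seq_len(nrow(part))) {
    s <- part$start[g]; e <- part$end[g]
    ndel <- if (e > s) sum(dead[(s + 1L):e]) else 0L
    new_part$start[g] <- s - removed_before[s + 1L]
    new_part$end[g] <- e - removed_before[s + 1L] - ndel
  }
  new_part <- new_part[new_part$end > new_part$start, , drop = FALSE]
  rownames(new_part) <- NULL
  out <- new_supermatrix(aln[, !dead, drop = FALSE], new_part)
  attr(out, "deleted_columns") <- sum(dead)
  out
}

#' Write a supermatrix and its side tables
#'
#' Emits the alignment (relaxed PHYLIP, sequential), a tab-separated
#' partition table (`gene`, `start`, `end`; 0-based half-open) and a
#' missing-data report (per-taxon and global fractions).
#'
#' @param sm A `supermatrix`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_supermatrix <- function(sm, dir, prefix = "supermatrix") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_aln <- file.path(dir, paste0(prefix, ".phy"))
  f_part <- file.path(dir, paste0(prefix, ".partitions.tsv"))
  f_miss <- file.path(dir, paste0(prefix, ".missing.tsv"))
  write_alignment(sm$alignment, f_aln, "phylip-sequential")
  utils::write.table(sm$partitions, f_part, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  miss <- data.frame(taxon = c(names(sm$per_taxon_missing), "_global_"),
                     missing_fraction = c(sm$per_taxon_missing,
                                          sm$global_missing))
  utils::write.table(miss, f_miss, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(f_aln, f_part, f_miss))
}
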