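# Reading and writing the standard formats the pipeline touches: FASTA,
# PHYLIP (relaxed, sequential and interleaved) and Newick.
#
# PHYLIP dialect: relaxed labels, whitespace-delimited, up to 64 characters.
# Strict 10-character PHYLIP would mangle taxon names such as
# "Reticulomyxa_filosa", so it is not supported for writing.

#' Read an amino-acid alignment from disk
#'
#' @param path Path to the file.
#' @param format One of `"fasta"`, `"phylip-sequential"`,
#'   `"phylip-interleaved"`.
#' @return An [aa_alignment()].
#' @details Validation is strict: ragged rows, duplicate taxon labels and
#'   characters outside the alphabet (20 amino acids, `-`, `X`, `?`) are
#'   errors, reported with the offending taxon and column.
#' @export
read_alignment <- function(path,
                           format = c("fasta", "phylip-sequential",
                                      "phylip-interleaved")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("no sequences in ", path)
    seqs <- stats::setNames(as.character(set), names(set))
    names(seqs) <- sub("\\s.*$", "", names(seqs))  # first token of header
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) stop("ragged alignment in ", path)
    aa_alignment(seqs)
  } else {
    read_phylip(path, interleaved = (format == "phylip-interleaved"))
  }
}

read_phylip <- function(path, interleaved = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty PHYLIP file: ", path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2])))) {
    stop("malformed PHYLIP header: '", lines[1], "'")
  }
  nt <- as.integer(hdr[1]); nc <- as.integer(hdr[2])
  body <- lines[-1]
  if (!interleaved) {
    if (length(body) < nt) stop("PHYLIP: expected ", nt, " sequence lines")
    labs <- character(nt); seqs <- character(nt)
    for (i in seq_len(nt)) {
      tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
      labs[i] <- tok[1]
      seqs[i] <- paste(tok[-1], collapse = "")
    }
  } else {
    # first block carries labels; subsequent blocks are bare continuation rows
    labs <- character(nt); seqs <- character(nt)
    blk <- 0L
    for (ln in body) {
      i <- blk %% nt + 1L
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      if (blk < nt) {
        labs[i] <- tok[1]
        seqs[i] <- paste(tok[-1], collapse = "")
      } else {
        seqs[i] <- paste0(seqs[i], paste(tok, collapse = ""))
      }
      blk <- blk + 1L
    }
    if (blk %% nt != 0L) stop("PHYLIP interleaved: ragged block structure")
  }
  if (any(nchar(seqs) != nc)) {
    stop("ragged alignment: PHYLIP row lengths disagree with header (",
         paste(unique(nchar(seqs)), collapse = ","), " vs ", nc, ")")
  }
  aa_alignment(stats::setNames(seqs, labs))
}

#' Write an amino-acid alignment to disk
#'
#' @param aln An [aa_alignment()].
#' @param path Output path.
#' @param format One of `"fasta"`, `"phylip-sequential"`,
#'   `"phylip-interleaved"`.
#' @param max_label PHYLIP label length limit (relaxed dialect, default 64).
#' @return `path`, invisibly. Output is byte-stable for a fixed input.
#' @export
write_alignment <- function(aln, path,
                            format = c("fasta", "phylip-sequential",
                                       "phylip-interleaved"),
                            max_label = 64L) {
  format <- match.arg(format)
  if (nrow(aln) == 0L) stop("no sequences")
  seqs <- alignment_strings(aln)
  if (format == "fasta") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(seqs)) {
      writeLines(c(paste0(">", names(seqs)[i]), seqs[i]), con)
    }
  } else {
    if (any(nchar(names(seqs)) > max_label)) {
      stop("taxon label exceeds PHYLIP relaxed limit of ", max_label,
           " characters")
    }
    if (any(grepl("\\s", names(seqs)))) stop("PHYLIP labels cannot contain whitespace")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(" ", length(seqs), ncol(aln)), con)
    w <- max(nchar(names(seqs)))
    if (format == "phylip-sequential") {
      writeLines(sprintf("%-*s  %s", w, names(seqs), seqs), con)
    } else {
      chunk <- 60L
      starts <- seq(1L, max(ncol(aln), 1L), by = chunk)
      for (b in seq_along(starts)) {
        piece <- substr(seqs, starts[b], min(starts[b] + chunk - 1L, ncol(aln)))
        if (b == 1L) {
          writeLines(sprintf("%-*s  %s", w, names(seqs), piece), con)
        } else {
          writeLines(c("", piece), con)
        }
      }
    }
  }
  invisible(path)
}

#' Parse a Newick tree string
#'
#' @param text A Newick string (single tree).
#' @return An `ape::phylo` tree. Branch lengths absent from the input stay
#'   absent (`NULL` `edge.length`), which is distinct from zero; operations
#'   that require lengths say so.
#' @export
parse_newick <- function(text) {
  text <- trimws(text)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("Newick parse error: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, "')')")
  }
  semi <- regexpr(";", text, fixed = TRUE)
  if (semi > 0 && semi < nchar(text)) {
    stop("Newick parse error: trailing garbage at offset ", semi + 1L)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("Newick parse error in: ", substr(text, 1, 60))
  }
  validate_tree(tr)
}

#' Serialise a tree to Newick
#' @param tree An `ape::phylo` tree.
#' @return A Newick string.
#' @export
write_newick <- function(tree) ape::write.tree(tree)

validate_tree <- function(tree, require_lengths = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (any(!nzchar(tree$tip.label))) stop("empty tip label")
  if (!is.null(tree$edge.length)) {
    if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
      stop("branch lengths must be finite and non-negative")
    }
  } else if (require_lengths) {
    stop("tree has no branch lengths, but lengths are required here")
  }
  tree
}

has_branch_lengths <- function(tree) !is.null(tree$edge.length)
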