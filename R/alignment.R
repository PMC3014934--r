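# Amino-acid alignment container used throughout the package.
#
# An `aa_alignment` is a character matrix (rows = taxa, columns = sites) over
# the 20 amino acids plus '-', 'X' and '?'.  All three non-residue symbols are
# treated downstream as total ambiguity (uncertainty over all 20 residues),
# which is the usual supermatrix convention for gaps and missing genes.

#' Amino-acid residue alphabet
#'
#' The 20 standard amino acids in the conventional exchangeability-matrix
#' order (ARNDCQEGHILKMFPSTWYV).
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# symbols treated as completely ambiguous / missing
missing_symbols <- function() c("-", "X", "?")

#' Construct an amino-acid alignment
#'
#' @param x Either a character matrix (rows = taxa; single characters per
#'   cell) with row names, or a named character vector of equal-length
#'   sequence strings.
#' @return An object of class `aa_alignment`: a character matrix with taxa as
#'   row names.
#' @examples
#' aln <- aa_alignment(c(t1 = "ARND", t2 = "AR-D"))
#' n_taxa(aln); n_sites(aln)
#' @export
aa_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named by taxon")
    lens <- nchar(x)
    if (length(unique(lens)) > 1L) {
      stop("ragged alignment: sequence lengths differ (",
           paste(unique(lens), collapse = ", "), ")")
    }
    m <- if (length(x) == 0L || lens[1] == 0L) {
      matrix(character(0), nrow = length(x), ncol = if (length(x)) lens[1] else 0L)
    } else {
      do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    }
    rownames(m) <- names(x)
    x <- m
  }
  if (!is.matrix(x) || !is.character(x)) stop("x must be a character matrix")
  validate_alignment(structure(x, class = "aa_alignment"))
}

validate_alignment <- function(aln) {
  taxa <- rownames(aln)
  if (is.null(taxa) || any(!nzchar(taxa))) stop("taxon labels must be non-empty")
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon: ", paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  ok <- aln %in% c(aa_alphabet(), missing_symbols())
  if (!all(ok)) {
    bad <- which(!ok)[1]
    pos <- arrayInd(bad, dim(aln))
    stop("alphabet violation: character '", aln[bad], "' at taxon '",
         taxa[pos[1]], "', column ", pos[2])
  }
  aln
}

#' @rdname aa_alignment
#' @param aln An `aa_alignment`.
#' @export
n_taxa <- function(aln) nrow(aln)

#' @rdname aa_alignment
#' @export
n_sites <- function(aln) ncol(aln)

#' @rdname aa_alignment
#' @export
taxa <- function(aln) rownames(aln)

#' Logical matrix marking missing/ambiguous cells
#' @param aln An `aa_alignment`.
#' @return Logical matrix of the same shape as `aln`.
#' @export
is_missing_cell <- function(aln) {
  matrix(aln %in% missing_symbols(), nrow = nrow(aln),
         dimnames = dimnames(aln))
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Amino-acid alignment:", nrow(x), "taxa,", ncol(x), "sites\n")
  miss <- mean(is_missing_cell(x))
  cat(sprintf("  missing/ambiguous cells: %.1f%%\n", 100 * miss))
  show <- utils::head(rownames(x), 5)
  for (t in show) {
    s <- paste(x[t, seq_len(min(50, ncol(x)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", t, s, if (ncol(x) > 50) "..." else ""))
  }
  if (nrow(x) > 5) cat("  ...", nrow(x) - 5, "more taxa\n")
  invisible(x)
}

# subset preserving class; i = taxa, j = columns
#' @export
`[.aa_alignment` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  structure(out, class = "aa_alignment")
}

# convert rows to named sequence strings
alignment_strings <- function(aln) {
  stats::setNames(apply(unclass(aln), 1, paste, collapse = ""), rownames(aln))
}
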