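# Molecular-signature detection: short insertions at the junctions of
# tandem-repeat proteins (the classic case being 1-2 extra residues between
# consecutive 76-residue ubiquitin monomers in polyubiquitin), and anchored
# insertions at a fixed reference position of a conserved protein.
#
# Scoring is plain match/mismatch with affine gaps: these signatures live in
# highly conserved proteins where identity alignment suffices and the
# behaviour is exactly testable.

#' The canonical 76-residue ubiquitin monomer
#'
#' Ubiquitin is essentially invariant across eukaryotes; this is the
#' standard monomer sequence used as the default tandem-repeat reference.
#' @return A 76-character string.
#' @export
ubiquitin_monomer <- function() {
  paste0("MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQL",
         "EDGRTLSDYNIQKESTLHLVLRLRGG")
}

# constant match/mismatch substitution matrix over the protein alphabet
identity_submat <- function(match = 1L, mismatch = -1L) {
  letters <- c(Biostrings::AA_ALPHABET)
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

align_pair <- function(pattern, subject, type,
                       match = 1, mismatch = -1,
                       gap_open = 3, gap_extend = 1) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(pattern), Biostrings::AAString(subject),
    substitutionMatrix = identity_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend, type = type)
}

#' Scan a protein for tandem monomer repeats and junction insertions
#'
#' Decomposes `query` into successive matches of the reference monomer by
#' repeated semi-global alignment (the whole monomer against the remaining
#' query). Residues falling between the end of monomer `i` and the start of
#' monomer `i + 1` are reported as the junction-`i` insertion when they are
#' at most `max_insert` long; longer inter-monomer stretches are flagged as
#' non-canonical. Terminal fragments shorter than half a monomer are
#' reported as tails, not monomers (sequence fragments routinely truncate
#' the last copy).
#'
#' @param query Protein sequence (string), at least one monomer long.
#' @param monomer Reference monomer (string), at least 20 residues.
#' @param max_insert Maximum canonical junction-insertion length (default 2).
#' @param min_identity Minimum per-monomer identity to the reference
#'   (default 0.6); if the first monomer fails this, the query is not a
#'   tandem repeat of the reference and an error is raised.
#' @return Object of class `junction_report`: `monomer_count`, `junctions`
#'   (data frame: `junction`, `insertion`, `score`, `identity`,
#'   `non_canonical`), `leading_tail`, `trailing_tail`.
#' @export
scan_tandem_insertions <- function(query, monomer = ubiquitin_monomer(),
                                   max_insert = 2L, min_identity = 0.6) {
  L <- nchar(monomer)
  if (L < 20L) stop("monomer must be at least 20 residues")
  if (nchar(query) < L) stop("query shorter than one monomer")
  pos <- 1L
  monomer_count <- 0L
  leading_tail <- ""
  trailing_tail <- ""
  jrows <- list()
  prev_gap <- NULL   # residues between previous monomer end and current start
  repeat {
    remaining <- substring(query, pos)
    if (nchar(remaining) < ceiling(L / 2)) {
      trailing_tail <- remaining
      break
    }
    if (nchar(remaining) < L) {
      # terminal partial monomer: compare against the monomer prefix
      pa <- align_pair(substr(monomer, 1L, nchar(remaining)), remaining,
                       type = "global")
      ident <- Biostrings::nmatch(pa) / nchar(remaining)
      if (ident >= min_identity) {
        monomer_count <- monomer_count + 1L
        if (!is.null(prev_gap)) {
          jrows[[length(jrows) + 1L]] <-
            data.frame(junction = length(jrows) + 1L, insertion = prev_gap,
                       score = Biostrings::score(pa), identity = ident,
                       non_canonical = nchar(prev_gap) > max_insert,
                       stringsAsFactors = FALSE)
        }
      } else {
        trailing_tail <- remaining
      }
      break
    }
    # search a bounded window so the *next* (leftmost) monomer copy is
    # found rather than an equally scoring later copy; widen once if the
    # junction stretch is unusually long
    for (wexp in c(20L, nchar(remaining))) {
      window <- substr(remaining, 1L, min(nchar(remaining), L + wexp))
      pa <- align_pair(monomer, window, type = "global-local")
      ident <- Biostrings::nmatch(pa) / L
      if (ident >= min_identity) break
    }
    if (ident < min_identity) {
      if (monomer_count == 0L) {
        stop("not a tandem repeat of the reference (identity ",
             sprintf("%.2f", ident), " < ", min_identity, ")")
      }
      trailing_tail <- remaining
      break
    }
    sub <- Biostrings::subject(pa)
    offset <- Biostrings::start(sub) - 1L
    if (monomer_count == 0L) {
      leading_tail <- substr(remaining, 1L, offset)
    } else {
      gap <- paste0(prev_gap, substr(remaining, 1L, offset))
      jrows[[length(jrows) + 1L]] <-
        data.frame(junction = length(jrows) + 1L, insertion = gap,
                   score = Biostrings::score(pa), identity = ident,
                   non_canonical = nchar(gap) > max_insert,
                   stringsAsFactors = FALSE)
    }
    prev_gap <- ""
    monomer_count <- monomer_count + 1L
    pos <- pos + Biostrings::end(sub)
  }
  junctions <- if (length(jrows)) do.call(rbind, jrows) else
    data.frame(junction = integer(0), insertion = character(0),
               score = numeric(0), identity = numeric(0),
               non_canonical = logical(0))
  structure(list(monomer_count = monomer_count, junctions = junctions,
                 leading_tail = leading_tail, trailing_tail = trailing_tail),
            class = "junction_report")
}

#' @export
print.junction_report <- function(x, ...) {
  cat("Tandem-repeat scan:", x$monomer_count, "monomers,",
      nrow(x$junctions), "junctions\n")
  if (nrow(x$junctions)) print.data.frame(x$junctions, digits = 3)
  if (nzchar(x$leading_tail)) cat("  leading tail:", x$leading_tail, "\n")
  if (nzchar(x$trailing_tail)) cat("  trailing tail:", x$trailing_tail, "\n")
  invisible(x)
}

#' Detect an insertion anchored at a fixed reference position
#'
#' Globally aligns `query` to `reference` and reports the residues inserted
#' between reference positions `anchor - 1` and `anchor` (1-based). The
#' insertion is only reported when the two flanking windows of `flank`
#' reference positions align with at most `max_flank_gaps` gapped columns
#' each; insertions or deletions elsewhere are listed separately.
#'
#' @param query,reference Protein sequences (strings).
#' @param anchor 1-based reference position; the insertion sits immediately
#'   before it. (Reference coordinate conventions differ between sources,
#'   so the anchor is a parameter, not a constant.)
#' @param flank Flank window size (default 10).
#' @param min_identity Minimum overall identity (default 0.6); below it an
#'   error ("reference mismatch") is raised.
#' @param max_flank_gaps Gapped columns tolerated per flank window.
#' @return Object of class `anchor_report`: `anchor`, `insertion` (possibly
#'   empty), `flanks_clean`, `identity`, `other_indels` (data frame of
#'   off-anchor indels with reference positions).
#' @export
detect_anchor_insertion <- function(query, reference, anchor, flank = 10L,
                                    min_identity = 0.6,
                                    max_flank_gaps = 1L) {
  nref <- nchar(reference)
  if (anchor - flank < 1L || anchor + flank - 1L > nref) {
    stop("anchor +/- flank must lie within the reference")
  }
  pa <- align_pair(query, reference, type = "global")
  ident <- Biostrings::nmatch(pa) / nref
  if (ident < min_identity) {
    stop("reference mismatch: identity ", sprintf("%.2f", ident),
         " < ", min_identity)
  }
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  # reference position *after* each alignment column
  rpos <- cumsum(ra != "-")

  at_anchor <- ra == "-" & rpos == anchor - 1L
  insertion <- paste(qa[at_anchor], collapse = "")

  # off-anchor indels
  ind <- which((ra == "-" | qa == "-") & !at_anchor)
  other <- if (length(ind)) {
    grp <- cumsum(c(1L, diff(ind) != 1L))
    do.call(rbind, lapply(split(ind, grp), function(ii) {
      data.frame(ref_pos = rpos[ii[1]],
                 type = if (ra[ii[1]] == "-") "insertion" else "deletion",
                 residues = paste(ifelse(ra[ii] == "-", qa[ii], ra[ii]),
                                  collapse = ""),
                 length = length(ii), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(ref_pos = integer(0), type = character(0),
               residues = character(0), length = integer(0))
  }
  rownames(other) <- NULL

  flank_gaps <- function(lo, hi) {
    cols <- which(rpos >= lo & rpos <= hi & !at_anchor)
    sum(ra[cols] == "-" | qa[cols] == "-")
  }
  clean <- flank_gaps(anchor - flank, anchor - 1L) <= max_flank_gaps &&
    flank_gaps(anchor, anchor + flank - 1L) <= max_flank_gaps
  if (!clean) insertion <- ""

  structure(list(anchor = anchor, insertion = insertion,
                 flanks_clean = clean, identity = ident,
                 other_indels = other),
            class = "anchor_report")
}

#' @export
print.anchor_report <- function(x, ...) {
  cat(sprintf("Anchor scan at reference position %d: %s\n", x$anchor,
              if (nzchar(x$insertion)) paste0("insertion '", x$insertion, "'")
              else "no insertion"))
  cat(sprintf("  overall identity %.2f; flanks %s\n", x$identity,
              if (x$flanks_clean) "clean" else "gapped"))
  if (nrow(x$other_indels)) {
    cat("  off-anchor indels:\n")
    print.data.frame(x$other_indels)
  }
  invisible(x)
}
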