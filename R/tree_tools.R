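# Topology enumeration, bipartitions and split support.

#' Bipartition (unrooted split) of a taxon universe
#'
#' @param side_a,side_b Character vectors of taxon labels; together they must
#'   partition the universe. Canonical form puts the side containing the
#'   lexicographically smallest taxon first.
#' @return An object of class `bipartition`.
#' @export
bipartition <- function(side_a, side_b) {
  side_a <- sort(unique(as.character(side_a)))
  side_b <- sort(unique(as.character(side_b)))
  if (length(side_a) == 0L || length(side_b) == 0L) stop("bipartition sides must be non-empty")
  if (length(intersect(side_a, side_b)) > 0L) stop("bipartition sides overlap")
  if (side_b[1] < side_a[1]) { tmp <- side_a; side_a <- side_b; side_b <- tmp }
  structure(list(side_a = side_a, side_b = side_b),
            class = "bipartition")
}

#' @export
print.bipartition <- function(x, ...) {
  cat(split_key(x), "\n")
  invisible(x)
}

#' @export
format.bipartition <- function(x, ...) split_key(x)

split_key <- function(bp) {
  paste(paste(bp$side_a, collapse = ","), paste(bp$side_b, collapse = ","),
        sep = "|")
}

#' Parse a split written as "a,b|c,d"
#' @param text A split string: two comma-separated taxon lists joined by `|`.
#' @return A [bipartition()].
#' @export
parse_split <- function(text) {
  halves <- strsplit(text, "|", fixed = TRUE)[[1]]
  if (length(halves) != 2L) stop("split must contain exactly one '|'")
  bipartition(strsplit(halves[1], ",", fixed = TRUE)[[1]],
              strsplit(halves[2], ",", fixed = TRUE)[[1]])
}

#' All bipartitions induced by the internal edges of a binary tree
#'
#' Trivial splits (one tip against the rest) are excluded. For unrooted
#' binary trees the count is `n - 3`.
#'
#' @param tree An `ape::phylo` tree (binary).
#' @return List of [bipartition()] objects.
#' @export
bipartitions <- function(tree) {
  if (!ape::is.binary(tree)) stop("non-binary tree")
  tips <- tree$tip.label
  n <- length(tips)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  out <- list()
  for (cl in pp) {
    a <- tips[cl]
    b <- setdiff(tips, a)
    if (length(a) <= 1L || length(b) <= 1L) next
    bp <- bipartition(a, b)
    k <- split_key(bp)
    if (!(k %in% keys)) {
      keys <- c(keys, k)
      out[[length(out) + 1L]] <- bp
    }
  }
  out
}

# label-invariant identity key for a topology: sorted split keys (unrooted)
# or sorted clade keys (rooted)
topology_key <- function(tree, rooted = ape::is.rooted(tree)) {
  tips <- tree$tip.label
  if (rooted) {
    pp <- ape::prop.part(tree)
    keys <- vapply(pp, function(cl) paste(sort(tips[cl]), collapse = ","), "")
  } else {
    keys <- vapply(bipartitions(tree), split_key, "")
  }
  paste(sort(keys), collapse = ";")
}

#' Exhaustively enumerate binary topologies
#'
#' Counts follow the double factorials: `(2n-3)!!` rooted and `(2n-5)!!`
#' unrooted. Five lineages therefore admit 105 rooted and 15 unrooted
#' topologies.
#'
#' @param tips Character vector of 2 to 8 tip labels.
#' @param rooted Enumerate rooted (`TRUE`) or unrooted (`FALSE`) topologies.
#' @return A `topology_set`: list with `universe`, `trees`, `constraint`.
#' @export
enumerate_topologies <- function(tips, rooted = TRUE) {
  tips <- as.character(tips)
  n <- length(tips)
  if (anyDuplicated(tips)) stop("duplicate tip labels")
  if (n < 2L) stop("need at least 2 tips")
  if (n > 8L) stop("refusing to enumerate more than 8 tips (combinatorial explosion)")
  trees <- if (n == 2L) {
    t0 <- ape::read.tree(text = paste0("(", tips[1], ",", tips[2], ");"))
    list(t0)
  } else if (n == 3L && !rooted) {
    list(ape::read.tree(text = paste0("(", paste(tips, collapse = ","), ");")))
  } else {
    tl <- phangorn::allTrees(n, rooted = rooted, tip.label = tips)
    lapply(seq_along(tl), function(i) tl[[i]])  # expand multiPhylo tip labels
  }
  topology_set(tips, trees, constraint = NULL)
}

topology_set <- function(universe, trees, constraint = NULL) {
  trees <- lapply(trees, function(tr) {
    if (!setequal(tr$tip.label, universe)) stop("tree does not span the stated universe")
    tr
  })
  structure(list(universe = sort(universe), trees = trees,
                 constraint = constraint),
            class = "topology_set")
}

#' @export
print.topology_set <- function(x, ...) {
  cat("Topology set:", length(x$trees), "trees over",
      length(x$universe), "tips\n")
  if (!is.null(x$constraint)) cat("  constraint:", x$constraint, "\n")
  invisible(x)
}

#' @export
length.topology_set <- function(x) length(x$trees)

# attach a new tip above the root of a rooted tree
attach_above_root <- function(tree, label) {
  nwk <- write_newick(tree)
  ape::read.tree(text = paste0("(", sub(";\\s*$", "", nwk), ":1,", label, ":1);"))
}

# attach a new tip to every branch of a tree (and, if rooted, above the root)
attach_everywhere <- function(tree, label, rooted) {
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    out[[length(out) + 1L]] <-
      phytools::bind.tip(tree, label, edge.length = 1,
                         where = child, position = tree$edge.length[e] / 2)
  }
  if (rooted) out[[length(out) + 1L]] <- attach_above_root(tree, label)
  out
}

#' Graft floating tips into a fixed backbone
#'
#' Generates every topology obtainable by attaching the floating tips (in all
#' orders and positions) while preserving the backbone's internal structure,
#' de-duplicated by bipartition-set identity. With no floating tips the
#' result is the singleton set containing the backbone.
#'
#' @param backbone An `ape::phylo` tree.
#' @param floating Character vector of new tip labels (disjoint from the
#'   backbone's tips).
#' @return A `topology_set` over the union of tip sets.
#' @export
graft_into_backbone <- function(backbone, floating) {
  validate_tree(backbone)
  floating <- as.character(floating)
  if (length(intersect(backbone$tip.label, floating)) > 0L) {
    stop("floating labels overlap the backbone tips")
  }
  rooted <- ape::is.rooted(backbone)
  current <- list(backbone)
  for (lab in floating) {
    nxt <- list()
    for (tr in current) nxt <- c(nxt, attach_everywhere(tr, lab, rooted))
    # deduplicate by topology identity
    keys <- vapply(nxt, topology_key, "", rooted = rooted)
    current <- nxt[!duplicated(keys)]
  }
  current <- lapply(current, function(tr) { tr$edge.length <- NULL; tr })
  topology_set(c(backbone$tip.label, floating), current,
               constraint = paste0("backbone(", length(backbone$tip.label), " tips)"))
}

#' Fraction of trees containing a bipartition
#'
#' If a tree lacks some taxa of the query's universe the query is restricted
#' to the induced taxon set; a query side that becomes empty after
#' restriction counts as absent (with a warning).
#'
#' @param query A [bipartition()].
#' @param trees List of `ape::phylo` trees.
#' @return Fraction in `[0, 1]`.
#' @export
support_of <- function(query, trees) {
  if (inherits(trees, "topology_set")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- list(trees)
  hits <- vapply(trees, function(tr) tree_has_split(tr, query), NA)
  mean(hits)
}

tree_has_split <- function(tree, query) {
  tips <- tree$tip.label
  a <- intersect(query$side_a, tips)
  b <- intersect(query$side_b, tips)
  if (length(a) == 0L || length(b) == 0L) {
    warning("query side empty after restriction to tree taxa; counted absent")
    return(FALSE)
  }
  if (length(a) == 1L || length(b) == 1L) {
    # trivial after restriction: present in every binary tree on those taxa
    return(TRUE)
  }
  # an edge supports the (possibly restricted) query if it separates every
  # member of side a from every member of side b
  for (bp in bipartitions(tree)) {
    if ((all(a %in% bp$side_a) && all(b %in% bp$side_b)) ||
        (all(a %in% bp$side_b) && all(b %in% bp$side_a))) {
      return(TRUE)
    }
  }
  FALSE
}
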