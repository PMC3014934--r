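# Simulators for every input the pipeline needs: alignments evolved on trees
# under the engine's models (with optional fast-site classes), adversarial
# long-branch-attraction scenarios, multi-gene sets with per-taxon
# missingness, and tandem-repeat proteins with junction insertions.
#
# All generators are bit-reproducible under a fixed seed. Site-class labels
# are retained as attributes on simulated alignments so rate-estimation
# quality is directly testable.

#' Simulate an amino-acid alignment on a tree
#'
#' Root states are drawn from the model's stationary frequencies (per
#' mixture component); evolution proceeds along edges via the model's
#' transition matrices. Each site's rate is a discrete-gamma category draw
#' times its site-class multiplier.
#'
#' @param tree Tree with branch lengths.
#' @param model An [build_model()] object.
#' @param n_sites Number of columns to simulate.
#' @param seed Integer seed (deterministic output).
#' @param site_class_mix Optional list of `list(fraction, rate)` site
#'   classes; fractions must sum to at most 1, the remainder evolving at
#'   rate 1. Class labels are kept in `attr(, "site_class")` (0 =
#'   background).
#' @return An [aa_alignment()] with attributes `site_class`, `site_rate`
#'   (the realised per-site rate multiplier) and `category`.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed,
                               site_class_mix = NULL) {
  validate_tree(tree, require_lengths = TRUE)
  set.seed(seed)
  n_sites <- as.integer(n_sites)

  fractions <- vapply(site_class_mix, `[[`, 0, 1)
  if (sum(fractions) > 1 + 1e-12) stop("site-class fractions sum above 1")
  class_rates <- c(1, vapply(site_class_mix, `[[`, 0, 2))
  class_prob <- c(1 - sum(fractions), fractions)
  site_class <- sample.int(length(class_prob), n_sites, replace = TRUE,
                           prob = class_prob) - 1L

  cat_draw <- sample.int(model$k, n_sites, replace = TRUE)
  comp_w <- vapply(model$components, `[[`, 0, "weight")
  comp_draw <- sample.int(length(comp_w), n_sites, replace = TRUE,
                          prob = comp_w)
  site_rate <- model$cat_rates[cat_draw] * class_rates[site_class + 1L]

  tr <- reorder(tree, "postorder")
  nt <- length(tr$tip.label)
  nn <- nt + tr$Nnode
  states <- matrix(NA_integer_, nn, n_sites)
  root <- nt + 1L

  # root states per component
  for (m in seq_along(model$components)) {
    sel <- comp_draw == m
    if (any(sel)) {
      states[root, sel] <- sample.int(20, sum(sel), replace = TRUE,
                                      prob = model$components[[m]]$freqs)
    }
  }

  # preorder traversal: parents before children
  edges <- tr$edge[rev(seq_len(nrow(tr$edge))), , drop = FALSE]
  lens <- tr$edge.length[rev(seq_len(nrow(tr$edge)))]
  # group sites by (component, effective rate) so each edge needs one P per
  # group; rates repeat heavily across sites
  grp <- interaction(comp_draw, site_rate, drop = TRUE)
  grp_sites <- split(seq_len(n_sites), grp)
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; u <- edges[e, 2]
    for (g in grp_sites) {
      m <- comp_draw[g[1]]
      P <- transition_matrix(model, lens[e], rate = site_rate[g[1]],
                             component = m)
      parent_states <- states[p, g]
      for (a in unique(parent_states)) {
        sel <- g[parent_states == a]
        states[u, sel] <- sample.int(20, length(sel), replace = TRUE,
                                     prob = P[a, ])
      }
    }
  }

  mat <- matrix(aa_alphabet()[states[seq_len(nt), , drop = FALSE]], nrow = nt)
  rownames(mat) <- tr$tip.label
  aln <- aa_alignment(mat)
  attr(aln, "site_class") <- site_class
  attr(aln, "site_rate") <- site_rate
  attr(aln, "category") <- cat_draw
  aln
}

#' Long-branch-attraction scenario description
#'
#' A 5-tip true tree in which the two long-branch taxa are deliberately not
#' sisters, plus a fast-evolving site class capable of inducing their
#' artifactual grouping under a rate-homogeneous inference model.
#'
#' Defaults are the package's versioned adversarial preset (v2): long
#' branches of 2.5 and short branches of 0.025 expected substitutions/site,
#' 30\% of the sites in a fast class evolving 20 times faster, 5,000 sites.
#' These values were calibrated once so that a rate-homogeneous inference
#' model reliably commits the artifact; weaker settings (e.g. 1.5/0.05 with
#' a 30\% fast class at 8x) leave maximum likelihood consistent enough to
#' recover the true tree in most replicates.
#'
#' @param long_branch_length,short_branch_length Terminal branch lengths.
#' @param fast_class_fraction Fraction of sites in the fast class, in
#'   `[0, 1)`.
#' @param fast_class_multiplier Rate multiplier of the fast class.
#' @param n_sites Alignment length.
#' @param seed Integer seed.
#' @return An object of class `lba_scenario`.
#' @export
lba_scenario <- function(long_branch_length = 2.5,
                         short_branch_length = 0.025,
                         fast_class_fraction = 0.3,
                         fast_class_multiplier = 20,
                         n_sites = 5000L,
                         seed = 1L) {
  if (fast_class_fraction < 0 || fast_class_fraction >= 1) {
    stop("fast_class_fraction must be in [0, 1)")
  }
  structure(list(long_branch_length = long_branch_length,
                 short_branch_length = short_branch_length,
                 fast_class_fraction = fast_class_fraction,
                 fast_class_multiplier = fast_class_multiplier,
                 n_sites = as.integer(n_sites),
                 seed = as.integer(seed)),
            class = "lba_scenario")
}

#' Build a long-branch-attraction test case
#'
#' The generating tree is the unrooted 5-taxon topology
#' `((t_short_1, t_long_1), (t_short_2, t_long_2), t_out)`: the two long
#' branches sit on non-sister tips, so any grouping of `t_long_1` with
#' `t_long_2` is an artifact. Sequences are simulated under a
#' rate-homogeneous base process (LG) plus the scenario's fast site class;
#' an inference model without rate heterogeneity then misreads the fast
#' sites as convergence, pulling the long branches together.
#'
#' @param scenario An [lba_scenario()].
#' @param model Generating model (default LG with a single rate category;
#'   rate variation enters through the fast class).
#' @return List with `tree` (the generating tree), `alignment` (with
#'   site-class attributes), and `truth`: named [bipartition()]s
#'   (`true_split_1`, `true_split_2`, `lba_split`).
#' @export
make_lba_case <- function(scenario = lba_scenario(), model = NULL) {
  s <- scenario
  if (is.null(model)) model <- build_model("LG", alpha = 1, k = 1)
  nwk <- sprintf(
    "((t_short_1:%g,t_long_1:%g):%g,(t_short_2:%g,t_long_2:%g):%g,t_out:%g);",
    s$short_branch_length, s$long_branch_length, s$short_branch_length,
    s$short_branch_length, s$long_branch_length, s$short_branch_length,
    s$short_branch_length)
  tree <- parse_newick(nwk)
  mix <- if (s$fast_class_fraction > 0) {
    list(list(s$fast_class_fraction, s$fast_class_multiplier))
  } else NULL
  aln <- simulate_alignment(tree, model, s$n_sites, s$seed,
                            site_class_mix = mix)
  tips <- tree$tip.label
  truth <- list(
    true_split_1 = bipartition(c("t_short_1", "t_long_1"),
                               setdiff(tips, c("t_short_1", "t_long_1"))),
    true_split_2 = bipartition(c("t_short_2", "t_long_2"),
                               setdiff(tips, c("t_short_2", "t_long_2"))),
    lba_split = bipartition(c("t_long_1", "t_long_2"),
                            setdiff(tips, c("t_long_1", "t_long_2"))))
  list(tree = tree, alignment = aln, truth = truth)
}

#' Multi-gene set specification
#'
#' @param n_genes Number of genes.
#' @param taxa Taxon universe (character vector).
#' @param tree Shared generating tree over `taxa` (with branch lengths).
#' @param presence_prob Per-gene, per-taxon probability that the taxon is
#'   sampled for that gene (0.6 gives roughly 40\% global missingness).
#' @param gene_lengths Either an explicit integer vector of length
#'   `n_genes`, or `NULL` to draw lengths uniformly from
#'   `length_range`.
#' @param length_range Range for random gene lengths (default 120--320,
#'   mean 220 columns per gene).
#' @param seed Integer seed.
#' @return An object of class `gene_set_spec`.
#' @export
gene_set_spec <- function(n_genes, taxa, tree, presence_prob = 0.6,
                          gene_lengths = NULL, length_range = c(120L, 320L),
                          seed = 1L) {
  if (presence_prob < 0 || presence_prob > 1) stop("presence_prob must be in [0,1]")
  if (!is.null(gene_lengths) && length(gene_lengths) != n_genes) {
    stop("gene_lengths must have one entry per gene")
  }
  structure(list(n_genes = as.integer(n_genes), taxa = taxa, tree = tree,
                 presence_prob = presence_prob,
                 gene_lengths = gene_lengths,
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "gene_set_spec")
}

#' Simulate a multi-gene alignment set with taxon dropout
#'
#' Genes are simulated independently on the shared tree; each taxon is
#' present in each gene with the spec's presence probability. A gene left
#' with fewer than 4 taxa is resampled (up to 100 tries). The output is
#' suitable for [concatenate()].
#'
#' @param spec A [gene_set_spec()].
#' @param model Generating model (default LG + gamma(0.5, K = 4)).
#' @return Named list of [aa_alignment()]s.
#' @export
make_gene_set <- function(spec, model = NULL) {
  if (is.null(model)) model <- build_model("LG", alpha = 0.5, k = 4)
  set.seed(spec$seed)
  lens <- if (!is.null(spec$gene_lengths)) {
    as.integer(spec$gene_lengths)
  } else {
    sample(spec$length_range[1]:spec$length_range[2], spec$n_genes,
           replace = TRUE)
  }
  presence <- matrix(NA, spec$n_genes, length(spec$taxa))
  for (g in seq_len(spec$n_genes)) {
    for (try in seq_len(100L)) {
      pres <- stats::runif(length(spec$taxa)) < spec$presence_prob
      if (sum(pres) >= 4L) break
      if (try == 100L) stop("could not sample a gene with at least 4 taxa")
    }
    presence[g, ] <- pres
  }
  gene_seeds <- sample.int(2^31 - 1, spec$n_genes)
  genes <- vector("list", spec$n_genes)
  names(genes) <- sprintf("gene%03d", seq_len(spec$n_genes))
  for (g in seq_len(spec$n_genes)) {
    full <- simulate_alignment(spec$tree, model, lens[g], gene_seeds[g])
    genes[[g]] <- full[spec$taxa[presence[g, ]], , drop = FALSE]
  }
  genes
}

#' Build a tandem-repeat protein with junction insertions
#'
#' Concatenates `n_monomers` copies of a monomer, inserting the given
#' residues at the stated junctions (junction `i` sits between monomers `i`
#' and `i + 1`). Optional point mutations perturb the copies.
#'
#' @param monomer Monomer sequence (string).
#' @param n_monomers Number of copies (>= 2).
#' @param insertions Named list or vector mapping junction index to an
#'   insertion string of at most `max_insert` residues.
#' @param mutation_rate Per-residue substitution probability (default 0).
#' @param seed Seed used when `mutation_rate > 0`.
#' @param max_insert Maximum insertion length (default 2).
#' @return A single protein sequence string.
#' @export
make_tandem_protein <- function(monomer, n_monomers, insertions = list(),
                                mutation_rate = 0, seed = 1L,
                                max_insert = 2L) {
  if (n_monomers < 2L) stop("need at least 2 monomers")
  ins <- rep("", n_monomers - 1L)
  if (length(insertions)) {
    ji <- as.integer(names(insertions))
    if (anyNA(ji) || any(ji < 1L) || any(ji >= n_monomers)) {
      stop("junction indices must be in 1..(n_monomers - 1)")
    }
    if (any(nchar(unlist(insertions)) > max_insert)) {
      stop("insertion longer than ", max_insert, " residues")
    }
    ins[ji] <- unlist(insertions)
  }
  copies <- rep(monomer, n_monomers)
  if (mutation_rate > 0) {
    set.seed(seed)
    copies <- vapply(copies, function(s) {
      ch <- strsplit(s, "")[[1]]
      hit <- stats::runif(length(ch)) < mutation_rate
      ch[hit] <- sample(aa_alphabet(), sum(hit), replace = TRUE)
      paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  paste0(paste0(copies[-n_monomers], ins, collapse = ""), copies[n_monomers])
}
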