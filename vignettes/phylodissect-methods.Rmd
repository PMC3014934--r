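---
title: "Dissecting supermatrix phylogenies: models, procedures and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting supermatrix phylogenies: models, procedures and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodissect)
```

## The problem this package addresses

Deep relationships among protist lineages are routinely inferred from
concatenated multi-gene amino-acid supermatrices. Such matrices are powerful
but fragile: a handful of fast-evolving sites or taxa can dominate the
signal, and systematic error — most famously long-branch attraction (LBA) —
can produce strongly supported wrong clades. phylodissect implements, as
reusable and tested components, the standard battery of robustness analyses
applied to such matrices:

* construction of the supermatrix itself (block trimming, gene filtering,
  partition-aware concatenation, missing-data accounting, taxon removal);
* a native amino-acid likelihood engine (empirical models, discrete-gamma
  rates, optional profile mixtures) exposing the per-site quantities the
  downstream procedures need;
* topology-averaged site-rate estimation and progressive fast-site removal
  with bootstrap monitoring of competing bipartitions;
* the approximately unbiased (AU) topology test and cross-validation model
  comparison;
* scans for rare genomic characters: short insertions at tandem-repeat
  (polyubiquitin) monomer junctions and anchored insertions in conserved
  proteins.

Everything can be exercised end to end on synthetic data; the simulators are
first-class, tested code.

## The likelihood model

The engine implements reversible continuous-time Markov models on the 20
amino acids. A model is built from an empirical exchangeability matrix $S$
(LG or WAG, taken from phangorn's tables) and a frequency vector $\pi$:
$Q = S\,\mathrm{diag}(\pi)$, diagonal set so rows sum to zero, rescaled so
the expected rate at stationarity $-\sum_a \pi_a Q_{aa} = 1$, i.e. branch
lengths are expected substitutions per site. Frequencies are either the
model's own or observed (+F) — residue proportions of the data matrix with a
pseudocount of 0.5 for residues absent from the alignment.

Among-site rate variation uses Yang's discrete gamma: $K$ equal-probability
categories (default $K=4$), category rates equal to the conditional means of
a $\Gamma(\alpha,\alpha)$ density within each quantile band (computed in
closed form from incomplete-gamma functions, so the rates average exactly 1).
The shape $\alpha$ is a fixed input per analysis (default 0.5, a typical
value for deep phylogenomic alignments); it is not profiled by default
because none of the downstream procedures are sensitive to modest
misspecification of $\alpha$, only to the induced ranking of sites.

Site-heterogeneous composition is supported as a finite profile mixture:
components $(\pi_m, w_m)$ each get their own normalised rate matrix, and the
site likelihood marginalises components and gamma categories. This provides
a tractable stand-in for Dirichlet-process mixture models in the
cross-validation framework; it is not an approximation of any particular
published mixture.

$P(t)$ is computed by symmetric eigendecomposition of
$\mathrm{diag}(\pi)^{1/2} Q\, \mathrm{diag}(\pi)^{-1/2}$ — reversibility
guarantees a real spectrum and a numerically stable exponential. Felsenstein
pruning runs over compressed site patterns in compiled code, with per-column
rescaling to avoid underflow. Gap, `X` and `?` are all treated as total
ambiguity (all-ones partials); a fully missing column therefore has
likelihood exactly 1, which keeps the likelihood of 40%-missing
concatenations well defined.

Branch lengths are optimised coordinate-wise: per-edge Brent line searches
using inside/outside partials, swept until the total log-likelihood improves
by less than `tol` (default `1e-6`, at most 30 sweeps), with lengths clamped
to $[10^{-8}, 20]$. The total never decreases across sweeps. There is
deliberately **no heuristic topology search**: maximum likelihood is exact
over an explicitly enumerated (or backbone-constrained) topology set. The
questions this package targets involve a handful of focal lineages — five
lineages admit 105 rooted topologies — so exhaustive evaluation is feasible
and removes search stochasticity from every downstream resampling procedure.

## Site rates and fast-site removal

Site rates are empirical-Bayes posterior means over the gamma categories,
$\hat r_i = \sum_k r_k w_k L_{ik} / \sum_k w_k L_{ik}$ (mixture components
marginalised). Category *assignments* (the other common convention) were
rejected because the posterior mean varies smoothly and breaks far fewer
ties when ranking sites. Because the ranking depends on the assumed
topology, rates are averaged over every topology in the candidate set, each
with independently optimised branch lengths.

Removal percentages refer to **cumulative rate mass**, not site counts:
columns are sorted by rate (descending, ties by column index for
reproducibility) and the minimal fastest prefix whose rates sum to the
requested percentage of the total is removed. With a long-tailed rate
distribution this retains far more than $100-p$ percent of the sites — e.g.
removing 90% of the rate mass of a 36,735-column matrix with gamma-like
rates typically leaves well over a third of the columns (a site-count
reading would leave exactly 10%), which is the behaviour real
phylogenomic matrices show under this protocol. A `site_fraction` mode is
provided for comparison.

The default schedule is the 14-step ladder 5, 10–50 by 10, 55–90 by 5 (in
percent). `support_curves()` reduces the matrix at each step, bootstraps the
topology set (each step's seed derived deterministically from the master
seed and step index), and records the fraction of replicate winners
containing each monitored bipartition. Posterior-probability columns are
emitted as `NA` placeholders so tables keep the shape of companion Bayesian
analyses, which are out of scope here.

## Bootstrap

The nonparametric bootstrap resamples alignment columns with replacement to
the original length and reruns the topology-set ML per replicate. Replicate
fits are warm-started from the full-data optima and use a looser
convergence tolerance (0.05 lnL by default): support values depend only on
which topology wins each replicate, not on the final decimals of its branch
lengths. Internally a replicate is just a re-weighting of site patterns, so
no sequence data are copied.

## AU test and cross-validation

The AU test is implemented natively via the multiscale bootstrap: at scales
$r \in \{0.5,\dots,1.4\}$, RELL resampling of the per-site log-likelihood
matrix ($\lceil rn \rceil$ columns, 1000 replicates per scale by default,
drawn as multinomial weights), winning proportions
$\mathrm{BP}(r)$, then a weighted least-squares fit of
$\Phi^{-1}(1-\mathrm{BP}(r)) = d\sqrt{r} + c/\sqrt{r}$ and
$p = 1 - \Phi(d - c)$. Candidates that never (or always) win are reported
with $p$ 0 (or 1) and an explicit diagnostic flag rather than a fabricated
fit; fits with fewer than two informative scales are likewise flagged.

One calibration subtlety is worth recording. For a *single realised* sample
of i.i.d. symmetric site-wise log-likelihood differences, the realised mean
difference is $O_p(\sqrt{2/n})$, which tilts the resampled winning
proportions by about one standard deviation; per-dataset $p$-values are then
spread over a wide range even though their average is one half. The
package's calibration check therefore uses an *exactly* symmetric sample
(each difference paired with its negation), under which both candidates'
$p$-values concentrate at 0.5 up to Monte-Carlo error — this is the property
the test can and should satisfy.

Cross-validation splits the columns without replacement into a learning set
(fraction 0.9, half-up rounding — a 36,735-column matrix learns on 33,062
and tests on 3,673 positions) and scores each candidate's test-set
log-likelihood after fitting branch lengths on the learning set, repeated
over 10 random splits. The framework is candidate-agnostic (any
model+topology pair); the shipped comparison contrasts a site-homogeneous
model with a profile mixture, the classic adequacy question for
compositionally heterogeneous matrices.

## Block trimming

`trim_blocks()` follows the Castresana block-selection algorithm with the
parameter set standard in this literature: a column is usable if at most
half its rows are gapped; "conserved"/"highly conserved" means the most
frequent residue occurs in at least 50% of taxa plus one; contiguous
non-conserved runs longer than 12 are rejected; blocks are trimmed back to
highly conserved flanks; gap-saturated columns and adjacent non-conserved
stretches are removed; surviving blocks must span at least 5 columns.
Trimming is idempotent (verified property). Paralogy and
focal-group-presence flags on genes are curation *inputs* — in real use they
come from inspecting single-gene trees — so the filter only does the
bookkeeping, with paralogy taking precedence for doubly flagged genes.

## The synthetic-data generators

`simulate_alignment()` draws root states from $\pi$, evolves them along the
tree with the model's own transition matrices, and assigns each site a
gamma-category draw times an optional site-class multiplier. Class labels
are retained as attributes, which turns qualitative claims ("fast sites
mislead the tree") into assertable tests. `make_gene_set()` emulates the
shape of a real multi-gene matrix: independent genes on a shared tree with
per-taxon presence probability (0.6 reproduces the ~40% global missingness
typical of EST-based supermatrices; genes are re-drawn if fewer than 4 taxa
remain, so with few taxa the realised missingness sits below the nominal
rate).

The adversarial LBA preset (`lba_scenario()`) places two long branches
(2.5 substitutions/site) on non-sister tips of a 5-taxon tree with short
branches of 0.025, and puts 30% of sites in a fast class evolving 20 times
faster; inference is done under a deliberately rate-homogeneous model
($K=1$). This preset was calibrated once, by simulation, to sit in the
regime where the artifact is decisive on the full data *and* reversible by
removing half of the estimated rate mass: markedly weaker settings (long
1.5, short 0.05, 30% at 8x) leave ML close enough to consistency that the
true tree usually wins anyway, while much hotter/larger fast classes carry
so much of the rate mass that the 50% step cannot excise them (or the
remaining signal is too thin and support collapses into noise, as in the
deepest removal steps of real analyses). The calibrated values are versioned
here and are not free knobs of the test suite.

What the simulators deliberately do **not** emulate: indels within genes,
compositional drift across lineages, codon structure, or alignment error.
Passing tests therefore demonstrate the correctness and qualitative
behaviour of the procedures, not that any particular empirical dataset is
artifact-free.

## Signature scans

`scan_tandem_insertions()` decomposes a query into successive monomer
matches by repeated semi-global alignment (whole monomer vs. a bounded
window of the remaining query — bounding the window guarantees the
*leftmost* matching copy is taken, so junction residues are attributed to
the junction where they occur). Identity scoring with affine gaps is used
instead of a substitution matrix: these signatures live in essentially
invariant proteins (the 76-residue ubiquitin monomer ships as the default
reference), identity alignment suffices, and the behaviour is exactly
testable. Residues between consecutive monomer matches are the junction
insertion; stretches longer than 2 are flagged non-canonical rather than
silently accepted; terminal fragments shorter than half a monomer are
reported as tails because real transcript fragments truncate the last copy.

`detect_anchor_insertion()` globally aligns query to reference and reports
residues inserted between reference positions `anchor-1` and `anchor`, but
only when both 10-residue flank windows align nearly gap-free — an
insertion reported at a ragged anchor is more likely alignment noise.
Because published coordinates for such anchors differ by one depending on
the author's convention, the anchor is a parameter, never a constant.

## Problem sizes used in the shipped checks

The test-suite and acceptance computations run at deliberately modest,
fixed sizes chosen to make each property measurable with clear margins:
exhaustive pruning-vs-enumeration checks at up to 5 taxa / 4 sites / 2
categories; branch-length and rate-rank recovery at 10,000 sites; the LBA
dissection at the preset's 5,000 sites with 40 bootstrap replicates on the
full data and the 50% rate-mass step; AU calibration at 10,000 sites with
1,000 replicates per scale; cross-validation with 10 replicates of a
3,000-column mixture-generated alignment; 500 random junction-insertion
trials. These sizes are the package's own choices and are stated here so
results are reproducible as printed.

## Known limitations

* ML is exact only over the supplied topology set; for more than 8 tips the
  enumeration refuses and a backbone constraint must be used.
* No invariant-sites category, codon models or Bayesian sampling.
* The profile mixture is finite and user-supplied; it stands in for, but
  does not approximate, Dirichlet-process mixtures.
* The AU fit follows the standard multiscale formulation without the
  higher-order corrections found in dedicated implementations; degenerate
  candidates are flagged rather than corrected.
* `alpha` is fixed per analysis rather than estimated; an outer 1-D
  optimisation would be straightforward but is rarely what these
  procedures are sensitive to.
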