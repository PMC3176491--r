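---
title: "Triplet motifs in quantitative epistasis networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triplet motifs in quantitative epistasis networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emapMotifs)
```

# The model

An E-MAP screen reports, for each tested gene pair, an S-score: the
deviation of double-mutant colony growth from the neutral (multiplicative)
expectation. Negative S-scores mark aggravating epistasis — the classic
synthetic sick/lethal signature of genes that can compensate for each
other — and positive S-scores mark alleviating epistasis, where the loss of
one gene masks or suppresses the cost of losing the other. A compendium
assembled from several screens is a sparse symmetric matrix: published
yeast compendia measure roughly a fifth of all pairs, and the
`ScoreMatrix` container therefore stores only measured pairs, with the
count of source datasets behind each (cross-study duplicates are averaged,
as are conflicting orientations within one file — one symmetrization policy
everywhere).

Thresholding turns scores into a signed network. We take the extreme
X-percentile tails on each side (the `percentile` argument; 1 by default,
matching the usual choice of the extreme 1% of S-scores), so equal numbers
of positive and negative interactions enter by construction, up to ties.
Genes with fewer than two supra-threshold interactions are then excluded as
noise. Closed triplets — triangles in the signed network — fall into four
classes by their sign multiset (NNN, NNP, NPP, PPP), and within each
triplet the edges are ranked by S-score into positions i (most negative),
ii, iii (most positive). The class frequencies are compared against a null
model that preserves the network's signed degree sequence, and the
positions are cross-tabulated against functional annotation.

The interpretive targets are the mixed classes. In NNP triplets the
positive pair is typically a physically interacting intra-complex pair and
the spanned gene (both N edges) belongs to a second complex that supports
the first. In NPP triplets the negative pair typically shares a pathway
and the positive-node gene (both P edges) acts on that pathway in an
opposing, regulatory manner. `roleGenes()` extracts exactly these
distinguished nodes.

# Parameters that matter

* `percentile` (tail mass per side, percent; default 1, range (0, 50]).
  Nearest-rank cutoffs are taken symmetrically from the two ends of the
  sorted score vector: with n scores and k = ⌈nX/100⌉, the cutoffs are the
  k-th smallest and k-th largest scores, compared inclusively. This makes
  the two tails exact mirror images — negating every score maps the N edge
  set onto the P edge set exactly, a symmetry the tests exercise end to
  end. A score qualifying for both cutoffs (possible only in heavily tied,
  degenerate matrices) is assigned N when ≤ 0, else P, keeping one edge per
  pair deterministically.
* `minDegree` (default 2). The gene filter is one pass computed on
  thresholded degrees: a gene is judged on the interactions it *achieved*
  beyond the threshold, not on what survives after other genes are
  removed, so removal cascades do not propagate. An iterate-to-fixpoint
  mode is available (`iterate = TRUE`) for sensitivity analysis.
* `q` (attempted switches per edge and sign class; default 100) and
  `nRandom` (ensemble size; default 1000). Standard mixing allowances for
  edge-switching chains; both are explicit arguments and recorded in the
  `NullSummary`.
* `minCommon` (default 10) for profile correlations: Spearman rank
  correlations over fewer than ten shared partners are too unstable at
  E-MAP sparsity, so such pairs are skipped rather than down-weighted.
  Ties receive average ranks. Summaries report mean ± SD (SE alongside).

# The null model

Edge switching picks two edges of the same sign and exchanges endpoints,
rejecting any proposal that would create a self-loop or place a second
edge — of either sign — on an occupied pair. Each node's negative degree
and positive degree are thus preserved exactly and the graph stays simple,
with at most one edge per gene pair across both signs (matching the input,
where a pair has one S-score). The two sign classes are switched as
independent chains, but run in alternating blocks (default three rounds per
sign): each block resamples one sign's conditional distribution given the
other's current occupancy, a Gibbs-type scan whose stationary distribution
is uniform over simple signed graphs with the given signed degree sequence.
The tests verify this directly: on a small network the sampler's per-class
mean triangle counts match, within three Monte-Carlo standard errors at
5,000 draws, the exact expectation computed by exhaustively enumerating
every simple signed graph with that degree sequence.

z-scores use the sample SD (n−1). When the degree sequence is rigid (one
realizable graph) the SD is zero and z is reported as NA rather than
infinite; a network with fewer than two edges in both sign classes is
likewise rigid and short-circuits to a degenerate ensemble. Because
z = (observed − mean)/SD, |z| ≈ 2 corresponds to a two-sided normal
p ≈ 0.05, which is used as the conventional significance line.

Random streams derive from one user seed through a counter scheme
(multiplier modulo 2³¹−1), so ensembles are reproducible and individual
draws independent of evaluation order.

# Feature matching and statistics

For each triplet and annotation channel a 3-bit code records which edges'
gene pairs share the feature, in position order: `001` means only the most
positive edge shares it. Term channels (complex, pathway, phenotype, GO
function/process/location) share by term-set intersection; pair channels
(physical, curated genetic, homology) by membership of the pair relation.
All eight codes are retained. For a channel where each gene holds a single
term, sharing is transitive and two 1-bits force the third; multi-term
annotation and pair relations break transitivity, so the observed
frequencies of `110`, `101`, `011` are attached to the code table as a
diagnostic rather than collapsed away.

The Fisher cross-tabulation tests one (channel, pattern, class)
combination on the 2×2 table {in class, not} × {code matches, not}. The
two-sided p sums hypergeometric point probabilities not exceeding the
observed table's (with the conventional 1e-7 relative guard for
floating-point ties); the odds ratio is (ad)/(bc) with the Haldane 0.5
correction applied when any cell is zero. Patterns can be literal codes or
position aggregates ("any-bit-at-iii"); both are emitted because summary
figures of this kind can be read either way, and the Bonferroni family is
all tests emitted in the run, with the family size attached to the table.

Edge-context fold changes compare, per channel and sign, the
feature-sharing fraction of edges in a triplet context (any triplet, or a
specific class) against same-sign edges in no triplet; the baseline's fold
change is identically 1, empty or zero baselines are flagged undefined
rather than propagated, and significance is declared at Bonferroni p <
0.01. Positional gene-set enrichment is a one-sided hypergeometric test of
term over-representation among the distinct genes occupying a motif role,
against a caller-supplied universe — conventionally the post-filter network
genes, which is also the universe over which the GO term-frequency window
is counted.

GO annotations are first closed under the ancestor relation and then
restricted to terms annotating between 2 and 40 universe genes (inclusive)
— rare terms carry no power, common ones no specificity. Because removing
an over-frequent term can strand genes and lower frequencies recomputed
after the next closure, the close-then-filter pass is repeated to a
fixpoint, which makes the operation idempotent; a cycle in the parent map
is a hard error naming a member. Phenotypes get the single blanket term
`viable` removed and are otherwise used as published, since phenotype
vocabularies do not support a comparable frequency refinement. The deeper
ontology term refinement used alongside the 2–40 window in earlier
integrated-network work is not reproduced; the window plus closure is the
implemented behaviour and a known limitation.

# The synthetic study

`generateEmap()` emulates the statistical shape of an E-MAP compendium —
symmetric scores, ~78% missing values — with planted structure expressing
the two mixed-motif models:

* complexes: positive cliques (5 complexes of 4 genes by default),
  intra-complex scores N(+6, 1);
* complex bridges: one gene of the next complex linked negatively to every
  gene of the current one, N(−6, 1) — the supportive two-complex
  arrangement, yielding C(4,2) = 6 NNP triplets per bridge;
* pathway units: redundant pairs with scores N(−6, 1), adjacent units
  fully bridged by negative edges, yielding NNN triangles;
* regulators: each positively linked, N(+6, 1), to every member of two
  adjacent pathway units; since all pairs among those members are
  negative, each regulator seeds C(4,2) = 6 NPP triplets with itself at
  the positive node;
* background: N(0, 1) on all other measured pairs.

Structural means of ±6 against unit background noise place planted edges
far outside the background tails, so percentile cutoffs wide enough to
admit them (5% per side at the default sizes, used by
`recoveryExperiment()`) capture the planted structure cleanly; the default
census then contains exactly the planted 20/30/30/20 triplets plus
occasional background triangles. Planted pairs are exempt from the missing
mask by default so the structure is testable at small n (a flag disables
this); missingness is uniform unless `blockMissing` emulates the
fragmented per-study block structure of real compendia. What the generator
does *not* emulate: correlated measurement error within rows, the
empirical negative-skew of real S-score distributions, overlapping complex
membership, and dosage effects — so passing recovery tests demonstrate the
pipeline's correctness, not performance guarantees on real screens.

The accompanying truth object labels every planted gene and pair, and the
generated `AnnotationSet` mirrors the planted structure (complex and
pathway membership, module phenotypes plus a blanket `viable` term,
intra-complex pairs as the physical relation, planted negative pairs as
the genetic relation, and a `go_function` channel whose
`pathway_regulator` label the positional enrichment should rank first).

# Numerical and design choices

* Percentile estimator: nearest-rank, applied symmetrically from both ends
  of the sorted scores; no interpolation, so cutoffs are always observed
  scores and the subset property holds exactly between nested tail masses.
* Within-triplet ties in S-score are broken lexicographically on the
  sorted gene-pair labels, making position codes deterministic.
* Participation statistics (fraction of triplet edges negative, mean
  triplets per N and per P edge) are computed over edges in at least one
  triplet; edges in none form the baseline of the fold-change analysis
  instead.
* The per-gene sign-polarity test is a two-sided exact binomial against
  0.5, Bonferroni-corrected across genes with at least one edge.
* Merging weights each source matrix's pair score by its own
  `n_sources`, so merging is associative as well as order-invariant.
* Degenerate inputs are first-class: empty censuses flag their summaries
  undefined, empty baselines flag fold changes undefined, rigid degree
  sequences yield NA z-scores, and an empty tail side after thresholding
  warns but proceeds.

Problem sizes in the shipped tests and the acceptance script — 100-gene
synthetic studies, 200–500-draw ensembles, 5,000 draws for the exact-null
comparison on a 5-node network — were chosen as the smallest sizes at
which the planted-structure and calibration statements are comfortably
stable under seed variation.

# Known limitations

* The published compendium itself is not bundled; reproducing published
  dataset statistics requires the original supplementary tables, loaded
  via `readScoreMatrix()`/`mergeScoreMatrices()`.
* Homology detection is consumed as a precomputed pair list (all-vs-all
  `blastp`, E ≤ 0.01) rather than executed.
* GO channels are frequency-filtered per channel; a joint window across
  function/process/location would give slightly different term sets.
* Only 3-node motifs are enumerated; higher-order motifs, and
  mixture-model or Bayesian module detection, are out of scope.
* Whether the one-pass or the iterated degree filter matches the published
  1,752-gene network is undecidable without the original data; one-pass is
  the default and both are exposed.
```{r session}
sessionInfo()
```
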