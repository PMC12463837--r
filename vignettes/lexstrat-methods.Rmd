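---
title: "Lexical distances as a proxy for population structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lexical distances as a proxy for population structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexstrat)
```

## The problem and the model

Populations that are candidates for genomic sequencing initiatives often
have no usable genetic data, while the languages they speak are well
documented. Because language is transmitted vertically alongside genes,
lexical similarity between languages retains a signal of shared population
history — often a stronger one than geographic proximity, since linguistic
boundaries can act as barriers to gene flow even between neighbours.
`lexstrat` turns that observation into a quantitative sampling tool.

The core quantity is the **normalized Levenshtein distance** (LDN). For
two word forms $a$ and $b$ with the same meaning (gloss),

$$\mathrm{LDN}(a,b) \;=\; \frac{\mathrm{lev}(a,b)}{\max(|a|,|b|)} \in [0,1],$$

where $\mathrm{lev}$ is the strict Levenshtein edit distance
(unit-cost substitution, insertion, deletion; no transposition) and
lengths are counted in Unicode code points. The lexical distance between
two language varieties is the mean LDN over all glosses at which **both**
varieties have a recorded form ("pairwise-complete" averaging): a gloss
missing in one member of a pair is excluded from that pair's mean but
still contributes to every other pair. The number of shared glosses behind
each entry is retained as a `support` matrix, and `pairwise_ldn()` refuses
pairs whose support falls below `min_shared` (default 1), because a mean
over zero glosses is undefined and a mean over very few is unreliable.

Assumptions worth stating explicitly:

* **One form per cell.** Synonym sets are not averaged; when a cell lists
  variants separated by `/`, only the first is kept. This keeps the
  estimator deterministic and the wordlist compiler in control.
* **Orthography, not phonology.** Distances are computed on normalized
  orthographic strings (Unicode NFC, lower-cased, whitespace collapsed),
  not on phonetic transcriptions or sound classes. Comparisons are
  therefore only meaningful within a consistently transcribed wordlist.
* **No triangle inequality.** Length-normalized edit distance is not a
  metric, and no step in the pipeline relies on metricity.

## Recovering structure

Three standard views of the LDN matrix are provided, each behind a small
wrapper that fixes the package's conventions:

* `classical_mds()` — Torgerson MDS: double-centre the squared distances,
  eigendecompose, scale the top $k \in \{2,3\}$ eigenvectors by
  $\sqrt{\lambda}$. Averaged LDN matrices are generally non-Euclidean, so
  negative eigenvalues are expected: they are never used for coordinates
  but are reported in the embedding so distortion can be assessed, along
  with a residual stress (sum of squared distance discrepancies). Axes
  whose eigenvalue is numerically zero (below $10^{-12}$ of the spectral
  radius) are zero-padded and flagged `degenerate`. Reflection
  indeterminacy is resolved deterministically: each axis is flipped so the
  lexicographically smallest variety has a nonpositive coordinate, which
  makes plots and regression tests reproducible.
* `agglomerative()` — Lance–Williams agglomeration via `hclust`, with
  both **average linkage** (UPGMA) and **Ward** exposed. Both appear in
  practice for this kind of data and they answer slightly different
  questions (cophenetic fidelity vs compact clusters), so the package
  implements both rather than hiding the choice; average linkage is the
  default. Ward uses the squared-distance (`ward.D2`) convention so merge
  heights stay in distance units. `cut_tree(t, k)` removes the $k-1$
  highest merges.
* `neighbor_joining()` — Saitou–Nei NJ via `ape::nj`, exact on additive
  matrices. On non-additive input NJ can produce negative branch lengths;
  these are clamped to zero with a warning and the affected edge indices
  kept as an attribute, since a negative length is an artifact of the
  least-squares step, not interpretable structure.

Trees serialize to Newick at 15 significant digits; labels containing
Newick metacharacters are single-quoted.

## Comparing distance matrices

`mantel()` computes the Mantel correlation $r$ — the Pearson correlation
of the strict lower triangles — and a permutation p-value obtained by
jointly permuting rows and columns of the second matrix, with the add-one
convention $p = (\#\{|r^*| \ge |r|\} + 1)/(B + 1)$. Defaults: $B = 9999$
permutations, two-sided tail. Two caveats are built into the
documentation and the errors rather than papered over:

* with $n$ labels there are only $n!$ distinct permutations, so at
  $n = 3$ (six permutations) the achievable p-values are very coarse —
  a strong correlation can still have $p \approx 0.1$ or worse purely
  from resolution;
* a constant lower triangle makes Pearson correlation undefined and is
  rejected.

For the uncertainty of $r$ when the first matrix is lexical,
`mantel_ci()` uses a **gloss-level percentile bootstrap**: glosses are the
natural sampling unit of a wordlist, so each replicate resamples glosses
with replacement, recomputes the LDN matrix, and recomputes $r$; the
2.5/97.5 percentiles are reported. Replicates in which some pair loses all
shared glosses are discarded and counted. This choice (rather than, say, a
Fisher-z approximation) is stated because bootstrap-CI methods for Mantel
correlations are not standardized; gloss resampling is reproducible and
its coverage is testable by simulation, which the test suite does at a
scaled-down size (20 repetitions of 200 replicates).

`geo_matrix()` builds great-circle distances from homeland centroid
coordinates using the haversine formula on a sphere of mean Earth radius
6371.0088 km — preferred over the spherical law of cosines for numerical
stability at short range; the two agree to well under $10^{-6}$ km on
random pairs, which the tests verify. Geographic comparisons therefore
require a user-supplied gazetteer of centroids; none is bundled, because
choosing a "homeland point" for a population is a substantive decision
the package should not make silently.

When two matrices share only part of their labels, every comparison runs
on the sorted intersection and warns about what was dropped.

## Prioritizing varieties for sampling

Two selection strategies operationalize "maximize captured diversity with
minimal redundancy":

* `select_maximin()` — farthest-point greedy: start from the pair
  attaining the matrix maximum, then repeatedly add the variety whose
  minimum distance to the panel is largest. The greedy construction
  carries the classic 2-approximation guarantee for the maximin radius,
  which the tests verify against exhaustive search at small $n$. Ties are
  broken lexicographically for bit-reproducibility.
* `select_medoids()` — one representative per cluster: the member
  minimizing the sum of distances to its co-members.

`bridge_scores()` formalizes the notion of a **bridge population** — a
variety whose lexicon is intermediate between two language families,
suggesting contact or admixture. For each variety, let $d_1 \le d_2$ be
the ordered pair of (mean distance to its own cluster's other members,
mean distance to the closest foreign cluster); then
$s = 1 - d_1/d_2 \in [0,1]$. A well-nested variety has $s$ near 1; a
variety equidistant between clusters has $s = 0$. The score is a
silhouette-style ratio on the distance matrix rather than a function of
MDS coordinates, because coordinates are orientation-dependent and lossy.
The default reporting threshold `s < 0.15` marks a variety as a bridge;
it is a tunable flag, not a significance test. Varieties alone in their
cluster have no within-cluster distance and are reported as `NA` with a
`singleton` flag.

## The synthetic generator: what it emulates and what it does not

`simulate_wordlist()` generates wordlists with **known** family structure
so that recovery can be scored exactly. Per gloss, a single root word is
drawn; each family's ancestral form evolves from it along a branch of
length `between_family_depth`, and each variety's form evolves from its
family ancestor along `within_family_depth`. Evolution is per-character
i.i.d.: each character is substituted with probability
$p = \min(1, \texttt{edit\_prob} \times \text{branch length})$ and
deleted or followed by an insertion with probability $p/4$ each (indels
rarer than substitutions keeps word lengths stable); words never shrink
below one character. Missingness is uniform at random. An optional hybrid
variety draws each gloss from a lineage of donor family A with
probability `mix`, else from donor B — a one-variety model of lexical
admixture.

Reference configuration (the package's fixed study conditions, used by
the tests and the acceptance script): 3 families × 4 varieties,
60 glosses (a Swadesh-scale list), root words of 6 characters,
`edit_prob` 0.12, depths 0.3 within / 3.0 between families,
5% missingness, hybrid mix 0.5, pseudo-F<sub>ST</sub> coupling 0.9.
Divergence at these settings gives within-family LDN around 0.1 and
between-family LDN around 0.8 — clearly separated families, comparable to
the separation between real language families, with enough gloss-level
noise that averaging matters.

`simulate_coupled_fst()` produces an F<sub>ST</sub>-like matrix by
rescaling the generating tree's path lengths to $[0, 0.2]$ (a realistic
F<sub>ST</sub> range for human populations) and mixing with independent
uniform noise at weight $1 - \text{coupling}$. It is a rescaled tree
metric plus noise — **not** a coalescent quantity — and exists to test
matrix-comparison machinery with a known coupling strength.

What the generator does **not** emulate, and hence what passing tests do
not show about real data: sound change is not phonological (no regular
correspondences, no sound classes); borrowing is limited to the single
hybrid mechanism (no contact networks, no stratified loanword layers);
families are balanced and equidistant; missingness is uncorrelated with
anything. Real wordlists violate all four, so success on synthetic data
demonstrates that the *machinery* is correct, not that LDN resolves any
particular real language family.

## Numerical and interface choices

* Character unit: Unicode code point (no grapheme clustering, no digraph
  tokenization) — deterministic across platforms. Forms are NFC-
  normalized, case-folded and whitespace-collapsed on input so encoding
  artifacts cannot inflate distances; a form that is empty after
  normalization becomes missing. The missing-token set defaults to
  `{"", "NA", "?"}` and is configurable.
* The edit-distance kernel is a two-row dynamic program in C++ (via
  Rcpp), with the whole pairwise-matrix loop pushed down to C++; the test
  suite checks it against a pure recursion over edit scripts, a memoized
  variant, and `utils::adist`.
* Distance matrices are validated on construction: exact symmetry, zero
  diagonal, nonnegativity, range $[0,1]$ for lexical/genetic kinds.
  Labeled-CSV output is written at 17 significant digits so a write/read
  round trip is bit-exact; PHYLIP lower-triangle output carries 12.
* Determinism: every stochastic routine (`mantel`, `mantel_ci`,
  `simulate_*`) takes a mandatory seed; the CLI refuses stochastic
  subcommands without `--seed` and writes a manifest (version, full
  parameter set, seed, input checksums) next to each output.
* Tie-breaking: maximin and medoid selection break ties
  lexicographically. Agglomeration and NJ inherit the tie behaviour of
  `hclust`/`ape::nj`, which is deterministic for a fixed input order;
  ties in those criteria are measure-zero for continuous data.
* Test problem sizes: structure-recovery properties run on point sets of
  up to 12 points and trees of 4–10 taxa (200 random trees for the NJ
  exactness check); permutation-test calibration uses 500 null replicates
  at $n = 8$ with 999 permutations; end-to-end pipeline rates use 100
  seeded replicates of the reference configuration. These sizes make the
  stochastic checks stable while keeping the default suite fast.

## Known limitations

* LDN treats any two non-identical characters as equally different;
  regular sound correspondences (which a historical linguist would credit
  as similarity) are invisible to it.
* The bridge score attributes intermediacy to admixture, but language
  shift, chance resemblance, or uneven missingness can produce the same
  signature; it is a screening statistic, not an inference.
* Published F<sub>ST</sub> values typically cover only a few population
  pairs (the bundled Kenyan fixture has four pairs over four
  populations — not enough for a full 4×4 matrix, so analyses use the
  complete 3-population triangle). Mantel tests at such sizes have
  essentially no power, and their p-values are resolution-limited; the
  correlation point estimate is the informative quantity.
* Geographic distance between population *centroids* ignores range
  overlap, migration corridors, and within-population dispersion.
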