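---
title: "Satellite chemical-space maps from extended similarity indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Satellite chemical-space maps from extended similarity indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemmaps)
```

# The problem

A chemical-space map places the molecules of a library in a low-dimensional
space so that structurally similar compounds sit close together. The
canonical construction — PCA of the full N × N Jaccard–Tanimoto similarity
matrix — costs O(N²) similarity evaluations and an O(N²)-sized eigenproblem,
which rules it out for the library sizes modern collections reach. The
satellite idea is to keep only an S × N block of the matrix: S reference
compounds ("satellites") whose similarities to everything else carry enough
information to reproduce the geometry of the full map. Two questions then
arise: *which* molecules to pick as satellites, and *how many* are enough.
This package answers the first with extended-similarity-based rankings and
the second with distance-correlation quality curves.

# The model

## Extended (n-ary) similarity

For a set of N molecules with M-bit binary fingerprints, the column sums
$\Sigma = (\sigma_1,\dots,\sigma_M)$ summarize the whole set. With
$\Delta\sigma_k = |2\sigma_k - N|$ and an integer *coincidence threshold*
$\gamma$, column k is

* **1-similar** when $2\sigma_k - N > \gamma$ (most molecules share the on-bit),
* **0-similar** when $N - 2\sigma_k > \gamma$ (most share the off-bit),
* **dissimilar** otherwise (the column is close to an even split).

Both inequalities are strict; $\gamma$ decides how lopsided a column must be
before it counts as a coincidence. Imperfect coincidences are weighted by
$f_s(\Delta\sigma_k) = \Delta\sigma_k/N$ (and the dissimilarity counterpart
$f_d(\Delta\sigma_k) = 1 - (\Delta\sigma_k - N\,\mathrm{mod}\,2)/N$, stored
with every classification). The extended Jaccard–Tanimoto index is

$$ s_{eJT} \;=\; \frac{\sum_{1\text{-}s} \Delta\sigma_k / N}
                      {\#\{1\text{-}similar\} + \#\{dissimilar\}} $$

— a weighted count of shared on-bits over "on or contested" columns, the
n-ary generalization of a/(a+b+c). `extended_jt()` implements exactly this
form; a `weighted = TRUE` mode replaces the counting denominator with the
$f_s$/$f_d$-weighted one ($\sum_{1\text{-}s} f_s + \sum_d f_d$) for users who
prefer the fully weighted family, but the counting denominator is the
default because it is the plain reading of the index definition. With
N = 2 and $\gamma = 0$ the index collapses to the pairwise Tanimoto
coefficient, which the test suite verifies on thousands of random pairs.

All of $\Sigma$, $\Delta\sigma$ and the counts are kept in integer
arithmetic; division happens once, at the final ratio, so the fast paths
are bit-reproducible.

## Choice of $\gamma$

The index definition leaves $\gamma$ open. The package default is the
*parity* policy $\gamma = N \bmod 2$, the convention of the reference
implementations of these indices: it corrects the similarity margin for odd
set sizes so that a one-molecule majority in an odd set is not counted as a
coincidence. Any fixed integer $0 \le \gamma < N$ may be supplied instead.
For leave-one-out work the parity policy is re-derived at the reduced size
($\gamma = (N-1) \bmod 2$), while a fixed integer is reused unchanged — the
reduced set is a set of $N-1$ molecules and is treated as such.

## Complementary similarity and the medoid/outlier ranking

The complementary similarity of molecule i is $s_{eJT}$ of the library
without i. If removing i *raises* the set similarity, i was an outlier; if
the set stays heterogeneous, i sits in a dense, central region. Because the
index depends on the set only through $\Sigma$, all N leave-one-out values
come from one pass: compute $\Sigma$ once, subtract each row
($\Sigma - m_i$), and apply the rules at size N − 1. This is O(N·M), and
`complementary_similarity()` is tested to be *identical to the last bit* to
brute-force recomputation of every subset, and to scale linearly rather
than quadratically. Ties in the ranking are broken by the original row
index, so every downstream selection is deterministic.

## Satellite sampling strategies

Given the ascending ranking (medoid first), `sample_satellites()` produces
a full permutation whose prefixes are the nested satellite sets:

* `medoid` — ascending complementary similarity;
* `periphery` — descending;
* `medoid_periphery` — alternate both ends (odd picks from the medoid side,
  even picks from the outlier side) until the pointers meet;
* `uniform` — split the ascending order into `n_batches` (default 5)
  contiguous batches and take one molecule per batch per cycle, ascending
  within each batch. When N is not divisible by the batch count the first
  `N mod n_batches` batches carry the extra elements, and exhausted batches
  are skipped; round-robin cycling (rather than draining batch 1 first) is
  used because draining would simply replicate medoid sampling;
* `random` — a seeded uniform shuffle, the baseline that structured
  sampling must beat. Four structured schemes plus this baseline give the
  five methods compared in practice.

## Map construction and quality

`pca_embed()` mean-centres the columns of its input (no variance scaling —
similarity columns share a scale, and rescaling would distort the map) and
projects onto the top two principal components by exact SVD; rank-deficient
inputs are padded with a zero second component. PCA is deterministic up to
per-component sign, and every quality number in the package depends only on
pairwise distances between scores, so the sign ambiguity is immaterial; a
test flips signs explicitly and checks all metrics are unchanged.

The embedded objects are the *satellites*, with their similarities to all N
library molecules as features (the S × N block). This is the reading under
which the backward algorithm's endpoint S = N reproduces the full-matrix
map exactly, and it is what makes the forward algorithm cheap. The
alternative reading — embed all N molecules using S similarity features —
can be had by transposing the feature block, but it is not what the
algorithms here validate, so it is not a mode of the run functions.

**Backward** (`backward_run()`): embed the full N × N Tanimoto matrix once;
its pairwise PC-score distances are the reference. For every s = 3…N take
the first s satellites of the selection, embed their S × N block, and
correlate satellite-pair distances in the reduced map against the same
pairs sliced from the reference distances. The curve records Pearson r and
R² at every s; the reported budget is the smallest s whose metric reaches
the threshold (default 0.90, applied to R²; a flag switches to r — the
quality target "0.90" is stated for a correlation metric without fixing
which, and R² is the orientation-free choice this package treats as
canonical).

**Forward** (`forward_run()`): start with ⌈0.25·N⌉ satellites, embed, then
repeatedly add ⌈0.05·N⌉ more (ceiling, so every step adds at least one
molecule), re-embed, and correlate the distances among the *previous*
satellite set — the elements the consecutive maps share, exactly the
prefix, thanks to nesting — between the two embeddings. Stop when the
metric exceeds the threshold (strictly, matching the "greater than" reading
of the forward stopping rule, versus "at least" in the backward one) or the
library is exhausted. The full N × N matrix is never formed;
`satellite_features()` computes the S × N block directly from the bit
matrices.

Degenerate configurations (all satellite scores coincident, zero distance
variance) make the correlation undefined: `distance_correlation()` raises
an error when called directly, and the run functions record `NA` for that
curve point rather than fabricating a value.

## Diversity summary

`diversity_summary()` reports the mean of the N(N−1)/2 pairwise Tanimoto
similarities (lower = more diverse) and the mean pairwise distance in the
full-matrix 2-PC embedding (higher = more spread out). These are the two
global numbers used to order libraries by diversity before comparing how
many satellites each needs — less diverse libraries are expected to be
mappable with fewer satellites.

# Fingerprints and curation

`read_smiles()` ingests whitespace-delimited SMILES files;
`canonicalize_and_dedup()` canonicalizes through the RDKit, drops
unparseable SMILES (reporting each identifier), and removes duplicates by
canonical SMILES, keeping the first occurrence — the duplicate-removal
policy must pick a survivor and first-wins preserves input order. No salt
stripping or charge neutralization is performed; callers wanting heavier
curation should do it upstream. `compute_fingerprints()` generates

* `maccs` — 166 structural keys (the toolkit emits 167 positions with
  index 0 unused; it is dropped so the width is the advertised 166),
* `ecfp4` — Morgan circular fingerprint, radius 2, folded to 1024 bits
  (the standard equivalence for "ECFP4"),
* `rdkit` — the topological path fingerprint at 2048 bits, toolkit
  defaults,

through a bundled python helper, since the RDKit has no R port. Exact bit
patterns can drift across RDKit releases at the margins; everything
downstream of the fingerprint matrix is toolkit-independent.

# The synthetic generator

`generate_library()` exists so that every pipeline stage is testable
without downloads or a chemistry toolkit: each cluster is a random binary
template of a given on-bit density whose members are independent per-bit
corruptions at `flip_prob`; singletons are fresh random rows. The defaults
— 3 clusters × 20 molecules, 128 bits, density 0.30, flip probability
0.05, 5 singletons — were fixed once as a plausible miniature of a
clustered screening library: density ~0.3 matches short structural
fingerprints, 5% noise keeps clusters tight but not degenerate, and the
singletons provide unambiguous outliers for the ranking to find. At these
settings within-cluster similarity demonstrably exceeds cluster-to-singleton
similarity, and singletons carry the largest complementary similarities.

What the generator does *not* emulate: correlated bits (real fingerprint
bits co-occur through substructure nesting), heavy-tailed cluster sizes,
and bit-density gradients across a library. Passing tests on synthetic data
therefore demonstrate the correctness of the machinery — rankings,
selections, curves, stopping rules — not chemical conclusions about any
real library; those require real fingerprint matrices, which the package
ingests via the fingerprints module.

Problem sizes in the test suite and acceptance script (libraries of tens
of molecules, 64–256 bits, 10-seed replications, plus one 2 000 vs 20 000
row timing contrast) were chosen as the smallest scales at which each
property is meaningfully exercised.

# Numerical choices and limitations

* Integer arithmetic throughout the similarity kernels; one final division.
* `0/0` in the extended index (no 1-similar and no dissimilar columns,
  i.e. everything 0-similar) is defined as similarity 0 with a warning —
  the conservative choice, refusing to call a set similar on shared
  *absences* alone under a counting denominator.
* A pair of all-zero fingerprints has Tanimoto 0 by convention; the
  diagonal of the pairwise matrix is 1 for any non-empty fingerprint.
* Percentage-to-count conversions use ceiling, so the forward run always
  progresses.
* `N = 1` extended similarity is allowed but warned about (every bit
  coincides with itself); complementary ranking requires N ≥ 3 so each
  leave-one-out set is a genuine set.
* The backward algorithm still requires the full N × N matrix once — it is
  the validation mode. For large libraries the forward mode is the usable
  one; its cost is dominated by the S × N blocks of the final iterations.
* Quality curves need not be monotone in s: adding a satellite can
  transiently worsen the reduced map, which is why the curve records every
  satellite count rather than stopping at the first dip.
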