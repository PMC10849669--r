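---
title: "Methods: NNLS signature refitting, cosine-UPGMA trees, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NNLS signature refitting, cosine-UPGMA trees, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msigkit)
```

# Scope and data model

`msigkit` operates on mutation **count matrices**, not variant files. The
central objects are:

* `MutationalCatalog` — samples × channels non-negative integer counts with a
  channel schema and optional per-sample metadata;
* `SignatureSet` — channels × signatures probability matrix (columns sum
  to 1);
* `ExposureResult` — samples × signatures non-negative activities plus a
  per-sample r-norm;
* `DistanceMatrix` and `ClusterTree` — cosine distances and annotated UPGMA
  merge trees.

The built-in schema is SBS96: the six pyrimidine-strand substitutions
C>A, C>G, C>T, T>A, T>C, T>G crossed with the sixteen 5'/3' flanking-base
contexts, ordered substitution-major and context-lexicographic — the
de-facto COSMIC column order. Labels on the purine strand are rejected
rather than folded: folding to the pyrimidine strand is a property of the
raw variant calls, which this package never sees, so silently folding
labels would hide an upstream convention error.

# Signature refitting

For each sample with count vector $c \in \mathbb{Z}_{\ge 0}^{96}$ and
reference profiles $P \in [0,1]^{96 \times K}$, the exposures solve

$$\hat e = \arg\min_{e \ge 0} \lVert P e - c \rVert_2^2,$$

and the reported **r-norm** is the attained minimum — the sum of squared
residuals of the decomposition. Fitting is on **raw counts** by default, so
exposures are in mutation-count units and the r-norm is on the count scale;
`normalizeInput = TRUE` fits the normalized spectrum instead, which only
rescales each sample's problem (exposures then sum to ≈1). Fractions per
sample are derived afterwards by `relativeExposures()`, which is invariant
under that rescaling.

No sparsity pruning or signature pre-selection is applied: the estimator is
plain NNLS, and all K reference signatures compete. Users wanting sparser
attributions should subset the `SignatureSet` themselves.

## The solver

`nnlsSolve()` implements the Lawson–Hanson active-set algorithm:

* start with all coefficients at zero; repeatedly move the variable with the
  **largest dual component** (gradient of the objective) into the passive
  set, taking the lowest index on exact ties;
* solve the unconstrained least-squares problem on the passive set via QR;
  if any passive coefficient would go non-positive, step only as far as the
  first zero crossing and demote the variables that hit zero;
* stop when every excluded variable has dual component
  $\le 10\,\varepsilon \, \max(\lVert P^{\mathsf T} c\rVert_\infty, 1)$,
  a scale-aware tolerance ($\varepsilon$ = machine epsilon).

At termination the Karush–Kuhn–Tucker conditions hold: the gradient is ~0 on
positive coefficients and non-positive elsewhere, which the test suite
asserts directly. Rank-deficient passive sets (possible with duplicated
signatures) are handled by dropping the QR-dependent columns for that solve;
the entry rule makes such states rare. The outer loop is capped at
$3K$ iterations; exceeding the cap raises an explicit numerical-failure
error rather than returning a non-optimal point. For a 96-channel problem
with tens of signatures a solve is microseconds, so per-sample looping over
catalogs is not a bottleneck.

The independent correctness oracles in the tests are (a) exhaustive
enumeration of the $2^K$ supports — the NNLS optimum is the unconstrained
solution on its support, so this oracle is exact for the small $K$ tested —
and (b) a dense non-negative grid (step 0.01) in dimensions where that is
affordable, plus agreement with the unconstrained QR solution whenever that
solution is already non-negative.

# Cosine similarity and UPGMA

Similarity between non-negative vectors is the cosine
$u \cdot v / (\lVert u\rVert \lVert v\rVert) \in [0, 1]$; distance is
defined as $1 - \text{similarity}$ so that identical directions are at 0 and
disjoint supports at 1. Cosine is scale-invariant, so clustering on counts
or on normalized spectra is identical; `sampleTree()` normalizes anyway for
clarity of intent. An all-zero vector has no direction; its similarity to
anything is defined as 0 (maximally distant) with a warning, a convention
chosen so batch runs survive empty samples.

`upgma()` is the classic unweighted pair-group method: repeatedly merge the
closest pair of clusters; the merged cluster's distance to any other is the
size-weighted arithmetic mean of its members' distances; the new node sits
at **half** the merge distance, so leaves are at height 0, heights are
non-decreasing, and the tree is ultrametric (pairwise path length = twice
the height of the lowest common ancestor — asserted in the tests via Newick
re-parsing). Among exactly tied pairs the lexicographically smallest pair of
cluster indices (creation order, leaves first) is merged, making output
fully deterministic. The test oracle is a naive $O(n^3)$ re-implementation
that recomputes every inter-cluster distance from the original matrix, plus
a cross-check of heights against average-linkage `hclust`.

Node annotations follow the force-directed-tree view of a cohort: each
internal node carries (a) the cosine similarity between the **summed raw
count vectors** of its two child clusters — summing is the natural aggregate
and is scale-free under cosine — and (b) the total mutation count beneath
the node, which is conserved bottom-up by construction. A tree built from a
bare distance matrix has no vectors to aggregate, so `upgma()` leaves
annotations `NA`; `sampleTree()` and `doubleCluster()` fill them. Signature
trees get similarities but no mutation totals (a column of activities has no
mutation-count interpretation).

`doubleCluster()` orders a heatmap by clustering exposure rows and columns
independently and reading off each tree's left-to-right leaf order. No
optimal-leaf-ordering rotation is applied — the natural merge order is used,
and the sorted matrix is exported as-is, leaving color scaling to the
consumer.

Newick export writes branch length = parent height − child height (hence all
non-negative), internal labels = the similarity annotation to 4 decimals,
and heights in fixed notation trimmed at ~12 decimals so round-trips
preserve heights to well under 1e-9.

# Summary statistics

* `sampleSummary()` — per-sample totals and per-substitution-class
  subtotals; subtotals partition the total exactly.
* `compareSpectra()` — per-channel table of two normalized spectra and their
  difference, with the spectra's cosine similarity and the residual sum of
  squares $\sum_{ch} (a_{ch} - b_{ch})^2$.
* `groupedLogBoxplot()` — per-group boxplot statistics of **log10** total
  burden. The log base is a display choice (decades of mutation burden);
  quartiles use linear interpolation between order statistics (R type 7);
  whiskers sit at the most extreme observation within 1.5 × IQR of the
  quartiles, clamped so they never retract past the box edges — with
  interpolated quartiles the most extreme in-fence point can otherwise fall
  inside the box; outliers are the points beyond the fences. Zero-total
  samples are excluded with a warning rather than erroring: log of zero is
  undefined, and a single empty sample should not kill a cohort summary.

# The synthetic benchmark

`generateCatalog()` draws, per sample: a uniform choice of
`exposuresActivePerSample` active signatures, Dirichlet(1) relative weights,
a lognormal total burden, exposures = weights × burden, expected counts
$P e$, and observed counts by the chosen noise mode (independent Poisson per
channel; multinomial with the rounded burden as total; or the rounded
expectation for `"none"`). Signature profiles are symmetric Dirichlet draws
over the 96 channels. Ground truth is returned exactly as drawn, and its
`rnorm` slot records the squared deviation of the observed counts from the
noise-free expectation.

Default parameters, fixed once:

| parameter | default | rationale |
|---|---|---|
| `nSamples` | 50 | a small cohort, enough for stable recovery averages |
| `nSignatures` | 5 | typical size of an informative refit panel |
| `exposuresActivePerSample` | 3 | sparse etiologies per tumor |
| `burdenMean` | 5000 | mutations/sample, a whole-genome-scale burden |
| `burdenDispersion` (CV) | 1.0 | heavy right tail, mimicking the orders-of-magnitude spread of per-cancer-type burden |
| `signatureConcentration` | 0.1 | peaked, COSMIC-like profiles; 1 would be flat-random, ≫1 near-uniform |
| `noise` | `"poisson"` | count sampling noise |
| `seed` | 20240119 | fixed benchmark stream |

Randomness is one seeded stream per entity: profiles at `seed`, sample *i*
at `seed + i`, so enlarging a cohort never reshuffles existing samples.

What the simulator emulates: sparse signature activity, bursty per-sample
burden, Poisson/multinomial counting noise, and exact ground truth. What it
does **not** emulate: trinucleotide opportunity (genome content), correlated
signatures (real COSMIC signatures can be near-collinear, which makes
refitting much harder than on independent Dirichlet draws), inter-sample
contamination, or caller artifacts. Passing the recovery benchmark therefore
demonstrates solver and pipeline correctness, not attribution accuracy on
real tumors with collinear references.

Benchmark sizes used throughout the tests and the acceptance script — 50-
to 100-sample catalogs, 200 small NNLS instances, 100 random distance
matrices with n ≤ 8, 100 random boxplot groups — keep the whole suite in the
tens of seconds while still exercising every degenerate branch (empty
samples, duplicated signatures, rank deficiency, ties at zero distance).

# Degenerate inputs, by policy

* zero-count sample → zero exposures, r-norm 0; all-zero spectrum; excluded
  from log boxplots (warning); maximally distant in cosine (warning);
* all-zero activity row in `relativeExposures()` → zero fractions plus a
  warning;
* empty portal-JSON array → an error (`no records`), not an empty catalog —
  silently empty results hide upstream failures;
* duplicate sample ids, unknown channel labels, negative or fractional
  counts → errors naming the offending id/label/row.

# Known limitations

* Only the SBS96 schema is built in; DBS/ID schemas would need a schema
  object and parser of their own.
* NNLS gives point estimates; no uncertainty on exposures.
* UPGMA is sensitive to ultrametric violations in the data; no bootstrap
  support values are computed.
* The portal-style JSON dialect is an emulation of API-shaped payloads
  (field names `sample`/`profile`/`matrix`/`mutationType`/`mutations`), not
  a pinned external contract.
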