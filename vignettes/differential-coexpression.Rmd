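---
title: "Differential co-expression networks across diagnostic states: methods and design"
author: "coexdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression networks across diagnostic states: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexdiff)
```

## The problem

Blood gene-expression profiles of cognitively normal subjects (NC), subjects
with mild cognitive impairment (MCI) and subjects with Alzheimer's disease
(AD) can differ not only in *which* genes are expressed, but in *how genes
are co-expressed*: a pair of transcripts tightly correlated in healthy blood
may decouple in disease, or vice versa. `coexdiff` implements a pipeline
that makes those co-expression changes explicit. Its stages are:

1. **Diagnosis merge.** Each expression sample is labelled with the
   diagnosis recorded on or nearest to its collection date.
2. **Probe filtering.** RMA-normalized log2 intensities are de-normalized
   (`2^x`) and probes are filtered in two stages: a variation/intensity
   filter, then a one-way ANOVA across the three diagnostic groups.
3. **Per-state signed networks.** For each state, pairwise Pearson
   correlation matrices are thresholded into a positive network
   (edges with `r > T`) and a negative network (`r < -T`).
4. **Rewiring scores.** A per-node statistic quantifies how much each
   probe's connections change across the three state networks.
5. **Consensus differential network.** Edges gained or lost in *both*
   condition states (MCI and AD) relative to the NC reference.

## Models and statistics

### Probe filter cascade

On the linear (de-normalized) scale, a probe is retained by stage 1 when

* its coefficient of variation `sd/mean` (sample standard deviation, `n-1`
  denominator, pooled over **all** samples regardless of group) lies in
  `[cv_min, cv_max] = [0.7, 10]`, and
* at least `min_frac = 20%` of samples have intensity **strictly greater**
  than `intensity_cut = 100`.

Stage 2 keeps stage-1 survivors whose one-way fixed-effects ANOVA across
the NC/MCI/AD groups has `p < 0.1` (strict). The stage order is
variation/intensity first, then ANOVA; since both filters are per-probe
conjunctions, the final survivor set would be identical in either order —
only the intermediate report counts depend on it.

Two points were genuinely open and are resolved as configuration with the
following defaults:

* **ANOVA scale.** The de-normalization is described as being done "for the
  calculations", so the ANOVA runs on the linear scale by default;
  `filter_config(anova_scale = "log2")` switches it. At the validated
  sample sizes (about 100 per group) the F-test is robust to the mild
  skew that exponentiation introduces; the null-calibration checks in the
  test suite verify the retention fraction directly.
* **CV denominator.** Sample (`n-1`) standard deviation. The alternative
  (population sd) differs by a factor `sqrt((n-1)/n)` that is irrelevant at
  the sample sizes involved, but the choice is fixed for reproducibility.

Degenerate probes do not crash the cascade: a zero-mean probe has an
undefined CV and is excluded with a flag; a probe with zero variance
everywhere gets ANOVA `p = 1` (flagged); zero within-group variance with
differing means gets `p = 0` (flagged).

### Direction table

For each retained probe, each condition is compared with NC by a two-sided
Welch (unequal-variance) *t*-test on the same scale as the filters, and
p-values are FDR-adjusted (Benjamini–Hochberg by default; the adjustment
family is the retained probe set within one contrast — the contrasts are
adjusted separately). The display convention reproduces the published
table style: direction alone when adjusted `p <= 0.1`; direction plus the
p-value when `0.1 < p <= 0.75`; a bare dash when `p > 0.75`, regardless of
direction. These three bands partition `[0, 1]` exhaustively and
exclusively, which the test suite asserts at the band boundaries.

"FDR adjusted" is interpreted as Benjamini–Hochberg because it is the
standard default; Benjamini–Yekutieli is available via
`bh_adjust(method = "BY")` for dependence-robust adjustment.

### Signed networks

Thresholds are strict (`r > T`, `r < -T`), so a correlation exactly at the
threshold is excluded; the two sign classes are therefore disjoint for any
`T > 0`, and raising `T` can only remove edges. Two threshold levels are
built by default: `T = 0.1` feeds the network comparisons (it removes only
non-correlations, keeping the comparison sensitive to weak rewiring), and
`T = 0.3` gives the "basic" networks for direct inspection. Isolated nodes
are never dropped: the comparison stages require identical node sets across
states. Zero-variance probes (possible in a single state's subset) have
undefined correlations; these are set to 0 — i.e. no edges — and flagged.

### Rewiring score

For node `v`, let `a_s(v)` be its adjacency vector in state `s` — entries
0/1 in binary mode (the default: the thresholded edge tables are the
comparison input) or `|r|` in weighted mode — and let
`c(v) = mean_s a_s(v)` be the entrywise centroid. The score is

```
score(v) = sum_s || a_s(v) - c(v) ||^2
```

the variance of the node's connectivity around its across-state centroid,
summed over adjacency slots. Useful properties, each covered by a test:

* `score(v) = 0` iff `v` has identical adjacency in every state;
* the score is invariant under permutation of the states;
* it decomposes additively over adjacency slots; a slot present in exactly
  1 or 2 of 3 states contributes exactly 2/3.

The exact normalization used by interactive network-comparison tools to
print their scores is not standardized, so the score family is exposed as
configuration — `variant = "raw"` (default), `"degree"` (divided by the
node's mean degree) or `"unsquared"` (sum of Euclidean, not squared,
distances) — rather than hard-coding a guess. Ranked reports are cut off
at score 5 by default, with ties broken lexicographically by node ID so
that rankings are deterministic.

### Consensus differential network

Relative to the reference network (NC), an edge is **gained** when absent
from the reference and present in *every* condition network, and **lost**
when present in the reference and absent from *every* condition network.
Edges that change in only some conditions are deliberately in neither set.
The comparison runs separately per sign class — positive and negative edge
universes are never mixed — and the gained and lost sets are disjoint by
construction.

## The synthetic-data generator

Controlled-access clinical expression data cannot ship with a package, so
`simulate_expression()` generates studies with the statistical structure
the analysis assumes, plus a serialized ground truth enumerating exactly
what was planted.

* **Baseline.** Per-probe baseline log2 means are drawn once from
  `N(baseline_log2_mean = 7.5, baseline_log2_sd = 0.5)` and shared across
  states; per-sample noise is `N(0, noise_sd = 1)` in log2 space. These
  magnitudes give linear-scale intensities of a few hundred with a CV near
  0.85 — typical of RMA summaries of blood arrays, and inside the 0.7–10
  filter window so that unstructured probes exercise the cascade
  non-trivially.
* **Differential expression** is planted as per-state log2 mean shifts.
* **Correlation blocks** use a single-factor model:
  `x = lambda * f + sqrt(1 - lambda^2) * eps` with `lambda = sqrt(|r|)`,
  shared factor `f` per state and block. Two members with same-sign
  loadings then have population correlation exactly `+|r|`; opposite-sign
  loadings give `-|r|`. This construction was chosen because the planted
  pairwise correlations are analytically known, which makes parameter
  recovery testable. A uniformly negative block target is representable
  only for 2-probe blocks (a single factor cannot make more than two
  variables mutually negatively correlated beyond `-1/(k-1)`); larger
  blocks plant negative correlations through an explicit loading split.
* **Diagnosis records** are dated at the collection date (configurable
  offset); optional decoy records at other offsets carry a different label
  so the nearest-date merge is exercised. Nearest-date ties break toward
  the earlier record, which keeps merges deterministic.
* **Determinism.** All draws happen in a fixed order under one seed;
  identical configurations are bit-identical, and fixtures written with
  full precision (17 significant digits) round-trip exactly through CSV.

What the generator does **not** emulate: batch and array effects, missing
values, probe-level cross-hybridization, heavy-tailed intensity noise, and
correlation structure beyond block factor models. Passing recovery tests
therefore demonstrates that the pipeline's inference machinery is correct
under its own model assumptions, not that any particular biological claim
about real cohorts is reproduced.

### Canned validation scenarios

Three canned configurations define the conditions under which the package
validates itself; sizes were chosen as the smallest at which the planted
signal is unambiguous by design rather than by tuning:

* `demo_config_rewired_hub()` — 30 probes, 150 samples/state, `r = 0.8`:
  a hub sharing a correlation block with nine partners in each state, but
  a *different* nine per state. The hub's planted binary rewiring score is
  18 (27 slots, each present in 1 of 3 states), far above what background
  sampling noise at `T = 0.1` produces for unstructured probes, so the hub
  should rank first.
* `demo_config_sign_flip()` — one 30-probe block, `|r| = 0.8` everywhere,
  with half the loadings negated in MCI and AD. Every cross-half pair
  flips from `+0.8` to `-0.8`: lost from the positive network, gained in
  the negative network, consistently in both conditions. Because every
  pair carries planted structure, consensus recovery has no null pairs
  whose sampling noise would contaminate precision. (A design that merely
  *omits* a block from the conditions cannot validate precision at
  `T = 0.1` with 150 samples: an absent edge still has a sample
  correlation, and the chance that |r| of a null pair crosses 0.1 in a
  given state is roughly 20%, flooding the lost set with false positives.
  The sign-flip design sidesteps this by making absence a planted fact.)
* `demo_config_small_study()` — 40 probes, 15 samples/state, with planted
  mean shifts and two blocks; this is the packaged fixture under
  `inst/extdata/fixture_small/` (synthetic data, stored at 6 significant
  digits to keep it small).

## Numerical and interface choices

* Welch tests, one-way ANOVA, BH adjustment and Pearson correlations are
  computed with R's `stats` primitives; the test suite checks them against
  naive closed-form oracles so the pipeline's use of them (alignment,
  grouping, family definition) is what is actually validated.
* Edge tables store `source < target` lexicographically, so edge identity
  is well defined and exports are stable. GraphML exports carry `weight`
  per edge and `sign`/`state`/`threshold` as graph attributes and
  round-trip through `import_graphml()`; SIF files use interaction type
  `pos`/`neg` (or `gained`/`lost` for differential networks) and list
  isolated nodes as single-column rows.
* The validation suite runs the oracle-equivalence checks on 50 random
  100-probe × 30-sample matrices (filter cascade) and 100 random
  8–10-node graph triples (rewiring, consensus), and the recovery and
  calibration checks at the canned-scenario sizes above plus a
  2000-probe × 300-sample null; these sizes make the whole suite complete
  in well under a minute on a single core while leaving the binomial
  envelopes of the calibration checks tight.

## Known limitations

* Pearson correlation is not invariant under the log/linear scale change;
  the package follows the convention of correlating de-normalized
  intensities, and offers log2-scale ANOVA but not (yet) log2-scale
  network construction as a switch — pass a log2 `ExpressionMatrix` to
  `build_state_networks()` directly if that variant is wanted.
* Rewiring scores come without significance assessment (no permutation
  p-values); the score ranks nodes, it does not test them.
* Probe-to-gene collapsing is out of scope: duplicate probes for one gene
  remain distinct nodes.
* The consensus rule is presence/absence logic on thresholded networks; it
  does not model effect sizes of correlation changes.
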