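---
title: "Methods: similarity networks for spiking populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity networks for spiking populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simnets)
```

## The problem

Large-scale extracellular recordings deliver spike trains from hundreds of
neurons at once, and a central question is which of those neurons are doing
*similar things* — processing related information, forming putative
functional subnetworks — without committing in advance to a tuning model or
a particular coding scheme. Correlation-based functional connectivity
compares spike trains *across* neurons at matched times and therefore
conflates similarity of computation with similarity of timing; two neurons
can encode the same variable with different temporal patterns, or with rate
versus spike-timing codes, and still deserve to be grouped together.

This package takes a different route: it compares neurons by the
**intrinsic geometry of their output spaces**. For each neuron we ask only
which of its own spike trains resemble which others; two neurons are
computationally similar when they agree about *which windows of the
experiment were alike*, regardless of what their spike trains look like.

## The pipeline

Given `N` simultaneously recorded neurons, each observed over the same `S`
equal-duration windows:

1. **Spike-train metric.** Distances between spike trains are measured
   with the Victor–Purpura edit distance: transforming one train into
   another costs 1 per inserted or deleted spike and `q · Δt` per second
   of spike displacement. The parameter `q` (units 1/s) sets the temporal
   accuracy `1/q` of the comparison: at `q = 0` the distance is the spike
   count difference (a pure rate comparison); large `q` penalizes timing
   differences down to milliseconds. The distance is computed exactly with
   the standard dynamic program in `O(|a||b|)` (`vp_distance()`).

2. **Fingerprints.** For each neuron, all `S(S−1)/2` pairwise distances
   among its own trains form its `S × S` SSIM matrix
   (`compute_ssims()`) — a "computational fingerprint" describing the
   relational structure of its responses. The total comparison count is
   exactly `N · S(S−1)/2`, linear in `N`.

3. **Computational similarity.** Fingerprints are compared across neurons
   with the Pearson correlation of their vectorized strict upper triangles
   (`cs_matrix()`), giving the `N × N` CS matrix. Pearson correlation is
   invariant to positive affine transforms, so neurons with proportional
   output-space geometries — at any absolute firing scale — score 1.

4. **Map and clusters.** The dissimilarity `d = 1 − r` is embedded with
   exact t-SNE initialized from classical MDS (`embed_map()`), and k-means
   with silhouette-based selection of the cluster number `Ksc`
   (`silhouette_curve()`, `select_k()`) proposes subnetworks.

5. **Validation.** A Mantel-style permutation test (`shuffle_test()`)
   jointly permutes the rows and columns of every neuron's SSIM matrix,
   destroying cross-neuron dependencies while preserving each matrix's
   symmetry, zero diagonal, and distance multiset. The silhouette curve of
   many such surrogates yields an acceptance band and a p-value for the
   observed cluster structure.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `q` | 10 | 1/s | temporal accuracy `1/q` of the spike-train metric; 0 = rate-only, 200 = 5 ms precision |
| `dims` | 3 (population map), 2 (single-neuron maps) | – | embedding dimension |
| `perplexity` | `min(30, floor((P−1)/3))` | points | t-SNE neighborhood size; clamped with a warning when too large for `P` points |
| `max_iter` | 1000 | – | t-SNE iterations |
| `k_range` | `2:min(20, N−1)` | clusters | candidate cluster numbers |
| `restarts` | 20 | – | k-means restarts per `k` (best by within-cluster SS) |
| `shuffles` (`M`) | 1000 | – | permutation surrogates; the add-one p-value is bounded below by `1/(M+1)`, so `M ≥ 1000` supports calls at `α = 0.01` with margin |
| `confidence` | 0.99 | – | coverage of the surrogate acceptance band |

There is no universally correct `q`: it is an analysis lens. Sweeping `q`
(e.g. 0, 10, 200) and comparing maps is the intended workflow; cluster
memberships that persist across `q` are rate-supported, those that appear
only at high `q` are timing-supported.

## Numerical and design choices

* **Window convention.** Stream segmentation uses half-open intervals
  `[start, start + duration)`, so a spike on a shared boundary is counted
  once, in the later window.
* **Diagonal exclusion.** The SSIM diagonal is identically zero by
  construction; including it in the Pearson vectorization would add `S`
  constant matched pairs to every comparison and mechanically inflate all
  correlations, so `cs_score()` correlates strict upper triangles only.
* **Similarity-to-distance map.** `d = 1 − r`, not `1 − |r|`:
  anticorrelated fingerprints disagree about which windows are alike and
  are treated as computationally dissimilar, not similar.
* **Degenerate fingerprints.** A constant off-diagonal (e.g. a silent
  neuron) makes the correlation undefined. Default policy excludes such
  neurons and logs them; a zero-fill policy retains them at similarity 0
  for users who need a fixed `N`.
* **Deterministic embedding.** t-SNE runs in exact mode (`theta = 0`) on
  the precomputed distance matrix, initialized from classical MDS of that
  same matrix (the distance-space analogue of PCA initialization, which is
  defined only for feature tables). MDS axis signs are fixed so each
  axis's largest-magnitude coordinate is positive. The result is
  bit-reproducible for fixed inputs, parameters and library versions.
* **Tie-breaking.** `select_k()` resolves silhouette ties toward the
  smallest `k` (parsimony).
* **p-value.** The add-one permutation estimator
  `p = (1 + #{max_k SC_surr ≥ SC_obs}) / (1 + M)` compares the observed SC
  at its own selected `Ksc` (itself a maximum over `k`) against the
  surrogate *maximum* over `k` — both sides undergo the same selection, so
  the comparison is exchangeable under the null and conservative. Per-`k`
  acceptance bands are also reported.
* **Fast versus full-fidelity null.** Re-running t-SNE for every surrogate
  is expensive and the null statistic does not need it. In the default
  fast mode each surrogate's k-means labels come from a 3-D classical-MDS
  projection of its CS distance matrix and silhouettes are evaluated on
  the CS distance itself; crucially the *observed* curve entering the
  comparison is computed through the identical route, so observed and
  surrogate statistics remain exchangeable. `mode = "embed"` re-embeds
  every surrogate for a map-space null.
* **Seeding.** One RNG sub-stream is derived per surrogate index from the
  master seed; results are independent of evaluation order.

## The simulator

`simulate_population()` generates the ground-truth population used to
validate the pipeline end to end: 3 subnetworks × 20 neurons × 3 encoding
schemes (180 neurons), 3 conditions × 10 trials of 1-s windows (S = 30).
Subnetwork `i` prefers condition `i`; within a subnetwork, neurons share
*what* they encode but not *how*:

* **rate** coders are homogeneous Poisson, 10 Hz baseline vs 20 Hz on
  preferred trials;
* **temporal** coders realize a frozen baseline spike-time template on both
  non-preferred conditions and a distinct preferred template, with equal
  template spike counts and per-trial Gaussian jitter (sd 3 ms);
* **mixed** coders use templates whose preferred-condition spike count is
  drawn at the elevated rate, so both rate and timing are informative.

Template trains additionally receive condition-independent deletion/
insertion noise (per-spike deletion probability 0.1, count-matched uniform
insertions). This detail is load-bearing: without it a temporal coder emits
the same spike count on every trial, its `q = 0` fingerprint is exactly
constant (degenerate), and the rate-blindness of temporal codes could not
be probed. With it, `q = 0` counts fluctuate without carrying condition
information, so at `q = 0` temporal coders collapse into an unstructured
central group while rate and mixed coders still separate — and for `q > 0`
the timing structure dominates and all three schemes co-cluster by
subnetwork. The two-template design (a shared baseline pattern plus a
distinct preferred pattern) is likewise what keeps rate and temporal coders
of the same subnetwork positively correlated at fine temporal accuracy
(`q = 200`): both fingerprint types then share the same
"preferred-vs-baseline" block orientation.

Firing rates and jitter are exposed in `sim_config()`; the defaults above
are implementation choices in the physiological range for cortical units,
fixed once and used throughout the test suite.

What the simulator does *not* emulate: slow non-stationarities (drift,
adaptation), correlated trial-to-trial variability across neurons, bursting
and refractory structure, and graded (rather than categorical) condition
preferences. Passing the validation suite therefore demonstrates that the
machinery recovers known structure under clean conditions; it does not
guarantee behavior on real recordings, where `q` sweeps and the permutation
test are the safeguards.

`simulate_tuned_poisson()` is a small demonstration generator
(condition-dependent Poisson rates under a circular Gaussian tuning curve)
used for single-neuron SSIM-map examples.

## Problem sizes used in validation

The packaged test suite exercises the full 180-neuron, S = 30 population
across 20 simulation seeds at `q = 10` and `q = 200` for ground-truth
recovery; the permutation test's false-positive rate is estimated from 50
structureless Poisson populations (N = 40, S = 30) at `M = 200`
surrogates, and its power on the structured population at `M = 1000`.
Edit-distance correctness is checked against a brute-force optimal-matching
enumeration (1000 random pairs of trains with up to 4 spikes) and an
independently written reference dynamic program (1000 random pairs, up to
~20 spikes, tolerance 1e-9).

## A short example

```{r example, eval = FALSE}
sim <- simulate_population(sim_config(seed = 1))
res <- run_simnets(sim$recording, q = 10, k_range = 2:10,
                   shuffles = 1000, seed = 1)
res          # Ksc, silhouette, permutation p-value
plot(res)    # population map colored by cluster
write_simnets_result(res, "results/run-q10")
```

## Known limitations

* Exact t-SNE and the full CS matrix are `O(N²)` in memory and time;
  populations beyond ~5,000 neurons need a Barnes–Hut or landmark variant.
* k-means assumes roughly convex clusters in map space; strongly elongated
  subnetwork geometries may be better served by density-based clustering
  on the CS distance matrix directly.
* The permutation null preserves each neuron's distance multiset but not
  temporal autocorrelation across windows; for windows cut from continuous
  data with strong slow dynamics the null may be liberal, and block-wise
  permutation would be a natural extension.
* A single `q` is applied to all neurons; populations mixing very
  different intrinsic timescales are only visible through `q` sweeps.
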