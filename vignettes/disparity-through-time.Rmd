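---
title: "Disparity through time from interpolated shapes: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disparity through time from interpolated shapes: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disparitree)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and why their defaults are what they
are, the numerical conventions, and what the synthetic tests do — and do
not — establish about real data.

## The problem and the model

Disparity, the morphological diversity of a clade, is classically measured
per time bin from the specimens sampled in that bin. When the fossil record
is patchy this conflates evolutionary signal with sampling: a bin with two
specimens of one subclade reports the disparity of that subclade, not of
the clade. The interpolation approach treats the dated phylogeny as the
sampling frame instead: every branch alive during a bin contributes a
hypothetical morphology, obtained by reconstructing shape variables at the
nodes and interpolating linearly along branches.

Three model components carry assumptions:

* **Brownian motion with a constant diffusion rate** underlies both the
  ancestral reconstruction and the linear ("gradual") interpolation. Under
  BM the ML point estimates of node values minimize
  $\sum_{\text{branches}} (x_c - x_p)^2 / v$ per axis — squared-change
  parsimony weighted by branch duration $v$ — and the conditional
  expectation of the trait along a branch is the linear interpolant between
  its endpoint estimates. The diffusion rate cancels from the point
  estimates, so it is never estimated; no punctuated (node-jump) variant is
  provided, because on trees dominated by long ghost lineages it would
  concentrate implausibly large jumps at sparse nodes.
* **'Equal' time-scaling** turns a topology plus tip ages and node minima
  into a dated tree deterministically: node age = oldest descendant tip age
  raised to any applicable constraint minimum (minima propagate upward),
  root extended by `vartime`, then every maximal chain of zero-duration
  branches receives time by evenly redistributing the duration of the
  nearest ancestral positive branch across itself and the chain. Tip ages
  and root-to-tip spans are preserved exactly; all durations end positive.
* **Sum of variances** as the disparity metric: the sum over retained axes
  of the sample variance (n − 1 denominator) of the interpolated values.
  It is relatively robust to uneven sampling and decomposes additively over
  axes. Only interpolated branch values enter a bin — observed terminals
  and reconstructed nodes are not appended separately, which keeps a
  lineage from being counted twice.

Uncertainty is handled by ensembles, not analytically: polytomy
resolutions, fossil ages within stratigraphic ranges, and constraint sets
are redrawn per replicate, and the per-bin distribution of the sum of
variances is summarised by its median, 2.5–97.5% quantiles, and range.

## Parameters that matter

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| `vartime` | Myr | 1 | Minimum time the root extension makes available for redistribution; the conventional setting for 'equal' scaling. |
| `fossil_age_mode` | — | `uniform` | `uniform` draws a tip age over its stratigraphic unit; `older_bound` pins it at the unit's older boundary (the two modes bracket the dating conventions in use). |
| `resolve_polytomies` | — | `TRUE` | Supertrees carry soft polytomies; random resolution propagates that uncertainty into the ensemble. |
| `n_replicates` | — | 1000 in `timescale_spec()`, 100 in `pipeline_config()` | 1000 matches common practice for tree ensembles; the pipeline default keeps interactive runs fast — raise it for final analyses. |
| `n_retained` | axes | broken-stick | Strict broken-stick run (ties do not count as exceeding); override when an external axis choice exists. |
| GPA `tol`, `max_iter` | — | 1e−10, 100 | Mean-shape convergence is quadratic in practice; 100 iterations is far beyond need, and non-convergence warns rather than fails. |
| `eps` (ancestral states) | Myr | 1e−8 | Durations below `eps` are floored with a warning; after 'equal' scaling they cannot occur, so this only guards degenerate hand-built trees. |

Ages are Ma before present throughout (larger = older); durations are Myr.

## Conventions and numerical choices

* **Bin midpoints.** A bin's sampling time is `(older + younger)/2`. A
  `midpoint` column may override this; the intended use is a Recent bin
  (e.g. `[0.0117, 0]`) pinned at 0 Ma so extant lineages enter at exactly
  their observed tip values. Bins with fewer than two crossing lineages
  yield missing disparity, never zero — zero would be a biological claim.
* **Branch membership at a slice** uses the closed age interval with
  deduplication: a node sitting exactly on the slice contributes once, via
  its parent branch; the root contributes its own value. This is a
  measure-zero case for continuous ages but must be deterministic because
  pinned midpoints (the Recent) and constraint-dated nodes can coincide
  with bin midpoints exactly.
* **Covariate binning** assigns a point to a bin when
  `younger ≤ age < older`, the oldest bin including its older boundary.
  A point on a shared boundary therefore belongs to the older bin, and a
  present-day point (age 0) is never lost.
* **Polytomy resolution** is by recursive random pairing: while a node has
  more than two children, a uniformly chosen pair of child subtrees is
  joined. For a trichotomy this is exactly uniform over the three
  resolutions; for higher orders it is the random-coalescent null, a
  defensible neutral choice that stays clade-conserving.
* **Zero-duration chains** in stage 3 of 'equal' scaling are processed
  top-down (parent closest to the root first; ties broken by node number),
  following zero branches downward (first child by node number on the rare
  exact ties). The processing order is part of the package's contract and
  is matched by the independent reference implementation in the test suite.
* **Reflections in GPA** are never applied; configurations whose optimal
  superimposition would require one are flagged by specimen id. Aligned
  shapes have centroid 0 and centroid size 1. Because unit centroid size is
  a spherical (not linear) constraint, exactly 2k − 3 covariance dimensions
  vanish identically after alignment and the scale dimension only shrinks
  quadratically with deviation size.
* **Spearman p-values** are exact (full permutation distribution of the
  rank statistic, two-sided around its mean) for n ≤ 9 and use the
  t-approximation above that; ties get average ranks, and an all-tied
  variable reports a flagged coefficient of 0.
* **GLS with AR(1) errors is fitted by REML**, not ML. ML's correlation
  estimate is biased downward by roughly $(1 + 3\phi)/n$ plus a penalty per
  estimated regression coefficient — at bin-count-scale series this bias is
  comparable to the Monte-Carlo precision of the package's own recovery
  checks, whereas REML removes the coefficient-driven part. `method = "ML"`
  remains available.
* **Reproducibility.** Every stochastic stage runs under a derived integer
  seed (`derive_seed(seed, stage, replicate)`, a fixed affine hash modulo
  2³¹ − 1), so replicate r is identical whether 10 or 1000 replicates are
  requested, and identical configurations produce byte-identical CSVs.

## The synthetic generator: what it emulates

`simulate_study()` builds the package's default study: a crown birth–death
tree (λ = 0.1, μ = 0.05 events/Myr, stopped when 20 lineages are alive —
about 40 tips in total with the extinct ones, and a crown depth usually
between 40 and 100 Myr), Brownian shape scores in p = 7 dimensions at rate
1 per Myr, stage-like 5-Myr stratigraphic units assigned to fossil tips
(fossil dating is typically finer than analysis bins), 10-Myr analysis bins
plus a pinned Recent bin, a supertree with a quarter of its internal edges
collapsed into polytomies, and constraint sets emulating a posterior sample
of clock trees. Each constraint set is one *coherent* chronogram — a common
rescaling factor uniform on 0.9–1.1 with 3% per-node log-normal jitter and
nestedness restored — read off at every node with at least two extant
descendants. Coherence matters: truly independent per-node minima do not
resemble any posterior sample, and through the 'equal' method's
max-propagation they would bias all dates old.

Landmark simulation wraps the same BM process in nuisance similarity
transforms (rotation uniform on the circle, log-scale sd 0.1, translation
sd 10 × mean-shape size) that the Procrustes step must remove.

What the generator does *not* emulate: rate heterogeneity across branches
or axes, selection or bounded traits, correlated axes (real PC scores are
uncorrelated only in-sample), non-uniform fossil recovery through time, and
supertree topological *error* (collapsed edges lose resolution but never
conflict with the truth). Passing tests therefore show the machinery is
correct and the uncertainty propagation behaves as designed under BM —
they do not show that BM, 'equal' dating, or sum-of-variances are adequate
for any particular empirical system.

## Known limitations

Two opposing systematic offsets separate the pipeline's output from the
generating truth, and neither is a bug:

* **Reconstruction shrinkage.** Squared-change/BM-ML node estimates are
  conditional means, so interior values are pulled toward the clade mean
  and deep-bin disparity computed from them underestimates the disparity of
  the true (unobserved) node values.
* **'Equal' dating inflation.** Node ages are maxima over noisy lower
  bounds (drawn fossil ages, constraint minima), and stage-3 redistribution
  lifts fossil-poor nodes further; dated nodes are therefore biased old
  relative to the true chronogram, inflating deep lineage counts and
  mid-bin disparity.

The ensemble bands quantify *sampling* uncertainty (topology, fossil ages,
constraint draws) and should be read as such: they do not absorb these
estimator biases, so the replicate min–max band need not bracket the true
generating curve in every bin — the acceptance checks compute exactly this
coverage on the default study. Consequences for practice: compare curves
computed the same way (clades against clades, tree set against tree set),
treat level differences between a reconstructed curve and any external
benchmark with caution, and treat deep bins crossed by few lineages as
qualitative.

Scale of the shipped checks: the test suite runs ensembles of 100 replicate
trees on the ~40-tip default study, 100–500 Monte-Carlo replicates for the
calibration and recovery checks, and exhaustive small-tree enumerations
(all rooted topologies on up to 5 tips) for the dating oracle — sizes at
which each check's Monte-Carlo error is well below its assertion tolerance.

## Interfaces

Everything is plain text: Newick/NEXUS trees (durations in Myr), CSV tables
for ranges, constraints (long format: `sample_id, clade_id, tip_id,
min_age`), scores, bins, covariates and results, TPS for landmarks, and a
YAML pipeline configuration (`read_pipeline_config()` /`run_pipeline()`).
The exported R functions are the package's interface; `run_pipeline()`
orchestrates the full analysis (whole clade, clade subsets, optional
fossil exclusion) and logs every replicate's derived seed and constraint
draw for auditability.
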