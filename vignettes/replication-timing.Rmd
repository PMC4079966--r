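---
title: "Replication timing profiles and domain calling from Repli-Seq fractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replication timing profiles and domain calling from Repli-Seq fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repliseqr)
```

# The measurement and the model

Repli-Seq measures *when* each part of a genome replicates. Cells are
pulse-labelled with a nucleoside analogue, sorted by DNA content into four
S-phase fractions — early (E), early-mid (E–M), late-mid (L–M), late (L) —
and the nascent DNA of each fraction is sequenced. A locus replicating
early yields reads predominantly in the E fraction; a late locus in the L
fraction; loci in between shift smoothly across the middle fractions.

## The continuous timing score

Each fraction's reads are reduced to RPKM (reads per kb per million mapped
reads) over non-overlapping 10-kb bins. Writing $x = (x_L, x_{LM},
x_{EM}, x_E)$ for a bin's four-fraction RPKM vector, its timing score is
the normalised weighted average

$$S(x) = \frac{\sum_k w_k\,x_k}{\sum_k x_k},
  \qquad w = (0.125,\; 0.375,\; 0.625,\; 0.875),$$

the weights being the midpoints of each fraction's nominal quarter of S
phase (latest fraction lowest). The score is a convex combination of the
weights, so it is bounded in $[0.125, 0.875]$ with the bounds attained
only when all reads fall in a single fraction; it is invariant to
rescaling $x$ by any positive constant (hence to library size); and it is
undefined exactly where all four fractions are zero. High values mean
early replication.

Profiles are smoothed per chromosome by local polynomial regression
(loess: tricube weights, degree 2) of score against bin midpoint. The
physical window is ~200 kb; because loess takes a *span* (a fraction of
points), the package converts the window as
`span = max(window_bp / bin_width, 4) / n_scored_bins`, which adapts to
chromosome length and never uses fewer than 4 points. Missing bins are
imputed from the fitted curve, and smoothed values are clipped back to
$[0.125, 0.875]$ (clipping is toggleable; the attainable range of the raw
score is the natural scale for the smoothed one). Chromosomes with fewer
than 4 scored bins are passed through unsmoothed with a warning.

The log2 timing ratio `log2((E + c)/(L + c))` uses only the extreme
fractions, whose contrast carries essentially all of the early/late
signal; the middle fractions are deliberately excluded. The pseudocount
`c` defaults to the 5th percentile of the nonzero E/L values — large
enough to tame empty bins, small enough to preserve dynamic range.

## Domain segmentation with a three-state HMM

For domain calling the package works on a sliding grid of 5-kb windows
every 1 kb, using only the E and L fractions jointly. Two corrections
precede modelling:

* **Chromosome weighting.** RPKM standardises library size, which hides
  per-chromosome copy-number differences in aneuploid lines. Every bin
  value is divided by the mean RPKM over all four fractions and all bins
  of its chromosome, restoring proportional representation of each
  chromosome. (Multiplying instead of dividing would invert the intended
  correction; the inverse is nevertheless retained behind
  `normalize_by_chromosome(invert = TRUE)` since the weighting direction
  is a judgement call.)
* **Percentile capping.** Per fraction, values above the genome-wide 95th
  percentile are set to it, guarding against spuriously amplified
  regions. Quantiles use linear interpolation between order statistics
  (R's default type 7).

The segmentation model is a hidden Markov model with three states —
early, late, indeterminate replication — each emitting a bivariate normal
over the joint (E, L) signal:

* **Initialisation.** k-means (k = 3, 10 restarts, fixed seed) on the 1-D
  log2(E/L) ratio; each cluster's bins supply one state's bivariate mean
  and covariance. Clusters are ordered by mean ratio (late lowest).
  Transitions start at 0.998 on the diagonal with the remainder split
  equally, and initial probabilities are uniform. The self-transition
  value is a design choice: it implies an expected run length of ~500
  windows, commensurate with the ~45-kb minimum domain scale below.
* **Training.** Baum-Welch per chromosome from the shared genome-wide
  initialisation, stopping when the log-likelihood improves by less than
  0.05 (cap 500 iterations, with a warning). All recursions run in log
  space (compiled; log-sum-exp) — this is part of the contract, since
  probability-space recursions underflow on long chromosomes.
* **Decoding.** Viterbi, in log space, ties broken toward the lower state
  index. After training, states are relabelled semantically by ranking
  their E-channel minus L-channel emission means: top = early, bottom =
  late, middle = indeterminate (training can permute states, so labels
  cannot be positional).
* **Minimum run length.** Runs shorter than 40 windows (~45 kb, the
  resolution limit set by label-incorporation kinetics) are merged:
  repeatedly, the globally shortest sub-threshold run is relabelled to
  its longer flank (ties to the left; the only flank at chromosome ends)
  and runs are coalesced. Shortest-first with deterministic tie-breaks
  makes the result order-independent and reproducible. A single
  sub-threshold run spanning a whole chromosome is left alone.

Numerical safeguards in training: emission covariances are floored at a
fixed eigenvalue (10⁻⁸ × the mean data variance, set once per run) — a
state whose re-estimated covariance would fall below the floor keeps its
previous one, and starved states or transition rows keep their previous
parameters. These partial updates are coordinate ascent on the EM
objective, so the log-likelihood remains monotonically non-decreasing;
clamping covariances after the fact would (and in adversarial tests did)
break that guarantee. Singular k-means cluster covariances are ridged by
εI (ε = 10⁻⁶ × mean variance) with a warning.

## Cross-line comparison and annotation

Static/dynamic classification is position-level on a 1-kb grid rather
than interval-intersection: early in all lines → `static_early`; late in
all → `static_late`; early in at least one and late in at least one →
`dynamic`; anything else (an indeterminate call without a conflict, or no
coverage) → `indeterminate`. A position-level rule defines genome
fractions unambiguously, is symmetric in sample order, and is monotone:
adding a line can only move positions toward dynamic/indeterminate.

Per-chromosome timing is summarised by five-number summaries of the 10-kb
bins plus a two-sided Mann-Whitney test of a target chromosome against
the pooled background — the standard rank test for the X-vs-autosome
comparison; no distributional assumption on the scores is needed.

Annotation utilities: `feature_density()` counts point features by their
start position (start-in membership makes densities additive over
disjoint regions and unambiguous at boundaries) per 100 kb;
`median_signal()` takes per-region medians of a genome-normalised track
(z-score by default, with the convention that a constant track z-scores
to 0; rank/quantile normalisation is available for cross-platform
tracks); `difference_ratio()` is the elementwise log2 ratio of two
summaries with a recorded ε; `order_bins_by_timing()` produces the
late-to-early bin ordering behind timing-ordered heatmaps, ties broken by
(chromosome, start).

# The synthetic-data generator

The generator exists so that every downstream stage can be tested against
known truth without any external data.

* **Genome.** Chromosomes are tiled with domains whose lengths are
  uniform on [100, 500] kb by default. Each new domain takes the label
  (early/late) that moves the running genome-wide early fraction toward
  the target — deterministic duty-cycle steering that keeps the achieved
  fraction within a few percentage points at 10 Mb and beyond while the
  lengths stay random. Each domain carries a constant true time $t$ drawn
  from its label's extreme fraction window: early $t \sim U(0.75, 1)$,
  late $t \sim U(0, 0.25)$, so planted labels coincide with the fraction
  windows the score is built on.
* **Reads.** Per 10-kb bin, the total read count is Poisson with mean 100
  (times the chromosome's copy-number multiplier — aneuploidy is a
  per-chromosome scalar). Reads are apportioned across fractions with
  $p_k(t) \propto \exp(-\kappa (t - m_k)^2)$, $m_k$ the fraction-window
  midpoints and $\kappa = 50$ by default; $\kappa = 0$ is a flat split,
  and the expected early share is strictly increasing in $t$. Reads are
  50-bp plus-strand intervals placed uniformly within the bin. The
  Gaussian-kernel form is the minimal smooth, symmetric model under which
  the weighted score is an approximately unbiased estimator of $t$.
* **Features.** TSS and ORC sites are homogeneous point processes within
  each domain at label-dependent densities (defaults 10 vs 2 per 100 kb
  for TSS, 8 vs 2 for ORC — early chromatin is gene- and origin-dense).
* **Derived lines.** `flip_domains()` relabels a subset of domains
  covering a requested genome fraction, redrawing their true times — the
  ground truth for static/dynamic recovery.

Fixing the seed fixes every output exactly (each sub-generator uses a
deterministic offset of the config seed, so read, TSS and ORC draws are
independent but individually reproducible).

What the generator does **not** emulate: mappability variation and
sequencing error; overdispersed (negative-binomial) counts; fragment-size
effects; gradual timing transitions within a domain (planted $t$ is
piecewise constant, so domain boundaries are unrealistically sharp); and
biological indeterminacy — real genomes have large regions without a
coherent timing signal, which is why published domain coverage on real
data is far below the near-total coverage recovered here. Passing the
recovery tests therefore demonstrates correctness of the pipeline's
machinery on well-posed input, not expected field performance on real
libraries.

# Problem sizes and test design

The test suite and the acceptance script run entirely on generated data:
20-Mb two-chromosome genomes at default depth for end-to-end recovery
(~200k reads, ~20,000 sliding windows — large enough that boundary
effects are negligible against the 100–500-kb domain scale, small enough
to run in seconds); 10⁴ bins for emission-parameter recovery; sequences
of ≤ 8 windows for the exhaustive Viterbi cross-check (3⁸ paths remain
enumerable); 10⁶ random vectors for the score's scale-invariance
property. The Viterbi implementation is verified against brute-force path
enumeration, and Baum-Welch monotonicity is asserted on every trace the
suite produces, including deliberately poor random initialisations.

# Known limitations

* Three states are fixed (no model-order selection), and decoding is
  Viterbi-only; posterior decoding is not offered.
* The HMM consumes the normalised, capped signal; feeding raw RPKM is
  possible but untested against the published procedure's intent.
* Replicate handling is by pooling reads before binning; no
  replicate-variance model.
* `feature_density()`/`median_signal()` use start-in membership; features
  defined as broad intervals should be reduced to a representative point
  first.
* BAM input requires Rsamtools; BED/bedGraph I/O requires rtracklayer
  (both optional dependencies).
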