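# repliseqr

Replication timing analysis for Repli-Seq experiments: continuous timing
profiles from four flow-sorted S-phase fractions, genome segmentation into
early/late replication domains with a three-state hidden Markov model, and
cross-cell-line classification of domains as static or dynamic.

## The problem and the method

Repli-Seq pulse-labels replicating DNA, sorts S-phase cells into four
fractions by DNA content — early (E), early-mid (E–M), late-mid (L–M) and
late (L) — and sequences the nascent DNA of each fraction. A region's reads
concentrate in the fraction during which it replicates, so the
across-fraction read distribution at each genomic position encodes its
replication time.

The package implements three analysis stages:

1. **Continuous timing profile.** Per-fraction RPKM is computed over
   non-overlapping 10-kb bins, and each bin is scored by the normalised
   weighted average

   $$S(x) = \frac{\sum_k w_k x_k}{\sum_k x_k}, \qquad
     w = (0.125,\ 0.375,\ 0.625,\ 0.875)$$

   where `x` is the bin's RPKM vector over the fractions ordered late →
   early and the weights are the midpoints of each fraction's quarter of S
   phase. The score lies in [0.125, 0.875]; high values replicate early.
   Profiles are smoothed per chromosome by local polynomial regression
   (loess, ~200-kb window).

2. **Domain segmentation.** On a sliding grid (5-kb windows every 1 kb),
   the joint (E, L) signal — chromosome-weighted and capped at the 95th
   percentile — is modelled with a three-state HMM whose states (early,
   late, indeterminate replication) emit bivariate normal distributions.
   Emissions are initialised by k-means (k = 3) on the log2(E/L) ratio,
   trained per chromosome by Baum-Welch until the log-likelihood gain is
   < 0.05, decoded with Viterbi, and state runs shorter than 40 windows
   (~45 kb) are merged into their larger neighbour.

3. **Static vs dynamic domains.** Across two or more cell lines, every
   1-kb position is classed `static_early` (early in all lines),
   `static_late` (late in all), `dynamic` (early in one line, late in
   another) or `indeterminate`; per-class genome fractions and
   per-chromosome timing summaries (with a Mann-Whitney target-vs-autosome
   test) quantify the comparison. Domains can be annotated with
   point-feature densities (TSS, ORC; per 100 kb) and median normalised
   signal enrichments.

A synthetic-data module generates multi-chromosome genomes with planted
early/late domains, fraction-specific reads whose across-fraction
proportions depend on the planted time, per-chromosome aneuploidy, and
point features with domain-dependent densities — so every stage is
testable against known ground truth.

## Worked example

```r
library(repliseqr)

cfg    <- sim_config(chrom_sizes = c(chr2L = 1e7, chr2R = 1e7), seed = 1)
truth  <- simulate_genome(cfg)            # planted domains + true times
reads  <- simulate_fraction_reads(truth)  # 200,904 reads across 4 fractions

profile <- run_profile(reads, cfg$chrom_sizes)
head(profile, 3)
#>   chrom start   end score smoothed ratio
#> 1 chr2L     0 10000 0.737    0.776  1.25
#> 2 chr2L 10000 20000 0.798    0.776  1.34
#> 3 chr2L 20000 30000 0.817    0.775  1.34
```

The first bins sit in a planted early domain: raw scores near 0.78 (high =
early), and a positive log2(E/L) ratio.

```r
seg <- run_domains(reads, cfg$chrom_sizes, repli_config(seed = 1),
                   sample = "lineA")
seg
#> Replication-domain segmentation for lineA
#>   early          50.6% (25 domains)
#>   late           49.4% (25 domains)
glance(seg)
#>   n_chromosomes n_domains  logLik max_iter_used all_converged
#> 1             2        50 109565.             8 TRUE
```

The HMM recovers the planted 50/50 early/late layout; `tidy()` on a
per-chromosome model shows the trained emissions (the early state has high
E-channel mean and zero L-channel mean, and vice versa).

```r
line2 <- flip_domains(truth, prop = 0.1, seed = 2)  # second cell line
cfgB  <- cfg; cfgB$seed <- 2L
segB  <- run_domains(simulate_fraction_reads(line2, cfgB),
                     cfg$chrom_sizes, repli_config(seed = 1),
                     sample = "lineB")
classify_positions(list(lineA = seg$domains, lineB = segB$domains))
#> Cross-sample replication classes ( 1000 bp grid )
#>   static_early   42.4%
#>   static_late    47.2%
#>   dynamic        10.4%
#>   indeterminate   0.0%
```

The 10% of the genome whose timing was flipped between the lines is
recovered as 10.4% dynamic. TSS simulated at 10/100 kb in early vs
2/100 kb in late domains annotate back at 9.25 (static early), 1.92
(static late) and 8.61 (dynamic) per 100 kb via `feature_density()`.

Plots: `plot_timing_profile(profile)`, `autoplot(seg)`,
`autoplot(classes)`.

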