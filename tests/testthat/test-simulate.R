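test_that("planted domains tile each chromosome and hit the early fraction", {
  cfg <- sim_config(chrom_sizes = c(c1 = 1e7, c2 = 1e7), frac_early = 0.4,
                    seed = 3)
  truth <- simulate_genome(cfg)
  for (ch in c("c1", "c2")) {
    d <- truth[truth$chrom == ch, ]
    expect_equal(d$start, c(0, head(d$end, -1)))  # disjoint, tiling
    expect_equal(max(d$end), 1e7)
  }
  early <- sum((truth$end - truth$start)[truth$label == "early"])
  expect_gt(early / 2e7, 0.35)
  expect_lt(early / 2e7, 0.45)
  # t ranges by label
  expect_true(all(truth$t[truth$label == "early"] >= 0.5))
  expect_true(all(truth$t[truth$label == "late"] <= 0.5))
})

test_that("forced tiling with fixed-length domains gives one early + one late", {
  cfg <- sim_config(chrom_sizes = c(c1 = 1e6), domain_min = 5e5,
                    domain_max = 5e5, frac_early = 0.5)
  truth <- simulate_genome(cfg)
  expect_equal(nrow(truth), 2)
  expect_equal(truth$label, c("early", "late"))
  expect_equal(truth$end - truth$start, c(5e5, 5e5))
})

test_that("generator is byte-identical under a fixed seed", {
  cfg <- small_config(seed = 9)
  t1 <- simulate_genome(cfg)
  t2 <- simulate_genome(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(simulate_fraction_reads(t1, cfg),
                   simulate_fraction_reads(t2, cfg))
  expect_identical(simulate_features(t1, cfg, "tss"),
                   simulate_features(t2, cfg, "tss"))
})

test_that("domain length bound exceeding a chromosome errors", {
  cfg <- sim_config(chrom_sizes = c(c1 = 1e5), domain_min = 2e5,
                    domain_max = 3e5)
  expect_error(simulate_genome(cfg), "domain_min")
})

test_that("read fractions concentrate in the matching S-phase window", {
  cfg <- small_config(concentration = 50)
  truth <- simulate_genome(cfg)
  reads <- simulate_fraction_reads(truth, cfg)
  tb <- truth_bins(truth, cfg$bin_width)
  # late-domain bins with t near the late midpoint should emit mostly
  # late-fraction reads; high-t bins mostly early-fraction reads
  hi <- tb[!is.na(tb$t) & tb$t > 0.9, ]
  if (nrow(hi) > 0) {
    sel <- mapply(function(ch, s) {
      r <- reads[reads$chrom == ch &
                 reads$start >= s & reads$start < s + cfg$bin_width, ]
      mean(r$fraction == "early")
    }, hi$chrom, hi$start)
    expect_gt(mean(sel), 0.8)
  }
  # monotonicity of the expected early share in t
  p <- repliseqr:::fraction_probs(seq(0.05, 0.95, by = 0.05), 50)
  expect_true(all(diff(p[, 4]) > 0))
})

test_that("flat concentration splits reads evenly across fractions", {
  cfg <- small_config(concentration = 0)
  truth <- simulate_genome(cfg)
  reads <- simulate_fraction_reads(truth, cfg)
  props <- table(reads$fraction) / nrow(reads)
  expect_true(all(abs(props - 0.25) < 0.01))
})

test_that("copy-number multipliers scale total read depth", {
  cfg <- sim_config(chrom_sizes = c(diploid = 2e6, tetra = 2e6),
                    copy_number = c(diploid = 1, tetra = 2), seed = 5)
  truth <- simulate_genome(cfg)
  reads <- simulate_fraction_reads(truth, cfg)
  n <- table(reads$chrom)
  expect_equal(unname(n[["tetra"]] / n[["diploid"]]), 2, tolerance = 0.05)
  # marginal over fractions recovers the configured per-bin mean
  n_bins <- sum(cfg$chrom_sizes) / cfg$bin_width
  expect_equal(nrow(reads) / n_bins, cfg$reads_per_bin * 1.5,
               tolerance = 0.05)
})

test_that("point features follow domain-dependent densities", {
  cfg <- sim_config(chrom_sizes = c(c1 = 5e6, c2 = 5e6),
                    tss_density = c(early = 10, late = 2), seed = 21)
  truth <- simulate_genome(cfg)
  tss <- simulate_features(truth, cfg, "tss")
  dens <- feature_density(tss, truth)
  for (lab in c("early", "late")) {
    d <- dens[dens$label == lab, ]
    n <- sum(d$count)
    expected <- cfg$tss_density[[lab]] * sum(d$length_bp) / 1e5
    expect_lt(abs(n - expected), 3 * sqrt(expected))  # Poisson 3-sigma
  }
  # zero density gives zero features
  cfg0 <- sim_config(chrom_sizes = c(c1 = 5e6),
                     orc_density = c(early = 0, late = 0))
  t0 <- simulate_genome(cfg0)
  expect_equal(nrow(simulate_features(t0, cfg0, "orc")), 0)
})

test_that("flip_domains switches close to the requested genome fraction", {
  cfg <- sim_config(chrom_sizes = c(c1 = 1e7, c2 = 1e7), seed = 11)
  truth <- simulate_genome(cfg)
  flipped <- flip_domains(truth, prop = 0.1, seed = 42)
  idx <- attr(flipped, "flipped")
  frac <- sum((flipped$end - flipped$start)[idx]) /
    sum(flipped$end - flipped$start)
  expect_gt(frac, 0.08)
  expect_lt(frac, 0.12)
  expect_true(all(flipped$label[idx] != truth$label[idx]))
  expect_equal(flipped$label[-idx], truth$label[-idx])
})
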