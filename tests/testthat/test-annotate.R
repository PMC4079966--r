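test_that("feature density counts starts in regions per 100 kb", {
  feats <- tibble::tibble(chrom = "c1", start = seq(0, 199e3, by = 25e3),
                          end = seq(0, 199e3, by = 25e3) + 1)
  region <- tibble::tibble(chrom = "c1", start = 0, end = 2e5)
  out <- feature_density(feats, region)
  expect_equal(out$count, 8L)
  expect_equal(out$density_per_100kb, 4)
  # empty feature set
  expect_equal(feature_density(feats[0, ], region)$density_per_100kb, 0)
  # zero-length region errors
  bad <- tibble::tibble(chrom = "c1", start = 10, end = 10)
  expect_error(feature_density(feats, bad), "positive length")
})

test_that("feature density is additive over disjoint regions", {
  withr::with_seed(6, {
    feats <- tibble::tibble(chrom = "c1",
                            start = sort(sample(0:999999, 500)))
    feats$end <- feats$start + 1
    parts <- tibble::tibble(chrom = "c1", start = c(0, 4e5),
                            end = c(4e5, 1e6))
    whole <- tibble::tibble(chrom = "c1", start = 0, end = 1e6)
    dp <- feature_density(feats, parts)
    dw <- feature_density(feats, whole)
    expect_equal(sum(dp$count), dw$count)
    expect_equal(sum(dp$count) / 1e6 * 1e5, dw$density_per_100kb)
  })
})

test_that("synthetic TSS densities reproduce the planted early/late ratio", {
  cfg <- sim_config(chrom_sizes = c(a = 5e6, b = 5e6),
                    tss_density = c(early = 10, late = 2), seed = 33)
  truth <- simulate_genome(cfg)
  tss <- simulate_features(truth, cfg, "tss")
  dens <- feature_density(tss, truth) |>
    dplyr::group_by(label) |>
    dplyr::summarise(density = sum(count) / sum(length_bp) * 1e5)
  ratio <- dens$density[dens$label == "early"] /
    dens$density[dens$label == "late"]
  expect_equal(ratio, 5, tolerance = 0.25)
})

test_that("median signal normalises genome-wide before region medians", {
  track <- tibble::tibble(chrom = "c1", start = 0:999 * 1e3,
                          score = rep(c(1, 0), c(300, 700)))
  regions <- tibble::tibble(chrom = "c1", start = c(0, 5e5),
                            end = c(3e5, 1e6),
                            label = c("early", "late"))
  none <- median_signal(track, regions, normalization = "none")
  expect_equal(none$median_signal, c(1, 0))  # indicator track
  z <- median_signal(tibble::tibble(chrom = "c1", start = 0:99 * 1e3,
                                    score = 5),
                     regions[1, ], normalization = "z")
  expect_equal(z$median_signal, 0)  # constant track z-scores to 0
  # region without coverage is NA
  far <- tibble::tibble(chrom = "c9", start = 0, end = 1e5)
  expect_true(is.na(median_signal(track, far)$median_signal))
})

test_that("marks planted denser in early domains rank early above late", {
  withr::with_seed(41, {
    hits <- 0
    for (rep in 1:20) {
      cfg <- sim_config(chrom_sizes = c(a = 3e6), seed = 500 + rep)
      truth <- simulate_genome(cfg)
      tb <- truth_bins(truth, 1e4)
      track <- tibble::tibble(
        chrom = tb$chrom, start = tb$start,
        score = stats::rpois(nrow(tb),
                             ifelse(tb$label == "early", 20, 10)))
      ms <- median_signal(track, truth, normalization = "z")
      # the truncated terminal domain may contain no track start: NA
      diff_el <- median(ms$median_signal[ms$label == "early"],
                        na.rm = TRUE) -
        median(ms$median_signal[ms$label == "late"], na.rm = TRUE)
      hits <- hits + (diff_el > 0)
    }
    expect_gte(hits / 20, 0.95)
  })
})

test_that("difference ratio is an elementwise log2 with recorded epsilon", {
  withr::with_seed(2, {
    a <- matrix(stats::rexp(20), 4)
    b <- matrix(stats::rexp(20), 4)
    dr <- difference_ratio(a, b, eps = 0.01)
    expect_equal(unclass(dr), log2((a + 0.01) / (b + 0.01)),
                 ignore_attr = TRUE)
    expect_equal(attr(dr, "eps"), 0.01)
    expect_equal(max(abs(difference_ratio(a, a))), 0)
    big <- difference_ratio(2 * a + 10, a + 5)
    expect_equal(as.vector(big), rep(1, 20), tolerance = 0.01)
    expect_error(difference_ratio(a, b[1:3, ]), "identical dimensions")
  })
})

test_that("bins are ordered late to early with deterministic ties", {
  prof <- tibble::tibble(chrom = "c1", start = 0:99 * 1e4, end = 1:100 * 1e4,
                         score = seq(0.2, 0.8, length.out = 100))
  ord <- order_bins_by_timing(prof)
  expect_equal(ord$start, prof$start)        # increasing timing: as-is
  prof_rev <- prof
  prof_rev$score <- rev(prof$score)
  expect_equal(order_bins_by_timing(prof_rev)$start, rev(prof$start))
  # ties broken by (chrom, start)
  tied <- tibble::tibble(chrom = rep(c("c2", "c1"), each = 3),
                         start = c(2e4, 0, 1e4, 1e4, 0, 2e4),
                         end = c(2e4, 0, 1e4, 1e4, 0, 2e4) + 1e4,
                         score = 0.5)
  ot <- order_bins_by_timing(tied)
  expect_equal(ot$chrom, rep(c("c1", "c2"), each = 3))
  expect_equal(ot$start, rep(c(0, 1e4, 2e4), 2))
  # track values attach in the sorted order
  track <- tibble::tibble(chrom = "c1", start = prof$start + 100,
                          score = prof$score * 10)
  with_track <- order_bins_by_timing(prof, list(mark = track),
                                     normalization = "none")
  expect_equal(with_track$mark, prof$score * 10)
})
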