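#' Point-feature density per region
#'
#' Counts features whose start position lies inside each region (start-in
#' membership, which makes densities additive over disjoint regions and
#' unambiguous at boundaries) and scales to features per 100 kb.
#'
#' @param features tibble of point features (`chrom`, `start`, ...).
#' @param regions tibble of regions (`chrom`, `start`, `end` and any
#'   grouping columns such as `label` or `class`, which are carried
#'   through).
#' @return the regions tibble with `count`, `length_bp` and
#'   `density_per_100kb` columns.
#' @export
feature_density <- function(features, regions) {
  len <- regions$end - regions$start
  if (any(len <= 0)) abort("regions must have positive length")
  regions$count <- purrr::map_int(seq_len(nrow(regions)), function(i) {
    sum(features$chrom == regions$chrom[i] &
        features$start >= regions$start[i] &
        features$start < regions$end[i])
  })
  regions$length_bp <- len
  regions$density_per_100kb <- regions$count / len * 1e5
  regions
}

# Genome-wide track normalisation used before region medians.
normalize_track <- function(values, normalization = c("z", "quantile",
                                                      "none")) {
  normalization <- match.arg(normalization)
  switch(normalization,
    z = {
      s <- sd(values)
      # z-score of a constant track is defined as 0 by convention
      if (is.na(s) || s == 0) rep(0, length(values))
      else (values - mean(values)) / s
    },
    quantile = (rank(values, ties.method = "average") - 0.5) / length(values),
    none = values)
}

#' Median normalised signal per region
#'
#' For each region, the median of a genome-normalised signal track over
#' the track records whose start lies in the region — the per-domain
#' enrichment summary used for chromatin marks, DNA-binding proteins and
#' expression. Normalisation (`z` by default, genome-wide per track) is
#' applied before taking medians; regions with no overlapping track datum
#' are returned as `NA`.
#'
#' @param track tibble with `chrom`, `start` and a `score` column
#'   (per-position or per-bin signal).
#' @param regions regions tibble (`chrom`, `start`, `end`, extra columns
#'   carried through).
#' @param normalization `"z"`, `"quantile"` or `"none"`.
#' @return the regions tibble with a `median_signal` column; the
#'   normalisation used is recorded as attribute `"normalization"`.
#' @export
median_signal <- function(track, regions,
                          normalization = c("z", "quantile", "none")) {
  normalization <- match.arg(normalization)
  norm <- normalize_track(track$score, normalization)
  regions$median_signal <- purrr::map_dbl(seq_len(nrow(regions)),
                                          function(i) {
    inside <- track$chrom == regions$chrom[i] &
      track$start >= regions$start[i] & track$start < regions$end[i]
    if (!any(inside)) NA_real_ else median(norm[inside])
  })
  attr(regions, "normalization") <- normalization
  regions
}

#' Log2 difference ratio between two enrichment summaries
#'
#' Elementwise `log2((a + eps) / (b + eps))`, the per-feature difference
#' ratio between two cell lines' region summaries. `eps` is recorded as an
#' attribute. Values are expected non-negative (use `normalization =
#' "quantile"` or `"none"` upstream).
#'
#' @param a,b numeric vectors or matrices of identical shape.
#' @param eps positive stabiliser.
#' @return the log2 ratio layer, attribute `"eps"` attached.
#' @export
difference_ratio <- function(a, b, eps = 0.01) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
    abort("`a` and `b` must have identical dimensions")
  }
  if (eps <= 0) abort("`eps` must be > 0")
  structure(log2((a + eps) / (b + eps)), eps = eps)
}

#' Order bins from late to early replication
#'
#' Sorts 10-kb profile bins ascending by timing score (late first, early
#' last; ties broken by chromosome then start, a stable deterministic
#' order) and attaches normalised values of any number of signal tracks
#' per bin — the layout behind timing-ordered enrichment heatmaps.
#'
#' @param profile a [timing_score()]/[smooth_profile()] table (`smoothed`
#'   used when present).
#' @param tracks named list of track tibbles (`chrom`, `start`, `score`);
#'   each track is averaged within the profile's bins after genome-wide
#'   normalisation.
#' @param normalization passed to [normalize_track()].
#' @return tibble of bins in late-to-early order with `timing` and one
#'   column per track.
#' @export
order_bins_by_timing <- function(profile, tracks = list(),
                                 normalization = "z") {
  timing <- if ("smoothed" %in% names(profile)) profile$smoothed
            else profile$score
  out <- profile[, c("chrom", "start", "end")]
  out$timing <- timing
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    norm <- normalize_track(tr$score, normalization)
    out[[nm]] <- purrr::map_dbl(seq_len(nrow(out)), function(i) {
      inside <- tr$chrom == out$chrom[i] &
        tr$start >= out$start[i] & tr$start < out$end[i]
      if (!any(inside)) NA_real_ else mean(norm[inside])
    })
  }
  out <- out[!is.na(out$timing), , drop = FALSE]
  out[order(out$timing, out$chrom, out$start), , drop = FALSE]
}
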