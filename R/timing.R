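#' Weighted replication-timing score of four-fraction signal
#'
#' The score of a bin with RPKM vector `x` over the four S-phase fractions
#' is the normalised weighted average \eqn{(\sum_k w_k x_k) / (\sum_k x_k)}
#' with weights the fraction-window midpoints ([timing_weights]). It lies
#' in \[0.125, 0.875\] (the bounds attained only when all reads fall in a
#' single fraction), is invariant to rescaling `x` by a positive constant,
#' and is missing (`NA`) exactly where all four fractions are zero. High
#' values mean early replication.
#'
#' @param x numeric vector of length 4 (late, late-mid, early-mid, early)
#'   or a matrix/data frame with one such row per bin; values must be
#'   non-negative.
#' @param weights the four fraction weights, latest fraction first.
#' @return numeric score(s) in \[0.125, 0.875\] or `NA`.
#' @examples
#' weighted_timing_score(c(0, 0, 0, 100))  # all reads earliest -> 0.875
#' weighted_timing_score(c(1, 1, 1, 1))    # flat -> 0.5
#' @export
weighted_timing_score <- function(x, weights = timing_weights) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != 4) abort("`x` must have four fraction columns")
  if (any(x < 0, na.rm = TRUE)) abort("fraction signal must be non-negative")
  total <- rowSums(x)
  score <- as.vector(x %*% unname(weights)) / total
  score[total == 0] <- NA_real_
  score
}

#' Compute the per-bin timing score for a fraction table
#'
#' @param signal a [bin_fractions()] table on the profile grid
#'   (10-kb nonoverlapping bins by default).
#' @param weights see [weighted_timing_score()].
#' @return tibble of class `timing_profile` with `chrom`, `start`, `end`
#'   and `score`.
#' @export
timing_score <- function(signal, weights = timing_weights) {
  out <- signal[, c("chrom", "start", "end")]
  out$score <- weighted_timing_score(as.matrix(signal[, fraction_levels]),
                                     weights)
  class(out) <- c("timing_profile", class(out))
  out
}

#' Smooth a timing profile along each chromosome
#'
#' Local polynomial regression (loess: tricube weights, degree 2) of the
#' raw score against the bin midpoint, fitted per chromosome with a
#' neighbourhood equivalent to `window_bp` (default 200 kb, i.e. 20 bins of
#' 10 kb), expressed as a span of `max(window_bp / bin_width, 4)` points
#' over the chromosome's non-missing bins. Missing bins are imputed from
#' the fitted curve and smoothed values are clipped to the attainable score
#' range \[0.125, 0.875\]. Chromosomes with fewer than 4 non-missing bins
#' are passed through unsmoothed with a warning.
#'
#' @param profile a [timing_score()] result.
#' @param window_bp physical smoothing window in bp.
#' @param clip clip smoothed values to \[0.125, 0.875\]?
#' @return the profile with an added `smoothed` column.
#' @export
smooth_profile <- function(profile, window_bp = 2e5, clip = TRUE) {
  width <- median(profile$end - profile$start)
  profile$smoothed <- NA_real_
  for (chrom in unique(profile$chrom)) {
    rows <- which(profile$chrom == chrom)
    mid <- (profile$start[rows] + profile$end[rows]) / 2
    y <- profile$score[rows]
    ok <- !is.na(y)
    if (sum(ok) < 4) {
      warn(paste0("chromosome ", chrom, " has fewer than 4 scored bins; ",
                  "emitting unsmoothed values"))
      profile$smoothed[rows] <- y
      next
    }
    span <- min(max(window_bp / width, 4) / sum(ok), 1)
    fit <- loess(y[ok] ~ mid[ok], span = span, degree = 2,
                 family = "gaussian", surface = "direct")
    profile$smoothed[rows] <- predict(fit, newdata = mid)
  }
  if (clip) {
    profile$smoothed <- pmin(pmax(profile$smoothed, 0.125), 0.875)
  }
  profile
}

#' Log2 early/late replication timing ratio
#'
#' `log2((early + pseudocount) / (late + pseudocount))` using only the
#' earliest and latest fractions. The pseudocount defaults to the 5th
#' percentile of the nonzero early/late RPKM values, which avoids infinite
#' ratios at empty bins while preserving dynamic range; if the two channels
#' are entirely zero the pseudocount falls back to 1.
#'
#' @param signal a [bin_fractions()] table.
#' @param pseudocount positive value added to both channels.
#' @return the table with an added `ratio` column.
#' @export
timing_ratio <- function(signal, pseudocount = NULL) {
  if (is.null(pseudocount)) {
    nz <- c(signal$early, signal$late)
    nz <- nz[nz > 0]
    pseudocount <- if (length(nz)) quantile(nz, 0.05, names = FALSE) else 1
  }
  if (pseudocount <= 0) abort("`pseudocount` must be > 0")
  signal$ratio <- log2((signal$early + pseudocount) /
                       (signal$late + pseudocount))
  attr(signal, "pseudocount") <- pseudocount
  signal
}
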