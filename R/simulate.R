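#' Configuration for the synthetic Repli-Seq generator
#'
#' Bundles everything the generator needs to produce a multi-chromosome
#' genome partitioned into early/late replication domains, four
#' fraction-specific read sets whose across-fraction proportions depend on
#' the planted replication time, per-chromosome copy-number effects, and
#' sparse point features (TSS, ORC) at domain-dependent densities.
#'
#' A bin's reads are apportioned across the four S-phase fractions with
#' probabilities \eqn{p_k(t) \propto \exp(-\kappa (t - m_k)^2)} where
#' \eqn{m_k} are the fraction-window midpoints (0.125, 0.375, 0.625, 0.875)
#' and \eqn{\kappa} (`concentration`) controls how sharply reads concentrate
#' in the fraction whose nominal time window contains the true time `t`.
#' `concentration = 0` gives a flat 1/4 split; large values confine reads to
#' a single fraction. Total reads per bin are Poisson with mean
#' `reads_per_bin` times the chromosome's copy-number multiplier.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp
#'   (at least one chromosome; two or more for realistic genomes).
#' @param domain_min,domain_max domain length bounds in bp.
#' @param frac_early target fraction of the genome in early domains,
#'   in (0, 1).
#' @param copy_number per-chromosome copy-number multiplier; a scalar or a
#'   named vector matching `chrom_sizes` (aneuploidy: e.g. 2 doubles a
#'   chromosome's read depth).
#' @param reads_per_bin mean total reads (summed over the four fractions)
#'   per full-width bin.
#' @param concentration fraction-assignment concentration \eqn{\kappa > 0}
#'   (0 is allowed and means a flat split).
#' @param bin_width simulation bin width in bp (the read-depth unit).
#' @param read_length simulated read length in bp; reads are single-end,
#'   plus strand.
#' @param tss_density,orc_density named vectors `c(early =, late =)` of
#'   point-feature densities per 100 kb by domain label.
#' @param seed integer seed; fixing it fixes every output byte-for-byte.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_genome()], [simulate_fraction_reads()],
#'   [simulate_features()]
#' @export
sim_config <- function(chrom_sizes = c(chr2L = 1e7, chr2R = 1e7),
                       domain_min = 1e5, domain_max = 5e5,
                       frac_early = 0.5,
                       copy_number = 1,
                       reads_per_bin = 100,
                       concentration = 50,
                       bin_width = 1e4,
                       read_length = 50,
                       tss_density = c(early = 10, late = 2),
                       orc_density = c(early = 8, late = 2),
                       seed = 1L) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    abort("`chrom_sizes` must be a named vector of chromosome lengths")
  }
  if (any(chrom_sizes <= 0)) abort("all chromosome lengths must be > 0")
  if (domain_min <= 0 || domain_max < domain_min) {
    abort("need 0 < domain_min <= domain_max")
  }
  if (frac_early <= 0 || frac_early >= 1) abort("`frac_early` must be in (0, 1)")
  if (concentration < 0) abort("`concentration` must be >= 0")
  if (reads_per_bin <= 0 || bin_width <= 0 || read_length <= 0) {
    abort("`reads_per_bin`, `bin_width` and `read_length` must be > 0")
  }
  if (length(copy_number) == 1L) {
    copy_number <- stats::setNames(rep(copy_number, length(chrom_sizes)),
                                   names(chrom_sizes))
  }
  if (!all(names(chrom_sizes) %in% names(copy_number))) {
    abort("`copy_number` must cover every chromosome")
  }
  for (d in list(tss_density, orc_density)) {
    if (!all(c("early", "late") %in% names(d)) || any(d < 0)) {
      abort("feature densities must be named c(early=, late=) and >= 0")
    }
  }
  structure(
    list(chrom_sizes = chrom_sizes, domain_min = domain_min,
         domain_max = domain_max, frac_early = frac_early,
         copy_number = copy_number[names(chrom_sizes)],
         reads_per_bin = reads_per_bin, concentration = concentration,
         bin_width = bin_width, read_length = read_length,
         tss_density = tss_density, orc_density = orc_density,
         seed = as.integer(seed)),
    class = "sim_config")
}

# True-time ranges by label, matching the extreme S-phase fraction
# windows: early domains draw t from the earliest window [0.75, 1], late
# domains from the latest [0, 0.25].
.t_range <- list(early = c(0.75, 1), late = c(0, 0.25))

#' Plant early/late replication domains on a synthetic genome
#'
#' Tiles each chromosome with domains of random length drawn from
#' `[domain_min, domain_max]`. Each new domain takes the label (early or
#' late) that moves the running genome-wide early fraction toward
#' `frac_early`, which keeps the achieved fraction within a few percentage
#' points of the target on genomes of 10 Mb and more. Every domain carries a
#' constant true replication time `t` drawn uniformly from the label's range
#' extreme fraction window (early: \[0.75, 1\], late: \[0, 0.25\]).
#'
#' @param config a [sim_config()].
#' @return a tibble of class `repli_truth` with columns `chrom`, `start`,
#'   `end` (0-based half-open), `label` and `t`; the intervals are disjoint
#'   and tile each chromosome. The config is attached as attribute
#'   `"config"`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$domain_min > min(config$chrom_sizes)) {
    abort("`domain_min` exceeds a chromosome length; domains cannot tile it")
  }
  withr::with_seed(config$seed, {
    early_bp <- 0
    total_bp <- 0
    rows <- list()
    for (chrom in names(config$chrom_sizes)) {
      size <- config$chrom_sizes[[chrom]]
      pos <- 0
      while (pos < size) {
        len <- if (config$domain_min == config$domain_max) config$domain_min
               else round(runif(1, config$domain_min, config$domain_max))
        end <- min(pos + len, size)
        label <- if (total_bp == 0 || early_bp / total_bp < config$frac_early)
          "early" else "late"
        rng <- .t_range[[label]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          chrom = chrom, start = pos, end = end, label = label,
          t = runif(1, rng[1], rng[2]))
        if (label == "early") early_bp <- early_bp + (end - pos)
        total_bp <- total_bp + (end - pos)
        pos <- end
      }
    }
    truth <- dplyr::bind_rows(rows)
  })
  attr(truth, "config") <- config
  class(truth) <- c("repli_truth", class(truth))
  truth
}

# Look up, per position, the planted domain row index (positions 0-based).
.truth_index <- function(truth, chrom, pos) {
  d <- truth[truth$chrom == chrom, , drop = FALSE]
  i <- findInterval(pos, d$start)
  i[i < 1L | pos >= d$end[pmax(i, 1L)]] <- NA_integer_
  list(domains = d, index = i)
}

#' Per-bin planted truth on a regular grid
#'
#' @param truth a [simulate_genome()] result.
#' @param width bin width in bp.
#' @return tibble with `chrom`, `start`, `end`, `label`, `t`: the planted
#'   label and true time of the domain containing each bin start.
#' @export
truth_bins <- function(truth, width = 1e4) {
  config <- attr(truth, "config")
  sizes <- if (!is.null(config)) config$chrom_sizes else
    tapply(truth$end, truth$chrom, max)[unique(truth$chrom)]
  grid <- bin_grid(sizes, width = width)
  purrr::map_dfr(split(grid, grid$chrom)[unique(grid$chrom)], function(g) {
    lk <- .truth_index(truth, g$chrom[1], g$start)
    g$label <- lk$domains$label[lk$index]
    g$t <- lk$domains$t[lk$index]
    g
  })
}

# Fraction-assignment probabilities p_k(t), rows = bins, cols = fractions
# ordered late .. early; p_k(t) proportional to exp(-kappa (t - m_k)^2).
fraction_probs <- function(t, concentration) {
  m <- matrix(unname(timing_weights), nrow = length(t), ncol = 4, byrow = TRUE)
  w <- exp(-concentration * (t - m)^2)
  w / rowSums(w)
}

#' Simulate four fraction-specific Repli-Seq read sets
#'
#' For each `bin_width` bin the total read count is Poisson with mean
#' `reads_per_bin` scaled by the chromosome's copy-number multiplier and by
#' the bin's width (the terminal bin of a chromosome may be short). Reads
#' are apportioned across the four fractions with the concentration model
#' described in [sim_config()] and placed uniformly within the bin as
#' single-end plus-strand intervals of `read_length` bp.
#'
#' @inheritParams truth_bins
#' @param config the [sim_config()] used to generate `truth`.
#' @return tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `strand` (`"+"`), and `fraction` (factor over [fraction_levels]).
#' @export
simulate_fraction_reads <- function(truth, config = attr(truth, "config")) {
  stopifnot(inherits(config, "sim_config"))
  missing_chroms <- setdiff(names(config$chrom_sizes), unique(truth$chrom))
  if (length(missing_chroms)) {
    abort(paste("truth does not cover chromosome(s):",
                paste(missing_chroms, collapse = ", ")))
  }
  bins <- truth_bins(truth, config$bin_width)
  withr::with_seed(config$seed + 1L, {
    lambda <- config$reads_per_bin *
      config$copy_number[bins$chrom] *
      (bins$end - bins$start) / config$bin_width
    n <- rpois(nrow(bins), lambda)
    keep <- n > 0L
    bins <- bins[keep, , drop = FALSE]
    n <- n[keep]
    p <- fraction_probs(bins$t, config$concentration)
    cum <- t(apply(p, 1, cumsum))
    bin_of_read <- rep.int(seq_len(nrow(bins)), n)
    u <- runif(length(bin_of_read))
    frac_idx <- 1L + (u > cum[bin_of_read, 1]) + (u > cum[bin_of_read, 2]) +
      (u > cum[bin_of_read, 3])
    bin_len <- bins$end[bin_of_read] - bins$start[bin_of_read]
    offset <- floor(runif(length(bin_of_read)) * pmax(bin_len, 1))
    start <- bins$start[bin_of_read] + pmin(offset, bin_len - 1)
    size <- config$chrom_sizes[bins$chrom[bin_of_read]]
    reads <- tibble::tibble(
      chrom = bins$chrom[bin_of_read],
      start = start,
      end = pmin(start + config$read_length, unname(size)),
      strand = "+",
      fraction = factor(fraction_levels[frac_idx], levels = fraction_levels))
    dplyr::arrange(reads, .data$chrom, .data$start)
  })
}

#' Simulate point features with domain-dependent density
#'
#' Places a homogeneous point process within every planted domain at the
#' density configured for the domain's label (per 100 kb), emulating
#' features such as transcription start sites or ORC binding sites that are
#' denser in early-replicating chromatin.
#'
#' @inheritParams simulate_fraction_reads
#' @param feature `"tss"` or `"orc"`, selecting which configured density
#'   pair to use.
#' @return tibble with `chrom`, `start`, `end` (= start + 1) and `feature`.
#' @export
simulate_features <- function(truth, config = attr(truth, "config"),
                              feature = c("tss", "orc")) {
  feature <- match.arg(feature)
  stopifnot(inherits(config, "sim_config"))
  density <- config[[paste0(feature, "_density")]]
  seed_offset <- if (feature == "tss") 2L else 3L
  withr::with_seed(config$seed + seed_offset, {
    lambda <- density[truth$label] * (truth$end - truth$start) / 1e5
    n <- rpois(nrow(truth), lambda)
    dom <- rep.int(seq_len(nrow(truth)), n)
    pos <- truth$start[dom] +
      floor(runif(length(dom)) * (truth$end[dom] - truth$start[dom]))
    out <- tibble::tibble(chrom = truth$chrom[dom], start = pos,
                          end = pos + 1, feature = feature)
    dplyr::arrange(out, .data$chrom, .data$start)
  })
}

#' Flip the label of planted domains to create a derived cell line
#'
#' Relabels a subset of domains (early to late or vice versa) covering
#' approximately `prop` of the genome, redrawing each flipped domain's true
#' time from its new label's range. Used to simulate a cell line that
#' shares most of its replication program with the original but switches
#' the timing of a known fraction of the genome.
#'
#' @inheritParams simulate_fraction_reads
#' @param prop target fraction of genome bp to switch.
#' @param seed seed for the domain selection and new times.
#' @return a new `repli_truth` whose attribute `"flipped"` gives the row
#'   indices of the switched domains.
#' @export
flip_domains <- function(truth, prop = 0.1, seed = 100L,
                         config = attr(truth, "config")) {
  target <- prop * sum(truth$end - truth$start)
  withr::with_seed(as.integer(seed), {
    ord <- sample.int(nrow(truth))
    len <- truth$end - truth$start
    cum <- 0
    chosen <- integer()
    for (i in ord) {
      if (abs(cum + len[i] - target) < abs(cum - target)) {
        chosen <- c(chosen, i)
        cum <- cum + len[i]
      }
      if (cum >= target) break
    }
    out <- truth
    out$label[chosen] <- ifelse(out$label[chosen] == "early", "late", "early")
    for (i in chosen) {
      rng <- .t_range[[out$label[i]]]
      out$t[i] <- runif(1, rng[1], rng[2])
    }
  })
  attr(out, "config") <- config
  attr(out, "flipped") <- sort(chosen)
  out
}
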