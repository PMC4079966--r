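#' Pipeline configuration with the study's default constants
#'
#' Collects every tunable of the profile/segmentation/comparison pipeline.
#' Defaults are the published analysis constants: 10-kb nonoverlapping
#' profile bins; 5-kb windows stepped every 1 kb for segmentation; timing
#' weights 0.125/0.375/0.625/0.875; ~200-kb loess window; 95th-percentile
#' signal cap; Baum-Welch log-likelihood tolerance 0.05; 40-window
#' (~45 kb) minimum run.
#'
#' @param profile_bin profile grid bin width (bp).
#' @param seg_width,seg_step segmentation window width and step (bp).
#' @param weights fraction timing weights (see [timing_weights]).
#' @param loess_window_bp smoothing window (bp).
#' @param cap_q percentile cap.
#' @param hmm_tol Baum-Welch stopping tolerance.
#' @param min_run minimum contiguous windows per domain.
#' @param self_trans initial self-transition probability.
#' @param chromosomes optional include-list of chromosome names; `NULL`
#'   means all chromosomes in the inputs.
#' @param seed seed used for k-means initialisation.
#' @return a `repli_config` list.
#' @export
repli_config <- function(profile_bin = 1e4, seg_width = 5e3, seg_step = 1e3,
                         weights = timing_weights, loess_window_bp = 2e5,
                         cap_q = 95, hmm_tol = 0.05, min_run = 40,
                         self_trans = 0.998, chromosomes = NULL,
                         seed = 1L) {
  structure(list(profile_bin = profile_bin, seg_width = seg_width,
                 seg_step = seg_step, weights = weights,
                 loess_window_bp = loess_window_bp, cap_q = cap_q,
                 hmm_tol = hmm_tol, min_run = min_run,
                 self_trans = self_trans, chromosomes = chromosomes,
                 seed = as.integer(seed)),
            class = "repli_config")
}

config_provenance <- function(config, seed = config$seed) {
  pl <- unclass(config)
  pl$weights <- as.list(pl$weights)
  list(config = pl, seed = seed)
}

filter_chroms <- function(chrom_sizes, config) {
  if (is.null(config$chromosomes)) return(chrom_sizes)
  keep <- intersect(config$chromosomes, names(chrom_sizes))
  dropped <- setdiff(config$chromosomes, names(chrom_sizes))
  if (length(dropped)) {
    warn(paste("chromosome(s) not present in the input, skipped:",
               paste(dropped, collapse = ", ")))
  }
  chrom_sizes[keep]
}

resolve_fraction_reads <- function(reads, chroms = NULL) {
  if (is.data.frame(reads)) {
    if (!"fraction" %in% names(reads)) {
      abort("`reads` data frame must carry a `fraction` column")
    }
    reads <- split(reads, factor(reads$fraction, levels = fraction_levels))
  }
  missing_fr <- setdiff(fraction_levels, names(reads))
  if (length(missing_fr)) {
    abort(paste("missing input for fraction(s):",
                paste(missing_fr, collapse = ", ")))
  }
  lapply(reads[fraction_levels], function(x) {
    if (is.character(x)) x <- read_reads(x)
    # drop reads outside the configured chromosome include-list silently:
    # the exclusion is deliberate, unlike reads on unknown chromosomes
    if (!is.null(chroms)) x <- x[x$chrom %in% chroms, , drop = FALSE]
    x
  })
}

#' Run the continuous timing-profile stage
#'
#' Binning (10-kb RPKM per fraction), weighted timing score, loess
#' smoothing, and the log2 early/late ratio, optionally written as
#' bedGraph tracks with a provenance sidecar.
#'
#' @param reads the four fraction read sets: a named list (`late`,
#'   `late_mid`, `early_mid`, `early`) of read tibbles or file paths
#'   (BED/BAM), or one tibble with a `fraction` column.
#' @param chrom_sizes named chromosome lengths or a chrom.sizes path.
#' @param config a [repli_config()].
#' @param out_dir if given, writes `score.bedGraph`,
#'   `smoothed.bedGraph` and `ratio.bedGraph` there.
#' @return a [timing_score()] profile tibble with `score`, `smoothed` and
#'   `ratio` columns.
#' @export
run_profile <- function(reads, chrom_sizes, config = repli_config(),
                        out_dir = NULL) {
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)
  chrom_sizes <- filter_chroms(chrom_sizes, config)
  reads <- resolve_fraction_reads(reads, names(chrom_sizes))
  grid <- bin_grid(chrom_sizes, width = config$profile_bin)
  signal <- bin_fractions(reads, grid)
  signal <- timing_ratio(signal)
  profile <- timing_score(signal, config$weights)
  profile <- smooth_profile(profile, window_bp = config$loess_window_bp)
  profile$ratio <- signal$ratio
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- config_provenance(config)
    for (col in c("score", "smoothed", "ratio")) {
      write_bedgraph(profile, col,
                     file.path(out_dir, paste0(col, ".bedGraph")), prov)
    }
  }
  profile
}

#' Run the domain-segmentation stage
#'
#' Binning on the sliding segmentation grid, per-chromosome weighting,
#' percentile capping, and the three-state HMM segmentation
#' ([segment_genome()]); optionally writes the domain BED (name = label,
#' score = mean posterior of the assigned state), per-chromosome model
#' JSON sidecars and the training trace.
#'
#' @inheritParams run_profile
#' @param sample sample id recorded on the domains.
#' @return a [segment_genome()] result.
#' @export
run_domains <- function(reads, chrom_sizes, config = repli_config(),
                        sample = "sample", out_dir = NULL) {
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)
  chrom_sizes <- filter_chroms(chrom_sizes, config)
  reads <- resolve_fraction_reads(reads, names(chrom_sizes))
  grid <- bin_grid(chrom_sizes, width = config$seg_width,
                   step = config$seg_step)
  signal <- bin_fractions(reads, grid)
  signal <- normalize_by_chromosome(signal)
  signal <- cap_percentile(signal, config$cap_q)
  signal <- timing_ratio(signal)
  seg <- segment_genome(signal, min_run = config$min_run,
                        tol = config$hmm_tol, seed = config$seed,
                        self_trans = config$self_trans, sample = sample)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- config_provenance(config)
    dom <- seg$domains
    dom$score <- domain_mean_posterior(seg)
    write_bed(dom, file.path(out_dir, paste0(sample, "_domains.bed")), prov)
    for (chrom in names(seg$models)) {
      write_model_json(seg$models[[chrom]],
                       file.path(out_dir,
                                 paste0(sample, "_", chrom, "_model.json")))
    }
  }
  seg
}

# Mean posterior probability of the assigned state over each domain.
domain_mean_posterior <- function(seg) {
  purrr::map_dbl(seq_len(nrow(seg$domains)), function(i) {
    d <- seg$domains[i, ]
    rows <- seg$states$chrom == d$chrom & seg$states$start >= d$start &
      seg$states$start < d$end
    mean(seg$states$posterior[rows])
  })
}

#' Run the cross-cell-line comparison stage
#'
#' Position-level static/dynamic classification over two or more domain
#' sets ([classify_positions()]) and the per-class genome fractions,
#' optionally written as a class BED and a JSON report.
#'
#' @param domain_sets list of domain tables or BED paths (BED name field =
#'   label).
#' @inheritParams run_profile
#' @return a [classify_positions()] result.
#' @export
run_compare <- function(domain_sets, config = repli_config(),
                        out_dir = NULL) {
  domain_sets <- lapply(domain_sets, function(d) {
    if (is.character(d)) {
      d <- read_bed(d)
      names(d)[names(d) == "name"] <- "label"
    }
    d
  })
  classes <- classify_positions(domain_sets, step = config$seg_step)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- config_provenance(config)
    iv <- classes$intervals
    iv$label <- iv$class
    write_bed(iv, file.path(out_dir, "classes.bed"), prov)
    report <- list(
      fractions = as.list(stats::setNames(classes$fractions$fraction,
                                          as.character(
                                            classes$fractions$class))),
      step = classes$step, provenance = prov)
    jsonlite::write_json(report, file.path(out_dir, "compare_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  classes
}
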