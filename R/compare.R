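#' Classify genome positions as static or dynamic across cell lines
#'
#' Applies the position-level rule on a regular grid (default 1 kb):
#' positions called early in every sample are `static_early`, late in
#' every sample `static_late`, early in at least one sample and late in at
#' least one other `dynamic`; everything else (an indeterminate call
#' without an early/late conflict, or no domain coverage) is
#' `indeterminate`. Contiguous same-class positions are merged into
#' intervals. The rule is symmetric in sample order, and adding a sample
#' can only move positions toward `dynamic` or `indeterminate`.
#'
#' @param domains a list of two or more domain tables (as in
#'   [segment_genome()]`$domains` or read from BED), or one table with a
#'   `sample` column; all samples must cover the same chromosome set.
#' @param step classification grid step in bp.
#' @return object of class `repli_classes`: list with `intervals` (tibble
#'   `chrom`, `start`, `end`, `class`), `fractions` (per-class bp and
#'   genome fraction) and `step`.
#' @export
classify_positions <- function(domains, step = 1000) {
  if (is.data.frame(domains)) {
    if (!"sample" %in% names(domains)) {
      abort("a single domain table needs a `sample` column")
    }
    domains <- split(domains, domains$sample)
  }
  if (length(domains) < 2) abort("need at least 2 samples to compare")
  chrom_sets <- lapply(domains, function(d) sort(unique(d$chrom)))
  if (length(unique(chrom_sets)) != 1) {
    mism <- unique(unlist(chrom_sets))
    missing_in <- purrr::map_chr(names(domains) %||% seq_along(domains),
      function(nm) {
        d <- chrom_sets[[nm]]
        paste0(nm, ": missing ", paste(setdiff(mism, d), collapse = ","))
      })
    abort(paste("samples cover mismatched chromosome sets —",
                paste(missing_in[grepl("missing .+", missing_in)],
                      collapse = "; ")))
  }
  chroms <- chrom_sets[[1]]
  sizes <- purrr::map_dbl(chroms, function(ch) {
    max(purrr::map_dbl(domains, function(d) max(d$end[d$chrom == ch])))
  })
  names(sizes) <- chroms

  intervals <- purrr::map_dfr(chroms, function(ch) {
    pos <- seq(0, sizes[[ch]] - 1, by = step)
    calls <- vapply(domains, function(d) {
      dd <- d[d$chrom == ch, , drop = FALSE]
      dd <- dd[order(dd$start), , drop = FALSE]
      i <- findInterval(pos, dd$start)
      lab <- rep(NA_character_, length(pos))
      hit <- i >= 1 & pos < dd$end[pmax(i, 1L)]
      lab[hit] <- dd$label[i[hit]]
      lab
    }, character(length(pos)))
    any_early <- rowSums(calls == "early", na.rm = TRUE) > 0
    any_late <- rowSums(calls == "late", na.rm = TRUE) > 0
    all_early <- rowSums(calls == "early", na.rm = TRUE) == ncol(calls)
    all_late <- rowSums(calls == "late", na.rm = TRUE) == ncol(calls)
    cls <- dplyr::case_when(
      all_early ~ "static_early",
      all_late ~ "static_late",
      any_early & any_late ~ "dynamic",
      TRUE ~ "indeterminate")
    r <- rle(cls)
    last <- cumsum(r$lengths)
    first <- c(1L, utils::head(last, -1) + 1L)
    tibble::tibble(chrom = ch, start = pos[first],
                   end = pmin(pos[last] + step, sizes[[ch]]),
                   class = r$values)
  })
  out <- structure(list(intervals = intervals, step = step),
                   class = "repli_classes")
  out$fractions <- genome_fractions(out)
  out
}

#' Genome fraction in each static/dynamic class
#'
#' @param classes a [classify_positions()] result (or its `intervals`
#'   tibble).
#' @param genome_size total bp to use as denominator; defaults to the bp
#'   covered by the classified intervals, in which case the fractions sum
#'   to 1 exactly.
#' @return tibble with `class`, `bp` and `fraction`, ordered
#'   static_early, static_late, dynamic, indeterminate.
#' @export
genome_fractions <- function(classes, genome_size = NULL) {
  intervals <- if (inherits(classes, "repli_classes")) classes$intervals
               else classes
  bp <- tapply(intervals$end - intervals$start, intervals$class, sum)
  if (is.null(genome_size)) genome_size <- sum(intervals$end - intervals$start)
  tibble::tibble(
    class = factor(class_levels, levels = class_levels),
    bp = as.numeric(bp[class_levels]) %>% tidyr::replace_na(0),
    fraction = .data$bp / genome_size)
}

#' @export
print.repli_classes <- function(x, ...) {
  cat("Cross-sample replication classes (", x$step, "bp grid )\n")
  f <- x$fractions
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-13s %5.1f%%\n", f$class[i], 100 * f$fraction[i]))
  }
  invisible(x)
}

#' @export
tidy.repli_classes <- function(x, ...) x$intervals

#' @export
glance.repli_classes <- function(x, ...) {
  f <- x$fractions
  tibble::tibble(
    static_early = f$fraction[f$class == "static_early"],
    static_late = f$fraction[f$class == "static_late"],
    dynamic = f$fraction[f$class == "dynamic"],
    indeterminate = f$fraction[f$class == "indeterminate"],
    n_intervals = nrow(x$intervals))
}

#' Per-chromosome timing summaries and a target-vs-autosome test
#'
#' Five-number summaries of the per-bin timing values for every
#' chromosome, plus a two-sided Mann-Whitney (Wilcoxon rank-sum) test of
#' the target chromosome's bins against the pooled background chromosomes
#' — the comparison used to ask whether the male X replicates earlier than
#' the autosomes.
#'
#' @param profile a [timing_score()]/[smooth_profile()] table; the
#'   `smoothed` column is used when present, else `score`. Missing bins
#'   are dropped.
#' @param target chromosome to test (e.g. `"chrX"`).
#' @param background chromosomes to pool; defaults to all others.
#' @return list of class `chrom_timing_summary` with `by_chromosome`
#'   (tibble of n, min, q1, median, q3, max, mean per chromosome) and
#'   `test` (tibble with the W statistic, p-value and group sizes).
#' @export
chromosome_timing_summary <- function(profile, target,
                                      background = NULL) {
  value <- if ("smoothed" %in% names(profile)) profile$smoothed
           else profile$score
  keep <- !is.na(value)
  chrom <- profile$chrom[keep]
  value <- value[keep]
  if (is.null(background)) background <- setdiff(unique(chrom), target)
  if (!any(chrom == target)) abort(paste("no scored bins on", target))
  if (!any(chrom %in% background)) abort("no scored bins in the background")
  by_chromosome <- purrr::map_dfr(unique(chrom), function(ch) {
    v <- value[chrom == ch]
    q <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    tibble::tibble(chrom = ch, n = length(v), min = q[1], q1 = q[2],
                   median = q[3], q3 = q[4], max = q[5], mean = mean(v))
  })
  wt <- wilcox.test(value[chrom == target],
                    value[chrom %in% background],
                    alternative = "two.sided", exact = FALSE)
  structure(
    list(by_chromosome = by_chromosome,
         test = tibble::tibble(
           target = target,
           statistic = unname(wt$statistic),
           p.value = wt$p.value,
           n_target = sum(chrom == target),
           n_background = sum(chrom %in% background))),
    class = "chrom_timing_summary")
}

#' @export
print.chrom_timing_summary <- function(x, ...) {
  print(x$by_chromosome)
  cat(sprintf("%s vs pooled background: Mann-Whitney p = %.3g\n",
              x$test$target, x$test$p.value))
  invisible(x)
}
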