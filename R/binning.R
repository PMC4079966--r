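#' Build a genomic bin grid
#'
#' Grids are 0-based half-open. With `step = width` the grid is
#' nonoverlapping (the 10-kb profile grid); with `step < width` it is a
#' sliding-window grid (the 5-kb windows stepped every 1 kb used for
#' segmentation). The terminal bin of each chromosome is truncated at the
#' chromosome end. `width` must be a multiple of `step`.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths, or a
#'   data frame with columns `chrom` and `size`.
#' @param width bin width in bp.
#' @param step distance between consecutive bin starts; defaults to `width`.
#' @return tibble with `chrom`, `start`, `end`, carrying `width` and `step`
#'   as attributes.
#' @examples
#' bin_grid(c(chr1 = 25000), width = 10000)
#' @export
bin_grid <- function(chrom_sizes, width, step = width) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- stats::setNames(chrom_sizes$size, chrom_sizes$chrom)
  }
  if (width <= 0 || step <= 0 || step > width) {
    abort("need width > 0 and 0 < step <= width")
  }
  if (width %% step != 0) abort("`width` must be a multiple of `step`")
  grid <- purrr::map_dfr(names(chrom_sizes), function(chrom) {
    size <- chrom_sizes[[chrom]]
    starts <- seq(0, size - 1, by = step)
    tibble::tibble(chrom = chrom, start = starts,
                   end = pmin(starts + width, size))
  })
  attr(grid, "width") <- width
  attr(grid, "step") <- step
  grid
}

grid_step <- function(grid) {
  s <- attr(grid, "step")
  if (is.null(s)) {
    d <- diff(grid$start[grid$chrom == grid$chrom[1]])
    s <- if (length(d)) min(d) else grid$end[1] - grid$start[1]
  }
  s
}

grid_width <- function(grid) {
  w <- attr(grid, "width")
  if (is.null(w)) w <- max(grid$end - grid$start)
  w
}

#' Count reads per bin
#'
#' Each read is reduced to its 5'-most aligned position (strand-aware:
#' `start` on the plus strand, `end - 1` on the minus strand) and assigned
#' to every window containing that position — exactly one window on a
#' nonoverlapping grid, `width/step` windows on a sliding grid. Reads on
#' chromosomes absent from the grid are skipped with a warning.
#'
#' @param reads data frame with `chrom`, `start`, `end` and optionally
#'   `strand` (assumed `"+"` when missing).
#' @param grid a [bin_grid()].
#' @return the grid tibble with an added `count` column.
#' @export
count_reads <- function(reads, grid) {
  width <- grid_width(grid)
  step <- grid_step(grid)
  k <- width %/% step
  strand <- if ("strand" %in% names(reads)) reads$strand else "+"
  pos <- ifelse(strand == "-", reads$end - 1, reads$start)
  off <- !(reads$chrom %in% grid$chrom)
  if (any(off)) {
    warn(paste0("skipping ", sum(off), " read(s) on chromosome(s) absent ",
                "from the grid: ",
                paste(unique(reads$chrom[off]), collapse = ", ")))
  }
  counts <- purrr::map(split(seq_len(nrow(grid)), grid$chrom), function(idx) {
    chrom <- grid$chrom[idx[1]]
    nwin <- length(idx)
    p <- pos[!off & reads$chrom == chrom]
    cell <- p %/% step
    cell <- cell[cell >= 0 & cell < nwin]
    cell_counts <- tabulate(cell + 1L, nbins = nwin)
    cs <- c(0, cumsum(cell_counts))
    # window j (0-based) spans cells j .. min(j + k, nwin) - 1
    j <- seq_len(nwin) - 1L
    cs[pmin(j + k, nwin) + 1L] - cs[j + 1L]
  })
  out <- grid
  out$count <- 0L
  for (chrom in names(counts)) {
    out$count[out$chrom == chrom] <- counts[[chrom]]
  }
  out
}

#' Convert per-bin counts to RPKM
#'
#' RPKM = count / (bin length in kb \eqn{\times} mapped reads in millions),
#' the depth- and length-normalised coverage unit used for all downstream
#' signal.
#'
#' @param counts a [count_reads()] result (columns `chrom`, `start`, `end`,
#'   `count`).
#' @param library_size total mapped reads for the fraction; must be > 0.
#' @return the input tibble with an `rpkm` column.
#' @export
rpkm <- function(counts, library_size) {
  if (length(library_size) != 1 || library_size <= 0) {
    abort("`library_size` must be a single count > 0")
  }
  counts$rpkm <- counts$count /
    (((counts$end - counts$start) / 1000) * (library_size / 1e6))
  counts
}

#' Bin four fraction read sets into a joint RPKM table
#'
#' @param reads data frame of reads with a `fraction` column over
#'   [fraction_levels], or a named list of per-fraction read tables.
#' @param grid a [bin_grid()].
#' @param library_sizes optional named per-fraction totals; defaults to the
#'   number of reads supplied per fraction.
#' @return tibble with `chrom`, `start`, `end` and one RPKM column per
#'   fraction (`late`, `late_mid`, `early_mid`, `early`); per-fraction
#'   library sizes are attached as attribute `"library_sizes"`.
#' @export
bin_fractions <- function(reads, grid, library_sizes = NULL) {
  if (is.data.frame(reads)) {
    if (!"fraction" %in% names(reads)) {
      abort("`reads` data frame must have a `fraction` column")
    }
    reads <- split(reads, factor(reads$fraction, levels = fraction_levels))
  }
  missing_fr <- setdiff(fraction_levels, names(reads))
  if (length(missing_fr)) {
    abort(paste("missing read set for fraction(s):",
                paste(missing_fr, collapse = ", ")))
  }
  if (is.null(library_sizes)) {
    library_sizes <- vapply(reads[fraction_levels], nrow, integer(1))
  }
  out <- grid[, c("chrom", "start", "end")]
  for (fr in fraction_levels) {
    out[[fr]] <- rpkm(count_reads(reads[[fr]], grid),
                      library_sizes[[fr]])$rpkm
  }
  attr(out, "width") <- grid_width(grid)
  attr(out, "step") <- grid_step(grid)
  attr(out, "library_sizes") <- library_sizes
  out
}

#' Weight fraction signal for proportional chromosome representation
#'
#' RPKM standardises library size, which hides per-chromosome copy-number
#' differences in aneuploid lines. Dividing every bin value by the mean
#' RPKM over all four fractions and all bins of its chromosome restores
#' proportional representation of each chromosome. Chromosomes whose mean
#' is zero are left untouched with a warning.
#'
#' @param signal a [bin_fractions()] table.
#' @param invert if `TRUE`, multiply by the per-chromosome mean instead of
#'   dividing (retained as the inverse reading of the weighting rule).
#' @return the table with fraction columns rescaled per chromosome.
#' @export
normalize_by_chromosome <- function(signal, invert = FALSE) {
  for (chrom in unique(signal$chrom)) {
    rows <- signal$chrom == chrom
    m <- mean(as.matrix(signal[rows, fraction_levels]))
    if (m == 0) {
      warn(paste0("chromosome ", chrom,
                  " has zero mean RPKM; left unnormalized"))
      next
    }
    for (fr in fraction_levels) {
      signal[[fr]][rows] <- if (invert) signal[[fr]][rows] * m
                            else signal[[fr]][rows] / m
    }
  }
  signal
}

#' Cap signal at a genome-wide percentile
#'
#' Guards against spuriously amplified regions by setting, per fraction,
#' every value above that fraction's genome-wide `q`-th percentile to the
#' percentile value (quantile type 7, linear interpolation). Idempotent and
#' order-preserving below the cap.
#'
#' @param signal a [bin_fractions()] table.
#' @param q percentile in (0, 100); default 95.
#' @return the capped table.
#' @export
cap_percentile <- function(signal, q = 95) {
  if (q <= 0 || q >= 100) abort("`q` must be in (0, 100)")
  for (fr in fraction_levels) {
    cap <- quantile(signal[[fr]], q / 100, names = FALSE, type = 7)
    signal[[fr]] <- pmin(signal[[fr]], cap)
  }
  signal
}
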