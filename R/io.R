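need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    abort(paste0("package `", pkg, "` is required for this reader/writer"))
  }
}

#' Read a two-column chrom.sizes file
#'
#' @param path tab-separated file with chromosome name and length.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("chrom", "size"),
                         col_types = "cd", comment = "#")
  stats::setNames(tbl$size, tbl$chrom)
}

# Interval tibble -> GRanges (0-based half-open in, 1-based closed inside).
as_granges <- function(df) {
  need_pkg("GenomicRanges")
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*")
}

gr_to_tibble <- function(gr) {
  tbl <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr))
  mcols <- as.data.frame(GenomicRanges::mcols(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand != "*")) tbl$strand <- strand
  dplyr::bind_cols(tbl, tibble::as_tibble(mcols))
}

#' Read intervals from a BED file
#'
#' @param path BED path (0-based half-open).
#' @return tibble with `chrom`, `start`, `end` plus `name`/`score`/`strand`
#'   when present.
#' @export
read_bed <- function(path) {
  need_pkg("rtracklayer")
  gr_to_tibble(rtracklayer::import(path, format = "BED"))
}

#' Read aligned reads from BED or BAM
#'
#' Unmapped records are skipped. BAM requires the `Rsamtools` package.
#'
#' @param path a `.bed` or `.bam` file.
#' @return tibble with `chrom`, `start`, `end`, `strand`, suitable for
#'   [count_reads()].
#' @export
read_reads <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    need_pkg("Rsamtools")
    p <- Rsamtools::ScanBamParam(
      what = c("rname", "pos", "strand", "qwidth"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    ok <- !is.na(b$pos)
    tibble::tibble(chrom = as.character(b$rname[ok]),
                   start = b$pos[ok] - 1,
                   end = b$pos[ok] - 1 + b$qwidth[ok],
                   strand = as.character(b$strand[ok]))
  } else {
    out <- read_bed(path)
    if (!"strand" %in% names(out)) out$strand <- "+"
    out
  }
}

#' Write intervals to BED
#'
#' @param df tibble with `chrom`, `start`, `end`; a `label` (or `name`)
#'   column becomes the BED name field and a `score` column the score
#'   field.
#' @param path output path.
#' @param provenance optional named list written as a JSON sidecar
#'   (`<path>.provenance.json`) recording how the file was produced.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, provenance = NULL) {
  need_pkg("rtracklayer")
  gr <- as_granges(df)
  nm <- if ("label" %in% names(df)) df$label
        else if ("name" %in% names(df)) df$name else NULL
  if (!is.null(nm)) gr$name <- as.character(nm)
  if ("score" %in% names(df)) gr$score <- df$score
  rtracklayer::export(gr, path, format = "BED")
  write_provenance(path, provenance)
  invisible(path)
}

#' Write a per-bin signal track to bedGraph
#'
#' @param df tibble with `chrom`, `start`, `end`.
#' @param value name of the column holding the track value; `NA` bins are
#'   dropped.
#' @param path output path.
#' @inheritParams write_bed
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(df, value, path, provenance = NULL) {
  need_pkg("rtracklayer")
  keep <- !is.na(df[[value]])
  gr <- as_granges(df[keep, , drop = FALSE])
  gr$score <- df[[value]][keep]
  rtracklayer::export(gr, path, format = "bedGraph")
  write_provenance(path, provenance)
  invisible(path)
}

write_provenance <- function(path, provenance) {
  if (is.null(provenance)) return(invisible(NULL))
  provenance$written <- basename(path)
  provenance$package_version <-
    as.character(utils::packageVersion("repliseqr"))
  jsonlite::write_json(provenance, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Serialise a trained HMM to JSON
#'
#' @param model a [repli_hmm()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(init = model$init, trans = model$trans, means = model$means,
         covs = model$covs, labels = model$labels,
         loglik_trace = model$loglik_trace, n_iter = model$n_iter,
         converged = model$converged),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
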