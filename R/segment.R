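#' Merge state runs shorter than a minimum length
#'
#' Replication domains shorter than ~45 kb are not resolvable given the
#' kinetics of BrdU incorporation, so decoded state runs shorter than
#' `min_run` bins (default 40) are merged into a neighbour: iteratively,
#' the globally shortest sub-threshold run is relabelled with the label of
#' its longer flanking run (the only flank at chromosome ends; ties go to
#' the left flank), runs are coalesced, and the scan repeats until no
#' sub-threshold run remains or a single run spans the chromosome.
#'
#' @param labels character/integer vector of per-bin labels for one
#'   chromosome, in genomic order.
#' @param min_run minimum run length in bins.
#' @return relabelled vector of the same length.
#' @examples
#' merge_short_runs(rep(c("early", "late", "early"), c(50, 10, 50)), 40)
#' @export
merge_short_runs <- function(labels, min_run = 40) {
  repeat {
    r <- rle(as.vector(labels))
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_run)
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    left <- if (i > 1) r$lengths[i - 1] else -1L
    right <- if (i < length(r$lengths)) r$lengths[i + 1] else -1L
    r$values[i] <- if (left >= right) r$values[i - 1] else r$values[i + 1]
    labels <- inverse.rle(r)
  }
  labels
}

#' Convert a decoded, merged state sequence to domain intervals
#'
#' Each bin (window) carries the label of its start step; maximal
#' same-label runs become intervals `[first start, last start + step)` in
#' 0-based half-open coordinates, so consecutive domains abut without gap
#' or overlap.
#'
#' @param states tibble with `chrom`, `start` and `label` columns, in
#'   genomic order (one row per window).
#' @param step distance between consecutive window starts in bp; taken
#'   from the table's `"step"` attribute when absent.
#' @return tibble with `chrom`, `start`, `end`, `label` — one row per
#'   domain, disjoint and sorted.
#' @export
states_to_domains <- function(states, step = NULL) {
  if (is.null(step)) step <- grid_step(states)
  purrr::map_dfr(split(states, states$chrom)[unique(states$chrom)],
                 function(s) {
    r <- rle(s$label)
    last <- cumsum(r$lengths)
    first <- c(1L, utils::head(last, -1) + 1L)
    tibble::tibble(chrom = s$chrom[1],
                   start = s$start[first],
                   end = s$start[last] + step,
                   label = r$values)
  })
}

#' Segment a genome into replication domains with the three-state HMM
#'
#' The full segmentation procedure for one cell line: emission parameters
#' are initialised genome-wide by k-means on the log2(early/late) ratio
#' ([init_kmeans()]); then, for each chromosome, the model is trained by
#' Baum-Welch on that chromosome's bivariate (early, late) signal, the
#' Viterbi path is decoded, states are relabelled by their trained
#' emission means, and runs shorter than `min_run` windows are merged.
#'
#' The intended input is the sliding-window fraction signal (5-kb windows
#' every 1 kb), chromosome-weighted ([normalize_by_chromosome()]) and
#' capped at the 95th percentile ([cap_percentile()]).
#'
#' @param signal a [timing_ratio()] table with `early`, `late`, `ratio`.
#' @param min_run minimum number of contiguous windows per domain
#'   (default 40, ~45 kb at 5-kb/1-kb windows).
#' @param tol,max_iter Baum-Welch stopping rule (see [baum_welch()]).
#' @param seed,nstart,self_trans k-means initialisation (see
#'   [init_kmeans()]).
#' @param sample id recorded on the output domains.
#' @return object of class `repli_segmentation`: a list with `domains`
#'   (tibble `chrom`,`start`,`end`,`label`,`sample`), `states` (per-window
#'   decoded and merged labels plus mean posterior of the assigned state),
#'   `init_model`, and `models` (one trained [repli_hmm()] per
#'   chromosome).
#' @export
segment_genome <- function(signal, min_run = 40, tol = 0.05, max_iter = 500,
                           seed = 1L, nstart = 10, self_trans = 0.998,
                           sample = "sample") {
  init_model <- init_kmeans(signal, seed = seed, nstart = nstart,
                            self_trans = self_trans)
  step <- grid_step(signal)
  models <- list()
  states <- purrr::map_dfr(split(signal, signal$chrom)[unique(signal$chrom)],
                           function(sig) {
    chrom <- sig$chrom[1]
    obs <- as_obs_matrix(sig)
    fit <- baum_welch(obs, init_model, tol = tol, max_iter = max_iter)
    models[[chrom]] <<- fit
    path <- viterbi(obs, fit)
    label <- merge_short_runs(fit$labels[path], min_run)
    ld <- emission_logdens(obs, fit)
    fb <- .fb_cpp(ld, log(fit$init), log(fit$trans))
    post <- fb$gamma[cbind(seq_along(path),
                           match(label, fit$labels))]
    tibble::tibble(chrom = chrom, start = sig$start, end = sig$end,
                   state = as.integer(path), label = label,
                   posterior = post)
  })
  attr(states, "step") <- step
  domains <- states_to_domains(states, step)
  domains$sample <- sample
  structure(list(domains = domains, states = states,
                 init_model = init_model, models = models,
                 sample = sample, min_run = min_run),
            class = "repli_segmentation")
}

#' @export
print.repli_segmentation <- function(x, ...) {
  cat("Replication-domain segmentation for", x$sample, "\n")
  bp <- tapply(x$domains$end - x$domains$start, x$domains$label, sum)
  for (lab in intersect(c("early", "late", "indeterminate"), names(bp))) {
    cat(sprintf("  %-13s %5.1f%% (%d domains)\n", lab,
                100 * bp[[lab]] / sum(bp),
                sum(x$domains$label == lab)))
  }
  invisible(x)
}

#' @export
tidy.repli_segmentation <- function(x, ...) x$domains

#' @export
glance.repli_segmentation <- function(x, ...) {
  gl <- purrr::map_dfr(x$models, glance, .id = "chrom")
  tibble::tibble(
    n_chromosomes = nrow(gl),
    n_domains = nrow(x$domains),
    logLik = sum(gl$logLik),
    max_iter_used = max(gl$n_iter),
    all_converged = all(gl$converged))
}
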