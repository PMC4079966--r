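#' Three-state Gaussian hidden Markov model for replication domains
#'
#' Constructs the segmentation model: three hidden states (late,
#' indeterminate, early replication) each emitting a bivariate normal over
#' the joint (early-fraction, late-fraction) signal, with initial state
#' probabilities and a row-stochastic transition matrix.
#'
#' @param init numeric vector of 3 initial probabilities (sums to 1).
#' @param trans 3x3 transition matrix, rows summing to 1.
#' @param means 3x2 matrix of emission means; column 1 is the
#'   early-fraction channel, column 2 the late-fraction channel.
#' @param covs list of three 2x2 symmetric positive-definite covariance
#'   matrices.
#' @param labels character state labels; defaults to rank by
#'   early-minus-late emission mean (see [assign_state_labels()]).
#' @return object of class `repli_hmm`.
#' @export
repli_hmm <- function(init, trans, means, covs, labels = NULL) {
  init <- as.numeric(init)
  trans <- as.matrix(trans)
  means <- as.matrix(means)
  if (length(init) != 3 || any(init < 0) || abs(sum(init) - 1) > 1e-8) {
    abort("`init` must be 3 non-negative probabilities summing to 1")
  }
  if (!all(dim(trans) == c(3, 3)) || any(trans < 0) ||
      any(abs(rowSums(trans) - 1) > 1e-8)) {
    abort("`trans` must be a 3x3 row-stochastic matrix")
  }
  if (!all(dim(means) == c(3, 2)) || length(covs) != 3) {
    abort("need 3 bivariate emission means and 3 covariance matrices")
  }
  covs <- lapply(covs, function(S) {
    S <- as.matrix(S)
    if (any(abs(S - t(S)) > 1e-8) || det(S) <= 0 || S[1, 1] <= 0) {
      abort("emission covariances must be symmetric positive definite")
    }
    S
  })
  model <- structure(
    list(init = init, trans = trans, means = means, covs = covs,
         loglik_trace = numeric(), n_iter = 0L, converged = NA),
    class = "repli_hmm")
  model$labels <- if (is.null(labels)) assign_state_labels(model) else labels
  model
}

#' @export
print.repli_hmm <- function(x, ...) {
  cat("Three-state bivariate-Gaussian HMM (repli_hmm)\n")
  cat("  state labels:", paste(x$labels, collapse = ", "), "\n")
  cat("  self-transitions:", paste(signif(diag(x$trans), 4), collapse = ", "),
      "\n")
  if (x$n_iter > 0) {
    cat("  trained:", x$n_iter, "Baum-Welch iterations, logLik",
        format(dplyr::last(x$loglik_trace)), "\n")
  }
  invisible(x)
}

# Closed-form bivariate normal log density, vectorised over rows of obs.
dbvnorm_log <- function(obs, mean, cov) {
  d1 <- obs[, 1] - mean[1]
  d2 <- obs[, 2] - mean[2]
  det_s <- cov[1, 1] * cov[2, 2] - cov[1, 2]^2
  q <- (cov[2, 2] * d1^2 - 2 * cov[1, 2] * d1 * d2 + cov[1, 1] * d2^2) / det_s
  -log(2 * pi) - 0.5 * log(det_s) - 0.5 * q
}

emission_logdens <- function(obs, model) {
  out <- vapply(1:3, function(k) {
    dbvnorm_log(obs, model$means[k, ], model$covs[[k]])
  }, numeric(nrow(obs)))
  matrix(out, nrow = nrow(obs), ncol = 3)
}

# Smallest eigenvalue of a symmetric 2x2 matrix, in closed form.
min_eigen2 <- function(S) {
  ((S[1, 1] + S[2, 2]) -
     sqrt((S[1, 1] - S[2, 2])^2 + 4 * S[1, 2]^2)) / 2
}

# Keep a covariance matrix symmetric positive definite by adding a small
# ridge proportional to the mean variance when needed.
regularize_cov <- function(S, quiet = FALSE) {
  S <- (S + t(S)) / 2
  eps <- 1e-6 * mean(diag(S))
  if (eps <= 0) eps <- 1e-10
  while (det(S) <= 0 || S[1, 1] <= 0 || S[2, 2] <= 0) {
    if (!quiet) warn("singular emission covariance; adding ridge")
    S <- S + diag(eps, 2)
    eps <- eps * 10
    quiet <- TRUE
  }
  S
}

#' Initialise emission parameters by k-means on the log2 ratio
#'
#' Clusters bins on the 1-D log2(early/late) ratio with k-means (k = 3, 10
#' restarts by default); each cluster's bins supply the bivariate mean and
#' covariance of the (early, late) signal for one HMM state. Clusters are
#' ordered by mean ratio and labelled late / indeterminate / early.
#' Transitions start heavily self-favouring (0.998 on the diagonal, the
#' remainder split equally) and initial probabilities are uniform.
#'
#' @param signal a [timing_ratio()] table with `early`, `late` and `ratio`
#'   columns (typically the normalised, capped 5-kb/1-kb signal).
#' @param k number of states (3).
#' @param seed seed for the k-means restarts.
#' @param nstart k-means restarts; the best within-cluster sum of squares
#'   wins.
#' @param self_trans initial self-transition probability.
#' @return an untrained [repli_hmm()].
#' @export
init_kmeans <- function(signal, k = 3, seed = 1L, nstart = 10,
                        self_trans = 0.998) {
  ratio <- signal$ratio
  ok <- is.finite(ratio)
  if (length(unique(ratio[ok])) < k) {
    abort(paste("need at least", k, "distinct finite log2-ratio values"))
  }
  km <- withr::with_seed(as.integer(seed),
                         kmeans(ratio[ok], centers = k, nstart = nstart))
  ord <- order(km$centers)
  obs <- as.matrix(signal[ok, c("early", "late")])
  means <- matrix(0, k, 2, dimnames = list(NULL, c("early", "late")))
  covs <- vector("list", k)
  for (s in seq_len(k)) {
    rows <- km$cluster == ord[s]
    means[s, ] <- colMeans(obs[rows, , drop = FALSE])
    covs[[s]] <- regularize_cov(stats::cov(obs[rows, , drop = FALSE]))
  }
  trans <- matrix((1 - self_trans) / (k - 1), k, k)
  diag(trans) <- self_trans
  repli_hmm(init = rep(1 / k, k), trans = trans, means = means, covs = covs,
            labels = c("late", "indeterminate", "early"))
}

#' Train the HMM by Baum-Welch expectation-maximisation
#'
#' Runs forward-backward in log space and re-estimates initial, transition
#' and Gaussian emission parameters until the log-likelihood improvement
#' between successive iterations falls below `tol` (default 0.05) or
#' `max_iter` is reached (with a warning). The log-likelihood trace is
#' non-decreasing (EM guarantee) and retained on the fitted model;
#' emission covariances are kept positive definite by ridge
#' regularisation.
#'
#' @param obs two-column matrix (early, late) of per-bin signal for one
#'   chromosome, or a signal table with `early`/`late` columns.
#' @param model a [repli_hmm()] (typically from [init_kmeans()]).
#' @param tol log-likelihood improvement threshold.
#' @param max_iter iteration cap.
#' @return the trained `repli_hmm` with `loglik_trace`, `n_iter` and
#'   `converged` filled in.
#' @export
baum_welch <- function(obs, model, tol = 0.05, max_iter = 500) {
  obs <- as_obs_matrix(obs)
  if (nrow(obs) < 2) abort("need at least 2 bins to train")
  # Covariance eigenvalue floor, fixed for the whole run: a state whose
  # re-estimated covariance would dip below it keeps its previous one
  # (a partial M-step, which preserves the EM monotonicity guarantee and
  # prevents the classic single-point Gaussian collapse).
  var_floor <- 1e-8 * mean(apply(obs, 2, var))
  trace <- numeric()
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ld <- emission_logdens(obs, model)
    fb <- .fb_cpp(ld, log(model$init), log(model$trans))
    if (!is.finite(fb$loglik)) {
      bad <- which(!is.finite(rowSums(ld)))
      abort(paste0("non-finite likelihood (bins ", min(bad), "-", max(bad),
                   "); check the input signal for NA/Inf"))
    }
    trace <- c(trace, fb$loglik)
    if (iter > 1 && trace[iter] - trace[iter - 1] < tol) {
      converged <- TRUE
      break
    }
    gamma <- fb$gamma
    ns <- colSums(gamma)
    model$init <- gamma[1, ] / sum(gamma[1, ])
    xi_rows <- rowSums(fb$xi)
    for (k in which(xi_rows > 0)) {
      model$trans[k, ] <- fb$xi[k, ] / xi_rows[k]
    }
    for (k in 1:3) {
      if (ns[k] <= 0) next  # starved state: keep its parameters
      mu <- colSums(gamma[, k] * obs) / ns[k]
      model$means[k, ] <- mu
      d <- sweep(obs, 2, mu)
      S <- crossprod(d * gamma[, k], d) / ns[k]
      S <- (S + t(S)) / 2
      if (min_eigen2(S) >= var_floor) model$covs[[k]] <- S
    }
  }
  if (!converged) {
    warn(paste("Baum-Welch hit the iteration cap (", max_iter,
               ") before the log-likelihood delta fell below", tol))
  }
  model$loglik_trace <- trace
  model$n_iter <- length(trace)
  model$converged <- converged
  model$labels <- assign_state_labels(model)
  model
}

as_obs_matrix <- function(obs) {
  if (is.data.frame(obs)) obs <- as.matrix(obs[, c("early", "late")])
  storage.mode(obs) <- "double"
  obs
}

#' Relabel trained states by their emission means
#'
#' Training can permute states, so labels are semantic: states are ranked
#' by the early-channel minus late-channel emission mean; the top rank is
#' `early`, the bottom `late`, the middle `indeterminate`.
#'
#' @param model a `repli_hmm`.
#' @return character vector of three labels in state order.
#' @export
assign_state_labels <- function(model) {
  sep <- model$means[, 1] - model$means[, 2]
  labels <- character(3)
  labels[order(sep)] <- c("late", "indeterminate", "early")
  labels
}

#' Decode the most probable state path (Viterbi)
#'
#' Maximum a posteriori state path under the model, computed in log space;
#' ties are broken toward the lower state index.
#'
#' @inheritParams baum_welch
#' @return integer vector of decoded states (1..3) with the path
#'   log-probability as attribute `"logprob"` and state labels as
#'   attribute `"labels"`.
#' @export
viterbi <- function(obs, model) {
  obs <- as_obs_matrix(obs)
  if (nrow(obs) == 0) {
    return(structure(integer(), logprob = -Inf, labels = model$labels))
  }
  ld <- emission_logdens(obs, model)
  vt <- .viterbi_cpp(ld, log(model$init), log(model$trans))
  structure(vt$path, logprob = vt$logprob, labels = model$labels)
}

#' @export
tidy.repli_hmm <- function(x, ...) {
  tibble::tibble(
    state = 1:3,
    label = x$labels,
    init = x$init,
    self_trans = diag(x$trans),
    mean_early = x$means[, 1],
    mean_late = x$means[, 2],
    var_early = vapply(x$covs, function(S) S[1, 1], numeric(1)),
    var_late = vapply(x$covs, function(S) S[2, 2], numeric(1)),
    cov_early_late = vapply(x$covs, function(S) S[1, 2], numeric(1)))
}

#' @export
glance.repli_hmm <- function(x, ...) {
  tibble::tibble(
    n_iter = x$n_iter,
    logLik = if (x$n_iter > 0) dplyr::last(x$loglik_trace) else NA_real_,
    delta = if (x$n_iter > 1) diff(utils::tail(x$loglik_trace, 2))
            else NA_real_,
    converged = x$converged)
}
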