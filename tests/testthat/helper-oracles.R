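# Shared fixtures and independent oracles, built in code at test time.

# Small two-chromosome simulation used across tests.
small_config <- function(seed = 7, ...) {
  sim_config(chrom_sizes = c(chrA = 2e6, chrB = 2e6), seed = seed, ...)
}

# Exhaustive-path Viterbi oracle: enumerates all K^T state paths and
# returns the maximum path log-probability (and one argmax path).
brute_viterbi <- function(logdens, logpi, logtrans) {
  T <- nrow(logdens)
  K <- ncol(logdens)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  lp <- apply(paths, 1, function(p) {
    s <- logpi[p[1]] + logdens[1, p[1]]
    if (T > 1) {
      for (t in 2:T) s <- s + logtrans[p[t - 1], p[t]] + logdens[t, p[t]]
    }
    s
  })
  list(logprob = max(lp), path = as.integer(paths[which.max(lp), ]))
}

# Random valid three-state bivariate-Gaussian model.
random_model <- function() {
  init <- runif(3)
  trans <- matrix(runif(9), 3)
  means <- matrix(stats::rnorm(6, sd = 2), 3, 2)
  covs <- replicate(3, {
    A <- matrix(stats::rnorm(4), 2)
    crossprod(A) + diag(0.3, 2)
  }, simplify = FALSE)
  repli_hmm(init / sum(init), trans / rowSums(trans), means, covs)
}

# Sample a state path and bivariate-normal emissions from a repli_hmm.
simulate_hmm_data <- function(model, n) {
  states <- integer(n)
  states[1] <- sample(3, 1, prob = model$init)
  for (t in seq_len(n)[-1]) {
    states[t] <- sample(3, 1, prob = model$trans[states[t - 1], ])
  }
  obs <- t(vapply(states, function(k) {
    L <- chol(model$covs[[k]])
    as.vector(model$means[k, ] + t(L) %*% stats::rnorm(2))
  }, numeric(2)))
  colnames(obs) <- c("early", "late")
  list(states = states, obs = obs)
}

# Per-window planted-label accuracy of a segmentation against its truth.
segmentation_accuracy <- function(seg, truth, step = 1000) {
  tb <- truth_bins(truth, step)
  key <- match(paste(seg$states$chrom, seg$states$start),
               paste(tb$chrom, tb$start))
  mean(seg$states$label == tb$label[key], na.rm = TRUE)
}

# Median distance from each planted domain boundary to the nearest
# recovered boundary (chromosome ends excluded).
median_boundary_error <- function(domains, truth) {
  errs <- unlist(lapply(unique(truth$chrom), function(ch) {
    tbound <- setdiff(truth$start[truth$chrom == ch], 0)
    rbound <- setdiff(domains$start[domains$chrom == ch], 0)
    if (!length(rbound)) return(rep(Inf, length(tbound)))
    vapply(tbound, function(b) min(abs(rbound - b)), numeric(1))
  }))
  median(errs)
}
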