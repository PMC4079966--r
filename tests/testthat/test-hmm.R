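test_that("model constructor validates probabilities and covariances", {
  m <- random_model()
  expect_s3_class(m, "repli_hmm")
  expect_equal(sum(m$init), 1)
  expect_equal(rowSums(m$trans), rep(1, 3))
  expect_error(repli_hmm(c(0.5, 0.5, 0.5), m$trans, m$means, m$covs),
               "summing to 1")
  bad_cov <- m$covs
  bad_cov[[2]] <- matrix(c(1, 2, 2, 1), 2)  # not positive definite
  expect_error(repli_hmm(m$init, m$trans, m$means, bad_cov),
               "positive definite")
})

test_that("Viterbi equals exhaustive enumeration on short sequences", {
  withr::with_seed(202, {
    for (trial in 1:25) {
      model <- random_model()
      n <- sample(1:8, 1)
      obs <- matrix(stats::rnorm(2 * n, sd = 2), ncol = 2)
      ld <- repliseqr:::emission_logdens(obs, model)
      vt <- viterbi(obs, model)
      bf <- brute_viterbi(ld, log(model$init), log(model$trans))
      expect_equal(attr(vt, "logprob"), bf$logprob, tolerance = 1e-10)
      expect_equal(as.integer(vt), bf$path)
    }
  })
})

test_that("Viterbi decodes bins sitting on well-separated state means", {
  means <- rbind(c(10, 0), c(5, 5), c(0, 10))
  covs <- replicate(3, diag(0.01, 2), simplify = FALSE)
  model <- repli_hmm(rep(1 / 3, 3), matrix(1 / 3, 3, 3), means, covs)
  obs <- means[c(1, 3, 2), ]
  expect_equal(as.integer(viterbi(obs, model)), c(1L, 3L, 2L))
  # single bin: the state with the highest emission density
  expect_equal(as.integer(viterbi(means[2, , drop = FALSE], model)), 2L)
  # empty input decodes to an empty path
  expect_length(viterbi(obs[0, , drop = FALSE], model), 0)
})

test_that("Baum-Welch log-likelihood is monotonically non-decreasing", {
  withr::with_seed(31, {
    truth_model <- repli_hmm(
      rep(1 / 3, 3),
      matrix(c(0.9, 0.05, 0.05, 0.05, 0.9, 0.05, 0.05, 0.05, 0.9), 3,
             byrow = TRUE),
      rbind(c(4, 1), c(2.5, 2.5), c(1, 4)),
      replicate(3, diag(0.5, 2), simplify = FALSE))
    dat <- simulate_hmm_data(truth_model, 2000)
    start <- random_model()
    fit <- baum_welch(dat$obs, start, tol = 1e-4, max_iter = 80) |>
      suppressWarnings()
    expect_gte(min(diff(fit$loglik_trace)), -1e-8)
  })
})

test_that("training recovers well-separated emission means", {
  withr::with_seed(77, {
    truth_model <- repli_hmm(
      rep(1 / 3, 3),
      matrix(c(0.98, 0.01, 0.01, 0.01, 0.98, 0.01, 0.01, 0.01, 0.98), 3,
             byrow = TRUE),
      rbind(c(6, 1), c(3, 3), c(1, 6)),
      replicate(3, diag(0.4, 2), simplify = FALSE))
    dat <- simulate_hmm_data(truth_model, 5000)
    sig <- tibble::as_tibble(dat$obs)
    sig$ratio <- log2(pmax(sig$early, 0.05) / pmax(sig$late, 0.05))
    init <- init_kmeans(sig, seed = 1)
    fit <- baum_welch(dat$obs, init)
    # states ranked early-minus-late match truth states 1..3 reversed
    ord <- order(fit$means[, 1] - fit$means[, 2], decreasing = TRUE)
    est <- fit$means[ord, ]
    tru <- truth_model$means[c(1, 2, 3), ]
    expect_lt(max(abs(est - tru) / abs(tru)), 0.10)
  })
})

test_that("infinite tolerance stops after one parameter update", {
  withr::with_seed(5, {
    model <- random_model()
    obs <- matrix(stats::rnorm(40, sd = 2), ncol = 2)
    fit <- baum_welch(obs, model, tol = Inf, max_iter = 100)
    expect_equal(fit$n_iter, 2)  # two E-steps, one M-step
    expect_false(identical(fit$means, model$means))
  })
})

test_that("k-means initialisation recovers separated ratio modes", {
  withr::with_seed(12, {
    n <- 900
    mode <- rep(c(-2, 0, 2), each = n / 3)
    sig <- tibble::tibble(
      early = 2^(mode / 2) + abs(stats::rnorm(n, sd = 0.05)),
      late = 2^(-mode / 2) + abs(stats::rnorm(n, sd = 0.05)))
    sig$ratio <- log2(sig$early / sig$late) + stats::rnorm(n, sd = 0.05)
    model <- init_kmeans(sig, seed = 3)
    expect_equal(model$labels, c("late", "indeterminate", "early"))
    # cluster mean ratios recover the modes
    est_ratio <- log2(model$means[, 1] / model$means[, 2])
    expect_equal(unname(est_ratio), c(-2, 0, 2), tolerance = 0.1)
    expect_equal(diag(model$trans), rep(0.998, 3))
    # determinism under a fixed seed
    expect_identical(tidy(model), tidy(init_kmeans(sig, seed = 3)))
    # all-identical input violates the distinct-values precondition
    flat <- tibble::tibble(early = rep(1, 10), late = rep(1, 10),
                           ratio = rep(0, 10))
    expect_error(init_kmeans(flat), "distinct")
  })
})

test_that("tidy and glance summarise a trained model", {
  withr::with_seed(8, {
    model <- random_model()
    obs <- matrix(stats::rnorm(200, sd = 2), ncol = 2)
    fit <- suppressWarnings(baum_welch(obs, model, tol = 0.05,
                                       max_iter = 50))
    td <- tidy(fit)
    expect_equal(nrow(td), 3)
    expect_setequal(td$label, c("late", "indeterminate", "early"))
    gl <- glance(fit)
    expect_equal(gl$n_iter, length(fit$loglik_trace))
    expect_equal(gl$logLik, max(fit$loglik_trace))
  })
})
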