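# EM, forward-backward, Viterbi, Calinski-Harabasz, model selection,
# surrogate ensembles. Oracles are path enumeration and hand computation.

test_that("k-means initialization finds well-separated cloud centroids", {
  set.seed(1)
  cloudA <- matrix(rnorm(200, mean = 0, sd = 0.3), 100, 2)
  cloudB <- matrix(rnorm(160, mean = 5, sd = 0.3), 80, 2)
  data <- rbind(cloudA, cloudB)
  init <- kmeans_init(data, K = 2, seed = 2)
  perm <- match_state_labels(init$means, rbind(colMeans(cloudA), colMeans(cloudB)))
  expect_equal(init$means[perm[1], ], colMeans(cloudA), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(init$means[perm[2], ], colMeans(cloudB), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(rowSums(init$transition), rep(1, 2))
  one <- kmeans_init(data, K = 1)
  expect_equal(one$means[1, ], colMeans(data), ignore_attr = TRUE)
  expect_equal(one$transition, matrix(1, 1, 1))
  expect_identical(kmeans_init(data, 2, seed = 7), kmeans_init(data, 2, seed = 7))
})

test_that("forward-backward posteriors equal brute-force path enumeration", {
  # K = 1: certain posterior, analytic likelihood
  set.seed(3)
  d1 <- matrix(rnorm(30), 10, 3)
  p1 <- hmm_parameters(matrix(0, 1, 3), list(diag(3)), matrix(1, 1, 1), 1)
  fb1 <- forward_backward(d1, p1)
  expect_equal(drop(fb1$gamma), rep(1, 10))
  expect_equal(fb1$log_likelihood,
               sum(apply(d1, 1, oracle_mvn_logdens, mu = rep(0, 3),
                         sigma = diag(3))))
  # K = 2, T = 3: all 8 paths enumerated
  for (i in 1:5) {
    params <- random_small_hmm(2, 2)
    data <- matrix(rnorm(6), 3, 2)
    fb <- forward_backward(data, params)
    expect_equal(fb$gamma, oracle_posterior(data, params), tolerance = 1e-10)
    expect_equal(max(abs(rowSums(fb$gamma) - 1)), 0, tolerance = 1e-8)
  }
})

test_that("identical emissions reduce posteriors to the chain marginals", {
  K <- 3
  trans <- matrix(c(0.7, 0.2, 0.1,
                    0.3, 0.5, 0.2,
                    0.25, 0.25, 0.5), K, K, byrow = TRUE)
  init <- c(0.6, 0.3, 0.1)
  means <- matrix(0, K, 2)  # all states share one emission model
  params <- hmm_parameters(means, rep(list(diag(2)), K), trans, init)
  data <- matrix(rnorm(16), 8, 2)
  fb <- forward_backward(data, params)
  marg <- init
  for (t in 1:8) {
    expect_equal(fb$gamma[t, ], marg, tolerance = 1e-10)
    marg <- drop(marg %*% trans)  # matrix-power oracle
  }
})

test_that("EM increases the likelihood monotonically and recovers a Gaussian", {
  set.seed(4)
  data <- matrix(rnorm(400, mean = 1.5, sd = 1), 200, 2)
  fit <- em_fit(data, K = 1, seed = 5)
  trace <- attr(fit, "loglik_trace")
  expect_true(all(diff(trace) > -1e-6))
  se <- 1 / sqrt(200)
  expect_lt(max(abs(fit$means - colMeans(data))), 1e-8)
  expect_lt(max(abs(fit$means - 1.5)), 3 * se)
  # monotonicity on a multi-state fit too
  params <- sample_hmm_params(K = 3, P = 4, mean_separation = 2, seed = 6)
  sim <- simulate_run(params, 300, seed = 7)
  fit3 <- em_fit(znormalize(sim$ts)$values, K = 3, seed = 8)
  expect_true(all(diff(attr(fit3, "loglik_trace")) > -1e-6))
  expect_equal(rowSums(fit3$transition), rep(1, 3), tolerance = 1e-10)
})

test_that("restart selection returns the maximum-likelihood restart", {
  params <- sample_hmm_params(K = 2, P = 3, mean_separation = 1.5, seed = 9)
  z <- znormalize(simulate_run(params, 200, seed = 10)$ts)$values
  single <- fit_with_restarts(z, K = 2, n_restarts = 1, seed = 11)
  direct <- em_fit(z, K = 2, seed = derive_seed_test(11, 1))
  expect_equal(single$means, direct$means)
  multi <- fit_with_restarts(z, K = 2, n_restarts = 4, seed = 12)
  expect_true(all(multi$log_likelihood >= attr(multi, "restart_logliks") - 1e-9))
  expect_equal(fit_with_restarts(z, K = 2, n_restarts = 3, seed = 13)$means,
               fit_with_restarts(z, K = 2, n_restarts = 3, seed = 13)$means)
})

test_that("Viterbi equals exhaustive path enumeration on random instances", {
  p1 <- hmm_parameters(matrix(0, 1, 2), list(diag(2)), matrix(1, 1, 1), 1)
  expect_equal(viterbi_decode(matrix(rnorm(10), 5, 2), p1)$labels, rep(1L, 5))
  set.seed(14)
  for (i in 1:25) {
    K <- sample(2:3, 1); T_ <- sample(3:8, 1)
    params <- random_small_hmm(K, 2)
    data <- matrix(rnorm(T_ * 2), T_, 2)
    dec <- viterbi_decode(data, params)
    expect_equal(attr(dec, "log_prob"), oracle_best_path_logprob(data, params),
                 tolerance = 1e-8)
    expect_equal(oracle_path_logprob(dec$labels, data, params),
                 attr(dec, "log_prob"), tolerance = 1e-8)
  }
})

test_that("state relabeling permutes decoded labels identically", {
  params <- sample_hmm_params(K = 3, P = 3, mean_separation = 2, seed = 15)
  data <- znormalize(simulate_run(params, 150, seed = 16)$ts)$values
  dec <- viterbi_decode(data, params)
  perm <- c(3L, 1L, 2L)  # state k of the original becomes perm[k]
  inv <- order(perm)
  permuted <- hmm_parameters(params$means[inv, ],
                             params$covariances[inv],
                             params$transition[inv, inv],
                             params$initial[inv])
  dec2 <- viterbi_decode(data, permuted)
  expect_equal(dec2$labels, perm[dec$labels])
})

test_that("Calinski-Harabasz matches hand computation and handles edge cases", {
  expect_equal(calinski_harabasz(c(0, 2, 10, 12), c(0, 0, 1, 1)), 50)
  expect_equal(calinski_harabasz(c(0, 0, 10, 10), c(0, 0, 1, 1)), 1e12)
  expect_error(calinski_harabasz(1:4, rep(1, 4)), "single cluster")
  # random instance vs an independent double-loop computation
  set.seed(17)
  X <- matrix(rnorm(60), 20, 3)
  lab <- sample(1:3, 20, replace = TRUE)
  g <- colMeans(X)
  B <- W <- 0
  for (l in unique(lab)) {
    idx <- lab == l
    m <- colMeans(X[idx, , drop = FALSE])
    B <- B + sum(idx) * sum((m - g)^2)
    for (i in which(idx)) W <- W + sum((X[i, ] - m)^2)
  }
  expect_equal(calinski_harabasz(X, lab),
               (B / (3 - 1)) / (W / (20 - 3)))
})

test_that("cross-validated selection recovers a trivially two-state dataset", {
  params <- sample_hmm_params(K = 2, P = 4, mean_separation = 4,
                              self_prob = 0.9, cov_style = "diagonal",
                              seed = 18)
  g <- simulate_group(params, n_subjects = 4, T_ = 150, seed = 19)
  sel <- select_K(g$runs, candidate_Ks = 2:3, n_restarts = 1, seed = 20)
  expect_equal(sel$K, 2)
  expect_equal(dim(sel$scores), c(4L, 2L))
  sel2 <- select_K(g$runs, candidate_Ks = 2:3, n_restarts = 1, seed = 20)
  expect_identical(sel$mean_scores, sel2$mean_scores)
})

test_that("surrogates preserve marginals but destroy cross-parcel covariance", {
  params <- sample_hmm_params(K = 3, P = 6, mean_separation = 2.5,
                              self_prob = 0.9, seed = 21)
  z <- znormalize(simulate_run(params, 400, seed = 22)$ts)$values
  # explicit zero offsets: the surrogate input equals the original data
  expect_identical(circular_shift(z, offsets = 0), z)
  real_fit <- em_fit(z, K = 3, seed = 23)
  ens <- fit_surrogate_ensemble(z, K = 3, n_iter = 6, seed = 24)
  expect_length(ens, 6)
  real_strength <- mean(covariance_strength(real_fit))
  null_strengths <- vapply(ens, function(e) mean(covariance_strength(e$params)), 0)
  # shifting destroys between-parcel covariance, so the mean absolute
  # covariance weight of every surrogate state set sits below the real fit's
  expect_true(all(null_strengths < real_strength))
  # per-parcel marginal multisets survive the shift inside the ensemble
  shifted <- circular_shift(z, seed = 25)
  expect_equal(apply(shifted, 2, sort), apply(z, 2, sort))
})
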