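# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately brute-force: enumeration, double loops and
# closed forms that do not share code with the implementation under test.

# Multivariate normal log-density via explicit solve/determinant.
oracle_mvn_logdens <- function(x, mu, sigma) {
  P <- length(mu)
  xc <- as.numeric(x - mu)
  as.numeric(-0.5 * (P * log(2 * pi) +
                       determinant(sigma, logarithm = TRUE)$modulus +
                       drop(t(xc) %*% solve(sigma) %*% xc)))
}

# All K^T state paths of length T (rows).
oracle_all_paths <- function(K, T_) {
  as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
}

# Joint log-probability of one path and the data under a Gaussian HMM.
oracle_path_logprob <- function(path, data, params) {
  lp <- log(params$initial[path[1]]) +
    oracle_mvn_logdens(data[1, ], params$means[path[1], ],
                       params$covariances[[path[1]]])
  for (t in seq_along(path)[-1]) {
    lp <- lp + log(params$transition[path[t - 1], path[t]]) +
      oracle_mvn_logdens(data[t, ], params$means[path[t], ],
                         params$covariances[[path[t]]])
  }
  lp
}

# Brute-force posterior state probabilities by path enumeration.
oracle_posterior <- function(data, params) {
  T_ <- nrow(data); K <- params$K
  paths <- oracle_all_paths(K, T_)
  lps <- apply(paths, 1, oracle_path_logprob, data = data, params = params)
  w <- exp(lps - max(lps)); w <- w / sum(w)
  gamma <- matrix(0, T_, K)
  for (t in seq_len(T_)) for (k in seq_len(K)) {
    gamma[t, k] <- sum(w[paths[, t] == k])
  }
  gamma
}

# Brute-force Viterbi: the maximum path log-probability.
oracle_best_path_logprob <- function(data, params) {
  paths <- oracle_all_paths(params$K, nrow(data))
  max(apply(paths, 1, oracle_path_logprob, data = data, params = params))
}

# Reference Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Random small, valid Gaussian HMM for property tests.
random_small_hmm <- function(K, P) {
  means <- matrix(rnorm(K * P, sd = 2), K, P)
  covs <- lapply(seq_len(K), function(k) {
    A <- matrix(rnorm(P * P), P, P)
    A %*% t(A) / P + diag(0.3, P)
  })
  trans <- matrix(stats::runif(K * K, 0.1, 1), K, K)
  trans <- trans / rowSums(trans)
  init <- stats::runif(K, 0.1, 1); init <- init / sum(init)
  hmm_parameters(means, covs, trans, init)
}

# Generating state means expressed in the z-normalized coordinate frame:
# population column moments under the chain's stationary distribution
# (uniform for the symmetric transition matrices used in recovery tests).
ztransformed_true_means <- function(params) {
  K <- params$K; P <- params$P
  pi_s <- rep(1 / K, K)
  m <- colSums(params$means * pi_s)
  second <- Reduce(`+`, lapply(seq_len(K), function(k) {
    pi_s[k] * (diag(params$covariances[[k]]) + params$means[k, ]^2)
  }))
  s <- sqrt(second - m^2)
  sweep(sweep(params$means, 2, m), 2, s, `/`)
}

# The package's deterministic child-seed scheme (used to cross-check that a
# single restart equals a direct EM call).
derive_seed_test <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629
}

# Shorthand: simulate a z-normalized concatenated group with truth attached.
make_group_data <- function(params, n_subjects, T_, seed, tr = 1,
                            parcel_categories = NULL) {
  g <- simulate_group(params, n_subjects = n_subjects, T_ = T_, tr = tr,
                      seed = seed, parcel_categories = parcel_categories)
  cc <- concatenate_runs(lapply(g$runs, znormalize))
  truth <- unlist(lapply(g$ground_truth$state_sequences, `[[`, "labels"))
  list(group = g, data = cc$data, run_boundary_index = cc$run_boundary_index,
       true_labels = truth)
}
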