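# Gaussian-emission hidden Markov model: k-means initialization, EM via the
# forward-backward algorithm, Viterbi decoding, Calinski-Harabasz model
# selection under leave-one-subject-out cross-validation, and surrogate
# ensembles fit to circular-shifted data.

#' Gaussian-emission HMM parameter set
#'
#' @param means K x P matrix of state mean activity patterns (z-units).
#' @param covariances List of K symmetric positive-definite P x P matrices
#'   (or a K x P x P array).
#' @param transition K x K matrix of transition probabilities, rows sum to 1.
#' @param initial Length-K initial state distribution.
#' @param log_likelihood Final data log-likelihood of the fit (optional).
#' @return An object of class `hmm_parameters`.
#' @export
hmm_parameters <- function(means, covariances, transition, initial,
                           log_likelihood = NA_real_) {
  means <- as.matrix(means)
  K <- nrow(means); P <- ncol(means)
  if (is.array(covariances) && length(dim(covariances)) == 3L) {
    covariances <- lapply(seq_len(dim(covariances)[1L]),
                          function(k) covariances[k, , ])
  }
  stopifnot(length(covariances) == K)
  transition <- as.matrix(transition)
  initial <- as.numeric(initial)
  if (!all(dim(transition) == c(K, K))) stop_domain("transition must be K x K")
  if (any(abs(rowSums(transition) - 1) > 1e-10)) {
    stop_domain("transition rows must sum to 1")
  }
  if (abs(sum(initial) - 1) > 1e-10) stop_domain("initial must sum to 1")
  for (k in seq_len(K)) {
    S <- covariances[[k]]
    if (!all(dim(S) == c(P, P)) || max(abs(S - t(S))) > 1e-8) {
      stop_domain("covariance ", k, " is not symmetric P x P")
    }
  }
  structure(list(K = K, P = P, means = means, covariances = covariances,
                 transition = transition, initial = initial,
                 log_likelihood = log_likelihood),
            class = "hmm_parameters")
}

#' @export
print.hmm_parameters <- function(x, ...) {
  cat(sprintf("<hmm_parameters> K = %d states, P = %d parcels, logLik = %s\n",
              x$K, x$P,
              if (is.na(x$log_likelihood)) "NA" else format(x$log_likelihood)))
  invisible(x)
}

#' Decoded state sequence
#'
#' Hard state labels (integers in `1..K`) per TR, with the run boundary
#' offsets of the data they were decoded from.
#'
#' @param labels Integer labels in `1..K`.
#' @param K State count.
#' @param run_boundary_index 0-based run start offsets.
#' @return An object of class `state_sequence`.
#' @export
state_sequence <- function(labels, K, run_boundary_index = 0L) {
  labels <- as.integer(labels)
  K <- as.integer(K)
  if (!length(labels)) stop_domain("empty state sequence")
  if (any(labels < 1L | labels > K)) stop_domain("labels must lie in 1..K")
  run_segments(run_boundary_index, length(labels))  # validates offsets
  structure(list(labels = labels, K = K,
                 run_boundary_index = as.integer(run_boundary_index)),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("<state_sequence> T = %d, K = %d, %d run(s)\n",
              length(x$labels), x$K, length(x$run_boundary_index)))
  invisible(x)
}

#' @export
length.state_sequence <- function(x) length(x$labels)

# T x K matrix of per-state log emission densities. Cholesky-based; a ridge
# escalation (x10 up to max_ridge) guards against near-singular covariances.
log_emission_densities <- function(data, params, max_ridge = 1e-2) {
  T_ <- nrow(data); P <- ncol(data)
  out <- matrix(NA_real_, T_, params$K)
  for (k in seq_len(params$K)) {
    S <- params$covariances[[k]]
    R <- NULL
    ridge <- 0
    repeat {
      R <- tryCatch(chol(S + diag(ridge, P)), error = function(e) NULL)
      if (!is.null(R)) break
      ridge <- if (ridge == 0) 1e-6 else ridge * 10
      if (ridge > max_ridge) {
        stop_domain("singular covariance for state ", k,
                    " (ridge escalation exhausted)")
      }
    }
    Xc <- sweep(data, 2, params$means[k, ])
    Z <- Xc %*% backsolve(R, diag(P))
    quad <- rowSums(Z * Z)
    logdet <- 2 * sum(log(diag(R)))
    out[, k] <- -0.5 * (P * log(2 * pi) + logdet + quad)
  }
  out
}

cov_list_with_ridge <- function(data, weights, means, ridge) {
  K <- nrow(means)
  lapply(seq_len(K), function(k) {
    w <- weights[, k]
    nk <- sum(w)
    Xc <- sweep(data, 2, means[k, ])
    S <- crossprod(Xc * w, Xc) / nk
    S <- (S + t(S)) / 2
    S + diag(ridge, ncol(data))
  })
}

#' Initialize HMM parameters by k-means clustering
#'
#' Runs [stats::kmeans()] (10 random starts, best inertia kept), then derives
#' state means and covariances from the hard assignments and the transition /
#' initial distributions from the assignment sequence with add-one smoothing.
#' Transitions never count pairs that straddle a run boundary.
#'
#' @param data T_total x P matrix of (z-normalized, concatenated) time series.
#' @param K Number of states.
#' @param run_boundary_index 0-based run start offsets.
#' @param seed RNG seed.
#' @param ridge Ridge added to every covariance diagonal.
#' @param nstart Random k-means initializations.
#' @return An [hmm_parameters()].
#' @export
kmeans_init <- function(data, K, run_boundary_index = 0L, seed = NULL,
                        ridge = 1e-6, nstart = 10) {
  data <- as.matrix(data)
  T_ <- nrow(data); P <- ncol(data)
  if (K == 1L) {
    return(hmm_parameters(matrix(colMeans(data), 1, P),
                          list(cov(data) + diag(ridge, P)),
                          matrix(1, 1, 1), 1))
  }
  km <- with_seed(seed, {
    for (attempt in 1:5) {
      fit <- tryCatch(
        suppressWarnings(kmeans(data, centers = K, nstart = nstart,
                                iter.max = 100)),
        error = function(e) NULL)
      if (!is.null(fit) && all(fit$size > 0)) break
      fit <- NULL
    }
    if (is.null(fit)) stop_domain("k-means initialization failed: empty clusters")
    fit
  })
  labels <- km$cluster
  means <- km$centers
  resp <- matrix(0, T_, K)
  resp[cbind(seq_len(T_), labels)] <- 1
  covs <- lapply(seq_len(K), function(k) {
    idx <- labels == k
    S <- if (sum(idx) > P) cov(data[idx, , drop = FALSE]) else diag(1, P)
    (S + t(S)) / 2 + diag(ridge, P)
  })
  segs <- run_segments(run_boundary_index, T_)
  trans <- matrix(1, K, K)  # add-one smoothing
  init <- rep(1, K)
  for (s in seq_len(nrow(segs))) {
    rows <- segs[s, "start"]:segs[s, "end"]
    init[labels[rows[1L]]] <- init[labels[rows[1L]]] + 1
    if (length(rows) > 1L) {
      from <- labels[rows[-length(rows)]]
      to <- labels[rows[-1L]]
      for (i in seq_along(from)) trans[from[i], to[i]] <- trans[from[i], to[i]] + 1
    }
  }
  hmm_parameters(means, covs, trans / rowSums(trans), init / sum(init))
}

#' Forward-backward posteriors and data log-likelihood
#'
#' Log-space forward-backward recursions. The forward pass restarts from the
#' initial distribution at every run boundary, and pairwise state
#' expectations exclude boundary-crossing pairs.
#'
#' @inheritParams kmeans_init
#' @param params An [hmm_parameters()].
#' @return List with `gamma` (T x K posterior state probabilities, rows sum
#'   to 1), `xi_sum` (K x K expected within-run transition counts), and
#'   `log_likelihood`.
#' @export
forward_backward <- function(data, params, run_boundary_index = 0L) {
  data <- as.matrix(data)
  segs <- run_segments(run_boundary_index, nrow(data))
  logB <- log_emission_densities(data, params)
  if (!all(is.finite(logB))) {
    stop_domain("non-finite emission density encountered")
  }
  .fb_cpp(logB, log(params$transition), log(params$initial),
          as.integer(segs[, "start"]) - 1L)
}

#' Fit a Gaussian HMM by expectation-maximization
#'
#' Starts from [kmeans_init()] and alternates forward-backward E-steps with
#' closed-form M-steps (posterior-weighted means and full covariances,
#' expected-count transition rows, run-start initial distribution) until the
#' log-likelihood gain drops below `tol` or `max_iter` iterations. A ridge is
#' added to every covariance at every M-step for numerical stability.
#'
#' @inheritParams kmeans_init
#' @param max_iter Maximum EM iterations.
#' @param tol Minimum log-likelihood gain to continue.
#' @param init Optional [hmm_parameters()] to start from (skips k-means).
#' @return An [hmm_parameters()] with `log_likelihood` set and attributes
#'   `loglik_trace` (per-iteration log-likelihood) and `n_iter`.
#' @export
em_fit <- function(data, run_boundary_index = 0L, K = 4, seed = NULL,
                   max_iter = 1000, tol = 1e-2, ridge = 1e-6, init = NULL) {
  data <- as.matrix(data)
  T_ <- nrow(data); P <- ncol(data)
  segs <- run_segments(run_boundary_index, T_)
  params <- if (is.null(init)) {
    kmeans_init(data, K, run_boundary_index, seed = seed, ridge = ridge)
  } else init
  trace <- numeric(0)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    fb <- forward_backward(data, params, run_boundary_index)
    trace <- c(trace, fb$log_likelihood)
    if (fb$log_likelihood - ll_prev < tol && it > 1L) break
    ll_prev <- fb$log_likelihood
    gamma <- fb$gamma
    nk <- colSums(gamma)
    if (any(nk < .Machine$double.eps * T_)) {
      stop_domain("a state's posterior mass collapsed to zero during EM")
    }
    means <- crossprod(gamma, data) / nk
    covs <- cov_list_with_ridge(data, gamma, means, ridge)
    xi <- fb$xi_sum
    rs <- rowSums(xi)
    trans <- xi / ifelse(rs > 0, rs, 1)
    trans[rs == 0, ] <- 1 / K
    init_rows <- segs[, "start"]
    initial <- colSums(gamma[init_rows, , drop = FALSE])
    initial <- initial / sum(initial)
    params <- hmm_parameters(means, covs, trans, initial)
  }
  params$log_likelihood <- trace[length(trace)]
  attr(params, "loglik_trace") <- trace
  attr(params, "n_iter") <- length(trace)
  params
}

#' Fit with random restarts, keeping the best likelihood
#'
#' Repeats [em_fit()] with restart seeds derived deterministically from
#' `seed` and returns the restart with the highest final log-likelihood
#' (the standard guard against EM local optima).
#'
#' @inheritParams em_fit
#' @param n_restarts Number of independent EM runs.
#' @return The best [hmm_parameters()]; attribute `restart_logliks` records
#'   every restart's final log-likelihood.
#' @export
fit_with_restarts <- function(data, run_boundary_index = 0L, K = 4,
                              n_restarts = 10, seed = 1, max_iter = 1000,
                              tol = 1e-2, ridge = 1e-6) {
  stopifnot(n_restarts >= 1)
  fits <- vector("list", n_restarts)
  errs <- character(0)
  for (r in seq_len(n_restarts)) {
    fits[[r]] <- tryCatch(
      em_fit(data, run_boundary_index, K, seed = derive_seed(seed, r),
             max_iter = max_iter, tol = tol, ridge = ridge),
      error = function(e) e)
    if (inherits(fits[[r]], "error")) errs <- c(errs, conditionMessage(fits[[r]]))
  }
  ok <- !vapply(fits, inherits, TRUE, "error")
  if (!any(ok)) stop_domain("all restarts failed: ", errs[1])
  lls <- vapply(fits[ok], `[[`, 0, "log_likelihood")
  best <- fits[ok][[which.max(lls)]]
  attr(best, "restart_logliks") <- lls
  best
}

#' Viterbi decoding of the most probable state path
#'
#' Per run, returns the jointly most probable hard state sequence given the
#' parameters. Ties are broken toward the lowest state index.
#'
#' @inheritParams forward_backward
#' @return A [state_sequence()]; attribute `log_prob` holds the summed path
#'   log-probability across runs.
#' @export
viterbi_decode <- function(data, params, run_boundary_index = 0L) {
  data <- as.matrix(data)
  segs <- run_segments(run_boundary_index, nrow(data))
  logB <- log_emission_densities(data, params)
  vt <- .viterbi_cpp(logB, log(params$transition), log(params$initial),
                     as.integer(segs[, "start"]) - 1L)
  seq <- state_sequence(vt$path + 1L, params$K, run_boundary_index)
  attr(seq, "log_prob") <- vt$log_prob
  seq
}

#' Calinski-Harabasz score of a hard labeling
#'
#' `(trace(B) / (k - 1)) / (trace(W) / (N - k))` with B and W the between-
#' and within-cluster scatter about the grand mean. Zero within-scatter
#' (perfectly tight clusters) is reported as the capped sentinel `1e12`.
#'
#' @param data N x P matrix (a vector is treated as one column).
#' @param labels Length-N integer labels; at least two distinct values.
#' @return The score (a single number).
#' @export
calinski_harabasz <- function(data, labels) {
  data <- as.matrix(data)
  if (is.null(dim(data)) || ncol(data) == 0) data <- matrix(data, ncol = 1)
  N <- nrow(data)
  labels <- as.integer(labels)
  stopifnot(length(labels) == N)
  levs <- sort(unique(labels))
  k <- length(levs)
  if (k < 2L) stop_domain("Calinski-Harabasz undefined for a single cluster")
  grand <- colMeans(data)
  B <- 0; W <- 0
  for (l in levs) {
    idx <- labels == l
    m <- colMeans(data[idx, , drop = FALSE])
    B <- B + sum(idx) * sum((m - grand)^2)
    W <- W + sum(sweep(data[idx, , drop = FALSE], 2, m)^2)
  }
  if (W == 0) return(1e12)
  (B / (k - 1)) / (W / (N - k))
}

#' Choose the number of states by cross-validated Calinski-Harabasz score
#'
#' Leave-one-subject-out model selection: for every candidate K and every
#' fold, the HMM is fit (with restarts) on all subjects but one, the held-out
#' subject's runs are Viterbi-decoded with the fitted model, and the
#' Calinski-Harabasz score of the held-out observations under the decoded
#' hard labels is recorded. The K with the largest fold-mean score wins;
#' ties go to the smallest K. A K whose folds fail (e.g. decoding collapses
#' to one state) is excluded with a warning.
#'
#' @param runs List of [parcel_timeseries()] (z-normalized internally).
#' @param candidate_Ks Candidate state counts.
#' @param n_restarts EM restarts per fold.
#' @param seed Master seed.
#' @param max_iter,tol Passed to [em_fit()].
#' @return List with `K` (chosen), `scores` (fold x K matrix), and
#'   `mean_scores`.
#' @export
select_K <- function(runs, candidate_Ks = 2:10, n_restarts = 3, seed = 1,
                     max_iter = 1000, tol = 1e-2) {
  subjects <- unique(vapply(runs, `[[`, "", "subject_id"))
  if (length(subjects) < 3L) stop_domain("need at least 3 subjects for LOSO folds")
  zruns <- lapply(runs, znormalize)
  per_subj <- lapply(subjects, function(s) {
    concatenate_runs(Filter(function(r) r$subject_id == s, zruns))
  })
  names(per_subj) <- subjects
  scores <- matrix(NA_real_, length(subjects), length(candidate_Ks),
                   dimnames = list(subjects, paste0("K", candidate_Ks)))
  for (ki in seq_along(candidate_Ks)) {
    K <- candidate_Ks[ki]
    for (fi in seq_along(subjects)) {
      res <- tryCatch({
        train <- concatenate_runs(
          zruns[vapply(zruns, `[[`, "", "subject_id") != subjects[fi]])
        fit <- fit_with_restarts(train$data, train$run_boundary_index, K,
                                 n_restarts = n_restarts,
                                 seed = derive_seed(seed, 1000 * ki + fi),
                                 max_iter = max_iter, tol = tol)
        held <- per_subj[[fi]]
        dec <- viterbi_decode(held$data, fit, held$run_boundary_index)
        calinski_harabasz(held$data, dec$labels)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning("fold ", subjects[fi], " failed for K = ", K, ": ",
                conditionMessage(res), call. = FALSE)
        scores[, ki] <- NA_real_
        break
      }
      scores[fi, ki] <- res
    }
  }
  mean_scores <- colMeans(scores)
  valid <- is.finite(mean_scores)
  if (!any(valid)) stop_domain("every candidate K failed")
  best <- candidate_Ks[valid][which.max(mean_scores[valid])]
  list(K = best, scores = scores, mean_scores = mean_scores)
}

#' Fit an ensemble of surrogate HMMs on circular-shifted data
#'
#' Each surrogate applies independent per-parcel circular shifts (within each
#' run) to the data, destroying cross-parcel covariance while preserving each
#' parcel's autocorrelation, then reruns the full fit + decode. The resulting
#' parameter/sequence ensemble is the chance reference for covariance
#' strength, transition structure, and gradient-space statistics.
#'
#' @inheritParams em_fit
#' @param n_iter Number of surrogates.
#' @param n_restarts EM restarts per surrogate.
#' @return List of `n_iter` elements, each `list(params, sequence)`. Failed
#'   iterates are dropped with a message.
#' @export
fit_surrogate_ensemble <- function(data, run_boundary_index = 0L, K = 4,
                                   n_iter = 100, seed = 1, n_restarts = 1,
                                   max_iter = 1000, tol = 1e-2) {
  stopifnot(n_iter >= 1)
  out <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    out[[i]] <- tryCatch({
      shifted <- circular_shift(data, run_boundary_index = run_boundary_index,
                                seed = derive_seed(seed, i))
      fit <- fit_with_restarts(shifted, run_boundary_index, K,
                               n_restarts = n_restarts,
                               seed = derive_seed(seed, n_iter + i),
                               max_iter = max_iter, tol = tol)
      list(params = fit,
           sequence = viterbi_decode(shifted, fit, run_boundary_index))
    }, error = function(e) {
      message("surrogate ", i, " failed: ", conditionMessage(e))
      NULL
    })
  }
  Filter(Negate(is.null), out)
}

#' Optimal state-label matching between two mean sets
#'
#' Finds the permutation of estimated states minimizing the total squared
#' distance between matched state means (exhaustive over permutations; K is
#' small in this setting). Used to compare fits whose label order is
#' arbitrary.
#'
#' @param estimated,reference K x P mean matrices.
#' @return Integer permutation `perm` such that `estimated[perm[k], ]` matches
#'   `reference[k, ]`.
#' @export
match_state_labels <- function(estimated, reference) {
  K <- nrow(reference)
  stopifnot(nrow(estimated) == K)
  D <- as.matrix(stats::dist(rbind(reference, estimated)))[seq_len(K),
                                                           K + seq_len(K)]^2
  perms <- all_permutations(K)
  costs <- vapply(perms, function(p) sum(D[cbind(seq_len(K), p)]), 0)
  perms[[which.min(costs)]]
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
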