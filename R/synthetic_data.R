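# Ground-truth-known generators: K-state Gaussian HMM parcel dynamics,
# state-coupled behavioral traces, and interleaved (ABAB) event structures.
# These emulate the statistical structure the analyses assume -- not realistic
# fMRI noise (no scanner drift, autocorrelation, or motion).

#' Draw a random Gaussian-HMM parameter set
#'
#' State means are placed on a sphere of radius
#' `mean_separation * sqrt(P) / 2` about the origin along the axes of a
#' random orthonormal frame (random directions when K > P), so
#' `mean_separation` acts as a single knob for decoding difficulty: every
#' pairwise mean distance equals `radius * sqrt(2)` and scales with the knob,
#' in units of the observation SD. Covariances are either the
#' identity (`"diagonal"`) or random full SPD matrices `A %*% t(A) / P +
#' ridge * I` (`"random_full"`, ridge 0.1). The transition matrix has
#' diagonal `self_prob` and uniform off-diagonal mass; the initial
#' distribution is uniform.
#'
#' @param K Number of states (>= 1).
#' @param P Number of parcels (>= 2).
#' @param mean_separation Mean-separation knob in SD units.
#' @param self_prob Self-transition probability (0 < p < 1; ignored at K=1).
#' @param cov_style `"diagonal"` or `"random_full"`.
#' @param seed RNG seed.
#' @return An [hmm_parameters()].
#' @export
sample_hmm_params <- function(K, P, mean_separation = 3, self_prob = 0.9,
                              cov_style = c("random_full", "diagonal"),
                              seed = NULL) {
  cov_style <- match.arg(cov_style)
  stopifnot(K >= 1, P >= 2)
  if (K > 1 && (self_prob <= 0 || self_prob >= 1)) {
    stop_domain("self_prob must lie strictly in (0, 1)")
  }
  with_seed(seed, {
    radius <- mean_separation * sqrt(P) / 2
    means <- if (K <= P) {
      # random orthonormal frame: equal pairwise separation radius * sqrt(2)
      Q <- qr.Q(qr(matrix(rnorm(P * P), P, P)))[, seq_len(K), drop = FALSE]
      t(Q) * radius
    } else {
      t(vapply(seq_len(K), function(k) {
        v <- rnorm(P)
        v / sqrt(sum(v^2)) * radius
      }, numeric(P)))
    }
    covs <- lapply(seq_len(K), function(k) {
      if (cov_style == "diagonal") {
        diag(1, P)
      } else {
        A <- matrix(rnorm(P * P), P, P)
        S <- A %*% t(A) / P + diag(0.1, P)
        if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
          stop_domain("covariance construction failed to be positive-definite")
        }
        S
      }
    })
    trans <- if (K == 1) matrix(1, 1, 1) else {
      m <- matrix((1 - self_prob) / (K - 1), K, K)
      diag(m) <- self_prob
      m
    }
    hmm_parameters(means, covs, trans, rep(1 / K, K))
  })
}

#' Simulate one subject-run from a Gaussian HMM
#'
#' Samples a first-order Markov state chain from the initial distribution and
#' transition matrix, then draws each TR's observation from the occupied
#' state's Gaussian.
#'
#' @param params An [hmm_parameters()].
#' @param T_ Number of TRs (>= 2).
#' @param tr Sampling interval in seconds.
#' @param seed RNG seed.
#' @param subject_id,run_id Identifiers for the emitted [parcel_timeseries()].
#' @param parcel_categories Optional category tags (default all cortical).
#' @param states Optional pre-drawn state chain (used to share sequences
#'   across subjects).
#' @return `list(ts = parcel_timeseries, states = state_sequence)`.
#' @export
simulate_run <- function(params, T_, tr = 1, seed = NULL, subject_id = "sub",
                         run_id = "run", parcel_categories = NULL,
                         states = NULL) {
  stopifnot(T_ >= 2)
  K <- params$K; P <- params$P
  with_seed(seed, {
    if (is.null(states)) {
      states <- integer(T_)
      states[1L] <- sample.int(K, 1L, prob = params$initial)
      for (t in 2L:T_) {
        states[t] <- sample.int(K, 1L, prob = params$transition[states[t - 1L], ])
      }
    } else {
      states <- as.integer(states)
      stopifnot(length(states) == T_, all(states >= 1L & states <= K))
    }
    chols <- lapply(params$covariances, chol)
    values <- matrix(NA_real_, T_, P)
    for (k in seq_len(K)) {
      idx <- which(states == k)
      if (!length(idx)) next
      Z <- matrix(rnorm(length(idx) * P), length(idx), P)
      values[idx, ] <- sweep(Z %*% chols[[k]], 2, params$means[k, ], `+`)
    }
    list(ts = parcel_timeseries(values, tr = tr, subject_id = subject_id,
                                run_id = run_id,
                                parcel_categories = parcel_categories),
         states = state_sequence(states, K))
  })
}

#' Blend the observation preceding each state change
#'
#' Post-processes a simulated run so that the sample just before every state
#' transition is a half-and-half mixture of the old-state observation and an
#' independent draw from the incoming state. This emulates the gradual,
#' hemodynamically blended transitions of real BOLD data -- the regime in
#' which cofluctuation genuinely drops at state boundaries -- which the plain
#' conditionally-independent emission model cannot produce.
#'
#' @param sim A `list(ts, states)` as returned by [simulate_run()].
#' @param params The generating [hmm_parameters()].
#' @param weight Mixing weight of the incoming-state draw in `[0, 1]`.
#' @param seed RNG seed for the incoming-state draws.
#' @return The modified `list(ts, states)`.
#' @export
blend_transition_samples <- function(sim, params, weight = 0.5, seed = NULL) {
  stopifnot(weight >= 0, weight <= 1)
  labels <- sim$states$labels
  vals <- sim$ts$values
  chols <- lapply(params$covariances, chol)
  with_seed(seed, {
    for (t in which(diff(labels) != 0)) {
      incoming <- params$means[labels[t + 1L], ] +
        drop(rnorm(params$P) %*% chols[[labels[t + 1L]]])
      vals[t, ] <- (1 - weight) * vals[t, ] + weight * incoming
    }
    sim$ts$values <- vals
    sim
  })
}

#' Simulate a multi-subject, multi-run group dataset
#'
#' Independent state sequences per subject-run from shared parameters; with
#' `shared_sequence = TRUE` every subject follows the same state chain per
#' run index, emulating stimulus-driven intersubject synchrony (observations
#' stay independent).
#'
#' @inheritParams simulate_run
#' @param n_subjects,runs_per_subject Counts (>= 1).
#' @param shared_sequence Share the state chain across subjects?
#' @param condition Condition tag recorded in the manifest.
#' @param dir Optional directory; when given, runs are written as TSV + JSON
#'   via [write_parcel_timeseries()] and the manifest paths point at them.
#' @return List with `runs` (list of [parcel_timeseries()]), `manifest`
#'   ([run_manifest()]), and `ground_truth` (`params`, per-run true
#'   `state_sequences`, `seed`).
#' @export
simulate_group <- function(params, n_subjects, runs_per_subject = 1, T_ = 600,
                           tr = 1, seed = 1, shared_sequence = FALSE,
                           parcel_categories = NULL, condition = "task",
                           dir = NULL) {
  stopifnot(n_subjects >= 1, runs_per_subject >= 1)
  runs <- list(); truth <- list()
  subj_ids <- sprintf("sub-%02d", seq_len(n_subjects))
  run_ids <- sprintf("run-%02d", seq_len(runs_per_subject))
  shared <- NULL
  if (shared_sequence) {
    shared <- lapply(seq_len(runs_per_subject), function(r) {
      simulate_run(params, T_, tr, seed = derive_seed(seed, 100000 + r))$states$labels
    })
  }
  k <- 0L
  for (si in seq_len(n_subjects)) {
    for (ri in seq_len(runs_per_subject)) {
      k <- k + 1L
      sim <- simulate_run(
        params, T_, tr, seed = derive_seed(seed, k),
        subject_id = subj_ids[si], run_id = run_ids[ri],
        parcel_categories = parcel_categories,
        states = if (shared_sequence) shared[[ri]] else NULL)
      runs[[k]] <- sim$ts
      truth[[k]] <- sim$states
    }
  }
  manifest <- run_manifest(
    subject_id = rep(subj_ids, each = runs_per_subject),
    run_id = rep(run_ids, times = n_subjects),
    condition = condition)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(length(runs))
    for (i in seq_along(runs)) {
      paths[i] <- file.path(dir, sprintf("%s_%s.tsv", manifest$subject_id[i],
                                         manifest$run_id[i]))
      write_parcel_timeseries(runs[[i]], paths[i])
    }
    manifest$path <- paths
    write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(runs = runs, manifest = manifest,
       ground_truth = list(params = params, state_sequences = truth, seed = seed))
}

#' Simulate an interleaved narrative event structure
#'
#' Event lengths are drawn uniform-integer in `[min_len, max_len]`; with
#' `pattern = "ABAB"` the storyline labels alternate (the two-storyline
#' sitcom design: n events yield n - 1 boundaries, each the first TR of a new
#' event).
#'
#' @param n_events Number of events (>= 2).
#' @param min_len,max_len Event length bounds in TRs.
#' @param pattern `"ABAB"` (alternating labels) or `"single"`.
#' @param T_ Optional run length; an error is raised if the events do not fit.
#' @param seed RNG seed.
#' @return An [event_boundaries()]; attribute `event_lengths` holds the drawn
#'   lengths.
#' @export
simulate_event_structure <- function(n_events, min_len = 20, max_len = 60,
                                     pattern = c("ABAB", "single"), T_ = NULL,
                                     seed = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(n_events >= 2, min_len <= max_len, min_len >= 1)
  with_seed(seed, {
    lens <- sample.int(max_len - min_len + 1L, n_events, replace = TRUE) +
      min_len - 1L
    if (!is.null(T_) && sum(lens) > T_) {
      stop_domain("event lengths total ", sum(lens), " TRs but run has ", T_)
    }
    labels <- if (pattern == "ABAB") {
      rep_len(c("A", "B"), n_events)
    } else rep("A", n_events)
    eb <- event_boundaries(cumsum(lens)[-n_events] + 1L, story_labels = labels)
    attr(eb, "event_lengths") <- lens
    eb
  })
}

#' Simulate a state-coupled attention trace
#'
#' Builds `effects[state_t] + noise`, optionally HRF-convolves it, and
#' z-normalizes, emulating an engagement rating (or inverted RT variability)
#' whose level depends on the occupied latent state.
#'
#' @param true_states A [state_sequence()] (or integer labels).
#' @param effects Per-state effect sizes, length K.
#' @param noise_sd Gaussian noise SD.
#' @param tr Sampling interval in seconds.
#' @param hrf Convolve with the canonical HRF?
#' @param seed RNG seed.
#' @return A [behavioral_trace()] of kind `"engagement"`, z-normalized.
#' @export
simulate_attention_trace <- function(true_states, effects, noise_sd = 0.5,
                                     tr = 1, hrf = TRUE, seed = NULL) {
  labels <- if (inherits(true_states, "state_sequence")) true_states$labels
            else as.integer(true_states)
  K <- max(labels)
  if (length(effects) < K) stop_domain("effects must have one entry per state")
  with_seed(seed, {
    raw <- effects[labels] + rnorm(length(labels), sd = noise_sd)
    tr_obj <- behavioral_trace(raw, tr = tr, kind = "engagement")
    if (hrf) tr_obj <- hrf_convolve(tr_obj)
    s <- sd(tr_obj$values)
    if (s == 0) stop_domain("attention trace is constant; cannot z-normalize")
    tr_obj$values <- (tr_obj$values - mean(tr_obj$values)) / s
    tr_obj
  })
}
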