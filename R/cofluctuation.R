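# Edge time series (moment-to-moment cofluctuation), covariance strength,
# global cofluctuation, per-state cofluctuation, and transition-aligned
# cofluctuation with connection-category grouping.

edge_category_names <- c("cortico-cortical", "cortico-subcortical",
                         "subcortico-subcortical")

#' Edge (cofluctuation) time series of a z-normalized run
#'
#' For every parcel pair i < j, the edge value at TR t is `|z_i(t) * z_j(t)|`:
#' the magnitude of the pair's moment-to-moment cofluctuation relative to
#' their baselines. Edges are ordered row-major over i < j. Each edge carries
#' a connection-category tag derived from the parcel categories.
#'
#' @param ts A z-normalized [parcel_timeseries()] (column means must be ~0;
#'   non-normalized input is refused).
#' @return An object of class `edge_timeseries` with `values` (E x T,
#'   nonnegative), `edge_index` (E x 2), `edge_category`, and `tr`.
#' @export
edge_timeseries <- function(ts) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  Z <- ts$values
  if (!is_znormalized(Z)) {
    stop_domain("input is not z-normalized; call znormalize() on the run first")
  }
  P <- ncol(Z)
  pr <- combn(P, 2)
  values <- abs(t(Z[, pr[1, ], drop = FALSE] * Z[, pr[2, ], drop = FALSE]))
  cat_i <- ts$parcel_categories[pr[1, ]]
  cat_j <- ts$parcel_categories[pr[2, ]]
  edge_cat <- ifelse(cat_i == "cortical" & cat_j == "cortical",
                     "cortico-cortical",
                     ifelse(cat_i == "subcortical" & cat_j == "subcortical",
                            "subcortico-subcortical", "cortico-subcortical"))
  structure(list(values = values, edge_index = t(pr),
                 edge_category = edge_cat, tr = ts$tr,
                 parcel_labels = ts$parcel_labels),
            class = "edge_timeseries")
}

#' @export
print.edge_timeseries <- function(x, ...) {
  cat(sprintf("<edge_timeseries> %d edges x %d TRs (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$edge_category)),
                            table(x$edge_category)), collapse = ", ")))
  invisible(x)
}

#' Covariance strength of each state
#'
#' Sum of absolute off-diagonal covariance weights over all parcel pairs
#' (each unordered pair counted once); an index of how strongly a state's
#' emission model couples parcels.
#'
#' @param covariances List/array of K symmetric P x P matrices, or an
#'   [hmm_parameters()].
#' @return Length-K numeric vector.
#' @export
covariance_strength <- function(covariances) {
  if (inherits(covariances, "hmm_parameters")) {
    covariances <- covariances$covariances
  }
  if (is.array(covariances) && length(dim(covariances)) == 3L) {
    covariances <- lapply(seq_len(dim(covariances)[1L]),
                          function(k) covariances[k, , ])
  }
  vapply(covariances, function(S) {
    S <- as.matrix(S)
    sum(abs(S[upper.tri(S)]))
  }, 0)
}

#' Global cofluctuation time course
#'
#' Mean cofluctuation over all edges at each TR; low values mark moments of
#' global desynchronization.
#'
#' @param edges An [edge_timeseries()].
#' @return Length-T nonnegative vector.
#' @export
global_cofluctuation <- function(edges) {
  stopifnot(inherits(edges, "edge_timeseries"))
  colMeans(edges$values)
}

#' Mean global cofluctuation per occupied state
#'
#' Averages a global cofluctuation time course within the TRs assigned to
#' each state. States that never occur are reported as `NA`.
#'
#' @param global_cf Length-T vector (see [global_cofluctuation()]).
#' @param seq A [state_sequence()] (or labels) of the same length.
#' @param K State count.
#' @return Length-K vector of state means.
#' @export
cofluctuation_by_state <- function(global_cf, seq, K = NULL) {
  labels <- seq_labels(seq)
  K <- seq_K(seq, K)
  if (length(global_cf) != length(labels)) stop_domain("length mismatch")
  vapply(seq_len(K), function(k) {
    idx <- labels == k
    if (!any(idx)) NA_real_ else mean(global_cf[idx])
  }, 0)
}

# Transition onsets (first TR of a new state), within runs only; when
# full_window_only, onsets whose window would leave the run are dropped.
transition_onsets <- function(seq, window = -3:3, full_window_only = TRUE) {
  labels <- seq_labels(seq)
  segs <- run_segments(seq_boundaries(seq), length(labels))
  onsets <- integer(0)
  for (s in seq_len(nrow(segs))) {
    rows <- segs[s, "start"]:segs[s, "end"]
    if (length(rows) < 2L) next
    cand <- rows[-1L][labels[rows[-1L]] != labels[rows[-length(rows)]]]
    if (full_window_only) {
      cand <- cand[cand + min(window) >= segs[s, "start"] &
                   cand + max(window) <= segs[s, "end"]]
    }
    onsets <- c(onsets, cand)
  }
  onsets
}

aligned_means_at <- function(x_mat, onsets, window) {
  # x_mat: series x T; returns series x length(window) mean over onsets
  out <- matrix(NA_real_, nrow(x_mat), length(window))
  for (wi in seq_along(window)) {
    out[, wi] <- rowMeans(x_mat[, onsets + window[wi], drop = FALSE])
  }
  out
}

#' Cofluctuation time-aligned to state transitions
#'
#' Extracts a window about every transition onset (the first TR of a new
#' state; transitions occur between t-1 and t), averages over transitions,
#' and aggregates edges by connection category plus a grand mean. Windows
#' clipped at run edges are dropped.
#'
#' @param x An [edge_timeseries()] or a length-T numeric vector (e.g. the
#'   global cofluctuation).
#' @param seq A [state_sequence()] aligned to `x`.
#' @param window Integer offsets about the onset (default `-3:3`).
#' @return Data frame with columns `offset`, `category` (`"all"` plus the
#'   connection categories for edge input), `mean`, and `n_transitions`.
#' @export
align_to_transitions <- function(x, seq, window = -3:3) {
  onsets <- transition_onsets(seq, window)
  if (!length(onsets)) {
    warning("no usable state transitions in the sequence", call. = FALSE)
    return(data.frame(offset = integer(0), category = character(0),
                      mean = numeric(0), n_transitions = integer(0)))
  }
  if (inherits(x, "edge_timeseries")) {
    per_edge <- aligned_means_at(x$values, onsets, window)
    cats <- unique(x$edge_category)
    res <- data.frame(offset = window, category = "all",
                      mean = colMeans(per_edge),
                      n_transitions = length(onsets))
    for (cc in cats) {
      res <- rbind(res, data.frame(
        offset = window, category = cc,
        mean = colMeans(per_edge[x$edge_category == cc, , drop = FALSE]),
        n_transitions = length(onsets)))
    }
    res
  } else {
    m <- aligned_means_at(matrix(as.numeric(x), nrow = 1), onsets, window)
    data.frame(offset = window, category = "all", mean = drop(m),
               n_transitions = length(onsets))
  }
}

#' Null for transition-aligned cofluctuation by onset shuffling
#'
#' Re-runs the alignment with the same number of onsets placed uniformly at
#' random (full windows only, within run), `n_iter` times; the reference
#' chance model for the transition-aligned traces.
#'
#' @inheritParams align_to_transitions
#' @param n_iter Number of shuffles.
#' @param seed RNG seed.
#' @return List with `null` (matrix `n_iter` x `length(window)` of grand
#'   means per offset; for edge input the grand mean over all edges),
#'   `band` (2 x offsets: mean +/- 1.96 sd), and `p_values` (two-tailed,
#'   add-one, per offset, versus the observed grand mean).
#' @export
transition_alignment_null <- function(x, seq, window = -3:3, n_iter = 1000,
                                      seed = 1) {
  labels <- seq_labels(seq)
  segs <- run_segments(seq_boundaries(seq), length(labels))
  onsets <- transition_onsets(seq, window)
  if (!length(onsets)) stop_domain("no usable transitions to build a null for")
  x_mat <- if (inherits(x, "edge_timeseries")) x$values
           else matrix(as.numeric(x), nrow = 1)
  valid <- integer(0)
  for (s in seq_len(nrow(segs))) {
    lo <- segs[s, "start"] - min(window)
    hi <- segs[s, "end"] - max(window)
    if (hi >= lo) valid <- c(valid, lo:hi)
  }
  observed <- colMeans(aligned_means_at(x_mat, onsets, window))
  null <- with_seed(seed, {
    t(vapply(seq_len(n_iter), function(i) {
      fake <- sample(valid, length(onsets), replace = length(valid) < length(onsets))
      colMeans(aligned_means_at(x_mat, fake, window))
    }, numeric(length(window))))
  })
  band <- apply(null, 2, function(v) null_band(v))
  p <- vapply(seq_along(window),
              function(wi) permutation_pvalue(observed[wi], null[, wi]), 0)
  list(observed = observed, null = null, band = band,
       p_values = setNames(p, window))
}
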