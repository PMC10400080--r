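# Sequence-level statistics: fractional occupancy, dwell times, transition
# matrices, intersubject sequence similarity, bootstrap condition contrasts.

seq_labels <- function(seq) {
  if (inherits(seq, "state_sequence")) seq$labels else as.integer(seq)
}

seq_boundaries <- function(seq) {
  if (inherits(seq, "state_sequence")) seq$run_boundary_index else 0L
}

seq_K <- function(seq, K = NULL) {
  if (!is.null(K)) return(as.integer(K))
  if (inherits(seq, "state_sequence")) seq$K else max(seq_labels(seq))
}

#' Fractional occupancy of each state
#'
#' Proportion of TRs spent in each state over the whole sequence (chance
#' level `1/K` for a uniform sequence).
#'
#' @param seq A [state_sequence()] or integer label vector.
#' @param K State count (inferred when `seq` is a `state_sequence`).
#' @return Length-K proportion vector summing to 1.
#' @export
fractional_occupancy <- function(seq, K = NULL) {
  labels <- seq_labels(seq)
  K <- seq_K(seq, K)
  tabulate(labels, nbins = K) / length(labels)
}

#' Dwell times (consecutive run lengths) per state
#'
#' Maximal runs of one state, computed within runs (a dwell never spans a
#' run boundary).
#'
#' @inheritParams fractional_occupancy
#' @return List of K integer vectors of dwell lengths in TRs.
#' @export
dwell_times <- function(seq, K = NULL) {
  labels <- seq_labels(seq)
  K <- seq_K(seq, K)
  segs <- run_segments(seq_boundaries(seq), length(labels))
  out <- rep(list(integer(0)), K)
  for (s in seq_len(nrow(segs))) {
    r <- rle(labels[segs[s, "start"]:segs[s, "end"]])
    for (k in seq_len(K)) {
      out[[k]] <- c(out[[k]], r$lengths[r$values == k])
    }
  }
  out
}

#' Transition count/probability matrix
#'
#' Counts consecutive within-run label pairs (from state at t-1, to state at
#' t; boundary-crossing pairs excluded) and normalizes rows ("to where does
#' each state transition") or columns ("from where is each state entered").
#' Rows/columns with no counts are emitted as zeros and flagged in attribute
#' `empty`.
#'
#' @inheritParams fractional_occupancy
#' @param normalization `"row"` or `"column"`.
#' @param include_self Keep self-transitions (diagonal)? The transition
#'   analyses of state switching typically drop them.
#' @return List of class `transition_matrix` with `counts`, `probabilities`,
#'   and `normalization`.
#' @export
transition_matrix <- function(seq, normalization = c("row", "column"),
                              K = NULL, include_self = TRUE) {
  normalization <- match.arg(normalization)
  labels <- seq_labels(seq)
  K <- seq_K(seq, K)
  segs <- run_segments(seq_boundaries(seq), length(labels))
  counts <- matrix(0L, K, K)
  for (s in seq_len(nrow(segs))) {
    rows <- segs[s, "start"]:segs[s, "end"]
    if (length(rows) < 2L) next
    from <- labels[rows[-length(rows)]]
    to <- labels[rows[-1L]]
    for (i in seq_along(from)) {
      counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
    }
  }
  if (!include_self) diag(counts) <- 0L
  probs <- matrix(0, K, K)
  if (normalization == "row") {
    rs <- rowSums(counts)
    nz <- rs > 0
    probs[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
    empty <- which(!nz)
  } else {
    cs <- colSums(counts)
    nz <- cs > 0
    probs[, nz] <- sweep(counts[, nz, drop = FALSE], 2, cs[nz], `/`)
    empty <- which(!nz)
  }
  structure(list(counts = counts, probabilities = probs,
                 normalization = normalization),
            class = "transition_matrix", empty = empty)
}

#' Similarity of two state sequences
#'
#' Proportion of TRs at which the same state occurs in both sequences (the
#' intersubject synchrony measure for hard-labeled dynamics).
#'
#' @param seqA,seqB Sequences of equal length.
#' @return Proportion in `[0, 1]`.
#' @export
sequence_similarity <- function(seqA, seqB) {
  a <- seq_labels(seqA); b <- seq_labels(seqB)
  if (length(a) != length(b)) stop_domain("sequences differ in length")
  mean(a == b)
}

#' Pairwise participant similarity
#'
#' [sequence_similarity()] over all unordered subject pairs.
#'
#' @param seqs List of >= 2 equal-length sequences (one per subject).
#' @return List with `mean`, `sd` (over pairs), `matrix` (symmetric, unit
#'   diagonal), and `pairs` (tidy per-pair data frame).
#' @export
pairwise_similarity <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) stop_domain("need at least 2 subjects")
  M <- diag(1, n)
  pr <- combn(n, 2)
  vals <- numeric(ncol(pr))
  for (i in seq_len(ncol(pr))) {
    vals[i] <- sequence_similarity(seqs[[pr[1, i]]], seqs[[pr[2, i]]])
    M[pr[1, i], pr[2, i]] <- M[pr[2, i], pr[1, i]] <- vals[i]
  }
  list(mean = mean(vals), sd = sd(vals), matrix = M,
       pairs = data.frame(i = pr[1, ], j = pr[2, ], similarity = vals))
}

#' Bootstrap contrast of paired pairwise similarities across conditions
#'
#' For two conditions measured on the same subject pairs: each outer iterate
#' resamples the pairs with replacement (`n_pairs` draws) and takes the
#' median of the paired differences A - B; repeated `n_outer` times. The
#' two-tailed p-value is the add-one-corrected proportion of medians crossing
#' zero.
#'
#' @param similaritiesA,similaritiesB Per-pair similarity vectors (same pair
#'   order).
#' @param n_outer Outer bootstrap iterations.
#' @param seed RNG seed.
#' @return List with `medians` (length `n_outer`), `p_value`, and
#'   `mean_difference`.
#' @export
bootstrap_condition_contrast <- function(similaritiesA, similaritiesB,
                                         n_outer = 1000, seed = 1) {
  a <- as.numeric(similaritiesA); b <- as.numeric(similaritiesB)
  if (length(a) != length(b)) stop_domain("conditions have different pair counts")
  if (length(a) < 2L) stop_domain("need at least 2 pairs")
  d <- a - b
  n <- length(d)
  medians <- with_seed(seed, {
    vapply(seq_len(n_outer),
           function(i) median(d[sample.int(n, n, replace = TRUE)]), 0)
  })
  p <- min(1, 2 * min((1 + sum(medians <= 0)) / (n_outer + 1),
                      (1 + sum(medians >= 0)) / (n_outer + 1)))
  list(medians = medians, p_value = p, mean_difference = mean(d))
}
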