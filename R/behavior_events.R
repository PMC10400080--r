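# Event-boundary-aligned state occurrence, boundary-conditioned transition
# sources, attention-by-state coupling, and blockwise occupancy -- each with
# its circular-shift or sign-permutation null.

as_seq_list <- function(seqs) {
  if (inherits(seqs, "state_sequence")) list(seqs) else seqs
}

#' Sign-permutation test of paired differences
#'
#' Tests whether subject-level paired differences are centered on zero by
#' flipping the sign of each subject's difference: exhaustively over all 2^N
#' patterns when N <= 12, otherwise by `n_iter` random flips (add-one
#' corrected). The statistic is the mean difference; the p-value is
#' two-tailed. This is the package's permutation substitute for paired
#' parametric/signed-rank contrasts.
#'
#' @param diffs Per-subject paired differences (NAs dropped).
#' @param n_iter Random sign flips when enumeration is infeasible.
#' @param seed RNG seed (random branch only).
#' @return List with `p_value`, `mean_difference`, `n`, and `exact`.
#' @export
sign_permutation_test <- function(diffs, n_iter = 5000, seed = 1) {
  d <- as.numeric(diffs)
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2L) stop_domain("need at least 2 paired differences")
  obs <- mean(d)
  if (n <= 12L) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stat <- abs(signs %*% d) / n
    p <- mean(stat >= abs(obs) - 1e-12)
    exact <- TRUE
  } else {
    stat <- with_seed(seed, {
      vapply(seq_len(n_iter),
             function(i) abs(mean(d * sample(c(-1, 1), n, replace = TRUE))), 0)
    })
    p <- (1 + sum(stat >= abs(obs) - 1e-12)) / (n_iter + 1)
    exact <- FALSE
  }
  list(p_value = min(1, p), mean_difference = obs, n = n, exact = exact)
}

#' State occurrence aligned to narrative event boundaries
#'
#' For every state and window offset: the probability that the state occupies
#' the TR at `boundary + offset`, averaged over boundaries within subject,
#' then across subjects. Offsets falling outside the run for a given
#' boundary are dropped for that boundary.
#'
#' @param seqs A [state_sequence()] or list of them (one per subject; equal
#'   lengths, single-run).
#' @param boundaries An [event_boundaries()] shared across subjects.
#' @param window Integer offsets about the boundary (default `-2:20`).
#' @param K State count (inferred from the sequences by default).
#' @return Object of class `aligned_occurrence`: `per_state_prob` (K x
#'   offsets, columns sum to 1), `offsets`, `n_boundaries`, `per_subject`
#'   (subjects x K x offsets array).
#' @export
boundary_aligned_occurrence <- function(seqs, boundaries, window = -2:20,
                                        K = NULL) {
  seqs <- as_seq_list(seqs)
  K <- seq_K(seqs[[1L]], K)
  btrs <- boundaries$boundary_trs
  n_subj <- length(seqs)
  per_subject <- array(NA_real_, c(n_subj, K, length(window)))
  for (si in seq_len(n_subj)) {
    labels <- seq_labels(seqs[[si]])
    T_ <- length(labels)
    if (any(btrs > T_)) stop_domain("boundary beyond run extent")
    for (wi in seq_along(window)) {
      pos <- btrs + window[wi]
      pos <- pos[pos >= 1L & pos <= T_]
      if (!length(pos)) next
      per_subject[si, , wi] <- tabulate(labels[pos], nbins = K) / length(pos)
    }
  }
  structure(list(per_state_prob = apply(per_subject, c(2, 3), mean, na.rm = TRUE),
                 offsets = window, n_boundaries = length(btrs),
                 per_subject = per_subject),
            class = "aligned_occurrence")
}

#' Chance bands and p-values for boundary-aligned occurrence
#'
#' The null relates the (unchanged) state dynamics to circular-shifted
#' boundary moments: per iterate, one random rotation offset is applied to
#' all boundary TRs (modulo the run length) and the group-level aligned
#' occurrence is recomputed. Per state and offset: two-tailed add-one
#' p-value, BH-FDR corrected across offsets within state.
#'
#' @inheritParams boundary_aligned_occurrence
#' @param n_iter Number of shifted-boundary iterates.
#' @param seed RNG seed.
#' @return List with `observed` ([boundary_aligned_occurrence()] result),
#'   `null` (array `n_iter` x K x offsets), `band` (K x offsets lo/hi list),
#'   `p_values` and `p_fdr` (K x offsets matrices).
#' @export
boundary_occurrence_null <- function(seqs, boundaries, window = -2:20,
                                     n_iter = 1000, seed = 1, K = NULL) {
  seqs <- as_seq_list(seqs)
  K <- seq_K(seqs[[1L]], K)
  obs <- boundary_aligned_occurrence(seqs, boundaries, window, K)
  T_ <- length(seq_labels(seqs[[1L]]))
  btrs <- boundaries$boundary_trs
  null <- with_seed(seed, {
    arr <- array(NA_real_, c(n_iter, K, length(window)))
    for (i in seq_len(n_iter)) {
      off <- sample.int(T_ - 1L, 1L)
      shifted <- sort(((btrs - 1L + off) %% T_) + 1L)
      bb <- event_boundaries(shifted)
      arr[i, , ] <- boundary_aligned_occurrence(seqs, bb, window, K)$per_state_prob
    }
    arr
  })
  p <- matrix(NA_real_, K, length(window))
  for (k in seq_len(K)) {
    for (wi in seq_along(window)) {
      p[k, wi] <- permutation_pvalue(obs$per_state_prob[k, wi], null[, k, wi])
    }
  }
  p_fdr <- t(apply(p, 1, fdr_bh))
  lo <- apply(null, c(2, 3), function(v) null_band(v)["lo"])
  hi <- apply(null, c(2, 3), function(v) null_band(v)["hi"])
  list(observed = obs, null = null, band = list(lo = lo, hi = hi),
       p_values = p, p_fdr = p_fdr)
}

#' Source states of transitions into a target state, at vs. away from boundaries
#'
#' Every transition into `target_state` is classified as boundary-adjacent
#' (its onset falls `window` TRs after some event boundary; default 5-15 TRs
#' at a 1 s TR, scaled as `round(5 / tr) .. round(15 / tr)` otherwise) or
#' not. Per subject and class, the proportions of source states are
#' computed; per source state, the boundary-vs-non-boundary proportion
#' difference is tested across subjects by [sign_permutation_test()], BH-FDR
#' corrected over the sources.
#'
#' @inheritParams boundary_aligned_occurrence
#' @param target_state State whose incoming transitions are classified.
#' @param window Post-boundary lag window (TR offsets).
#' @param tr Sampling interval, used to scale the default window.
#' @return List with `proportions` (data frame: subject, source, class,
#'   proportion), `contrasts` (per source: mean difference, p, p_fdr), and
#'   `n_transitions`.
#' @export
boundary_transition_classification <- function(seqs, boundaries, target_state,
                                               window = NULL, tr = 1,
                                               K = NULL) {
  seqs <- as_seq_list(seqs)
  K <- seq_K(seqs[[1L]], K)
  if (!target_state %in% seq_len(K)) stop_domain("invalid target_state")
  if (is.null(window)) window <- seq.int(round(5 / tr), round(15 / tr))
  btrs <- boundaries$boundary_trs
  sources <- setdiff(seq_len(K), target_state)
  rows <- list()
  n_trans <- 0L
  for (si in seq_along(seqs)) {
    labels <- seq_labels(seqs[[si]])
    segs <- run_segments(seq_boundaries(seqs[[si]]), length(labels))
    onsets <- integer(0); from <- integer(0)
    for (s in seq_len(nrow(segs))) {
      rr <- segs[s, "start"]:segs[s, "end"]
      t_on <- rr[-1L][labels[rr[-1L]] == target_state &
                      labels[rr[-length(rr)]] != target_state]
      onsets <- c(onsets, t_on)
      from <- c(from, labels[t_on - 1L])
    }
    n_trans <- n_trans + length(onsets)
    near <- vapply(onsets, function(t) any((t - btrs) %in% window), TRUE)
    for (cls in c("boundary", "non_boundary")) {
      sel <- if (cls == "boundary") near else !near
      if (!any(sel)) next
      prop <- tabulate(from[sel], nbins = K)[sources] / sum(sel)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = si, source = sources, class = cls, proportion = prop)
    }
  }
  props <- do.call(rbind, rows)
  contrasts <- do.call(rbind, lapply(sources, function(src) {
    d <- vapply(seq_along(seqs), function(si) {
      pb <- props$proportion[props$subject == si & props$source == src &
                             props$class == "boundary"]
      pn <- props$proportion[props$subject == si & props$source == src &
                             props$class == "non_boundary"]
      if (!length(pb) || !length(pn)) NA_real_ else pb - pn
    }, 0)
    if (sum(is.finite(d)) < 2L) {
      return(data.frame(source = src, mean_difference = mean(d, na.rm = TRUE),
                        p = NA_real_))
    }
    st <- sign_permutation_test(d)
    data.frame(source = src, mean_difference = st$mean_difference, p = st$p_value)
  }))
  contrasts$p_fdr <- ifelse(is.na(contrasts$p), NA, fdr_bh(ifelse(is.na(contrasts$p), 1, contrasts$p)))
  list(proportions = props, contrasts = contrasts, n_transitions = n_trans)
}

#' Mean attention measure per occupied state, with circular-shift null
#'
#' Averages each subject's behavioral trace within the TRs of each decoded
#' state, then across subjects (states absent in a subject are missing for
#' that subject). The null circular-shifts each subject's trace against the
#' unchanged state dynamics; per state: two-tailed add-one p, BH-FDR over
#' the states.
#'
#' @param traces A [behavioral_trace()] shared by all subjects, or a list of
#'   per-subject traces.
#' @inheritParams boundary_aligned_occurrence
#' @param n_iter Null iterations.
#' @param seed RNG seed.
#' @return List with `state_means` (group, length K), `per_subject`
#'   (subjects x K), `null` (n_iter x K), `p_values`, `p_fdr`, `z`.
#' @export
attention_by_state <- function(traces, seqs, n_iter = 1000, seed = 1,
                               K = NULL) {
  seqs <- as_seq_list(seqs)
  if (inherits(traces, "behavioral_trace")) {
    traces <- rep(list(traces), length(seqs))
  }
  stopifnot(length(traces) == length(seqs))
  K <- seq_K(seqs[[1L]], K)
  n_subj <- length(seqs)
  per_state <- function(vals, labels) {
    vapply(seq_len(K), function(k) {
      idx <- labels == k
      if (!any(idx)) NA_real_ else mean(vals[idx])
    }, 0)
  }
  per_subject <- t(vapply(seq_len(n_subj), function(si) {
    v <- traces[[si]]$values
    l <- seq_labels(seqs[[si]])
    if (length(v) != length(l)) stop_domain("trace/sequence length mismatch")
    per_state(v, l)
  }, numeric(K)))
  observed <- colMeans(per_subject, na.rm = TRUE)
  null <- with_seed(seed, {
    m <- matrix(NA_real_, n_iter, K)
    for (i in seq_len(n_iter)) {
      it <- t(vapply(seq_len(n_subj), function(si) {
        v <- circular_shift(traces[[si]]$values)
        per_state(v, seq_labels(seqs[[si]]))
      }, numeric(K)))
      m[i, ] <- colMeans(it, na.rm = TRUE)
    }
    m
  })
  p <- vapply(seq_len(K), function(k) permutation_pvalue(observed[k], null[, k]), 0)
  z <- vapply(seq_len(K), function(k) {
    tryCatch(zstat_vs_null(observed[k], null[, k]), error = function(e) NA_real_)
  }, 0)
  list(state_means = observed, per_subject = per_subject, null = null,
       p_values = p, p_fdr = fdr_bh(p), z = z)
}

#' Fractional occupancy per task block, with paired contrasts
#'
#' Computes each state's fractional occupancy within every labeled TR block,
#' averages blocks of the same type within subject, and contrasts block
#' types pairwise per state by [sign_permutation_test()] (BH-FDR over
#' states within each block-type pair).
#'
#' @inheritParams boundary_aligned_occurrence
#' @param block_table Data frame with columns `start_tr`, `end_tr`, `label`;
#'   blocks must not overlap.
#' @return List with `occupancy` (data frame: subject, block label, state,
#'   occupancy) and `contrasts` (data frame: labelA, labelB, state,
#'   mean_difference, p, p_fdr).
#' @export
blockwise_occupancy <- function(seqs, block_table, K = NULL) {
  seqs <- as_seq_list(seqs)
  K <- seq_K(seqs[[1L]], K)
  bt <- block_table
  stopifnot(all(c("start_tr", "end_tr", "label") %in% names(bt)))
  if (any(bt$end_tr < bt$start_tr)) stop_domain("empty block (end < start)")
  o <- order(bt$start_tr)
  if (any(bt$start_tr[o][-1] <= bt$end_tr[o][-nrow(bt)])) {
    stop_domain("blocks overlap")
  }
  occ <- list()
  for (si in seq_along(seqs)) {
    labels <- seq_labels(seqs[[si]])
    for (bi in seq_len(nrow(bt))) {
      if (bt$end_tr[bi] > length(labels)) stop_domain("block beyond run extent")
      fo <- tabulate(labels[bt$start_tr[bi]:bt$end_tr[bi]], nbins = K) /
        (bt$end_tr[bi] - bt$start_tr[bi] + 1L)
      occ[[length(occ) + 1L]] <- data.frame(
        subject = si, label = bt$label[bi], state = seq_len(K), occupancy = fo)
    }
  }
  occ <- do.call(rbind, occ)
  # within-subject mean over blocks of the same type
  agg <- stats::aggregate(occupancy ~ subject + label + state, occ, mean)
  types <- unique(agg$label)
  contrasts <- NULL
  if (length(types) >= 2L) {
    prs <- combn(types, 2)
    contrasts <- do.call(rbind, lapply(seq_len(ncol(prs)), function(pi) {
      la <- prs[1, pi]; lb <- prs[2, pi]
      res <- do.call(rbind, lapply(seq_len(K), function(k) {
        d <- vapply(seq_along(seqs), function(si) {
          va <- agg$occupancy[agg$subject == si & agg$label == la & agg$state == k]
          vb <- agg$occupancy[agg$subject == si & agg$label == lb & agg$state == k]
          if (!length(va) || !length(vb)) NA_real_ else va - vb
        }, 0)
        st <- sign_permutation_test(d)
        data.frame(labelA = la, labelB = lb, state = k,
                   mean_difference = st$mean_difference, p = st$p_value)
      }))
      res$p_fdr <- fdr_bh(res$p)
      res
    }))
  }
  list(occupancy = agg, contrasts = contrasts)
}
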