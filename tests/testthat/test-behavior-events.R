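# Event-boundary-aligned occurrence, boundary-conditioned transition sources,
# attention-by-state coupling, blockwise occupancy, sign-permutation test.

# Group of sequences where `forced` occupies `force_len` TRs after every
# boundary and the rest of the chain is a uniform-ish HMM draw.
forced_boundary_group <- function(n_subj, T_, boundaries, forced = 2L,
                                  force_len = 10L, K = 4, seed = 1) {
  params <- sample_hmm_params(K = K, P = 4, self_prob = 0.85, seed = seed)
  lapply(seq_len(n_subj), function(si) {
    lab <- simulate_run(params, T_, seed = seed + 100 * si)$states$labels
    for (b in boundaries) {
      idx <- b:min(T_, b + force_len - 1L)
      lab[idx] <- forced
    }
    state_sequence(lab, K)
  })
}

test_that("sign-permutation test: exact enumeration and random agreement", {
  d <- c(0.2, 0.25, 0.18, 0.3, 0.22, 0.27)
  ex <- sign_permutation_test(d)
  expect_true(ex$exact)
  expect_equal(ex$p_value, 2 / 64)  # only all-plus / all-minus reach |mean(d)|
  zero <- sign_permutation_test(c(-1, 1, -1, 1))
  expect_equal(zero$p_value, 1)
  big <- rnorm(20, 0.5, 0.2)
  rnd <- sign_permutation_test(big, n_iter = 2000, seed = 3)
  expect_false(rnd$exact)
  expect_lt(rnd$p_value, 0.01)
  expect_error(sign_permutation_test(1), "at least 2")
})

test_that("boundary-aligned occurrence reproduces raw indicators", {
  lab <- c(rep(1L, 9), rep(2L, 5), rep(1L, 6))
  eb <- event_boundaries(10L)
  al <- boundary_aligned_occurrence(state_sequence(lab, 2), eb, window = -2:6)
  # single subject, single boundary: proportions are the 0/1 indicators
  expect_equal(al$per_state_prob[2, ], as.numeric(lab[10 + (-2:6)] == 2))
  expect_equal(colSums(al$per_state_prob), rep(1, 9))
  # a state occupying every TR has proportion 1 at all offsets
  mono <- boundary_aligned_occurrence(state_sequence(rep(1L, 30), 3),
                                      event_boundaries(c(5L, 15L)), -2:5)
  expect_equal(mono$per_state_prob[1, ], rep(1, 8))
  # offsets beyond the run are dropped per boundary, not padded
  edge <- boundary_aligned_occurrence(state_sequence(lab, 2),
                                      event_boundaries(c(10L, 18L)),
                                      window = 0:4)
  expect_false(anyNA(edge$per_state_prob))
  expect_error(boundary_aligned_occurrence(state_sequence(lab, 2),
                                           event_boundaries(50L), -2:2),
               "beyond run")
})

test_that("a state forced after boundaries dominates the post-boundary window", {
  eb <- event_boundaries(c(60L, 140L, 230L, 310L, 390L))
  seqs <- forced_boundary_group(6, 450, eb$boundary_trs, forced = 2L,
                                force_len = 10L, seed = 4)
  al <- boundary_aligned_occurrence(seqs, eb, window = -2:20)
  inside <- al$per_state_prob[2, al$offsets %in% 0:9]
  outside <- al$per_state_prob[2, al$offsets %in% 15:20]
  expect_true(all(inside == 1))
  expect_lt(mean(outside), 0.6)
})

test_that("boundary occurrence null flags the forced window and only it", {
  # irregular event lengths (as in the generator) over a long run: a joint
  # boundary shift can realign the set with the true post-boundary windows
  # only for the handful of shifts smaller than the forced window itself
  eb <- event_boundaries(c(40L, 130L, 305L, 420L, 560L, 700L, 820L, 1005L,
                           1150L, 1290L, 1380L, 1470L))
  seqs <- forced_boundary_group(8, 1500, eb$boundary_trs, forced = 2L,
                                force_len = 8L, seed = 5)
  res <- boundary_occurrence_null(seqs, eb, window = -2:12, n_iter = 1000,
                                  seed = 6)
  sig <- res$p_fdr[2, ] <= 0.05
  expect_true(all(sig[res$observed$offsets %in% 1:7]))
  expect_true(all(!sig[res$observed$offsets %in% 9:12]))
  expect_identical(
    res$null[1:50, , ],
    boundary_occurrence_null(seqs, eb, -2:12, n_iter = 50, seed = 6)$null)
  # an unrelated sequence yields no significant offsets
  set.seed(7)
  unrel <- lapply(1:8, function(i) {
    state_sequence(sample.int(4, 1500, replace = TRUE), 4)
  })
  res0 <- boundary_occurrence_null(unrel, eb, window = -2:20, n_iter = 300,
                                   seed = 8)
  expect_true(all(res0$p_fdr > 0.01, na.rm = TRUE))
})

test_that("transitions into a target state are classified by boundary lag", {
  # no boundaries: every transition is non-boundary
  lab <- c(1L, 1L, 2L, 2L, 1L, 2L, 1L, 1L, 2L, 2L)
  none <- boundary_transition_classification(
    list(state_sequence(lab, 2), state_sequence(rev(lab), 2)),
    event_boundaries(integer(0)), target_state = 2L, window = 5:15)
  expect_true(all(none$proportions$class == "non_boundary"))
  # proportions over sources sum to 1 within each subject/class
  eb <- event_boundaries(c(50L, 150L, 250L))
  seqs <- forced_boundary_group(5, 350, eb$boundary_trs + 7L, forced = 3L,
                                force_len = 6L, K = 4, seed = 9)
  cls <- boundary_transition_classification(seqs, eb, target_state = 3L,
                                            window = 5:15)
  sums <- aggregate(proportion ~ subject + class, cls$proportions, sum)
  expect_equal(sums$proportion, rep(1, nrow(sums)), tolerance = 1e-12)
  expect_equal(nrow(cls$contrasts), 3)  # one row per source state
})

test_that("a source forced to precede the target only after boundaries is detected", {
  # construction: after each boundary the chain visits source 4 then target 2;
  # elsewhere transitions into 2 come from anywhere
  set.seed(10)
  eb <- event_boundaries(c(50L, 120L, 200L, 280L, 360L))
  seqs <- lapply(1:8, function(si) {
    lab <- sample(c(1L, 3L), 430, replace = TRUE)
    # background transitions into 2 from 1 or 3
    bg <- sample(setdiff(5:425, as.vector(outer(eb$boundary_trs, 0:20, `+`))), 12)
    for (t in bg) lab[t:(t + 2)] <- 2L
    for (b in eb$boundary_trs) {
      lab[(b + 4):(b + 7)] <- 4L
      lab[(b + 8):(b + 12)] <- 2L
    }
    state_sequence(lab, 4)
  })
  cls <- boundary_transition_classification(seqs, eb, target_state = 2L,
                                            window = 5:15)
  c4 <- cls$contrasts[cls$contrasts$source == 4, ]
  expect_gt(c4$mean_difference, 0.5)
  expect_lt(c4$p_fdr, 0.05)
})

test_that("attention-by-state recovers per-state means and calibrated nulls", {
  # hand-computable example
  trace <- behavioral_trace(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), tr = 1)
  seq10 <- state_sequence(c(1L, 1L, 2L, 2L, 1L, 2L, 1L, 1L, 2L, 2L), 2)
  res <- attention_by_state(trace, seq10, n_iter = 50, seed = 11)
  expect_equal(unname(res$state_means),
               c(mean(c(1, 2, 5, 7, 8)), mean(c(3, 4, 6, 9, 10))))
  # constant trace: equal means, nothing significant
  flat <- attention_by_state(behavioral_trace(rep(2, 10), tr = 1), seq10,
                             n_iter = 50, seed = 12)
  expect_equal(unname(diff(flat$state_means)), 0)
  expect_true(all(flat$p_values == 1))
  # power construction: one engaged state, 8 subjects
  params <- sample_hmm_params(K = 4, P = 4, self_prob = 0.9, seed = 13)
  seqs <- list(); traces <- list()
  for (si in 1:8) {
    st <- simulate_run(params, 600, seed = 14 + si)$states
    seqs[[si]] <- st
    traces[[si]] <- simulate_attention_trace(st, c(1, 0, 0, 0), noise_sd = 0.5,
                                             seed = 40 + si)
  }
  pow <- attention_by_state(traces, seqs, n_iter = 300, seed = 15)
  expect_equal(which.max(pow$state_means), 1L)
  expect_lt(pow$p_fdr[1], 0.01)
  expect_gt(pow$z[1], 0)
})

test_that("blockwise occupancy equals whole-run occupancy for one block", {
  set.seed(16)
  lab <- sample.int(3, 120, replace = TRUE)
  blocks <- data.frame(start_tr = 1L, end_tr = 120L, label = "all")
  bo <- blockwise_occupancy(state_sequence(lab, 3), blocks)
  expect_equal(bo$occupancy$occupancy[order(bo$occupancy$state)],
               fractional_occupancy(lab, K = 3))
  expect_null(bo$contrasts)
  expect_error(blockwise_occupancy(state_sequence(lab, 3),
                                   data.frame(start_tr = c(1L, 40L),
                                              end_tr = c(50L, 80L),
                                              label = c("a", "b"))),
               "overlap")
})

test_that("blockwise contrasts detect a state enriched in one block type", {
  # 'task' blocks draw uniformly from 4 states; 'rest' blocks force state 3
  set.seed(17)
  blocks <- data.frame(start_tr = c(1L, 61L, 121L, 181L),
                       end_tr = c(60L, 120L, 180L, 240L),
                       label = c("task", "rest", "task", "rest"))
  seqs <- lapply(1:6, function(si) {
    lab <- sample.int(4, 240, replace = TRUE)
    rest_trs <- c(61:120, 181:240)
    lab[rest_trs] <- sample(c(3L, 3L, 3L, 1L, 2L, 4L), 120, replace = TRUE)
    state_sequence(lab, 4)
  })
  bo <- blockwise_occupancy(seqs, blocks)
  per_block_sums <- aggregate(occupancy ~ subject + label, bo$occupancy, sum)
  expect_equal(per_block_sums$occupancy, rep(1, nrow(per_block_sums)),
               tolerance = 1e-12)
  c3 <- bo$contrasts[bo$contrasts$state == 3, ]
  # label order is alphabetical: rest - task difference is positive
  expect_gt(c3$mean_difference * ifelse(c3$labelA == "rest", 1, -1), 0.1)
  expect_lt(c3$p_fdr, 0.05)
})
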