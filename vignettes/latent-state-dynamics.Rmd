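---
title: "Latent brain-state dynamics: models, nulls, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent brain-state dynamics: models, nulls, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurostates)
```

# The model

`neurostates` characterizes large-scale brain dynamics as transitions among a
small number of discrete latent states. The observed data are parcellated
fMRI time series: for each subject-run, a $T \times P$ matrix $y_{1:T}$ of
BOLD amplitudes ($T$ time points sampled every TR seconds, $P$ parcels),
z-normalized within run and concatenated across runs and subjects.

The generative model is a Gaussian-emission hidden Markov model. A hidden
first-order Markov chain $x_t \in \{1, \dots, K\}$ with transition matrix
$A = (a_{ij})$, $\sum_j a_{ij} = 1$, and initial distribution $\pi$ emits

$$y_t \mid x_t = s \;\sim\; \mathcal{N}(\mu_s, \Sigma_s),$$

with a full $P \times P$ covariance per state: a state is a recurring
*pattern* of mean activity **and** parcel-to-parcel coupling, not just an
activation level. Estimation is by expectation-maximization over the
forward-backward recursions; decoding of the single most probable state path
is by the Viterbi algorithm. Both recursions restart from $\pi$ at every run
boundary, and no transition is counted across a boundary, so concatenation
never manufactures spurious dynamics.

## Model order

$K$ is selected by leave-one-subject-out cross-validation: for each candidate
$K$, the model is fit on all subjects but one, the held-out subject's runs
are Viterbi-decoded under the fitted model, and the Calinski-Harabasz score

$$\mathrm{CH} = \frac{\mathrm{tr}(B)/(k-1)}{\mathrm{tr}(W)/(N-k)}$$

of the held-out observations under the decoded hard labels is recorded
($B$, $W$ = between/within-cluster scatter). The $K$ with the largest
fold-mean score wins; ties go to the smallest $K$. The score is computed on
the raw held-out observations with decoded labels (posteriors are not used);
infinite scores from zero within-scatter are capped at a large sentinel
($10^{12}$) before averaging.

## Downstream statistics

* **Fractional occupancy** — the proportion of TRs a state occupies (chance
  $1/K$); **dwell times** — lengths of maximal constant-state runs.
* **Transition matrices** — within-run counts of consecutive label pairs,
  row-normalized ("to where") or column-normalized ("from where").
* **Intersubject synchrony** — the proportion of TRs at which two subjects
  occupy the same state, over all unordered pairs, with a pairs-bootstrap
  (median-of-differences) contrast between conditions.
* **Cofluctuation** — for z-scored parcels $i, j$, the edge time series
  $|z_i(t) \, z_j(t)|$; its mean over all edges is the global cofluctuation,
  summarized per state and time-aligned to transition onsets (the first TR of
  a new state) over a $-3..+3$ TR window. Edges aggregate into
  cortico-cortical, cortico-subcortical and subcortico-subcortical
  categories. **Covariance strength** of a state is
  $\sum_{i<j} |\Sigma_{s,ij}|$.
* **Gradients** — a group functional connectome (subject-mean Pearson
  correlation matrix) is sparsified row-wise at the 90th percentile, turned
  into a cosine-similarity affinity, and decomposed by a diffusion-map
  embedding (anisotropic normalization $\alpha = 0.5$, diffusion time 0).
  State mean patterns project onto gradient $g$ as
  $\frac{1}{P}\sum_p \mathrm{grad}_{pg}\,\mu_{sp}$; the share of raw
  time-series variance a gradient explains is the parcel-mean squared
  correlation between each parcel series and the gradient-projected series.
* **Event and behavior coupling** — state occurrence aligned to narrative
  event boundaries ($-2..+20$ TRs); classification of transitions into a
  target state by whether they fall 5–15 TRs after a boundary (scaled as
  `round(5/tr)..round(15/tr)` for other TRs); per-state means of an
  HRF-convolved attention trace; per-block fractional occupancy.

## Inference: circular-shift nulls throughout

Every test is permutation-based. The chance model is the *circular shift*:
rotating a series by a random offset (drawn in $1..T-1$; 0 is excluded so a
surrogate always differs from the original) preserves its autocorrelation and
marginal distribution while destroying its alignment with everything else.
Shifts are always applied within run. Depending on the question, the shifted
object is the parcel time series (independent per-parcel shifts followed by a
full HMM refit — the surrogate ensemble used for covariance strength,
transition structure and gradient-space tests), the state sequence, the
behavioral trace, the boundary moments, or the transition onsets.

P-values are two-tailed and add-one corrected,
$p = \min\!\big(1,\, 2\min\big(\tfrac{1+\#\{null \ge obs\}}{n+1},
\tfrac{1+\#\{null \le obs\}}{n+1}\big)\big)$, so they are valid at finite
$n$; chance bands are null mean $\pm 1.96$ SD. Multiple comparisons use
Benjamini-Hochberg FDR (over states, offsets, sources, or $K \times G$
gradient positions, matching each analysis's family). Paired group contrasts
use sign permutation of subject-level differences — exact enumeration up to
$N = 12$ subjects, sampled beyond — as the package's uniform, distribution-free
replacement for paired t/signed-rank tests: same inferential target, no
parametric machinery.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tol` (EM) | 1e-2 | log-lik | stop when an iteration gains less than this; matches common HMM practice |
| `max_iter` (EM) | 1000 | iterations | hard cap on EM |
| `ridge` | 1e-6 | variance | added to every M-step covariance diagonal; keeps $\Sigma_s$ invertible at $P$ up to 25 |
| `n_restarts` | 10 | fits | EM restarts, best final likelihood kept |
| `threshold_quantile` | 0.90 | quantile | row-wise connectome sparsification |
| `alpha` | 0.5 | — | diffusion-map anisotropic normalization |
| `window` (transitions) | $-3..+3$ | TR | cofluctuation alignment window |
| `window` (boundaries) | $-2..+20$ | TR | boundary-aligned occurrence window |
| boundary lag window | 5–15 | TR (at 1 s) | post-boundary classification of transitions |
| `n_iter` (nulls) | 1000 | iterates | reducible for desk-scale runs |
| HRF | double-gamma | — | shapes 6 and 16, rate 1/s, undershoot ratio 1/6, 32 s support; peak at 5 s |

# The synthetic-data generator

`sample_hmm_params` / `simulate_run` / `simulate_group` produce groups of
subject-runs with known ground truth. Design choices:

* **State means** sit on a sphere of radius
  `mean_separation * sqrt(P) / 2` along a *random orthonormal frame*
  (random directions when $K > P$). Orthogonality makes every pairwise mean
  distance exactly `radius * sqrt(2)`, so `mean_separation` is a single
  faithful knob for decoding difficulty. With uniformly random directions,
  two states can land nearly parallel; separation then varies wildly between
  pairs, and a merged labeling can legitimately out-score the true one under
  cluster-validity criteria — which would test the luck of the draw, not the
  procedure.
* **Covariances** are either the identity (`diagonal`) or random full SPD
  matrices $AA^\top/P + 0.1I$ (`random_full`).
* **Transitions** have diagonal `self_prob` (default 0.9, i.e. mean dwell 10
  TRs, the order of magnitude of observed state dwellings at a 1 s TR) and
  uniform off-diagonal mass; the initial distribution is uniform.
* **Event structures** draw event lengths uniform-integer in
  `[min_len, max_len]` with alternating A/B storyline labels.
* **Attention traces** are `effects[state_t]` plus Gaussian noise,
  HRF-convolved and z-normalized.
* `shared_sequence` forces one state chain across subjects, emulating
  stimulus-driven synchrony.

What the generator does **not** emulate: scanner drift, autocorrelated
noise, head motion, or hemodynamic smoothing of the state signal itself.
Emissions are conditionally independent given the state. One consequence is
worth spelling out: with instantaneous state switches and accurate decoding,
the sample just before a transition is an ordinary draw from the old state,
so the transition-aligned cofluctuation trace is *flat* in expectation —
the pre-transition desynchronization seen in real BOLD data arises from
gradual, hemodynamically blended transitions, which conditionally-iid
emissions cannot produce. `blend_transition_samples()` adds exactly that
ingredient (the pre-transition sample becomes a half-and-half mixture of the
old-state observation and an incoming-state draw); on such data the pipeline
robustly reproduces the dip at offset $-1$ relative to $+3$. Passing tests on
blended data therefore show the *measurement chain* (z-scoring, edge
products, decoded-transition alignment) detects boundary desynchronization
when it exists; they do not show that iid-emission HMM data contain it.

# Numerical choices

* All densities in log space; log-sum-exp normalization; the forward-backward
  and Viterbi inner loops are compiled (Rcpp).
* Viterbi ties break toward the lowest state index.
* Sample standard deviation (denominator $T-1$) everywhere.
* k-means initialization: 10 random starts, best inertia; transition/initial
  counts from hard assignments with add-one smoothing.
* Cholesky-based Gaussian densities with escalating ridge (x10 up to 1e-2)
  before declaring a covariance singular.
* Diffusion embedding: negatives clipped to 0 before thresholding; per-component
  sign fixed by making the largest-magnitude loading positive; variance
  ratios are each eigenvalue over the sum of all non-trivial positive
  eigenvalues; a disconnected affinity graph is an error, not a warning.
* Partial alignment windows at run edges are dropped, never padded.
* RT-variability traces: gaps filled by linear interpolation (edges by the
  nearest valid value), linear detrend *then* deviance-from-mean, resampling
  to the TR grid by linear interpolation at TR-aligned times, and the
  subject's mean variability prepended as the first-TR value after
  detrending (the order is a package decision; the convention the measure
  was introduced with does not pin it down).
* Boundary-shift nulls rotate the whole boundary set by one shared offset
  per iterate, preserving the inter-boundary spacing structure.
* Gradient extremity tests pool all $K$ null states' positions per axis per
  surrogate (null fits carry no state correspondence to the real fit).

# Validation scale

The test suite and the acceptance script run everything end-to-end at desk
scale, chosen so the full suite completes in minutes on one core: model-order
recovery uses 8 subjects x 600 TRs x 10 parcels over $K = 2..6$ with 3 EM
restarts per fold; parameter recovery uses the same group; chain statistics
(transition convergence, geometric dwell times) use single runs of 50,000
TRs; null-calibration checks use 200 synthetic repeats at 200 permutation
iterates; oracle equivalences (Viterbi vs exhaustive enumeration, posteriors
vs path enumeration) use $T \le 8$, $K \le 3$. Parameter recovery is
assessed by the mean absolute error of the state mean patterns (per-entry
extremes scale with sampling noise at these sizes) against the generating
means mapped through each run's realized z-transform.

# Known limitations

* No hidden semi-Markov (explicit dwell) models, autoregressive emissions, or
  hierarchical group HMMs.
* The Calinski-Harabasz criterion is computed on observations with hard
  decoded labels; soft-posterior variants are not implemented.
* Gradient estimation works at the parcel level; voxelwise gradients and
  comparisons against published voxel maps are out of scope (externally
  computed parcel-level gradient vectors can be supplied as a matrix).
* Parametric alternatives (repeated-measures ANOVA, mixed-effects models with
  motion covariates) are deliberately not wrapped; the permutation tools are
  the package's inferential surface.
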