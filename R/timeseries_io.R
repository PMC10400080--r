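# Parcel time-series containers, on-disk formats, and the normalization /
# convolution preprocessing the state analyses assume.

#' Parcel time series container
#'
#' One subject-run of parcellated fMRI data: a T x P numeric matrix (rows are
#' time points sampled every `tr` seconds, columns are parcels), plus the
#' metadata the downstream analyses need.
#'
#' @param values Numeric T x P matrix, all finite, T >= 2, P >= 2.
#' @param tr Sampling interval in seconds (repetition time).
#' @param subject_id,run_id Identifier strings.
#' @param parcel_labels Character vector of P unique parcel names. Defaults to
#'   the matrix column names, or `"parcel_1"...` when absent.
#' @param parcel_categories Character vector of P tags, each `"cortical"` or
#'   `"subcortical"`; used to group edges into connection categories.
#' @return An object of class `parcel_timeseries`.
#' @export
parcel_timeseries <- function(values, tr, subject_id = "sub", run_id = "run",
                              parcel_labels = NULL, parcel_categories = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop_domain("parcel time series needs at least 2 time points and 2 parcels")
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_domain(sprintf("non-finite value at time %d, parcel %d", bad[1], bad[2]))
  }
  if (!is_scalar_number(tr) || tr <= 0) stop_domain("tr must be a positive number")
  P <- ncol(values)
  if (is.null(parcel_labels)) {
    parcel_labels <- colnames(values)
    if (is.null(parcel_labels)) parcel_labels <- paste0("parcel_", seq_len(P))
  }
  if (length(parcel_labels) != P) stop_domain("parcel_labels length must equal P")
  if (anyDuplicated(parcel_labels)) stop_domain("parcel labels must be unique")
  if (is.null(parcel_categories)) parcel_categories <- rep("cortical", P)
  if (length(parcel_categories) != P ||
      !all(parcel_categories %in% c("cortical", "subcortical"))) {
    stop_domain("parcel_categories must be length P with values 'cortical'/'subcortical'")
  }
  colnames(values) <- parcel_labels
  structure(
    list(values = values, tr = tr, subject_id = as.character(subject_id),
         run_id = as.character(run_id), parcel_labels = as.character(parcel_labels),
         parcel_categories = as.character(parcel_categories)),
    class = "parcel_timeseries")
}

#' @export
print.parcel_timeseries <- function(x, ...) {
  cat(sprintf("<parcel_timeseries> %s/%s: %d TRs x %d parcels, TR = %gs\n",
              x$subject_id, x$run_id, nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}

#' @export
dim.parcel_timeseries <- function(x) dim(x$values)

#' Behavioral trace container
#'
#' A per-TR behavioral measure (inverted response-time variability or a
#' continuous engagement rating) aligned to one fMRI run.
#'
#' @param values Numeric vector, one value per TR.
#' @param tr Sampling interval in seconds.
#' @param kind `"rt_variability_inverted"` or `"engagement"`.
#' @param hrf_convolved Has the trace already been convolved with the
#'   hemodynamic response function?
#' @return An object of class `behavioral_trace`.
#' @export
behavioral_trace <- function(values, tr,
                             kind = c("engagement", "rt_variability_inverted"),
                             hrf_convolved = FALSE) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop_domain("behavioral trace must be finite")
  if (!is_scalar_number(tr) || tr <= 0) stop_domain("tr must be a positive number")
  structure(list(values = values, tr = tr, kind = kind,
                 hrf_convolved = isTRUE(hrf_convolved)),
            class = "behavioral_trace")
}

#' Event boundary table
#'
#' TR indices at which one narrative event ends and the next begins, with
#' per-event storyline labels (e.g. the interleaved ABAB structure of a
#' two-storyline sitcom stimulus). A boundary TR is the first TR of the new
#' event. `n_events` is always `length(boundary_trs) + 1`.
#'
#' @param boundary_trs Strictly increasing integer TR indices (1-based).
#' @param story_labels Optional per-event labels, length `n_events`.
#' @param hemodynamic_delay_tr Nominal hemodynamic delay in TRs, metadata used
#'   when reporting boundary-aligned results (not applied as a data shift).
#' @return An object of class `event_boundaries`.
#' @export
event_boundaries <- function(boundary_trs, story_labels = NULL,
                             hemodynamic_delay_tr = 5L) {
  boundary_trs <- as.integer(boundary_trs)
  if (length(boundary_trs) && (is.unsorted(boundary_trs, strictly = TRUE) ||
                               any(boundary_trs < 1L))) {
    stop_domain("boundary_trs must be strictly increasing positive integers")
  }
  n_events <- length(boundary_trs) + 1L
  if (!is.null(story_labels) && length(story_labels) != n_events) {
    stop_domain("story_labels must have one entry per event (boundaries + 1)")
  }
  if (hemodynamic_delay_tr < 0) stop_domain("hemodynamic delay must be >= 0")
  structure(list(boundary_trs = boundary_trs, n_events = n_events,
                 hemodynamic_delay_tr = as.integer(hemodynamic_delay_tr),
                 story_labels = story_labels),
            class = "event_boundaries")
}

#' Read a parcel time series from TSV (+ JSON sidecar)
#'
#' The on-disk format is a tab-separated matrix with a header row of parcel
#' labels (rows = TRs) and an optional JSON sidecar `<path>.json` holding
#' `tr`, `subject_id`, `run_id` and `parcel_categories`. Metadata given as
#' arguments (e.g. from a run manifest) override the sidecar.
#'
#' @param path Path to the TSV file.
#' @param n_parcels Declared parcel count; the file is rejected if its column
#'   count disagrees (guards against transposed matrices).
#' @param tr,subject_id,run_id,parcel_categories Optional metadata overrides.
#' @return A [parcel_timeseries()].
#' @export
load_parcel_timeseries <- function(path, n_parcels = NULL, tr = NULL,
                                   subject_id = NULL, run_id = NULL,
                                   parcel_categories = NULL) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  mat <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = nrow(df), dimnames = list(NULL, names(df)))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop_domain(sprintf("non-numeric cell in %s at row %d, column %d ('%s')",
                        path, bad[1], bad[2], names(df)[bad[2]]))
  }
  if (!is.null(n_parcels) && ncol(mat) != n_parcels) {
    stop_domain(sprintf("%s has %d columns but %d parcels were declared",
                        path, ncol(mat), n_parcels))
  }
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  parcel_timeseries(
    mat,
    tr = tr %||% meta$tr %||% 1,
    subject_id = subject_id %||% meta$subject_id %||% "sub",
    run_id = run_id %||% meta$run_id %||% "run",
    parcel_labels = names(df),
    parcel_categories = parcel_categories %||% meta$parcel_categories)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a parcel time series as TSV + JSON sidecar
#'
#' @param ts A [parcel_timeseries()].
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_parcel_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  write.table(ts$values, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(tr = ts$tr, subject_id = ts$subject_id, run_id = ts$run_id,
         parcel_categories = ts$parcel_categories),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run manifest
#'
#' Ordered table of subject-runs making up a group dataset. The row order is
#' the concatenation order used when pooling runs for model fitting.
#'
#' @param subject_id,run_id Character vectors (equal length).
#' @param path File paths of the per-run TSVs (may be `NA` for in-memory data).
#' @param condition Optional per-run condition tags (task, movie, rest, ...).
#' @return A `data.frame` of class `run_manifest`.
#' @export
run_manifest <- function(subject_id, run_id, path = NA_character_,
                         condition = NA_character_) {
  df <- data.frame(subject_id = as.character(subject_id),
                   run_id = as.character(run_id),
                   path = as.character(path),
                   condition = as.character(condition),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("subject_id", "run_id")])) {
    stop_domain("(subject_id, run_id) pairs must be unique")
  }
  class(df) <- c("run_manifest", "data.frame")
  df
}

#' Read event boundaries from a two-column TSV
#'
#' Expected columns: `boundary_tr` (integer) and `story_label` (label of the
#' event *starting* at that boundary; the first event's label is taken from an
#' optional leading row with `boundary_tr = 0`, otherwise labels are omitted).
#'
#' @param path TSV path.
#' @inheritParams event_boundaries
#' @return An [event_boundaries()].
#' @export
read_event_boundaries <- function(path, hemodynamic_delay_tr = 5L) {
  df <- read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("boundary_tr", "story_label") %in% names(df))) {
    stop_domain("boundary TSV needs columns boundary_tr, story_label")
  }
  first <- df$boundary_tr == 0
  labels <- c(df$story_label[first], df$story_label[!first])
  if (!any(first)) labels <- NULL
  event_boundaries(df$boundary_tr[!first], story_labels = labels,
                   hemodynamic_delay_tr = hemodynamic_delay_tr)
}

#' Z-normalize each parcel within a run
#'
#' Columns are centered and scaled to sample standard deviation 1 (denominator
#' T - 1), the normalization assumed by the cofluctuation edge construction.
#'
#' @param ts A [parcel_timeseries()], or a plain numeric matrix.
#' @return Same type as the input, z-normalized column-wise.
#' @export
znormalize <- function(ts) {
  mat <- if (inherits(ts, "parcel_timeseries")) ts$values else as.matrix(ts)
  sds <- apply(mat, 2, sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- which(sds == 0 | !is.finite(sds))[1L]
    nm <- colnames(mat)[bad] %||% as.character(bad)
    stop_domain("parcel '", nm, "' has zero variance; cannot z-normalize")
  }
  z <- scale(mat, center = TRUE, scale = sds)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  if (inherits(ts, "parcel_timeseries")) {
    ts$values <- z
    ts
  } else z
}

is_znormalized <- function(mat, tol = 1e-6) {
  all(abs(colMeans(mat)) < tol)
}

#' Concatenate runs into one matrix with run boundary offsets
#'
#' Stacks runs row-wise in manifest order and records each run's 0-based start
#' offset so later steps (EM restarts, transition counting, circular shifts)
#' never cross run boundaries.
#'
#' @param runs List of [parcel_timeseries()] sharing P, TR and parcel labels.
#' @param manifest Optional [run_manifest()] giving the concatenation order by
#'   (subject_id, run_id); defaults to list order.
#' @return A list with `data` (T_total x P matrix), `run_boundary_index`
#'   (0-based start offsets, one per run), and `runs` metadata (subject/run id
#'   and length per run).
#' @export
concatenate_runs <- function(runs, manifest = NULL) {
  stopifnot(length(runs) >= 1L, all(vapply(runs, inherits, TRUE, "parcel_timeseries")))
  if (!is.null(manifest)) {
    key <- function(s, r) paste(s, r, sep = "\r")
    have <- key(vapply(runs, `[[`, "", "subject_id"), vapply(runs, `[[`, "", "run_id"))
    want <- key(manifest$subject_id, manifest$run_id)
    idx <- match(want, have)
    if (anyNA(idx)) stop_domain("manifest lists runs not supplied")
    runs <- runs[idx]
  }
  ref <- runs[[1L]]
  for (r in runs[-1L]) {
    if (!identical(r$parcel_labels, ref$parcel_labels)) {
      stop_domain("runs have different parcel labels/order; cannot concatenate")
    }
    if (!isTRUE(all.equal(r$tr, ref$tr))) stop_domain("runs have different TRs")
  }
  lens <- vapply(runs, function(r) nrow(r$values), 0L)
  list(data = do.call(rbind, lapply(runs, `[[`, "values")),
       run_boundary_index = as.integer(cumsum(c(0L, lens[-length(lens)]))),
       runs = data.frame(subject_id = vapply(runs, `[[`, "", "subject_id"),
                         run_id = vapply(runs, `[[`, "", "run_id"),
                         n_tr = lens, stringsAsFactors = FALSE))
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma HRF: a response gamma (shape 6, rate 1/s; mode at
#' 5 s) minus an undershoot gamma (shape 16, rate 1/s) scaled by
#' `undershoot_ratio`, sampled causally at the TR grid over `duration`
#' seconds.
#'
#' @param tr Sampling interval in seconds (> 0).
#' @param duration Kernel support in seconds (>= 16).
#' @param peak_shape,undershoot_shape,rate Gamma parameters (1/s rate).
#' @param undershoot_ratio Relative undershoot amplitude.
#' @return Numeric kernel of length `duration / tr`, normalized to peak 1.
#' @export
canonical_hrf <- function(tr, duration = 32, peak_shape = 6,
                          undershoot_shape = 16, rate = 1,
                          undershoot_ratio = 1 / 6) {
  if (!is_scalar_number(tr) || tr <= 0) stop_domain("tr must be > 0")
  if (duration < 16) stop_domain("duration must be at least 16 s")
  t <- seq(0, duration - tr, by = tr)
  h <- dgamma(t, shape = peak_shape, rate = rate) -
    undershoot_ratio * dgamma(t, shape = undershoot_shape, rate = rate)
  h / max(h)
}

#' Convolve a behavioral trace with the canonical HRF
#'
#' Causal convolution truncated to the input length, so that sample t mixes
#' only samples at or before t. Refuses traces already flagged as convolved.
#'
#' @param trace A [behavioral_trace()].
#' @param kernel HRF kernel; default [canonical_hrf()] at the trace's TR.
#' @return The convolved [behavioral_trace()] with `hrf_convolved = TRUE`.
#' @export
hrf_convolve <- function(trace, kernel = NULL) {
  stopifnot(inherits(trace, "behavioral_trace"))
  if (trace$hrf_convolved) {
    stop_domain("trace is already HRF-convolved; refusing to convolve twice")
  }
  if (is.null(kernel)) kernel <- canonical_hrf(trace$tr)
  x <- trace$values
  out <- convolve(c(x, rep(0, length(kernel))), rev(kernel), type = "open")
  trace$values <- out[seq_along(x)]
  trace$hrf_convolved <- TRUE
  trace
}

#' Response-time variability trace from per-trial response times
#'
#' Builds the attention proxy used with continuous-performance-task runs.
#' Missing (incorrect / no-response) trials are filled by 1-D linear
#' interpolation (edge gaps by the nearest valid value), the series is
#' linearly detrended, variability is the absolute deviation from the
#' post-detrend mean, the trial-grid series is resampled to the TR grid by
#' linear interpolation when the trial duration differs from the TR, the
#' subject's mean variability is prepended as the first-TR value, and the
#' result is z-normalized (and sign-inverted when `invert = TRUE`, so that
#' larger values mean more stable, attentive responding).
#'
#' @param rts Per-trial response times in seconds; `NA` marks missing or
#'   incorrect trials.
#' @param trial_duration Trial length in seconds.
#' @param tr fMRI sampling interval in seconds.
#' @param n_tr Target trace length in TRs; defaults to
#'   `round(n_trials * trial_duration / tr)`.
#' @param invert Sign-invert after z-normalization (attention proxy).
#' @return A [behavioral_trace()] of kind `"rt_variability_inverted"` (not yet
#'   HRF-convolved).
#' @export
rt_variability_trace <- function(rts, trial_duration, tr, n_tr = NULL,
                                 invert = TRUE) {
  rts <- as.numeric(rts)
  n <- length(rts)
  ok <- is.finite(rts)
  if (sum(ok) < 2L) stop_domain("need at least 2 non-missing trials")
  filled <- approx(x = which(ok), y = rts[ok], xout = seq_len(n),
                   method = "linear", rule = 2)$y
  detrended <- stats::resid(lm(filled ~ seq_len(n)))
  dev <- abs(detrended - mean(detrended))
  if (is.null(n_tr)) n_tr <- round(n * trial_duration / tr)
  # trial i is anchored at its end time i * trial_duration
  trial_times <- seq_len(n) * trial_duration
  tr_times <- seq_len(n_tr) * tr
  resampled <- approx(trial_times, dev, xout = tr_times, rule = 2)$y
  resampled[1L] <- mean(dev)  # first TR carries the subject's mean variability
  if (sd(resampled) < 1e-12) {
    stop_domain("RT variability is constant; z-normalization undefined")
  }
  z <- as.numeric(scale(resampled))
  if (invert) z <- -z
  behavioral_trace(z, tr = tr, kind = "rt_variability_inverted")
}
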