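# Circular-shift surrogates, permutation p-values, and FDR correction shared
# by every analysis module.

#' Null distribution container
#'
#' @param values Realizations of a statistic under the null.
#' @param statistic_name Label for reporting.
#' @param seed Seed used to generate the distribution (metadata).
#' @return An object of class `null_distribution`.
#' @export
null_distribution <- function(values, statistic_name = "statistic", seed = NA) {
  values <- as.numeric(values)
  if (!length(values)) stop_domain("empty null distribution")
  structure(list(values = values, n_iter = length(values),
                 statistic_name = statistic_name, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s: %d iterates, mean %.4g, sd %.4g\n",
              x$statistic_name, x$n_iter, mean(x$values), sd(x$values)))
  invisible(x)
}

#' Circular-shift a time series (independently per column)
#'
#' Rotates each column by an offset with wraparound, preserving each column's
#' autocorrelation and marginal distribution while destroying its temporal
#' alignment with everything else. When run boundaries are given, each run
#' segment is rotated independently so shifted values never cross runs.
#' Random offsets are drawn uniformly in `1..(T_run - 1)` (0 is excluded so a
#' random surrogate always differs from the original).
#'
#' @param x Numeric vector or T x P matrix.
#' @param offsets Integer offsets, one per column (recycled), or `NULL` to
#'   draw them randomly.
#' @param run_boundary_index 0-based run start offsets (default: one run).
#' @param seed RNG seed for random offsets.
#' @return Shifted object of the same shape.
#' @export
circular_shift <- function(x, offsets = NULL, run_boundary_index = 0L,
                           seed = NULL) {
  vec <- is.null(dim(x))
  mat <- if (vec) matrix(as.numeric(x), ncol = 1L) else as.matrix(x)
  segs <- run_segments(run_boundary_index, nrow(mat))
  out <- with_seed(seed, {
    res <- mat
    for (s in seq_len(nrow(segs))) {
      rows <- segs[s, "start"]:segs[s, "end"]
      Tn <- length(rows)
      if (Tn < 2L) next
      offs <- if (is.null(offsets)) {
        sample.int(Tn - 1L, ncol(mat), replace = TRUE)
      } else rep_len(as.integer(offsets), ncol(mat)) %% Tn
      for (j in seq_len(ncol(mat))) {
        o <- offs[j] %% Tn
        if (o > 0L) res[rows, j] <- mat[rows, j][c((Tn - o + 1L):Tn, 1L:(Tn - o))]
      }
    }
    res
  })
  if (vec) drop(out) else out
}

#' Two-tailed permutation p-value
#'
#' Add-one corrected: `p = min(1, 2 * min((1 + #{null >= obs}) / (n + 1),
#' (1 + #{null <= obs}) / (n + 1)))`, valid at finite n.
#'
#' @param observed Observed statistic.
#' @param null A [null_distribution()] or numeric vector of null realizations.
#' @param tails `"two"` (default) or `"upper"`/`"lower"`.
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(observed, null, tails = c("two", "upper", "lower")) {
  tails <- match.arg(tails)
  vals <- if (inherits(null, "null_distribution")) null$values else as.numeric(null)
  if (!length(vals)) stop_domain("empty null distribution")
  n <- length(vals)
  p_up <- (1 + sum(vals >= observed)) / (n + 1)
  p_lo <- (1 + sum(vals <= observed)) / (n + 1)
  switch(tails,
         two = min(1, 2 * min(p_up, p_lo)),
         upper = p_up,
         lower = p_lo)
}

#' Null band (mean +/- 1.96 sd)
#'
#' The chance band conventionally drawn around permutation nulls.
#'
#' @inheritParams permutation_pvalue
#' @return Named vector `c(lo, hi)`.
#' @export
null_band <- function(null) {
  vals <- if (inherits(null, "null_distribution")) null$values else as.numeric(null)
  if (length(vals) < 2L) stop_domain("need at least 2 null iterates for a band")
  m <- mean(vals); s <- sd(vals)
  c(lo = m - 1.96 * s, hi = m + 1.96 * s)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values via [stats::p.adjust()].
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param q Optional FDR level; when given, the rejection indicator is
#'   attached as attribute `"reject"`.
#' @return Adjusted p-values (same order as input).
#' @export
fdr_bh <- function(pvalues, q = NULL) {
  pvalues <- as.numeric(pvalues)
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop_domain("p-values must lie in [0, 1]")
  }
  adj <- p.adjust(pvalues, method = "BH")
  if (!is.null(q)) attr(adj, "reject") <- adj <= q
  adj
}

#' Z-statistic of an observation against a permutation null
#'
#' @inheritParams permutation_pvalue
#' @return `(observed - mean(null)) / sd(null)`.
#' @export
zstat_vs_null <- function(observed, null) {
  vals <- if (inherits(null, "null_distribution")) null$values else as.numeric(null)
  s <- sd(vals)
  if (!is.finite(s) || s == 0) stop_domain("null distribution has zero sd")
  (observed - mean(vals)) / s
}
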