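# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so library code never perturbs
#' user-level random streams.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed deterministically from a master seed; kept below 2^31.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Start/end row indices of each run given 0-based start offsets and total rows.
run_segments <- function(run_boundary_index, total) {
  starts <- as.integer(run_boundary_index) + 1L
  stopifnot(starts[1] == 1L, !is.unsorted(starts), all(starts <= total))
  ends <- c(starts[-1] - 1L, as.integer(total))
  cbind(start = starts, end = ends)
}

stop_domain <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
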