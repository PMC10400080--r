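# Diffusion-map connectivity gradients: group functional connectome,
# row-thresholded cosine affinity, diffusion embedding, projection of state
# means into gradient space, explained time-series variance, and the
# state-distance / extremity permutation tests against surrogate ensembles.

#' Group-average functional connectome
#'
#' Per subject: z-normalize each run, concatenate the subject's runs, and
#' take the Pearson correlation matrix; then average the subject matrices
#' and zero the diagonal (it carries no connectivity information and would
#' dominate the later row-thresholding).
#'
#' @param runs List of [parcel_timeseries()] (one or more runs per subject).
#' @return P x P symmetric matrix with zero diagonal.
#' @export
functional_connectome <- function(runs) {
  stopifnot(length(runs) >= 1L)
  subjects <- unique(vapply(runs, `[[`, "", "subject_id"))
  mats <- lapply(subjects, function(s) {
    cc <- concatenate_runs(lapply(Filter(function(r) r$subject_id == s, runs),
                                  znormalize))
    cor(cc$data)
  })
  fc <- Reduce(`+`, mats) / length(mats)
  diag(fc) <- 0
  fc
}

#' Diffusion-map embedding of a functional connectome
#'
#' Standard connectivity-gradient pipeline: negatives clipped to zero, each
#' row thresholded at its `threshold_quantile` quantile (entries below it
#' zeroed, for sparseness), cosine similarity between the thresholded rows as
#' the affinity, then a diffusion-map decomposition with anisotropic
#' normalization `alpha` at diffusion time 0. The top-G nontrivial
#' components are returned with their eigenvalue variance ratios
#' (eigenvalue over the sum of all nontrivial positive eigenvalues).
#' Each component's sign is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param fc P x P symmetric connectivity matrix.
#' @param threshold_quantile Row-wise sparsification quantile (default 0.90).
#' @param alpha Anisotropic diffusion normalization (default 0.5).
#' @param G Number of gradients to return (>= 2).
#' @return An object of class `gradient_embedding`: `coordinates` (P x G),
#'   `eigenvalues`, `variance_ratio`, `alpha`, `threshold_quantile`.
#' @export
diffusion_embedding <- function(fc, threshold_quantile = 0.90, alpha = 0.5,
                                G = 2) {
  fc <- as.matrix(fc)
  P <- nrow(fc)
  if (P < 3L) stop_domain("need at least 3 parcels")
  if (G < 1L || G > P - 1L) stop_domain("G must lie in 1..P-1")
  W0 <- pmax(fc, 0)
  diag(W0) <- 0
  thr <- t(apply(W0, 1, function(r) {
    q <- quantile(r, threshold_quantile)
    ifelse(r >= q, r, 0)
  }))
  # cosine similarity between thresholded connectivity profiles
  nrm <- sqrt(rowSums(thr^2))
  if (any(nrm == 0)) {
    stop_domain("parcel(s) ", paste(which(nrm == 0), collapse = ", "),
                " have empty thresholded profiles")
  }
  A <- (thr %*% t(thr)) / (nrm %o% nrm)
  A <- pmin(pmax((A + t(A)) / 2, 0), 1)
  comp <- graph_components(A > 0)
  if (max(comp) > 1L) {
    stop_domain("affinity graph is disconnected (components: ",
                paste(tabulate(comp), collapse = ", "), ")")
  }
  d <- rowSums(A)
  W_alpha <- A / (d^alpha %o% d^alpha)
  d_alpha <- rowSums(W_alpha)
  # symmetric conjugate of the Markov operator
  S <- W_alpha / sqrt(d_alpha %o% d_alpha)
  eig <- eigen(S, symmetric = TRUE)
  psi <- (eig$vectors / sqrt(d_alpha))[, -1, drop = FALSE]  # right eigvecs of Markov op, trivial dropped
  lambdas <- eig$values[-1]
  pos <- lambdas > .Machine$double.eps
  lambdas <- lambdas[pos]
  psi <- psi[, pos, drop = FALSE]
  coords <- psi[, seq_len(G), drop = FALSE]
  for (g in seq_len(G)) {
    if (coords[which.max(abs(coords[, g])), g] < 0) coords[, g] <- -coords[, g]
  }
  colnames(coords) <- paste0("gradient_", seq_len(G))
  structure(list(coordinates = coords, eigenvalues = lambdas[seq_len(G)],
                 variance_ratio = lambdas[seq_len(G)] / sum(lambdas),
                 all_eigenvalues = lambdas, alpha = alpha,
                 threshold_quantile = threshold_quantile),
            class = "gradient_embedding")
}

#' @export
print.gradient_embedding <- function(x, ...) {
  cat(sprintf("<gradient_embedding> %d parcels x %d gradients; variance ratios: %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.3f", x$variance_ratio), collapse = ", ")))
  invisible(x)
}

grad_coords <- function(embedding) {
  if (inherits(embedding, "gradient_embedding")) embedding$coordinates
  else as.matrix(embedding)
}

#' Project state mean patterns into gradient space
#'
#' State k's coordinate on gradient g is the mean over parcels of the
#' element-wise product of the gradient loadings and the state's mean
#' activity pattern; a state with zero mean activity sits at the origin.
#'
#' @param state_means K x P matrix (or an [hmm_parameters()]).
#' @param embedding A [diffusion_embedding()] result or a P x G matrix of
#'   (possibly externally defined) gradient loadings.
#' @return K x G coordinate matrix.
#' @export
project_states <- function(state_means, embedding) {
  if (inherits(state_means, "hmm_parameters")) state_means <- state_means$means
  coords <- grad_coords(embedding)
  stopifnot(ncol(state_means) == nrow(coords))
  out <- state_means %*% coords / nrow(coords)
  rownames(out) <- paste0("state_", seq_len(nrow(out)))
  out
}

#' Permutation tests on state positions in gradient space
#'
#' Two questions against a surrogate-HMM null ensemble: (i) are the states
#' more mutually distant in gradient space than chance (mean pairwise
#' Euclidean distance, two-tailed permutation p); (ii) does each state sit at
#' a more extreme position on each gradient axis than chance (per state and
#' axis, against the pooled null state positions on that axis, two-tailed,
#' BH-FDR over the K x G comparisons).
#'
#' @param state_coords K x G observed coordinates (see [project_states()]).
#' @param null_coords List of K x G null coordinate matrices (e.g. surrogate
#'   fits from [fit_surrogate_ensemble()] projected with [project_states()]).
#' @return List with `mean_distance`, `null_mean_distances`, `p_distance`,
#'   and `extremity` (data frame: state, gradient, coordinate, p, p_fdr).
#' @export
state_distance_test <- function(state_coords, null_coords) {
  if (!length(null_coords)) stop_domain("null ensemble is empty")
  obs_d <- mean(stats::dist(state_coords))
  null_d <- vapply(null_coords, function(m) mean(stats::dist(m)), 0)
  K <- nrow(state_coords); G <- ncol(state_coords)
  ext <- expand.grid(state = seq_len(K), gradient = seq_len(G))
  ext$coordinate <- state_coords[cbind(ext$state, ext$gradient)]
  ext$p <- vapply(seq_len(nrow(ext)), function(i) {
    pool <- unlist(lapply(null_coords, function(m) m[, ext$gradient[i]]))
    permutation_pvalue(ext$coordinate[i], pool)
  }, 0)
  ext$p_fdr <- fdr_bh(ext$p)
  list(mean_distance = obs_d, null_mean_distances = null_d,
       p_distance = permutation_pvalue(obs_d, null_d), extremity = ext)
}

#' Variance of the parcel time series explained by gradient projections
#'
#' Projects the concatenated group time series onto each gradient (per-TR
#' mean of gradient-weighted parcel activity) and reports, per gradient, the
#' mean over parcels of the squared Pearson correlation between each parcel
#' series and the projected series, plus their total.
#'
#' @param runs List of [parcel_timeseries()], or a single T x P matrix.
#' @param embedding A [diffusion_embedding()] result or P x G loading matrix.
#' @return List with `r2` (per gradient) and `total`.
#' @export
explained_timeseries_variance <- function(runs, embedding) {
  coords <- grad_coords(embedding)
  data <- if (is.list(runs) && all(vapply(runs, inherits, TRUE, "parcel_timeseries"))) {
    concatenate_runs(lapply(runs, znormalize))$data
  } else as.matrix(runs)
  stopifnot(ncol(data) == nrow(coords))
  proj <- data %*% coords / nrow(coords)
  r2 <- vapply(seq_len(ncol(coords)), function(g) {
    if (sd(proj[, g]) == 0) stop_domain("projected series for gradient ", g,
                                        " is constant")
    mean(cor(data, proj[, g])^2)
  }, 0)
  names(r2) <- colnames(coords)
  list(r2 = r2, total = sum(r2))
}

# Connected components of an undirected adjacency (logical) matrix.
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[u, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
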