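# Shared EM machinery for both denoising stages. Both stages are exponential
# mixture models over a fixed candidate set (the unique observed items): the
# component "centres" are restricted to observed candidates, so the full
# read-by-candidate distance matrix can be computed once and the M step is an
# exact full scan.

#' Initialise clusters by complete-linkage clustering
#'
#' Complete-linkage hierarchical clustering of the items, cut at height
#' `cutoff`: every within-cluster pair was merged at height at most `cutoff`.
#' Used to initialise the EM mixtures (the cut also fixes the initial number
#' of components `L`).
#'
#' @param distances square matrix (symmetrised by averaging with its
#'   transpose) or `dist` object of pairwise distances.
#' @param cutoff merge-height cut-off.
#' @return integer vector of cluster memberships (`1..L`).
#' @export
init_complete_linkage <- function(distances, cutoff) {
  if (inherits(distances, "dist")) {
    n <- attr(distances, "Size")
    d <- distances
  } else {
    distances <- as.matrix(distances)
    n <- nrow(distances)
    if (n == 0) stop("no items to cluster")
    d <- as.dist((distances + t(distances)) / 2)
  }
  if (n == 0) stop("no items to cluster")
  if (n == 1) return(1L)
  tree <- hclust(d, method = "complete")
  unname(cutree(tree, h = min(cutoff, max(tree$height))))
}

#' EM expectation step
#'
#' Responsibilities `z[i, j] = tau_j exp(-d[i, j] / sigma) / sum_k tau_k
#' exp(-d[i, k] / sigma)`, computed in log space.
#'
#' @param dists N x L matrix of distances from each read to each component.
#' @param tau component weights summing to 1.
#' @param sigma cluster scale of the exponential kernel.
#' @return N x L responsibility matrix with unit row sums.
#' @export
em_e_step <- function(dists, tau, sigma) {
  if (all(tau == 0)) stop("all component weights are zero")
  lg <- sweep(-dists / sigma, 2, log(tau), "+")
  mx <- apply(lg, 1, max)
  z <- exp(lg - mx)
  z / rowSums(z)
}

#' EM maximisation step
#'
#' For each component, picks the candidate with the smallest
#' responsibility-weighted total distance to all reads, and recomputes the
#' component weights as the (read-weighted) mean responsibility. Components
#' whose weight falls to zero are retained (flagged by `tau = 0`) so component
#' indices stay stable across iterations.
#'
#' @param resp N x L responsibility matrix.
#' @param dist_to_candidates N x P matrix of distances from each read to each
#'   candidate centre.
#' @param weights per-read multiplicities (default 1).
#' @return list with `centre` (candidate index per component, ties to the
#'   lowest index) and `tau`.
#' @export
em_m_step <- function(resp, dist_to_candidates, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(resp))
  zw <- resp * weights
  score <- crossprod(zw, dist_to_candidates)  # L x P
  centre <- apply(score, 1, which.min)
  tau <- colSums(zw) / sum(weights)
  list(centre = as.integer(centre), tau = tau)
}

em_loglik <- function(dist_comp, tau, sigma, weights) {
  lg <- sweep(-dist_comp / sigma, 2, log(tau), "+")
  lg[, tau == 0] <- -Inf
  mx <- apply(lg, 1, max)
  sum(weights * (mx + log(rowSums(exp(lg - mx)))))
}

# Core EM loop. D_full: N x P distances to all candidate centres; init:
# initial hard cluster memberships. Alternates M step / distance refresh /
# E step until max |delta z| < tol. Returns centres, weights,
# responsibilities, hard read mapping (argmax responsibility, first index on
# ties) and the observed-data log-likelihood trace.
run_em <- function(D_full, init, sigma, weights = NULL, max_iter = 1000,
                   tol = 1e-6) {
  N <- nrow(D_full)
  if (is.null(weights)) weights <- rep(1, N)
  L <- max(init)
  z <- matrix(0, N, L)
  z[cbind(seq_len(N), init)] <- 1
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m <- em_m_step(z, D_full, weights)
    Dc <- D_full[, m$centre, drop = FALSE]
    loglik <- c(loglik, em_loglik(Dc, m$tau, sigma, weights))
    tau_safe <- m$tau
    active <- tau_safe > 0
    z_new <- matrix(0, N, L)
    z_new[, active] <- em_e_step(Dc[, active, drop = FALSE],
                                 tau_safe[active], sigma)
    delta <- max(abs(z_new - z))
    z <- z_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("EM did not converge within ", max_iter, " iterations")
  }
  mapping <- apply(z, 1, which.max)
  list(centre = m$centre, tau = m$tau, z = z, mapping = as.integer(mapping),
       loglik = loglik, converged = converged, iterations = length(loglik))
}
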