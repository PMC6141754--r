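## Project each row of Q onto the probability simplex (Condat/Michelot).
project_simplex_rows <- function(Q) {
  t(apply(Q, 1, function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    theta <- (css[rho] - 1) / rho
    pmax(v - theta, 0)
  }))
}

## One alternating-least-squares pass of X ~ Q G with Q rows on the
## simplex and G entries in [0, 1]. X holds allele dosages on [0, 1].
als_fit <- function(X, K, max_iter = 60, tol = 1e-5, seed = 1L) {
  n <- nrow(X); p <- ncol(X)
  set.seed(seed)
  Q <- matrix(stats::rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  G <- matrix(stats::runif(K * p, 0.2, 0.8), K, p)
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    ## update Q given G: rows share the same normal equations matrix
    GtG <- tcrossprod(G) + diag(1e-8, K)
    Q <- X %*% t(G) %*% solve(GtG)
    Q <- project_simplex_rows(pmax(Q, 0))
    deg <- rowSums(Q) == 0
    if (any(deg)) Q[deg, ] <- 1 / K
    ## update G given Q
    QtQ <- crossprod(Q) + diag(1e-8, K)
    G <- solve(QtQ, crossprod(Q, X))
    G <- pmin(pmax(G, 1e-4), 1 - 1e-4)
    obj <- sum((X - Q %*% G)^2)
    if (abs(obj_old - obj) < tol * (1 + obj)) break
    obj_old <- obj
  }
  list(Q = Q, G = G, rss = obj)
}

## Binomial cross-entropy of observed dosage y (0/0.5/1 scale, counts of
## 2 trials) under predicted frequency p.
binom_cross_entropy <- function(y, p) {
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  k <- round(2 * y)  # allele count 0/1/2
  -mean(k * log(p) + (2 - k) * log(1 - p))
}

#' Admixture (ancestry) estimation with a cross-entropy criterion
#'
#' Factorizes the allele-dosage matrix (scores rescaled to [0, 1]) into
#' Q (genotypes x K admixture proportions, rows on the simplex) times G
#' (K x SNPs ancestral allele frequencies) by alternating least squares
#' with simplex and box constraints — the same model family as sparse
#' NMF ancestry estimation. Model choice uses a masked-entry
#' cross-entropy: a random fraction of entries is held out, the
#' factorization is fitted on the rest (held-out entries EM-refilled from
#' the current fit), and the held-out allele counts are scored under the
#' binomial likelihood of the fitted frequencies. The best of `n_runs`
#' restarts (by fit RSS) is kept. Missing calls are handled the same way
#' as masked entries.
#'
#' @param gm A [genotype_matrix()] (missing calls allowed) or score
#'   matrix.
#' @param K Number of ancestral clusters (>= 1).
#' @param n_runs Random restarts.
#' @param mask_fraction Fraction of entries masked for the
#'   cross-entropy score, in (0, 0.5).
#' @param seed Integer seed.
#' @param max_iter ALS iterations per run.
#' @return List of class `ancestry_result`: `K`, `Q`, `G`,
#'   `cross_entropy` (masked-entry score), `N_Q` (per-genotype effective
#'   cluster count, see [effective_clusters()]).
#' @export
estimate_ancestry <- function(gm, K, n_runs = 3, mask_fraction = 0.05,
                              seed = 1L, max_iter = 60) {
  sc <- if (inherits(gm, "genotype_matrix")) gm$scores else as.matrix(gm)
  if (K < 1) stop("K must be >= 1")
  if (K > nrow(sc)) stop("K exceeds the genotype count")
  if (mask_fraction <= 0 || mask_fraction >= 0.5)
    stop("mask_fraction must be in (0, 0.5)")
  X <- (sc + 1) / 2  # dosage on [0, 1]
  n <- nrow(X); p <- ncol(X)
  set.seed(sub_seed(seed, 21L))
  obs <- which(!is.na(X))
  mask <- sample(obs, ceiling(mask_fraction * length(obs)))
  Xfit <- X
  Xfit[mask] <- NA
  ## initialize unobserved entries at column means
  mu <- colMeans(Xfit, na.rm = TRUE)
  mu[is.na(mu)] <- 0.5
  na_idx <- which(is.na(Xfit))
  Xfit[na_idx] <- matrix(mu, n, p, byrow = TRUE)[na_idx]

  if (K == 1) {
    Q <- matrix(1, n, 1)
    G <- matrix(colMeans(Xfit), 1, p)
    ce <- binom_cross_entropy(X[mask], (Q %*% G)[mask])
    res <- list(K = 1L, Q = Q, G = pmin(pmax(G, 1e-4), 1 - 1e-4),
                cross_entropy = ce, N_Q = rep(1, n))
    class(res) <- "ancestry_result"
    return(res)
  }

  best <- NULL
  for (r in seq_len(n_runs)) {
    fit <- NULL
    Xr <- Xfit
    ## EM outer loop: refit after refilling the held-out entries
    for (outer in 1:3) {
      fit <- als_fit(Xr, K, max_iter = max_iter,
                     seed = sub_seed(seed, 100L + 7L * r + outer))
      pred <- fit$Q %*% fit$G
      Xr[na_idx] <- pred[na_idx]
    }
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  pred <- best$Q %*% best$G
  ce <- binom_cross_entropy(X[mask], pred[mask])
  nq <- apply(best$Q, 1, effective_clusters, K = K)
  res <- list(K = as.integer(K), Q = best$Q, G = best$G,
              cross_entropy = ce, N_Q = nq)
  class(res) <- "ancestry_result"
  res
}

#' Cross-entropy curve over candidate cluster numbers
#'
#' Runs [estimate_ancestry()] for each K and tabulates the masked-entry
#' cross-entropy, the standard model-choice curve: its minimum (or elbow)
#' indicates the supported number of ancestral clusters.
#'
#' @param gm Genotypes as in [estimate_ancestry()].
#' @param K_range Integer vector of K values (default 1:8).
#' @param ... Passed to [estimate_ancestry()].
#' @return data.frame `K`, `cross_entropy`.
#' @export
cross_entropy_curve <- function(gm, K_range = 1:8, ...) {
  ce <- vapply(K_range, function(k)
    estimate_ancestry(gm, K = k, ...)$cross_entropy, numeric(1))
  data.frame(K = K_range, cross_entropy = ce)
}

#' Effective number of ancestral clusters per genotype (N_Q)
#'
#' Inverse Simpson index of the admixture proportion vector:
#' `N_Q = 1 / sum(Q_i^2)`. Ranges from 1 (unadmixed, one-hot Q) to K
#' (uniform Q); larger values mean stronger admixture.
#'
#' @param Q_row Numeric vector of admixture proportions (must sum to 1).
#' @param K Cluster count (defaults to `length(Q_row)`).
#' @param tol Tolerance on the simplex constraint.
#' @return Scalar N_Q in [1, K].
#' @export
effective_clusters <- function(Q_row, K = length(Q_row), tol = 1e-6) {
  if (abs(sum(Q_row) - 1) > tol || any(Q_row < -tol))
    stop("Q_row must lie on the probability simplex")
  nq <- 1 / sum(Q_row^2)
  min(max(nq, 1), K)
}
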