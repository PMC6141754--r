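#' SNP quality control
#'
#' Applies the array-data filter cascade in a fixed order: (1) remove
#' monomorphic SNPs, (2) remove SNPs with missing-call rate above
#' `max_missing`, (3) remove SNPs with minor allele frequency below
#' `min_maf`. MAF is computed from non-missing calls pooled over all
#' genotypes (the cohort is filtered once, before any per-population
#' analysis). Stage counts are order-dependent, hence the fixed cascade.
#'
#' @param gm A [genotype_matrix()].
#' @param max_missing Maximum tolerated missing-call fraction (default
#'   0.5, i.e. SNPs with > 50\% missing are dropped).
#' @param min_maf Minimum minor allele frequency (default 0.05).
#' @return List with `gm` (filtered matrix) and `report`, a list holding
#'   `per_snp` (data.frame: `snp_id`, `maf`, `missing_rate`,
#'   `monomorphic`, `pass`) and `stage_counts` (named vector of SNPs
#'   surviving after each stage, starting from the input count).
#' @export
qc_filter <- function(gm, max_missing = 0.5, min_maf = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"),
            max_missing >= 0, max_missing <= 1,
            min_maf >= 0, min_maf <= 1)
  sc <- gm$scores
  n_obs <- colSums(!is.na(sc))
  miss <- 1 - n_obs / nrow(sc)
  ## allele frequency of the +1 allele from dosage (score + 1)/2
  p <- (colMeans(sc, na.rm = TRUE) + 1) / 2
  p[n_obs == 0] <- NA
  maf <- pmin(p, 1 - p)
  mono <- vapply(seq_len(ncol(sc)), function(j) {
    v <- sc[, j]; length(unique(v[!is.na(v)])) <= 1
  }, logical(1))

  keep1 <- !mono
  keep2 <- keep1 & miss <= max_missing
  keep3 <- keep2 & !is.na(maf) & maf >= min_maf
  stage_counts <- c(input = ncol(sc),
                    non_monomorphic = sum(keep1),
                    missingness = sum(keep2),
                    maf = sum(keep3))
  per_snp <- data.frame(snp_id = colnames(sc), maf = maf,
                        missing_rate = miss, monomorphic = mono,
                        pass = keep3, stringsAsFactors = FALSE)
  if (!any(keep3)) stop("no SNPs survive quality control")
  list(gm = gm[, keep3],
       report = list(per_snp = per_snp, stage_counts = stage_counts))
}

#' Impute missing genotype scores
#'
#' `method = "em"` iterates relationship-conditioned prediction to a
#' fixed point: missing entries are initialized at the per-SNP mean; each
#' iteration recomputes the realized relationship matrix A from the
#' current complete matrix and replaces every missing entry by its
#' conditional expectation given the observed calls in its column under a
#' Gaussian working model with covariance proportional to A. Observed
#' entries are never altered; imputed values are clipped to [-1, 1].
#' `method = "mean"` is the one-step per-SNP mean fallback.
#'
#' @param gm A [genotype_matrix()]; every SNP needs >= 1 observed call.
#' @param method `"em"` or `"mean"`.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the largest entry change.
#' @param eig_floor Eigenvalues of A below `eig_floor * mean(diag(A))`
#'   are raised to that floor before conditioning; the centering step of
#'   the realized relationship makes A singular along the all-ones
#'   direction, and the floor keeps that artifact from dominating the
#'   conditional prediction.
#' @return Numeric matrix (genotypes x SNPs) with no missing values, of
#'   the same dimnames as the input; attribute `"converged"` reports EM
#'   convergence (with a warning when `FALSE`).
#' @export
impute_em <- function(gm, method = c("em", "mean"), max_iter = 50,
                      tol = 1e-4, eig_floor = 0.05) {
  method <- match.arg(method)
  sc <- if (inherits(gm, "genotype_matrix")) gm$scores else as.matrix(gm)
  if (any(colSums(!is.na(sc)) == 0))
    stop("every SNP needs at least one observed call")
  miss <- is.na(sc)
  if (!any(miss)) {
    out <- sc; attr(out, "converged") <- TRUE
    return(out)
  }
  mu <- colMeans(sc, na.rm = TRUE)
  x <- sc
  x[miss] <- matrix(mu, nrow(sc), ncol(sc), byrow = TRUE)[miss]
  if (method == "mean") {
    attr(x, "converged") <- TRUE
    return(x)
  }
  miss_cols <- which(colSums(miss) > 0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    A <- realized_relationship(x)
    eg <- eigen(A, symmetric = TRUE)
    d <- pmax(eg$values, max(eig_floor * mean(diag(A)), 1e-12))
    P <- eg$vectors %*% (t(eg$vectors) / d)
    delta <- 0
    for (j in miss_cols) {
      m <- which(miss[, j])
      o <- which(!miss[, j])
      r_o <- sc[o, j] - mu[j]
      ## E[x_m | x_o] via the precision matrix of the working Gaussian
      rhs <- P[m, o, drop = FALSE] %*% r_o
      new <- tryCatch(mu[j] - drop(solve(P[m, m, drop = FALSE], rhs)),
                      error = function(e) x[m, j])
      new <- pmin(pmax(new, -1), 1)
      bad <- !is.finite(new)
      if (any(bad)) new[bad] <- x[m, j][bad]
      delta <- max(delta, max(abs(new - x[m, j])))
      x[m, j] <- new
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM imputation did not converge in ", max_iter, " iterations")
  attr(x, "converged") <- converged
  x
}
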