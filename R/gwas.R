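#' Kinship- and PC-adjusted single-marker mixed-model scan
#'
#' Per-SNP model: `trait = intercept + PC covariates + marker +
#' polygenic + residual`, with the polygenic effect covarying as
#' `sigma_g^2 * K`. Variance components are estimated once on the
#' marker-free null model (the P3D/EMMAX scheme) by REML on the spectral
#' decomposition of K, then every marker is tested on the rotated
#' (generalized least squares) scale with a two-sided t test. Markers
#' collinear with the covariates are flagged untestable (`NA` p) rather
#' than crashing the scan.
#'
#' @param x Complete (imputed) score matrix or [genotype_matrix()].
#' @param y Named numeric vector of clonal values (aligned to genotypes;
#'   names matched against rownames when present).
#' @param K Kinship matrix from [kinship()]; `NULL` for the identity
#'   (the scan then reduces exactly to single-marker OLS when
#'   `n_pc = 0`).
#' @param n_pc Number of genotype principal components included as fixed
#'   covariates (computed from the same matrix as the kinship).
#' @param min_p Floor applied to p-values before taking -log10.
#' @return data.frame of class `gwas_result`: `snp_id`, `effect`,
#'   `minus_log10_p`, `p_value`, `q_value`, `sig_fdr` (q < 0.1),
#'   `sig_logp` (-log10 p > 3).
#' @export
mixed_model_scan <- function(x, y, K = NULL, n_pc = 0, min_p = 1e-300) {
  if (inherits(x, "genotype_matrix")) x <- x$scores
  if (anyNA(x)) stop("scan needs a complete matrix; impute first")
  if (!is.null(names(y)) && !is.null(rownames(x))) {
    if (!all(rownames(x) %in% names(y)))
      stop("genotypes of x and y do not align")
    y <- y[rownames(x)]
  }
  n <- nrow(x)
  stopifnot(length(y) == n, n_pc >= 0)

  X0 <- matrix(1, n, 1)
  if (n_pc > 0) {
    pcs <- pca_genotypes(x, n_pc = n_pc)$scores
    X0 <- cbind(X0, pcs)
  }

  if (is.null(K)) {
    U <- diag(n); w <- rep(1, n)  # unit weights: plain OLS
  } else {
    eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
    d <- pmax(eg$values, 1e-9)
    ## REML profile over the variance ratio delta = sigma_e^2/sigma_g^2
    Uy <- crossprod(eg$vectors, y)
    UX <- crossprod(eg$vectors, X0)
    q <- ncol(X0)
    reml_nll <- function(log_delta) {
      delta <- exp(log_delta)
      v <- d + delta
      W <- UX / sqrt(v)
      z <- Uy / sqrt(v)
      XtX <- crossprod(W)
      beta <- solve(XtX, crossprod(W, z))
      r <- z - W %*% beta
      s2 <- sum(r^2) / (n - q)
      0.5 * ((n - q) * log(s2) + sum(log(v)) +
               determinant(XtX, logarithm = TRUE)$modulus + (n - q))
    }
    opt <- stats::optimize(reml_nll, c(-10, 10))
    delta <- exp(opt$minimum)
    U <- eg$vectors
    w <- 1 / sqrt(d + delta)
  }
  ## rotate and weight once; per-marker GLS is then ordinary LS
  yt <- w * crossprod(U, y)
  Xt <- w * crossprod(U, X0)
  St <- w * crossprod(U, x)
  ## residualize against covariates
  qrX <- qr(Xt)
  ry <- stats::resid(stats::lm.fit(Xt, yt))
  RS <- St - Xt %*% qr.coef(qrX, St)
  q <- ncol(Xt)
  ss <- colSums(RS^2)
  sy <- colSums(RS * drop(ry))
  yy <- sum(ry^2)
  testable <- ss > 1e-10 * n
  beta <- ifelse(testable, sy / ss, NA)
  df <- n - q - 1
  sigma2 <- (yy - ifelse(testable, beta^2 * ss, 0)) / df
  tstat <- beta / sqrt(sigma2 / ss)
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  p <- pmax(p, min_p)
  qv <- rep(NA_real_, length(p))
  qv[!is.na(p)] <- bh_qvalues(p[!is.na(p)])
  out <- data.frame(snp_id = colnames(x), effect = beta,
                    p_value = p, minus_log10_p = -log10(p),
                    q_value = qv,
                    sig_fdr = !is.na(qv) & qv < 0.1,
                    sig_logp = !is.na(p) & -log10(p) > 3,
                    stringsAsFactors = FALSE)
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Genomic inflation factor
#'
#' Median chi-square statistic of the scan divided by the null median,
#' a standard diagnostic of confounding control.
#'
#' @param p_values Vector of p-values.
#' @return Scalar lambda.
#' @export
genomic_inflation <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} p_(j) * m / j` over
#' the ascending order statistics, capped at 1 and mapped back to the
#' input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_qvalues <- function(p_values) {
  if (!length(p_values)) stop("empty p-value vector")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- rev(cummin(rev(p_values[o] * m / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

#' Place an unmapped SNP by LD with the mapped SNPs
#'
#' Computes r2 between the unmapped SNP and every mapped SNP; if the
#' highest r2 exceeds `r2_threshold`, the unmapped SNP is assigned the
#' paired SNP's map position. Ties on r2 break by smaller cM, then
#' lexicographic SNP id, for determinism.
#'
#' @param snp_id Id of the unmapped SNP (must be in `gm`).
#' @param gm A [genotype_matrix()].
#' @param map A [genetic_map()] with at least one mapped SNP.
#' @param r2_threshold Minimum r2 for placement (default 0.6).
#' @param estimator Passed to [ld_r2()].
#' @return List: `placed` (logical), and when placed `linkage_group`,
#'   `cM`, `paired_snp`, `r2`; otherwise `best_r2`.
#' @export
place_unmapped <- function(snp_id, gm, map, r2_threshold = 0.6,
                           estimator = "em") {
  map_row <- map[map$snp_id == snp_id, ]
  if (nrow(map_row) == 1 && map_row$mapped)
    stop(snp_id, " is already mapped")
  mapped <- map[map$mapped, ]
  if (!nrow(mapped)) stop("map contains no mapped SNPs")
  target <- gm$scores[, snp_id]
  r2 <- vapply(mapped$snp_id, function(s) {
    out <- tryCatch(ld_r2(target, gm$scores[, s], estimator = estimator),
                    error = function(e) list(r2 = NA_real_))
    if (is.na(out$r2)) -Inf else out$r2
  }, numeric(1))
  ord <- order(-r2, mapped$cM, mapped$snp_id)
  best <- ord[1]
  if (r2[best] > r2_threshold) {
    list(placed = TRUE, linkage_group = mapped$linkage_group[best],
         cM = mapped$cM[best], paired_snp = mapped$snp_id[best],
         r2 = unname(r2[best]))
  } else {
    list(placed = FALSE, best_r2 = unname(max(r2[is.finite(r2)], -Inf)))
  }
}

#' Detect cross-population common significant regions
#'
#' Among placed SNPs passing `-log10(p) > logp_threshold` in each
#' population's scan, finds maximal same-linkage-group groups whose cM
#' span is below `window_cM` and that contain at least one SNP from every
#' required population. Regions are reported sorted by linkage group and
#' position.
#'
#' @param results Named list of per-population `gwas_result` data.frames.
#' @param map A [genetic_map()] giving each SNP's placement (apply
#'   [place_unmapped()] beforehand and update the map if unmapped hits
#'   should count).
#' @param window_cM Maximum span of a region (default 10).
#' @param min_populations Minimum populations represented (default all).
#' @param logp_threshold Significance threshold on -log10(p).
#' @return data.frame: `linkage_group`, `cM_min`, `cM_max`, `span_cM`,
#'   `n_populations`, `snp_ids`, `populations` (semicolon-joined);
#'   zero rows when no region qualifies.
#' @export
find_common_regions <- function(results, map, window_cM = 10,
                                min_populations = length(results),
                                logp_threshold = 3) {
  if (length(results) < 2) stop("need scans from at least 2 populations")
  hits <- do.call(rbind, lapply(names(results), function(popn) {
    r <- results[[popn]]
    r <- r[r$minus_log10_p > logp_threshold, , drop = FALSE]
    if (!nrow(r)) return(NULL)
    m <- map[match(r$snp_id, map$snp_id), ]
    keep <- !is.na(m$mapped) & m$mapped
    if (!any(keep)) return(NULL)
    data.frame(population = popn, snp_id = r$snp_id[keep],
               linkage_group = m$linkage_group[keep], cM = m$cM[keep],
               minus_log10_p = r$minus_log10_p[keep],
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(linkage_group = integer(0), cM_min = numeric(0),
                      cM_max = numeric(0), span_cM = numeric(0),
                      n_populations = integer(0), snp_ids = character(0),
                      populations = character(0))
  if (is.null(hits) || !nrow(hits)) return(empty)
  regions <- list()
  for (lg in sort(unique(hits$linkage_group))) {
    h <- hits[hits$linkage_group == lg, ]
    h <- h[order(h$cM, h$snp_id), ]
    ## every maximal run of hits with span < window
    for (i in seq_len(nrow(h))) {
      j <- max(which(h$cM - h$cM[i] < window_cM))
      grp <- h[i:j, ]
      if (length(unique(grp$population)) < min_populations) next
      key <- paste(sort(unique(grp$snp_id)), collapse = ";")
      regions[[key]] <- data.frame(
        linkage_group = lg, cM_min = min(grp$cM), cM_max = max(grp$cM),
        span_cM = max(grp$cM) - min(grp$cM),
        n_populations = length(unique(grp$population)),
        snp_ids = paste(grp$snp_id, collapse = ";"),
        populations = paste(grp$population, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(regions)) return(empty)
  out <- do.call(rbind, regions)
  ## drop regions whose SNP set is a subset of another region's
  sets <- lapply(strsplit(out$snp_ids, ";"), unique)
  keep <- vapply(seq_along(sets), function(i)
    !any(vapply(seq_along(sets), function(j)
      i != j && all(sets[[i]] %in% sets[[j]]) &&
        length(sets[[j]]) > length(sets[[i]]), logical(1))),
    logical(1))
  out <- out[keep, , drop = FALSE]
  out <- unique(out)
  out <- out[order(out$linkage_group, out$cM_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}
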