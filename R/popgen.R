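#' Expected and observed heterozygosity
#'
#' Per SNP, the allele frequency p is estimated from non-missing calls;
#' expected heterozygosity is 2p(1-p), by default with the unbiased
#' small-sample correction n/(n-1); observed heterozygosity is the
#' fraction of heterozygous (score 0) calls.
#'
#' @param gm A [genotype_matrix()].
#' @param by_population If `TRUE` (and labels are present), compute per
#'   population; otherwise pooled.
#' @param correct Apply the n/(n-1) small-sample correction to H_E.
#' @return A list per group with `per_snp` (data.frame `snp_id`, `he`,
#'   `ho`, `n`) and `summary` (mean `he`, mean `ho`, `n` genotypes).
#'   When pooled, a single such list.
#' @export
heterozygosities <- function(gm, by_population = TRUE, correct = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  one <- function(sc, n_geno) {
    if (n_geno < 2) stop("need at least 2 genotypes per population")
    n <- colSums(!is.na(sc))
    p <- (colMeans(sc, na.rm = TRUE) + 1) / 2
    he <- 2 * p * (1 - p)
    if (correct) he <- ifelse(n > 1, he * n / (n - 1), NA)
    ho <- colMeans(sc == 0, na.rm = TRUE)
    per <- data.frame(snp_id = colnames(sc), he = he, ho = ho, n = n,
                      stringsAsFactors = FALSE)
    list(per_snp = per,
         summary = c(he = mean(he, na.rm = TRUE),
                     ho = mean(ho, na.rm = TRUE), n = n_geno))
  }
  if (by_population && !is.null(gm$population)) {
    lapply(split(seq_len(nrow(gm$scores)), gm$population), function(i)
      one(gm$scores[i, , drop = FALSE], length(i)))
  } else {
    one(gm$scores, nrow(gm$scores))
  }
}

## EM haplotype-frequency estimation for two unphased biallelic loci.
## Scores -1/0/1 are dosages of the "1" allele minus 1. Returns the four
## haplotype frequencies (AB, Ab, aB, ab) with A/B the +1 alleles.
em_haplotypes <- function(a, b, max_iter = 100, tol = 1e-8) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep] + 1; b <- b[keep] + 1  # dosages 0/1/2
  n <- length(a)
  tab <- matrix(0, 3, 3)
  for (i in seq_len(n)) tab[a[i] + 1, b[i] + 1] <- tab[a[i] + 1, b[i] + 1] + 1
  pA <- mean(a) / 2; pB <- mean(b) / 2
  ## haplotypes: h[1]=ab, h[2]=aB, h[3]=Ab, h[4]=AB
  h <- c((1 - pA) * (1 - pB), (1 - pA) * pB, pA * (1 - pB), pA * pB)
  h <- pmax(h, 1e-12); h <- h / sum(h)
  ndh <- tab[2, 2]  # double heterozygotes: phase-ambiguous
  for (it in seq_len(max_iter)) {
    ## expected count of AB/ab (cis) configuration among double hets
    cis <- h[4] * h[1]
    trans <- h[3] * h[2]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    cnt <- numeric(4)
    cnt[1] <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1] + w * ndh
    cnt[2] <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3] + (1 - w) * ndh
    cnt[3] <- 2 * tab[3, 1] + tab[2, 1] + tab[3, 2] + (1 - w) * ndh
    cnt[4] <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + w * ndh
    newh <- cnt / (2 * n)
    if (max(abs(newh - h)) < tol) { h <- newh; break }
    h <- newh
  }
  names(h) <- c("ab", "aB", "Ab", "AB")
  h
}

#' Linkage disequilibrium r2 between two SNPs
#'
#' Default estimator: maximum-likelihood haplotype frequencies for
#' unphased diploid data via EM (random mating assumed), with
#' r2 = D^2 / (pA pa pB pb) and significance from the asymptotic
#' chi-square statistic N_hap * r2 (1 df, N_hap = 2 x complete pairs).
#' Alternative `estimator = "composite"`: squared Pearson correlation of
#' the genotype scores, with the same chi-square form on 2n.
#'
#' @param snp_a,snp_b Numeric score vectors (-1/0/1, NA allowed).
#' @param estimator `"em"` or `"composite"`.
#' @param min_pairs Minimum complete pairs required.
#' @return List `r2`, `p_value`, `n_pairs`, `monomorphic` (flag; when
#'   `TRUE`, `r2` and `p_value` are `NA`).
#' @export
ld_r2 <- function(snp_a, snp_b, estimator = c("em", "composite"),
                  min_pairs = 10) {
  estimator <- match.arg(estimator)
  keep <- !is.na(snp_a) & !is.na(snp_b)
  if (sum(keep) < min_pairs)
    stop("need at least ", min_pairs, " complete pairs of calls")
  a <- snp_a[keep]; b <- snp_b[keep]
  if (length(unique(a)) <= 1 || length(unique(b)) <= 1)
    return(list(r2 = NA_real_, p_value = NA_real_, n_pairs = length(a),
                monomorphic = TRUE))
  if (abs(stats::cor(a, b)) == 1) {
    ## degenerate perfect LD: haplotypes fully determined
    return(list(r2 = 1, p_value = stats::pchisq(2 * length(a), 1,
                                                lower.tail = FALSE),
                n_pairs = length(a), monomorphic = FALSE))
  }
  if (estimator == "composite") {
    r2 <- stats::cor(a, b)^2
  } else {
    h <- em_haplotypes(a, b)
    pA <- h["AB"] + h["Ab"]; pB <- h["AB"] + h["aB"]
    D <- h["AB"] - pA * pB
    den <- pA * (1 - pA) * pB * (1 - pB)
    r2 <- if (den > 0) unname(D^2 / den) else NA_real_
  }
  n_hap <- 2 * length(a)
  p <- stats::pchisq(n_hap * r2, df = 1, lower.tail = FALSE)
  list(r2 = r2, p_value = p, n_pairs = length(a), monomorphic = FALSE)
}

#' LD profiles within linkage groups or isotigs
#'
#' Enumerates all SNP pairs sharing a linkage group (distance in cM) or
#' an isotig (distance in bp), computes r2 and its significance for each,
#' and summarizes per population: mean r2, percentage of significant
#' pairs (p < `sig_alpha`), and a binned decay curve.
#'
#' @param gm A [genotype_matrix()].
#' @param map A [genetic_map()].
#' @param mode `"within_LG"` or `"within_isotig"`.
#' @param by_population Compute per population when labels are present.
#' @param bin_width Decay-curve bin width (default 1 cM or 500 bp by mode).
#' @param sig_alpha Significance level for the "significant pairs" ratio.
#' @param max_pairs Optional cap: subsample pairs beyond this count
#'   (seeded) to bound runtime.
#' @param estimator Passed to [ld_r2()].
#' @param seed Seed for pair subsampling.
#' @return Per population (or pooled), a list with `pairs` (data.frame:
#'   ids, group, distance, r2, p_value), `summary` (mean_r2,
#'   pct_significant, n_pairs) and `decay` (binned mean r2). Populations
#'   with no eligible pairs yield `NULL` entries rather than an error;
#'   an error is raised only when no pairs exist at all.
#' @export
ld_profiles <- function(gm, map, mode = c("within_LG", "within_isotig"),
                        by_population = TRUE, bin_width = NULL,
                        sig_alpha = 0.01, max_pairs = 50000, seed = 1L,
                        estimator = "em") {
  mode <- match.arg(mode)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (mode == "within_isotig" && all(is.na(map$isotig)))
    stop("map carries no isotig placement")
  if (is.null(bin_width))
    bin_width <- if (mode == "within_LG") 1 else 500
  map <- map[match(snp_ids(gm), map$snp_id), ]
  if (mode == "within_LG") {
    grp <- ifelse(map$mapped, map$linkage_group, NA)
    pos <- map$cM
  } else {
    grp <- map$isotig
    pos <- map$bp
  }
  eligible <- which(!is.na(grp) & !is.na(pos))
  pair_idx <- do.call(rbind, lapply(split(eligible, grp[eligible]),
    function(ix) {
      if (length(ix) < 2) return(NULL)
      t(utils::combn(ix, 2))
    }))
  if (is.null(pair_idx) || nrow(pair_idx) == 0) {
    ## e.g. a single SNP per group: flagged-empty result, not a crash
    return(structure(list(pairs = NULL,
                          summary = c(mean_r2 = NA, pct_significant = NA,
                                      n_pairs = 0),
                          decay = NULL, empty = TRUE),
                     class = "ld_profile_empty"))
  }
  if (nrow(pair_idx) > max_pairs) {
    set.seed(sub_seed(seed, 11L))
    pair_idx <- pair_idx[sample.int(nrow(pair_idx), max_pairs), ]
  }

  one_pop <- function(sc) {
    res <- vapply(seq_len(nrow(pair_idx)), function(k) {
      i <- pair_idx[k, 1]; j <- pair_idx[k, 2]
      out <- tryCatch(ld_r2(sc[, i], sc[, j], estimator = estimator),
                      error = function(e) list(r2 = NA, p_value = NA))
      c(out$r2, out$p_value)
    }, numeric(2))
    pairs <- data.frame(snp_a = snp_ids(gm)[pair_idx[, 1]],
                        snp_b = snp_ids(gm)[pair_idx[, 2]],
                        group = grp[pair_idx[, 1]],
                        distance = abs(pos[pair_idx[, 1]] -
                                       pos[pair_idx[, 2]]),
                        r2 = res[1, ], p_value = res[2, ],
                        stringsAsFactors = FALSE)
    ok <- !is.na(pairs$r2)
    if (!any(ok)) return(NULL)
    bins <- floor(pairs$distance[ok] / bin_width) * bin_width
    decay <- stats::aggregate(pairs$r2[ok], list(bin = bins), mean)
    names(decay)[2] <- "mean_r2"
    list(pairs = pairs,
         summary = c(mean_r2 = mean(pairs$r2[ok]),
                     pct_significant =
                       100 * mean(pairs$p_value[ok] < sig_alpha),
                     n_pairs = sum(ok)),
         decay = decay)
  }
  if (by_population && !is.null(gm$population)) {
    lapply(split(seq_len(nrow(gm$scores)), gm$population), function(i)
      one_pop(gm$scores[i, , drop = FALSE]))
  } else {
    one_pop(gm$scores)
  }
}

## VanRaden realized relationship from a complete -1/0/1 (or imputed
## real-valued) score matrix: center columns by 2(p-0.5), scale the
## cross-product by 2 sum p(1-p).
realized_relationship <- function(x) {
  p <- (colMeans(x) + 1) / 2
  W <- sweep(x, 2, 2 * (p - 0.5))
  den <- 2 * sum(p * (1 - p))
  if (den <= 0) stop("all SNPs monomorphic: kinship undefined")
  tcrossprod(W) / den
}

#' Realized additive-relationship (kinship) matrix
#'
#' VanRaden-type genomic relationship on the -1/0/1 score scale: columns
#' centered by twice the allele-frequency deviation from 0.5, and the
#' genotype cross-product scaled by 2 sum p(1-p). Diagonal entries are
#' about 1 + f for inbreeding f.
#'
#' @param x Complete numeric score matrix (genotypes x SNPs) or a
#'   [genotype_matrix()] without missing values (impute first).
#' @return Symmetric genotypes x genotypes matrix.
#' @export
kinship <- function(x) {
  if (inherits(x, "genotype_matrix")) x <- x$scores
  if (anyNA(x)) stop("kinship needs a complete matrix; impute first")
  realized_relationship(x)
}

#' Principal component analysis of genotypes
#'
#' PCA of the column-centered (optionally scaled) score matrix. The sign
#' of each component is fixed so its largest-magnitude loading is
#' positive, making scores reproducible across platforms.
#'
#' @param x Complete score matrix or imputed [genotype_matrix()].
#' @param scale. Scale columns to unit variance (default `FALSE`).
#' @param n_pc Number of components to return (default all).
#' @return List `scores` (genotypes x PCs), `variance_share` (per-PC
#'   fraction of total variance), `loadings`.
#' @export
pca_genotypes <- function(x, scale. = FALSE, n_pc = NULL) {
  if (inherits(x, "genotype_matrix")) x <- x$scores
  if (anyNA(x)) stop("PCA needs a complete matrix; impute first")
  if (nrow(x) < 2) stop("need at least 2 genotypes")
  keep <- apply(x, 2, stats::sd) > 0
  if (scale.) x <- x[, keep, drop = FALSE]
  pr <- stats::prcomp(x, center = TRUE, scale. = scale.)
  flip <- apply(pr$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pr$x, 2, flip, `*`)
  loadings <- sweep(pr$rotation, 2, flip, `*`)
  vs <- pr$sdev^2 / sum(pr$sdev^2)
  if (!is.null(n_pc)) {
    n_pc <- min(n_pc, ncol(scores))
    scores <- scores[, seq_len(n_pc), drop = FALSE]
    loadings <- loadings[, seq_len(n_pc), drop = FALSE]
  }
  list(scores = scores, variance_share = vs, loadings = loadings)
}
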