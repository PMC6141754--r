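#' Specification for a synthetic multi-population cohort
#'
#' Describes an admixed plus-tree style cohort: several breeding
#' populations of unrelated genotypes, each genotype an admixture of K
#' ancestral clusters, with array SNPs placed on a genetic map. Linkage
#' disequilibrium arises from ancestry mosaics: each haplotype is a chain
#' of ancestral segments with exponentially distributed lengths, so
#' shorter `recombination_block_cM` means faster LD decay.
#'
#' @param n_populations Number of breeding populations.
#' @param n_genotypes_per_pop Integer vector (recycled) of genotypes per
#'   population. Defaults mirror a three-population cohort of unrelated
#'   selections (181, 159, 136).
#' @param n_ancestral_clusters Number K of ancestral clusters.
#' @param n_snps_mapped Mapped SNP count (placed on the genetic map).
#' @param n_snps_unmapped Unmapped SNP count; each is a noisy copy of a
#'   random mapped SNP so its true source is known.
#' @param n_linkage_groups Number of linkage groups.
#' @param map_length_cM Length of each linkage group in cM (recycled).
#' @param divergence Ancestral-frequency divergence (Balding-Nichols F),
#'   in (0, 1).
#' @param admixture_concentration Either a single Dirichlet concentration
#'   used for every population, or a matrix (populations x K) of
#'   per-population Dirichlet parameters over the clusters. Smaller values
#'   give more one-hot (less admixed) genotypes.
#' @param recombination_block_cM Mean ancestral-segment length in cM.
#' @param missing_rate Fraction of calls set missing completely at random.
#' @param unmapped_flip_prob Per-genotype probability that an unmapped
#'   SNP's copied score is resampled, controlling its r2 to the source.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_populations = 3,
                        n_genotypes_per_pop = c(181, 159, 136),
                        n_ancestral_clusters = 4,
                        n_snps_mapped = 1000,
                        n_snps_unmapped = 0,
                        n_linkage_groups = 11,
                        map_length_cM = 120,
                        divergence = 0.2,
                        admixture_concentration = 0.5,
                        recombination_block_cM = 3,
                        missing_rate = 0.02,
                        unmapped_flip_prob = 0.02,
                        seed = 1L) {
  n_genotypes_per_pop <- rep_len(n_genotypes_per_pop, n_populations)
  map_length_cM <- rep_len(map_length_cM, n_linkage_groups)
  stopifnot(n_populations >= 1, all(n_genotypes_per_pop >= 1),
            n_ancestral_clusters >= 1, n_snps_mapped >= 1,
            n_snps_unmapped >= 0, n_linkage_groups >= 1,
            all(map_length_cM > 0),
            divergence > 0, divergence < 1,
            recombination_block_cM > 0,
            missing_rate >= 0, missing_rate < 1)
  ac <- admixture_concentration
  if (is.matrix(ac)) {
    stopifnot(nrow(ac) == n_populations,
              ncol(ac) == n_ancestral_clusters)
  } else {
    stopifnot(length(ac) %in% c(1L, n_ancestral_clusters))
    ac <- matrix(rep_len(ac, n_ancestral_clusters),
                 nrow = n_populations, ncol = n_ancestral_clusters,
                 byrow = TRUE)
  }
  if (any(ac <= 0)) stop("Dirichlet concentrations must be positive")
  structure(list(n_populations = n_populations,
                 n_genotypes_per_pop = n_genotypes_per_pop,
                 n_ancestral_clusters = n_ancestral_clusters,
                 n_snps_mapped = n_snps_mapped,
                 n_snps_unmapped = n_snps_unmapped,
                 n_linkage_groups = n_linkage_groups,
                 map_length_cM = map_length_cM,
                 divergence = divergence,
                 admixture_concentration = ac,
                 recombination_block_cM = recombination_block_cM,
                 missing_rate = missing_rate,
                 unmapped_flip_prob = unmapped_flip_prob,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Specification for a simulated quantitative trait
#'
#' @param architecture `"polygenic"` or `"oligogenic"`; a label recorded
#'   in the truth table (the generative model is governed by `n_qtl` and
#'   the effect distribution).
#' @param n_qtl Number of QTL SNPs sampled from the genotyped markers.
#' @param heritability_broad Broad-sense H2 in [0, 1]: share of phenotypic
#'   variance that is genetic when noise is added downstream.
#' @param dominance_fraction Share of the genetic variance contributed by
#'   per-QTL dominance deviations, in [0, 1).
#' @param qtl_effect_distribution `"gaussian"` (iid N(0,1) effects) or
#'   `"geometric"` (effect of the i-th QTL proportional to 0.9^i, giving a
#'   few large and many small effects).
#' @param seed Integer seed.
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(architecture = c("polygenic", "oligogenic"),
                       n_qtl = 200,
                       heritability_broad = 0.5,
                       dominance_fraction = 0,
                       qtl_effect_distribution = c("gaussian", "geometric"),
                       seed = 1L) {
  architecture <- match.arg(architecture)
  qtl_effect_distribution <- match.arg(qtl_effect_distribution)
  if (n_qtl < 1) stop("n_qtl must be at least 1")
  stopifnot(heritability_broad >= 0, heritability_broad <= 1,
            dominance_fraction >= 0, dominance_fraction < 1)
  structure(list(architecture = architecture, n_qtl = n_qtl,
                 heritability_broad = heritability_broad,
                 dominance_fraction = dominance_fraction,
                 qtl_effect_distribution = qtl_effect_distribution,
                 seed = as.integer(seed)),
            class = "trait_spec")
}

#' Specification for a clonal field-trial design
#'
#' Plot-mean records follow
#' `y = mu + site + block-in-site + genotype + genotype-x-site + error`,
#' with sites and blocks-in-sites treated as design effects and genotype,
#' genotype-by-site and residual as random components.
#'
#' @param n_sites Number of test sites.
#' @param n_blocks_per_site Blocks per site.
#' @param site_variance,site_block_variance,gxe_variance,residual_variance
#'   Non-negative variance components for site, block-in-site,
#'   genotype-by-site interaction, and plot residual.
#' @param sites_per_genotype Number of sites each genotype is planted at
#'   (sampled without replacement), emulating partially overlapping site
#'   series; every genotype appears at >= 1 site.
#' @param mu Overall mean.
#' @return A list of class `trial_design_spec`.
#' @export
trial_design_spec <- function(n_sites = 5, n_blocks_per_site = 3,
                              site_variance = 1,
                              site_block_variance = 0.25,
                              gxe_variance = 0.5,
                              residual_variance = 1,
                              sites_per_genotype = NULL,
                              mu = 10) {
  stopifnot(n_sites >= 1, n_blocks_per_site >= 1,
            site_variance >= 0, site_block_variance >= 0,
            gxe_variance >= 0, residual_variance >= 0)
  if (is.null(sites_per_genotype)) sites_per_genotype <- n_sites
  if (sites_per_genotype < 1 || sites_per_genotype > n_sites)
    stop("sites_per_genotype must be in 1..n_sites")
  structure(list(n_sites = n_sites,
                 n_blocks_per_site = n_blocks_per_site,
                 site_variance = site_variance,
                 site_block_variance = site_block_variance,
                 gxe_variance = gxe_variance,
                 residual_variance = residual_variance,
                 sites_per_genotype = sites_per_genotype,
                 mu = mu),
            class = "trial_design_spec")
}

## Derive a sub-seed from the master seed; keeps every stream below 2^31.
sub_seed <- function(seed, k) (as.integer(seed) * 97L + k * 1009L) %% 2147483629L

#' Simulate ancestral allele-frequency matrix
#'
#' Balding-Nichols construction: a base frequency per SNP is drawn from
#' Uniform(0.1, 0.9), and each ancestral cluster's frequency from a Beta
#' distribution around it with divergence parameter F (the between-cluster
#' FST). Frequencies are clipped to (0.02, 0.98) so no cluster is fixed.
#'
#' @param spec A [cohort_spec()].
#' @param require_structure If `TRUE`, reject K < 2 (ancestry-dependent
#'   downstream analyses need at least two clusters).
#' @return Matrix of allele frequencies, K clusters x SNPs.
#' @export
simulate_ancestral_frequencies <- function(spec, require_structure = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  K <- spec$n_ancestral_clusters
  if (require_structure && K < 2)
    stop("at least 2 ancestral clusters required for structure analyses")
  p <- spec$n_snps_mapped + spec$n_snps_unmapped
  FST <- spec$divergence
  set.seed(sub_seed(spec$seed, 1L))
  base <- stats::runif(p, 0.1, 0.9)
  a <- base * (1 - FST) / FST
  b <- (1 - base) * (1 - FST) / FST
  freqs <- matrix(stats::rbeta(K * p, rep(a, each = K), rep(b, each = K)),
                  nrow = K, ncol = p)
  pmin(pmax(freqs, 0.02), 0.98)
}

## Sample one haplotype's per-SNP cluster assignment along the map:
## segment lengths ~ Exp(mean = block_cM), each segment's cluster ~ Q row.
mosaic_clusters <- function(pos_by_lg, q_row, block_cM) {
  K <- length(q_row)
  unlist(lapply(pos_by_lg, function(pos) {
    if (!length(pos)) return(integer(0))
    L <- max(pos)
    ## enough breakpoints to cover the LG
    n_seg <- max(2L, ceiling(L / block_cM * 3) + 5L)
    lens <- stats::rexp(n_seg, rate = 1 / block_cM)
    while (sum(lens) < L)
      lens <- c(lens, stats::rexp(n_seg, rate = 1 / block_cM))
    ends <- cumsum(lens)
    seg <- findInterval(pos, ends) + 1L
    cl <- sample.int(K, max(seg), replace = TRUE, prob = q_row)
    cl[seg]
  }), use.names = FALSE)
}

#' Simulate admixed genotypes on a genetic map
#'
#' Each genotype draws an admixture vector Q from its population's
#' Dirichlet; its two haplotypes are ancestry mosaics with exponential
#' segment lengths (mean `recombination_block_cM`), and alleles within a
#' segment are Bernoulli draws from that cluster's frequency. Scores are
#' the allele-dosage sum recoded to -1/0/1. Unmapped SNPs are copies of
#' random mapped SNPs with per-genotype score resampling at rate
#' `unmapped_flip_prob`; their source SNP is recorded. Missing calls are
#' introduced completely at random.
#'
#' @param freqs Ancestral frequency matrix from
#'   [simulate_ancestral_frequencies()].
#' @param spec A [cohort_spec()].
#' @return A list with `gm` ([genotype_matrix()]), `map`
#'   ([genetic_map()]), `Q` (true admixture matrix, genotypes x K),
#'   `realized_ancestry` (fraction of haplotype-SNP draws from each
#'   cluster), `unmapped_source` (named vector: source mapped SNP of each
#'   unmapped SNP), and `scores_complete` (scores before masking).
#' @export
simulate_admixed_genotypes <- function(freqs, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_snps_mapped < 1) stop("map must contain at least one mapped SNP")
  K <- spec$n_ancestral_clusters
  stopifnot(nrow(freqs) == K)
  set.seed(sub_seed(spec$seed, 2L))
  n <- sum(spec$n_genotypes_per_pop)
  pop <- rep(paste0("pop", seq_len(spec$n_populations)),
             spec$n_genotypes_per_pop)

  ## map: mapped SNPs spread over LGs at uniform positions
  lg_sizes <- tabulate(rep_len(seq_len(spec$n_linkage_groups),
                               spec$n_snps_mapped),
                       spec$n_linkage_groups)
  lg <- rep(seq_len(spec$n_linkage_groups), lg_sizes)
  pos <- unlist(lapply(seq_len(spec$n_linkage_groups), function(g)
    sort(stats::runif(lg_sizes[g], 0, spec$map_length_cM[g]))))
  snp_m <- sprintf("SNP%05d", seq_len(spec$n_snps_mapped))
  pos_by_lg <- split(pos, lg)

  ## per-genotype Q rows
  Q <- t(vapply(seq_len(n), function(i) {
    a <- spec$admixture_concentration[match(pop[i], unique(pop)), ]
    g <- stats::rgamma(K, shape = a)
    g / sum(g)
  }, numeric(K)))
  rownames(Q) <- sprintf("G%03d", seq_len(n))

  scores <- matrix(0L, n, spec$n_snps_mapped)
  realized <- matrix(0, n, K)
  for (i in seq_len(n)) {
    dose <- integer(spec$n_snps_mapped)
    for (h in 1:2) {
      cl <- mosaic_clusters(pos_by_lg, Q[i, ], spec$recombination_block_cM)
      ## pos_by_lg preserves map order within LG; lg blocks are contiguous
      f <- freqs[cbind(cl, seq_len(spec$n_snps_mapped))]
      dose <- dose + (stats::runif(spec$n_snps_mapped) < f)
      realized[i, ] <- realized[i, ] + tabulate(cl, K)
    }
    scores[i, ] <- dose - 1L
  }
  realized <- realized / (2 * spec$n_snps_mapped)

  ## unmapped SNPs: noisy copies of random mapped SNPs
  unmapped_source <- character(0)
  if (spec$n_snps_unmapped > 0) {
    src <- sample.int(spec$n_snps_mapped, spec$n_snps_unmapped,
                      replace = TRUE)
    um <- matrix(0L, n, spec$n_snps_unmapped)
    for (j in seq_len(spec$n_snps_unmapped)) {
      col <- scores[, src[j]]
      flip <- stats::runif(n) < spec$unmapped_flip_prob
      col[flip] <- sample(c(-1L, 0L, 1L), sum(flip), replace = TRUE)
      um[, j] <- col
    }
    snp_u <- sprintf("USNP%04d", seq_len(spec$n_snps_unmapped))
    unmapped_source <- stats::setNames(snp_m[src], snp_u)
    scores <- cbind(scores, um)
    snp_all <- c(snp_m, snp_u)
  } else snp_all <- snp_m

  dimnames(scores) <- list(rownames(Q), snp_all)
  scores_complete <- scores
  sc <- scores
  if (spec$missing_rate > 0) {
    mask <- stats::runif(length(sc)) < spec$missing_rate
    sc[mask] <- NA
  }
  map <- genetic_map(snp_all,
                     linkage_group = c(lg, rep(NA, spec$n_snps_unmapped)),
                     cM = c(pos, rep(NA, spec$n_snps_unmapped)))
  list(gm = genotype_matrix(sc, population = pop),
       map = map, Q = Q, realized_ancestry = realized,
       unmapped_source = unmapped_source,
       scores_complete = scores_complete)
}

#' Simulate a quantitative trait over a genotype matrix
#'
#' QTL SNPs are sampled from the markers; additive values are the
#' score-weighted sum of effects, with an optional per-QTL dominance
#' deviation (an extra effect for heterozygotes) mixed in at
#' `dominance_fraction` of the genetic variance. The total genetic value
#' is standardized to zero mean and unit variance.
#'
#' @param scores Complete numeric score matrix (genotypes x SNPs), or a
#'   [genotype_matrix()] without missing calls.
#' @param trait A [trait_spec()].
#' @return List with `genetic_values` (named, standardized), `qtl` truth
#'   table (`snp_id`, `index`, `additive_effect`, `dominance_effect`), and
#'   the `trait_spec`.
#' @export
simulate_trait <- function(scores, trait) {
  stopifnot(inherits(trait, "trait_spec"))
  if (inherits(scores, "genotype_matrix")) scores <- scores$scores
  if (anyNA(scores)) stop("trait simulation needs a complete score matrix")
  if (trait$n_qtl > ncol(scores))
    stop("n_qtl exceeds available SNPs")
  set.seed(sub_seed(trait$seed, 3L))
  idx <- sample.int(ncol(scores), trait$n_qtl)
  eff <- switch(trait$qtl_effect_distribution,
                gaussian = stats::rnorm(trait$n_qtl),
                geometric = stats::rnorm(trait$n_qtl) *
                  0.9^(seq_len(trait$n_qtl) - 1))
  add <- drop(scores[, idx, drop = FALSE] %*% eff)
  g <- add
  dom_eff <- rep(0, trait$n_qtl)
  if (trait$dominance_fraction > 0) {
    dom_eff <- stats::rnorm(trait$n_qtl) * abs(eff)
    het <- (scores[, idx, drop = FALSE] == 0) * 1
    dom <- drop(het %*% dom_eff)
    wa <- sqrt(1 - trait$dominance_fraction)
    wd <- sqrt(trait$dominance_fraction)
    sa <- stats::sd(add); sdom <- stats::sd(dom)
    if (sdom > 0) g <- wa * add / sa + wd * dom / sdom
  }
  if (stats::sd(g) > 0) g <- (g - mean(g)) / stats::sd(g)
  names(g) <- rownames(scores)
  list(genetic_values = g,
       qtl = data.frame(snp_id = colnames(scores)[idx], index = idx,
                        additive_effect = eff, dominance_effect = dom_eff,
                        stringsAsFactors = FALSE),
       trait_spec = trait)
}

#' Simulate plot-mean clonal trial records
#'
#' Generates records under
#' `y = mu + site + block-in-site + genotype + genotype-x-site + error`,
#' honoring a partially overlapping genotype-by-site incidence.
#'
#' @param genetic_values Named numeric vector of true clonal genetic
#'   values (one per genotype).
#' @param design A [trial_design_spec()].
#' @param seed Integer seed.
#' @return A `data.frame` with columns `site`, `block`, `genotype`,
#'   `value`; attribute `"effects"` carries the sampled site/block/gxe
#'   effects for oracle checks.
#' @export
simulate_trial_records <- function(genetic_values, design, seed = 1L) {
  stopifnot(inherits(design, "trial_design_spec"))
  n <- length(genetic_values)
  ids <- names(genetic_values)
  if (is.null(ids)) ids <- sprintf("G%03d", seq_len(n))
  set.seed(sub_seed(seed, 4L))
  s_eff <- stats::rnorm(design$n_sites, 0, sqrt(design$site_variance))
  b_eff <- matrix(stats::rnorm(design$n_sites * design$n_blocks_per_site,
                               0, sqrt(design$site_block_variance)),
                  design$n_sites, design$n_blocks_per_site)
  gxe <- matrix(stats::rnorm(design$n_sites * n, 0,
                             sqrt(design$gxe_variance)),
                design$n_sites, n)
  site_of <- lapply(seq_len(n), function(i)
    sort(sample.int(design$n_sites, design$sites_per_genotype)))
  rec <- do.call(rbind, lapply(seq_len(n), function(i) {
    expand.grid(site = site_of[[i]],
                block = seq_len(design$n_blocks_per_site),
                genotype = i)
  }))
  e <- stats::rnorm(nrow(rec), 0, sqrt(design$residual_variance))
  val <- design$mu + s_eff[rec$site] + b_eff[cbind(rec$site, rec$block)] +
    genetic_values[rec$genotype] + gxe[cbind(rec$site, rec$genotype)] + e
  out <- data.frame(site = paste0("site", rec$site),
                    block = paste0("block", rec$block),
                    genotype = ids[rec$genotype],
                    value = as.numeric(val),
                    stringsAsFactors = FALSE)
  attr(out, "effects") <- list(site = s_eff, block = b_eff, gxe = gxe)
  out
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper chaining ancestral frequencies, admixed genotypes
#' and (optionally) one or more traits.
#'
#' @param spec A [cohort_spec()].
#' @param traits Optional named list of [trait_spec()]s.
#' @return The [simulate_admixed_genotypes()] result plus `freqs` and a
#'   `traits` list of [simulate_trait()] results.
#' @export
simulate_cohort <- function(spec, traits = NULL) {
  freqs <- simulate_ancestral_frequencies(spec)
  cohort <- simulate_admixed_genotypes(freqs, spec)
  cohort$freqs <- freqs
  if (!is.null(traits)) {
    cohort$traits <- lapply(traits, function(tr)
      simulate_trait(cohort$scores_complete, tr))
  }
  cohort
}
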