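test_that("ancestral frequency draws respect the divergence model", {
  # near-zero divergence: clusters collapse onto the shared base frequency
  spec0 <- cohort_spec(n_ancestral_clusters = 4, n_snps_mapped = 500,
                       divergence = 1e-3, seed = 3)
  f0 <- simulate_ancestral_frequencies(spec0)
  expect_lt(max(apply(f0, 2, function(v) diff(range(v)))), 0.15)

  # divergence 0.2, K = 4: Hudson pairwise FST near the target
  spec <- cohort_spec(n_ancestral_clusters = 4, n_snps_mapped = 2000,
                      divergence = 0.2, seed = 4)
  f <- simulate_ancestral_frequencies(spec)
  hudson <- function(p1, p2)
    mean((p1 - p2)^2) / mean(p1 * (1 - p2) + p2 * (1 - p1))
  pairs <- utils::combn(4, 2)
  fst <- mean(apply(pairs, 2, function(ij) hudson(f[ij[1], ], f[ij[2], ])))
  expect_gt(fst, 0.2 * 0.7)
  expect_lt(fst, 0.2 * 1.3)

  # clipping contract: frequencies never leave (0, 1)
  specb <- cohort_spec(n_ancestral_clusters = 5, n_snps_mapped = 20000,
                       divergence = 0.6, seed = 5)
  fb <- simulate_ancestral_frequencies(specb)
  expect_true(all(fb > 0 & fb < 1))

  expect_error(simulate_ancestral_frequencies(
    cohort_spec(n_ancestral_clusters = 1, seed = 1),
    require_structure = TRUE), "clusters")
})

test_that("admixed genotype simulation is seeded, structured and mosaic", {
  co1 <- small_cohort(seed = 11)
  co2 <- small_cohort(seed = 11)
  expect_identical(co1$gm$scores, co2$gm$scores)
  expect_identical(co1$Q, co2$Q)

  # one-hot admixture + strong divergence: populations separate in PCA
  spec <- cohort_spec(n_populations = 2, n_genotypes_per_pop = 40,
                      n_ancestral_clusters = 2, n_snps_mapped = 400,
                      n_linkage_groups = 4, divergence = 0.35,
                      admixture_concentration = rbind(c(20, .05), c(.05, 20)),
                      missing_rate = 0, seed = 12)
  co <- simulate_cohort(spec)
  pc <- pca_genotypes(co$scores_complete, n_pc = 2)
  lab <- as.integer(co$gm$population)
  # silhouette on PC1-2 against own vs other population centroid
  cent <- rbind(colMeans(pc$scores[lab == 1, ]),
                colMeans(pc$scores[lab == 2, ]))
  d_own <- sqrt(rowSums((pc$scores - cent[lab, ])^2))
  d_oth <- sqrt(rowSums((pc$scores - cent[3 - lab, ])^2))
  sil <- mean((d_oth - d_own) / pmax(d_oth, d_own))
  expect_gt(sil, 0)
  expect_gt(mean(d_oth > d_own), 0.95)

  # free-recombination limit: adjacent r2 matches unlinked pairs
  spec_free <- cohort_spec(n_populations = 1, n_genotypes_per_pop = 150,
                           n_ancestral_clusters = 2, n_snps_mapped = 200,
                           n_linkage_groups = 2, divergence = 0.2,
                           recombination_block_cM = 0.01,
                           missing_rate = 0, seed = 13)
  cof <- simulate_cohort(spec_free)
  x <- cof$scores_complete
  m <- cof$map
  adj <- vapply(seq_len(ncol(x) - 1), function(j) {
    if (m$linkage_group[j] != m$linkage_group[j + 1]) return(NA_real_)
    suppressWarnings(stats::cor(x[, j], x[, j + 1])^2)
  }, numeric(1))
  set.seed(1)
  rnd <- replicate(150, {
    ij <- sample(ncol(x), 2)
    suppressWarnings(stats::cor(x[, ij[1]], x[, ij[2]])^2)
  })
  expect_lt(abs(mean(adj, na.rm = TRUE) - mean(rnd, na.rm = TRUE)), 0.02)
})

test_that("realized ancestry fractions converge to the sampled Q rows", {
  spec <- cohort_spec(n_populations = 1, n_genotypes_per_pop = 30,
                      n_ancestral_clusters = 3, n_snps_mapped = 20000,
                      n_linkage_groups = 10, divergence = 0.2,
                      admixture_concentration = 0.8, missing_rate = 0,
                      seed = 14)
  co <- simulate_cohort(spec)
  l1 <- rowSums(abs(co$realized_ancestry - co$Q))
  expect_lt(mean(l1), 0.05)
})

test_that("mean r2 decays with map distance, averaged over replicates", {
  curves <- sapply(1:8, function(r) {
    co <- simulate_cohort(cohort_spec(
      n_populations = 1, n_genotypes_per_pop = 80,
      n_ancestral_clusters = 3, n_snps_mapped = 120,
      n_linkage_groups = 2, map_length_cM = 60, divergence = 0.25,
      recombination_block_cM = 5, missing_rate = 0, seed = 400 + r))
    prof <- ld_profiles(co$gm, co$map, by_population = FALSE,
                        bin_width = 10, estimator = "composite")
    full <- merge(data.frame(bin = seq(0, 50, 10)), prof$decay,
                  all.x = TRUE)
    full$mean_r2
  })
  avg <- rowMeans(curves, na.rm = TRUE)
  expect_true(all(diff(avg) <= 0.01))  # monotone non-increasing (tol)
  expect_gt(avg[1], avg[length(avg)])
})

test_that("trait simulation honors the spec and recovers QTLs", {
  x <- random_scores(200, 100, seed = 21)
  tr <- simulate_trait(x, trait_spec("polygenic", n_qtl = 50,
                                     dominance_fraction = 0, seed = 22))
  add <- drop(x[, tr$qtl$index] %*% tr$qtl$additive_effect)
  expect_gt(stats::cor(tr$genetic_values, add), 0.999999)
  expect_equal(mean(tr$genetic_values), 0, tolerance = 1e-12)
  expect_equal(stats::sd(tr$genetic_values), 1, tolerance = 1e-12)

  # oligogenic: top-5 marginal slopes recover >= 4/5 QTLs (or r2>0.8 proxies)
  hits <- sapply(1:5, function(r) {
    x <- random_scores(400, 150, seed = 30 + r)
    tr <- simulate_trait(x, trait_spec("oligogenic", n_qtl = 5,
                                       seed = 40 + r))
    slopes <- abs(vapply(seq_len(ncol(x)), function(j)
      stats::coef(stats::lm(tr$genetic_values ~ x[, j]))[2], numeric(1)))
    top5 <- order(slopes, decreasing = TRUE)[1:5]
    sum(vapply(top5, function(j) {
      j %in% tr$qtl$index ||
        any(vapply(tr$qtl$index, function(q)
          stats::cor(x[, j], x[, q])^2 > 0.8, logical(1)))
    }, logical(1)))
  })
  expect_gte(sum(hits >= 4), 4)  # a near-zero sampled effect may hide a QTL

  expect_error(trait_spec(n_qtl = 0), "n_qtl")
  expect_error(simulate_trait(x, trait_spec(n_qtl = 1e5)), "exceeds")
})

test_that("trial records follow the variance-component model", {
  gv <- stats::setNames(rnorm(30), sprintf("G%03d", 1:30))
  # all non-genetic variances zero, one site: records = mu + genetic value
  des0 <- trial_design_spec(n_sites = 1, n_blocks_per_site = 2,
                            site_variance = 0, site_block_variance = 0,
                            gxe_variance = 0, residual_variance = 0,
                            mu = 5)
  rec0 <- simulate_trial_records(gv, des0, seed = 51)
  expect_equal(rec0$value, 5 + unname(gv[rec0$genotype]), tolerance = 1e-12)

  # huge residual noise: clonal repeatability (ICC) near zero
  desN <- trial_design_spec(n_sites = 4, n_blocks_per_site = 3,
                            site_variance = 0, site_block_variance = 0,
                            gxe_variance = 0, residual_variance = 400)
  recN <- simulate_trial_records(gv, desN, seed = 52)
  a <- stats::aov(value ~ genotype, data = recN)
  ms <- summary(a)[[1]]$`Mean Sq`
  k <- nrow(recN) / 30
  icc <- (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
  expect_lt(abs(icc), 0.05)

  # reproducible given the seed; every genotype appears at >= 1 site
  expect_identical(simulate_trial_records(gv, desN, seed = 52), recN)
  desS <- trial_design_spec(n_sites = 6, sites_per_genotype = 2)
  recS <- simulate_trial_records(gv, desS, seed = 53)
  expect_true(all(names(gv) %in% recS$genotype))
  expect_error(trial_design_spec(n_sites = 3, sites_per_genotype = 5),
               "sites_per_genotype")
})
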