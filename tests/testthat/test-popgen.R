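test_that("heterozygosities match closed-form cases and HWE sampling", {
  m <- cbind(allhet = rep(0, 50), mono = rep(1, 50),
             mix = c(rep(-1, 20), rep(0, 10), rep(1, 20)))
  rownames(m) <- sprintf("G%02d", 1:50)
  gm <- genotype_matrix(m)
  h <- heterozygosities(gm, by_population = FALSE, correct = FALSE)
  expect_equal(h$per_snp$ho[1], 1)
  expect_equal(h$per_snp$he[1], 0.5)
  expect_equal(h$per_snp$he[2], 0)
  expect_equal(h$per_snp$ho[2], 0)

  # HWE draws at p = 0.3: mean H_O tracks mean H_E
  set.seed(61)
  n <- 500; p <- 2000
  dose <- matrix(rbinom(n * p, 2, 0.3), n, p)
  gm2 <- genotype_matrix(matrix(dose - 1, n, p))
  h2 <- heterozygosities(gm2, by_population = FALSE, correct = FALSE)
  expect_lt(abs(h2$summary[["he"]] - h2$summary[["ho"]]), 0.01)

  expect_error(heterozygosities(genotype_matrix(m[1, , drop = FALSE]),
                                by_population = FALSE), "2 genotypes")
})

test_that("EM r2 matches the phased oracle and its limits", {
  # identical SNPs: exactly 1
  sc <- haplotype_pair_scores(500, c(.25, .25, .25, .25), seed = 62)
  expect_identical(ld_r2(sc$a, sc$a)$r2, 1)

  # linkage equilibrium at n = 1e4: r2 under 0.01
  eq <- haplotype_pair_scores(1e4, c(.25, .25, .25, .25), seed = 63)
  expect_lt(ld_r2(eq$a, eq$b)$r2, 0.01)

  # worked 4-haplotype example: (AB, Ab, aB, ab) = (.4, .1, .1, .4)
  # D = .4*.4 - .1*.1 = 0.15, r2 = .15^2 / .5^4 = 0.36
  wk <- haplotype_pair_scores(1e4, c(.4, .1, .1, .4), seed = 64)
  est <- ld_r2(wk$a, wk$b)
  expect_equal(est$r2, 0.36, tolerance = 0.02 / 0.36)
  expect_lt(est$p_value, 1e-10)

  # composite estimator agrees to sampling accuracy on the same data
  comp <- ld_r2(wk$a, wk$b, estimator = "composite")
  expect_equal(comp$r2, est$r2, tolerance = 0.05)

  expect_error(ld_r2(c(-1, 1), c(1, -1)), "complete pairs")
  mono <- ld_r2(rep(1, 50), sample(c(-1, 0, 1), 50, TRUE))
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$r2))
})

test_that("LD profiles separate cohorts by block length and handle edge maps", {
  # longer ancestry blocks give more within-LG LD, replicate-paired
  wins <- sapply(1:8, function(r) {
    mk <- function(block, seed) {
      co <- simulate_cohort(cohort_spec(
        n_populations = 1, n_genotypes_per_pop = 70,
        n_ancestral_clusters = 3, n_snps_mapped = 80,
        n_linkage_groups = 2, map_length_cM = 50, divergence = 0.25,
        recombination_block_cM = block, missing_rate = 0, seed = seed))
      ld_profiles(co$gm, co$map, by_population = FALSE,
                  estimator = "composite")$summary[["mean_r2"]]
    }
    mk(5, 600 + r) > mk(1, 600 + r)
  })
  expect_gte(sum(wins), 7)  # sign test at the 5% level for 8 pairs

  # single SNP per LG: flagged-empty, no crash
  gm <- genotype_matrix(random_scores(30, 3, seed = 65))
  map1 <- genetic_map(snp_ids(gm), 1:3, c(10, 20, 30))
  prof <- ld_profiles(gm, map1, by_population = FALSE)
  expect_true(isTRUE(prof$empty))

  expect_error(ld_profiles(gm, map1, mode = "within_isotig",
                           by_population = FALSE), "isotig")
})

test_that("kinship has VanRaden structure", {
  x <- random_scores(40, 800, seed = 66)
  x[2, ] <- x[1, ]
  K <- kinship(x)
  expect_equal(K, t(K))
  expect_equal(K[1, 2], K[1, 1], tolerance = 1e-10)
  expect_equal(K[1, 2], K[2, 2], tolerance = 1e-10)
  ev <- eigen(K + diag(1e-6, 40), symmetric = TRUE, only.values = TRUE)
  expect_true(all(ev$values > -1e-8))

  # unrelated cohort: off-diagonals vanish as SNPs grow (up to the
  # -1/(n-1) centering bias, so use a roomy n)
  x1 <- random_scores(200, 500, seed = 67)
  x2 <- random_scores(200, 20000, seed = 68)
  off <- function(K) mean(abs(K[upper.tri(K)]))
  expect_lt(off(kinship(x2)), off(kinship(x1)))
  expect_lt(off(kinship(x2)), 0.02)

  expect_error(kinship(matrix(1, 5, 4)), "monomorphic")
})

test_that("genotype PCA separates clusters and is deterministic in sign", {
  spec <- cohort_spec(n_populations = 2, n_genotypes_per_pop = 30,
                      n_ancestral_clusters = 2, n_snps_mapped = 300,
                      n_linkage_groups = 3, divergence = 0.35,
                      admixture_concentration = rbind(c(25, .05), c(.05, 25)),
                      missing_rate = 0, seed = 69)
  co <- simulate_cohort(spec)
  pc <- pca_genotypes(co$scores_complete)
  lab <- as.integer(co$gm$population)
  r1 <- range(pc$scores[lab == 1, 1])
  r2 <- range(pc$scores[lab == 2, 1])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])  # zero overlap on PC1
  expect_equal(sum(pc$variance_share), 1)

  x <- co$scores_complete
  x <- rbind(x, dup = x[1, ])
  pc2 <- pca_genotypes(x)
  expect_equal(pc2$scores[1, ], pc2$scores[nrow(x), ], tolerance = 1e-8)

  expect_error(pca_genotypes(x[1, , drop = FALSE]), "2 genotypes")
})

test_that("N_Q is the inverse Simpson index with its stated properties", {
  expect_equal(effective_clusters(c(1, 0, 0, 0)), 1)
  expect_equal(effective_clusters(rep(0.25, 4)), 4)
  expect_equal(effective_clusters(c(0.5, 0.5, 0, 0)), 2)
  expect_error(effective_clusters(c(0.5, 0.2)), "simplex")

  # Schur-concavity: a mean-preserving contraction never lowers N_Q
  set.seed(70)
  for (i in 1:1000) {
    q <- random_simplex(sample(2:6, 1))
    hi <- which.max(q); lo <- which.min(q)
    eps <- runif(1, 0, (q[hi] - q[lo]) / 2)
    q2 <- q; q2[hi] <- q[hi] - eps; q2[lo] <- q[lo] + eps
    expect_gte(effective_clusters(q2) + 1e-12, effective_clusters(q))
  }
})

test_that("ancestry estimation recovers clusters and scores models", {
  # K = 1: trivial factorization, null-model cross-entropy
  gm <- genotype_matrix(random_scores(30, 60, seed = 71))
  a1 <- estimate_ancestry(gm, K = 1, seed = 1)
  expect_equal(unname(a1$Q[, 1]), rep(1, 30))
  expect_equal(a1$N_Q, rep(1, 30))

  # one-hot 3-cluster cohort: >= 95% of labels recovered up to permutation
  spec <- cohort_spec(n_populations = 3, n_genotypes_per_pop = 40,
                      n_ancestral_clusters = 3, n_snps_mapped = 500,
                      n_linkage_groups = 5, divergence = 0.3,
                      admixture_concentration = diag(3) * 20 + 0.05,
                      missing_rate = 0, seed = 72)
  co <- simulate_cohort(spec)
  anc <- estimate_ancestry(co$gm, K = 3, n_runs = 3, seed = 2)
  expect_true(all(abs(rowSums(anc$Q) - 1) < 1e-6))
  expect_true(all(anc$N_Q >= 1 & anc$N_Q <= 3))
  true_cl <- apply(co$Q, 1, which.max)
  est_cl <- apply(anc$Q, 1, which.max)
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  match_rate <- max(apply(perms, 1, function(pm)
    mean(est_cl == pm[true_cl])))
  expect_gte(match_rate, 0.95)

  expect_error(estimate_ancestry(gm, K = 40), "genotype count")
  expect_error(estimate_ancestry(gm, K = 2, mask_fraction = 0.7),
               "mask_fraction")
})

test_that("cross-entropy curve supports the simulated cluster number", {
  # 4-cluster cohorts: the curve bottoms out at (or elbows at) K = 4
  hits <- sapply(1:5, function(r) {
    co <- simulate_cohort(cohort_spec(
      n_populations = 3, n_genotypes_per_pop = 40,
      n_ancestral_clusters = 4, n_snps_mapped = 400,
      n_linkage_groups = 4, divergence = 0.3,
      admixture_concentration = 0.3, missing_rate = 0.02,
      seed = 700 + r))
    cc <- cross_entropy_curve(co$gm, K_range = 1:6, n_runs = 2,
                              seed = 70 + r)
    cc$K[which.min(cc$cross_entropy)]
  })
  expect_gte(sum(hits == 4), 3)
  expect_true(all(abs(hits - 4) <= 1))
})

test_that("population mean N_Q falls as admixture becomes one-hot", {
  # mirrors the mechanism behind the population ordering of N_Q
  wins <- sapply(1:8, function(r) {
    mk <- function(conc, seed) {
      co <- simulate_cohort(cohort_spec(
        n_populations = 1, n_genotypes_per_pop = 40,
        n_ancestral_clusters = 4, n_snps_mapped = 100,
        n_linkage_groups = 2, divergence = 0.25,
        admixture_concentration = conc, missing_rate = 0, seed = seed))
      mean(apply(co$Q, 1, effective_clusters))
    }
    mk(1.5, 800 + r) > mk(0.15, 800 + r)
  })
  expect_gte(sum(wins), 7)
})
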