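# Shared fixture builders: everything is generated in code, seeded.

# Small unstructured score matrix with iid SNPs.
random_scores <- function(n, p, seed = 1, values = c(-1, 0, 1)) {
  set.seed(seed)
  matrix(sample(values, n * p, replace = TRUE), n, p,
         dimnames = list(sprintf("G%03d", seq_len(n)),
                         sprintf("S%04d", seq_len(p))))
}

# Unphased scores for two loci drawn from given haplotype frequencies
# (order AB, Ab, aB, ab), n diploid genotypes.
haplotype_pair_scores <- function(n, freqs, seed = 1) {
  set.seed(seed)
  hap <- matrix(c(1, 1, 1, 0, 0, 1, 0, 0), ncol = 2, byrow = TRUE)
  h1 <- hap[sample(4, n, TRUE, freqs), ]
  h2 <- hap[sample(4, n, TRUE, freqs), ]
  list(a = h1[, 1] + h2[, 1] - 1, b = h1[, 2] + h2[, 2] - 1)
}

# A default small admixed cohort used by several tests.
small_cohort <- function(seed = 1, ...) {
  simulate_cohort(cohort_spec(n_populations = 2,
                              n_genotypes_per_pop = c(40, 40),
                              n_ancestral_clusters = 2,
                              n_snps_mapped = 200, n_linkage_groups = 4,
                              divergence = 0.2, missing_rate = 0.02,
                              seed = seed, ...))
}

# Random point on the K-simplex.
random_simplex <- function(K) {
  g <- rgamma(K, 1)
  g / sum(g)
}

# Brute-force Benjamini-Hochberg step-up, written independently of the
# package implementation: for each p_i, q_i = min over j with
# p_(j) >= p_i of p_(j) * m / j.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[o] <- q
  out
}
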