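---
title: "Methods and design of conifergp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of conifergp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`conifergp` implements a complete genome-wide analysis chain for
breeding populations of unrelated, clonally replicated plus trees
genotyped on biallelic SNP arrays: quality control and imputation,
population-genetic characterization, clonal-value estimation, mixed-model
association, genomic prediction, and low-density panel selection. This
vignette records the models behind each stage, the tunable parameters
that matter, and the design choices made where the design was genuinely
open.

## The data model

Genotypes are scores in {-1, 0, 1} (the two homozygotes and the
heterozygote) with missing calls tracked explicitly
(`genotype_matrix()`). A genetic map (`genetic_map()`) places a subset
of SNPs on linkage groups at centimorgan positions; the remainder are
"unmapped" and can be positioned only through linkage disequilibrium.
SNPs may additionally carry an isotig (EST contig) id and a base-pair
position within it, giving a second, physical notion of distance for LD
summaries.

## Quality control and imputation

`qc_filter()` applies the array-QC cascade in a fixed order —
monomorphic SNPs, then missing-call rate (default > 50% removed), then
minor allele frequency (default < 5% removed) — because the per-stage
survivor counts are order-dependent and are part of the report. MAF is
computed on the pooled cohort: filtering happens once, before any
per-population analysis, and is idempotent.

`impute_em()` produces the complete matrix needed by kinship, PCA, GWAS
and prediction. The EM mode iterates two steps to a fixed point:
compute the realized relationship matrix A from the current complete
matrix, then replace each missing entry by its conditional expectation
given the observed calls in its column under a Gaussian working model
with covariance proportional to A. Observed calls are never altered and
imputed values stay in [-1, 1]. One numerical subtlety: because A is
built from columns centered at their own sample frequencies, it is
singular along the all-ones direction, and a naive conditional chases
that artifact instead of genuine relatedness. Eigenvalues of A below
`eig_floor` times the mean diagonal (default 0.05) are therefore raised
to that floor before conditioning. A one-step per-SNP mean mode
(`method = "mean"`) is provided for large matrices where the iterated
scheme is unnecessary; it is what the bundled acceptance script uses
ahead of kinship and PCA, where column centering absorbs the difference.

## Population-genetic characterization

*Diversity.* `heterozygosities()` reports per-SNP and averaged expected
heterozygosity 2p(1-p) — by default with the unbiased n/(n-1)
small-sample correction, switchable off — and observed heterozygosity as
the fraction of score-0 calls.

*Linkage disequilibrium.* `ld_r2()` estimates r-squared between two
unphased diploid loci by EM maximum-likelihood haplotype frequencies
under random mating, r2 = D^2 / (pA pa pB pb). Significance uses the
asymptotic chi-square statistic N r2 with 1 df on the haplotype-count
scale (N = twice the complete pairs); the underlying two-locus test is
not uniquely standard, so a composite squared-correlation estimator is
available as `estimator = "composite"` and the chi-square form is
shared. Perfectly correlated inputs short-circuit to r2 = 1 exactly
rather than relying on EM convergence. `ld_profiles()` enumerates
within-linkage-group (cM) or within-isotig (bp) pairs, reports the mean
r2, the percentage of pairs significant at p < 0.01, and a binned decay
curve; groups with a single SNP yield a flagged-empty result.

*Kinship and PCA.* `kinship()` is the VanRaden realized relationship on
the score scale: columns centered by 2(p - 0.5), cross-product scaled
by 2 sum p(1-p). Note the centering forces row sums of the matrix to
zero, so off-diagonals of an unstructured cohort converge not to zero
but to -1/(n-1); tests account for this. `pca_genotypes()` decomposes
the centered (optionally scaled) matrix and fixes each component's sign
so the largest-magnitude loading is positive.

*Ancestry.* `estimate_ancestry()` factorizes the allele-dosage matrix
into admixture proportions Q (rows on the simplex) and ancestral
frequencies G (entries in [0, 1]) by alternating least squares with
projection — the same model family as sparse-NMF ancestry estimators,
chosen because only Q, the model-choice score, and N_Q are consumed
downstream. Model choice uses a masked-entry cross-entropy: a random
entry subset (default 5%) is held out, the fit proceeds on the rest with
EM refills, and the held-out allele counts are scored under the binomial
likelihood of the fitted frequencies; `cross_entropy_curve()` sweeps K.
The per-genotype effective number of clusters is the inverse Simpson
index N_Q = 1 / sum(Q_i^2). This functional form is the one consistent
with its two defining properties — range 1 (unadmixed) to K (uniformly
admixed), increasing with admixture strength — and it is Schur-concave,
which the tests verify directly.

## Clonal values

Plot-mean trial records follow

    value = mu + site + block-in-site + genotype
            + genotype-x-site + residual

with site and block-in-site fixed and the rest random.
`fit_clonal_model()` estimates the three variance components by REML
(via lme4) and returns genotype BLUPs as the clonal values; for
single-site garden data the site, block and interaction terms drop
automatically, and a `ramet_mean` mode returns plain per-genotype means
for small balanced gardens. `genetic_effect_lrt()` tests the genotype
term by the deviance of maximum-likelihood fits with and without it,
referred to chi-square with 1 df. Because the null pins a variance to
the boundary this is conservative (simulated size about 0.03 at nominal
0.05); the 50:50 chi0/chi1 mixture is available via
`boundary_correction = TRUE`, with the plain rule as the default
convention.

## Mixed-model association

`mixed_model_scan()` fits, per SNP,

    trait = intercept + PCs + marker + polygenic + residual

with the polygenic effect covarying as sigma_g^2 K. The variance ratio
is estimated once on the marker-free null model by REML on the spectral
decomposition of K and reused for every marker (the P3D/EMMAX scheme —
the standard desk-scale choice; exact per-marker REML would change
p-values marginally at far higher cost). After rotation and weighting,
each marker is an ordinary least-squares contrast with a two-sided t
test; with K identity and no PCs the scan reduces exactly to
single-marker regression, which the tests assert to 1e-6. Markers
collinear with the covariates are flagged untestable rather than
crashing. P-values are floored at 1e-300 before -log10.

Multiple testing uses hand-rolled Benjamini–Hochberg step-up q-values
(`bh_qvalues()`), cross-checked in the tests against both a brute-force
enumeration and `p.adjust`. Significance flags follow two conventions:
FDR q < 0.1 and -log10(p) > 3.

Unmapped SNPs that reach significance are positioned by
`place_unmapped()`: compute r2 to every mapped SNP and, if the maximum
exceeds 0.6, adopt the partner's position (ties break by smaller cM then
id, for determinism). `find_common_regions()` then looks across
per-population scans for same-linkage-group groups of significant SNPs
spanning less than 10 cM with every population represented (the
all-populations default matches the cross-population design;
`min_populations` exposes the laxer variant). Maximal groups are
reported; subsets of larger regions are suppressed.

## Genomic prediction

Three models, one interface, evaluated by `cross_validate()`:

* `gblup_fit_predict()` — mixed model y = mu + g + e with
  g ~ N(0, sigma_g^2 K); REML through the eigendecomposition of the
  training block, prediction by the kinship cross-block conditional
  expectation. Equivalent to marker ridge regression when K = WW'/c,
  an identity the acceptance tests verify to 1e-6.
* `bayesb_fit_predict()` — spike-and-slab whole-genome regression: each
  marker effect is zero with probability 1 - pi or drawn from a normal
  slab whose variance has a scaled-inverse-chi-square prior (marginally
  a scaled-t slab). The Gibbs sampler is compiled (Rcpp), with the
  reference chain settings of 20,000 iterations and 10,000 burn-in as
  defaults; test profiles use shortened chains (1,500–4,000 iterations),
  a reduction the chain-stability test justifies. The prior inclusion
  probability pi defaults to 0.05 fixed, with Beta(1,1) sampling
  switchable; the slab scale is set from the phenotypic variance and the
  expected number of included markers unless given.
* `rf_fit_predict()` — bagged regression trees at the reference
  regression defaults (500 trees, p/3 features per split). Its value is
  non-additive signal: on a pure two-marker interaction trait it
  predicts where GBLUP cannot, the mechanism that motivates including a
  non-linear model alongside the linear ones.

Cross-validation partitions genotypes into 10 folds, refits per fold,
and scores the Pearson correlation between phenotype and prediction.
Accuracy is computed on the pooled validation predictions of each
replicate (lower-variance; the per-fold-mean convention is available via
`per_fold = TRUE`), then averaged over 10 replicates with a standard
error. Genotypes are put in canonical (sorted-id) order first, making
results invariant to input row order. Fold assignment is simple random;
note that with near-zero signal the pooled correlation acquires a small
negative bias (fold-specific training means), which is visible in
permutation nulls and worth knowing when reading accuracies near zero.

## Panel selection

`gwas_based_select()` implements the greedy spaced-selection loop:
take the highest-scoring SNP, exclude all SNPs within ±d on its linkage
group (initial d = 10 cM), repeat; when candidates are exhausted, halve
d and re-admit SNPs at distinct positions lying more than the relaxed d
from every selected SNP on the same linkage group; once all distinct
positions are taken, fill remaining slots in descending score order.
Two readings of the relaxation step were possible; measuring the
relaxed radius from the *selected* SNPs is the one implemented, because
measuring it from every excluded SNP leaves no admissible candidate at
all. The exclusion radius applies within a linkage group only —
cross-group distance is undefined. Ties break by score, then linkage
group, then position, then id, so the procedure is fully deterministic,
and because selection is a single ordering, panels are nested across
sizes. `semi_random_select()` assigns a random permutation of ranks
1..m as scores and reuses the same machinery, preserving the spacing
discipline while discarding the association signal.

`accuracy_curve()` runs cross-validation restricted to each panel and
flags sizes whose replicate accuracies are not significantly below the
best size's (two-sample t test, p >= 0.05). By default the GWAS scores
driving selection are recomputed inside each training fold, so marker
selection never sees validation genotypes; `paper_mode = TRUE` selects
once from a whole-data scan, the simpler protocol whose optimism the
default avoids. Panels are built once per fold at the largest size and
prefixed, keeping the curve affordable.

## The synthetic cohort generator

No plus-tree genotype or phenotype data are redistributable, so every
stage is exercised on synthetic cohorts (`cohort_spec()`,
`simulate_cohort()`) built to emulate the study design rather than any
particular dataset:

* *Ancestral frequencies* follow a Balding–Nichols construction: a base
  frequency per SNP from Uniform(0.1, 0.9), cluster frequencies from a
  Beta around it whose divergence parameter is the between-cluster FST
  (verified against a Hudson-estimator oracle), clipped to (0.02, 0.98).
* *Genotypes* are ancestry mosaics: each haplotype is a chain of
  exponential-length ancestral segments (mean `recombination_block_cM`)
  walked along the map, with alleles drawn from the segment's cluster
  frequencies. This admixture-LD mechanism produces the map-distance
  decay and lets block length play the role that founder history plays
  across real populations (longer blocks, more LD, as in a recently
  founded population); it deliberately does not model mutation,
  coalescent depth, or selection.
* *Defaults* mirror the study structure: three populations of 181, 159
  and 136 genotypes, K = 4 ancestral clusters, 11 linkage groups, MCAR
  missingness at 2%. SNP counts are scaled to desk size (the acceptance
  script uses 1,500 mapped SNPs); the generator takes the full-scale
  values when asked. Dirichlet concentration 0.5 gives moderate
  admixture; lowering it toward one-hot reproduces the
  lower-effective-clusters regime.
* *Unmapped SNPs* are copies of random mapped SNPs with per-genotype
  score resampling at 2%, so their true source is known and the r2 > 0.6
  placement rule has ground truth.
* *Traits* sample QTLs from the markers with Gaussian or geometric-decay
  effects and an optional dominance share; genetic values are
  standardized, and the truth table (ids, effects) is returned for
  oracle tests. *Trial records* add site, block-in-site,
  genotype-by-site and residual noise at specified variances over a
  partially overlapping genotype-by-site incidence.
* All randomness flows from one integer seed through fixed offsets, so
  every object is byte-reproducible.

What passing tests on these cohorts do show: the estimators recover
planted truth (FST, cluster labels and number, QTLs, variance
components), the scan is calibrated and controls structure-driven
confounding, and the panel-selection contrast between trait
architectures behaves as the theory predicts. What they cannot show:
behavior under real array artifacts (informative missingness, batch
effects), long-range physical LD inside coding regions, or selection
footprints — conclusions about real cohorts still require real data.

## Numerical choices and test profiles

* REML variance-ratio searches run on log(delta) in [-12, 12] by Brent
  optimization; kinship blocks get a 1e-6 ridge before decomposition.
* EM haplotype estimation iterates to 1e-8 with a 100-iteration cap;
  LD on fewer than 10 complete pairs is refused.
* The clonal-model suite runs 20 replicates of the (1, 0.5, 2)
  components design at 100 genotypes x 10 sites x 3 blocks, and sizes
  the null LRT on 500 replicates of a compact 40-genotype design.
* The panel-architecture suite uses 20 cohorts of 300 genotypes x 1,000
  mapped SNPs with GBLUP, panel sizes 50 and 500, and 3 CV replicates;
  BayesB tests run shortened chains. These profiles are the package's
  own test scale, chosen to keep the full suite in minutes while leaving
  each comparison's power intact.
* The pipeline has no compiled dependencies beyond the BayesB sampler;
  everything else is base R linear algebra plus lme4, randomForest and
  (optionally) vcfR. There is no command-line wrapper: like its peer
  analysis packages, `conifergp` is driven from R, and
  `scripts/acceptance.R` shows the full pipeline end to end.

## Known limitations

* The ancestry solver is a least-squares factorization, not a
  regularized NMF with sparsity penalties; cross-entropy values are
  comparable across K within a dataset but not across datasets.
* EM imputation conditions on a floored-spectrum relationship matrix;
  with very few genotypes it degrades gracefully toward mean imputation
  rather than exploiting weak relatedness.
* The LRT's chi-square(1) reference is conservative at the boundary by
  construction; report the mixture-corrected p when size matters.
* GBLUP's REML can drive the genetic variance to zero on strongly
  oligogenic traits — a model-fit fact, visible in the acceptance
  numbers, not an implementation defect; BayesB is the appropriate model
  there.
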