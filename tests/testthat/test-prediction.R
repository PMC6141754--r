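test_that("GBLUP interpolates duplicates and equals marker ridge", {
  # duplicated genotype across train/test, near-noiseless trait:
  # the test copy inherits the twin's phenotype deviation
  x <- random_scores(40, 300, seed = 101)
  x[40, ] <- x[1, ]
  tr <- simulate_trait(x, trait_spec(n_qtl = 100, seed = 102))
  y <- tr$genetic_values
  K <- kinship(x)
  gb <- gblup_fit_predict(y[1:39], K, "G040")
  expect_equal(unname(gb$predictions), unname(y[1]), tolerance = 0.05)

  # GBLUP/ridge duality on a 30 x 100 instance
  W <- random_scores(30, 100, seed = 103)
  set.seed(104)
  yy <- stats::setNames(rnorm(30), rownames(W))
  K2 <- kinship(W)
  gb2 <- gblup_fit_predict(yy[1:20], K2, rownames(W)[21:30])
  p <- (colMeans(W) + 1) / 2
  Wc <- sweep(W, 2, 2 * (p - 0.5))
  cc <- 2 * sum(p * (1 - p))
  lam <- cc * gb2$sigma2_e / gb2$sigma2_g
  beta <- solve(crossprod(Wc[1:20, ]) + diag(lam, 100),
                crossprod(Wc[1:20, ], yy[1:20] - gb2$mu))
  ridge_pred <- gb2$mu + unname(drop(Wc[21:30, ] %*% beta))
  expect_equal(unname(gb2$predictions), ridge_pred, tolerance = 1e-6)

  # permuted phenotypes: accuracy centered at zero
  xp <- random_scores(45, 300, seed = 121)
  trp <- simulate_trait(xp, trait_spec(n_qtl = 100, seed = 122))
  yp_all <- trp$genetic_values
  Kp <- kinship(xp)
  accs <- sapply(1:25, function(r) {
    set.seed(200 + r)
    yp <- stats::setNames(sample(yp_all[1:30]), rownames(xp)[1:30])
    pr <- gblup_fit_predict(yp, Kp, rownames(xp)[31:45])$predictions
    suppressWarnings(stats::cor(yp_all[31:45], pr))
  })
  expect_lt(abs(mean(accs)), 0.12)

  expect_error(gblup_fit_predict(unname(y[1:10]), K, "G020"), "named")
})

test_that("BayesB concentrates on true QTLs and shrinks under the null", {
  rec <- sapply(1:5, function(r) {
    x <- random_scores(300, 250, seed = 300 + r)
    tr <- simulate_trait(x, trait_spec("oligogenic", n_qtl = 5,
                                       seed = 310 + r))
    set.seed(320 + r)
    y <- tr$genetic_values + rnorm(300, 0, sqrt(1 / 0.7 - 1))
    fit <- bayesb_fit_predict(x[1:250, ], y[1:250], x[251:300, ],
                              iterations = 1500, burn_in = 500,
                              seed = 330 + r)
    med <- stats::median(fit$inclusion_prob)
    mean(fit$inclusion_prob[tr$qtl$index]) > med
  })
  expect_gte(sum(rec), 4)

  # pure-noise trait: posterior mean effects shrink hard
  x <- random_scores(200, 150, seed = 105)
  set.seed(106)
  y0 <- rnorm(200)
  fit0 <- bayesb_fit_predict(x[1:150, ], y0[1:150], x[151:200, ],
                             iterations = 1500, burn_in = 500, seed = 107)
  expect_lt(mean(abs(fit0$beta)), 0.1 * stats::sd(y0))

  # lengthening a converged chain barely changes the predictions
  x2 <- random_scores(200, 120, seed = 108)
  tr2 <- simulate_trait(x2, trait_spec("oligogenic", n_qtl = 5, seed = 109))
  set.seed(110)
  y2 <- tr2$genetic_values + rnorm(200, 0, 0.5)
  f1 <- bayesb_fit_predict(x2[1:150, ], y2[1:150], x2[151:200, ],
                           iterations = 2000, burn_in = 1000, seed = 111)
  f2 <- bayesb_fit_predict(x2[1:150, ], y2[1:150], x2[151:200, ],
                           iterations = 4000, burn_in = 1000, seed = 111)
  expect_gt(stats::cor(f1$predictions, f2$predictions), 0.98)

  expect_error(bayesb_fit_predict(x2[1:10, ], y2[1:10], x2[11:12, ],
                                  iterations = 100, burn_in = 100),
               "burn_in")
})

test_that("random forest captures pure interactions that GBLUP misses", {
  wins <- sapply(1:5, function(r) {
    set.seed(500 + r)
    n <- 600; p <- 40
    x <- matrix(sample(c(-1, 0, 1), n * p, TRUE), n, p,
                dimnames = list(sprintf("G%03d", 1:n),
                                sprintf("S%03d", 1:p)))
    # two balanced +/-1 markers: XOR has no marginal effects
    x[, 1] <- sample(c(-1, 1), n, TRUE)
    x[, 2] <- sample(c(-1, 1), n, TRUE)
    y <- as.numeric(x[, 1] * x[, 2] > 0) + rnorm(n, 0, 0.2)
    names(y) <- rownames(x)
    tr <- 1:450; te <- 451:600
    rf <- rf_fit_predict(x[tr, ], y[tr], x[te, ], n_trees = 500,
                         mtry = 20, nodesize = 3, seed = 510 + r)
    gb <- gblup_fit_predict(y[tr], kinship(x), rownames(x)[te])
    acc_rf <- stats::cor(y[te], rf$predictions)
    acc_gb <- stats::cor(y[te], gb$predictions)
    acc_rf > 0.3 && acc_gb < 0.1
  })
  expect_gte(sum(wins), 4)

  # constant response: constant prediction with a warning
  x <- random_scores(30, 20, seed = 112)
  expect_warning(out <- rf_fit_predict(x[1:20, ], rep(2, 20), x[21:30, ]),
                 "constant")
  expect_true(all(out$predictions == 2))

  # bagging stabilizes: many trees give less seed-to-seed spread
  x3 <- random_scores(150, 40, seed = 113)
  tr3 <- simulate_trait(x3, trait_spec(n_qtl = 10, seed = 114))
  set.seed(115)
  y3 <- tr3$genetic_values + rnorm(150, 0, 0.5)
  spread <- function(nt) {
    accs <- sapply(1:6, function(s) {
      pr <- rf_fit_predict(x3[1:100, ], y3[1:100], x3[101:150, ],
                           n_trees = nt, seed = s)$predictions
      stats::cor(y3[101:150], pr)
    })
    stats::sd(accs)
  }
  expect_lt(spread(400), spread(1))
})

test_that("cross-validation is seeded, pooled and size-responsive", {
  x <- random_scores(200, 40, seed = 116)
  tr <- simulate_trait(x, trait_spec(n_qtl = 40, seed = 117))
  y <- tr$genetic_values  # deterministic linear trait

  cv1 <- cross_validate(x, y, "GBLUP", folds = 5, replicates = 3, seed = 9)
  cv2 <- cross_validate(x, y, "GBLUP", folds = 5, replicates = 3, seed = 9)
  expect_identical(cv1$accuracy, cv2$accuracy)
  expect_gt(cv1$mean, 0.95)
  expect_true(all(cv1$accuracy >= -1 & cv1$accuracy <= 1))
  # folds partition the genotypes each replicate
  expect_true(all(apply(cv1$fold_assignments, 1, function(f)
    all(tabulate(f, 5) == 40))))

  # genotype row order does not change GBLUP accuracy
  set.seed(10)
  perm <- sample(200)
  cv3 <- cross_validate(x[perm, ], y[perm], "GBLUP", folds = 5,
                        replicates = 3, seed = 9)
  expect_equal(sort(cv3$accuracy), sort(cv1$accuracy), tolerance = 1e-8)

  # accuracy grows with training-pool size on a noisy polygenic trait
  xb <- random_scores(450, 300, seed = 118)
  trb <- simulate_trait(xb, trait_spec(n_qtl = 300, seed = 119))
  set.seed(120)
  yb <- trb$genetic_values + rnorm(450, 0, 1)
  names(yb) <- rownames(xb)
  cv_small <- cross_validate(xb[1:150, ], yb[1:150], "GBLUP",
                             folds = 5, replicates = 5, seed = 10)
  cv_big <- cross_validate(xb, yb, "GBLUP", folds = 5, replicates = 5,
                           seed = 10)
  expect_gt(cv_big$mean, cv_small$mean)

  expect_error(cross_validate(x[1:8, ], y[1:8], "GBLUP", folds = 10),
               "folds")
})
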