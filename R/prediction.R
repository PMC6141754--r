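#' GBLUP: fit on training genotypes, predict the rest
#'
#' Mixed model `y = mu + g + e` with `g ~ N(0, sigma_g^2 K)`. The
#' variance ratio is estimated by REML on the training block of K
#' (spectral decomposition), and predictions for test genotypes are the
#' conditional expectations of g given the training records (the
#' kinship cross-block regression). Deterministic.
#'
#' @param y_train Named numeric vector of training phenotypes.
#' @param K Kinship over all genotypes (train and test), with dimnames.
#' @param test_ids Ids (or indices) of genotypes to predict.
#' @param ridge Ridge added to the training block for stability.
#' @return List: `predictions` (named, test genotypes; `mu + g_hat`),
#'   `mu`, `sigma2_g`, `sigma2_e`, `g_hat_all`.
#' @export
gblup_fit_predict <- function(y_train, K, test_ids, ridge = 1e-6) {
  ids <- rownames(K)
  if (is.null(ids)) {
    ids <- as.character(seq_len(nrow(K)))
    dimnames(K) <- list(ids, ids)
  }
  tr <- names(y_train)
  if (is.null(tr)) stop("y_train must be named by genotype id")
  if (!all(tr %in% ids)) stop("kinship must cover all training genotypes")
  test_ids <- as.character(test_ids)
  if (!all(test_ids %in% ids)) stop("kinship must cover all test genotypes")
  n <- length(tr)
  Ktt <- K[tr, tr] + diag(ridge, n)
  eg <- eigen((Ktt + t(Ktt)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 1e-10)
  if (min(eg$values) < -1e-6)
    stop("kinship not positive semidefinite after ridge")
  Uy <- drop(crossprod(eg$vectors, y_train))
  U1 <- drop(crossprod(eg$vectors, rep(1, n)))
  reml_nll <- function(log_delta) {
    delta <- exp(log_delta)  # sigma_e^2 / sigma_g^2
    v <- d + delta
    mu <- sum(U1 * Uy / v) / sum(U1^2 / v)
    r <- Uy - mu * U1
    s2 <- sum(r^2 / v) / (n - 1)
    0.5 * ((n - 1) * log(s2) + sum(log(v)) + log(sum(U1^2 / v)) + (n - 1))
  }
  opt <- stats::optimize(reml_nll, c(-12, 12))
  delta <- exp(opt$minimum)
  v <- d + delta
  mu <- sum(U1 * Uy / v) / sum(U1^2 / v)
  sigma2_g <- sum((Uy - mu * U1)^2 / v) / (n - 1)
  sigma2_e <- delta * sigma2_g
  ## g_hat = K[, tr] (Ktt + delta I)^{-1} (y - mu)
  alpha <- eg$vectors %*% ((Uy - mu * U1) / v)
  g_hat <- drop(K[, tr, drop = FALSE] %*% alpha)
  names(g_hat) <- ids
  preds <- mu + g_hat[test_ids]
  list(predictions = preds, mu = mu, sigma2_g = sigma2_g,
       sigma2_e = sigma2_e, g_hat_all = g_hat)
}

#' BayesB: spike-and-slab whole-genome regression
#'
#' MCMC (Gibbs) over per-marker effects that are zero with probability
#' `1 - pi` or drawn from a normal slab whose variance carries a scaled
#' inverse-chi-square prior (marginally a scaled-t slab). Predictions are
#' posterior-mean marker effects applied to the test genotypes plus the
#' posterior-mean intercept.
#'
#' @param X_train,X_test Score matrices (rows genotypes, columns
#'   markers; columns must match).
#' @param y_train Training phenotypes.
#' @param iterations Total MCMC iterations (reference setting 20000).
#' @param burn_in Discarded iterations (reference setting 10000).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param pi Prior inclusion probability of a marker.
#' @param update_pi Sample pi with a Beta(1,1) prior.
#' @param nu,s2 Slab degrees of freedom and scale; `s2 = NULL` sets the
#'   scale from the phenotypic variance and expected included markers.
#' @param seed Chain seed.
#' @return List: `predictions` (named by test rownames), `mu`, `beta`
#'   (posterior means), `inclusion_prob`, `seed`.
#' @export
bayesb_fit_predict <- function(X_train, y_train, X_test,
                               iterations = 20000, burn_in = 10000,
                               thin = 5, pi = 0.05, update_pi = FALSE,
                               nu = 4, s2 = NULL, seed = 1L) {
  if (burn_in >= iterations) stop("burn_in must be below iterations")
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  stopifnot(ncol(X_train) == ncol(X_test),
            nrow(X_train) == length(y_train))
  p <- ncol(X_train)
  vy <- stats::var(y_train)
  if (is.null(s2)) {
    msx <- mean(apply(X_train, 2, stats::var))
    if (msx <= 0) msx <- 1
    s2 <- vy * 0.5 / (msx * max(p * pi, 1)) * (nu - 2) / nu
    s2 <- max(s2, 1e-8)
  }
  set.seed(seed)
  fit <- .bayesb_gibbs(X_train, as.numeric(y_train),
                       as.integer(iterations), as.integer(burn_in),
                       as.integer(thin), pi, nu, s2,
                       4, vy * 0.5, update_pi)
  preds <- drop(X_test %*% fit$beta) + fit$mu
  names(preds) <- rownames(X_test)
  list(predictions = preds, mu = fit$mu, beta = fit$beta,
       inclusion_prob = fit$inclusion_prob, seed = seed)
}

#' Random-forest regression prediction
#'
#' Bagged regression trees with random feature subsampling, at the
#' regression defaults of the reference implementation (500 trees,
#' p/3 candidate features per split).
#'
#' @param X_train,X_test Score matrices.
#' @param y_train Training phenotypes.
#' @param n_trees Number of trees.
#' @param mtry Features per split (default `max(p/3, 1)`).
#' @param nodesize Minimum leaf size.
#' @param seed Seed.
#' @return List: `predictions` (named), `model`.
#' @export
rf_fit_predict <- function(X_train, y_train, X_test, n_trees = 500,
                           mtry = NULL, nodesize = 5, seed = 1L) {
  stopifnot(n_trees >= 1)
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  if (stats::var(y_train) == 0) {
    warning("constant training response: returning constant prediction")
    preds <- rep(y_train[1], nrow(X_test))
    names(preds) <- rownames(X_test)
    return(list(predictions = preds, model = NULL))
  }
  if (is.null(mtry)) mtry <- max(floor(ncol(X_train) / 3), 1)
  set.seed(seed)
  fit <- randomForest::randomForest(x = X_train, y = as.numeric(y_train),
                                    ntree = n_trees, mtry = mtry,
                                    nodesize = nodesize)
  preds <- stats::predict(fit, X_test)
  names(preds) <- rownames(X_test)
  list(predictions = preds, model = fit)
}

#' Replicated k-fold cross-validation of genomic prediction
#'
#' Per replicate, genotypes are randomly partitioned into `folds` folds;
#' the model is refit on each training split and the held-out genotypes
#' predicted. Accuracy is the Pearson correlation between phenotype and
#' prediction over the pooled validation set of the replicate (set
#' `per_fold = TRUE` for the average of per-fold correlations instead).
#'
#' @param x Complete score matrix (genotypes x SNPs) with rownames.
#' @param y Named phenotype vector (clonal values).
#' @param model `"GBLUP"`, `"BayesB"` or `"RF"`.
#' @param folds Folds per replicate (default 10).
#' @param replicates Replicates (default 10).
#' @param seed Seed governing fold assignment and model seeds.
#' @param K Optional precomputed kinship (GBLUP); computed from `x` when
#'   absent.
#' @param per_fold Use the per-fold-mean accuracy convention.
#' @param model_args Extra arguments for the model function (e.g.
#'   reduced BayesB chains).
#' @return List of class `cv_result`: `accuracy` (per-replicate vector),
#'   `mean`, `se`, `model`, `folds`, `replicates`, `seed`,
#'   `fold_assignments` (replicates x genotypes matrix).
#' @export
cross_validate <- function(x, y, model = c("GBLUP", "BayesB", "RF"),
                           folds = 10, replicates = 10, seed = 1L,
                           K = NULL, per_fold = FALSE,
                           model_args = list()) {
  model <- match.arg(model)
  x <- as.matrix(x)
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("G%03d", seq_len(nrow(x)))
  if (is.null(names(y))) names(y) <- rownames(x)
  ## canonical genotype order: results do not depend on input row order
  x <- x[order(rownames(x)), , drop = FALSE]
  y <- y[rownames(x)]
  if (!is.null(K)) K <- K[rownames(x), rownames(x)]
  n <- nrow(x)
  if (n < folds) stop("need at least as many genotypes as folds")
  if (model == "GBLUP" && is.null(K)) K <- kinship(x)
  acc <- numeric(replicates)
  assign_mat <- matrix(NA_integer_, replicates, n,
                       dimnames = list(NULL, rownames(x)))
  for (r in seq_len(replicates)) {
    set.seed(sub_seed(seed, 1000L + r))
    fold_of <- sample(rep_len(seq_len(folds), n))
    assign_mat[r, ] <- fold_of
    if (min(tabulate(fold_of, folds)) < 2)
      stop("a fold has fewer than 2 genotypes; reduce folds")
    preds <- rep(NA_real_, n); names(preds) <- rownames(x)
    fold_acc <- numeric(folds)
    for (f in seq_len(folds)) {
      test <- which(fold_of == f); train <- which(fold_of != f)
      pr <- switch(model,
        GBLUP = do.call(gblup_fit_predict,
                        c(list(y_train = y[train], K = K,
                               test_ids = rownames(x)[test]),
                          model_args))$predictions,
        BayesB = do.call(bayesb_fit_predict,
                         c(list(X_train = x[train, , drop = FALSE],
                                y_train = y[train],
                                X_test = x[test, , drop = FALSE],
                                seed = sub_seed(seed, 5000L + r * 31L + f)),
                           model_args))$predictions,
        RF = do.call(rf_fit_predict,
                     c(list(X_train = x[train, , drop = FALSE],
                            y_train = y[train],
                            X_test = x[test, , drop = FALSE],
                            seed = sub_seed(seed, 7000L + r * 31L + f)),
                       model_args))$predictions)
      preds[test] <- pr
      fold_acc[f] <- suppressWarnings(stats::cor(y[test], pr))
    }
    acc[r] <- if (per_fold) mean(fold_acc, na.rm = TRUE)
              else suppressWarnings(stats::cor(y, preds))
  }
  structure(list(accuracy = acc, mean = mean(acc),
                 se = stats::sd(acc) / sqrt(replicates),
                 model = model, folds = folds, replicates = replicates,
                 seed = seed, fold_assignments = assign_mat),
            class = "cv_result")
}
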