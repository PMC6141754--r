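#' GWAS-based greedy SNP panel selection
#'
#' Implements the six-step greedy loop for picking a low-density panel
#' from mapped SNPs: (i) select the SNP with the highest score
#' (-log10 p); (ii) exclude all SNPs within +/- d cM on the same linkage
#' group (initial d = 10); (iii) repeat while candidates remain; (iv)
#' once all SNPs are selected or excluded, halve d and re-admit SNPs at
#' positions distinct from every selected SNP and more than the relaxed
#' d from each same-LG selected SNP, taking again the highest score; (v)
#' repeat with further halving until all distinct positions are
#' exhausted; (vi) fill the remaining slots purely in descending score
#' order. Ties break by higher score, lower linkage group, lower cM,
#' then lexicographic SNP id, making the procedure fully deterministic.
#' Because selection is an ordering, panels are nested across sizes.
#'
#' @param scores Named numeric vector of per-SNP scores (names = SNP
#'   ids), e.g. -log10(p) from a scan.
#' @param map A [genetic_map()]; all scored SNPs must be mapped.
#' @param target_n Panel size.
#' @param initial_d Initial exclusion radius in cM (default 10).
#' @return data.frame of class `selected_panel`: `rank`, `snp_id`,
#'   `linkage_group`, `cM`, `score`, `d_in_force`, `phase`
#'   (`"exclusion"`, `"relaxed"` or `"fill"`).
#' @export
gwas_based_select <- function(scores, map, target_n,
                              initial_d = 10) {
  stopifnot(initial_d > 0)
  ids <- names(scores)
  if (is.null(ids)) stop("scores must be named by SNP id")
  m <- map[match(ids, map$snp_id), ]
  if (any(is.na(m$snp_id)) || !all(m$mapped))
    stop("all scored SNPs must be present and mapped in the map")
  if (target_n > length(ids)) stop("target_n exceeds the SNP count")
  n <- length(ids)
  lg <- m$linkage_group; cm <- m$cM
  ord_key <- order(-scores, lg, cm, ids)  # global tie-broken ranking
  rank_of <- integer(n); rank_of[ord_key] <- seq_len(n)

  selected <- integer(0)
  d_used <- numeric(0)
  phase_used <- character(0)
  is_sel <- rep(FALSE, n)
  excluded <- rep(FALSE, n)
  ## min same-LG distance of each SNP to the selected set, kept current
  mindist <- rep(Inf, n)
  d <- initial_d

  take <- function(j, ph) {
    selected <<- c(selected, j)
    is_sel[j] <<- TRUE
    d_used <<- c(d_used, d)
    phase_used <<- c(phase_used, ph)
    same <- lg == lg[j]
    mindist[same] <<- pmin(mindist[same], abs(cm[same] - cm[j]))
  }

  ## phase one: exclusion at the initial radius
  repeat {
    if (length(selected) >= target_n) break
    cand <- which(!excluded & !is_sel)
    if (!length(cand)) break
    j <- cand[which.min(rank_of[cand])]
    take(j, "exclusion")
    excluded <- excluded | (lg == lg[j] & abs(cm - cm[j]) <= d)
  }

  ## phase two: halve d and re-admit SNPs at distinct positions
  ## (mindist > 0) lying more than the relaxed d from every same-LG
  ## selected SNP; within a level the discipline applies to new picks too
  while (length(selected) < target_n && any(!is_sel & mindist > 0)) {
    d <- d / 2
    repeat {
      if (length(selected) >= target_n) break
      cand <- which(!is_sel & mindist > d)
      if (!length(cand)) break
      j <- cand[which.min(rank_of[cand])]
      take(j, "relaxed")
    }
  }

  ## phase three: fill by descending score
  while (length(selected) < target_n) {
    cand <- which(!is_sel)
    j <- cand[which.min(rank_of[cand])]
    take(j, "fill")
  }

  out <- data.frame(rank = seq_along(selected),
                    snp_id = ids[selected],
                    linkage_group = lg[selected], cM = cm[selected],
                    score = unname(scores[selected]),
                    d_in_force = d_used, phase = phase_used,
                    stringsAsFactors = FALSE)
  out <- out[seq_len(target_n), , drop = FALSE]
  class(out) <- c("selected_panel", "data.frame")
  out
}

#' Semi-random SNP panel selection
#'
#' Assigns a uniformly random permutation of the ranks 1..m as scores
#' (m = mapped SNP count) and runs the GWAS-based greedy selection
#' unchanged, so panels keep the same spatial spacing discipline but are
#' otherwise random. Deterministic given the seed.
#'
#' @param map A [genetic_map()]; only its mapped SNPs participate.
#' @param target_n Panel size.
#' @param seed Integer seed.
#' @param initial_d Initial exclusion radius in cM.
#' @return A `selected_panel` (see [gwas_based_select()]).
#' @export
semi_random_select <- function(map, target_n, seed = 1L,
                               initial_d = 10) {
  mapped <- map[map$mapped, ]
  if (!nrow(mapped)) stop("map contains no mapped SNPs")
  set.seed(sub_seed(seed, 31L))
  sc <- stats::setNames(sample.int(nrow(mapped)), mapped$snp_id)
  gwas_based_select(sc, map, target_n, initial_d = initial_d)
}

#' Prediction accuracy versus panel size
#'
#' For each selection procedure and panel size, runs replicated k-fold
#' cross-validation restricted to the selected SNPs and tests each
#' size's replicate accuracies against the best size's by a two-sample
#' t test; sizes with p >= 0.05 are flagged as statistically
#' indistinguishable from the best. By default the GWAS scores driving
#' the GWAS-based selection are recomputed inside each training fold so
#' marker selection never sees the validation genotypes; `paper_mode =
#' TRUE` selects once from a whole-data scan (simpler, optimistic).
#'
#' @param x Complete score matrix (genotypes x SNPs), mapped SNPs only.
#' @param y Named phenotype vector.
#' @param map A [genetic_map()] covering the columns of `x`.
#' @param panel_sizes Panel sizes; capped at the mapped SNP count.
#' @param procedures Subset of `c("gwas_based", "semi_random")`.
#' @param model Prediction model passed to [cross_validate()].
#' @param folds,replicates CV settings.
#' @param n_pc,K GWAS scan settings (kinship computed from `x` when
#'   `K` is `NULL`).
#' @param initial_d Exclusion radius for selection.
#' @param paper_mode Select from a whole-data scan instead of per-fold.
#' @param seed Seed.
#' @param model_args Passed to the prediction model.
#' @return data.frame of class `accuracy_curve`: `procedure`, `size`,
#'   `mean`, `se`, `t_stat`, `p_vs_best`, `not_worse_than_best`, plus
#'   attribute `"replicate_accuracies"` (list of per-cell vectors).
#' @export
accuracy_curve <- function(x, y, map,
                           panel_sizes = c(10, 25, 50, 100, 250, 500,
                                           1000, 2500, 5000),
                           procedures = c("gwas_based", "semi_random"),
                           model = "GBLUP", folds = 10, replicates = 10,
                           n_pc = 0, K = NULL, initial_d = 10,
                           paper_mode = FALSE, seed = 1L,
                           model_args = list()) {
  x <- as.matrix(x)
  mapped_ids <- intersect(colnames(x), map$snp_id[map$mapped])
  x <- x[, mapped_ids, drop = FALSE]
  map <- map[map$snp_id %in% mapped_ids, , drop = FALSE]
  m_tot <- ncol(x)
  panel_sizes <- sort(unique(pmin(panel_sizes, m_tot)))
  if (any(panel_sizes < 1)) stop("panel sizes must be positive")
  if (is.null(names(y))) names(y) <- rownames(x)
  y <- y[rownames(x)]
  if (is.null(K)) K <- kinship(x)

  scan_scores <- function(rows) {
    res <- mixed_model_scan(x[rows, , drop = FALSE], y[rows],
                            K = K[rows, rows], n_pc = n_pc)
    stats::setNames(res$minus_log10_p, res$snp_id)
  }
  full_panel <- list()
  if ("gwas_based" %in% procedures && paper_mode)
    full_panel$gwas_based <- gwas_based_select(scan_scores(seq_len(nrow(x))),
                                               map, m_tot, initial_d)
  if ("semi_random" %in% procedures)
    full_panel$semi_random <- semi_random_select(map, m_tot, seed = seed,
                                                 initial_d = initial_d)

  max_size <- max(panel_sizes)
  preds_cell <- list()  # per (proc, size): pooled predictions by replicate
  for (proc in procedures) for (sz in panel_sizes)
    preds_cell[[paste(proc, sz, sep = "_")]] <-
      matrix(NA_real_, replicates, nrow(x))
  for (r in seq_len(replicates)) {
    set.seed(sub_seed(seed, 2000L + r))
    fold_of <- sample(rep_len(seq_len(folds), nrow(x)))
    for (f in seq_len(folds)) {
      test <- which(fold_of == f); train <- which(fold_of != f)
      ## one nested panel per procedure per fold; sizes take prefixes
      panels <- list()
      if ("gwas_based" %in% procedures) {
        panels$gwas_based <- if (paper_mode)
          full_panel$gwas_based$snp_id[seq_len(max_size)]
        else gwas_based_select(scan_scores(train), map, max_size,
                               initial_d)$snp_id
      }
      if ("semi_random" %in% procedures)
        panels$semi_random <- full_panel$semi_random$snp_id[seq_len(max_size)]
      for (proc in procedures) for (sz in panel_sizes) {
        xs <- x[, panels[[proc]][seq_len(sz)], drop = FALSE]
        pr <- switch(model,
          GBLUP = gblup_fit_predict(y[train], kinship(xs),
                                    rownames(x)[test])$predictions,
          BayesB = do.call(bayesb_fit_predict,
                           c(list(xs[train, , drop = FALSE], y[train],
                                  xs[test, , drop = FALSE],
                                  seed = sub_seed(seed, 3000L + r * 17L + f)),
                             model_args))$predictions,
          RF = do.call(rf_fit_predict,
                       c(list(xs[train, , drop = FALSE], y[train],
                              xs[test, , drop = FALSE],
                              seed = sub_seed(seed, 4000L + r * 17L + f)),
                         model_args))$predictions,
          stop("unknown model ", model))
        preds_cell[[paste(proc, sz, sep = "_")]][r, test] <- pr
      }
    }
  }
  cells <- list()
  for (proc in procedures) for (sz in panel_sizes) {
    key <- paste(proc, sz, sep = "_")
    acc <- apply(preds_cell[[key]], 1, function(p)
      suppressWarnings(stats::cor(y, p)))
    cells[[key]] <- list(procedure = proc, size = sz, accuracy = acc)
  }
  tab <- do.call(rbind, lapply(cells, function(cl)
    data.frame(procedure = cl$procedure, size = cl$size,
               mean = mean(cl$accuracy),
               se = stats::sd(cl$accuracy) / sqrt(length(cl$accuracy)),
               stringsAsFactors = FALSE)))
  ## t test of every cell against the best cell within its procedure
  tab$t_stat <- NA_real_; tab$p_vs_best <- NA_real_
  for (proc in procedures) {
    rows <- which(tab$procedure == proc)
    best <- rows[which.max(tab$mean[rows])]
    best_acc <- cells[[rownames(tab)[best]]]$accuracy
    for (i in rows) {
      a <- cells[[rownames(tab)[i]]]$accuracy
      if (i == best || isTRUE(all.equal(a, best_acc))) {
        tab$t_stat[i] <- 0; tab$p_vs_best[i] <- 1
      } else {
        tt <- stats::t.test(a, best_acc)
        tab$t_stat[i] <- unname(tt$statistic)
        tab$p_vs_best[i] <- tt$p.value
      }
    }
  }
  tab$not_worse_than_best <- tab$p_vs_best >= 0.05
  rownames(tab) <- NULL
  attr(tab, "replicate_accuracies") <-
    lapply(cells, function(cl) cl$accuracy)
  class(tab) <- c("accuracy_curve", "data.frame")
  tab
}
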