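#' Fit the clonal mixed model to trial records
#'
#' Plot-mean records from replicated clonal trials are modeled as
#' `value = mu + site + block-in-site + genotype + genotype-x-site +
#' residual`, with site and block-in-site fixed and genotype,
#' genotype-by-site and residual random. Variance components are
#' estimated by REML and genotype-level genetic (clonal) values are the
#' BLUPs of the genotype effect. The model reduces automatically for
#' single-site (garden) data: the site, block and genotype-by-site terms
#' are dropped when inestimable (one site, or one block per site).
#'
#' @param records data.frame with columns `site`, `block`, `genotype`,
#'   `value` (block may be omitted for garden data).
#' @param ramet_mean If `TRUE`, bypass the mixed model and return the
#'   plain per-genotype mean (the garden-trait convention when replication
#'   is balanced and small).
#' @return List of class `clonal_fit`: `clonal_values` (named vector of
#'   genotype BLUPs, or means in `ramet_mean` mode), `varcomp` (named
#'   vector: genotype, genotype_x_site, residual), `fixed` (fixed-effect
#'   estimates), `logLik_reml`, `model` (the lme4 fit or `NULL`),
#'   `formula_used`.
#' @export
fit_clonal_model <- function(records, ramet_mean = FALSE) {
  need <- c("site", "genotype", "value")
  if (!all(need %in% names(records)))
    stop("records need columns site, genotype, value")
  if (!all(is.finite(records$value))) stop("non-finite responses")
  records$site <- factor(records$site)
  records$genotype <- factor(records$genotype)
  n_geno <- nlevels(records$genotype)
  if (n_geno < 2) stop("need at least 2 genotypes")
  if (ramet_mean) {
    cv <- tapply(records$value, records$genotype, mean)
    return(structure(list(clonal_values = cv - mean(cv),
                          varcomp = NULL, fixed = c(mu = mean(cv)),
                          logLik_reml = NA, model = NULL,
                          formula_used = "per-genotype ramet mean"),
                     class = "clonal_fit"))
  }
  n_site <- nlevels(records$site)
  has_block <- "block" %in% names(records) &&
    length(unique(records$block)) > 1 && n_site >= 1
  multi_site <- n_site > 1
  ## genotype-x-site needs replication within genotype-site cells or
  ## multiple sites; drop for single-site data where it aliases residual
  terms_fixed <- c(if (multi_site) "site",
                   if (has_block && multi_site) "site:block"
                   else if (has_block) "block")
  terms_rand <- c("(1 | genotype)",
                  if (multi_site) "(1 | genotype:site)")
  rhs <- paste(c(if (length(terms_fixed)) terms_fixed else "1",
                 terms_rand), collapse = " + ")
  form <- stats::as.formula(paste("value ~", rhs))
  if ("block" %in% names(records)) records$block <- factor(records$block)
  fit <- lme4::lmer(form, data = records, REML = TRUE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  varcomp <- c(genotype = getv("genotype"),
               genotype_x_site = getv("genotype:site"),
               residual = getv("Residual"))
  blup <- lme4::ranef(fit)$genotype
  cv <- stats::setNames(blup[["(Intercept)"]], rownames(blup))
  cv <- cv[levels(records$genotype)]
  names(cv) <- levels(records$genotype)
  cv[is.na(cv)] <- 0
  structure(list(clonal_values = cv, varcomp = varcomp,
                 fixed = lme4::fixef(fit),
                 logLik_reml = as.numeric(stats::logLik(fit)),
                 model = fit, formula_used = deparse(form)),
            class = "clonal_fit")
}

#' Likelihood-ratio test of the genetic (clonal) effect
#'
#' Compares maximum-likelihood fits of the trial model with and without
#' the genotype term. The deviance is `-2 * (logL_without - logL_with)`
#' and is referred to a chi-square distribution with 1 degree of freedom
#' (the conventional rule; since the null puts the variance on the
#' boundary this is conservative — `boundary_correction = TRUE` applies
#' the 50:50 chi0/chi1 mixture instead).
#'
#' @param records As in [fit_clonal_model()].
#' @param boundary_correction Use the mixture reference distribution.
#' @return List of class `lrt_result`: `deviance`, `p_value`,
#'   `logLik_with`, `logLik_without`.
#' @export
genetic_effect_lrt <- function(records, boundary_correction = FALSE) {
  records$site <- factor(records$site)
  records$genotype <- factor(records$genotype)
  if (nlevels(records$genotype) < 2) stop("need at least 2 genotypes")
  n_site <- nlevels(records$site)
  multi_site <- n_site > 1
  has_block <- "block" %in% names(records) &&
    length(unique(records$block)) > 1
  if (has_block) records$block <- factor(records$block)
  terms_fixed <- c(if (multi_site) "site",
                   if (has_block && multi_site) "site:block"
                   else if (has_block) "block")
  fx <- if (length(terms_fixed)) paste(terms_fixed, collapse = " + ")
        else "1"
  rand_common <- if (multi_site) " + (1 | genotype:site)" else ""
  f_with <- stats::as.formula(
    paste("value ~", fx, "+ (1 | genotype)", rand_common))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit_with <- lme4::lmer(f_with, data = records, REML = FALSE,
                         control = ctrl)
  if (multi_site) {
    f_wo <- stats::as.formula(paste("value ~", fx, "+ (1 | genotype:site)"))
    fit_wo <- lme4::lmer(f_wo, data = records, REML = FALSE,
                         control = ctrl)
  } else {
    f_wo <- stats::as.formula(paste("value ~", fx))
    fit_wo <- stats::lm(f_wo, data = records)
  }
  l1 <- as.numeric(stats::logLik(fit_wo))
  l2 <- as.numeric(stats::logLik(fit_with))
  dev <- max(-2 * (l1 - l2), 0)
  p <- stats::pchisq(dev, df = 1, lower.tail = FALSE)
  if (boundary_correction) p <- ifelse(dev == 0, 1, p / 2)
  structure(list(deviance = dev, p_value = p,
                 logLik_with = l2, logLik_without = l1),
            class = "lrt_result")
}
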