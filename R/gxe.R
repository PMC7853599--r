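#' Genotype-by-year mixed model for a trait
#'
#' Fits the multi-year model `value = mu + G + Y + GY + e` on spatially
#' corrected plot values, with year fixed, the genotype-by-year interaction
#' random, and genotype either fixed (yielding BLUEs) or random (yielding
#' BLUPs and the genotypic variance component).  Only genotypes present in
#' every year enter.  Variance components are estimated by REML
#' ([lme4::lmer()]); with an exactly noise-free trait the model degenerates
#' and the fit falls back to ordinary least squares with zero variance
#' components.
#'
#' @param data Data frame with columns `genotype_id`, `year`, `value` (one
#'   row per plot).
#' @param genotype_role `"fixed"` (BLUEs) or `"random"` (BLUPs + sigma2_g).
#' @return Object of class `gxe_fit`: `blues` or `blups` (named vector),
#'   `year_effects`, `varcomp` (list `sigma2_g`, `sigma2_gy`, `sigma2_e`,
#'   `n_years`, `n_reps`), `mu`, `genotype_role`, `n_genotypes`, `dropped`
#'   (genotypes absent in some year).
#' @export
fit_gxe <- function(data, genotype_role = c("fixed", "random")) {
  genotype_role <- match.arg(genotype_role)
  stopifnot(all(c("genotype_id", "year", "value") %in% names(data)))
  data <- data[is.finite(data$value), ]
  years <- unique(data$year)
  if (length(years) < 2) stop("GY not identifiable: need at least 2 years")
  per_gen <- tapply(data$year, data$genotype_id,
                    function(y) length(unique(y)))
  keep <- names(per_gen)[per_gen == length(years)]
  dropped <- setdiff(unique(data$genotype_id), keep)
  data <- data[data$genotype_id %in% keep, ]
  if (length(keep) < 2) stop("need at least 2 genotypes present in all years")
  df <- data.frame(value = data$value,
                   genotype = factor(data$genotype_id),
                   year = factor(data$year))
  df$gy <- interaction(df$genotype, df$year, drop = TRUE)
  n_reps <- stats::median(table(df$gy))
  # exactly deterministic data: REML degenerates, use OLS directly
  ols <- stats::lm(value ~ genotype + year, data = df)
  noise_free <- stats::sigma(ols) < 1e-8 * max(stats::sd(df$value), 1e-12)

  mu_blue <- function(fixef_vec, g_lv, y_lv) {
    ge <- c(0, fixef_vec[paste0("genotype", g_lv[-1])])
    ye <- c(0, fixef_vec[paste0("year", y_lv[-1])])
    ge[is.na(ge)] <- 0; ye[is.na(ye)] <- 0
    stats::setNames(unname(fixef_vec["(Intercept)"]) + ge + mean(ye), g_lv)
  }
  g_lv <- levels(df$genotype); y_lv <- levels(df$year)

  if (noise_free) {
    blues <- mu_blue(stats::coef(ols), g_lv, y_lv)
    vc <- list(sigma2_g = stats::var(blues), sigma2_gy = 0, sigma2_e = 0,
               n_years = length(y_lv), n_reps = as.integer(n_reps))
    out <- list(mu = mean(blues), year_effects = NULL, varcomp = vc,
                genotype_role = genotype_role, n_genotypes = length(g_lv),
                dropped = dropped)
    if (genotype_role == "fixed") {
      out$blues <- blues
      out$varcomp$sigma2_g <- NA_real_
    } else {
      out$blups <- blues
    }
    class(out) <- "gxe_fit"
    return(out)
  }

  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            optCtrl = list(rhobeg = 0.2, rhoend = 2e-10),
                            check.conv.singular = "ignore")
  if (genotype_role == "fixed") {
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(value ~ genotype + year + (1 | gy), data = df, REML = TRUE,
                 control = ctrl)))
    vcs <- as.data.frame(lme4::VarCorr(fit))
    s2gy <- vcs$vcov[vcs$grp == "gy"]
    s2e <- vcs$vcov[vcs$grp == "Residual"]
    blues <- mu_blue(lme4::fixef(fit), g_lv, y_lv)
    out <- list(
      blues = blues,
      mu = mean(blues),
      year_effects = stats::setNames(
        c(0, lme4::fixef(fit)[paste0("year", y_lv[-1])]), y_lv),
      varcomp = list(sigma2_g = NA_real_, sigma2_gy = max(s2gy, 0),
                     sigma2_e = max(s2e, 0), n_years = length(y_lv),
                     n_reps = as.integer(n_reps)),
      genotype_role = genotype_role, n_genotypes = length(g_lv),
      dropped = dropped)
  } else {
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(value ~ year + (1 | genotype) + (1 | gy), data = df,
                 REML = TRUE, control = ctrl)))
    vcs <- as.data.frame(lme4::VarCorr(fit))
    s2g <- vcs$vcov[vcs$grp == "genotype"]
    s2gy <- vcs$vcov[vcs$grp == "gy"]
    s2e <- vcs$vcov[vcs$grp == "Residual"]
    fe <- lme4::fixef(fit)
    ye <- stats::setNames(c(0, fe[paste0("year", y_lv[-1])]), y_lv)
    mu <- unname(fe["(Intercept)"]) + mean(ye)
    re <- lme4::ranef(fit)$genotype
    blups <- stats::setNames(mu + re[g_lv, 1], g_lv)
    out <- list(
      blups = blups, mu = mu, year_effects = ye,
      varcomp = list(sigma2_g = max(s2g, 0), sigma2_gy = max(s2gy, 0),
                     sigma2_e = max(s2e, 0), n_years = length(y_lv),
                     n_reps = as.integer(n_reps)),
      genotype_role = genotype_role, n_genotypes = length(g_lv),
      dropped = dropped)
  }
  class(out) <- "gxe_fit"
  out
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat(sprintf("Genotype-by-year fit (genotype %s): %d genotypes, %d years\n",
              x$genotype_role, x$n_genotypes, x$varcomp$n_years))
  vc <- x$varcomp
  cat(sprintf("  sigma2_g = %s, sigma2_gy = %.4g, sigma2_e = %.4g\n",
              if (is.na(vc$sigma2_g)) "(genotype fixed)" else
                sprintf("%.4g", vc$sigma2_g), vc$sigma2_gy, vc$sigma2_e))
  if (!is.na(vc$sigma2_g))
    cat(sprintf("  H2 = %.2f\n", heritability(vc)))
  invisible(x)
}

#' @export
coef.gxe_fit <- function(object, ...) {
  if (object$genotype_role == "fixed") object$blues else object$blups
}

#' Broad-sense heritability from variance components
#'
#' `H2 = s2_g / (s2_g + s2_gy / n_years + s2_e / (n_years * n_reps))` —
#' the share of genotypic variance in the variance of a genotype mean over
#' `n_years` years with `n_reps` replicates per year.
#'
#' @param vc A `varcomp` list (as in [fit_gxe()]) or the genotypic variance
#'   `sigma2_g` when components are given separately.
#' @param sigma2_gy,sigma2_e Interaction and residual variances (when `vc`
#'   is numeric).
#' @param n_years,n_reps Design sizes.
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(vc, sigma2_gy = NULL, sigma2_e = NULL,
                         n_years = 3, n_reps = 2) {
  if (is.list(vc)) {
    sigma2_g <- vc$sigma2_g; sigma2_gy <- vc$sigma2_gy
    sigma2_e <- vc$sigma2_e
    n_years <- vc$n_years %||% n_years
    n_reps <- vc$n_reps %||% n_reps
  } else sigma2_g <- vc
  stopifnot(sigma2_g >= 0, sigma2_gy >= 0, sigma2_e >= 0)
  den <- sigma2_g + sigma2_gy / n_years + sigma2_e / (n_years * n_reps)
  if (den <= 0) stop("all variance components are zero")
  sigma2_g / den
}

#' Heritability for single-replicate traits
#'
#' For traits scored once per environment the interaction term is not
#' separable; the model omits it and divides the residual variance by the
#' number of year-site replications: `H2 = s2_g / (s2_g + s2_e / n_env)`.
#'
#' @param sigma2_g Genotypic variance.
#' @param sigma2_e Residual variance.
#' @param n_env Number of environments (year-site replications).
#' @return Heritability in `[0, 1]`.
#' @export
heritability_single_rep <- function(sigma2_g, sigma2_e, n_env = 3) {
  stopifnot(sigma2_g >= 0, sigma2_e >= 0, n_env >= 1)
  den <- sigma2_g + sigma2_e / n_env
  if (den <= 0) stop("all variance components are zero")
  sigma2_g / den
}

#' Percentage of total variance per component
#'
#' @param vc A `varcomp` list or numeric vector of components.
#' @return Named numeric vector of percentages summing to 100.
#' @export
percent_variance <- function(vc) {
  x <- if (is.list(vc))
    c(genotype = vc$sigma2_g, genotype_year = vc$sigma2_gy,
      residual = vc$sigma2_e)
  else vc
  tot <- sum(x)
  if (!is.finite(tot) || tot <= 0) stop("total variance must be positive")
  100 * x / tot
}

#' Pearson correlation matrix of genotype-level trait values
#'
#' Pairwise-complete Pearson correlations with two-sided t-based p-values;
#' traits with zero variance give `NA` entries and a warning.
#'
#' @param blues Data frame or matrix of genotype-level values, one column
#'   per trait (non-numeric columns are dropped).
#' @return List with matrices `r`, `p` and `n`.
#' @export
trait_correlations <- function(blues) {
  x <- as.data.frame(blues)
  x <- x[vapply(x, is.numeric, logical(1))]
  m <- as.matrix(x)
  k <- ncol(m)
  if (nrow(m) < 3) stop("need at least 3 genotypes")
  const <- apply(m, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  if (any(const))
    warning("constant trait(s): ", paste(colnames(m)[const], collapse = ", "))
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(colnames(m),
                                                        colnames(m)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cc <- stats::complete.cases(m[, i], m[, j])
    n[i, j] <- sum(cc)
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    if (const[i] || const[j] || n[i, j] < 3) next
    ct <- stats::cor.test(m[cc, i], m[cc, j])
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(r = r, p = p, n = n)
}

#' Cross-year prediction accuracy of a trait model
#'
#' Trains a linear model on one year's genotype-level values and reports the
#' squared Pearson correlation between predictions and the observed values
#' of an independent year, over the shared genotypes.
#'
#' @param train,test Data frames of genotype-level values; must contain
#'   `genotype_id`, the response and the predictors.
#' @param formula Model formula, e.g. `fh ~ slope + vigour + gdd_se`.
#' @return Squared Pearson correlation (R2).
#' @export
cross_year_r2 <- function(train, test, formula) {
  shared <- intersect(train$genotype_id, test$genotype_id)
  if (length(shared) < 10) stop("need at least 10 shared genotypes")
  tr <- train[match(shared, train$genotype_id), ]
  te <- test[match(shared, test$genotype_id), ]
  fit <- stats::lm(formula, data = tr)
  pred <- stats::predict(fit, newdata = te)
  obs <- stats::model.response(stats::model.frame(formula, data = te))
  stats::cor(pred, obs, use = "complete.obs")^2
}

#' Bonferroni-corrected significance threshold on the -log10 scale
#'
#' @param alpha Pointwise significance level.
#' @param n_tests Number of tests.
#' @return `-log10(alpha / n_tests)`.
#' @export
bonferroni_neglog_threshold <- function(alpha = 0.05, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  -log10(alpha / n_tests)
}
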