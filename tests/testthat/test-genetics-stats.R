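test_that("noiseless additive data give exact BLUEs and zero components", {
  g <- stats::setNames(c(1, 2, 4), c("A", "B", "C"))
  ye <- stats::setNames(c(0, 1), c(2015, 2016))
  d <- expand.grid(genotype_id = names(g), year = names(ye), rep = 1:2)
  d$value <- 10 + g[d$genotype_id] + ye[as.character(d$year)]
  fx <- fit_gxe(d, "fixed")
  expect_equal(unname(coef(fx)[c("A", "B", "C")]),
               unname(10 + g + mean(ye)), tolerance = 1e-9)
  expect_equal(fx$varcomp$sigma2_gy, 0)
  expect_equal(fx$varcomp$sigma2_e, 0)
  rn <- fit_gxe(d, "random")
  expect_equal(unname(coef(rn)[c("A", "B", "C")]),
               unname(10 + g + mean(ye)), tolerance = 1e-9)
  expect_error(fit_gxe(d[d$year == 2015, ]), "GY not identifiable")
})

test_that("REML on balanced data equals the expected-mean-squares oracle", {
  d <- make_balanced_gxe(n_genotypes = 80, seed = 21)
  rn <- fit_gxe(d, "random")
  ems <- ems_varcomp(d)
  for (cmp in c("sigma2_g", "sigma2_gy", "sigma2_e"))
    expect_equal(rn$varcomp[[cmp]], ems[[cmp]],
                 tolerance = 1e-6)
})

test_that("only genotypes present in all years enter and BLUPs shrink", {
  d <- make_balanced_gxe(n_genotypes = 40, seed = 22)
  d <- d[!(d$genotype_id == "G001" & d$year == 2015), ]
  fx <- fit_gxe(d, "fixed")
  expect_false("G001" %in% names(coef(fx)))
  expect_true("G001" %in% fx$dropped)
  rn <- fit_gxe(d, "random")
  expect_lt(stats::var(coef(rn)), stats::var(coef(fx)))
})

test_that("variance-component recovery is unbiased at trial scale", {
  est <- sapply(1:3, function(s) {
    d <- make_balanced_gxe(n_genotypes = 200, s2g = 1, s2gy = 0.5,
                           s2e = 0.25, seed = 100 + s)
    unlist(fit_gxe(d, "random")$varcomp[c("sigma2_g", "sigma2_gy",
                                          "sigma2_e")])
  })
  m <- rowMeans(est)
  expect_lt(abs(m[1] - 1) / 1, 0.15)
  expect_lt(abs(m[2] - 0.5) / 0.5, 0.15)
  expect_lt(abs(m[3] - 0.25) / 0.25, 0.15)
})

test_that("heritability obeys its limits and monotonicity", {
  expect_equal(heritability(1, 0, 0), 1)
  expect_equal(heritability(0, 1, 1), 0)
  expect_error(heritability(0, 0, 0), "zero")
  h <- heritability(2, 1, 1, n_years = 3, n_reps = 2)
  expect_gt(h, heritability(2, 2, 1, n_years = 3, n_reps = 2))
  expect_gt(h, heritability(2, 1, 2, n_years = 3, n_reps = 2))
  expect_lt(h, heritability(3, 1, 1, n_years = 3, n_reps = 2))
  set.seed(1)
  for (i in 1:20) {
    v <- stats::runif(3)
    expect_true(heritability(v[1], v[2], v[3]) >= 0 &&
                  heritability(v[1], v[2], v[3]) <= 1)
  }
})

test_that("single-replicate heritability follows the reduced formula", {
  expect_equal(heritability_single_rep(1, 0), 1)
  expect_equal(heritability_single_rep(1, 1, n_env = 1), 0.5)
  expect_equal(heritability_single_rep(2, 3, n_env = 3), 2 / 3)
})

test_that("variance shares sum to 100 percent", {
  expect_equal(unname(percent_variance(c(1, 1, 1))),
               rep(100 / 3, 3), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:20) {
    v <- stats::runif(3, 0.01, 10)
    expect_equal(sum(percent_variance(v)), 100, tolerance = 1e-9)
  }
  expect_error(percent_variance(c(0, 0, 0)), "positive")
})

test_that("trait correlations are symmetric with unit diagonal", {
  set.seed(3)
  x <- stats::rnorm(50)
  tab <- data.frame(a = x, b = -x, c = stats::rnorm(50))
  tc <- trait_correlations(tab)
  expect_equal(unname(diag(tc$r)), c(1, 1, 1))
  expect_equal(tc$r["a", "b"], -1, tolerance = 1e-12)
  expect_equal(tc$r, t(tc$r))
  expect_true(all(tc$p[upper.tri(tc$p)] >= 0))
  tab$d <- 1
  expect_warning(trait_correlations(tab), "constant")
})

test_that("a configured slope-height dependence is detected at its magnitude", {
  set.seed(4)
  n <- 400
  slope <- stats::rnorm(n)
  fh <- 0.6 * slope + sqrt(1 - 0.6^2) * stats::rnorm(n)
  tc <- trait_correlations(data.frame(slope = slope, fh = fh))
  expect_lt(abs(tc$r["slope", "fh"] - 0.6), 0.1)
  expect_lt(tc$p["slope", "fh"], 1e-6)
})

test_that("height model recovers a pure single-predictor signal", {
  set.seed(5)
  d <- data.frame(slope = stats::rnorm(60), vigour = stats::rnorm(60),
                  gdd_se = stats::rnorm(60))
  d$fh <- 2 + 3 * d$slope
  hm <- fit_height_model(d, response = "fh",
                         predictors = c("slope", "vigour", "gdd_se"))
  expect_equal(hm$r_squared, 1, tolerance = 1e-9)
  ss <- hm$anova[, "Sum Sq"]
  names(ss) <- rownames(hm$anova)
  expect_gt(ss["slope"], 1e6 * max(ss[c("vigour", "gdd_se")], 1e-12))
})

test_that("type II sums of squares match hand computation on a 2x2 factorial", {
  # balanced 8-row design: effects A = 2, B = 1, interaction 0.5
  d <- expand.grid(A = c(0, 1), B = c(0, 1), rep = 1:2)
  d$y <- 1 + 2 * d$A + 1 * d$B + 0.5 * d$A * d$B +
    c(0.1, -0.1, 0.05, -0.05, -0.1, 0.1, -0.05, 0.05)
  hm <- fit_height_model(d, response = "y", predictors = c("A", "B"))
  ss <- hm$anova[, "Sum Sq"]
  names(ss) <- rownames(hm$anova)
  # independent computation via residual sums of squares of nested fits
  rss <- function(f) sum(stats::residuals(stats::lm(f, data = d))^2)
  ss_a <- rss(y ~ B) - rss(y ~ A + B)
  ss_b <- rss(y ~ A) - rss(y ~ A + B)
  ss_ab <- rss(y ~ A + B) - rss(y ~ A * B)
  expect_equal(unname(ss["A"]), ss_a, tolerance = 1e-10)
  expect_equal(unname(ss["B"]), ss_b, tolerance = 1e-10)
  expect_equal(unname(ss["A:B"]), ss_ab, tolerance = 1e-10)
  # balanced orthogonal design: type II equals sequential type I
  a1 <- stats::anova(stats::lm(y ~ A * B, data = d))
  expect_equal(unname(ss[c("A", "B", "A:B")]),
               a1[c("A", "B", "A:B"), "Sum Sq"], tolerance = 1e-10)
})

test_that("singular terms are dropped and named", {
  set.seed(6)
  d <- data.frame(slope = stats::rnorm(40), vigour = stats::rnorm(40))
  d$dup <- d$slope  # exact collinearity
  d$fh <- 1 + d$slope + 0.5 * d$vigour + stats::rnorm(40, 0, 0.1)
  hm <- fit_height_model(d, response = "fh",
                         predictors = c("slope", "vigour", "dup"),
                         interactions = FALSE)
  expect_true("dup" %in% hm$dropped_terms)
  expect_false(anyNA(coef(hm)))
})

test_that("simulated dwarfing alleles surface in the height model", {
  cfg <- trial_config(n_genotypes = 120, seed = 31)
  run <- run_pipeline(cfg)
  hm <- run$height_model
  expect_gt(hm$r_squared, 0.8)
  p <- hm$anova[, "Pr(>F)"]
  names(p) <- rownames(hm$anova)
  expect_lt(p["slope"], 1e-6)
  expect_lt(p["vigour"], 1e-6)
  expect_lt(p["rht_d1"], 0.05)
  expect_lt(p["rht_b1"], 0.05)
})

test_that("cross-year prediction accuracy behaves at its limits", {
  set.seed(7)
  d <- data.frame(genotype_id = sprintf("G%02d", 1:40),
                  slope = stats::rnorm(40))
  d$fh <- 1 + 2 * d$slope
  expect_equal(cross_year_r2(d, d, fh ~ slope), 1, tolerance = 1e-12)
  d2 <- d
  d2$fh <- stats::rnorm(40)  # prediction uncorrelated with truth
  expect_lt(cross_year_r2(d, d2, fh ~ slope), 0.15)
  expect_error(cross_year_r2(d[1:5, ], d2[6:10, ], fh ~ slope), "shared")
})

test_that("the multiple-testing threshold follows the Bonferroni rule", {
  expect_equal(round(bonferroni_neglog_threshold(0.05, 1), 2), 1.30)
  expect_equal(round(bonferroni_neglog_threshold(0.001, 13450), 2), 7.13)
  expect_error(bonferroni_neglog_threshold(1.5, 10), "alpha")
  expect_error(bonferroni_neglog_threshold(0.05, 0), "n_tests")
})
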