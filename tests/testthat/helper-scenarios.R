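# Shared scenario builders for the test suite.  All fixtures are generated
# in code; seeds are fixed so every run is deterministic.

# A fully deterministic trial: constant temperature, identical years, no
# measurement noise, no genotype-by-year deviations, no spatial field.
# Under constant 14 C the thermal elongation window is moved so that it
# still falls inside the measurement campaign.
noiseless_config <- function(n_genotypes = 20, seed = 42) {
  trial_config(
    n_genotypes = n_genotypes, seed = seed,
    noise_sd = 0, amplitude = 0, ar_sd = 0,
    year_temp_shift = stats::setNames(c(0, 0, 0), 2015:2017),
    gy_sd = c(slope = 0, vigour = 0, window = 0),
    start_gdd_mean = 2620
  )
}

# Deterministic seasonal weather, identical in every year: no AR(1) noise,
# no measurement noise, no genotype-by-year deviations.  Every trait is then
# an exact function of genotype, so heritability is exactly one.
deterministic_config <- function(n_genotypes = 15, seed = 42) {
  trial_config(
    n_genotypes = n_genotypes, seed = seed,
    noise_sd = 0, ar_sd = 0,
    year_temp_shift = stats::setNames(c(0, 0, 0), 2015:2017),
    gy_sd = c(slope = 0, vigour = 0, window = 0)
  )
}

# Realistic weather but no observation noise and no genotype-by-year
# deviations: the growth law should be recovered exactly from each plot.
exact_recovery_config <- function(n_genotypes = 15, seed = 42) {
  trial_config(
    n_genotypes = n_genotypes, seed = seed,
    noise_sd = 0,
    gy_sd = c(slope = 0, vigour = 0, window = 0)
  )
}

# Single-year, single-date plot values with known genotype means, for
# spatial-model tests.
make_plot_values <- function(n_genotypes = 40, noise_sd = 0, seed = 1) {
  set.seed(seed)
  ids <- sprintf("G%03d", seq_len(n_genotypes))
  lay <- layout_augmented_design(ids)
  gmeans <- stats::setNames(stats::rnorm(n_genotypes, 900, 100), ids)
  val <- gmeans[lay$genotype_id] + stats::rnorm(nrow(lay), 0, noise_sd)
  list(values = data.frame(plot_id = lay$plot_id,
                           genotype_id = lay$genotype_id,
                           row = lay$row, range = lay$range,
                           value = as.numeric(val),
                           stringsAsFactors = FALSE),
       layout = lay, gmeans = gmeans)
}

# Centred quadratic bowl over the grid, in the units of the plot values.
bowl_surface <- function(depth = 60, r0 = 20, c0 = 20, scale = 20) {
  function(row, range) depth * (((row - r0) / scale)^2 +
                                ((range - c0) / scale)^2 - 1)
}

# Plot-level response fits with independent true slope and vigour defined
# at a known critical temperature.
make_synthetic_fits <- function(n = 500, t_crit = 9, slope_sd = 0.27,
                                vigour_sd = 1, seed = 1) {
  set.seed(seed)
  s <- stats::rnorm(n, 1.2, slope_sd)
  v <- stats::rnorm(n, 16, vigour_sd)
  data.frame(plot_id = sprintf("P%04d", seq_len(n)),
             slope = s, intercept0 = v - t_crit * s, ok = TRUE)
}

# Balanced genotype x year x replicate table with known variance components.
make_balanced_gxe <- function(n_genotypes = 300, n_years = 3, n_reps = 2,
                              s2g = 1, s2gy = 0.5, s2e = 0.25, seed = 1) {
  set.seed(seed)
  g <- stats::rnorm(n_genotypes, 0, sqrt(s2g))
  ye <- stats::rnorm(n_years, 0, 1)
  gy <- matrix(stats::rnorm(n_genotypes * n_years, 0, sqrt(s2gy)),
               n_genotypes, n_years)
  d <- expand.grid(gi = seq_len(n_genotypes), yi = seq_len(n_years),
                   rep = seq_len(n_reps))
  d$genotype_id <- sprintf("G%03d", d$gi)
  d$year <- 2014 + d$yi
  d$value <- 10 + g[d$gi] + ye[d$yi] + gy[cbind(d$gi, d$yi)] +
    stats::rnorm(nrow(d), 0, sqrt(s2e))
  attr(d, "true_g") <- g
  d
}

# Expected-mean-squares estimators for the balanced two-way mixed model.
ems_varcomp <- function(d) {
  m <- tapply(d$value, list(d$genotype_id, d$year), mean)
  ng <- nrow(m); ny <- ncol(m)
  nr <- nrow(d) / (ng * ny)
  gm <- rowMeans(m); ym <- colMeans(m); mu <- mean(m)
  msg <- ny * nr * stats::var(gm)
  msgy <- nr * sum((m - outer(gm, rep(1, ny)) - outer(rep(1, ng), ym) +
                      mu)^2) / ((ng - 1) * (ny - 1))
  cell <- m[cbind(match(d$genotype_id, rownames(m)),
                  match(d$year, colnames(m)))]
  mse <- sum((d$value - cell)^2) / (ng * ny * (nr - 1))
  list(sigma2_g = (msg - msgy) / (ny * nr),
       sigma2_gy = (msgy - mse) / nr,
       sigma2_e = mse)
}
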