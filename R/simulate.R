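#' Simulate a daily air-temperature series for one growing season
#'
#' Generates daily mean air temperatures from sowing onwards as an annual
#' cosine (minimum in mid January, maximum in mid July) plus stationary AR(1)
#' weather noise.  The cosine is offset so that the expected mean over the
#' measurement window equals `mean_temp`, i.e. `mean_temp` is the seasonal
#' mean temperature during stem elongation, not the annual mean.
#'
#' @param year Label for the season (integer or character).
#' @param sowing_date Sowing date (`Date` or ISO-8601 string).
#' @param n_days Number of days to simulate from sowing (inclusive).
#' @param mean_temp Target mean temperature (degree C) over the measurement
#'   window.
#' @param amplitude Half-range of the annual temperature cycle (degree C);
#'   0 gives a flat seasonal profile.
#' @param ar_rho Lag-1 autocorrelation of the AR(1) weather noise.
#' @param ar_sd Marginal standard deviation (degree C) of the AR(1) noise.
#' @param window Measurement window in days after sowing, `c(first, last)`;
#'   used only to anchor the seasonal mean.
#' @param bounds Plausibility band for daily means (degree C); values are
#'   clamped to it.
#' @param seed Optional integer seed; the draw is reproducible given the seed.
#'
#' @return A data frame of class `temperature_series` with columns `year`,
#'   `date` and `tmean_c`, and attributes `sowing_date` and `window`.
#' @export
simulate_temperature <- function(year, sowing_date, n_days = 250,
                                 mean_temp = 14, amplitude = 8,
                                 ar_rho = 0.6, ar_sd = 3,
                                 window = c(170, 245),
                                 bounds = c(-5, 30), seed = NULL) {
  if (n_days <= 0) stop("simulation window length must be positive")
  stopifnot(ar_sd >= 0, abs(ar_rho) < 1, length(window) == 2)
  sowing_date <- as.Date(sowing_date)
  dates <- sowing_date + seq_len(n_days) - 1L
  # seasonal cycle phased on days after sowing (minimum ~3 months in for an
  # autumn sowing, maximum in mid-summer) so equal-length seasons share one
  # deterministic profile
  base <- amplitude * cos(2 * pi * (seq_len(n_days) - 274) / 365)
  in_window <- seq_len(n_days) >= window[1] & seq_len(n_days) <= window[2]
  if (!any(in_window)) in_window <- rep(TRUE, n_days)
  offset <- mean_temp - mean(base[in_window])
  if (!is.null(seed)) set.seed(seed)
  eps <- if (ar_sd > 0) {
    innov_sd <- ar_sd * sqrt(1 - ar_rho^2)
    e <- numeric(n_days)
    e[1] <- stats::rnorm(1, 0, ar_sd)
    z <- stats::rnorm(n_days - 1, 0, innov_sd)
    for (d in seq_len(n_days - 1)) e[d + 1] <- ar_rho * e[d] + z[d]
    e
  } else {
    numeric(n_days)
  }
  tmean <- pmin(pmax(offset + base + eps, bounds[1]), bounds[2])
  out <- data.frame(year = year, date = dates, tmean_c = tmean)
  attr(out, "sowing_date") <- sowing_date
  attr(out, "window") <- window
  class(out) <- c("temperature_series", "data.frame")
  out
}

#' Draw genotype-level ground-truth parameters
#'
#' Each genotype gets a temperature-response slope (mm per degree C per day),
#' a vigour (growth rate at the reference temperature, mm per day), a thermal
#' window for stem elongation (start/end in growing degree-days after sowing)
#' and biallelic labels at the dwarfing loci Rht-B1 and Rht-D1 and the
#' photoperiod locus Ppd-D1.  Allele effects act on vigour (Rht) and on the
#' start of elongation (Ppd), so final height inherits them.
#'
#' The nominal final height is derived from the other parameters: expected
#' elongation gain at the nominal window temperature, scaled so that the
#' pre-elongation canopy sits at `baseline_frac` of final height, with a small
#' margin (`plateau_margin`) so the height cap is reached and a plateau forms.
#'
#' @param n_genotypes Number of genotypes.
#' @param slope_mean,slope_sd Population mean / genotypic sd of the slope.
#' @param vigour_mean,vigour_sd Population mean / genotypic sd of vigour.
#' @param t_ref Reference temperature (degree C) at which vigour is defined;
#'   slope and vigour are drawn independently, so this is the generative
#'   critical temperature.
#' @param start_gdd_mean,start_gdd_sd Thermal time at elongation onset.
#' @param se_gdd_mean,se_gdd_sd Thermal duration of elongation.
#' @param nominal_temp Nominal window temperature used to convert the thermal
#'   window into expected calendar duration when deriving final height.
#' @param baseline_frac Pre-elongation canopy height as a fraction of final
#'   height.
#' @param plateau_margin Fraction of the expected gain used as the height cap.
#' @param allele_freq Mutant-allele frequencies, named `rht_b1`, `rht_d1`,
#'   `ppd_d1`.
#' @param allele_effects Additive effects of the mutant alleles: `rht_b1`,
#'   `rht_d1` on vigour (mm per day), `ppd_d1` on start of elongation
#'   (degree C days), and `rht_b1_fh`, `rht_d1_fh` direct shifts of final
#'   height (mm) beyond what the slower growth already implies.  Set to
#'   zeros to switch allele effects off.
#' @param seed Optional integer seed.
#'
#' @return Data frame with one row per genotype: `genotype_id`, `true_slope`,
#'   `true_vigour`, `true_start_gdd`, `true_end_gdd`, `true_final_height`
#'   (m), `rht_b1`, `rht_d1`, `ppd_d1` ("wt"/"mut").
#' @export
make_genotype_params <- function(n_genotypes = 330,
                                 slope_mean = 1.2, slope_sd = 0.27,
                                 vigour_mean = 17, vigour_sd = 1.0,
                                 t_ref = 9,
                                 start_gdd_mean = 1150, start_gdd_sd = 35,
                                 se_gdd_mean = 560, se_gdd_sd = 25,
                                 nominal_temp = 14,
                                 baseline_frac = 0.12,
                                 plateau_margin = 0.97,
                                 allele_freq = c(rht_b1 = 0.07,
                                                 rht_d1 = 0.58,
                                                 ppd_d1 = 0.13),
                                 allele_effects = c(rht_b1 = -2.5,
                                                    rht_d1 = -2.0,
                                                    ppd_d1 = -30,
                                                    rht_b1_fh = -60,
                                                    rht_d1_fh = -50),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  id <- sprintf("G%03d", seq_len(n_genotypes))
  slope <- stats::rnorm(n_genotypes, slope_mean, slope_sd)
  slope <- pmin(pmax(slope, 0.2), 2.2)
  vig <- stats::rnorm(n_genotypes, vigour_mean, vigour_sd)
  draw_allele <- function(p) ifelse(stats::runif(n_genotypes) < p, "mut", "wt")
  rht_b1 <- draw_allele(allele_freq[["rht_b1"]])
  rht_d1 <- draw_allele(allele_freq[["rht_d1"]])
  ppd_d1 <- draw_allele(allele_freq[["ppd_d1"]])
  ae <- function(nm) if (nm %in% names(allele_effects))
    allele_effects[[nm]] else 0
  vig <- vig +
    (rht_b1 == "mut") * ae("rht_b1") +
    (rht_d1 == "mut") * ae("rht_d1")
  # keep expected elongation rate positive over plausible window temps (>= 2 C)
  vig <- pmax(vig, slope * (t_ref - 2) + 1)
  start_gdd <- stats::rnorm(n_genotypes, start_gdd_mean, start_gdd_sd) +
    (ppd_d1 == "mut") * ae("ppd_d1")
  se_gdd <- pmax(stats::rnorm(n_genotypes, se_gdd_mean, se_gdd_sd), 100)
  t_nom <- se_gdd / nominal_temp
  gain <- vig * t_nom + slope * (se_gdd - t_ref * t_nom)  # mm
  fh_mm <- plateau_margin * gain / (1 - baseline_frac) +
    (rht_b1 == "mut") * ae("rht_b1_fh") +
    (rht_d1 == "mut") * ae("rht_d1_fh")
  data.frame(
    genotype_id = id,
    true_slope = slope,
    true_vigour = vig,
    true_start_gdd = start_gdd,
    true_end_gdd = start_gdd + se_gdd,
    true_final_height = fh_mm / 1000,
    rht_b1 = rht_b1, rht_d1 = rht_d1, ppd_d1 = ppd_d1,
    stringsAsFactors = FALSE
  )
}

#' Lay out an augmented field design with two diagonal replicate blocks
#'
#' Replicate 1 fills a near-square block in the top-left corner of the grid
#' row-major; replicate 2 fills the transposed block anchored at the
#' bottom-right corner, so the blocks sit on a diagonal.  `gap` is the
#' diagonal separation used when recommending a grid size; placement fails
#' with a capacity error if the two blocks would overlap.
#'
#' @param genotype_ids Character vector of genotype labels.
#' @param grid_rows,grid_ranges Grid dimensions.  Defaults (`NULL`) size the
#'   grid so both blocks fit with a `gap`-cell diagonal separation.
#' @param gap Diagonal gap (cells) between replicate blocks used for default
#'   grid sizing.
#' @param block_rows Rows of the replicate-1 block; default near-square.
#'
#' @return Data frame with columns `plot_id`, `genotype_id`, `replicate`,
#'   `row`, `range`; one row per plot, every genotype appearing exactly twice.
#' @export
layout_augmented_design <- function(genotype_ids, grid_rows = NULL,
                                    grid_ranges = NULL, gap = 5,
                                    block_rows = NULL) {
  n <- length(genotype_ids)
  if (n < 1) stop("need at least one genotype")
  if (anyDuplicated(genotype_ids)) stop("genotype_ids must be unique")
  br1 <- if (is.null(block_rows)) ceiling(sqrt(n)) else block_rows
  bc1 <- ceiling(n / br1)
  br2 <- bc1
  bc2 <- br1
  need_rows <- br1 + gap + br2
  need_ranges <- bc1 + gap + bc2
  if (is.null(grid_rows)) grid_rows <- need_rows
  if (is.null(grid_ranges)) grid_ranges <- need_ranges
  fill <- function(rows, ranges, k) {
    cells <- expand.grid(range = ranges, row = rows)[, c("row", "range")]
    cells[seq_len(k), , drop = FALSE]
  }
  b1 <- fill(seq_len(br1), seq_len(bc1), n)
  r2_rows <- (grid_rows - br2 + 1):grid_rows
  r2_ranges <- (grid_ranges - bc2 + 1):grid_ranges
  if (r2_rows[1] < 1 || r2_ranges[1] < 1 ||
      (r2_rows[1] <= br1 && r2_ranges[1] <= bc1)) {
    stop(sprintf(
      paste0("grid %dx%d too small for two diagonal replicate blocks of ",
             "%d genotypes; need at least %d rows x %d ranges"),
      grid_rows, grid_ranges, n, need_rows, need_ranges))
  }
  b2 <- fill(r2_rows, r2_ranges, n)
  out <- rbind(
    data.frame(genotype_id = genotype_ids, replicate = 1L, b1,
               stringsAsFactors = FALSE),
    data.frame(genotype_id = genotype_ids, replicate = 2L, b2,
               stringsAsFactors = FALSE)
  )
  if (anyDuplicated(out[, c("row", "range")]))
    stop("internal error: cell collision in layout")  # nocov
  out$plot_id <- sprintf("P%04d", seq_len(nrow(out)))
  out[, c("plot_id", "genotype_id", "replicate", "row", "range")]
}

#' Twice-weekly measurement schedule
#'
#' Alternating 3- and 4-day steps between `from` and `to` days after sowing.
#'
#' @param from,to Window in days after sowing.
#' @return Integer vector of measurement days after sowing.
#' @export
measurement_schedule <- function(from = 177, to = 253) {
  days <- from
  step <- 3L
  while (days[length(days)] + step <= to) {
    days <- c(days, days[length(days)] + step)
    step <- if (step == 3L) 4L else 3L
  }
  days
}

#' Simulate plot-level canopy-height time series
#'
#' Latent daily growth inside a genotype's thermal elongation window is
#' `vigour + slope * (T_d - t_ref)` (mm per day, clamped at zero), integrated
#' to height and capped at the genotype's final height; outside the window
#' growth is zero.  Genotype-by-year deviations of slope, vigour and window
#' are shared by both replicates of a genotype within a year; observation
#' noise is additive Gaussian on each measured height.
#'
#' @param genotypes Data frame from [make_genotype_params()].
#' @param layout Data frame from [layout_augmented_design()].
#' @param temperature A `temperature_series` for the year.
#' @param noise_sd Measurement noise sd in mm (LIDAR-height repeatability).
#' @param schedule Measurement days after sowing; default twice weekly.
#' @param t_ref Reference temperature of the growth law (degree C).
#' @param baseline_frac Pre-elongation canopy height as a fraction of final
#'   height.
#' @param gy_sd Named numeric: genotype-by-year sd of `slope` (mm/C/d),
#'   `vigour` (mm/d) and `window` (degree C days).  Zeros give a purely
#'   genotypic simulation.
#' @param gdd_base Base temperature for thermal time (degree C).
#' @param seed Optional integer seed.
#'
#' @return Data frame with columns `plot_id`, `genotype_id`, `year`, `date`,
#'   `height_m`, ordered by plot and date.
#' @export
simulate_height_series <- function(genotypes, layout, temperature,
                                   noise_sd = 2,
                                   schedule = measurement_schedule(),
                                   t_ref = 9, baseline_frac = 0.12,
                                   gy_sd = c(slope = 0.18, vigour = 0.5,
                                             window = 15),
                                   gdd_base = 0, seed = NULL) {
  stopifnot(noise_sd >= 0)
  sowing <- attr(temperature, "sowing_date")
  if (is.null(sowing)) sowing <- min(temperature$date)
  meas_dates <- as.Date(sowing) + schedule - 1L
  if (any(!meas_dates %in% temperature$date))
    stop("measurement schedule extends beyond temperature coverage")
  if (!is.null(seed)) set.seed(seed)
  year <- temperature$year[1]
  tt <- accumulate_gdd(temperature, base = gdd_base, sowing_date = sowing)
  gdd <- tt$gdd
  tmean <- temperature$tmean_c
  ng <- nrow(genotypes)
  dev <- data.frame(
    genotype_id = genotypes$genotype_id,
    slope = stats::rnorm(ng, 0, gy_sd[["slope"]]),
    vigour = stats::rnorm(ng, 0, gy_sd[["vigour"]]),
    window = stats::rnorm(ng, 0, gy_sd[["window"]])
  )
  meas_idx <- match(meas_dates, temperature$date)
  res <- vector("list", nrow(layout))
  for (p in seq_len(nrow(layout))) {
    g <- match(layout$genotype_id[p], genotypes$genotype_id)
    if (is.na(g)) stop("layout genotype missing from genotype table: ",
                       layout$genotype_id[p])
    slope <- genotypes$true_slope[g] + dev$slope[g]
    vig <- genotypes$true_vigour[g] + dev$vigour[g]
    start <- genotypes$true_start_gdd[g] + dev$window[g]
    end <- genotypes$true_end_gdd[g] + dev$window[g]
    fh_mm <- genotypes$true_final_height[g] * 1000
    base_mm <- baseline_frac * fh_mm
    growing <- gdd > start & gdd <= end
    rate <- pmax(0, vig + slope * (tmean - t_ref)) * growing
    latent <- pmin(base_mm + cumsum(rate), fh_mm)
    h <- latent[meas_idx]
    if (noise_sd > 0) h <- h + stats::rnorm(length(h), 0, noise_sd)
    res[[p]] <- data.frame(
      plot_id = layout$plot_id[p], genotype_id = layout$genotype_id[p],
      year = year, date = meas_dates, height_m = pmax(h, 0) / 1000,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, res)
}

#' Inject a smooth spatial field plus random row/range effects
#'
#' Adds a static per-plot offset (evaluated smooth surface plus independent
#' row and range effects) to every observation of each plot, returning both
#' the modified heights and the injected offsets so ground truth is retained.
#'
#' @param heights Height data frame (`plot_id`, `date`, `height_m`, ...).
#' @param layout Layout data frame with `plot_id`, `row`, `range`.
#' @param surface_fun Function of `(row, range)` returning an offset in mm;
#'   `NULL` for no smooth surface.
#' @param row_sd,range_sd Standard deviations (mm) of random row and range
#'   effects.
#' @param seed Optional integer seed.
#'
#' @return List with `heights` (modified copy) and `offsets` (data frame
#'   `plot_id`, `row`, `range`, `offset_mm`).
#' @export
inject_spatial_field <- function(heights, layout, surface_fun = NULL,
                                 row_sd = 0, range_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- sort(unique(layout$row))
  ranges <- sort(unique(layout$range))
  row_eff <- stats::setNames(stats::rnorm(length(rows), 0, row_sd), rows)
  range_eff <- stats::setNames(stats::rnorm(length(ranges), 0, range_sd),
                               ranges)
  surf <- if (is.null(surface_fun)) 0 else
    mapply(surface_fun, layout$row, layout$range)
  offset <- surf + row_eff[as.character(layout$row)] +
    range_eff[as.character(layout$range)]
  offsets <- data.frame(plot_id = layout$plot_id, row = layout$row,
                        range = layout$range, offset_mm = as.numeric(offset),
                        stringsAsFactors = FALSE)
  out <- heights
  out$height_m <- out$height_m +
    offsets$offset_mm[match(out$plot_id, offsets$plot_id)] / 1000
  list(heights = out, offsets = offsets)
}

#' Configuration for a synthetic multi-year trial
#'
#' Collects every tunable of the generator with defaults emulating a
#' three-season augmented wheat trial of about 330 genotypes in two
#' replicates, measured twice weekly during stem elongation.
#'
#' @param n_genotypes Number of genotypes.
#' @param years Season labels.
#' @param noise_sd Height measurement noise sd, mm.
#' @param mean_temp,amplitude,ar_rho,ar_sd Climate parameters, see
#'   [simulate_temperature()].
#' @param year_temp_shift Named per-year shifts (degree C) added to
#'   `mean_temp`; default draws mild year contrasts deterministically from
#'   the year label order.
#' @param gy_sd Genotype-by-year sds, see [simulate_height_series()].
#' @param t_ref Generative critical temperature, degree C.
#' @param spatial Either `NULL` (no field trends) or a list with elements
#'   `surface_fun`, `row_sd`, `range_sd` passed to [inject_spatial_field()].
#' @param gdd_base Base temperature for thermal time.
#' @param seed Master seed; per-year and per-stage seeds are derived from it.
#' @param ... Passed to [make_genotype_params()].
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(n_genotypes = 330, years = 2015:2017,
                         noise_sd = 2, mean_temp = 14, amplitude = 8,
                         ar_rho = 0.6, ar_sd = 3,
                         year_temp_shift = NULL,
                         gy_sd = c(slope = 0.18, vigour = 0.5, window = 15),
                         t_ref = 9, spatial = NULL, gdd_base = 0,
                         seed = 1, ...) {
  if (is.null(year_temp_shift))
    year_temp_shift <- stats::setNames(
      seq_along(years) - mean(seq_along(years)), years)
  structure(list(
    n_genotypes = n_genotypes, years = years, noise_sd = noise_sd,
    mean_temp = mean_temp, amplitude = amplitude, ar_rho = ar_rho,
    ar_sd = ar_sd, year_temp_shift = year_temp_shift, gy_sd = gy_sd,
    t_ref = t_ref, spatial = spatial, gdd_base = gdd_base, seed = seed,
    genotype_args = list(...)
  ), class = "trial_config")
}

#' Simulate a complete multi-year field trial
#'
#' Draws genotype ground truth once, then simulates for each year a
#' temperature series, the augmented layout and plot-level height series,
#' optionally overlaid with a spatial field.
#'
#' @param config A [trial_config()].
#' @return List of class `canopy_trial` with data frames `plots`, `heights`,
#'   `temperature`, `truth`, `alleles`, and (when a spatial field is
#'   configured) `spatial_offsets`, plus the `config`.
#' @export
simulate_trial <- function(config = trial_config()) {
  stopifnot(inherits(config, "trial_config"))
  truth <- do.call(make_genotype_params, c(
    list(n_genotypes = config$n_genotypes, t_ref = config$t_ref,
         nominal_temp = config$mean_temp, seed = config$seed),
    config$genotype_args))
  layout0 <- layout_augmented_design(truth$genotype_id)
  plots <- list(); heights <- list(); temps <- list(); offs <- list()
  for (k in seq_along(config$years)) {
    yr <- config$years[k]
    yseed <- config$seed + 1000L * k
    tm <- simulate_temperature(
      year = yr, sowing_date = sprintf("%d-10-15", as.integer(yr) - 1L),
      mean_temp = config$mean_temp + config$year_temp_shift[[as.character(yr)]],
      amplitude = config$amplitude, ar_rho = config$ar_rho,
      ar_sd = config$ar_sd, seed = yseed)
    lay <- layout0
    lay$plot_id <- sprintf("%s_%s", yr, lay$plot_id)
    lay$year <- yr
    hh <- simulate_height_series(
      truth, lay, tm, noise_sd = config$noise_sd, t_ref = config$t_ref,
      gy_sd = config$gy_sd, gdd_base = config$gdd_base, seed = yseed + 1L)
    if (!is.null(config$spatial)) {
      sp <- config$spatial
      inj <- inject_spatial_field(hh, lay,
                                  surface_fun = sp$surface_fun,
                                  row_sd = sp$row_sd %||% 0,
                                  range_sd = sp$range_sd %||% 0,
                                  seed = yseed + 2L)
      hh <- inj$heights
      io <- inj$offsets
      io$year <- yr
      offs[[k]] <- io
    }
    plots[[k]] <- lay
    heights[[k]] <- hh
    temps[[k]] <- as.data.frame(tm)
    attr(temps[[k]], "sowing_date") <- attr(tm, "sowing_date")
  }
  sow <- do.call(rbind, lapply(temps, function(x)
    data.frame(year = x$year[1], sowing_date = attr(x, "sowing_date"))))
  out <- list(
    plots = do.call(rbind, plots),
    heights = do.call(rbind, heights),
    temperature = do.call(rbind, temps),
    sowing = sow,
    truth = truth,
    alleles = truth[, c("genotype_id", "rht_b1", "rht_d1", "ppd_d1")],
    config = config
  )
  if (length(offs)) out$spatial_offsets <- do.call(rbind, offs)
  class(out) <- "canopy_trial"
  out
}

#' @export
print.canopy_trial <- function(x, ...) {
  cat("Synthetic canopy-height trial\n")
  cat(sprintf("  %d genotypes, %d years (%s), %d plots, %d height records\n",
              nrow(x$truth), length(unique(x$plots$year)),
              paste(unique(x$plots$year), collapse = ", "),
              nrow(x$plots), nrow(x$heights)))
  cat(sprintf("  noise sd %.1f mm, spatial field: %s\n",
              x$config$noise_sd,
              if (is.null(x$config$spatial)) "none" else "injected"))
  invisible(x)
}

#' Write the tidy CSV files of a simulated trial
#'
#' @param trial A `canopy_trial`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_trial_csv <- function(trial, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    plots = file.path(dir, "plots.csv"),
    heights = file.path(dir, "heights.csv"),
    temperature = file.path(dir, "temperature.csv"),
    sowing = file.path(dir, "sowing.csv"),
    truth = file.path(dir, "truth.csv"),
    alleles = file.path(dir, "alleles.csv")
  )
  utils::write.csv(trial$plots[, c("plot_id", "genotype_id", "year",
                                   "replicate", "row", "range")],
                   paths["plots"], row.names = FALSE)
  utils::write.csv(trial$heights[, c("plot_id", "date", "height_m")],
                   paths["heights"], row.names = FALSE)
  utils::write.csv(trial$temperature, paths["temperature"], row.names = FALSE)
  utils::write.csv(trial$sowing, paths["sowing"], row.names = FALSE)
  utils::write.csv(trial$truth, paths["truth"], row.names = FALSE)
  utils::write.csv(trial$alleles, paths["alleles"], row.names = FALSE)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
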