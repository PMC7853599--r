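#' Plot-level regression of stem elongation rate on temperature
#'
#' Ordinary least squares of interval SER (mm per day) on mean interval
#' temperature.  The slope is the temperature responsiveness of growth; the
#' intercept at 0 degree C is reported and can be translated to any reference
#' temperature with [intercept_at()].
#'
#' @param intervals Data frame with `ser` and `tmean_interval` for one plot.
#' @return List of class `plot_response`: `slope` (mm/C/d), `intercept0`
#'   (mm/d), `r_squared`, `residual_sd`, `n_intervals`.
#' @export
fit_plot_response <- function(intervals) {
  x <- intervals$tmean_interval
  y <- intervals$ser
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 intervals to fit the response")
  if (stats::var(x) <= 0) stop("temperature not identifiable: zero variance")
  fit <- stats::lm.fit(cbind(1, x), y)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  structure(list(
    slope = unname(beta[2]),
    intercept0 = unname(beta[1]),
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    residual_sd = sqrt(rss / max(n - 2, 1)),
    n_intervals = n
  ), class = "plot_response")
}

#' @export
print.plot_response <- function(x, ...) {
  cat(sprintf(
    "SER ~ temperature fit: slope %.3f mm/C/d, intercept(0C) %.2f mm/d, R2 %.2f (n=%d)\n",
    x$slope, x$intercept0, x$r_squared, x$n_intervals))
  invisible(x)
}

#' Regression intercept evaluated at a reference temperature
#'
#' The intercept at temperature T is the predicted SER at T:
#' `intercept0 + slope * T`.
#'
#' @param fit A `plot_response`, or a data frame with columns `slope` and
#'   `intercept0`.
#' @param temp Reference temperature(s), degree C.
#' @return Numeric vector of intercepts, mm per day.
#' @export
intercept_at <- function(fit, temp) {
  if (is.data.frame(fit)) fit$intercept0 + fit$slope * temp
  else fit$intercept0 + fit$slope * temp
}

#' Fit the SER~temperature response for every plot
#'
#' By default the regression is restricted to the stem-elongation phase:
#' only intervals whose endpoint heights lie between `min_frac` and
#' `max_frac` of the plot's detected final height enter, excluding the flat
#' pre-shooting baseline, partial onset/plateau intervals and the
#' post-elongation plateau (the same 15%/95% proxies that delimit the phase
#' traits).  Set `phase_only = FALSE` to regress over all intervals.
#'
#' @param heights Data frame `plot_id`, `genotype_id`, `year`, `date`,
#'   `height_m`.
#' @param temperature Data frame `year`, `date`, `tmean_c`.
#' @param phase_only Restrict intervals to the elongation phase?
#' @param min_frac,max_frac Phase window as fractions of final height.
#' @return Data frame with one row per plot: `plot_id`, `genotype_id`,
#'   `year`, `slope`, `intercept0`, `r_squared`, `residual_sd`,
#'   `n_intervals`, `ok` (FALSE where the regression preconditions failed).
#' @export
fit_thermal_response <- function(heights, temperature, phase_only = TRUE,
                                 min_frac = 0.15, max_frac = 0.95) {
  heights$date <- as.Date(heights$date)
  temperature$date <- as.Date(temperature$date)
  rows <- lapply(split(heights, heights$plot_id), function(sp) {
    sp <- sp[order(sp$date), ]
    yr <- sp$year[1]
    tm <- temperature[temperature$year == yr, ]
    base <- data.frame(
      plot_id = sp$plot_id[1],
      genotype_id = if ("genotype_id" %in% names(sp)) sp$genotype_id[1]
                    else NA_character_,
      year = yr, stringsAsFactors = FALSE)
    fit <- tryCatch({
      iv <- interval_temperature(compute_ser(sp), tm)
      if (phase_only) {
        fh <- detect_final_height(sp)$fh
        nstart <- sp$height_m[-nrow(sp)] / fh
        nend <- sp$height_m[-1] / fh
        keep <- nstart >= min_frac & nend <= max_frac
        if (sum(keep) >= 3) iv <- iv[keep, ]
      }
      fit_plot_response(iv)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      cbind(base, data.frame(slope = NA_real_, intercept0 = NA_real_,
                             r_squared = NA_real_, residual_sd = NA_real_,
                             n_intervals = NA_integer_, ok = FALSE))
    } else {
      cbind(base, data.frame(slope = fit$slope, intercept0 = fit$intercept0,
                             r_squared = fit$r_squared,
                             residual_sd = fit$residual_sd,
                             n_intervals = fit$n_intervals, ok = TRUE))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan for the critical temperature where slope and intercept decorrelate
#'
#' For each grid temperature T the Pearson correlation across plots between
#' the regression slope and the intercept evaluated at T is computed; the
#' critical temperature is the grid point with the smallest absolute
#' correlation (ties broken toward lower T).  The intercept at the critical
#' temperature is the temperature-independent vigour.
#'
#' @param fits Data frame of plot fits (columns `slope`, `intercept0`;
#'   typically one year of [fit_thermal_response()] output, rows with
#'   `ok == FALSE` are dropped).
#' @param grid Temperature grid, degree C.
#' @return Object of class `tcrit_scan`: `t_crit`, `min_abs_r`, `grid`,
#'   `correlations`, `n_plots`, `out_of_range` flag (no sign change inside
#'   the grid), `year` if present in `fits`.
#' @export
scan_tcrit <- function(fits, grid = seq(1, 22, by = 0.01)) {
  if ("ok" %in% names(fits)) fits <- fits[fits$ok, ]
  s <- fits$slope
  b <- fits$intercept0
  keep <- is.finite(s) & is.finite(b)
  s <- s[keep]; b <- b[keep]
  if (length(s) < 3) stop("need at least 3 plots with finite fits")
  vs <- stats::var(s)
  if (vs <= 0) stop("correlation undefined: all slopes identical")
  vb <- stats::var(b)
  csb <- stats::cov(s, b)
  num <- csb + grid * vs
  den <- sqrt(vs) * sqrt(pmax(vb + 2 * grid * csb + grid^2 * vs, 0))
  r <- num / den
  # a vanishing intercept variance means the correlation numerator is zero
  # there as well: treat the degenerate point as the zero it represents
  r[!is.finite(r)] <- 0
  i <- which.min(abs(r))
  out_of_range <- !(min(r) < 0 && max(r) > 0) && abs(r[i]) > 0
  structure(list(
    year = if ("year" %in% names(fits) && length(unique(fits$year)) == 1)
      fits$year[1] else NA,
    t_crit = grid[i],
    min_abs_r = abs(r[i]),
    grid = grid,
    correlations = r,
    n_plots = length(s),
    out_of_range = out_of_range
  ), class = "tcrit_scan")
}

#' @export
print.tcrit_scan <- function(x, ...) {
  cat(sprintf("Critical-temperature scan (%d plots%s)\n", x$n_plots,
              if (!is.na(x$year)) paste0(", year ", x$year) else ""))
  cat(sprintf("  T_crit = %.2f C  (|r| at T_crit = %.4f)%s\n",
              x$t_crit, x$min_abs_r,
              if (x$out_of_range) "  [zero outside scan range]" else ""))
  invisible(x)
}

#' @export
plot.tcrit_scan <- function(x, ...) {
  plot(x$grid, x$correlations, type = "l",
       xlab = "Intercept temperature (°C)",
       ylab = "r(slope, intercept)", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = x$t_crit, lty = 2)
  invisible(x)
}

#' Closed-form zero of the slope-intercept correlation
#'
#' The correlation numerator `cov(slope, intercept0) + T * var(slope)` is
#' linear in T, so its exact zero is `-cov/var`.  Used as an analytic check
#' of the grid scan.
#'
#' @param fits Data frame with `slope`, `intercept0`.
#' @return The exact zero-correlation temperature, degree C.
#' @export
closed_form_tcrit <- function(fits) {
  if ("ok" %in% names(fits)) fits <- fits[fits$ok, ]
  s <- fits$slope; b <- fits$intercept0
  keep <- is.finite(s) & is.finite(b)
  s <- s[keep]; b <- b[keep]
  vs <- stats::var(s)
  if (!is.finite(vs) || vs <= 0) stop("degenerate slope variance")
  -stats::cov(s, b) / vs
}

#' Attach the vigour (intercept at the critical temperature) to plot fits
#'
#' @param fits [fit_thermal_response()] output.
#' @param t_crit Critical temperature(s): a single value or a named vector /
#'   data frame (`year`, `t_crit`) for per-year values.
#' @return `fits` with added columns `t_crit` and `intercept_tcrit`.
#' @export
vigour_at <- function(fits, t_crit) {
  if (is.data.frame(t_crit)) {
    tc <- t_crit$t_crit[match(fits$year, t_crit$year)]
  } else if (!is.null(names(t_crit))) {
    tc <- t_crit[as.character(fits$year)]
  } else {
    tc <- rep(t_crit, nrow(fits))
  }
  fits$t_crit <- as.numeric(tc)
  fits$intercept_tcrit <- fits$intercept0 + fits$slope * fits$t_crit
  fits
}

#' Genotype-by-year means of slope and vigour over replicates
#'
#' Averages the plot-level response parameters over the replicates of each
#' genotype within each year, levelling out weak single-plot fits.
#'
#' @param fits [vigour_at()]-augmented fit table (needs `genotype_id`,
#'   `year`, `slope`, `intercept_tcrit`, `ok`).
#' @return List with `summary` (data frame `genotype_id`, `year`, `slope`,
#'   `vigour`, `n_plots`) and `skipped` (genotype-years with no usable fit).
#' @export
genotype_response_summary <- function(fits) {
  use <- fits[fits$ok & is.finite(fits$slope), ]
  key <- interaction(use$genotype_id, use$year, drop = TRUE)
  agg <- do.call(rbind, lapply(split(use, key), function(g) {
    data.frame(genotype_id = g$genotype_id[1], year = g$year[1],
               slope = mean(g$slope),
               vigour = mean(g$intercept_tcrit),
               n_plots = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  all_gy <- unique(fits[, c("genotype_id", "year")])
  got <- paste(agg$genotype_id, agg$year)
  skipped <- all_gy[!paste(all_gy$genotype_id, all_gy$year) %in% got, ]
  rownames(skipped) <- NULL
  list(summary = agg, skipped = skipped)
}
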