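#' Stem elongation rate between consecutive measurements
#'
#' SER for each interval between consecutive observations of one plot:
#' height difference divided by interval length, reported in mm per day
#' (heights are stored in metres).
#'
#' @param series Data frame for a single plot with columns `date` and
#'   `height_m` (additional id columns are carried through).
#' @return Data frame with one row per consecutive pair: `plot_id` (if
#'   present), `interval_start`, `interval_end`, `delta_t` (days), `ser`
#'   (mm per day).
#' @export
compute_ser <- function(series) {
  if (nrow(series) < 2) stop("need at least two observations")
  o <- order(series$date)
  series <- series[o, ]
  if (anyDuplicated(series$date)) {
    pid <- if ("plot_id" %in% names(series)) series$plot_id[1] else "<plot>"
    stop("duplicate measurement dates in plot ", pid)
  }
  n <- nrow(series)
  dt <- as.numeric(diff(as.Date(series$date)), units = "days")
  out <- data.frame(
    interval_start = as.Date(series$date[-n]),
    interval_end = as.Date(series$date[-1]),
    delta_t = dt,
    ser = diff(series$height_m) * 1000 / dt
  )
  if ("plot_id" %in% names(series))
    out <- cbind(plot_id = series$plot_id[1], out)
  out
}

#' Mean temperature over measurement intervals
#'
#' Averages the daily means over the half-open interval
#' `(interval_start, interval_end]`, attributing each day's growth to exactly
#' one interval.
#'
#' @param records Data frame with `interval_start`, `interval_end`.
#' @param temperature Data frame with `date`, `tmean_c` covering all interval
#'   days.
#' @return `records` with an added `tmean_interval` column (degree C).
#' @export
interval_temperature <- function(records, temperature) {
  tdate <- as.Date(temperature$date)
  tv <- temperature$tmean_c
  out <- vapply(seq_len(nrow(records)), function(i) {
    days <- seq(as.Date(records$interval_start[i]) + 1,
                as.Date(records$interval_end[i]), by = "day")
    idx <- match(days, tdate)
    if (anyNA(idx))
      stop("temperature series missing days: ",
           paste(format(days[is.na(idx)]), collapse = ", "))
    mean(tv[idx])
  }, numeric(1))
  records$tmean_interval <- out
  records
}

#' Accumulate growing degree-days from sowing
#'
#' Thermal time is zero at sowing; each subsequent day contributes
#' `max(tmean - base, 0)`.
#'
#' @param temperature Data frame with `date`, `tmean_c`.
#' @param base Base temperature, degree C.
#' @param sowing_date Sowing date; defaults to the series' `sowing_date`
#'   attribute, else the day before the first record.
#' @return Data frame of class `thermal_time` with `date` and `gdd`
#'   (degree C days, non-decreasing, 0 at sowing).
#' @export
accumulate_gdd <- function(temperature, base = 0, sowing_date = NULL) {
  if (is.null(sowing_date)) sowing_date <- attr(temperature, "sowing_date")
  dates <- as.Date(temperature$date)
  if (is.null(sowing_date)) sowing_date <- min(dates) - 1
  sowing_date <- as.Date(sowing_date)
  contrib <- pmax(temperature$tmean_c - base, 0)
  contrib[dates <= sowing_date] <- 0
  out <- data.frame(date = dates, gdd = cumsum(contrib))
  attr(out, "base_temperature") <- base
  attr(out, "sowing_date") <- sowing_date
  class(out) <- c("thermal_time", "data.frame")
  out
}

#' Detect final height as the onset of a measurement plateau
#'
#' Final height (FH) is the maximum height at or before the first observation
#' that is followed by `k_flat` consecutive height increases smaller than
#' `tol_mm`.  The search starts at the steepest observed increment, so a flat
#' pre-elongation baseline (series that begin before shooting) is not
#' mistaken for the plateau.  If no plateau exists the maximum observed
#' height is returned with a `no_plateau` flag.
#'
#' @param series Data frame for one plot with `date`, `height_m`.
#' @param k_flat Number of consecutive flat increments required.
#' @param tol_mm Flatness tolerance in mm.
#' @return List: `fh` (m), `plateau_date` (`NA` if none), `no_plateau` flag.
#' @export
detect_final_height <- function(series, k_flat = 3, tol_mm = 5) {
  if (nrow(series) < k_flat + 1) stop("need at least k_flat + 1 observations")
  o <- order(series$date)
  h <- series$height_m[o]
  d <- as.Date(series$date)[o]
  inc_mm <- diff(h) * 1000
  flat <- inc_mm < tol_mm
  n <- length(flat)
  idx <- NA_integer_
  if (n >= k_flat) {
    runs <- stats::filter(as.numeric(flat), rep(1, k_flat), sides = 1)
    hit <- which(runs == k_flat) - k_flat + 1L  # first increment of each run
    hit <- hit[hit >= which.max(inc_mm)]       # plateau follows peak growth
    if (length(hit)) idx <- hit[1]
  }
  if (is.na(idx)) {
    list(fh = max(h), plateau_date = as.Date(NA), no_plateau = TRUE)
  } else {
    list(fh = max(h[seq_len(idx)]), plateau_date = d[idx], no_plateau = FALSE)
  }
}

#' Thermal time at 15% and 95% of final height
#'
#' Normalized canopy height (percentage of FH at each measurement) is
#' linearly interpolated to daily values on the calendar axis; the thermal
#' times of the first upward crossings of 15% and 95% are returned, with
#' sub-day linear interpolation of both the crossing time and the thermal-time
#' map.
#'
#' @param series Data frame for one plot with `date`, `height_m`.
#' @param fh Final height in m.
#' @param thermal_time A [accumulate_gdd()] map covering the observed dates.
#' @return List with `gdd15` and `gdd95` (degree C days).
#' @export
extract_phase_timings <- function(series, fh, thermal_time) {
  stopifnot(fh > 0)
  o <- order(series$date)
  d <- as.numeric(as.Date(series$date)[o])
  norm <- 100 * series$height_m[o] / fh
  if (max(norm) < 95) stop("phase incomplete: series never reaches 95% of FH")
  day_grid <- seq(min(d), max(d))
  nh <- stats::approx(d, norm, xout = day_grid)$y
  td <- as.numeric(thermal_time$date)
  if (min(d) < min(td) || max(d) > max(td))
    stop("thermal time map does not cover observation dates")
  cross_day <- function(thr) {
    above <- nh >= thr
    if (above[1]) return(day_grid[1])
    i <- which(!above[-length(above)] & above[-1])[1] # first upward crossing
    if (is.na(i)) return(NA_real_)
    frac <- (thr - nh[i]) / (nh[i + 1] - nh[i])
    day_grid[i] + frac
  }
  gdd_at <- function(day) stats::approx(td, thermal_time$gdd, xout = day)$y
  list(gdd15 = gdd_at(cross_day(15)), gdd95 = gdd_at(cross_day(95)))
}

#' Elongation duration in thermal time and calendar days
#'
#' @param gdd15,gdd95 Thermal times of the 15% and 95% crossings.
#' @param thermal_time A [accumulate_gdd()] map (used to invert thermal time
#'   back to calendar days by linear interpolation).
#' @return List with `gdd_se` (degree C days, exactly `gdd95 - gdd15`) and
#'   `time_se` (days).
#' @export
derive_durations <- function(gdd15, gdd95, thermal_time) {
  if (!is.finite(gdd15) || !is.finite(gdd95) || gdd15 >= gdd95)
    stop("invalid phase timings: require gdd15 < gdd95")
  td <- as.numeric(as.Date(thermal_time$date))
  # invert the (strictly increasing where growth occurs) cumulative map
  day_at <- function(g) stats::approx(thermal_time$gdd, td, xout = g,
                                      ties = "ordered")$y
  list(gdd_se = gdd95 - gdd15, time_se = day_at(gdd95) - day_at(gdd15))
}

#' Per-plot growth and phenology traits
#'
#' Convenience wrapper running final-height detection, phase timing and
#' duration extraction for every plot of a (possibly multi-year) height
#' table.
#'
#' @param heights Data frame `plot_id`, `date`, `height_m` (and optionally
#'   `genotype_id`, `year`).
#' @param temperature Data frame `year`, `date`, `tmean_c`.
#' @param sowing Data frame `year`, `sowing_date`.
#' @param gdd_base Base temperature for thermal time.
#' @param k_flat,tol_mm Plateau detection settings.
#' @return Data frame with one row per plot: `plot_id`, `genotype_id`,
#'   `year`, `fh_m`, `gdd15`, `gdd95`, `gdd_se`, `time_se`, `no_plateau`,
#'   `phase_incomplete`.
#' @export
extract_traits <- function(heights, temperature, sowing, gdd_base = 0,
                           k_flat = 3, tol_mm = 5) {
  heights$date <- as.Date(heights$date)
  temperature$date <- as.Date(temperature$date)
  years <- unique(heights$year)
  maps <- lapply(years, function(yr) {
    tm <- temperature[temperature$year == yr, ]
    sd_ <- as.Date(sowing$sowing_date[match(yr, sowing$year)])
    accumulate_gdd(tm, base = gdd_base, sowing_date = sd_)
  })
  names(maps) <- as.character(years)
  rows <- lapply(split(heights, heights$plot_id), function(sp) {
    sp <- sp[order(sp$date), ]
    tt <- maps[[as.character(sp$year[1])]]
    fhd <- detect_final_height(sp, k_flat = k_flat, tol_mm = tol_mm)
    pt <- tryCatch(extract_phase_timings(sp, fhd$fh, tt),
                   error = function(e) NULL)
    incomplete <- is.null(pt)
    dur <- if (!incomplete && is.finite(pt$gdd15) && is.finite(pt$gdd95) &&
               pt$gdd15 < pt$gdd95)
      derive_durations(pt$gdd15, pt$gdd95, tt)
    else list(gdd_se = NA_real_, time_se = NA_real_)
    data.frame(
      plot_id = sp$plot_id[1],
      genotype_id = if ("genotype_id" %in% names(sp)) sp$genotype_id[1]
                    else NA_character_,
      year = sp$year[1],
      fh_m = fhd$fh,
      gdd15 = if (incomplete) NA_real_ else pt$gdd15,
      gdd95 = if (incomplete) NA_real_ else pt$gdd95,
      gdd_se = dur$gdd_se, time_se = dur$time_se,
      no_plateau = fhd$no_plateau,
      phase_incomplete = incomplete,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
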