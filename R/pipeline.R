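#' Read a trial from its tidy CSV files
#'
#' Expects the schemas written by [write_trial_csv()]: `plots.csv`,
#' `heights.csv`, `temperature.csv`, `sowing.csv` and optionally `truth.csv`
#' and `alleles.csv`.
#'
#' @param dir Directory containing the CSV files.
#' @return A list of class `canopy_trial`.
#' @export
read_trial_csv <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    stringsAsFactors = FALSE)
  plots <- rd("plots.csv")
  heights <- rd("heights.csv")
  heights$date <- as.Date(heights$date)
  if (!"genotype_id" %in% names(heights))
    heights$genotype_id <- plots$genotype_id[match(heights$plot_id,
                                                   plots$plot_id)]
  if (!"year" %in% names(heights))
    heights$year <- plots$year[match(heights$plot_id, plots$plot_id)]
  temperature <- rd("temperature.csv")
  temperature$date <- as.Date(temperature$date)
  sowing <- rd("sowing.csv")
  sowing$sowing_date <- as.Date(sowing$sowing_date)
  out <- list(plots = plots, heights = heights, temperature = temperature,
              sowing = sowing)
  if (file.exists(file.path(dir, "truth.csv"))) out$truth <- rd("truth.csv")
  if (file.exists(file.path(dir, "alleles.csv")))
    out$alleles <- rd("alleles.csv")
  class(out) <- "canopy_trial"
  out
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are passed to [trial_config()].
#'
#' @param path YAML file.
#' @return A `trial_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$gy_sd)) y$gy_sd <- unlist(y$gy_sd)
  if (!is.null(y$year_temp_shift)) y$year_temp_shift <- unlist(y$year_temp_shift)
  do.call(trial_config, y)
}

#' Run the full analysis pipeline
#'
#' Simulate (or take) a multi-year trial, optionally correct spatial field
#' trends per measurement date, extract growth and phenology traits, fit the
#' plot-level temperature response, scan the per-year critical temperature,
#' aggregate genotype-by-year models (BLUEs, BLUPs, variance components,
#' heritability) for every trait, and fit the final-height prediction model.
#'
#' @param config A [trial_config()]; ignored when `trial` is supplied.
#' @param trial Optional `canopy_trial` (e.g. from [read_trial_csv()]).
#' @param correct_spatial Apply per-date spatial correction; defaults to
#'   TRUE when the trial carries injected spatial effects or was read from
#'   disk.
#' @param outdir Optional directory for CSV outputs and the JSON run report.
#' @param traits Trait columns to aggregate across years.
#' @return Object of class `pipeline_run` with elements `trial`, `traits_plot`,
#'   `response_fits`, `tcrit` (per-year scans), `gxe` (per-trait fits),
#'   `blues`, `blups`, `heritability`, `correlations`, `height_model`,
#'   `cross_year_r2`, `report`.
#' @export
run_pipeline <- function(config = trial_config(), trial = NULL,
                         correct_spatial = NULL, outdir = NULL,
                         traits = c("fh", "gdd15", "gdd95", "gdd_se",
                                    "time_se", "slope", "vigour")) {
  if (is.null(trial)) trial <- simulate_trial(config)
  cfg <- trial$config %||% config
  if (is.null(correct_spatial))
    correct_spatial <- !is.null(trial$spatial_offsets)
  heights <- trial$heights
  if (correct_spatial)
    heights <- suppressWarnings(
      correct_timeseries(heights, trial$plots))

  traits_plot <- extract_traits(heights, trial$temperature, trial$sowing,
                                gdd_base = cfg$gdd_base %||% 0)
  fits <- fit_thermal_response(heights, trial$temperature)
  scans <- lapply(split(fits, fits$year), function(fy)
    tryCatch(scan_tcrit(fy), error = function(e) NULL))
  scans <- scans[!vapply(scans, is.null, logical(1))]
  tcrit_tab <- do.call(rbind, lapply(scans, function(s)
    data.frame(year = s$year, t_crit = s$t_crit, min_abs_r = s$min_abs_r,
               n_plots = s$n_plots, out_of_range = s$out_of_range)))
  if (!is.null(tcrit_tab) && nrow(tcrit_tab) > 0) {
    fits <- vigour_at(fits, tcrit_tab)
    traits_plot$slope <- fits$slope[match(traits_plot$plot_id, fits$plot_id)]
    traits_plot$vigour <- fits$intercept_tcrit[match(traits_plot$plot_id,
                                                     fits$plot_id)]
  } else {
    warning("critical-temperature scan failed in every year; ",
            "slope and vigour traits are not aggregated")
    traits <- setdiff(traits, c("slope", "vigour"))
  }
  traits_plot$fh <- traits_plot$fh_m

  gxe <- list(); blues <- list(); blups <- list(); h2 <- c()
  for (tr in traits) {
    col <- if (tr == "fh") "fh" else tr
    dd <- data.frame(genotype_id = traits_plot$genotype_id,
                     year = traits_plot$year,
                     value = traits_plot[[col]])
    fx <- tryCatch(fit_gxe(dd, "fixed"), error = function(e) NULL)
    rn <- tryCatch(fit_gxe(dd, "random"), error = function(e) NULL)
    if (is.null(fx) || is.null(rn)) next
    gxe[[tr]] <- list(fixed = fx, random = rn)
    blues[[tr]] <- coef(fx)
    blups[[tr]] <- coef(rn)
    h2[tr] <- if (sum(rn$varcomp$sigma2_gy, rn$varcomp$sigma2_e) == 0) 1
              else heritability(rn$varcomp)
  }
  gids <- Reduce(intersect, lapply(blues, names))
  blues_tab <- data.frame(genotype_id = gids,
                          lapply(blues, function(v) unname(v[gids])),
                          stringsAsFactors = FALSE)
  blups_tab <- data.frame(genotype_id = gids,
                          lapply(blups, function(v) unname(v[gids])),
                          stringsAsFactors = FALSE)
  corr <- trait_correlations(blues_tab[, -1])

  hm <- NULL
  if (!is.null(trial$alleles)) {
    md <- merge(blues_tab, trial$alleles, by = "genotype_id")
    hm <- tryCatch(fit_height_model(md), error = function(e) NULL)
  }

  # per-year genotype means for cross-year prediction of final height
  cy <- NULL
  yrs <- sort(unique(traits_plot$year))
  if (length(yrs) >= 2) {
    per_year <- lapply(yrs, function(yr) {
      dd <- traits_plot[traits_plot$year == yr, ]
      agg <- stats::aggregate(dd[, c("fh", "slope", "vigour", "gdd_se")],
                              by = list(genotype_id = dd$genotype_id),
                              FUN = mean, na.rm = TRUE)
      agg
    })
    names(per_year) <- as.character(yrs)
    cy <- matrix(NA_real_, length(yrs), length(yrs),
                 dimnames = list(train = yrs, test = yrs))
    for (i in seq_along(yrs)) for (j in seq_along(yrs)) {
      if (i == j) next
      cy[i, j] <- tryCatch(
        cross_year_r2(per_year[[i]], per_year[[j]],
                      fh ~ slope + vigour + gdd_se),
        error = function(e) NA_real_)
    }
  }

  report <- list(
    n_genotypes = length(gids),
    n_plots = length(unique(traits_plot$plot_id)),
    years = as.character(sort(unique(traits_plot$year))),
    spatially_corrected = correct_spatial,
    t_crit = if (!is.null(tcrit_tab))
      stats::setNames(tcrit_tab$t_crit, tcrit_tab$year) else NULL,
    heritability = as.list(round(h2, 4)),
    height_model_r2 = if (!is.null(hm)) hm$r_squared else NULL,
    cross_year_r2 = if (!is.null(cy)) round(cy, 4) else NULL,
    config = cfg[setdiff(names(cfg), "spatial")],
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )

  out <- structure(list(
    trial = trial, heights_corrected = if (correct_spatial) heights else NULL,
    traits_plot = traits_plot, response_fits = fits, tcrit = tcrit_tab,
    scans = scans, gxe = gxe, blues = blues_tab, blups = blups_tab,
    heritability = h2, correlations = corr, height_model = hm,
    cross_year_r2 = cy, report = report
  ), class = "pipeline_run")

  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Canopy temperature-response pipeline run\n")
  cat(sprintf("  %d genotypes across years %s\n", x$report$n_genotypes,
              paste(x$report$years, collapse = ", ")))
  if (!is.null(x$tcrit)) {
    cat("  T_crit per year: ",
        paste(sprintf("%s: %.2f C", x$tcrit$year, x$tcrit$t_crit),
              collapse = ", "), "\n")
  }
  cat("  Heritability:\n")
  for (tr in names(x$heritability))
    cat(sprintf("    %-8s H2 = %.2f\n", tr, x$heritability[[tr]]))
  if (!is.null(x$height_model))
    cat(sprintf("  Final-height model R2 = %.3f\n",
                x$height_model$r_squared))
  invisible(x)
}

#' Write pipeline outputs as CSV files plus a JSON run report
#'
#' @param run A `pipeline_run`.
#' @param dir Output directory.
#' @return Invisibly, the report path.
#' @export
write_pipeline_outputs <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(run$traits_plot, file.path(dir, "traits_plot.csv"),
                   row.names = FALSE)
  utils::write.csv(run$response_fits, file.path(dir, "response_fits.csv"),
                   row.names = FALSE)
  if (!is.null(run$tcrit))
    utils::write.csv(run$tcrit, file.path(dir, "tcrit.csv"),
                     row.names = FALSE)
  utils::write.csv(run$blues, file.path(dir, "blues.csv"), row.names = FALSE)
  utils::write.csv(run$blups, file.path(dir, "blups.csv"), row.names = FALSE)
  if (!is.null(run$heights_corrected))
    utils::write.csv(run$heights_corrected,
                     file.path(dir, "heights_corrected.csv"),
                     row.names = FALSE)
  vc <- do.call(rbind, lapply(names(run$gxe), function(tr) {
    v <- run$gxe[[tr]]$random$varcomp
    data.frame(trait = tr, sigma2_g = v$sigma2_g, sigma2_gy = v$sigma2_gy,
               sigma2_e = v$sigma2_e,
               h2 = unname(run$heritability[tr]))
  }))
  utils::write.csv(vc, file.path(dir, "varcomp.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$correlations$r),
                   file.path(dir, "correlations.csv"))
  path <- file.path(dir, "run_report.json")
  jsonlite::write_json(run$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
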