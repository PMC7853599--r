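#' Spatial correction of plot values on a field grid
#'
#' Fits genotype effects plus a smooth bivariate field surface (tensor-product
#' P-splines over row and range, second-order difference penalties, smoothing
#' by REML) plus ridge-penalized random row and range effects, and returns
#' for each plot the spatially corrected value: estimated genotype effect
#' plus residual, with surface and row/range effects removed.
#'
#' @param values Data frame with columns `plot_id`, `genotype_id`, `row`,
#'   `range`, `value`.
#' @param knot_fraction Spline knots per axis as a fraction of the number of
#'   distinct rows / ranges (default two-thirds).
#' @param smoothing_selector Smoothness selection criterion passed to
#'   [mgcv::gam()] (`"REML"`, falling back to `"GCV.Cp"` on failure).
#' @return Object of class `spatial_fit` with elements `corrected` (data
#'   frame `plot_id`, `value`, `corrected`, `spatial_part`),
#'   `genotype_effects`, `row_effects`, `range_effects` (zero-centred),
#'   `model` (the underlying `gam`).
#' @export
fit_spatial_model <- function(values, knot_fraction = 2 / 3,
                              smoothing_selector = "REML") {
  stopifnot(all(c("plot_id", "genotype_id", "row", "range", "value")
                %in% names(values)))
  if (length(unique(values$genotype_id)) < 2)
    stop("spatial model needs at least 2 genotypes")
  df <- data.frame(
    value = values$value,
    genotype = factor(values$genotype_id),
    row = as.numeric(values$row),
    range = as.numeric(values$range),
    row_f = factor(values$row),
    range_f = factor(values$range)
  )
  nr <- length(unique(df$row))
  nc <- length(unique(df$range))
  kr <- max(3, min(nr, ceiling(knot_fraction * nr)))
  kc <- max(3, min(nc, ceiling(knot_fraction * nc)))
  use_surface <- nr >= 5 && nc >= 5
  form <- if (use_surface)
    value ~ genotype + te(row, range, bs = "ps", m = 2, k = c(kr, kc)) +
      s(row_f, bs = "re") + s(range_f, bs = "re")
  else
    value ~ genotype + s(row_f, bs = "re") + s(range_f, bs = "re")
  # exactly noise-free genotype data leave no residual information for the
  # field terms: the correction is the identity there
  ols <- stats::lm(value ~ genotype, data = df)
  scale <- max(stats::sd(df$value), 1e-12)
  if (stats::sigma(ols) < 1e-9 * scale) {
    g_est <- stats::setNames(
      as.numeric(tapply(df$value, df$genotype, mean)[levels(df$genotype)]),
      levels(df$genotype))
    return(structure(list(
      corrected = data.frame(plot_id = values$plot_id, value = df$value,
                             corrected = df$value,
                             spatial_part = rep(0, nrow(df)),
                             stringsAsFactors = FALSE),
      genotype_effects = g_est,
      row_effects = stats::setNames(rep(0, nlevels(df$row_f)),
                                    levels(df$row_f)),
      range_effects = stats::setNames(rep(0, nlevels(df$range_f)),
                                      levels(df$range_f)),
      model = ols
    ), class = "spatial_fit"))
  }
  fit <- tryCatch(
    mgcv::gam(form, data = df, method = smoothing_selector, select = TRUE),
    error = function(e)
      mgcv::gam(form, data = df, method = "GCV.Cp", select = TRUE))
  terms <- stats::predict(fit, type = "terms")
  spatial_cols <- grepl("^te\\(row,range\\)|^s\\(row_f\\)|^s\\(range_f\\)",
                        colnames(terms))
  spatial_part <- rowSums(terms[, spatial_cols, drop = FALSE])
  # random-effect smooths are not sum-to-zero constrained; recentre so the
  # correction preserves the grand mean, folding the shift into the genotype
  # estimates
  sp_shift <- mean(spatial_part)
  spatial_part <- spatial_part - sp_shift
  corrected <- df$value - spatial_part
  co <- stats::coef(fit)
  g_lv <- levels(df$genotype)
  g_eff <- c(0, co[paste0("genotype", g_lv[-1])])
  g_est <- unname(co["(Intercept)"]) + g_eff + sp_shift
  names(g_est) <- g_lv
  re_pred <- function(fac, smooth_label) {
    idx <- grep(smooth_label, names(co), fixed = TRUE)
    eff <- stats::setNames(co[idx], levels(df[[fac]]))
    eff - mean(eff)
  }
  structure(list(
    corrected = data.frame(plot_id = values$plot_id, value = df$value,
                           corrected = corrected,
                           spatial_part = spatial_part,
                           stringsAsFactors = FALSE),
    genotype_effects = g_est,
    row_effects = re_pred("row_f", "s(row_f)."),
    range_effects = re_pred("range_f", "s(range_f)."),
    model = fit
  ), class = "spatial_fit")
}

#' @export
print.spatial_fit <- function(x, ...) {
  cat(sprintf(
    "Spatial field correction: %d plots, %d genotypes, spatial sd removed %.3g\n",
    nrow(x$corrected), length(x$genotype_effects),
    stats::sd(x$corrected$spatial_part)))
  invisible(x)
}

#' Per-timepoint spatial correction of canopy-height series
#'
#' Applies [fit_spatial_model()] independently at every measurement date
#' within each year, replacing each height by its spatially corrected value
#' (genotype estimate plus residual).  Dates measured on fewer plots than
#' `min_coverage` of the layout, or with fewer plots than genotypes, are
#' passed through uncorrected with a warning.
#'
#' @param heights Data frame `plot_id`, `genotype_id`, `year`, `date`,
#'   `height_m`.
#' @param layout Data frame `plot_id`, `row`, `range`.
#' @param min_coverage Minimum fraction of plots that must be present at a
#'   date for it to be corrected.
#' @param ... Passed to [fit_spatial_model()].
#' @return `heights` with `height_m` replaced by the corrected values (a
#'   `height_raw_m` column keeps the input).
#' @export
correct_timeseries <- function(heights, layout, min_coverage = 0.9, ...) {
  heights$date <- as.Date(heights$date)
  heights$height_raw_m <- heights$height_m
  lay_row <- layout$row[match(heights$plot_id, layout$plot_id)]
  lay_range <- layout$range[match(heights$plot_id, layout$plot_id)]
  if (anyNA(lay_row)) stop("layout missing plots present in heights")
  heights$.row <- lay_row
  heights$.range <- lay_range
  key <- interaction(heights$year, heights$date, drop = TRUE)
  parts <- split(heights, key)
  n_plots_year <- tapply(layout$plot_id, rep(1, nrow(layout)), length)
  out <- lapply(parts, function(dd) {
    n_gen <- length(unique(dd$genotype_id))
    coverage <- nrow(dd) / length(unique(layout$plot_id))
    if (nrow(dd) <= n_gen || coverage < min_coverage) {
      warning(sprintf("date %s (%s): insufficient plots for correction; skipped",
                      format(dd$date[1]), dd$year[1]))
      return(dd)
    }
    sf <- fit_spatial_model(
      data.frame(plot_id = dd$plot_id, genotype_id = dd$genotype_id,
                 row = dd$.row, range = dd$.range, value = dd$height_m,
                 stringsAsFactors = FALSE), ...)
    dd$height_m <- sf$corrected$corrected
    dd
  })
  res <- do.call(rbind, out)
  res$.row <- NULL
  res$.range <- NULL
  rownames(res) <- NULL
  res[order(res$plot_id, res$date), ]
}
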