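test_that("SER is the height difference per day in mm", {
  s <- data.frame(plot_id = "p1",
                  date = as.Date("2016-05-01") + c(0, 3, 6),
                  height_m = c(0.200, 0.260, 0.260))
  r <- compute_ser(s)
  expect_equal(nrow(r), 2)
  expect_equal(r$ser, c(20, 0))
  expect_equal(r$delta_t, c(3, 3))

  flat <- data.frame(date = as.Date("2016-05-01") + c(0, 4, 8),
                     height_m = rep(0.5, 3))
  expect_equal(compute_ser(flat)$ser, c(0, 0))

  dup <- data.frame(plot_id = "bad",
                    date = as.Date("2016-05-01") + c(0, 0, 3),
                    height_m = c(0.1, 0.1, 0.2))
  expect_error(compute_ser(dup), "bad")
  expect_error(compute_ser(flat[1, ]), "two observations")
})

test_that("interval temperature averages over the half-open interval", {
  temps <- data.frame(date = as.Date("2016-05-01") + 0:9,
                      tmean_c = c(15, 10, 12, 14, 15, 15, 15, 15, 15, 15))
  rec <- data.frame(interval_start = as.Date("2016-05-01"),
                    interval_end = as.Date("2016-05-04"))
  # days 2,3,4 of the series: 10, 12, 14
  expect_equal(interval_temperature(rec, temps)$tmean_interval, 12)

  cst <- data.frame(date = as.Date("2016-05-01") + 0:9, tmean_c = 15)
  expect_equal(interval_temperature(rec, cst)$tmean_interval, 15)

  rec2 <- data.frame(interval_start = as.Date("2016-05-08"),
                     interval_end = as.Date("2016-05-12"))
  expect_error(interval_temperature(rec2, temps), "missing days")
})

test_that("interval temperature matches a brute-force day loop", {
  tm <- simulate_temperature(2016, "2015-10-15", seed = 3)
  starts <- as.Date("2016-04-05") + c(0, 7, 12)
  ends <- starts + c(3, 4, 3)
  rec <- data.frame(interval_start = starts, interval_end = ends)
  got <- interval_temperature(rec, tm)$tmean_interval
  for (i in seq_along(starts)) {
    acc <- 0; nn <- 0
    for (d in seq_len(nrow(tm))) {
      if (tm$date[d] > starts[i] && tm$date[d] <= ends[i]) {
        acc <- acc + tm$tmean_c[d]; nn <- nn + 1
      }
    }
    expect_equal(got[i], acc / nn)
  }
})

test_that("growing degree-days accumulate with clamping at the base", {
  tm <- data.frame(date = as.Date("2016-03-01") + 0:2,
                   tmean_c = c(10, 12, 8))
  expect_equal(accumulate_gdd(tm, base = 0,
                              sowing_date = "2016-02-29")$gdd,
               c(10, 22, 30))
  expect_equal(accumulate_gdd(tm, base = 5,
                              sowing_date = "2016-02-29")$gdd,
               c(5, 12, 15))
  neg <- data.frame(date = as.Date("2016-03-01") + 0:2,
                    tmean_c = c(10, -2, 8))
  expect_equal(accumulate_gdd(neg, base = 0,
                              sowing_date = "2016-02-29")$gdd,
               c(10, 10, 18))
  # zero at sowing, non-decreasing
  tm2 <- simulate_temperature(2016, "2015-10-15", seed = 1)
  g <- accumulate_gdd(tm2, sowing_date = "2015-10-15")
  expect_equal(g$gdd[1], 0)  # sowing-day itself contributes nothing
  expect_true(all(diff(g$gdd) >= 0))
})

test_that("plateau detection finds constructed plateaus and flags their absence", {
  d0 <- as.Date("2016-05-01")
  up <- data.frame(date = d0 + seq(0, 44, by = 4),
                   height_m = c(seq(0.2, 1.0, by = 0.1), 1.0, 1.0, 1.0))
  res <- detect_final_height(up)
  expect_false(res$no_plateau)
  expect_equal(res$fh, 1.0)

  mono <- data.frame(date = d0 + seq(0, 24, by = 4),
                     height_m = seq(0.2, 0.8, by = 0.1))
  res2 <- detect_final_height(mono)
  expect_true(res2$no_plateau)
  expect_equal(res2$fh, 0.8)

  # plateau value, not a later noisy maximum, is reported
  noisy <- data.frame(date = d0 + seq(0, 40, by = 4),
                      height_m = c(0.2, 0.4, 0.6, 0.8, 1.0, 1.001, 1.002,
                                   1.003, 1.004, 1.005, 1.006))
  expect_equal(detect_final_height(noisy)$fh, 1.0)
  expect_error(detect_final_height(mono[1:3, ]), "k_flat")
})

test_that("raising the flatness tolerance never delays the plateau", {
  set.seed(31)
  d0 <- as.Date("2016-05-01")
  for (i in 1:20) {
    h <- cumsum(pmax(stats::rnorm(15, 20, 15), 0)) / 1000
    s <- data.frame(date = d0 + seq(0, by = 4, length.out = 15),
                    height_m = h)
    prev <- as.Date(Inf)
    for (tol in c(1, 5, 20, 60)) {
      r <- detect_final_height(s, tol_mm = tol)
      cur <- if (r$no_plateau) as.Date(Inf) else r$plateau_date
      expect_lte(as.numeric(cur), as.numeric(prev))
      prev <- cur
    }
  }
})

test_that("phase timings interpolate linearly to the 15% and 95% crossings", {
  # constant 10 C/day: gdd = 10 * day; height linear from 0 at GDD 500
  # to fh at GDD 1500
  days <- as.Date("2016-01-01") + 0:200
  tt <- data.frame(date = days, gdd = 10 * (0:200))
  obs_days <- seq(40, 170, by = 5)
  fh <- 1.2
  h <- pmin(pmax((10 * obs_days - 500) / 1000, 0), 1) * fh
  s <- data.frame(date = as.Date("2016-01-01") + obs_days, height_m = h)
  pt <- extract_phase_timings(s, fh, tt)
  expect_equal(pt$gdd15, 650, tolerance = 1e-8)
  expect_equal(pt$gdd95, 1450, tolerance = 1e-8)
  dur <- derive_durations(pt$gdd15, pt$gdd95, tt)
  expect_equal(dur$gdd_se, 800, tolerance = 1e-8)
  expect_equal(dur$time_se, 80, tolerance = 1e-8)

  short <- s[s$height_m < 0.9 * fh, ]
  expect_error(extract_phase_timings(short, fh, tt), "phase incomplete")
  expect_error(derive_durations(1450, 650, tt), "gdd15 < gdd95")
})

test_that("time_se equals gdd_se over the rate for uniform accumulation", {
  tt <- data.frame(date = as.Date("2016-01-01") + 0:200, gdd = 10 * (0:200))
  dur <- derive_durations(650, 1450, tt)
  expect_equal(dur$time_se, dur$gdd_se / 10, tolerance = 1e-10)
})

test_that("noiseless simulated plots recover the generator's truths", {
  cfg <- noiseless_config(n_genotypes = 10)
  trial <- simulate_trial(cfg)
  # noiseless series warrant a tight flatness tolerance, so the plateau is
  # located exactly where growth stops
  tp <- extract_traits(trial$heights, trial$temperature, trial$sowing,
                       tol_mm = 1)
  truth <- trial$truth
  i <- match(tp$genotype_id, truth$genotype_id)
  expect_true(all(!tp$phase_incomplete))
  # final height equals the cap exactly
  expect_equal(tp$fh_m, truth$true_final_height[i], tolerance = 1e-12)
  # crossing of 15% of final height sits within one measurement interval
  # (3-4 days at 14 C, ~56 degC d) of the thermal onset of elongation
  expect_true(all(abs(tp$gdd15 - truth$true_start_gdd[i]) < 60))

  # day-loop oracle: rebuild each latent daily trajectory from the genotype
  # truths and locate the daily 95% crossing in thermal time
  yr <- 2015
  tm <- trial$temperature[trial$temperature$year == yr, ]
  sow <- trial$sowing$sowing_date[trial$sowing$year == yr]
  gdd_d <- cumsum(ifelse(as.Date(tm$date) > as.Date(sow),
                         pmax(tm$tmean_c, 0), 0))
  for (g in truth$genotype_id) {
    p <- truth[truth$genotype_id == g, ]
    fh_mm <- p$true_final_height * 1000
    h <- 0.12 * fh_mm
    cross95 <- NA_real_
    for (d in seq_along(gdd_d)) {
      if (gdd_d[d] > p$true_start_gdd && gdd_d[d] <= p$true_end_gdd)
        h <- min(h + p$true_vigour + p$true_slope * (tm$tmean_c[d] - 9),
                 fh_mm)
      if (is.na(cross95) && h >= 0.95 * fh_mm) { cross95 <- gdd_d[d]; break }
    }
    got <- tp$gdd95[tp$genotype_id == g & tp$year == yr]
    expect_true(all(abs(got - cross95) < 60), info = g)
  }
  # identities
  expect_equal(tp$gdd_se, tp$gdd95 - tp$gdd15, tolerance = 1e-12)
  expect_true(all(tp$gdd15 < tp$gdd95))
})

test_that("SER composed with cumulative daily growth is the identity", {
  set.seed(12)
  rates <- pmax(stats::rnorm(30, 20, 8), 0)
  h <- cumsum(rates) / 1000
  s <- data.frame(date = as.Date("2016-05-01") + 1:30, height_m = h)
  r <- compute_ser(s)
  expect_equal(r$ser, rates[-1], tolerance = 1e-12)
})
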