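test_that("climatology of a constant series is the constant, with offset thresholds", {
  clim <- compute_climatology(flat_sst(29), climatology_config(baseline_years = 1985:1990))
  expect_equal(clim$mmm, 29)
  expect_equal(clim$bleaching_threshold, 29.5)
  expect_equal(unname(clim$cooling_threshold), rep(28.5, 12))
  expect_equal(unname(clim$monthly_mean), rep(29, 12))
})

test_that("climatology of a noiseless sinusoid matches the closed-form month means", {
  dates <- seq(as.Date("1985-01-01"), as.Date("1990-12-31"), by = "day")
  peak <- 105; A <- 1.3; base <- 28
  doy <- as.integer(format(dates, "%j"))
  sst <- data.frame(date = dates, sst_c = base + A * cos(2 * pi * (doy - peak) / 365.25))
  clim <- compute_climatology(sst, climatology_config(baseline_years = 1985:1990))

  # oracle: geometric-sum closed form for the mean of cos over each month's days
  w <- 2 * pi / 365.25
  month_mean <- function(m) {
    vals <- unlist(lapply(1985:1990, function(y) {
      d <- seq(as.Date(sprintf("%d-%02d-01", y, m)),
               by = "day", length.out = 31)
      d <- d[as.integer(format(d, "%m")) == m]
      j <- as.integer(format(d, "%j"))
      n <- length(j)
      th <- w * (j[1] - peak)
      # sum_{k=0}^{n-1} cos(th + k w) = Re[ e^{i th} (1 - e^{i n w}) / (1 - e^{i w}) ]
      Re(exp(1i * th) * (1 - exp(1i * n * w)) / (1 - exp(1i * w))) / n
    }))
    base + A * mean(vals)
  }
  oracle <- vapply(1:12, month_mean, numeric(1))
  expect_equal(unname(clim$monthly_mean), oracle, tolerance = 1e-9)
  expect_equal(clim$mmm, max(oracle), tolerance = 1e-9)
})

test_that("a calendar month absent from every baseline year is a named error", {
  s <- flat_sst(29, "1985-01-01", "1985-11-30")   # December never observed
  expect_error(compute_climatology(s, climatology_config(baseline_years = 1985)),
               "Dec", class = "reefshift_climatology_error")
})

test_that("DHW reaches its closed-form steady state and decays as exceedance stops", {
  clim <- compute_climatology(flat_sst(29), climatology_config(baseline_years = 1985:1990))
  n <- 200
  dates <- seq(as.Date("1994-01-01"), by = "day", length.out = n)

  for (h in c(0.7, 1, 2)) {
    s <- data.frame(date = dates, sst_c = rep(29 + h, n))
    dhw <- compute_dhw(s, clim)
    expect_equal(dhw$dhw_c_weeks[n], 84 * h / 7)   # = 12 h degC-weeks
    expect_true(all(is.na(dhw$dhw_c_weeks[1:83])))
  }

  step <- data.frame(date = seq(as.Date("1994-01-01"), by = "day", length.out = 84),
                     sst_c = c(rep(30, 42), rep(28.5, 42)))
  dhw <- compute_dhw(step, clim)
  expect_equal(dhw$dhw_c_weeks[84], 42 * 1 / 7)    # 6 degC-weeks

  # never above the threshold -> identically zero
  calm <- data.frame(date = dates, sst_c = rep(29.4, n))
  expect_true(all(compute_dhw(calm, clim)$dhw_c_weeks == 0, na.rm = TRUE))

  # day-count variant accumulates 1 per exceedance day regardless of magnitude
  s2 <- data.frame(date = dates, sst_c = rep(31, n))
  expect_equal(compute_dhw(s2, clim, count_days = TRUE)$dhw_c_weeks[n], 12)
  expect_equal(compute_dhw(s2, clim)$dhw_c_weeks[n], 24)
})

test_that("DHW equals the brute-force window sum on random series and is translation-consistent", {
  set.seed(11)
  dates <- seq(as.Date("1994-01-01"), by = "day", length.out = 400)
  sst <- data.frame(date = dates, sst_c = 29 + cumsum(rnorm(400, 0, 0.15)))
  clim <- compute_climatology(flat_sst(29), climatology_config(baseline_years = 1985:1990))
  dhw <- compute_dhw(sst, clim)
  hot <- ifelse(sst$sst_c > clim$bleaching_threshold, sst$sst_c - clim$mmm, 0)
  brute <- vapply(seq_along(hot), function(i) {
    if (i < 84) NA_real_ else sum(hot[(i - 83):i]) / 7
  }, numeric(1))
  expect_equal(dhw$dhw_c_weeks, brute, tolerance = 1e-12)

  shifted <- sst; shifted$sst_c <- shifted$sst_c + 2.5
  clim2 <- compute_climatology(flat_sst(31.5), climatology_config(baseline_years = 1985:1990))
  expect_equal(compute_dhw(shifted, clim2)$dhw_c_weeks, dhw$dhw_c_weeks)

  short <- sst[1:30, ]
  expect_warning(out <- compute_dhw(short, clim), "shorter")
  expect_equal(nrow(out), 0)
})

test_that("annual exceedance counts saturate, localize, and respond monotonically to offsets", {
  clim <- compute_climatology(flat_sst(29), climatology_config(baseline_years = 1985:1990))
  at_mmm <- flat_sst(29, "1994-01-01", "1995-12-31")
  ann <- annual_exceedance(at_mmm, clim)
  expect_equal(ann$warm_days, c(0L, 0L))
  expect_equal(ann$cool_days, c(0L, 0L))

  cold <- flat_sst(28.4, "1994-01-01", "1994-12-31")   # cooling threshold - 0.1
  expect_equal(annual_exceedance(cold, clim)$cool_days, 365L)

  inject <- flat_sst(29, "1994-01-01", "1994-12-31")
  inject$sst_c[50:59] <- 29.6                          # exactly 10 warm days
  expect_equal(annual_exceedance(inject, clim)$warm_days, 10L)

  set.seed(21)
  noisy <- flat_sst(29, "1994-01-01", "1994-12-31")
  noisy$sst_c <- noisy$sst_c + rnorm(nrow(noisy), 0, 0.6)
  counts <- sapply(c(0.2, 0.5, 0.8), function(off) {
    cl <- compute_climatology(flat_sst(29),
                              climatology_config(baseline_years = 1985:1990,
                                                 hotspot_offset = off, cool_offset = off))
    a <- annual_exceedance(noisy, cl)
    c(a$warm_days, a$cool_days)
  })
  expect_true(all(diff(counts[1, ]) <= 0))   # warm days non-increasing in offset
  expect_true(all(diff(counts[2, ]) <= 0))   # cool days non-increasing in offset
})

test_that("fit_trend recovers exact lines and reports the standard decomposition", {
  x <- 1:20
  fit <- fit_trend(x, 3 + 0.7 * x)
  expect_equal(fit$slope, 0.7)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$df, c(1, 18))
  expect_error(fit_trend(rep(1, 10), rnorm(10)), class = "reefshift_fit_error")
  expect_error(fit_trend(1:2, 1:2), class = "reefshift_fit_error")

  set.seed(4)
  cov <- data.frame(oni = rnorm(40))
  y <- 1 + 0.5 * (1:40) + 2 * cov$oni + rnorm(40, 0, 0.1)
  fit2 <- fit_trend(1:40, y, covariates = cov)
  expect_equal(unname(fit2$coefficients["oni"]), 2, tolerance = 0.05)
  expect_equal(fit2$df[1], 2)
})

test_that("simulated warming trends are recovered within 3 SE across 20 seeds", {
  # oracle: OLS on the noiseless series; the seasonal component's calendar
  # sampling contributes a small deterministic offset shared by every seed
  clean <- sst_sim_config(start_date = "1985-01-01", end_date = "2024-12-31",
                          trend = 0.23, noise_sd = 0, anomaly_events = list(),
                          seed = 1L)
  sst0 <- simulate_sst(clean)
  slope0 <- fit_trend(sst0$date, sst0$sst_c)$slope_per_decade
  expect_lt(abs(slope0 - 0.23), 0.02)

  slopes <- vapply(1:20, function(s) {
    cfg <- sst_sim_config(start_date = "1985-01-01", end_date = "2024-12-31",
                          trend = 0.23, anomaly_events = list(), seed = 300L + s)
    sst <- simulate_sst(cfg)
    fit_trend(sst$date, sst$sst_c)$slope_per_decade
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - slope0), 3 * se)
})

test_that("logger aggregation reproduces translations and diurnal ranges", {
  ts <- seq(as.POSIXct("2024-06-01 00:00", tz = "UTC"),
            as.POSIXct("2024-07-31 23:00", tz = "UTC"), by = "hour")
  const <- data.frame(site = "A", datetime = ts, temp_c = 28)
  agg <- aggregate_logger(const)
  expect_equal(agg$mean_c, c(28, 28))
  expect_equal(agg$max_c, agg$min_c)

  two <- rbind(const, transform(const, site = "B", temp_c = 28 + 1.63))
  agg2 <- aggregate_logger(two)
  expect_equal(agg2$mean_c[agg2$site == "B"] - agg2$mean_c[agg2$site == "A"],
               c(1.63, 1.63))

  a <- 0.9
  hrs <- as.numeric(format(ts, "%H"))
  diurnal <- data.frame(site = "C", datetime = ts,
                        temp_c = 28 + a * sin(2 * pi * hrs / 24))
  agg3 <- aggregate_logger(diurnal)
  expect_equal(agg3$max_c - agg3$min_c, rep(2 * a, 2), tolerance = 0.02)
})
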