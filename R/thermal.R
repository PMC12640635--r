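#' Climatology configuration
#'
#' Settings for the SST climatology and the modified degree-heating-weeks
#' (DHW) accumulation. The defaults follow the NOAA Coral Reef Watch
#' convention adapted for localized bleaching sensitivity: a bleaching
#' threshold of MMM + 0.5 degC (rather than + 1 degC), a cooling threshold
#' of the climatological monthly mean - 0.5 degC, and a 12-week (84-day)
#' trailing accumulation window.
#'
#' @param baseline_years integer vector of years defining the climatological
#'   baseline. Default `c(1985:1990, 1993)` excludes 1991-1992 (volcanic
#'   aerosol anomalies).
#' @param hotspot_offset degC added to MMM to form the bleaching threshold.
#' @param cool_offset degC subtracted from each monthly mean to form the
#'   cooling threshold.
#' @param window_days trailing accumulation window, in days (12 weeks = 84).
#' @return A `climatology_config` list.
#' @export
climatology_config <- function(baseline_years = c(1985:1990, 1993),
                               hotspot_offset = 0.5,
                               cool_offset = 0.5,
                               window_days = 84L) {
  if (!length(baseline_years)) {
    stop_("baseline_years must be nonempty", class = "reefshift_config_error")
  }
  if (hotspot_offset < 0 || cool_offset < 0) {
    stop_("offsets must be >= 0", class = "reefshift_config_error")
  }
  if (window_days < 7) {
    stop_("window_days must be >= 7", class = "reefshift_config_error")
  }
  structure(list(baseline_years = as.integer(baseline_years),
                 hotspot_offset = hotspot_offset,
                 cool_offset = cool_offset,
                 window_days = as.integer(window_days)),
            class = "climatology_config")
}

#' Compute a thermal-stress climatology from daily SST
#'
#' Two-stage climatology: daily values are averaged within each year-month,
#' those year-month means are averaged (unweighted) across the baseline
#' years to give twelve climatological monthly means, and the Maximum of
#' Monthly Means (MMM) is their maximum. The bleaching threshold is
#' MMM + `hotspot_offset`; the cooling threshold is the monthly mean minus
#' `cool_offset` (one value per calendar month).
#'
#' @param series data.frame with columns `date` (Date or ISO 8601) and
#'   `sst_c` (degC).
#' @param config a [climatology_config()].
#' @return A `thermal_climatology` object: `monthly_mean` (12 values),
#'   `mmm`, `bleaching_threshold`, `cooling_threshold` (12 values), plus the
#'   config used.
#' @export
compute_climatology <- function(series, config = climatology_config()) {
  series <- validate_sst(series)
  date <- as_date(series$date)
  yr <- as.integer(format(date, "%Y"))
  mo <- as.integer(format(date, "%m"))
  keep <- yr %in% config$baseline_years & !is.na(series$sst_c)
  if (!any(keep)) {
    stop_("no data in baseline years", class = "reefshift_climatology_error")
  }
  ym_mean <- tapply(series$sst_c[keep], list(yr[keep], mo[keep]), mean)
  monthly_mean <- apply(ym_mean, 2, mean, na.rm = TRUE)
  present <- as.integer(colnames(ym_mean))
  full <- rep(NA_real_, 12)
  full[present] <- monthly_mean
  if (anyNA(full)) {
    stop_("calendar month(s) absent from all baseline years: ",
          paste(month.abb[which(is.na(full))], collapse = ", "),
          class = "reefshift_climatology_error")
  }
  mmm <- max(full)
  structure(list(monthly_mean = stats::setNames(full, month.abb),
                 mmm = mmm,
                 bleaching_threshold = mmm + config$hotspot_offset,
                 cooling_threshold = stats::setNames(full - config$cool_offset, month.abb),
                 config = config),
            class = "thermal_climatology")
}

#' @export
print.thermal_climatology <- function(x, ...) {
  cat("Thermal climatology (baseline:",
      paste(range(x$config$baseline_years), collapse = "-"), ")\n")
  cat(sprintf("  MMM                 %.3f degC\n", x$mmm))
  cat(sprintf("  bleaching threshold %.3f degC (MMM + %.2f)\n",
              x$bleaching_threshold, x$config$hotspot_offset))
  cat("  monthly means:", paste(sprintf("%.2f", x$monthly_mean), collapse = " "), "\n")
  invisible(x)
}

#' Modified degree heating weeks
#'
#' Accumulates thermal stress over a trailing window: on each day with
#' SST strictly above the bleaching threshold (MMM + `hotspot_offset`) the
#' hotspot magnitude SST - MMM is accumulated; the sum over the trailing
#' `window_days` is divided by 7 to express the result in degC-weeks.
#' Setting `count_days = TRUE` instead accumulates a day count (exceedance
#' days / 7), exposed for sensitivity analysis.
#'
#' Days missing from the series contribute zero to the window; a warning is
#' issued when more than 10% of the covered range is missing. DHW is
#' reported as `NA` for the first `window_days - 1` dates (incomplete
#' trailing window).
#'
#' @param series daily SST data.frame (`date`, `sst_c`).
#' @param clim a [compute_climatology()] result.
#' @param config a [climatology_config()]; defaults to the one stored in
#'   `clim`.
#' @param count_days accumulate exceedance-day counts instead of hotspot
#'   magnitudes.
#' @return data.frame with columns `date`, `dhw_c_weeks`.
#' @export
compute_dhw <- function(series, clim, config = clim$config, count_days = FALSE) {
  series <- validate_sst(series)
  dates <- as_date(series$date)
  grid <- seq(min(dates), max(dates), by = "day")
  if (length(grid) < config$window_days) {
    warning("series shorter than the accumulation window; empty DHW result")
    return(data.frame(date = as.Date(character()), dhw_c_weeks = numeric()))
  }
  sst <- rep(NA_real_, length(grid))
  sst[match(dates, grid)] <- series$sst_c
  n_missing <- sum(is.na(sst))
  if (n_missing > 0.10 * length(grid)) {
    warning(sprintf("%d of %d days missing (> 10%%); they contribute 0 to DHW",
                    n_missing, length(grid)))
  }
  exceed <- !is.na(sst) & sst > clim$bleaching_threshold
  hotspot <- ifelse(exceed, if (count_days) 1 else sst - clim$mmm, 0)
  w <- config$window_days
  cs <- cumsum(hotspot)
  dhw <- (cs - c(rep(0, w), utils::head(cs, -w))) / 7
  dhw[seq_len(w - 1L)] <- NA_real_
  data.frame(date = grid, dhw_c_weeks = dhw)
}

#' Annual threshold-exceedance frequencies
#'
#' Counts, per calendar year, warm days (SST strictly above the bleaching
#' threshold) and cool days (SST strictly below that calendar month's
#' cooling threshold). Missing days are excluded from both counts.
#'
#' @inheritParams compute_dhw
#' @return data.frame with columns `year`, `warm_days`, `cool_days`.
#' @export
annual_exceedance <- function(series, clim) {
  series <- validate_sst(series)
  date <- as_date(series$date)
  ok <- !is.na(series$sst_c)
  yr <- as.integer(format(date, "%Y"))[ok]
  mo <- as.integer(format(date, "%m"))[ok]
  sst <- series$sst_c[ok]
  warm <- sst > clim$bleaching_threshold
  cool <- sst < clim$cooling_threshold[mo]
  years <- sort(unique(yr))
  data.frame(year = years,
             warm_days = as.integer(tapply(warm, factor(yr, years), sum)),
             cool_days = as.integer(tapply(cool, factor(yr, years), sum)))
}

#' Ordinary least-squares trend fit
#'
#' Thin wrapper around [stats::lm()] returning the slope of the first
#' predictor with the standard F / R-squared decomposition, used for
#' long-term SST trends and annual exceedance-frequency trends. Optional
#' covariates (e.g. a monthly ENSO index aligned to `x`) enter additively.
#'
#' @param x numeric predictor (or Date, converted to decimal years so the
#'   slope is per year).
#' @param y numeric response.
#' @param covariates optional data.frame of additional predictors.
#' @return A `trend_fit` list: `slope`, `intercept`, `r_squared`,
#'   `f_statistic`, `df` (c(model, residual)), `p_value`, `coefficients`,
#'   and `slope_per_decade` when `x` is date-like.
#' @export
fit_trend <- function(x, y, covariates = NULL) {
  dated <- inherits(x, "Date")
  if (dated) x <- year_fraction(x)
  if (length(x) != length(y)) {
    stop_("x and y lengths differ", class = "reefshift_fit_error")
  }
  if (length(x) < 3) stop_("need n >= 3", class = "reefshift_fit_error")
  if (stats::sd(x) == 0) {
    stop_("predictor has zero variance", class = "reefshift_fit_error")
  }
  dat <- data.frame(.y = y, .x = x)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  out <- list(slope = unname(coef(fit)[".x"]),
              intercept = unname(coef(fit)[1]),
              r_squared = sm$r.squared,
              f_statistic = unname(fstat["value"]),
              df = unname(c(fstat["numdf"], fstat["dendf"])),
              p_value = unname(stats::pf(fstat["value"], fstat["numdf"],
                                         fstat["dendf"], lower.tail = FALSE)),
              coefficients = coef(fit),
              n = length(y))
  if (dated) out$slope_per_decade <- out$slope * 10
  structure(out, class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("OLS trend: slope = %.4g", x$slope))
  if (!is.null(x$slope_per_decade)) {
    cat(sprintf(" (%.3f per decade)", x$slope_per_decade))
  }
  cat(sprintf("\n  R^2 = %.3f, F(%d,%d) = %.2f, p = %.3g\n",
              x$r_squared, x$df[1], x$df[2], x$f_statistic, x$p_value))
  invisible(x)
}

#' Monthly aggregation of in-situ logger records
#'
#' Collapses sub-daily logger temperatures to one row per site-month with
#' mean, maximum and minimum; months with no data are omitted.
#'
#' @param records data.frame with columns `site`, `datetime` (POSIXct or
#'   parseable), `temp_c`.
#' @return data.frame: `site`, `year`, `month`, `mean_c`, `max_c`, `min_c`.
#' @export
aggregate_logger <- function(records) {
  check_columns(records, c("site", "datetime", "temp_c"), "logger table")
  ts <- records$datetime
  if (!inherits(ts, "POSIXt")) ts <- as.POSIXct(ts, tz = "UTC")
  if (anyNA(ts)) stop_("unparseable logger timestamps", class = "reefshift_validation_error")
  key <- data.frame(site = trimws(as.character(records$site)),
                    year = as.integer(format(ts, "%Y")),
                    month = as.integer(format(ts, "%m")))
  agg <- function(f) stats::aggregate(records$temp_c, key, f)$x
  out <- stats::aggregate(records$temp_c, key, mean)
  names(out)[4] <- "mean_c"
  out$max_c <- agg(max)
  out$min_c <- agg(min)
  out[order(out$site, out$year, out$month), , drop = FALSE]
}
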