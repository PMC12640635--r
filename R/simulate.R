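#' Default episodic warm-anomaly events for the SST generator
#'
#' Half-sine warm pulses emulating the El Nino events visible in a
#' 1985-2025 eastern-Pacific record, including a triple-peak 2023-24 event
#' whose largest pulse pushes the warm-season peak to ~31.2 degC.
#' @return list of events (`start_date`, `duration_days`, `peak_magnitude`).
#' @export
default_anomaly_events <- function() {
  ev <- function(s, d, m) list(start_date = as.Date(s), duration_days = d, peak_magnitude = m)
  list(ev("1997-06-01", 330, 1.1),
       ev("2009-10-01", 210, 0.8),
       ev("2015-06-01", 400, 1.2),
       ev("2019-11-01", 150, 0.7),
       ev("2023-06-01", 150, 1.0),
       ev("2023-11-01", 170, 1.4),
       ev("2024-04-20", 120, 0.9))
}

#' Configuration for the daily-SST generator
#'
#' The defaults state the world the analysis targets: a ~40-year daily
#' record with an annual cycle peaking in boreal spring, a linear warming
#' trend of 0.23 degC per decade, stationary AR(1) noise, and the
#' [default_anomaly_events()] warm pulses. With these defaults the
#' baseline-period climatology lands near MMM = 29.08 degC and the series
#' maximum near 31.2 degC.
#'
#' @param start_date,end_date series extent (>= 2 years apart).
#' @param base_mean annual-mean SST, degC.
#' @param seasonal_amplitude amplitude of the annual sinusoid, degC.
#' @param seasonal_peak_doy calendar day of the seasonal maximum.
#' @param trend linear warming, degC per decade.
#' @param ar1_coef lag-1 autocorrelation of the daily noise, in [0, 1).
#' @param noise_sd stationary SD of the daily noise, degC.
#' @param anomaly_events list of half-sine warm pulses.
#' @param seed integer seed.
#' @return `sst_sim_config` list.
#' @export
sst_sim_config <- function(start_date = "1985-01-01", end_date = "2025-03-31",
                           base_mean = 28.0, seasonal_amplitude = 1.0,
                           seasonal_peak_doy = 105L,
                           trend = 0.23, ar1_coef = 0.75, noise_sd = 0.25,
                           anomaly_events = default_anomaly_events(),
                           seed = 1L) {
  start_date <- as_date(start_date); end_date <- as_date(end_date)
  if (as.numeric(end_date - start_date) < 2 * 365) {
    stop_("SST simulation needs >= 2 years", class = "reefshift_config_error")
  }
  if (noise_sd < 0) stop_("noise_sd must be >= 0", class = "reefshift_config_error")
  if (abs(ar1_coef) >= 1) stop_("|ar1_coef| must be < 1", class = "reefshift_config_error")
  structure(list(start_date = start_date, end_date = end_date,
                 base_mean = base_mean, seasonal_amplitude = seasonal_amplitude,
                 seasonal_peak_doy = as.integer(seasonal_peak_doy),
                 trend = trend, ar1_coef = ar1_coef, noise_sd = noise_sd,
                 anomaly_events = anomaly_events, seed = as.integer(seed)),
            class = "sst_sim_config")
}

#' Simulate a daily SST series
#'
#' `SST(t) = base_mean + seasonal sinusoid + trend + AR(1) noise + warm
#' pulses`. The AR(1) process is initialized at its stationary distribution
#' (no burn-in artifact) and parameterized by its stationary SD, so the
#' marginal noise SD equals `noise_sd` for any `ar1_coef`. Each anomaly
#' event adds `peak_magnitude * sin(pi * d / duration)` on days
#' `d = 0 .. duration - 1` after its start. Bit-identical under a fixed
#' seed.
#'
#' @param config an [sst_sim_config()].
#' @return data.frame with columns `date`, `sst_c` (one row per day).
#' @export
simulate_sst <- function(config = sst_sim_config()) {
  stopifnot(inherits(config, "sst_sim_config"))
  dates <- seq(config$start_date, config$end_date, by = "day")
  n <- length(dates)
  t_years <- year_fraction(dates) - year_fraction(config$start_date)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- config$seasonal_amplitude *
    cos(2 * pi * (doy - config$seasonal_peak_doy) / 365.25)
  trend <- (config$trend / 10) * t_years

  set.seed(config$seed)
  noise <- numeric(n)
  if (config$noise_sd > 0) {
    noise[1] <- stats::rnorm(1, 0, config$noise_sd)
    innov_sd <- config$noise_sd * sqrt(1 - config$ar1_coef^2)
    eps <- stats::rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) noise[i] <- config$ar1_coef * noise[i - 1] + eps[i - 1]
  }

  bumps <- numeric(n)
  for (ev in config$anomaly_events) {
    i0 <- match(as_date(ev$start_date), dates)
    if (is.na(i0)) next
    d <- seq_len(ev$duration_days) - 1L
    idx <- i0 + d
    keep <- idx <= n
    bumps[idx[keep]] <- bumps[idx[keep]] +
      ev$peak_magnitude * sin(pi * d[keep] / ev$duration_days)
  }

  data.frame(date = dates,
             sst_c = config$base_mean + seasonal + trend + noise + bumps)
}

#' Nine monitored reef sites, ordered by recovery feasibility
#'
#' Site names from best to worst stated recovery potential; the generator's
#' per-site defaults (benthic quality tilt, bleaching, diversity) are keyed
#' to this order.
#' @export
reef_sites <- c("Chorro", "Esquina", "Este Intermedio", "Tina", "Cueva",
                "Barco Somero", "Ancla", "San Josecito", "Barco Profundo")

default_benthic_weights <- function() {
  # before/after category profiles of a coral-to-turf shift; the leftover
  # "other" mass covers sand/rubble/rock so transects close to 1
  before <- c(coral = 0.193, macroalgae = 0.017, turf = 0.337, cca = 0.094,
              cyanobacteria = 0.016, bleached = 0.192, dead_coral = 0.093)
  before <- c(before, other = 1 - sum(before))
  after <- c(coral = 0.115, macroalgae = 0.011, turf = 0.575, cca = 0.106,
             cyanobacteria = 0.004, bleached = 0.260, dead_coral = 0.017)
  after <- c(after, other = 0.05)
  list(before = before / sum(before), after = after / sum(after))
}

#' Configuration for the benthic / belt-transect survey generator
#'
#' Defaults state a nine-site monitoring program surveyed monthly from
#' March 2024 to February 2025 with three transects per survey. Benthic
#' cover is a Dirichlet draw whose concentration switches from a
#' coral-dominated to a turf-dominated profile at `period_breakpoint`, with
#' a per-site quality tilt (favourable categories up-weighted at
#' high-feasibility sites). Belt transects draw colony counts from a
#' Poisson-multinomial with per-site taxon-abundance profiles whose
#' evenness hits a target effective number of taxa (`site_diversity`,
#' `= exp(H)`); colony health states follow a site-level logit-normal
#' bleached fraction.
#'
#' @param sites site names.
#' @param transects_per_survey transects per site per date.
#' @param survey_dates survey dates.
#' @param period_breakpoint first date of the shifted (post-disturbance)
#'   compositional regime.
#' @param baseline_concentration,shift_concentration named positive
#'   category weights for the Dirichlet draws (identical name sets).
#' @param concentration_total total Dirichlet concentration (controls
#'   transect-to-transect variability).
#' @param site_quality named per-site tilt in [-1, 1]; positive favours
#'   coral/cca, negative favours turf/cyanobacteria/bleached/dead_coral.
#' @param taxa_pool coral taxon names for belt transects.
#' @param site_diversity named per-site effective number of taxa (`exp(H)`);
#'   1 means a single taxon.
#' @param site_bleaching_logit_mean named per-site logit-scale mean
#'   bleached fraction.
#' @param site_bleaching_logit_sd SD of the site-level logit-normal draw.
#' @param colonies_per_transect_mean Poisson mean colony count per transect.
#' @param seed integer seed.
#' @return `survey_sim_config` list.
#' @export
survey_sim_config <- function(sites = reef_sites,
                              transects_per_survey = 3L,
                              survey_dates = seq(as.Date("2024-03-15"),
                                                 as.Date("2025-02-15"), by = "month"),
                              period_breakpoint = "2024-10-01",
                              baseline_concentration = default_benthic_weights()$before,
                              shift_concentration = default_benthic_weights()$after,
                              concentration_total = 60,
                              site_quality = stats::setNames(
                                seq(0.8, -0.8, length.out = length(sites)), sites),
                              taxa_pool = c("Pocillopora spp.", "Porites lobata",
                                            "Pavona clavus", "Pavona gigantea",
                                            "Pavona varians", "Pavona maldiviensis",
                                            "Pavona chiriquiensis", "Pavona frondifera",
                                            "Psammocora stellata", "Psammocora profundacella",
                                            "Tubastraea coccinea", "Gardineroseris planulata"),
                              site_diversity = stats::setNames(
                                exp(c(0.80, 0.60, 0.43, 0.80, 1.28, 0.90, 1.14, 0.12, 0.70)),
                                reef_sites)[sites],
                              site_bleaching_logit_mean = stats::setNames(
                                -1.17 + 0.48 * c(-1.6, -1.2, -0.8, -0.4, 0, 0.3, 0.6, 1.0, 1.5),
                                reef_sites)[sites],
                              site_bleaching_logit_sd = 0.15,
                              colonies_per_transect_mean = 80,
                              seed = 1L) {
  if (any(baseline_concentration <= 0) || any(shift_concentration <= 0)) {
    stop_("concentration weights must be strictly positive",
          class = "reefshift_config_error")
  }
  if (!setequal(names(baseline_concentration), names(shift_concentration))) {
    stop_("baseline and shift concentrations name different categories",
          class = "reefshift_config_error")
  }
  if (!is.null(names(site_quality)) && length(setdiff(names(site_quality), sites))) {
    stop_("site_quality names unknown site(s)", class = "reefshift_config_error")
  }
  if (anyNA(site_diversity) || anyNA(site_bleaching_logit_mean)) {
    stop_("custom sites need explicit site_diversity and site_bleaching_logit_mean",
          class = "reefshift_config_error")
  }
  if (any(site_diversity < 1) || any(site_diversity > length(taxa_pool))) {
    stop_("site_diversity (effective taxa) must lie in [1, #taxa]",
          class = "reefshift_config_error")
  }
  structure(list(sites = sites, transects_per_survey = as.integer(transects_per_survey),
                 survey_dates = as_date(survey_dates),
                 period_breakpoint = as_date(period_breakpoint),
                 baseline_concentration = baseline_concentration,
                 shift_concentration = shift_concentration[names(baseline_concentration)],
                 concentration_total = concentration_total,
                 site_quality = site_quality,
                 taxa_pool = taxa_pool,
                 site_diversity = site_diversity,
                 site_bleaching_logit_mean = site_bleaching_logit_mean,
                 site_bleaching_logit_sd = site_bleaching_logit_sd,
                 colonies_per_transect_mean = colonies_per_transect_mean,
                 seed = as.integer(seed)),
            class = "survey_sim_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# geometric taxon-abundance profile whose Shannon entropy equals `target_h`
geometric_profile <- function(k, target_h) {
  entropy <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  if (target_h <= 1e-9) return(c(1, rep(0, k - 1)))
  if (target_h >= log(k) - 1e-9) return(rep(1 / k, k))
  f <- function(r) entropy(r^(0:(k - 1)) / sum(r^(0:(k - 1)))) - target_h
  r <- stats::uniroot(f, c(1e-8, 1 - 1e-8), tol = 1e-12)$root
  r^(0:(k - 1)) / sum(r^(0:(k - 1)))
}

# Profile whose *plug-in* Shannon estimate at n colonies is expected near
# `target_h`: the plug-in estimator is biased low by ~ (S_obs - 1) / (2n)
# (Miller-Madow), so the population entropy is raised by that amount,
# iterating because the expected observed richness S_obs depends on the
# profile. Reported site diversity is an observed statistic, so the
# generator targets the statistic, not the population quantity.
sample_matched_profile <- function(k, target_h, n) {
  if (target_h <= 1e-9) return(geometric_profile(k, 0))
  h_adj <- target_h
  p <- geometric_profile(k, h_adj)
  for (i in 1:3) {
    s_obs <- sum(1 - (1 - p)^n)
    h_adj <- min(target_h + (s_obs - 1) / (2 * n), log(k))
    p <- geometric_profile(k, h_adj)
  }
  p
}

#' Simulate benthic-cover and coral belt-transect surveys
#'
#' Per transect, benthic proportions are a Dirichlet draw (so they sum to 1
#' exactly) with concentration `concentration_total * profile`, where the
#' profile is the baseline or shifted category mix (by survey date relative
#' to `period_breakpoint`) tilted by the site's quality. Belt transects
#' draw a Poisson colony count, allocate colonies multinomially across taxa
#' using the site's entropy-matched abundance profile, and assign each
#' colony a health state with a site-level logit-normal bleached fraction
#' split across the four non-healthy states.
#'
#' @param config a [survey_sim_config()].
#' @return list with `benthic` (site, date, transect, category, proportion)
#'   and `belt` (site, date, transect, taxon, health_state, count; zero
#'   counts omitted).
#' @export
simulate_surveys <- function(config = survey_sim_config()) {
  stopifnot(inherits(config, "survey_sim_config"))
  set.seed(config$seed)
  cats <- names(config$baseline_concentration)
  fav <- intersect(c("coral", "cca"), cats)
  unfav <- intersect(c("turf", "cyanobacteria", "bleached", "dead_coral"), cats)
  nonhealthy <- c("pale", "partially_bleached", "mostly_bleached", "bleached")
  state_split <- c(0.35, 0.30, 0.20, 0.15)

  site_b <- stats::plogis(stats::rnorm(length(config$sites),
                                       config$site_bleaching_logit_mean[config$sites],
                                       config$site_bleaching_logit_sd))
  names(site_b) <- config$sites
  site_taxa <- lapply(config$site_diversity[config$sites], function(s) {
    sample_matched_profile(length(config$taxa_pool), log(s),
                           config$colonies_per_transect_mean)
  })

  benthic <- list(); belt <- list(); k <- 0L
  for (s in config$sites) {
    q <- 0
    if (!is.null(config$site_quality) && s %in% names(config$site_quality)) {
      q <- unname(config$site_quality[s])
    }
    # exponential tilt: strong enough that site contrasts span the observed
    # range (coral cover ~55% at the best sites down to ~1% at the worst)
    tilt <- stats::setNames(rep(1, length(cats)), cats)
    tilt[fav] <- exp(1.5 * q)
    tilt[unfav] <- exp(-1.2 * q)
    for (d in seq_along(config$survey_dates)) {
      date <- config$survey_dates[d]
      prof <- if (date < config$period_breakpoint) config$baseline_concentration
              else config$shift_concentration
      alpha <- prof * tilt
      alpha <- config$concentration_total * alpha / sum(alpha)
      for (tr in seq_len(config$transects_per_survey)) {
        k <- k + 1L
        p <- rdirichlet1(alpha)
        benthic[[k]] <- data.frame(site = s, date = date, transect = tr,
                                   category = cats, proportion = p)
        n_col <- stats::rpois(1, config$colonies_per_transect_mean)
        if (n_col > 0) {
          taxon_n <- drop(stats::rmultinom(1, n_col, site_taxa[[s]]))
          b <- site_b[[s]]
          probs <- c(1 - b, b * state_split)
          rows <- lapply(which(taxon_n > 0), function(j) {
            st <- drop(stats::rmultinom(1, taxon_n[j], probs))
            keep <- st > 0
            data.frame(site = s, date = date, transect = tr,
                       taxon = config$taxa_pool[j],
                       health_state = c("healthy", nonhealthy)[keep],
                       count = st[keep])
          })
          belt[[k]] <- do.call(rbind, rows)
        }
      }
    }
  }
  list(benthic = do.call(rbind, benthic),
       belt = do.call(rbind, belt))
}
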