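# Shared in-code fixtures; everything is generated, nothing is stored.

# small flat SST series (constant unless overridden)
flat_sst <- function(value = 29, start = "1985-01-01", end = "1993-12-31") {
  dates <- seq(as.Date(start), as.Date(end), by = "day")
  data.frame(date = dates, sst_c = rep(value, length(dates)))
}

# tiny 2+2 community matrix used by the SIMPER brute-force oracle
toy_matrix <- function() {
  data.frame(
    site = "A", date = as.Date("2024-01-01") + c(0, 1, 200, 201), transect = 1:4,
    period = factor(c("before", "before", "after", "after"),
                    levels = c("before", "after")),
    coral = c(0.6, 0.5, 0.2, 0.3),
    turf = c(0.2, 0.3, 0.6, 0.5),
    cca = c(0.2, 0.2, 0.2, 0.2))
}

# brute-force per-variable mean between-group Bray-Curtis contributions
oracle_between_contrib <- function(X, is_after) {
  vars <- seq_len(ncol(X))
  acc <- matrix(NA_real_, nrow = sum(!is_after) * sum(is_after), ncol = ncol(X))
  k <- 0
  for (i in which(!is_after)) {
    for (j in which(is_after)) {
      k <- k + 1
      acc[k, ] <- abs(X[i, ] - X[j, ]) / (sum(X[i, ]) + sum(X[j, ]))
    }
  }
  acc
}

# quick small survey world for pipeline-level tests
small_survey_config <- function(seed = 1L, shift = TRUE) {
  w <- default_benthic_weights_for_tests()
  survey_sim_config(
    sites = c("North", "South"),
    transects_per_survey = 3L,
    survey_dates = seq(as.Date("2024-03-15"), as.Date("2025-02-15"), by = "2 months"),
    period_breakpoint = "2024-10-01",
    baseline_concentration = w$before,
    shift_concentration = if (shift) w$after else w$before,
    site_quality = c(North = 0.4, South = -0.4),
    site_diversity = c(North = 3, South = 2),
    site_bleaching_logit_mean = c(North = -1.5, South = -0.8),
    seed = seed)
}

default_benthic_weights_for_tests <- function() {
  before <- c(coral = 0.20, macroalgae = 0.02, turf = 0.33, cca = 0.09,
              cyanobacteria = 0.02, bleached = 0.19, dead_coral = 0.09, other = 0.06)
  after <- c(coral = 0.10, macroalgae = 0.01, turf = 0.53, cca = 0.10,
             cyanobacteria = 0.004, bleached = 0.24, dead_coral = 0.016, other = 0.05)
  list(before = before / sum(before), after = after / sum(after))
}
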