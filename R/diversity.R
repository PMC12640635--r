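#' Health states recognised on a belt transect
#' @export
HEALTH_STATES <- c("healthy", "pale", "partially_bleached", "mostly_bleached", "bleached")

#' Shannon diversity index (natural log)
#'
#' `H = -sum(p_i * log(p_i))` over taxa with positive counts, with
#' `p_i = count_i / total`. Reported in nats; the maximum for k taxa is
#' `log(k)`.
#'
#' @param counts nonnegative per-taxon abundances.
#' @return Shannon H in nats.
#' @export
shannon_index <- function(counts) {
  if (any(counts < 0)) stop_("negative counts", class = "reefshift_validation_error")
  total <- sum(counts)
  if (total == 0) {
    stop_("no individuals: diversity undefined", class = "reefshift_undefined_error")
  }
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Per-transect diversity from a belt table
#'
#' Aggregates a long belt table (site, date, transect, taxon, health_state,
#' count) to one row per transect with Shannon H, taxon richness and total
#' colony abundance.
#'
#' @param belt long belt-transect data.frame.
#' @return data.frame: `site`, `date`, `transect`, `shannon_h`, `richness`,
#'   `total_abundance`.
#' @export
diversity_table <- function(belt) {
  check_columns(belt, c("site", "date", "transect", "taxon", "count"), "belt table")
  key <- interaction(belt$site, as.character(belt$date), belt$transect, drop = TRUE)
  one <- function(idx) {
    taxon_counts <- tapply(belt$count[idx], belt$taxon[idx], sum)
    taxon_counts <- taxon_counts[!is.na(taxon_counts) & taxon_counts > 0]
    data.frame(site = belt$site[idx][1], date = as_date(belt$date[idx][1]),
               transect = belt$transect[idx][1],
               shannon_h = if (length(taxon_counts)) shannon_index(taxon_counts) else NA_real_,
               richness = length(taxon_counts),
               total_abundance = sum(belt$count[idx]))
  }
  rows <- lapply(split(seq_len(nrow(belt)), key), one)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$site, out$date, out$transect), , drop = FALSE]
}

#' Bleaching prevalence per transect
#'
#' Prevalence is the fraction of surveyed colonies whose health state falls
#' in `bleached_states`. The default counts every non-healthy state (pale
#' through fully bleached); pass a narrower set to exclude e.g. `pale`.
#' The choice is recorded in the result's `bleached_states` attribute.
#'
#' @param belt long belt-transect data.frame with a `health_state` column.
#' @param bleached_states subset of [HEALTH_STATES] counted as bleached.
#' @return data.frame: `site`, `date`, `transect`, `prevalence`,
#'   `n_colonies`; transects with zero colonies get `NA` prevalence.
#' @export
bleaching_prevalence <- function(belt,
                                 bleached_states = c("pale", "partially_bleached",
                                                     "mostly_bleached", "bleached")) {
  check_columns(belt, c("site", "date", "transect", "taxon", "health_state", "count"),
                "belt table")
  unknown <- setdiff(unique(belt$health_state), HEALTH_STATES)
  if (length(unknown)) {
    stop_("unknown health state(s): ", paste(unknown, collapse = ", "),
          class = "reefshift_validation_error")
  }
  key <- interaction(belt$site, as.character(belt$date), belt$transect, drop = TRUE)
  bl <- belt$health_state %in% bleached_states
  n <- tapply(belt$count, key, sum)
  nb <- tapply(belt$count * bl, key, sum)
  idx <- match(levels(key), key)
  out <- data.frame(site = belt$site[idx], date = as_date(belt$date[idx]),
                    transect = belt$transect[idx],
                    prevalence = ifelse(n[levels(key)] > 0,
                                        nb[levels(key)] / n[levels(key)], NA_real_),
                    n_colonies = as.integer(n[levels(key)]))
  rownames(out) <- NULL
  out <- out[order(out$site, out$date, out$transect), , drop = FALSE]
  attr(out, "bleached_states") <- bleached_states
  out
}

#' Inverse logit
#'
#' `1 / (1 + exp(-x))`; maps a logit-scale estimate (e.g. a beta-regression
#' intercept) back to a proportion.
#'
#' @param x numeric, logit scale.
#' @return proportion(s) in (0, 1).
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Logit transform
#' @param p proportion(s) in (0, 1).
#' @return logit-scale value(s).
#' @export
logit <- function(p) stats::qlogis(p)

#' Bound proportions away from 0 and 1
#'
#' Clips proportions to the interval used before logit-link
#' modelling to avoid boundary issues.
#'
#' @param values proportions in `[0, 1]`.
#' @param lower,upper bounds (defaults 0.0001 and 0.9999).
#' @return clipped values.
#' @export
bound_proportions <- function(values, lower = 0.0001, upper = 0.9999) {
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    stop_("values outside [0, 1]", class = "reefshift_validation_error")
  }
  pmin(pmax(values, lower), upper)
}
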