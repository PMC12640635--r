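#' Default controlled vocabulary for benthic categories
#' @export
BENTHIC_CATEGORIES <- c("coral", "macroalgae", "turf", "cca", "cyanobacteria",
                        "bleached", "dead_coral", "sand", "rubble", "rock", "other")

validate_sst <- function(df) {
  check_columns(df, c("date", "sst_c"), "SST table")
  df$date <- as_date(df$date)
  if (anyNA(df$date)) stop_("unparseable SST dates", class = "reefshift_validation_error")
  if (is.unsorted(df$date, strictly = TRUE)) {
    df <- df[order(df$date), , drop = FALSE]
    if (anyDuplicated(df$date)) {
      stop_("duplicate dates in SST series", class = "reefshift_validation_error")
    }
  }
  if (any(!is.finite(df$sst_c) & !is.na(df$sst_c))) {
    stop_("non-finite SST values", class = "reefshift_validation_error")
  }
  df
}

#' Read and validate a daily SST CSV
#'
#' Expected columns: `date` (ISO 8601), `sst_c`.
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_sst <- function(path) validate_sst(utils::read.csv(path, stringsAsFactors = FALSE))

check_proportions <- function(p, rows, what) {
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad)) {
    stop_(what, ": proportion out of [0,1] at row ", rows[bad[1]],
          " (value ", p[bad[1]], ")", class = "reefshift_validation_error")
  }
}

#' Read and validate a long benthic-cover CSV
#'
#' Expected columns: `site`, `date`, `transect`, `category`, `proportion`.
#' Categories are checked against a controlled vocabulary; per-transect
#' proportion sums within `1 +/- sum_tol` are renormalized to 1 with a
#' warning (closure error from mixed survey methods), larger deviations are
#' errors. Sums below `1 - sum_tol` are allowed when `partial = TRUE`
#' (categories not exhaustively recorded).
#'
#' @param path CSV path (or a data.frame, validated in place).
#' @param categories allowed category names (case-insensitive match).
#' @param sum_tol closure-error tolerance around 1 (default 0.05).
#' @param partial allow transects whose categories sum to < 1 - sum_tol.
#' @return validated (possibly renormalized) data.frame.
#' @export
read_benthic <- function(path, categories = BENTHIC_CATEGORIES,
                         sum_tol = 0.05, partial = FALSE) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("site", "date", "transect", "category", "proportion"),
                "benthic table")
  df$site <- trimws(as.character(df$site))
  df$date <- as_date(df$date)
  df$category <- tolower(trimws(as.character(df$category)))
  unknown <- setdiff(unique(df$category), tolower(categories))
  if (length(unknown)) {
    stop_("unknown benthic categor(ies): ", paste(unknown, collapse = ", "),
          class = "reefshift_validation_error")
  }
  check_proportions(df$proportion, seq_len(nrow(df)), "benthic table")
  key <- interaction(df$site, as.character(df$date), df$transect, drop = TRUE)
  sums <- tapply(df$proportion, key, sum)
  off <- abs(sums - 1) > sqrt(.Machine$double.eps)
  high <- sums > 1 + sum_tol
  low <- sums < 1 - sum_tol
  if (any(high) || (any(low) && !partial)) {
    bad <- names(sums)[which(high | (low & !partial))[1]]
    stop_("transect ", bad, " proportions sum to ",
          round(sums[bad], 3), " (outside 1 +/- ", sum_tol, ")",
          class = "reefshift_validation_error")
  }
  renorm <- off & !low
  if (any(renorm)) {
    warning(sum(renorm), " transect(s) renormalized to sum 1 (closure error <= ",
            sum_tol, ")")
    idx <- key %in% names(sums)[renorm]
    df$proportion[idx] <- df$proportion[idx] / sums[as.character(key[idx])]
  }
  df
}

#' Read and validate a long belt-transect CSV
#'
#' Expected columns: `site`, `date`, `transect`, `taxon`, `health_state`,
#' `count`. Health states are checked against [HEALTH_STATES]; counts must
#' be nonnegative integers.
#'
#' @param path CSV path (or a data.frame, validated in place).
#' @return validated data.frame.
#' @export
read_belt <- function(path) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("site", "date", "transect", "taxon", "health_state", "count"),
                "belt table")
  df$site <- trimws(as.character(df$site))
  df$date <- as_date(df$date)
  df$health_state <- tolower(trimws(as.character(df$health_state)))
  unknown <- setdiff(unique(df$health_state), HEALTH_STATES)
  if (length(unknown)) {
    stop_("unknown health state(s): ", paste(unknown, collapse = ", "),
          class = "reefshift_validation_error")
  }
  bad <- which(df$count < 0 | df$count != round(df$count))
  if (length(bad)) {
    stop_("belt table: count must be a nonnegative integer at row ", bad[1],
          class = "reefshift_validation_error")
  }
  df
}

#' Read and validate a logger CSV
#'
#' Expected columns: `site`, `datetime`, `temp_c` (timestamps keep
#' time-of-day).
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_logger <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("site", "datetime", "temp_c"), "logger table")
  ts <- as.POSIXct(df$datetime, tz = "UTC")
  if (anyNA(ts)) stop_("unparseable logger timestamps", class = "reefshift_validation_error")
  df$datetime <- ts
  df$site <- trimws(as.character(df$site))
  df
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order: thermal-stress climatology (if an SST path is
#' configured), SIMPER on the configured before/after windows, diversity
#' and bleaching-prevalence tables, and the recovery-feasibility index.
#' All stage outputs are written as CSV under `out_dir` together with a
#' `summary.json` (stage results and full provenance; content is
#' deterministic given the config, so repeated runs are byte-identical).
#'
#' @param config a list, or path to a JSON file, with elements:
#'   `benthic`, `belt` (paths, required), `sst`, `logger` (paths, optional),
#'   `out_dir`, `climatology` (baseline_years, hotspot_offset, cool_offset,
#'   window_days), `periods` (`before`/`after` date pairs), `simper`
#'   (`n_permutations`, `seed`), `erfi` (`window`, `direction`,
#'   `bleached_states`).
#' @return invisible list of stage results; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  for (req in c("benthic", "belt", "out_dir", "periods", "erfi")) {
    if (is.null(config[[req]])) {
      stop_("pipeline config missing '", req, "'", class = "reefshift_config_error")
    }
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  stage <- "read inputs"
  wrap <- function(expr) {
    tryCatch(expr, error = function(e) {
      manifest <- list(failed_stage = stage, completed = names(results),
                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop_("stage '", stage, "' failed: ", conditionMessage(e),
            class = "reefshift_stage_error")
    })
  }

  benthic <- wrap(read_benthic(config$benthic))
  belt <- wrap(read_belt(config$belt))

  if (!is.null(config$sst)) {
    stage <- "thermal_stress"
    wrap({
      sst <- read_sst(config$sst)
      cc <- do.call(climatology_config, config$climatology %||% list())
      clim <- compute_climatology(sst, cc)
      dhw <- compute_dhw(sst, clim)
      ann <- annual_exceedance(sst, clim)
      utils::write.csv(data.frame(month = month.abb, mean_c = unname(clim$monthly_mean)),
                       file.path(out_dir, "climatology.csv"), row.names = FALSE)
      utils::write.csv(dhw, file.path(out_dir, "dhw.csv"), row.names = FALSE)
      utils::write.csv(ann, file.path(out_dir, "annual_exceedance.csv"), row.names = FALSE)
      trend <- fit_trend(sst$date, sst$sst_c)
      results$thermal <- list(mmm = clim$mmm,
                               bleaching_threshold = clim$bleaching_threshold,
                               sst_trend_per_decade = trend$slope_per_decade,
                               max_sst = max(sst$sst_c, na.rm = TRUE))
    })
    if (!is.null(config$logger)) {
      stage <- "logger"
      wrap({
        lg <- aggregate_logger(read_logger(config$logger))
        utils::write.csv(lg, file.path(out_dir, "logger_monthly.csv"), row.names = FALSE)
        results$logger <- list(n_site_months = nrow(lg))
      })
    }
  }

  stage <- "community_dynamics"
  wrap({
    sim_cfg <- config$simper %||% list()
    mat <- community_matrix(benthic, lapply(config$periods, as_date))
    simp <- simper(mat, n_permutations = sim_cfg$n_permutations %||% 100L,
                   seed = sim_cfg$seed %||% 1L)
    utils::write.csv(as.data.frame(simp), file.path(out_dir, "simper.csv"),
                     row.names = FALSE)
    results$simper <- list(
      overall_dissimilarity = attr(simp, "overall_dissimilarity"),
      top_variable = simp$variable[1],
      percent_change = as.list(stats::setNames(simp$percent_change, simp$variable)),
      p_value = as.list(stats::setNames(simp$p_value, simp$variable)))
  })

  stage <- "diversity_bleaching"
  wrap({
    div <- diversity_table(belt)
    states <- config$erfi$bleached_states %||%
      c("pale", "partially_bleached", "mostly_bleached", "bleached")
    prev <- bleaching_prevalence(belt, states)
    utils::write.csv(div, file.path(out_dir, "diversity.csv"), row.names = FALSE)
    utils::write.csv(prev, file.path(out_dir, "prevalence.csv"), row.names = FALSE)
    results$diversity <- list(
      mean_shannon = as.list(tapply(div$shannon_h, div$site, mean)),
      mean_prevalence = as.list(tapply(prev$prevalence, prev$site, mean, na.rm = TRUE)),
      bleached_states = states)
  })

  stage <- "erfi"
  wrap({
    e <- config$erfi
    direction <- unlist(e$direction %||% as.list(erfi_direction_weights))
    states <- e$bleached_states %||%
      c("pale", "partially_bleached", "mostly_bleached", "bleached")
    res <- run_erfi(benthic, belt, as_date(unlist(e$window)),
                    direction = direction, bleached_states = states)
    utils::write.csv(res$scores, file.path(out_dir, "erfi_scores.csv"), row.names = FALSE)
    wtab <- cbind(res$weights,
                  as.data.frame(res$loadings)[match(res$weights$variable,
                                                    rownames(res$loadings)), ,
                                              drop = FALSE])
    utils::write.csv(wtab, file.path(out_dir, "erfi_weights.csv"), row.names = FALSE)
    results$erfi <- list(ranking = res$scores$site,
                          raw = as.list(stats::setNames(res$scores$raw, res$scores$site)),
                          meta = res$meta)
  })

  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(config = config[setdiff(names(config), "out_dir")],
                            results = results),
                       summary_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(list(failed_stage = NULL, completed = names(results)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
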