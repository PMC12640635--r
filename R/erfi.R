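#' Default expert direction weights for the recovery-feasibility index
#'
#' Favourable indicators carry positive weights (coral cover strongest),
#' unfavourable ones negative (turf algae strongest negative).
#' @export
erfi_direction_weights <- c(coral = 4, cca = 2, diversity = 2,
                            cyanobacteria = -2, bleaching = -2, turf = -3)

#' Column-standardize a site-indicator matrix
#'
#' z-scores each indicator across sites: `z_ij = (x_ij - mean_j) / sd_j`.
#' Zero-variance columns cannot be standardized and are dropped with a
#' message. The SD convention is the sample SD (n - 1 denominator) by
#' default, matching mainstream statistical software; set
#' `sd_population = TRUE` for the n denominator.
#'
#' @param x numeric matrix or data.frame, rows = sites, columns =
#'   indicators; rownames identify sites.
#' @param sd_population use the population (n) SD instead of sample (n-1).
#' @return z-score matrix with attributes `center`, `scale`, `dropped`.
#' @export
standardize_indicators <- function(x, sd_population = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_("need >= 2 sites", class = "reefshift_standardize_error")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  ctr <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  if (sd_population) s <- s * sqrt((nrow(x) - 1) / nrow(x))
  keep <- s > 0
  dropped <- colnames(x)[!keep]
  if (!any(keep)) {
    stop_("all indicator columns have zero variance",
          class = "reefshift_standardize_error")
  }
  if (length(dropped)) {
    message("dropping zero-variance indicator(s): ", paste(dropped, collapse = ", "))
  }
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, s[keep], "/")
  attr(z, "center") <- ctr[keep]
  attr(z, "scale") <- s[keep]
  attr(z, "dropped") <- dropped
  z
}

#' PCA-loading magnitude weights
#'
#' Runs a principal component analysis on the standardized indicator matrix
#' (singular-value decomposition via [stats::prcomp()], equivalent to an
#' eigen-decomposition of the correlation matrix) and sums the absolute
#' loadings of each variable on the first `n_components` components:
#' `L_j = |l_j1| + |l_j2| + |l_j3|`. `L_j` is invariant to eigenvector sign
#' flips. When fewer components are retrievable than requested, the
#' available ones are used and the deficit is flagged.
#'
#' @param z standardized matrix from [standardize_indicators()].
#' @param n_components number of leading components to sum over (default 3).
#' @return list: `L` (named magnitudes), `loadings` (variables x components),
#'   `sdev`, `n_components_used`.
#' @export
pca_loadings <- function(z, n_components = 3L) {
  if (nrow(z) < 2) stop_("need >= 2 sites", class = "reefshift_decomposition_error")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  avail <- sum(pc$sdev > sqrt(.Machine$double.eps))
  used <- min(n_components, avail)
  if (used < n_components) {
    warning(sprintf("only %d principal component(s) retrievable (requested %d)",
                    used, n_components))
  }
  load <- pc$rotation[, seq_len(used), drop = FALSE]
  list(L = rowSums(abs(load)), loadings = load, sdev = pc$sdev,
       n_components_used = used)
}

#' Composite recovery-feasibility scores
#'
#' Combines the loading magnitudes `L_j` with expert direction weights
#' `D_j` into composite weights `C_j = L_j * D_j`, scores each site as the
#' weighted sum of its z-scores, `raw_i = sum_j C_j * z_ij`, and min-max
#' normalizes the raw scores to `[0, 1]`. Because each z column sums to
#' zero across sites, the raw scores always sum to zero.
#'
#' @param z standardized matrix from [standardize_indicators()].
#' @param L named loading magnitudes covering every column of `z`.
#' @param direction named direction weights covering every column of `z`.
#' @return An `erfi_result`: `scores` (site, raw, normalized, rank),
#'   `weights` (variable, L, D, C), plus `z`.
#' @export
erfi_scores <- function(z, L, direction = erfi_direction_weights) {
  vars <- colnames(z)
  miss <- setdiff(vars, names(L))
  if (length(miss)) stop_("no loading magnitude for: ", paste(miss, collapse = ", "),
                          class = "reefshift_config_error")
  miss <- setdiff(vars, names(direction))
  if (length(miss)) stop_("no direction weight for: ", paste(miss, collapse = ", "),
                          class = "reefshift_config_error")
  C <- L[vars] * direction[vars]
  raw <- drop(z %*% C)
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    warning("all raw scores equal; normalized scores set to 0.5")
    normalized <- rep(0.5, length(raw))
  } else {
    normalized <- (raw - rng[1]) / (rng[2] - rng[1])
  }
  scores <- data.frame(site = rownames(z) %||% as.character(seq_along(raw)),
                       raw = unname(raw), normalized = unname(normalized))
  scores$rank <- rank(-scores$raw, ties.method = "min")
  scores <- scores[order(scores$rank), , drop = FALSE]
  rownames(scores) <- NULL
  weights <- data.frame(variable = vars, L = unname(L[vars]),
                        D = unname(direction[vars]), C = unname(C))
  structure(list(scores = scores, weights = weights, z = z),
            class = "erfi_result")
}

#' @export
print.erfi_result <- function(x, ...) {
  cat("Ecological Recovery Feasibility Index\n")
  cat("  composite weights C_j = L_j * D_j:\n")
  print.data.frame(x$weights, digits = 3, row.names = FALSE)
  cat("  site scores (raw = sum_j C_j z_ij; normalized to [0,1]):\n")
  print.data.frame(x$scores, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Assemble site-level indicators from survey tables
#'
#' Within a date window, averages each site's benthic cover (coral, cca,
#' turf, cyanobacteria), belt-transect bleaching prevalence and Shannon
#' diversity over all transects and dates (unweighted mean).
#'
#' @param benthic long benthic data.frame.
#' @param belt long belt-transect data.frame.
#' @param window inclusive date pair `c(start, end)`.
#' @param bleached_states passed to [bleaching_prevalence()].
#' @return sites x 6 indicator matrix (`coral`, `cca`, `turf`,
#'   `cyanobacteria`, `bleaching`, `diversity`).
#' @export
site_indicators <- function(benthic, belt, window,
                            bleached_states = c("pale", "partially_bleached",
                                                "mostly_bleached", "bleached")) {
  window <- as_date(window)
  bdate <- as_date(benthic$date)
  ben <- benthic[bdate >= window[1] & bdate <= window[2] &
                   benthic$category %in% c("coral", "cca", "turf", "cyanobacteria"), ]
  ldate <- as_date(belt$date)
  bel <- belt[ldate >= window[1] & ldate <= window[2], , drop = FALSE]
  if (!nrow(ben) || !nrow(bel)) {
    stop_("no surveys inside the indicator window", class = "reefshift_validation_error")
  }
  cover <- tapply(ben$proportion, list(ben$site, ben$category), mean)
  div <- diversity_table(bel)
  prev <- bleaching_prevalence(bel, bleached_states)
  sites <- sort(unique(c(rownames(cover), div$site)))
  dropped <- setdiff(sites, intersect(rownames(cover), div$site))
  if (length(dropped)) {
    warning("site(s) without both survey types in window excluded: ",
            paste(dropped, collapse = ", "))
    sites <- setdiff(sites, dropped)
  }
  m <- cbind(coral = cover[sites, "coral"],
             cca = cover[sites, "cca"],
             turf = cover[sites, "turf"],
             cyanobacteria = cover[sites, "cyanobacteria"],
             bleaching = tapply(prev$prevalence, prev$site, mean, na.rm = TRUE)[sites],
             diversity = tapply(div$shannon_h, div$site, mean, na.rm = TRUE)[sites])
  if (anyNA(m)) {
    stop_("indicator matrix has missing cells (a site lacks a benthic category in the window)",
          class = "reefshift_validation_error")
  }
  m
}

#' Run the full recovery-feasibility index
#'
#' Pipeline: [site_indicators()] over the window, [standardize_indicators()],
#' [pca_loadings()] on the standardized matrix, then [erfi_scores()] with
#' the direction weights. Full provenance (window, weights, loadings,
#' z-scores) is kept on the result.
#'
#' @inheritParams site_indicators
#' @param direction named direction weights (defaults to
#'   [erfi_direction_weights]).
#' @param n_components leading components for the loading magnitudes.
#' @param sd_population SD convention for [standardize_indicators()].
#' @return An `erfi_result` with an extra `meta` element.
#' @export
run_erfi <- function(benthic, belt, window,
                     direction = erfi_direction_weights,
                     bleached_states = c("pale", "partially_bleached",
                                         "mostly_bleached", "bleached"),
                     n_components = 3L, sd_population = FALSE) {
  x <- site_indicators(benthic, belt, window, bleached_states)
  z <- standardize_indicators(x, sd_population = sd_population)
  w <- pca_loadings(z, n_components)
  res <- erfi_scores(z, w$L, direction)
  res$loadings <- w$loadings
  res$indicators <- x
  res$meta <- list(window = as.character(as_date(window)),
                   direction = as.list(direction),
                   bleached_states = bleached_states,
                   n_components_used = w$n_components_used,
                   sd_convention = if (sd_population) "population" else "sample",
                   aggregation = "unweighted mean over transects and dates")
  res
}
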