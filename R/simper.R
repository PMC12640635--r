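#' Bray-Curtis dissimilarity with per-variable contributions
#'
#' For two nonnegative sample vectors the dissimilarity is
#' `sum(|a - b|) / sum(a + b)`; the per-variable contribution is
#' `|a_j - b_j| / sum(a + b)`, so contributions sum exactly to the
#' dissimilarity. This is the decomposition SIMPER averages over
#' between-group sample pairs.
#'
#' @param a,b equal-length nonnegative numeric vectors.
#' @return list with `dissimilarity` and named `contributions`.
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) {
    stop_("vectors differ in length", class = "reefshift_validation_error")
  }
  if (any(a < 0) || any(b < 0)) {
    stop_("negative abundances", class = "reefshift_validation_error")
  }
  tot <- sum(a) + sum(b)
  if (tot == 0) {
    stop_("both samples all-zero: dissimilarity undefined",
          class = "reefshift_undefined_error")
  }
  contrib <- abs(a - b) / tot
  list(dissimilarity = sum(contrib), contributions = contrib)
}

#' Percentage change between period means
#'
#' `100 * (after - before) / before`. Undefined (returned as `NA` with a
#' warning, not an error) when `before` is zero.
#'
#' @param before,after nonnegative scalars or vectors (recycled).
#' @return numeric percentage change(s).
#' @export
percentage_change <- function(before, after) {
  if (any(before < 0, na.rm = TRUE) || any(after < 0, na.rm = TRUE)) {
    stop_("proportions must be nonnegative", class = "reefshift_validation_error")
  }
  out <- 100 * (after - before) / before
  undef <- !is.na(before) & before == 0
  if (any(undef)) {
    out[undef] <- NA_real_
    warning("percentage change undefined where the 'before' mean is 0")
  }
  out
}

#' Build a wide community matrix from a long benthic table
#'
#' Pivots the long benthic table (site, date, transect, category,
#' proportion) to one row per transect-survey with one column per analysis
#' variable, and labels each row `before` / `after` from two named date
#' windows. Rows outside both windows are dropped. Variables never recorded
#' for a transect become `NA` (handled by [impute_missing()]).
#'
#' @param benthic long benthic data.frame.
#' @param periods list of two date windows,
#'   `list(before = c(start, end), after = c(start, end))` (inclusive).
#' @param variables analysis variables (columns of the matrix); defaults to
#'   the ecologically relevant benthic set.
#' @return data.frame with columns `site`, `date`, `transect`, `period` and
#'   one numeric column per variable.
#' @export
community_matrix <- function(benthic, periods,
                             variables = c("coral", "macroalgae", "turf", "cca",
                                           "cyanobacteria", "bleached", "dead_coral")) {
  check_columns(benthic, c("site", "date", "transect", "category", "proportion"),
                "benthic table")
  stopifnot(length(periods) == 2)
  if (is.null(names(periods)) || !all(nzchar(names(periods)))) {
    names(periods) <- c("before", "after")
  }
  date <- as_date(benthic$date)
  lab <- rep(NA_character_, nrow(benthic))
  for (p in names(periods)) {
    win <- as_date(periods[[p]])
    lab[date >= win[1] & date <= win[2]] <- p
  }
  keep <- !is.na(lab) & benthic$category %in% variables
  if (!any(keep)) stop_("no rows fall inside the period windows",
                        class = "reefshift_validation_error")
  b <- benthic[keep, , drop = FALSE]
  b$period <- lab[keep]
  key <- interaction(b$site, as.character(b$date), b$transect, drop = TRUE)
  rows <- !duplicated(key)
  out <- data.frame(site = b$site[rows], date = as_date(b$date[rows]),
                    transect = b$transect[rows], period = b$period[rows],
                    stringsAsFactors = FALSE)
  for (v in variables) {
    out[[v]] <- NA_real_
    sel <- b$category == v
    out[[v]][match(key[sel], key[rows])] <- b$proportion[sel]
  }
  # 'before' sorts before 'after' chronologically, not alphabetically
  out$period <- factor(out$period, levels = names(periods))
  out[order(out$period, out$site, out$date, out$transect), , drop = FALSE]
}

meta_cols <- c("site", "date", "transect", "period")

variable_cols <- function(mat) setdiff(names(mat), meta_cols)

#' Impute missing community-matrix cells
#'
#' Each missing cell is replaced by the mean of that variable over the same
#' site and period; when that mean is itself undefined (the variable is
#' absent from the whole site-period) the global mean of the variable is
#' used. Errors if a variable is missing everywhere.
#'
#' @param mat a [community_matrix()] data.frame.
#' @return The matrix with no missing cells; attribute `n_imputed` reports
#'   how many cells were filled.
#' @export
impute_missing <- function(mat) {
  vars <- variable_cols(mat)
  n_imputed <- 0L
  for (v in vars) {
    x <- mat[[v]]
    if (!anyNA(x)) next
    if (all(is.na(x))) {
      stop_("variable '", v, "' is missing everywhere",
            class = "reefshift_imputation_error")
    }
    grp <- interaction(mat$site, mat$period, drop = TRUE)
    grp_mean <- tapply(x, grp, mean, na.rm = TRUE)
    fill <- grp_mean[as.character(grp)]
    fill[is.nan(fill)] <- mean(x, na.rm = TRUE)
    miss <- is.na(x)
    x[miss] <- fill[miss]
    n_imputed <- n_imputed + sum(miss)
    mat[[v]] <- x
  }
  attr(mat, "n_imputed") <- n_imputed
  mat
}

# n1 x n2 x p array of per-variable Bray-Curtis contributions for every
# cross pair; shared by the observed statistic and every permutation.
pairwise_contributions <- function(X) {
  n <- nrow(X)
  tot <- rowSums(X)
  denom <- outer(tot, tot, "+")
  p <- ncol(X)
  out <- array(0, dim = c(n, n, p))
  for (j in seq_len(p)) {
    out[, , j] <- abs(outer(X[, j], X[, j], "-")) / denom
  }
  out
}

between_group_means <- function(contrib, is_after) {
  apply(contrib[!is_after, is_after, , drop = FALSE], 3, mean)
}

#' SIMPER: similarity-percentage decomposition between two periods
#'
#' Computes, for every between-period pair of samples, the per-variable
#' Bray-Curtis contributions; averages them (`average_contribution`);
#' ranks variables by that average (ties broken by variable name);
#' reports the consistency ratio (mean / SD of the pairwise contributions),
#' per-period means, percentage change, the cumulative share of the summed
#' averages, and a permutation p-value. The permutation test shuffles the
#' period labels across samples; per variable,
#' `p = (1 + #permuted average contributions >= observed) / (1 + n_permutations)`,
#' so with 100 permutations the attainable floor is 1/101 = 0.0099.
#'
#' Missing cells are imputed first via [impute_missing()].
#'
#' @param mat a [community_matrix()] data.frame (two period labels, each
#'   with at least two samples).
#' @param n_permutations number of label permutations (default 100).
#' @param seed integer seed for the permutations (required: permutation
#'   inference is only reproducible under an explicit seed).
#' @return A `simper_result` data.frame (one row per variable, ranked) with
#'   attributes `overall_dissimilarity`, `n_permutations`, `seed`,
#'   `n_before`, `n_after`.
#' @export
simper <- function(mat, n_permutations = 100L, seed) {
  if (missing(seed)) stop_("an explicit seed is required", class = "reefshift_config_error")
  vars <- variable_cols(mat)
  mat <- impute_missing(mat)
  per <- as.character(mat$period)
  levs <- if (is.factor(mat$period)) levels(mat$period) else sort(unique(per), decreasing = TRUE)
  if (length(unique(per)) != 2) {
    stop_("exactly two period labels required", class = "reefshift_inference_error")
  }
  n_per <- table(factor(per, levs))
  if (any(n_per < 2)) {
    stop_("each period needs >= 2 samples", class = "reefshift_inference_error")
  }
  X <- as.matrix(mat[vars])
  is_after <- per == levs[2]
  contrib <- pairwise_contributions(X)

  obs <- between_group_means(contrib, is_after)
  # pairwise SD for the consistency ratio (between-group pairs only)
  flat <- matrix(contrib[!is_after, is_after, ], ncol = length(vars))
  pair_sd <- apply(flat, 2, stats::sd)
  ratio <- ifelse(pair_sd > 0, obs / pair_sd, NA_real_)

  set.seed(seed)
  n <- nrow(X)
  n_after <- sum(is_after)
  exceed <- integer(length(vars))
  for (i in seq_len(n_permutations)) {
    perm_after <- logical(n)
    perm_after[sample.int(n, n_after)] <- TRUE
    exceed <- exceed + (between_group_means(contrib, perm_after) >= obs)
  }
  p_value <- (1 + exceed) / (1 + n_permutations)

  mean_before <- colMeans(X[!is_after, , drop = FALSE])
  mean_after <- colMeans(X[is_after, , drop = FALSE])
  pct <- suppressWarnings(percentage_change(mean_before, mean_after))

  ord <- order(-obs, vars)
  res <- data.frame(variable = vars,
                    average_contribution = obs,
                    consistency_ratio = ratio,
                    mean_before = mean_before,
                    mean_after = mean_after,
                    percent_change = pct,
                    p_value = p_value,
                    row.names = NULL)[ord, , drop = FALSE]
  res$cumulative_contribution <- cumsum(res$average_contribution) /
    sum(res$average_contribution)
  res <- res[c("variable", "average_contribution", "consistency_ratio",
               "mean_before", "mean_after", "cumulative_contribution",
               "percent_change", "p_value")]
  rownames(res) <- NULL
  structure(res,
            class = c("simper_result", "data.frame"),
            overall_dissimilarity = sum(obs),
            n_permutations = as.integer(n_permutations),
            seed = as.integer(seed),
            n_before = as.integer(n_per[1]), n_after = as.integer(n_per[2]))
}

#' @export
print.simper_result <- function(x, digits = 4, ...) {
  cat(sprintf("SIMPER: %d x %d samples, mean between-group Bray-Curtis = %.4f (%d permutations)\n",
              attr(x, "n_before"), attr(x, "n_after"),
              attr(x, "overall_dissimilarity"), attr(x, "n_permutations")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Site-level SIMPER runs
#'
#' Runs [simper()] separately within each site; permutations shuffle period
#' labels within that site's samples only.
#'
#' @inheritParams simper
#' @return named list of `simper_result` objects, one per site with enough
#'   samples (sites with fewer than 2 samples per period are skipped with a
#'   warning).
#' @export
simper_by_site <- function(mat, n_permutations = 100L, seed) {
  if (missing(seed)) stop_("an explicit seed is required", class = "reefshift_config_error")
  out <- list()
  for (s in unique(as.character(mat$site))) {
    sub <- mat[mat$site == s, , drop = FALSE]
    ok <- tryCatch({
      out[[s]] <- simper(sub, n_permutations, seed)
      TRUE
    }, reefshift_inference_error = function(e) FALSE)
    if (!ok) warning("site '", s, "' skipped: a period has < 2 samples")
  }
  out
}
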