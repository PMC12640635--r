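test_that("bray_curtis matches hand computations and rejects degenerate input", {
  expect_equal(bray_curtis(c(0.4, 0.6), c(0.4, 0.6))$dissimilarity, 0)
  bc <- bray_curtis(c(1, 0), c(0, 1))
  expect_equal(bc$dissimilarity, 1)
  expect_equal(unname(bc$contributions), c(0.5, 0.5))
  bc2 <- bray_curtis(c(0.3, 0.7), c(0.5, 0.5))
  expect_equal(bc2$dissimilarity, 0.2)
  expect_equal(unname(bc2$contributions), c(0.1, 0.1))
  expect_error(bray_curtis(c(0, 0), c(0, 0)), class = "reefshift_undefined_error")
  expect_error(bray_curtis(c(-0.1, 1), c(0, 1)), class = "reefshift_validation_error")
})

test_that("percentage_change reproduces the period-mean arithmetic", {
  expect_equal(round(percentage_change(0.337, 0.575), 2), 70.62)
  expect_equal(round(percentage_change(0.193, 0.115), 2), -40.41)
  expect_equal(percentage_change(0.4, 0.4), 0)
  expect_warning(out <- percentage_change(0, 0.2), "undefined")
  expect_true(is.na(out))
})

test_that("imputation applies the site-period mean with a global-mean fallback", {
  mat <- toy_matrix()
  expect_identical(impute_missing(mat)[names(mat)], mat[names(mat)])
  expect_equal(attr(impute_missing(mat), "n_imputed"), 0L)

  m2 <- mat
  m2$turf[2] <- NA                       # site A / before mean of remaining turf = 0.2
  out <- impute_missing(m2)
  expect_equal(out$turf[2], 0.2)
  expect_equal(attr(out, "n_imputed"), 1L)

  # 3-site toy where one site-period has no turf at all -> global mean branch
  m3 <- rbind(mat, mat, mat)
  m3$site <- rep(c("A", "B", "C"), each = 4)
  m3$turf[m3$site == "C" & m3$period == "before"] <- NA
  out3 <- impute_missing(m3)
  gmean <- mean(m3$turf, na.rm = TRUE)
  expect_equal(out3$turf[out3$site == "C" & out3$period == "before"],
               rep(gmean, 2))

  m4 <- mat; m4$cca <- NA
  expect_error(impute_missing(m4), class = "reefshift_imputation_error")
})

test_that("simper matches exhaustive hand enumeration on a 2+2 toy", {
  mat <- toy_matrix()
  X <- as.matrix(mat[c("coral", "turf", "cca")])
  is_after <- mat$period == "after"
  pairs <- oracle_between_contrib(X, is_after)    # all 4 between-group pairs

  res <- simper(mat, n_permutations = 100, seed = 1)
  byvar <- setNames(res$average_contribution, res$variable)
  expect_equal(byvar[c("coral", "turf", "cca")], colMeans(pairs),
               ignore_attr = TRUE)
  ratio <- setNames(res$consistency_ratio, res$variable)
  expect_equal(ratio[c("coral", "turf", "cca")],
               colMeans(pairs) / apply(pairs, 2, sd), ignore_attr = TRUE)
  expect_equal(attr(res, "overall_dissimilarity"), sum(colMeans(pairs)))
  expect_equal(setNames(res$mean_before, res$variable)[colnames(X)],
               colMeans(X[!is_after, ]), ignore_attr = TRUE)

  # ranking is by average contribution, cumulative share reaches exactly 1
  expect_true(!is.unsorted(rev(res$average_contribution)))
  expect_equal(res$cumulative_contribution[nrow(res)], 1)

  # estimator converges to the exhaustive relabeling probability
  combos <- combn(4, 2)
  exhaustive <- sapply(seq_len(ncol(combos)), function(k) {
    lab <- logical(4); lab[combos[, k]] <- TRUE
    colMeans(oracle_between_contrib(X, lab))
  })
  q <- rowMeans(exhaustive >= colMeans(pairs))    # P(perm stat >= observed)
  big <- simper(mat, n_permutations = 4000, seed = 2)
  phat <- setNames(big$p_value, big$variable)[colnames(X)]
  # 4-sigma Monte-Carlo band around the exhaustive probability
  band <- 4 * sqrt(pmax(q * (1 - q), 0.25 / 4000) / 4000) + 2 / 4001
  expect_true(all(abs(unname(phat) - q) <= band))
})

test_that("identical periods give zero change and maximal p-values", {
  mat <- toy_matrix()
  mat[mat$period == "after", c("coral", "turf", "cca")] <-
    mat[mat$period == "before", c("coral", "turf", "cca")]
  res <- simper(mat, n_permutations = 50, seed = 1)
  expect_equal(res$percent_change, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3))
})

test_that("contributions conserve the mean between-group dissimilarity (1e-12)", {
  set.seed(77)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1); p <- sample(3:7, 1)
    X <- matrix(runif((n1 + n2) * p), ncol = p,
                dimnames = list(NULL, paste0("v", 1:p)))
    mat <- data.frame(site = "s", date = as.Date("2024-01-01") + seq_len(n1 + n2),
                      transect = seq_len(n1 + n2),
                      period = factor(rep(c("before", "after"), c(n1, n2)),
                                      levels = c("before", "after")))
    mat <- cbind(mat, as.data.frame(X))
    res <- simper(mat, n_permutations = 10, seed = rep)
    is_after <- rep(c(FALSE, TRUE), c(n1, n2))
    d <- mean(vapply(which(!is_after), function(i) {
      mean(vapply(which(is_after), function(j) {
        bray_curtis(X[i, ], X[j, ])$dissimilarity
      }, numeric(1)))
    }, numeric(1)))
    expect_equal(sum(res$average_contribution), d, tolerance = 1e-12)
  }
})

test_that("permutation p-values respect the add-one floor and are seed-reproducible", {
  set.seed(5)
  n <- 10
  mat <- data.frame(site = "s", date = as.Date("2024-01-01") + 1:(2 * n),
                    transect = 1:(2 * n),
                    period = factor(rep(c("before", "after"), each = n),
                                    levels = c("before", "after")),
                    coral = c(runif(n, 0.6, 0.8), runif(n, 0.05, 0.1)),
                    turf = c(runif(n, 0.1, 0.2), runif(n, 0.7, 0.9)))
  res <- simper(mat, n_permutations = 100, seed = 31)
  expect_true(all(res$p_value >= 1 / 101))
  expect_equal(min(res$p_value), 1 / 101)       # clear shift attains the floor
  res2 <- simper(mat, n_permutations = 100, seed = 31)
  expect_identical(as.data.frame(res), as.data.frame(res2))
  expect_error(simper(mat, 100), class = "reefshift_config_error")
})

test_that("simper is invariant to row and column order", {
  mat <- toy_matrix()
  res <- simper(mat, n_permutations = 200, seed = 8)
  shuffled <- mat[c(3, 1, 4, 2), c("site", "date", "transect", "period",
                                   "cca", "coral", "turf")]
  res2 <- simper(shuffled, n_permutations = 200, seed = 8)
  expect_equal(setNames(res$average_contribution, res$variable),
               setNames(res2$average_contribution, res2$variable)[res$variable])
  expect_equal(setNames(res$mean_after, res$variable),
               setNames(res2$mean_after, res2$variable)[res$variable])
})

test_that("average contributions agree with the vegan reference on a random matrix", {
  set.seed(123)
  X <- matrix(runif(60), ncol = 5, dimnames = list(NULL, paste0("v", 1:5)))
  grp <- rep(c("before", "after"), each = 6)
  mat <- data.frame(site = "s", date = as.Date("2024-01-01") + 1:12, transect = 1:12,
                    period = factor(grp, levels = c("before", "after")))
  mat <- cbind(mat, as.data.frame(X))
  res <- simper(mat, n_permutations = 10, seed = 1)

  ref <- vegan::simper(X, grp, permutations = 0)
  key <- names(ref)[1]
  ours <- setNames(res$average_contribution, res$variable)
  expect_equal(ours[ref[[key]]$species], ref[[key]]$average, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(setNames(res$consistency_ratio, res$variable)[ref[[key]]$species],
               ref[[key]]$average / ref[[key]]$sd, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("site-level runs permute within sites and skip undersized sites", {
  mat <- rbind(toy_matrix(), transform(toy_matrix(), site = "B"))
  tiny <- toy_matrix()[1:3, ]; tiny$site <- "C"
  expect_warning(out <- simper_by_site(rbind(mat, tiny), n_permutations = 20, seed = 1),
                 "skipped")
  expect_setequal(names(out), c("A", "B"))
  expect_s3_class(out$A, "simper_result")
})
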