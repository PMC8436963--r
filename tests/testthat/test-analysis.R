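# Permutation tests, correlations, PCA, CoV, replicate error, ANOVA,
# hierarchy.

test_that("permutation test is exact for perfect pairing and reproducible", {
  set.seed(51)
  rows <- list()
  for (g in 1:8) {
    v <- rnorm(14, sd = 2)
    rows[[length(rows) + 1L]] <- index_row(sprintf("g%d", g), "FL", v)
    rows[[length(rows) + 1L]] <- index_row(sprintf("g%d", g), "FR", v)
  }
  data <- index_dataset(do.call(rbind, rows))
  res <- permutation_test(data, identity_metric(), c("FL", "FR"),
                          n_perm = 200, seed = 7)
  expect_equal(res$observed_ratio, 0)
  expect_equal(res$p_value, 1 / 201)        # smallest attainable p

  res2 <- permutation_test(data, identity_metric(), c("FL", "FR"),
                           n_perm = 200, seed = 7)
  expect_identical(res, res2)               # same seed, same everything
  expect_error(permutation_test(random_index_dataset(3), identity_metric(),
                                c("FL", "FR"), 10, 1), "5 geckos")
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(52)
  hits <- 0L
  n_sim <- 200
  for (i in seq_len(n_sim)) {
    data <- random_index_dataset(8)
    p <- permutation_test(data, identity_metric(), c("FL", "FR"),
                          n_perm = 99, seed = i)$p_value
    if (p <= 0.05) hits <- hits + 1L
  }
  expect_lte(hits / n_sim, 0.05 + 2.5 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("index correlations match the textbook formula and flag perfection", {
  x <- c(1, 2, 4, 7, 11)
  y <- c(2, 1, 5, 6, 13)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  X <- matrix(rnorm(5 * 14), 5, 14)
  X[, 1] <- x; X[, 2] <- y
  X[, 3] <- 2 * x + 1                         # exact linear function
  set.seed(53)
  res <- index_correlations(index_dataset(matrix_index_df(X)),
                            n_perm = 200, seed = 3)
  expect_equal(res$r["FM", "SS"], r_hand)
  expect_equal(res$r["FM", "SSD"], 1)
  expect_equal(diag(res$r), rep(1, 14), ignore_attr = TRUE)
  expect_true(isSymmetric(res$r))
  # parametric option agrees with cor.test
  resp <- index_correlations(index_dataset(matrix_index_df(X)),
                             method = "parametric")
  expect_equal(resp$p["FM", "SS"], stats::cor.test(x, y)$p.value)
})

test_that("independent variables rarely show significant correlation", {
  set.seed(54)
  X <- matrix(rnorm(1000 * 14), 1000, 14)
  res <- index_correlations(index_dataset(matrix_index_df(X)),
                            n_perm = 199, seed = 9)
  off <- abs(res$r[upper.tri(res$r)])
  expect_true(mean(off < 0.1) > 0.95)
  expect_true(mean(res$p[upper.tri(res$p)] > 0.05) > 0.8)
})

test_that("body-part correlations recover a shared head-tail factor", {
  set.seed(55)
  rows <- list()
  for (g in 1:20) {
    f <- rnorm(1, sd = 2)                        # shared HD/TA size factor
    hd <- rnorm(14, sd = 0.4); hd[9] <- hd[9] + f   # SA index
    ta <- rnorm(14, sd = 0.4); ta[9] <- ta[9] + f
    rows[[length(rows) + 1L]] <- index_row(sprintf("g%02d", g), "HD", hd)
    rows[[length(rows) + 1L]] <- index_row(sprintf("g%02d", g), "TA", ta)
    rows[[length(rows) + 1L]] <- index_row(sprintf("g%02d", g), "FL",
                                           rnorm(14, sd = 0.4))
    rows[[length(rows) + 1L]] <- index_row(sprintf("g%02d", g), "BL",
                                           rnorm(14, sd = 0.4))
  }
  data <- index_dataset(do.call(rbind, rows))
  res <- bodypart_correlations(data, n_perm = 199, seed = 4)
  hdta <- res[res$pair == "HD-TA", ]
  expect_gt(hdta$r_SA, 0.5)
  expect_lt(hdta$p_SA, 0.05)
  flbl <- res[res$pair == "FL-BL", ]
  expect_lt(abs(flbl$r_SA), 0.5)                  # independent noise
  # a pair with < 4 geckos is missing
  expect_true(all(is.na(res[res$pair == "FR-BR", grep("^r_", names(res))])))
  expect_equal(nrow(res), 21L)
})

test_that("PCA explains non-increasing fractions that sum to one", {
  set.seed(56)
  X <- matrix(rnorm(40 * 14), 40, 14)
  res <- pca_indices(index_dataset(matrix_index_df(X)))
  expect_equal(sum(res$explained_fraction), 1)
  expect_true(all(diff(res$explained_fraction) <= 1e-12))
  # sign convention: each component's largest-magnitude loading positive
  for (j in 1:14) {
    v <- res$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("PCA matches a direct eigendecomposition and catches rank-1 data", {
  set.seed(57)
  X <- matrix(rnorm(20 * 14), 20, 14)
  res <- pca_indices(index_dataset(matrix_index_df(X)))
  ev <- eigen(stats::cor(X), symmetric = TRUE)
  expect_equal(res$explained_fraction, ev$values / 14, tolerance = 1e-9)
  for (j in c(1, 5)) {
    v <- ev$vectors[, j]
    v <- v * sign(v[which.max(abs(v))])
    expect_equal(unname(res$loadings[, j]), v, tolerance = 1e-6)
  }

  base <- rnorm(20)
  X1 <- outer(base, seq(0.5, 4, length.out = 14)) +
    matrix(rnorm(280, sd = 1e-3), 20, 14)
  res1 <- pca_indices(index_dataset(matrix_index_df(X1)))
  expect_gt(res1$explained_fraction[1], 0.99)

  Xc <- X; Xc[, 4] <- 7                       # constant column
  expect_error(pca_indices(index_dataset(matrix_index_df(Xc))), "EE")
})

test_that("coefficients of variation behave as sd/mean", {
  X <- matrix(5, 6, 14)
  X[, 1] <- c(1, 3, 1, 3, 1, 3)
  df <- rbind(matrix_index_df(X[1:3, , drop = FALSE], part = "HD"),
              matrix_index_df(X[4:6, , drop = FALSE], part = "TA"))
  res <- coefficient_of_variation(index_dataset(df))
  all_row <- res[res$body_part == "all", ]
  expect_equal(all_row$FM, stats::sd(X[, 1]) / 2)
  expect_equal(all_row$SS, 0)                 # constant values
  # scale invariance
  df10 <- df; df10[, INDEX_NAMES] <- df10[, INDEX_NAMES] * 10
  res10 <- coefficient_of_variation(index_dataset(df10))
  expect_equal(res10[res10$body_part == "all", INDEX_NAMES],
               all_row[, INDEX_NAMES])
  # hand value: {1, 3} has CoV sqrt(2)/2
  two <- matrix(5, 2, 14); two[, 1] <- c(1, 3)
  r2 <- coefficient_of_variation(index_dataset(matrix_index_df(two, "HD")))
  expect_equal(r2[r2$body_part == "HD", "FM"], sqrt(2) / 2)
})

test_that("replicate error equals d^2/4 for two replicates and detects jitter scale", {
  x <- rnorm(14); y <- x; y[1] <- y[1] + 2      # d^2 = 4 in identity metric
  rep_df <- rbind(
    cbind(matrix_index_df(rbind(x), "FL"), replicate = 1),
    cbind(matrix_index_df(rbind(y), "FL"), replicate = 2),
    cbind(matrix_index_df(rbind(x + 10), "FL")[1, ], replicate = 1),
    cbind(matrix_index_df(rbind(x + 10), "FL")[1, ], replicate = 2))
  rep_df$gecko_id <- c("g1", "g1", "g2", "g2")
  res <- replicate_error(rep_df, identity_metric())
  # g1: centroid midway, each replicate at squared distance d^2/4 = 1 ->
  # error 1; g2: identical replicates -> 0; per-part mean = 0.5
  expect_equal(res$error[res$body_part == "FL"], 0.5)
  # between-individual distance uses the replicate-averaged vectors
  btw <- sum(((x + y) / 2 - (x + 10))^2)
  expect_equal(res$between[res$body_part == "FL"], btw)
})

test_that("replicate error is far below between-gecko spread in calm cohorts", {
  set.seed(58)
  rep_rows <- list()
  for (g in 1:6) {
    base <- rnorm(14, sd = 3)
    for (r in 1:3) {
      d <- cbind(matrix_index_df(rbind(base + rnorm(14, sd = 0.05)), "HD"),
                 replicate = r)
      d$gecko_id <- sprintf("g%d", g)
      rep_rows[[length(rep_rows) + 1L]] <- d
    }
  }
  res <- replicate_error(do.call(rbind, rep_rows), identity_metric())
  expect_gt(res$between_over_error[res$body_part == "HD"], 10)
})

test_that("sides ANOVA decomposes sums of squares exactly", {
  set.seed(59)
  arr <- array(rnorm(6 * 2 * 4), c(6, 2, 4))
  res <- sides_anova(arr)
  total <- sum((arr - mean(arr))^2)
  expect_equal(sum(res$table$SS), total, tolerance = 1e-9)
  expect_equal(res$table$df, c(1, 5, 5, 36))
  expect_equal(sum(res$table$df), length(arr) - 1)
})

test_that("sides ANOVA detects asymmetry against replicate noise", {
  set.seed(60)
  n <- 8; r <- 4
  shift <- matrix(rnorm(n * 2, sd = 2), n, 2)     # per (gecko, side) level
  arr <- array(0, c(n, 2, r))
  for (i in 1:n) for (s in 1:2) arr[i, s, ] <- shift[i, s] + rnorm(r, sd = 0.1)
  res <- sides_anova(arr)
  expect_gt(res$F_interaction, 10)
  expect_lt(res$p_interaction, 0.05)

  flat <- array(1, c(3, 2, 2))
  res0 <- sides_anova(flat)
  expect_true(is.na(res0$F_interaction))          # all SS zero, signalled
  expect_error(sides_anova(array(1, c(1, 2, 3))), ">= 2")
})

test_that("patterning hierarchy violations are counted per implication", {
  ok <- data.frame(gecko_id = c("a", "b", "c"),
                   FL = c(TRUE, FALSE, FALSE), FR = c(TRUE, FALSE, FALSE),
                   BL = c(TRUE, FALSE, FALSE), BR = c(FALSE, FALSE, FALSE),
                   HD = TRUE, TR = c(TRUE, TRUE, FALSE), TA = TRUE)
  res <- hierarchy_check(ok)
  expect_equal(res$total_violations, 0)

  bad <- ok
  bad$TR[1] <- FALSE                      # patterned leg without trunk
  res2 <- hierarchy_check(bad)
  expect_equal(res2$legs_imply_trunk$violations, 1)
  expect_equal(res2$legs_imply_trunk$violators, "a")

  bad2 <- ok
  bad2$HD[2] <- FALSE                     # trunk without head
  res3 <- hierarchy_check(bad2)
  expect_equal(res3$trunk_implies_head_tail$violations, 1)
  expect_equal(res3$trunk_implies_head_tail$violators, "b")

  all_on <- ok
  all_on[, BODY_PARTS] <- TRUE
  expect_equal(hierarchy_check(all_on)$total_violations, 0)
})

test_that("significance stars follow the published thresholds", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 0.0009, 0.000009, NA)),
               c("", "*", "**", "***", "****", ""))
})
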