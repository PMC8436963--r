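# Statistical analyses on the index dataset: permutation tests for the
# within/between distance ratio, index and body-part correlation matrices,
# PCA, coefficients of variation, replicate measurement error, the
# sides x individuals ANOVA for fluctuating asymmetry, and the
# patterning-hierarchy check.

#' Significance stars at the 0.05 / 0.01 / 0.001 / 0.00001 thresholds
#' @param p numeric vector of p-values.
#' @return character vector of "", "*", "**", "***", "****".
#' @export
p_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[!is.na(p) & p < 0.00001] <- "****"
  out
}

#' Permutation test for within- vs between-individual distances
#'
#' Null hypothesis: the mean within-individual squared distance for the
#' given pair of body parts is greater than or equal to the
#' between-individual one (ratio >= 1); the one-sided alternative is that
#' it is strictly smaller. The null distribution is generated by uniformly
#' permuting the gecko labels of the second part's index vectors against
#' the first part's; p = (1 + #\{null ratio <= observed\}) / (1 + n_perm).
#'
#' @param data an `index_dataset`.
#' @param spec a fitted `distance_spec`.
#' @param pair character 2-vector of body parts.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for reproducibility.
#' @return object of class `permutation_result`: observed summary, p-value
#'   and null-ratio summary (mean, 5% and 95% quantiles).
#' @export
permutation_test <- function(data, spec, pair, n_perm = 10000L,
                             seed = NULL) {
  AB <- .paired_matrices(data, pair)
  if (AB$n < 5L)
    stop("need at least 5 geckos with both parts qualifying")
  if (!is.null(seed)) set.seed(seed)
  D <- .sqdist_matrix(AB$A, AB$B, spec)
  obs <- .wb_from_matrix(D, seq_len(AB$n))
  null_ratios <- vapply(seq_len(n_perm), function(i) {
    .wb_from_matrix(D, sample.int(AB$n))$ratio
  }, 1)
  p <- (1 + sum(null_ratios <= obs$ratio)) / (1 + n_perm)
  structure(
    list(pair = pair, observed = obs, observed_ratio = obs$ratio,
         n_perm = as.integer(n_perm), p_value = p, seed = seed,
         null_mean = mean(null_ratios),
         null_q05 = unname(stats::quantile(null_ratios, 0.05)),
         null_q95 = unname(stats::quantile(null_ratios, 0.95))),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %s-%s: ratio %.3f (within %.3f / between %.3f), p = %.4g %s\n",
    x$pair[1L], x$pair[2L], x$observed_ratio, x$observed$mean_within,
    x$observed$mean_between, x$p_value, p_stars(x$p_value)))
  invisible(x)
}

# two-sided permutation p for a correlation between x and y
.perm_cor_p <- function(x, y, r_obs, n_perm) {
  null_r <- vapply(seq_len(n_perm), function(i) {
    stats::cor(x, sample(y))
  }, 1)
  (1 + sum(abs(null_r) >= abs(r_obs))) / (1 + n_perm)
}

#' Pairwise Pearson correlations between the 14 indices
#'
#' Computed over all qualifying complete patterns pooled across body
#' parts; p-values by permutation of one variable (two-sided), or by the
#' parametric t test.
#'
#' @param data an `index_dataset`.
#' @param n_perm permutations per pair (default 1000).
#' @param seed RNG seed.
#' @param method `"permutation"` (default) or `"parametric"`.
#' @return list of 14 x 14 matrices `r`, `p`, plus `stars` and `n`.
#' @export
index_correlations <- function(data, n_perm = 1000L, seed = NULL,
                               method = c("permutation", "parametric")) {
  method <- match.arg(method)
  cm <- .complete_matrix(data)
  if (nrow(cm$X) < 4L) stop("need at least 4 complete qualifying patterns")
  if (!is.null(seed)) set.seed(seed)
  m <- length(INDEX_NAMES)
  R <- matrix(NA_real_, m, m, dimnames = list(INDEX_NAMES, INDEX_NAMES))
  P <- R
  diag(R) <- 1
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      x <- cm$X[, i]; y <- cm$X[, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      r <- stats::cor(x, y)
      p <- if (method == "permutation") {
        .perm_cor_p(x, y, r, n_perm)
      } else {
        stats::cor.test(x, y)$p.value
      }
      R[i, j] <- R[j, i] <- r
      P[i, j] <- P[j, i] <- p
    }
  }
  list(r = R, p = P,
       stars = matrix(p_stars(P), m, m,
                      dimnames = dimnames(R)),
       n = nrow(cm$X))
}

#' Within-individual correlations of indices between body-part pairs
#'
#' For each unordered pair of body parts and each index, the Pearson
#' correlation across geckos that have qualifying patterns on both parts.
#' Cells with fewer than 4 such geckos are missing.
#'
#' @inheritParams index_correlations
#' @return data.frame, one row per body-part pair, columns per index of
#'   `r_<index>`, `p_<index>`, plus `n` and `n_significant`.
#' @export
bodypart_correlations <- function(data, n_perm = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  combos <- utils::combn(BODY_PARTS, 2L)
  rows <- list()
  for (k in seq_len(ncol(combos))) {
    pair <- combos[, k]
    AB <- .paired_matrices(data, pair)
    r <- stats::setNames(rep(NA_real_, length(INDEX_NAMES)), INDEX_NAMES)
    p <- r
    if (AB$n >= 4L) {
      for (i in seq_along(INDEX_NAMES)) {
        x <- AB$A[, i]; y <- AB$B[, i]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next
        r[i] <- stats::cor(x, y)
        p[i] <- .perm_cor_p(x, y, r[i], n_perm)
      }
    }
    rows[[k]] <- data.frame(
      pair = paste(pair, collapse = "-"), n = AB$n,
      n_significant = sum(!is.na(p) & p < 0.05),
      as.list(stats::setNames(r, paste0("r_", INDEX_NAMES))),
      as.list(stats::setNames(p, paste0("p_", INDEX_NAMES))),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Principal component analysis of the 14 indices
#'
#' Indices are standardized to zero mean and unit variance (the indices
#' carry mixed units), so this is an eigendecomposition of the correlation
#' matrix. The sign of each component is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param data an `index_dataset`.
#' @return list: `loadings` (14 x 14), `explained_fraction` (14-vector,
#'   non-increasing, sums to 1), `scores`, `n`.
#' @export
pca_indices <- function(data) {
  cm <- .complete_matrix(data)
  if (nrow(cm$X) < 15L) stop("need at least 15 complete qualifying patterns")
  sds <- apply(cm$X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant index column(s): ",
         paste(INDEX_NAMES[sds == 0], collapse = ", "))
  pc <- stats::prcomp(cm$X, center = TRUE, scale. = TRUE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, 1)
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  list(loadings = loadings,
       explained_fraction = pc$sdev^2 / sum(pc$sdev^2),
       scores = scores, n = nrow(cm$X))
}

#' Coefficients of variation of the indices
#'
#' sd/mean (sample sd) per index, per body part and pooled over all
#' qualifying patterns. Missing when the group has fewer than 2 values or
#' zero mean.
#'
#' @param data an `index_dataset`.
#' @return data.frame: `body_part` (including `"all"`), one column per
#'   index.
#' @export
coefficient_of_variation <- function(data) {
  cm <- .complete_matrix(data)
  cov1 <- function(X) {
    vapply(seq_len(ncol(X)), function(j) {
      v <- X[, j]
      if (length(v) < 2L || mean(v) == 0) return(NA_real_)
      stats::sd(v) / mean(v)
    }, 1)
  }
  groups <- c(stats::setNames(as.list(BODY_PARTS), BODY_PARTS),
              list(all = BODY_PARTS))
  rows <- lapply(names(groups), function(g) {
    X <- cm$X[cm$body_part %in% groups[[g]], , drop = FALSE]
    data.frame(body_part = g,
               as.list(stats::setNames(cov1(X), INDEX_NAMES)),
               n = nrow(X), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Replicate measurement error in pattern space
#'
#' For each gecko x body part with >= 2 complete replicates, the mean
#' squared distance of the replicate index vectors from their centroid —
#' an absolute measure of measurement error. Aggregated per body part and
#' compared with (i) the mean between-individual squared distance of the
#' same part and (ii) for legs, the within-individual left-right leg
#' distance.
#'
#' @param rep_df data.frame of per-replicate indices (columns `gecko_id`,
#'   `body_part`, `replicate`, `qualifying`, the 14 indices).
#' @param spec a fitted `distance_spec`.
#' @return data.frame per body part: `error` (mean squared replicate
#'   distance from centroid), `between` and `within_legs` mean squared
#'   distances, and the factors `between_over_error`,
#'   `within_over_error`.
#' @export
replicate_error <- function(rep_df, spec) {
  keep <- rep_df$qualifying & stats::complete.cases(rep_df[, INDEX_NAMES])
  rep_df <- rep_df[keep, , drop = FALSE]
  key <- interaction(rep_df$gecko_id, rep_df$body_part, drop = TRUE)
  errs <- lapply(split(rep_df, key), function(d) {
    if (nrow(d) < 2L) {
      warning(sprintf("%s %s: single replicate, skipped",
                      d$gecko_id[1L], d$body_part[1L]))
      return(NULL)
    }
    X <- as.matrix(d[, INDEX_NAMES])
    ctr <- matrix(colMeans(X), 1L)
    data.frame(gecko_id = d$gecko_id[1L], body_part = d$body_part[1L],
               error = mean(.sqdist_matrix(X, ctr, spec)),
               stringsAsFactors = FALSE)
  })
  errs <- do.call(rbind, errs)
  if (is.null(errs)) stop("no gecko x body part with >= 2 replicates")

  # averaged vectors for the comparison distances
  avg <- stats::aggregate(rep_df[, INDEX_NAMES],
                          by = rep_df[, c("gecko_id", "body_part")], mean)
  avg$qualifying <- TRUE
  ds <- index_dataset(avg)

  rows <- lapply(unique(errs$body_part), function(p) {
    e <- mean(errs$error[errs$body_part == p])
    cm <- .complete_matrix(ds, parts = p)
    btw <- NA_real_
    if (nrow(cm$X) >= 2L) {
      D <- .sqdist_matrix(cm$X, cm$X, spec)
      btw <- mean(D[upper.tri(D)])
    }
    wth <- NA_real_
    pairing <- switch(p, FL = , FR = c("FL", "FR"),
                      BL = , BR = c("BL", "BR"), NULL)
    if (!is.null(pairing)) {
      AB <- .paired_matrices(ds, pairing)
      if (AB$n >= 1L)
        wth <- mean(diag(.sqdist_matrix(AB$A, AB$B, spec)))
    }
    data.frame(body_part = p, n = sum(errs$body_part == p), error = e,
               between = btw, within_legs = wth,
               between_over_error = btw / e, within_over_error = wth / e,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-way sides x individuals ANOVA for one index
#'
#' Mixed-model ANOVA on a balanced gecko x side x replicate array:
#' "sides" is fixed, "individuals" random. F_interaction = MS_SI / MS_E
#' tests nondirectional (fluctuating) asymmetry against measurement
#' error; F_sides = MS_S / MS_SI tests directional asymmetry.
#'
#' @param values numeric array `n_geckos x 2 x n_replicates` (sides in
#'   dimension 2), or a data.frame with columns `value`, `gecko`, `side`,
#'   `replicate`.
#' @return object of class `anova_sides`: per-source SS/df/MS table and
#'   the two F statistics with p-values (`NA` when a denominator mean
#'   square is 0).
#' @export
sides_anova <- function(values) {
  if (is.data.frame(values)) {
    tab <- table(values$gecko, values$side)
    if (length(unique(tab)) != 1L || ncol(tab) != 2L)
      stop("design must be balanced with exactly 2 sides")
    df <- data.frame(y = values$value, gecko = factor(values$gecko),
                     side = factor(values$side))
    n <- nlevels(df$gecko); r <- unique(tab)[1L]
  } else {
    stopifnot(length(dim(values)) == 3L, dim(values)[2L] == 2L)
    n <- dim(values)[1L]; r <- dim(values)[3L]
    df <- data.frame(
      y = as.vector(values),
      gecko = factor(rep(seq_len(n), times = 2L * r)),
      side = factor(rep(rep(1:2, each = n), times = r)))
  }
  if (n < 2L || r < 2L) stop("need >= 2 individuals and >= 2 replicates")
  fit <- stats::aov(y ~ side * gecko, data = df)
  ss <- summary(fit)[[1L]]
  src <- trimws(rownames(ss))
  SS <- stats::setNames(ss[["Sum Sq"]], src)
  DF <- stats::setNames(ss[["Df"]], src)
  tab <- data.frame(
    source = c("sides", "individuals", "sides_x_individuals", "error"),
    SS = SS[c("side", "gecko", "side:gecko", "Residuals")],
    df = DF[c("side", "gecko", "side:gecko", "Residuals")],
    row.names = NULL)
  tab$MS <- tab$SS / tab$df
  ms <- stats::setNames(tab$MS, tab$source)
  # a denominator mean square of zero (to float precision) is signalled
  eps <- 1e-12 * max(sum(tab$SS), 1)
  f_sides <- if (ms[["sides_x_individuals"]] > eps)
    ms[["sides"]] / ms[["sides_x_individuals"]] else NA_real_
  f_inter <- if (ms[["error"]] > eps)
    ms[["sides_x_individuals"]] / ms[["error"]] else NA_real_
  structure(
    list(table = tab, n_individuals = n, n_replicates = r,
         F_sides = f_sides,
         p_sides = if (is.na(f_sides)) NA_real_ else
           stats::pf(f_sides, tab$df[1L], tab$df[3L], lower.tail = FALSE),
         F_interaction = f_inter,
         p_interaction = if (is.na(f_inter)) NA_real_ else
           stats::pf(f_inter, tab$df[3L], tab$df[4L], lower.tail = FALSE)),
    class = "anova_sides")
}

#' @export
print.anova_sides <- function(x, ...) {
  print(x$table)
  cat(sprintf("F_sides = %.3f (p = %.4g), F_interaction = %.3f (p = %.4g)\n",
              x$F_sides, x$p_sides, x$F_interaction, x$p_interaction))
  invisible(x)
}

#' Check the head/tail -> trunk -> legs patterning hierarchy
#'
#' Tests, per gecko, the implications "any leg patterned implies trunk
#' patterned" and "trunk patterned implies head and tail patterned".
#'
#' @param presence data.frame or matrix of logicals with one row per gecko
#'   and columns named by `BODY_PARTS` (row names or a `gecko_id` column
#'   identify the geckos).
#' @return list with per-implication violation counts and the violating
#'   gecko ids.
#' @export
hierarchy_check <- function(presence) {
  if (is.data.frame(presence) && "gecko_id" %in% names(presence)) {
    ids <- presence$gecko_id
    presence <- as.matrix(presence[, BODY_PARTS])
  } else {
    ids <- rownames(presence)
    presence <- as.matrix(presence[, BODY_PARTS])
    if (is.null(ids)) ids <- as.character(seq_len(nrow(presence)))
  }
  mode(presence) <- "logical"
  any_leg <- presence[, "FL"] | presence[, "FR"] |
    presence[, "BL"] | presence[, "BR"]
  v1 <- any_leg & !presence[, "TR"]
  v2 <- presence[, "TR"] & !(presence[, "HD"] & presence[, "TA"])
  list(
    legs_imply_trunk = list(violations = sum(v1), violators = ids[v1]),
    trunk_implies_head_tail = list(violations = sum(v2),
                                   violators = ids[v2]),
    total_violations = sum(v1) + sum(v2))
}
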