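# Distances on 14-dimensional pattern space.
#
# Two squared distances compare replicate-averaged index vectors:
#   * Mahalanobis: (x-y)' S^-1 (x-y), S the sample covariance of all
#     qualifying patterns pooled across body parts;
#   * Developmental Noise: sum_i w_i (x_i - y_i)^2, with w_i the inverse
#     of the mean left-right variance of index i over the two front-leg
#     patterns of geckos patterned on all four legs. Indices dominated by
#     stochastic developmental variation are thereby down-weighted.
# Reported distances are always the squares, rescaled so that the mean
# squared distance between leg patterns of different individuals is 1.

#' Assemble an index dataset from a table of pattern indices
#'
#' @param df data.frame with columns `gecko_id`, `body_part`, `qualifying`
#'   and the 14 index columns ([INDEX_NAMES]); at most one row per
#'   gecko x body part (use the replicate-averaged rows).
#' @return object of class `index_dataset`.
#' @export
index_dataset <- function(df) {
  need <- c("gecko_id", "body_part", "qualifying", INDEX_NAMES)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  key <- paste(df$gecko_id, df$body_part)
  if (anyDuplicated(key))
    stop("more than one row per gecko x body part; average replicates first")
  df <- df[order(df$gecko_id, match(df$body_part, BODY_PARTS)), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(df = df), class = "index_dataset")
}

#' @export
print.index_dataset <- function(x, ...) {
  cat(sprintf("<index_dataset> %d rows (%d qualifying), %d geckos\n",
              nrow(x$df), sum(x$df$qualifying),
              length(unique(x$df$gecko_id))))
  invisible(x)
}

# qualifying rows with complete index vectors, as a numeric matrix
.complete_matrix <- function(data, parts = BODY_PARTS) {
  df <- data$df
  keep <- df$qualifying & df$body_part %in% parts &
    stats::complete.cases(df[, INDEX_NAMES])
  df <- df[keep, , drop = FALSE]
  X <- as.matrix(df[, INDEX_NAMES])
  rownames(X) <- NULL
  list(X = X, gecko_id = df$gecko_id, body_part = df$body_part)
}

# index vector of one gecko x part, or NULL when absent/incomplete
.row_vector <- function(data, gecko, part) {
  df <- data$df
  i <- which(df$gecko_id == gecko & df$body_part == part & df$qualifying)
  if (length(i) != 1L) return(NULL)
  v <- as.numeric(df[i, INDEX_NAMES])
  if (anyNA(v)) return(NULL)
  v
}

#' Fit the Mahalanobis metric on pattern space
#'
#' S is the sample covariance of all qualifying complete patterns, pooled
#' across body parts. A ridge epsilon*I (epsilon = 1e-8 * trace(S)/14) is
#' added only when the condition number exceeds 1e12 (e.g. duplicated
#' columns).
#'
#' @param data an `index_dataset`.
#' @return object of class `distance_spec` with `kind = "mahalanobis"`,
#'   the inverse covariance `S_inv` and `scale_c = 1` (see
#'   [calibrate_scale()]).
#' @export
fit_mahalanobis <- function(data) {
  cm <- .complete_matrix(data)
  if (nrow(cm$X) < 2L) stop("need at least 2 complete qualifying patterns")
  S <- stats::cov(cm$X)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e12) {
    S <- S + diag(1e-8 * sum(diag(S)) / ncol(S), ncol(S))
  }
  structure(
    list(kind = "mahalanobis", S_inv = solve(S), weights = NULL,
         scale_c = 1, n_fit = nrow(cm$X)),
    class = "distance_spec")
}

#' Fit the Developmental Noise metric
#'
#' For every gecko with qualifying patterns on all four legs, the
#' left-right variance of index i over its two front legs is
#' S_i^n = (FL_i - FR_i)^2 / 2; the weight is w_i = 1 / mean_n(S_i^n).
#' Back legs enter the all-four-legs eligibility requirement but never the
#' weights.
#'
#' @param data an `index_dataset`.
#' @return a `distance_spec` with `kind = "devnoise"` and the 14 weights.
#' @export
fit_devnoise <- function(data) {
  geckos <- unique(data$df$gecko_id)
  pairs <- list()
  for (g in geckos) {
    legs <- lapply(c("FL", "FR", "BL", "BR"), function(p)
      .row_vector(data, g, p))
    if (any(vapply(legs, is.null, TRUE))) next
    pairs[[g]] <- (legs[[1L]] - legs[[2L]])^2 / 2    # front-leg variance
  }
  if (length(pairs) == 0L)
    stop("no gecko has qualifying patterns on all four legs")
  Svar <- do.call(rbind, pairs)
  mean_var <- colMeans(Svar)
  if (any(mean_var == 0))
    stop("index identical across both front legs of every gecko: ",
         paste(INDEX_NAMES[mean_var == 0], collapse = ", "))
  structure(
    list(kind = "devnoise", S_inv = NULL,
         weights = stats::setNames(1 / mean_var, INDEX_NAMES),
         scale_c = 1, n_fit = length(pairs),
         geckos_used = names(pairs)),
    class = "distance_spec")
}

#' @export
print.distance_spec <- function(x, ...) {
  cat(sprintf("<distance_spec> %s (fit on %d %s), scale_c = %.4g\n",
              x$kind, x$n_fit,
              if (x$kind == "mahalanobis") "patterns" else "geckos",
              x$scale_c))
  invisible(x)
}

#' Squared distance between two patterns
#'
#' Mahalanobis: (x-y)' S^-1 (x-y); Developmental Noise:
#' sum_i w_i (x_i-y_i)^2. The result is multiplied by the calibration
#' constant `scale_c`.
#'
#' @param x,y numeric 14-vectors (no missing entries).
#' @param spec a fitted `distance_spec`.
#' @return non-negative scalar.
#' @export
squared_distance <- function(x, y, spec) {
  if (anyNA(x) || anyNA(y)) stop("missing index values in distance input")
  d <- x - y
  v <- if (spec$kind == "mahalanobis") {
    drop(d %*% spec$S_inv %*% d)
  } else {
    sum(spec$weights * d^2)
  }
  v * spec$scale_c
}

# squared-distance matrix between the rows of A and of B
.sqdist_matrix <- function(A, B, spec) {
  if (spec$kind == "mahalanobis") {
    M <- spec$S_inv
    AM <- A %*% M
    D <- matrix(rowSums(AM * A), nrow(A), nrow(B)) +
      matrix(rowSums((B %*% M) * B), nrow(A), nrow(B), byrow = TRUE) -
      2 * AM %*% t(B)
  } else {
    W <- sqrt(spec$weights)
    Aw <- sweep(A, 2L, W, `*`); Bw <- sweep(B, 2L, W, `*`)
    D <- matrix(rowSums(Aw^2), nrow(A), nrow(B)) +
      matrix(rowSums(Bw^2), nrow(A), nrow(B), byrow = TRUE) -
      2 * Aw %*% t(Bw)
  }
  pmax(D, 0) * spec$scale_c
}

#' Calibrate the distance scale on between-individual leg patterns
#'
#' Sets `scale_c` so that the mean squared distance over all unordered
#' pairs of qualifying leg patterns belonging to different geckos equals
#' 1, regardless of leg identity.
#'
#' @param data an `index_dataset`.
#' @param spec a fitted `distance_spec`.
#' @return the `distance_spec` with `scale_c` set.
#' @export
calibrate_scale <- function(data, spec) {
  cm <- .complete_matrix(data, parts = c("FL", "FR", "BL", "BR"))
  n <- nrow(cm$X)
  if (n < 2L || length(unique(cm$gecko_id)) < 2L)
    stop("need qualifying leg patterns from at least 2 geckos")
  base <- spec; base$scale_c <- 1
  D <- .sqdist_matrix(cm$X, cm$X, base)
  cross <- outer(cm$gecko_id, cm$gecko_id, `!=`) & upper.tri(D)
  m <- mean(D[cross])
  if (!is.finite(m) || m <= 0) stop("no between-individual leg variation")
  spec$scale_c <- 1 / m
  spec
}

#' Within- vs between-individual mean squared distance for a pair of parts
#'
#' Within: mean over geckos g (with both parts qualifying) of
#' d^2(A_g, B_g). Between: mean over unordered gecko pairs g != h of
#' (d^2(A_g, B_h) + d^2(A_h, B_g)) / 2.
#'
#' @param data an `index_dataset`.
#' @param spec a fitted (and typically calibrated) `distance_spec`.
#' @param pair character 2-vector of body parts, e.g. `c("FL", "FR")`.
#' @return list: `mean_within`, `mean_between`, `ratio` (`NA` when between
#'   is 0), `n_within` (geckos), `n_between` (gecko pairs).
#' @export
within_between_summary <- function(data, spec, pair) {
  stopifnot(length(pair) == 2L, all(pair %in% BODY_PARTS))
  AB <- .paired_matrices(data, pair)
  if (AB$n < 2L)
    stop("need at least 2 geckos with both parts qualifying")
  D <- .sqdist_matrix(AB$A, AB$B, spec)
  .wb_from_matrix(D, seq_len(AB$n), n_within = AB$n)
}

# geckos having complete qualifying patterns on both parts, as matrices
#' @keywords internal
.paired_matrices <- function(data, pair) {
  geckos <- unique(data$df$gecko_id)
  A <- list(); B <- list()
  for (g in geckos) {
    a <- .row_vector(data, g, pair[1L]); b <- .row_vector(data, g, pair[2L])
    if (is.null(a) || is.null(b)) next
    A[[g]] <- a; B[[g]] <- b
  }
  list(A = do.call(rbind, A), B = do.call(rbind, B), n = length(A),
       geckos = names(A))
}

# within/between summary for pairing i -> perm[i] on a squared-distance
# matrix D[i, j] = d^2(A_i, B_j)
#' @keywords internal
.wb_from_matrix <- function(D, perm, n_within = nrow(D)) {
  n <- nrow(D)
  within <- mean(D[cbind(seq_len(n), perm)])
  between <- (sum(D) - sum(D[cbind(seq_len(n), perm)])) / (n * (n - 1L))
  list(mean_within = within, mean_between = between,
       ratio = if (between > 0) within / between else NA_real_,
       n_within = n_within, n_between = n * (n - 1L) / 2L)
}
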