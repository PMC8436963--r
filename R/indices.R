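# The 14 pattern indices describing one region's spot pattern.
#
#   FM          fraction of melanistic area (all spots / mask)   [0,1]
#   SS,  SSD    mean / sd of spot major-axis length, cm          interior
#   EE,  EED    mean / sd of major:minor axis ratio (>= 1)       interior
#   PL          characteristic wavelength (spectral peak), cm    all
#   MD,  MDD    mean / sd of mean distance to the 3 closest
#               other spot centroids, cm                         all
#   SA,  SAD    mean / sd of spot area, cm^2                     interior
#   SI,  SID    mean / sd of green values over pooled spot px    all
#   EL,  ELD    mean / sd of spot elongation area/(2 d^2), d =
#               erosion steps until the spot vanishes            interior
#
# Standard deviations are sample (n-1) throughout. An index whose spot
# class is empty (or, for the sd of a single spot, undefined) is NA.

#' Names of the 14 pattern indices, in canonical order
#' @export
INDEX_NAMES <- c("FM", "SS", "SSD", "EE", "EED", "PL", "MD", "MDD",
                 "SA", "SAD", "SI", "SID", "EL", "ELD")

#' Equivalent-ellipse axes of a pixel set
#'
#' Axes of the ellipse with the same normalized second central moments as
#' the pixel set, using the standard +1/12 per-pixel moment correction:
#' full axis lengths are 4 * sqrt(eigenvalue).
#'
#' @param pixel_idx linear pixel indices (column-major).
#' @param h number of image rows.
#' @return list `major`, `minor` (full lengths, px; major >= minor) and
#'   `orientation` (radians, major axis against the column axis).
#' @export
equivalent_ellipse <- function(pixel_idx, h) {
  stopifnot(length(pixel_idx) >= 1L)
  rc <- idx_to_rc(pixel_idx, h)
  r <- rc[, 1L]; cc <- rc[, 2L]
  mrr <- mean((r - mean(r))^2) + 1 / 12
  mcc <- mean((cc - mean(cc))^2) + 1 / 12
  mrc <- mean((r - mean(r)) * (cc - mean(cc)))
  disc <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
  l1 <- (mrr + mcc + disc) / 2
  l2 <- (mrr + mcc - disc) / 2
  list(major = 4 * sqrt(l1), minor = max(4 * sqrt(max(l2, 0)), 1),
       orientation = 0.5 * atan2(2 * mrc, mcc - mrr))
}

#' Spot thickness: erosion steps until the spot disappears
#'
#' Successive 3x3-cross (4-connected) erosions of the (already
#' hole-filled) spot, counting steps until no pixel remains. The cross
#' element peels one unit of inradius per step, so thickness measures the
#' spot's half-width: a single pixel has thickness 1, a 20x20 solid
#' square 10, and a digital disk of radius 10 also 10 (making the
#' elongation EL = area/(2 d^2) of a disk pi/2, its minimum over convex
#' shapes of a given width).
#'
#' @param m logical matrix containing just the spot.
#' @return integer >= 1.
#' @export
spot_thickness <- function(m) {
  stopifnot(any(m))
  # crop to the bounding box to keep repeated erosions cheap
  rs <- range(which(rowSums(m) > 0)); cs <- range(which(colSums(m) > 0))
  m <- m[rs[1L]:rs[2L], cs[1L]:cs[2L], drop = FALSE]
  d <- 0L
  while (any(m)) {
    m <- erode_cross(m, 1L)
    d <- d + 1L
  }
  d
}

#' Characteristic wavelength of a binary pattern (peak length)
#'
#' The binary spot field is cropped to the mask bounding box, out-of-mask
#' pixels are set to the in-mask mean, the mean is removed, and the field
#' is zero-padded to the next power-of-two square N. The radially averaged
#' 2-D FFT power spectrum is maximized over integer-radius annuli
#' r = 1..N/2; the peak radius r* gives PL = (N / r*) * cm_per_pixel.
#' Wavelengths too long to be resolved are excluded from the search: at
#' least `min_periods` full periods must fit across the smaller
#' bounding-box dimension, which keeps window-envelope leakage at very low
#' frequencies from masquerading as a pattern wavelength.
#'
#' @param field a `binary_pattern`, or a logical matrix of the spot field.
#' @param mask region mask (ignored when `field` is a `binary_pattern`).
#' @param cm_per_pixel physical scale (ignored for a `binary_pattern`).
#' @param min_periods minimum number of pattern periods that must fit in
#'   the window (default 2; 0 searches all annuli).
#' @return wavelength in cm, or `NA` for a uniform (no dark / all dark)
#'   field.
#' @export
peak_length <- function(field, mask = NULL, cm_per_pixel = NULL,
                        min_periods = 2) {
  if (inherits(field, "binary_pattern")) {
    mask <- field$mask
    cm_per_pixel <- field$cm_per_pixel
    field <- field$dark
  }
  stopifnot(is.matrix(field), is.matrix(mask), !is.null(cm_per_pixel))
  nin <- sum(mask)
  ndark <- sum(field & mask)
  if (ndark == 0L || ndark == nin) return(NA_real_)

  rs <- range(which(rowSums(mask) > 0)); cs <- range(which(colSums(mask) > 0))
  f <- (field & mask)[rs[1L]:rs[2L], cs[1L]:cs[2L], drop = FALSE] * 1
  mk <- mask[rs[1L]:rs[2L], cs[1L]:cs[2L], drop = FALSE]
  m0 <- mean(f[mk])
  f[!mk] <- m0
  f <- f - m0                              # out-of-mask pixels become 0
  N <- 2L^ceiling(log2(max(dim(f))))
  padded <- matrix(0, N, N)
  padded[seq_len(nrow(f)), seq_len(ncol(f))] <- f

  P <- Mod(stats::fft(padded))^2
  fr <- c(0:(N / 2L), (N / 2L - 1L):1L)     # |signed frequency| per index
  rad <- sqrt(outer(fr^2, fr^2, `+`))
  bin <- as.integer(round(rad))
  r_min <- max(1L, as.integer(floor(min_periods * N / min(dim(f)))))
  keep <- bin >= r_min & bin <= N / 2L
  if (!any(keep)) return(NA_real_)
  mean_power <- tapply(P[keep], bin[keep], mean)
  r_star <- as.integer(names(mean_power)[which.max(mean_power)])
  (N / r_star) * cm_per_pixel
}

#' Mean distance to the closest other spot centroids
#'
#' For every spot, the mean Euclidean distance from its centroid to the
#' `k` closest other spots' centroids (k is reduced to n-1 when fewer
#' other spots exist). MD is the mean and MDD the sample sd of these
#' per-spot means, both in cm.
#'
#' @param centroids n x 2 matrix of centroids (px), or a list of spots.
#' @param k number of neighbours (default 3).
#' @param cm_per_pixel physical scale.
#' @return list `MD`, `MDD` (cm); both `NA` when n < 2 (`MDD` 0 when the
#'   per-spot means are all equal by forced k = 1 with n = 2).
#' @export
nearest_neighbor_stats <- function(centroids, k = 3L, cm_per_pixel = 1) {
  if (is.list(centroids) && !is.matrix(centroids)) {
    centroids <- do.call(rbind, lapply(centroids, `[[`, "centroid"))
  }
  n <- nrow(centroids)
  if (is.null(n) || n < 2L) return(list(MD = NA_real_, MDD = NA_real_))
  D <- as.matrix(stats::dist(centroids))
  k_eff <- min(k, n - 1L)
  per_spot <- vapply(seq_len(n), function(i) {
    mean(sort(D[i, -i])[seq_len(k_eff)])
  }, 1)
  list(MD = mean(per_spot) * cm_per_pixel,
       MDD = (if (n > 1L) stats::sd(per_spot) else NA_real_) * cm_per_pixel)
}

.mean_sd <- function(v) {
  if (length(v) == 0L) return(c(NA_real_, NA_real_))
  c(mean(v), if (length(v) > 1L) stats::sd(v) else NA_real_)
}

#' Compute the 14 pattern indices of one region
#'
#' @param spotset `spot_set` from [extract_spots()].
#' @param pattern the `binary_pattern` it came from.
#' @param image the original `region_image`.
#' @param ee_convention `"ratio"` (major/minor, >= 1; default) or
#'   `"eccentricity"` (sqrt(1 - (minor/major)^2)).
#' @return object of class `pattern_indices`: the 14 values plus spot
#'   counts, the qualifying flag and identity metadata.
#' @export
compute_indices <- function(spotset, pattern, image,
                            ee_convention = c("ratio", "eccentricity")) {
  ee_convention <- match.arg(ee_convention)
  stopifnot(all(dim(pattern$mask) == dim(image$mask)))
  scale <- pattern$cm_per_pixel
  spots <- spotset$spots
  interior <- Filter(function(s) s$interior, spots)
  green <- channel_matrix(image, "G")

  fm <- sum(vapply(spots, `[[`, 1L, "area_px")) / sum(pattern$mask)

  ss <- .mean_sd(vapply(interior, `[[`, 1, "major_axis_px") * scale)
  ee_vals <- vapply(interior, function(s) {
    q <- s$major_axis_px / s$minor_axis_px
    if (ee_convention == "ratio") q else sqrt(1 - 1 / q^2)
  }, 1)
  ee <- .mean_sd(ee_vals)
  sa <- .mean_sd(vapply(interior, `[[`, 1, "area_cm2"))
  el <- .mean_sd(vapply(interior,
                        function(s) s$area_px / (2 * s$thickness_d^2), 1))

  pl <- if (length(spots)) {
    peak_length(spotset$spot_mask, pattern$mask, scale)
  } else NA_real_
  nn <- nearest_neighbor_stats(spots, k = 3L, cm_per_pixel = scale)
  si <- if (length(spots)) {
    px <- unlist(lapply(spots, `[[`, "pixel_idx"))
    .mean_sd(green[px])
  } else c(NA_real_, NA_real_)

  vals <- c(FM = fm, SS = ss[1L], SSD = ss[2L], EE = ee[1L], EED = ee[2L],
            PL = pl, MD = nn$MD, MDD = nn$MDD, SA = sa[1L], SAD = sa[2L],
            SI = si[1L], SID = si[2L], EL = el[1L], ELD = el[2L])
  structure(
    list(values = vals, n_all = spotset$n_all,
         n_interior = spotset$n_interior, qualifying = spotset$qualifying,
         gecko_id = spotset$gecko_id, body_part = spotset$body_part,
         replicate = spotset$replicate, averaged = FALSE),
    class = "pattern_indices")
}

#' @export
print.pattern_indices <- function(x, digits = 4, ...) {
  cat(sprintf("<pattern_indices> %s %s %s (%d spots, %d interior, %squalifying)\n",
              x$gecko_id, x$body_part,
              if (x$averaged) "averaged" else paste("rep", x$replicate),
              x$n_all, x$n_interior, if (x$qualifying) "" else "non-"))
  print(round(x$values, digits))
  invisible(x)
}

#' @export
as.data.frame.pattern_indices <- function(x, ...) {
  data.frame(gecko_id = x$gecko_id, body_part = x$body_part,
             replicate = if (x$averaged) NA_integer_ else x$replicate,
             averaged = x$averaged, qualifying = x$qualifying,
             n_all = x$n_all, n_interior = x$n_interior,
             as.list(x$values), stringsAsFactors = FALSE)
}

#' Average the pattern indices of replicate photographs
#'
#' Per-index arithmetic mean over the replicates of one gecko x body part;
#' spot counts are averaged too. An index missing in some replicate is
#' averaged over the non-missing ones, with a warning.
#'
#' @param replicates list of `pattern_indices` for the same gecko and
#'   body part.
#' @return a `pattern_indices` with `averaged = TRUE`.
#' @export
average_replicates <- function(replicates) {
  if (length(replicates) == 0L) stop("no replicates to average")
  ids <- unique(vapply(replicates, `[[`, "", "gecko_id"))
  parts <- unique(vapply(replicates, `[[`, "", "body_part"))
  if (length(ids) != 1L || length(parts) != 1L)
    stop("replicates must belong to one gecko and one body part")
  V <- do.call(rbind, lapply(replicates, `[[`, "values"))
  partial <- apply(is.na(V), 2L, any) & !apply(is.na(V), 2L, all)
  if (any(partial))
    warning(sprintf("%s %s: averaging over non-missing replicates for %s",
                    ids, parts,
                    paste(INDEX_NAMES[partial], collapse = ", ")))
  vals <- colMeans(V, na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  structure(
    list(values = vals,
         n_all = mean(vapply(replicates, `[[`, 1L, "n_all")),
         n_interior = mean(vapply(replicates, `[[`, 1L, "n_interior")),
         qualifying = all(vapply(replicates, `[[`, TRUE, "qualifying")),
         gecko_id = ids, body_part = parts, replicate = NA_integer_,
         averaged = TRUE),
    class = "pattern_indices")
}
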