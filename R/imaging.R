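# Robust-background (Niblack) binarization of a region photograph.
#
# The whole region is the Niblack window: a pixel is dark when its green
# value falls below T = mu - k*sigma, where mu and sigma are computed over
# the region and k is a per-body-part factor. T is floored at 60 (out of
# 255) everywhere and additionally capped at 108 for the trunk. Before the
# threshold statistics are computed, pixels flagged as lighting artifacts
# (shadows / glare, per-part channel rules) are excluded from the
# statistics; see `artifact_mask`.

# Per-morphological-type constants: Niblack factor, artifact rules.
.niblack_k <- c(limb = 0.85, head = 0.50, trunk = 0.85, tail = 0.85)
.threshold_floor <- 60
.trunk_cap <- 108

#' Mean and population standard deviation of a channel over selected pixels
#'
#' @param image a `region_image`.
#' @param channel `"R"`, `"G"` or `"B"`.
#' @param used logical matrix selecting the pixels (must lie within the
#'   region mask); defaults to the full mask.
#' @return list with `mu` and `sigma` (population sd, divisor n).
#' @export
region_stats <- function(image, channel = "G", used = NULL) {
  if (is.null(used)) used <- image$mask
  stopifnot(is.logical(used), all(dim(used) == dim(image$mask)))
  if (any(used & !image$mask)) stop("'used' must be a subset of the mask")
  v <- channel_matrix(image, channel)[used]
  if (length(v) < 2L) stop("degenerate region: fewer than 2 usable pixels")
  mu <- mean(v)
  list(mu = mu, sigma = sqrt(mean((v - mu)^2)))
}

#' Flag shadow and glare pixels of a region photograph
#'
#' Limbs: shadows are green < mu_G - 0.3 sigma_G and glare green >
#' mu_G + 0.3 sigma_G; trunk: shadows are blue < mu_B - 0.85 sigma_B (no
#' glare rule); head and tail have no artifact rules. Statistics are taken
#' over the full region mask.
#'
#' @param image a `region_image`.
#' @return list of logical matrices `shadow` and `glare`.
#' @export
artifact_mask <- function(image) {
  type <- body_part_type(image$body_part)
  h <- nrow(image$mask); w <- ncol(image$mask)
  none <- matrix(FALSE, h, w)
  if (type %in% c("head", "tail")) {
    return(list(shadow = none, glare = none))
  }
  if (type == "limb") {
    s <- region_stats(image, "G")
    g <- channel_matrix(image, "G")
    shadow <- image$mask & (g < s$mu - 0.3 * s$sigma)
    glare <- image$mask & (g > s$mu + 0.3 * s$sigma)
    return(list(shadow = shadow, glare = glare))
  }
  # trunk: shadows via the blue channel, which barely distinguishes
  # melanistic spots from the yellowish background skin
  s <- region_stats(image, "B")
  b <- channel_matrix(image, "B")
  list(shadow = image$mask & (b < s$mu - 0.85 * s$sigma), glare = none)
}

#' Compute the per-body-part binarization threshold
#'
#' T = mu - k*sigma with k = 0.85 for limbs, trunk and tail and k = 0.50
#' for the head, floored at 60; the trunk threshold is additionally capped
#' at 108.
#'
#' @param mu mean green intensity of the used pixels.
#' @param sigma standard deviation of the same.
#' @param body_part one of `BODY_PARTS`.
#' @param k Niblack factor; `NULL` (default) selects the per-part value
#'   (0.85 limbs/trunk/tail, 0.50 head).
#' @param floor global lower bound on the threshold (default 60).
#' @param cap upper bound; `NULL` selects the per-part default (108 for
#'   the trunk, none otherwise).
#' @return a `threshold_report` list: `mu`, `sigma`, `k`, `floor`, `cap`
#'   (`NA` unless capped), `T`, and artifact exclusion counts (filled in
#'   by `binarize`).
#' @export
compute_threshold <- function(mu, sigma, body_part, k = NULL,
                              floor = .threshold_floor, cap = NULL) {
  stopifnot(is.numeric(mu), is.numeric(sigma), sigma >= 0)
  type <- body_part_type(body_part)
  if (is.null(k)) k <- .niblack_k[[type]]
  if (is.null(cap)) cap <- if (type == "trunk") .trunk_cap else NA_real_
  T <- max(mu - k * sigma, floor)
  if (!is.na(cap)) T <- min(T, cap)
  structure(
    list(mu = mu, sigma = sigma, k = k, floor = floor, cap = cap,
         T = T, n_excluded_shadow = 0L, n_excluded_glare = 0L),
    class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf(
    "<threshold_report> mu=%.2f sigma=%.2f k=%.2f -> T=%.2f (floor %g%s); excluded %d shadow / %d glare px\n",
    x$mu, x$sigma, x$k, x$T, x$floor,
    if (!is.na(x$cap)) sprintf(", cap %g", x$cap) else "",
    x$n_excluded_shadow, x$n_excluded_glare))
  invisible(x)
}

#' Binarize a region photograph into a dark/light pattern
#'
#' Pipeline: (1) flag shadow/glare pixels (`artifact_mask`); (2) recompute
#' green-channel statistics over the mask minus flagged pixels; (3) derive
#' the threshold (`compute_threshold`); (4) classify dark pixels as strictly
#' below the threshold. Glare pixels can never be dark. How shadow pixels
#' are treated is configurable: by default they are excluded from the
#' threshold statistics but remain eligible for dark classification, because
#' on spotted regions the shadow rule necessarily flags the darkest --
#' i.e. melanistic -- pixels themselves; `"exclude_dark"` additionally bars
#' them from the dark set, and `"none"` disables artifact handling.
#'
#' @param image a `region_image`.
#' @param artifact_action `"exclude_stats"` (default), `"exclude_dark"`,
#'   or `"none"`.
#' @param k,floor,cap threshold overrides, see [compute_threshold()].
#' @return object of class `binary_pattern`: logical `dark` and `mask`
#'   matrices, `cm_per_pixel`, the `threshold_report`, and identity
#'   metadata.
#' @export
binarize <- function(image,
                     artifact_action = c("exclude_stats", "exclude_dark",
                                         "none"),
                     k = NULL, floor = .threshold_floor, cap = NULL) {
  artifact_action <- match.arg(artifact_action)
  if (artifact_action == "none") {
    h <- nrow(image$mask); w <- ncol(image$mask)
    art <- list(shadow = matrix(FALSE, h, w), glare = matrix(FALSE, h, w))
  } else {
    art <- artifact_mask(image)
  }
  used <- image$mask & !art$shadow & !art$glare
  # strongly bimodal regions can leave the between-modes band empty; fall
  # back to full-region statistics (plain Niblack) in that case
  if (sum(used) < 2L) used <- image$mask
  s <- region_stats(image, "G", used)
  rep <- compute_threshold(s$mu, s$sigma, image$body_part,
                           k = k, floor = floor, cap = cap)
  rep$n_excluded_shadow <- sum(art$shadow)
  rep$n_excluded_glare <- sum(art$glare)
  g <- channel_matrix(image, "G")
  dark <- image$mask & (g < rep$T) & !art$glare
  if (artifact_action == "exclude_dark") dark <- dark & !art$shadow
  structure(
    list(dark = dark, mask = image$mask, cm_per_pixel = image$cm_per_pixel,
         report = rep, body_part = image$body_part,
         gecko_id = image$gecko_id, replicate = image$replicate),
    class = "binary_pattern")
}

#' @export
print.binary_pattern <- function(x, ...) {
  cat(sprintf("<binary_pattern> %s %s rep %d: %d dark of %d mask px (T=%.2f)\n",
              x$gecko_id, x$body_part, x$replicate,
              sum(x$dark), sum(x$mask), x$report$T))
  invisible(x)
}
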