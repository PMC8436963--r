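# Synthetic region images with known ground truth.
#
# Dark elliptical spots are placed on a jittered hexagonal lattice inside a
# region mask and rendered onto a lighter, noisy background, optionally
# with a shadow gradient and a glare blob. The hexagonal lattice gives the
# pattern a true characteristic wavelength -- the nearest-neighbour centre
# spacing lambda, stored in the truth record as `pl_cm`. (For an infinite
# point lattice the radial spectral peak would sit at the plane spacing
# sqrt(3)/2 * lambda; in the small windows generated here the measured
# peak empirically tracks lambda itself, with a mild downward bias.)

#' Specification of one synthetic region pattern
#'
#' @param height,width canvas size in pixels.
#' @param mask_shape `"rectangle"`, `"ellipse"` or `"capsule"` (rounded
#'   band, limb/tail-like).
#' @param lambda_px hexagonal lattice nearest-neighbour spacing (px).
#' @param jitter fraction of `lambda_px` (in `[0, 1)`) by which lattice
#'   points are uniformly displaced per coordinate.
#' @param a_meanlog,a_sdlog lognormal parameters of the spot semi-major
#'   axis (px).
#' @param ratio_meanlog,ratio_sdlog lognormal parameters of the major:minor
#'   axis ratio (truncated at 1).
#' @param bg_green_mean,bg_green_sd background green level and noise sd.
#' @param spot_green_mean,spot_green_sd spot green level and noise sd
#'   (spot mean must be below background mean).
#' @param red_offset red channel = green + offset.
#' @param bg_blue_mean,blue_sd,spot_blue_drop blue channel background
#'   level, noise, and the (small) darkening of spots in blue.
#' @param shadow_amp,shadow_frac amplitude (intensity units) and width
#'   (fraction of columns) of a linear shadow ramp on the left edge;
#'   0 disables it.
#' @param glare_amp,glare_sigma amplitude and Gaussian radius (px) of a
#'   glare blob; 0 disables it.
#' @param n_speckles number of 1-5 px dark speckles added to the dark
#'   field (sub-minimum-size artifacts).
#' @param cm_per_pixel physical scale.
#' @param seed optional RNG seed (`generate_pattern` is bit-reproducible
#'   for a fixed seed).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(height = 150L, width = 110L,
                           mask_shape = c("capsule", "rectangle", "ellipse"),
                           lambda_px = 38, jitter = 0.15,
                           a_meanlog = log(13.5), a_sdlog = 0.08,
                           ratio_meanlog = log(1.3), ratio_sdlog = 0.08,
                           bg_green_mean = 182, bg_green_sd = 5,
                           spot_green_mean = 45, spot_green_sd = 5,
                           red_offset = 25,
                           bg_blue_mean = 95, blue_sd = 5,
                           spot_blue_drop = 6,
                           shadow_amp = 0, shadow_frac = 0.35,
                           glare_amp = 0, glare_sigma = 12,
                           n_speckles = 0L,
                           cm_per_pixel = 0.01, seed = NULL) {
  mask_shape <- match.arg(mask_shape)
  stopifnot(jitter >= 0, jitter < 1, lambda_px > 0,
            spot_green_mean < bg_green_mean,
            bg_green_sd >= 0, spot_green_sd >= 0, blue_sd >= 0,
            cm_per_pixel > 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

# region mask for a synthetic spec; `offset` shifts the analytic shape by
# a (possibly fractional) number of pixels, emulating repositioning
.synth_mask <- function(spec, offset = c(0, 0)) {
  h <- spec$height; w <- spec$width
  r <- matrix(seq_len(h), h, w) - offset[1L]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - offset[2L]
  switch(spec$mask_shape,
    rectangle = matrix(TRUE, h, w),
    ellipse = ((r - (h + 1) / 2) / (h / 2 - 1))^2 +
      ((cc - (w + 1) / 2) / (w / 2 - 1))^2 <= 1,
    capsule = {
      # band with semicircular caps along the longer axis
      if (h >= w) {
        rad <- w / 2 - 1
        mid <- abs(cc - (w + 1) / 2) <= rad &
          r >= rad & r <= h - rad
        caps <- (r - rad)^2 + (cc - (w + 1) / 2)^2 <= rad^2 |
          (r - (h - rad))^2 + (cc - (w + 1) / 2)^2 <= rad^2
        mid | caps
      } else {
        rad <- h / 2 - 1
        mid <- abs(r - (h + 1) / 2) <= rad &
          cc >= rad & cc <= w - rad
        caps <- (cc - rad)^2 + (r - (h + 1) / 2)^2 <= rad^2 |
          (cc - (w - rad))^2 + (r - (h + 1) / 2)^2 <= rad^2
        mid | caps
      }
    })
}

# rasterize a table of ellipses (row, col, a, b, theta) at a real offset
.render_dark <- function(ellipses, mask, h, w, offset = c(0, 0)) {
  dark <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(ellipses))) {
    px <- .raster_ellipse(c(ellipses$row[i] + offset[1L],
                            ellipses$col[i] + offset[2L]),
                          ellipses$a[i], ellipses$b[i], ellipses$theta[i],
                          h, w)
    px <- px[mask[px]]
    dark[px] <- TRUE
  }
  dark
}

# rasterize one ellipse, returning linear pixel indices inside the canvas
.raster_ellipse <- function(center, a, b, theta, h, w) {
  r0 <- center[1L]; c0 <- center[2L]
  rr <- max(1L, floor(r0 - a)):min(h, ceiling(r0 + a))
  cc <- max(1L, floor(c0 - a)):min(w, ceiling(c0 + a))
  dR <- matrix(rr - r0, length(rr), length(cc))
  dC <- matrix(cc - c0, length(rr), length(cc), byrow = TRUE)
  u <- dC * cos(theta) + dR * sin(theta)
  v <- -dC * sin(theta) + dR * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  ri <- matrix(rr, length(rr), length(cc))[inside]
  ci <- matrix(cc, length(rr), length(cc), byrow = TRUE)[inside]
  (ci - 1L) * h + ri
}

# raw random draws behind one pattern realization: unjittered lattice,
# per-spot jitter, log-sizes, log axis ratios, orientations
.draw_pattern_params <- function(spec) {
  lam <- spec$lambda_px
  dy <- lam * sqrt(3) / 2
  rows <- seq(lam / 2, spec$height - lam / 4, by = dy)
  pts0 <- list()
  for (i in seq_along(rows)) {
    xs <- seq(lam / 2 + (i %% 2) * lam / 2, spec$width - lam / 4, by = lam)
    if (!length(xs)) next
    pts0[[i]] <- cbind(row = rows[i], col = xs)
  }
  pts0 <- do.call(rbind, pts0)
  if (is.null(pts0) || nrow(pts0) == 0L)
    stop("region too small for lattice")
  n <- nrow(pts0)
  jit <- if (spec$jitter > 0) {
    matrix(stats::runif(2L * n, -spec$jitter * lam / 2,
                        spec$jitter * lam / 2), ncol = 2L)
  } else matrix(0, n, 2L)
  list(pts0 = pts0, jit = jit,
       logsize = stats::rnorm(n, spec$a_meanlog, spec$a_sdlog),
       logratio = stats::rnorm(n, spec$ratio_meanlog, spec$ratio_sdlog),
       theta = stats::runif(n, 0, pi))
}

#' Perturb pattern parameters (shared developmental program, noisy sides)
#'
#' Adds `amount`-scaled Gaussian noise to a base realization's per-spot
#' jitter, log-sizes, log axis ratios and orientations. Two perturbed
#' copies of one base emulate the left and right members of a leg pair:
#' at `amount = 0` the sides carry identical patterns, and the
#' within-pair pattern distance grows monotonically with `amount`.
#'
#' @param params base draws from a `generate_pattern` call (its
#'   `params` element).
#' @param spec the `synthetic_spec` the base was drawn under.
#' @param amount non-negative perturbation scale (1 = comparable to the
#'   base draw's own spread).
#' @return a perturbed params list, usable as `generate_pattern(spec,
#'   params = ...)`.
#' @export
perturb_pattern_params <- function(params, spec, amount = 1) {
  stopifnot(amount >= 0)
  n <- nrow(params$pts0)
  lam <- spec$lambda_px
  # slight whole-pattern dilation: the two sides of a real pair differ a
  # little in overall spot spacing as well as in per-spot detail
  scale_f <- exp(stats::rnorm(1L, 0, amount * 0.03))
  ctr <- c(spec$height + 1, spec$width + 1) / 2
  params$pts0 <- sweep(sweep(params$pts0, 2L, ctr, `-`) * scale_f,
                       2L, ctr, `+`)
  params$jit <- params$jit +
    matrix(stats::rnorm(2L * n, 0, amount * spec$jitter * lam / 4),
           ncol = 2L)
  params$logsize <- params$logsize + stats::rnorm(n, 0, amount * spec$a_sdlog)
  params$logratio <- params$logratio +
    stats::rnorm(n, 0, amount * spec$ratio_sdlog)
  params$theta <- (params$theta + stats::rnorm(n, 0, amount * 0.4)) %% pi
  params
}

#' Generate a synthetic binary spot pattern with ground truth
#'
#' Ellipses with lognormal semi-major axes and axis ratios are rasterized
#' at jittered hexagonal lattice points whose centre falls inside the
#' region mask. Overlap is impossible by construction: a crowding rule
#' caps every semi-major axis at half the gap to the nearest neighbour
#' (minus the separation a 2-iteration closing needs), so spots can
#' neither touch nor be merged by contour smoothing.
#'
#' @param spec a `synthetic_spec`.
#' @param min_spot_px spot-size floor used for the truth summaries
#'   (default 350, matching the extraction default).
#' @param params optionally, a pre-drawn (possibly perturbed) parameter
#'   set; see [perturb_pattern_params()]. Fresh draws are made when
#'   `NULL`.
#' @return list: `pattern` (a `binary_pattern` holding the ground-truth
#'   dark field and its generating `ellipses`), `params` (the raw
#'   draws), and `truth` with the per-spot table (`area_px`, axes,
#'   ratio, `interior`) and the summary values `n_spots`, `fm`, `sa_cm2`,
#'   `ee`, `pl_cm` (summaries are over spots at or above `min_spot_px`,
#'   the spots the extraction pipeline is defined to retain).
#' @export
generate_pattern <- function(spec, min_spot_px = MIN_SPOT_PX,
                             params = NULL) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  mask <- .synth_mask(spec)
  if (is.null(params)) params <- .draw_pattern_params(spec)

  pts_all <- params$pts0 + params$jit
  inmask <- mask[cbind(pmin(pmax(round(pts_all[, 1L]), 1L), h),
                       pmin(pmax(round(pts_all[, 2L]), 1L), w))]
  pts <- pts_all[inmask, , drop = FALSE]
  n <- nrow(pts)
  if (n == 0L) stop("no lattice points inside the mask")
  a <- exp(params$logsize[inmask])
  q <- pmax(exp(params$logratio[inmask]), 1)
  theta <- params$theta[inmask]
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  # crowding cap: no spot outgrows half the gap to its nearest neighbour
  a <- pmin(a, (apply(D, 1L, min) - 7) / 2)
  if (any(a <= 0)) {
    keep <- a > 0
    pts <- pts[keep, , drop = FALSE]; a <- a[keep]; q <- q[keep]
    theta <- theta[keep]
    n <- length(a)
  }
  ellipses <- data.frame(row = pts[, 1L], col = pts[, 2L], a = a,
                         b = a / q, theta = theta)
  dark <- matrix(FALSE, h, w)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    px <- .raster_ellipse(pts[i, ], a[i], a[i] / q[i], theta[i], h, w)
    px <- px[mask[px]]
    dark[px] <- TRUE
    rows[[i]] <- data.frame(
      row = pts[i, 1L], col = pts[i, 2L], area_px = length(px),
      major_px = 2 * a[i], minor_px = 2 * a[i] / q[i], ratio = q[i],
      interior = length(px) > 0L && classify_interior(px, mask))
  }
  spots <- do.call(rbind, rows)
  if (spec$n_speckles > 0L) {
    free <- which(mask & !dilate_box(dark, 2L))
    for (k in seq_len(spec$n_speckles)) {
      ctr <- free[sample.int(length(free), 1L)]
      sz <- sample.int(5L, 1L)
      rc <- idx_to_rc(ctr, h)
      px <- (pmin(pmax(rc[, 2L] + sample(-2:2, sz, TRUE), 1L), w) - 1L) * h +
        pmin(pmax(rc[, 1L] + sample(-2:2, sz, TRUE), 1L), h)
      px <- unique(px[mask[px]])
      dark[px] <- TRUE
    }
  }
  keep <- spots$area_px >= min_spot_px
  int_keep <- keep & spots$interior
  truth <- list(
    spots = spots,
    n_spots = sum(keep), n_interior = sum(int_keep),
    lambda_px = spec$lambda_px,
    fm = sum(spots$area_px[keep]) / sum(mask),
    sa_cm2 = mean(spots$area_px[int_keep]) * spec$cm_per_pixel^2,
    ee = mean(spots$ratio[int_keep]),
    pl_cm = spec$lambda_px * spec$cm_per_pixel)
  pattern <- structure(
    list(dark = dark, mask = mask, cm_per_pixel = spec$cm_per_pixel,
         report = NULL, body_part = "TR", gecko_id = "synthetic",
         replicate = 1L, ellipses = ellipses),
    class = "binary_pattern")
  list(pattern = pattern, truth = truth, params = params)
}

#' Render a binary pattern as a synthetic photograph
#'
#' The green channel is background noise with spot pixels darkened; red is
#' a fixed offset above green; blue is comparatively flat so that
#' melanistic spots barely register in it. Optional artifacts: a linear
#' shadow ramp subtracted from all channels on the left edge, and an
#' additive glare blob. A rigid `shift` (rows, cols) emulates replicate
#' repositioning of the animal: patterns that carry their generating
#' ellipses (from [generate_pattern()]) are re-rasterized at the shifted
#' (sub-pixel) position together with their mask, so replicates differ in
#' boundary-pixel sampling the way re-posed photographs do; other patterns
#' are translated by whole pixels. A small per-replicate lighting drift
#' (`light_drift`) shifts all channels.
#'
#' @param pattern a `binary_pattern` (e.g. from [generate_pattern()]).
#' @param spec the `synthetic_spec` with the rendering parameters.
#' @param body_part,gecko_id,replicate identity metadata for the result.
#' @param shift numeric 2-vector, rigid translation in pixels (fractional
#'   values allowed for generated patterns).
#' @param light_drift additive intensity shift on all channels.
#' @return a `region_image`.
#' @export
render_image <- function(pattern, spec, body_part = "TR",
                         gecko_id = "synthetic", replicate = 1L,
                         shift = c(0, 0), light_drift = 0) {
  if (!is.null(pattern$ellipses) && any(shift != 0)) {
    h0 <- nrow(pattern$mask); w0 <- ncol(pattern$mask)
    mask <- .synth_mask(spec, offset = shift)
    dark <- .render_dark(pattern$ellipses, mask, h0, w0, offset = shift)
  } else {
    dark <- pattern$dark; mask <- pattern$mask
    if (any(shift != 0)) {
      dark <- shift_matrix(dark, round(shift[1L]), round(shift[2L]),
                           fill = FALSE)
      mask <- shift_matrix(mask, round(shift[1L]), round(shift[2L]),
                           fill = FALSE)
    }
  }
  h <- nrow(mask); w <- ncol(mask)
  n <- h * w
  G <- matrix(stats::rnorm(n, spec$bg_green_mean, spec$bg_green_sd), h, w)
  G[dark] <- stats::rnorm(sum(dark), spec$spot_green_mean,
                          spec$spot_green_sd)
  B <- matrix(stats::rnorm(n, spec$bg_blue_mean, spec$blue_sd), h, w)
  B[dark] <- B[dark] - spec$spot_blue_drop
  R <- G + spec$red_offset
  if (spec$shadow_amp > 0) {
    w0 <- spec$shadow_frac * w
    ramp <- pmax(0, (w0 - matrix(seq_len(w), h, w, byrow = TRUE)) / w0)
    G <- G - spec$shadow_amp * ramp
    R <- R - spec$shadow_amp * ramp
    B <- B - spec$shadow_amp * ramp
  }
  if (spec$glare_amp > 0) {
    r0 <- 0.3 * h; c0 <- 0.7 * w
    dr <- matrix(seq_len(h), h, w) - r0
    dc <- matrix(seq_len(w), h, w, byrow = TRUE) - c0
    blob <- spec$glare_amp * exp(-(dr^2 + dc^2) / (2 * spec$glare_sigma^2))
    G <- G + blob; R <- R + blob; B <- B + blob
  }
  if (light_drift != 0) {
    G <- G + light_drift; R <- R + light_drift; B <- B + light_drift
  }
  clip <- function(m) {
    m <- round(m); m[m < 0] <- 0; m[m > 255] <- 255
    m[!mask] <- 255
    m
  }
  px <- array(0, dim = c(h, w, 3L))
  px[, , 1L] <- clip(R); px[, , 2L] <- clip(G); px[, , 3L] <- clip(B)
  region_image(px, mask, body_part, gecko_id, replicate, spec$cm_per_pixel)
}
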