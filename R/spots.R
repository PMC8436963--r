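# From a binary dark/light pattern to a cleaned, classified set of spots.
#
# Pipeline: 8-connected component labelling -> minimum-size filter (350 px)
# -> per-component hole filling -> contour smoothing (morphological closing
# then opening) -> relabel and re-filter -> interior/boundary
# classification -> per-spot geometry. A region "qualifies" as patterned
# when it has enough interior spots (>= 4 for limbs, >= 6 for trunk and
# tail; the head always qualifies).

#' Default minimum spot size in pixels
#' @export
MIN_SPOT_PX <- 350L

# minimum interior spots for a pattern to qualify, per morphological type
.qualify_min <- c(limb = 4L, head = 0L, trunk = 6L, tail = 6L)

#' Drop connected components smaller than a minimum pixel area
#'
#' The minimum is inclusive: a component of exactly `min_spot_px` pixels is
#' retained.
#'
#' @param components list of linear-pixel-index vectors.
#' @param min_spot_px minimum area in pixels (default 350).
#' @return filtered list.
#' @export
filter_min_size <- function(components, min_spot_px = MIN_SPOT_PX) {
  stopifnot(min_spot_px >= 1)
  components[vapply(components, length, 1L) >= min_spot_px]
}

#' Fill enclosed holes of a boolean image
#'
#' Background pixels from which the image border cannot be reached by a
#' 4-connected background walk are converted to foreground. Filling a solid
#' or open (C-shaped) component leaves it unchanged; filling an annulus
#' yields a solid disk. Idempotent.
#'
#' @param m logical matrix.
#' @param mask optional region mask; filled pixels outside it are discarded.
#' @return logical matrix.
#' @export
fill_holes <- function(m, mask = NULL) {
  h <- nrow(m); w <- ncol(m)
  bg <- label_components(!m, connectivity = 4L)
  border_labels <- unique(c(bg[1L, ], bg[h, ], bg[, 1L], bg[, w]))
  border_labels <- border_labels[border_labels > 0L]
  hole <- !m & !(bg %in% border_labels)
  dim(hole) <- dim(m)
  out <- m | hole
  if (!is.null(mask)) out <- out & mask
  out
}

#' Smooth spot contours by morphological closing then opening
#'
#' `iterations` successive dilations then erosions (closing), followed by
#' the same number of erosions then dilations (opening), with a 3x3 square
#' structuring element. The image is padded so that closing is not clipped
#' at the matrix border; the result is restricted to `mask` when given.
#'
#' @param m logical matrix.
#' @param iterations non-negative integer (default 2); 0 is the identity.
#' @param mask optional region mask.
#' @return logical matrix.
#' @export
smooth_contours <- function(m, iterations = 2L, mask = NULL) {
  stopifnot(iterations >= 0)
  if (iterations > 0L) {
    p <- iterations + 1L
    h <- nrow(m); w <- ncol(m)
    mp <- matrix(FALSE, h + 2L * p, w + 2L * p)
    mp[p + seq_len(h), p + seq_len(w)] <- m
    mp <- erode_box(dilate_box(mp, iterations), iterations)   # closing
    mp <- dilate_box(erode_box(mp, iterations), iterations)   # opening
    m <- mp[p + seq_len(h), p + seq_len(w)]
  }
  if (!is.null(mask)) m <- m & mask
  m
}

#' Is a component an interior spot?
#'
#' A spot is interior when none of its pixels is 8-adjacent to a pixel
#' outside the region mask or to the image border; otherwise it is a
#' boundary spot.
#'
#' @param pixel_idx linear pixel indices of the component.
#' @param mask logical region mask.
#' @return `TRUE` for interior, `FALSE` for boundary.
#' @export
classify_interior <- function(pixel_idx, mask) {
  h <- nrow(mask); w <- ncol(mask)
  rc <- idx_to_rc(pixel_idx, h)
  if (any(rc[, 1L] == 1L | rc[, 1L] == h | rc[, 2L] == 1L | rc[, 2L] == w))
    return(FALSE)
  off <- .box_offsets()
  for (k in seq_len(nrow(off))) {
    if (off$dr[k] == 0L && off$dc[k] == 0L) next
    nidx <- (rc[, 2L] + off$dc[k] - 1L) * h + (rc[, 1L] + off$dr[k])
    if (any(!mask[nidx])) return(FALSE)
  }
  TRUE
}

# per-spot geometry/intensity record
.make_spot <- function(pixel_idx, mask, green, cm_per_pixel) {
  h <- nrow(mask)
  rc <- idx_to_rc(pixel_idx, h)
  ell <- equivalent_ellipse(pixel_idx, h)
  sp <- matrix(FALSE, h, ncol(mask))
  sp[pixel_idx] <- TRUE
  list(
    pixel_idx = pixel_idx,
    area_px = length(pixel_idx),
    area_cm2 = length(pixel_idx) * cm_per_pixel^2,
    centroid = c(row = mean(rc[, 1L]) - 1, col = mean(rc[, 2L]) - 1),
    major_axis_px = ell$major,
    minor_axis_px = ell$minor,
    orientation = ell$orientation,
    thickness_d = spot_thickness(sp),
    interior = classify_interior(pixel_idx, mask),
    mean_green = mean(green[pixel_idx]))
}

#' Extract the cleaned spot set from a binary pattern
#'
#' Runs the full cleaning pipeline (label, size-filter, hole-fill, smooth,
#' relabel, re-filter, classify) and computes per-spot geometry. Spot
#' intensities are taken from the original photograph.
#'
#' @param pattern a `binary_pattern`.
#' @param image the `region_image` the pattern came from.
#' @param min_spot_px minimum spot area in pixels (default 350).
#' @param smooth_iterations contour-smoothing iterations (default 2).
#' @param qualify_min per-type qualifying minima (override).
#' @return object of class `spot_set`: list of spots, counts, the
#'   qualifying flag, and the cleaned union mask `spot_mask`.
#' @export
extract_spots <- function(pattern, image, min_spot_px = MIN_SPOT_PX,
                          smooth_iterations = 2L,
                          qualify_min = .qualify_min) {
  stopifnot(all(dim(pattern$mask) == dim(image$mask)))
  green <- channel_matrix(image, "G")
  h <- nrow(pattern$mask); w <- ncol(pattern$mask)

  comps <- component_pixels(label_components(pattern$dark, 8L))
  comps <- filter_min_size(comps, min_spot_px)
  un <- matrix(FALSE, h, w)
  if (length(comps)) un[unlist(comps)] <- TRUE
  # filling the union is equivalent to per-component filling: a hole of
  # the union is enclosed by a single component (filling a ring swallows
  # anything sitting inside it either way)
  un <- fill_holes(un, pattern$mask)
  un <- smooth_contours(un, smooth_iterations, mask = pattern$mask)
  comps <- filter_min_size(component_pixels(label_components(un, 8L)),
                           min_spot_px)
  un <- matrix(FALSE, h, w)
  if (length(comps)) un[unlist(comps)] <- TRUE

  spots <- lapply(comps, .make_spot, mask = pattern$mask, green = green,
                  cm_per_pixel = pattern$cm_per_pixel)
  n_interior <- sum(vapply(spots, `[[`, TRUE, "interior"))
  structure(
    list(spots = spots, n_all = length(spots), n_interior = n_interior,
         spot_mask = un, mask = pattern$mask,
         cm_per_pixel = pattern$cm_per_pixel, body_part = pattern$body_part,
         gecko_id = pattern$gecko_id, replicate = pattern$replicate,
         qualifying = classify_patterned(n_interior, pattern$body_part,
                                         qualify_min)),
    class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set> %s %s rep %d: %d spots (%d interior), %squalifying\n",
              x$gecko_id, x$body_part, x$replicate, x$n_all, x$n_interior,
              if (x$qualifying) "" else "non-"))
  invisible(x)
}

#' Does a spot count qualify the region as patterned?
#'
#' Limbs need at least 4 interior spots, trunk and tail at least 6; the
#' head always qualifies.
#'
#' @param n_interior number of interior spots (or a `spot_set`).
#' @param body_part one of `BODY_PARTS`.
#' @param qualify_min named vector of per-type minima (override).
#' @return logical.
#' @export
classify_patterned <- function(n_interior, body_part,
                               qualify_min = .qualify_min) {
  if (inherits(n_interior, "spot_set")) {
    body_part <- n_interior$body_part
    n_interior <- n_interior$n_interior
  }
  n_interior >= qualify_min[[body_part_type(body_part)]]
}

#' Render a spot set as a debug image
#'
#' 0 = background, 128 = boundary spot, 255 = interior spot.
#'
#' @param spotset a `spot_set`.
#' @param path optional PNG output path.
#' @return the numeric matrix, invisibly if written.
#' @export
spot_debug_image <- function(spotset, path = NULL) {
  img <- matrix(0, nrow(spotset$mask), ncol(spotset$mask))
  for (s in spotset$spots) img[s$pixel_idx] <- if (s$interior) 255 else 128
  if (!is.null(path)) {
    png::writePNG(img / 255, path)
    return(invisible(img))
  }
  img
}
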