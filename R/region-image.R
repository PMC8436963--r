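# RegionImage: an RGB photograph restricted to one body-region mask, with
# the identity metadata and physical scale needed downstream.

#' Body part codes
#'
#' The seven analysed regions: front-left/right and back-left/right legs,
#' head, trunk, tail.
#' @export
BODY_PARTS <- c("FL", "FR", "BL", "BR", "HD", "TR", "TA")

#' Morphological type of a body part
#'
#' The thresholding and artifact rules are tuned per morphological type,
#' not per individual part: the four legs share one rule set.
#'
#' @param body_part one of `BODY_PARTS`.
#' @return `"limb"`, `"head"`, `"trunk"` or `"tail"`.
#' @export
body_part_type <- function(body_part) {
  body_part <- match.arg(body_part, BODY_PARTS)
  switch(body_part,
    FL = , FR = , BL = , BR = "limb",
    HD = "head",
    TR = "trunk",
    TA = "tail")
}

#' Construct a RegionImage
#'
#' @param pixels H x W x 3 numeric array, each channel in 0..255.
#' @param mask H x W logical matrix, `TRUE` inside the analysed region.
#' @param body_part one of `BODY_PARTS`.
#' @param gecko_id individual identifier.
#' @param replicate replicate (photo set) number, >= 1.
#' @param cm_per_pixel physical scale in cm per pixel, > 0.
#' @return object of class `region_image`.
#' @export
region_image <- function(pixels, mask, body_part, gecko_id = "g?",
                         replicate = 1L, cm_per_pixel = 0.01) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3L] == 3L)
  stopifnot(is.matrix(mask), all(dim(mask) == dim(pixels)[1:2]))
  mask <- mask & !is.na(mask)
  if (!any(mask)) stop("mask has no interior pixels")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]")
  if (!is.numeric(cm_per_pixel) || cm_per_pixel <= 0)
    stop("cm_per_pixel must be positive")
  body_part <- match.arg(body_part, BODY_PARTS)
  structure(
    list(pixels = pixels, mask = mask, body_part = body_part,
         gecko_id = as.character(gecko_id), replicate = as.integer(replicate),
         cm_per_pixel = cm_per_pixel),
    class = "region_image")
}

#' @export
print.region_image <- function(x, ...) {
  cat(sprintf("<region_image> %s %s rep %d  %dx%d px (%d in mask), %.4g cm/px\n",
              x$gecko_id, x$body_part, x$replicate,
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$cm_per_pixel))
  invisible(x)
}

#' Extract one colour channel as a matrix
#' @param image a `region_image`.
#' @param channel `"R"`, `"G"` or `"B"`.
#' @return numeric H x W matrix.
#' @export
channel_matrix <- function(image, channel = c("G", "R", "B")) {
  channel <- match.arg(channel)
  k <- match(channel, c("R", "G", "B"))
  image$pixels[, , k]
}

#' Read a region photograph and its mask from disk
#'
#' PNG and TIFF images (8-bit RGB or greyscale) are supported; masks are
#' single-channel images where any non-zero pixel is inside the region.
#'
#' @param image_path path to the PNG/TIFF photograph.
#' @param mask_path path to the PNG/TIFF mask.
#' @inheritParams region_image
#' @return a `region_image`.
#' @export
read_region_image <- function(image_path, mask_path, body_part,
                              gecko_id = "g?", replicate = 1L,
                              cm_per_pixel = 0.01) {
  px <- read_image_255(image_path)
  mk <- read_image_255(mask_path)
  if (length(dim(mk)) == 3L) mk <- mk[, , 1L]
  region_image(px, mk > 0, body_part, gecko_id, replicate, cm_per_pixel)
}

# Read PNG/TIFF into a 0..255 array; greyscale images are replicated to RGB.
#' @keywords internal
read_image_255 <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  a <- a * 255
  if (length(dim(a)) == 2L) {
    a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  } else if (dim(a)[3L] == 4L) {
    a <- a[, , 1:3]                      # drop alpha
  } else if (dim(a)[3L] == 2L) {
    a <- array(rep(a[, , 1L], 3L), dim = c(dim(a)[1:2], 3L))
  }
  round(a)
}

#' Read a metadata table describing a set of region photographs
#'
#' Expected columns: `image_path`, `mask_path`, `gecko_id`, `body_part`,
#' `replicate`, `cm_per_pixel`. Relative paths are resolved against the
#' directory containing the CSV.
#'
#' @param path CSV file.
#' @return data.frame with the columns above.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "mask_path", "gecko_id", "body_part",
            "replicate", "cm_per_pixel")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata is missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(md$body_part), BODY_PARTS)
  if (length(bad)) stop("unknown body_part values: ", paste(bad, collapse = ", "))
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", md$image_path)
  md$image_path[rel] <- file.path(base, md$image_path[rel])
  rel <- !grepl("^(/|[A-Za-z]:)", md$mask_path)
  md$mask_path[rel] <- file.path(base, md$mask_path[rel])
  md
}
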