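# Low-level boolean-image primitives shared by the imaging and spot modules.
#
# Images are plain R matrices indexed [row, col]; logical matrices serve as
# masks. Everything outside the matrix is background: erosion eats border
# pixels and dilation is clipped at the border.

#' Shift a matrix by whole pixels, filling with a constant
#'
#' @param m matrix.
#' @param dr,dc integer shifts (positive = down / right).
#' @param fill value for vacated cells.
#' @return matrix of the same shape.
#' @keywords internal
shift_matrix <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- seq_len(h) - dr
  cs <- seq_len(w) - dc
  ok_r <- rs >= 1L & rs <= h
  ok_c <- cs >= 1L & cs <= w
  out[which(ok_r), which(ok_c)] <- m[rs[ok_r], cs[ok_c], drop = FALSE]
  out
}

.box_offsets <- function() {
  expand.grid(dr = -1:1, dc = -1:1)
}

#' Binary dilation with a 3x3 square structuring element
#'
#' Out-of-image pixels are background, so dilation is clipped at the border.
#'
#' @param m logical matrix.
#' @param iterations number of successive dilations (0 = identity).
#' @return logical matrix.
#' @export
dilate_box <- function(m, iterations = 1L) {
  stopifnot(iterations >= 0)
  off <- .box_offsets()
  for (i in seq_len(iterations)) {
    acc <- m
    for (k in seq_len(nrow(off))) {
      if (off$dr[k] == 0L && off$dc[k] == 0L) next
      acc <- acc | shift_matrix(m, off$dr[k], off$dc[k], fill = FALSE)
    }
    m <- acc
  }
  m
}

#' Binary erosion with a 3x3 square structuring element
#'
#' Out-of-image pixels are background, so border pixels are always eroded.
#'
#' @inheritParams dilate_box
#' @return logical matrix.
#' @export
erode_box <- function(m, iterations = 1L) {
  stopifnot(iterations >= 0)
  off <- .box_offsets()
  for (i in seq_len(iterations)) {
    acc <- m
    for (k in seq_len(nrow(off))) {
      if (off$dr[k] == 0L && off$dc[k] == 0L) next
      acc <- acc & shift_matrix(m, off$dr[k], off$dc[k], fill = FALSE)
    }
    m <- acc
  }
  m
}

#' Label connected components of a boolean image
#'
#' Components are labelled 1, 2, ... in deterministic scanline order of their
#' top-most (then left-most) pixel. Spots use 8-connectivity; the complementary
#' background flood in hole filling uses 4-connectivity.
#'
#' @param m logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix; 0 = background, k = pixels of component k.
#' @export
label_components <- function(m, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  h <- nrow(m); w <- ncol(m)
  idx <- which(m)                       # column-major linear indices
  if (length(idx) == 0L) {
    return(matrix(0L, h, w))
  }
  pos <- integer(h * w)                 # linear index -> vertex id
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    nr <- r + o[1L]; nc <- cc + o[2L]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nidx <- (nc[ok] - 1L) * h + nr[ok]
    hit <- m[nidx]
    from <- c(from, pos[idx[ok][hit]])
    to <- c(to, pos[nidx[hit]])
  }
  g <- igraph::make_graph(edges = rbind(from, to), n = length(idx),
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  # scanline key: row-major order of each component's first pixel
  key <- (r - 1L) * w + (cc - 1L)
  first <- tapply(key, memb, min)
  relabel <- integer(length(first))
  relabel[order(first)] <- seq_along(first)
  lab <- matrix(0L, h, w)
  lab[idx] <- relabel[memb]
  lab
}

#' Split a label matrix into per-component linear pixel index vectors
#' @keywords internal
component_pixels <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(list())
  unname(split(idx, lab[idx]))
}

#' Pixel indices to (row, col) coordinates (1-based)
#' @keywords internal
idx_to_rc <- function(idx, h) {
  cbind(row = ((idx - 1L) %% h) + 1L, col = ((idx - 1L) %/% h) + 1L)
}

#' Binary erosion with a 3x3 cross (4-connected) structuring element
#'
#' Removes pixels with any 4-neighbour (or out-of-image side) in the
#' background. Successive cross erosions peel one unit of inradius per
#' step, so the extinction time of a convex spot is its half-width: this
#' is the erosion used for the spot-thickness measure.
#'
#' @inheritParams dilate_box
#' @return logical matrix.
#' @export
erode_cross <- function(m, iterations = 1L) {
  stopifnot(iterations >= 0)
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (i in seq_len(iterations)) {
    acc <- m
    for (o in offs) acc <- acc & shift_matrix(m, o[1L], o[2L], fill = FALSE)
    m <- acc
  }
  m
}
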