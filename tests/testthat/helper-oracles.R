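# Independent brute-force oracles and small fixture builders. These are
# deliberately naive (queue-based flood fills, explicit loops) so they
# share no code path with the package implementation they check.

# BFS flood-fill connected-component labelling
flood_label <- function(m, connectivity = 8L) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  offs <- if (connectivity == 8L) {
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  } else {
    list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  }
  for (cc in seq_len(w)) for (r in seq_len(h)) {
    if (!m[r, cc] || lab[r, cc] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, cc))
    lab[r, cc] <- nxt
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (o in offs) {
        rr <- p[1L] + o[1L]; ww <- p[2L] + o[2L]
        if (rr >= 1L && rr <= h && ww >= 1L && ww <= w &&
            m[rr, ww] && lab[rr, ww] == 0L) {
          lab[rr, ww] <- nxt
          queue[[length(queue) + 1L]] <- c(rr, ww)
        }
      }
    }
  }
  lab
}

# pixelwise erosion with a 3x3 box, outside = background
brute_erode <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    if (!m[r, cc]) next
    keep <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; ww <- cc + dc
      if (rr < 1L || rr > h || ww < 1L || ww > w || !m[rr, ww]) keep <- FALSE
    }
    out[r, cc] <- keep
  }
  out
}

# pixelwise erosion with a 3x3 cross, outside = background
brute_erode_cross <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    if (!m[r, cc]) next
    keep <- TRUE
    for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + o[1]; ww <- cc + o[2]
      if (rr < 1L || rr > h || ww < 1L || ww > w || !m[rr, ww]) keep <- FALSE
    }
    out[r, cc] <- keep
  }
  out
}

brute_thickness <- function(m) {
  d <- 0L
  while (any(m)) {
    m <- brute_erode_cross(m)
    d <- d + 1L
  }
  d
}

# second-central-moment ellipse axes via explicit sums
brute_ellipse <- function(rows, cols) {
  n <- length(rows)
  mr <- sum(rows) / n; mc <- sum(cols) / n
  srr <- 0; scc <- 0; src <- 0
  for (i in seq_len(n)) {
    srr <- srr + (rows[i] - mr)^2
    scc <- scc + (cols[i] - mc)^2
    src <- src + (rows[i] - mr) * (cols[i] - mc)
  }
  srr <- srr / n + 1 / 12; scc <- scc / n + 1 / 12; src <- src / n
  tr <- srr + scc; disc <- sqrt((srr - scc)^2 + 4 * src^2)
  c(major = 4 * sqrt((tr + disc) / 2), minor = 4 * sqrt(max((tr - disc) / 2, 0)))
}

# mean distance to the k closest other centroids, explicit loops
brute_md <- function(centroids, k = 3L) {
  n <- nrow(centroids)
  per <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((centroids[-i, 1L] - centroids[i, 1L])^2 +
              (centroids[-i, 2L] - centroids[i, 2L])^2)
    per[i] <- mean(sort(d)[seq_len(min(k, n - 1L))])
  }
  c(MD = mean(per), MDD = stats::sd(per))
}

# a flat-colour region image: every channel the same matrix unless given
make_region_image <- function(G, mask = NULL, body_part = "HD",
                              R = NULL, B = NULL, cm_per_pixel = 0.01,
                              gecko_id = "t", replicate = 1L) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(G), ncol(G))
  px <- array(0, dim = c(nrow(G), ncol(G), 3L))
  px[, , 1L] <- if (is.null(R)) G else R
  px[, , 2L] <- G
  px[, , 3L] <- if (is.null(B)) G else B
  region_image(px, mask, body_part, gecko_id, replicate, cm_per_pixel)
}

make_disk <- function(h, w, r0, c0, rad) {
  r <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (r - r0)^2 + (cc - c0)^2 <= rad^2
}

make_ellipse_mask <- function(h, w, r0, c0, a, b, theta = 0) {
  r <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  dR <- r - r0; dC <- cc - c0
  u <- dC * cos(theta) + dR * sin(theta)
  v <- -dC * sin(theta) + dR * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# minimal index table row for metric/stats tests
index_row <- function(gecko, part, values, qualifying = TRUE) {
  v <- as.list(stats::setNames(values, INDEX_NAMES))
  data.frame(gecko_id = gecko, body_part = part, qualifying = qualifying,
             v, stringsAsFactors = FALSE)
}

# one-part index table straight from a numeric matrix (one gecko per row)
matrix_index_df <- function(X, part = "FL") {
  df <- data.frame(gecko_id = sprintf("g%05d", seq_len(nrow(X))),
                   body_part = part, qualifying = TRUE,
                   stringsAsFactors = FALSE)
  df[, INDEX_NAMES] <- X
  df
}

# dataset of i.i.d. normal index vectors for n geckos x given parts
random_index_dataset <- function(n_geckos, parts = c("FL", "FR"),
                                 mean = 0, sd = 1) {
  rows <- list()
  for (g in seq_len(n_geckos)) {
    for (p in parts) {
      rows[[length(rows) + 1L]] <-
        index_row(sprintf("g%02d", g), p, rnorm(14, mean, sd))
    }
  }
  index_dataset(do.call(rbind, rows))
}

# identity-weight developmental-noise metric (unit weights, no scaling)
identity_metric <- function() {
  structure(list(kind = "devnoise", S_inv = NULL,
                 weights = stats::setNames(rep(1, 14), INDEX_NAMES),
                 scale_c = 1, n_fit = 0L),
            class = "distance_spec")
}
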