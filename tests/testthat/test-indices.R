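# Per-spot geometry and the 14 pattern indices.

test_that("equivalent ellipse recovers disk and ellipse axes within 2%", {
  disk <- make_disk(61, 61, 31, 31, 20)
  e <- equivalent_ellipse(which(disk), 61)
  expect_equal(e$major, 40, tolerance = 0.02)
  expect_equal(e$minor, 40, tolerance = 0.02)

  ell <- make_ellipse_mask(81, 81, 41, 41, a = 30, b = 10)
  e2 <- equivalent_ellipse(which(ell), 81)
  expect_equal(e2$major, 60, tolerance = 0.02)
  expect_equal(e2$minor, 20, tolerance = 0.02)

  # rotating by 90 degrees swaps nothing
  ell90 <- make_ellipse_mask(81, 81, 41, 41, a = 30, b = 10, theta = pi / 2)
  e3 <- equivalent_ellipse(which(ell90), 81)
  expect_equal(e3$major, e2$major, tolerance = 0.01)
  expect_equal(e3$minor, e2$minor, tolerance = 0.01)
})

test_that("equivalent ellipse matches the explicit-sum oracle", {
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(runif(400) < 0.3, 20, 20)
    if (!any(m)) next
    idx <- which(m)
    rc <- cbind((idx - 1) %% 20 + 1, (idx - 1) %/% 20 + 1)
    e <- equivalent_ellipse(idx, 20)
    o <- brute_ellipse(rc[, 1], rc[, 2])
    expect_equal(e$major, unname(o["major"]), tolerance = 1e-12)
    expect_equal(max(e$minor, 1), max(unname(o["minor"]), 1),
                 tolerance = 1e-12)
  }
})

test_that("spot thickness counts erosion steps to extinction", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(spot_thickness(one), 1L)

  sq <- matrix(FALSE, 30, 30); sq[6:25, 6:25] <- TRUE   # 20x20 solid
  expect_equal(spot_thickness(sq), 10L)
  expect_equal(spot_thickness(sq), brute_thickness(sq))

  disk <- make_disk(31, 31, 16, 16, 10)
  d <- spot_thickness(disk)
  expect_equal(d, brute_thickness(disk))
  expect_true(abs(d - 10) <= 1)
  # the boundary-inclusive raster makes the half-width r or r+1, so EL
  # sits near its disk value pi/2 up to that digitization
  el <- sum(disk) / (2 * d^2)
  expect_equal(el, pi / 2, tolerance = 0.2)

  set.seed(32)
  for (i in 1:10) {
    m <- make_ellipse_mask(40, 40, 20, 20, a = runif(1, 3, 12),
                           b = runif(1, 2, 8), theta = runif(1, 0, pi))
    expect_equal(spot_thickness(m), brute_thickness(m))
  }
})

test_that("peak length finds stripe periods and scales linearly", {
  h <- 96L; w <- 128L
  stripes <- matrix(rep(rep(c(TRUE, FALSE), each = 16L), length.out = w),
                    h, w, byrow = TRUE)          # vertical, period 32 px
  mask <- matrix(TRUE, h, w)
  pl <- peak_length(stripes, mask, cm_per_pixel = 0.01)
  expect_equal(pl, 32 * 0.01, tolerance = 0.1)   # one annulus width
  expect_equal(peak_length(stripes, mask, cm_per_pixel = 0.02), 2 * pl)

  expect_true(is.na(peak_length(matrix(FALSE, 8, 8), matrix(TRUE, 8, 8), 1)))
  expect_true(is.na(peak_length(matrix(TRUE, 8, 8), matrix(TRUE, 8, 8), 1)))
})

test_that("peak length resolves the hexagonal plane spacing in large windows", {
  # with many lattice rows the radial spectral ring sits at the
  # lattice-plane spacing sqrt(3)/2 * lambda
  set.seed(33)
  ratios <- vapply(1:20, function(s) {
    tpl <- synthetic_spec(height = 180L, width = 180L,
                          mask_shape = "rectangle", lambda_px = 20,
                          jitter = 0.1, a_meanlog = log(6), a_sdlog = 0.05,
                          seed = s)
    gen <- generate_pattern(tpl, min_spot_px = 1L)
    peak_length(gen$pattern) / (sqrt(3) / 2 * 20 * 0.01)
  }, 1)
  expect_equal(mean(ratios), 1, tolerance = 0.1)
})

test_that("nearest-neighbour stats match brute force", {
  # 4 spots at the corners of a square of side s
  s <- 40
  ctr <- rbind(c(0, 0), c(0, s), c(s, 0), c(s, s))
  nn <- nearest_neighbor_stats(ctr, k = 3, cm_per_pixel = 1)
  expect_equal(nn$MD, (2 * s + s * sqrt(2)) / 3)
  expect_equal(nn$MDD, 0)

  two <- rbind(c(0, 0), c(0, 13))              # forced k_eff = 1
  nn2 <- nearest_neighbor_stats(two, cm_per_pixel = 1)
  expect_equal(nn2$MD, 13)
  expect_equal(nn2$MDD, 0)

  expect_true(is.na(nearest_neighbor_stats(rbind(c(1, 1)))$MD))

  set.seed(34)
  for (i in 1:10) {
    ctr <- matrix(runif(20, 0, 100), ncol = 2)
    nn <- nearest_neighbor_stats(ctr, k = 3, cm_per_pixel = 0.5)
    o <- brute_md(ctr, 3)
    expect_equal(nn$MD, unname(o["MD"]) * 0.5, tolerance = 1e-12)
    expect_equal(nn$MDD, unname(o["MDD"]) * 0.5, tolerance = 1e-12)
  }
})

# build a spot_set + indices from a hand-made dark field
measure_field <- function(dark, g = NULL, mask = NULL, body_part = "TR",
                          cm_per_pixel = 0.01) {
  if (is.null(g)) { g <- matrix(200, nrow(dark), ncol(dark)); g[dark] <- 42 }
  img <- make_region_image(g, mask = mask, body_part = body_part,
                           cm_per_pixel = cm_per_pixel)
  pat <- binarize(img, artifact_action = "none")
  ss <- extract_spots(pat, img)
  list(ind = compute_indices(ss, pat, img), ss = ss, pat = pat, img = img)
}

test_that("FM is the all-spot area fraction and SI the pooled spot green", {
  dark <- matrix(FALSE, 100, 100)
  dark[41:60, 41:60] <- TRUE                   # single 400-px spot
  r <- measure_field(dark)
  expect_equal(unname(r$ind$values["FM"]), 400 / 10000)
  expect_equal(unname(r$ind$values["SI"]), 42)
  expect_equal(unname(r$ind$values["SID"]), 0)
  expect_equal(unname(r$ind$values["SA"]), 400 * 0.01^2)
  expect_equal(r$ind$n_all, 1L)
})

test_that("identical disks give EE near 1 and SA near the disk area", {
  dark <- matrix(FALSE, 120, 160)
  for (ctr in list(c(30, 30), c(30, 90), c(90, 30), c(90, 90), c(60, 140))) {
    dark <- dark | make_disk(120, 160, ctr[1], ctr[2], 12)
  }
  r <- measure_field(dark)
  expect_equal(r$ind$n_interior, 5L)
  expect_equal(unname(r$ind$values["EE"]), 1, tolerance = 0.03)
  expect_equal(unname(r$ind$values["EED"]), 0, tolerance = 0.03)
  # against the rasterized disk area (3%: contour smoothing only) and the
  # continuous disk area (5%: + digitization)
  expect_equal(unname(r$ind$values["SA"]),
               sum(make_disk(120, 160, 30, 30, 12)) * 1e-4,
               tolerance = 0.03)
  expect_equal(unname(r$ind$values["SA"]), pi * 12^2 * 1e-4,
               tolerance = 0.05)
})

test_that("FM, SA, MD, EE and EL match brute-force recomputation", {
  set.seed(36)
  for (i in 1:12) {
    tpl <- synthetic_spec(height = 120L, width = 140L,
                          mask_shape = "rectangle",
                          lambda_px = 36, a_meanlog = log(13),
                          seed = 400 + i)
    gen <- generate_pattern(tpl, min_spot_px = 50L)
    r <- measure_field(gen$pattern$dark, cm_per_pixel = 0.01)
    ss <- r$ss
    if (ss$n_all < 2 || ss$n_interior < 1) next
    areas <- vapply(ss$spots, `[[`, 1L, "area_px")
    inter <- vapply(ss$spots, `[[`, TRUE, "interior")
    expect_equal(unname(r$ind$values["FM"]), sum(areas) / sum(ss$mask),
                 tolerance = 1e-9)
    expect_equal(unname(r$ind$values["SA"]),
                 mean(areas[inter]) * 1e-4, tolerance = 1e-9)
    ctr <- do.call(rbind, lapply(ss$spots, `[[`, "centroid"))
    o <- brute_md(ctr, 3)
    expect_equal(unname(r$ind$values["MD"]), unname(o["MD"]) * 0.01,
                 tolerance = 1e-9)
    ee_o <- mean(vapply(ss$spots[inter], function(s) {
      rc <- cbind((s$pixel_idx - 1) %% 120 + 1, (s$pixel_idx - 1) %/% 120 + 1)
      b <- brute_ellipse(rc[, 1], rc[, 2])
      unname(b["major"] / max(b["minor"], 1))
    }, 1))
    expect_equal(unname(r$ind$values["EE"]), ee_o, tolerance = 1e-9)
    el_o <- vapply(ss$spots[inter], function(s) {
      m <- matrix(FALSE, 120, 140); m[s$pixel_idx] <- TRUE
      s$area_px / (2 * brute_thickness(m)^2)
    }, 1)
    expect_equal(unname(r$ind$values["EL"]), mean(el_o), tolerance = 1e-12)
    d_impl <- vapply(ss$spots[inter], `[[`, 1L, "thickness_d")
    d_oracle <- vapply(ss$spots[inter], function(s) {
      m <- matrix(FALSE, 120, 140); m[s$pixel_idx] <- TRUE
      brute_thickness(m)
    }, 1L)
    expect_identical(d_impl, d_oracle)             # exact integer match
  }
})

test_that("indices obey scale covariance in cm_per_pixel", {
  dark <- matrix(FALSE, 120, 160)
  geom <- list(c(30, 30, 14, 10, 0.4), c(30, 90, 12, 11, 1.2),
               c(90, 40, 15, 9, 2.1), c(80, 130, 13, 10, 0.0))
  for (gm in geom)
    dark <- dark | make_ellipse_mask(120, 160, gm[1], gm[2], gm[3], gm[4],
                                     gm[5])
  r1 <- measure_field(dark, cm_per_pixel = 0.01)$ind$values
  r2 <- measure_field(dark, cm_per_pixel = 0.02)$ind$values
  for (nm in c("SS", "SSD", "PL", "MD", "MDD"))
    expect_equal(unname(r2[nm] / r1[nm]), 2, tolerance = 1e-9)
  for (nm in c("SA", "SAD"))
    expect_equal(unname(r2[nm] / r1[nm]), 4, tolerance = 1e-9)
  for (nm in c("FM", "EE", "EED", "SI", "SID", "EL", "ELD"))
    expect_equal(unname(r2[nm]), unname(r1[nm]), tolerance = 1e-9)
})

test_that("indices are invariant under translation and 90-degree rotation", {
  dark <- matrix(FALSE, 100, 120)
  for (ctr in list(c(30, 30), c(30, 85), c(70, 40), c(68, 95)))
    dark <- dark | make_ellipse_mask(100, 120, ctr[1], ctr[2], 13, 9, 1.1)
  v0 <- measure_field(dark)$ind$values
  vt <- measure_field(shift_matrix(dark, 5, 7))$ind$values
  vr <- measure_field(t(dark[nrow(dark):1, ]))$ind$values   # rotate 90
  for (nm in setdiff(INDEX_NAMES, "PL")) {
    expect_equal(unname(vt[nm]), unname(v0[nm]), tolerance = 1e-9)
    expect_equal(unname(vr[nm]), unname(v0[nm]), tolerance = 1e-9)
  }
  # PL: equal up to FFT annulus discretization
  expect_equal(unname(vr["PL"]), unname(v0["PL"]), tolerance = 0.35)
})

test_that("replicate averaging is the per-index mean with strict qualifying", {
  mk <- function(fm, qual = TRUE) {
    structure(list(values = setNames(c(fm, rep(1, 13)), INDEX_NAMES),
                   n_all = 5L, n_interior = 4L, qualifying = qual,
                   gecko_id = "g1", body_part = "FL", replicate = 1L,
                   averaged = FALSE), class = "pattern_indices")
  }
  avg <- average_replicates(list(mk(0.1), mk(0.2), mk(0.3), mk(0.4)))
  expect_equal(unname(avg$values["FM"]), 0.25)
  expect_true(avg$averaged)
  expect_true(avg$qualifying)

  one <- average_replicates(list(mk(0.3)))
  expect_equal(unname(one$values["FM"]), 0.3)

  r3 <- mk(0.5); r3$values["PL"] <- NA_real_
  expect_warning(avg2 <- average_replicates(list(mk(0.1), r3)), "PL")
  expect_equal(unname(avg2$values["PL"]), 1)     # mean over non-missing
  expect_equal(unname(avg2$values["FM"]), 0.3)

  avg3 <- average_replicates(list(mk(0.1), mk(0.2, qual = FALSE)))
  expect_false(avg3$qualifying)
  expect_error(average_replicates(list()), "no replicates")
  m2 <- mk(0.1); m2$gecko_id <- "g2"
  expect_error(average_replicates(list(mk(0.1), m2)), "one gecko")
})
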