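# Whole synthetic cohorts: a "genetic" latent vector per gecko, per-part
# deterministic offsets (head/tail/trunk spots larger than leg spots, as
# in real animals), independent per-part developmental noise, and
# replicate-level repositioning + photographic noise. Each body part's
# physical pattern is generated once and photographed `n_replicates`
# times, so replicate variation is pure measurement error.

# per-morphological-type generator templates
.part_template <- function(body_part, cm_per_pixel) {
  switch(body_part_type(body_part),
    limb = synthetic_spec(height = 170L, width = 120L,
                          mask_shape = "capsule", lambda_px = 38,
                          a_meanlog = log(13.5),
                          cm_per_pixel = cm_per_pixel),
    head = synthetic_spec(height = 150L, width = 120L,
                          mask_shape = "ellipse", lambda_px = 46,
                          a_meanlog = log(16.5),
                          cm_per_pixel = cm_per_pixel),
    trunk = synthetic_spec(height = 190L, width = 150L,
                           mask_shape = "rectangle", lambda_px = 50,
                           a_meanlog = log(16.5),
                           cm_per_pixel = cm_per_pixel),
    tail = synthetic_spec(height = 230L, width = 96L,
                          mask_shape = "capsule", lambda_px = 44,
                          a_meanlog = log(15),
                          cm_per_pixel = cm_per_pixel))
}

#' Specification of a synthetic cohort
#'
#' The latent "genetic" vector per gecko has three dimensions: log spot
#' size factor, log lattice-spacing factor, and a spot-intensity shift.
#' Each body part adds an independent developmental-noise draw on the same
#' dimensions, scaled by `dev_scale`; each replicate photograph adds a
#' rigid translation and fresh pixel noise.
#'
#' @param n_geckos number of individuals (default 25).
#' @param n_replicates photographs per body part (default 4).
#' @param parts body parts to generate (default all seven).
#' @param sd_g genetic latent standard deviations
#'   `c(size, spacing, intensity)`.
#' @param cor_g correlation between the size and spacing latents.
#' @param sd_dev developmental-noise standard deviations on the same
#'   scale.
#' @param dev_scale injected developmental-noise scale (0 = the two
#'   sides of a leg pair carry identical patterns). The side-to-side
#'   parameter perturbation is `0.3 * dev_scale` times the between-animal
#'   draw spread, so the default 1 leaves within-pair differences clearly
#'   smaller than between-animal ones; `sd_dev` is scaled by the same
#'   factor.
#' @param replicate_jitter_px maximum rigid translation per replicate.
#' @param cm_per_pixel physical scale.
#' @param seed RNG seed; the whole cohort is bit-reproducible.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_geckos = 25L, n_replicates = 4L,
                        parts = BODY_PARTS,
                        sd_g = c(size = 0.10, spacing = 0.06,
                                 intensity = 6),
                        cor_g = 0.3,
                        sd_dev = c(size = 0.05, spacing = 0.03,
                                   intensity = 2),
                        dev_scale = 1,
                        replicate_jitter_px = 2L,
                        cm_per_pixel = 0.01, seed = 1L) {
  stopifnot(n_geckos >= 1L, n_replicates >= 1L,
            all(parts %in% BODY_PARTS),
            all(sd_g >= 0), all(sd_dev >= 0), dev_scale >= 0,
            abs(cor_g) < 1)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a full synthetic cohort with ground truth
#'
#' Left and right members of a leg pair (FL/FR, BL/BR) share one base
#' pattern realization; each side is an independently perturbed copy of
#' it, with the perturbation scaled by `dev_scale` (see
#' [perturb_pattern_params()]). At `dev_scale = 0` the two sides carry
#' identical patterns and within-pair variation reduces to photographic
#' measurement error; head, trunk and tail are independent realizations.
#'
#' @param spec a `cohort_spec`.
#' @return list: `images` (list of `region_image`, one per gecko x part x
#'   replicate), `metadata` (data.frame `gecko_id`, `body_part`,
#'   `replicate`, `image` list index, `cm_per_pixel`), `truth` (one row
#'   per gecko x part: spot counts, `fm`, `sa_cm2`, `ee`, `pl_cm`), and
#'   `latents` (the genetic draws).
#' @export
generate_cohort <- function(spec) {
  set.seed(spec$seed)
  # genetic covariance: size-spacing correlation, intensity independent
  Sg <- diag(spec$sd_g^2)
  Sg[1L, 2L] <- Sg[2L, 1L] <- spec$cor_g * spec$sd_g[1L] * spec$sd_g[2L]
  L <- chol(Sg)
  ids <- sprintf("g%02d", seq_len(spec$n_geckos))
  images <- list(); meta <- list(); truth <- list()
  latents <- matrix(NA_real_, spec$n_geckos, 3L,
                    dimnames = list(ids, c("size", "spacing", "intensity")))
  kimg <- 0L
  pairs <- list(c("FL", "FR"), c("BL", "BR"))

  emit <- function(gen, ps, gecko, part) {
    truth[[length(truth) + 1L]] <<- data.frame(
      gecko_id = gecko, body_part = part,
      n_spots = gen$truth$n_spots, n_interior = gen$truth$n_interior,
      fm = gen$truth$fm, sa_cm2 = gen$truth$sa_cm2, ee = gen$truth$ee,
      pl_cm = gen$truth$pl_cm, stringsAsFactors = FALSE)
    for (rep in seq_len(spec$n_replicates)) {
      j <- spec$replicate_jitter_px
      shift <- if (j > 0) stats::runif(2L, -j, j) else c(0, 0)
      kimg <<- kimg + 1L
      images[[kimg]] <<- render_image(gen$pattern, ps, body_part = part,
                                      gecko_id = gecko, replicate = rep,
                                      shift = shift,
                                      light_drift = stats::rnorm(1L, 0, 2))
      meta[[kimg]] <<- data.frame(
        gecko_id = gecko, body_part = part, replicate = rep,
        image = kimg, cm_per_pixel = spec$cm_per_pixel,
        stringsAsFactors = FALSE)
    }
  }

  for (gi in seq_len(spec$n_geckos)) {
    z <- drop(stats::rnorm(3L) %*% L)
    latents[gi, ] <- z

    for (pair in pairs) {
      sides <- intersect(pair, spec$parts)
      if (length(sides) == 0L) next
      ps <- .part_template(pair[1L], spec$cm_per_pixel)
      ps$a_meanlog <- ps$a_meanlog + z[1L]
      ps$lambda_px <- ps$lambda_px * exp(z[2L])
      ps$spot_green_mean <- ps$spot_green_mean + z[3L]
      base <- .draw_pattern_params(ps)
      for (part in sides) {
        dev <- stats::rnorm(3L, 0, spec$dev_scale * spec$sd_dev)
        prm <- perturb_pattern_params(base, ps,
                                      amount = 0.3 * spec$dev_scale)
        prm$logsize <- prm$logsize + dev[1L]     # whole-pattern size shift
        ps_side <- ps
        ps_side$spot_green_mean <- ps_side$spot_green_mean + dev[3L]
        gen <- generate_pattern(ps_side, params = prm)
        emit(gen, ps_side, ids[gi], part)
      }
    }

    for (part in intersect(c("HD", "TR", "TA"), spec$parts)) {
      dev <- stats::rnorm(3L, 0, spec$dev_scale * spec$sd_dev)
      ps <- .part_template(part, spec$cm_per_pixel)
      ps$a_meanlog <- ps$a_meanlog + z[1L] + dev[1L]
      ps$lambda_px <- ps$lambda_px * exp(z[2L] + dev[2L])
      ps$spot_green_mean <- ps$spot_green_mean + z[3L] + dev[3L]
      gen <- generate_pattern(ps)
      emit(gen, ps, ids[gi], part)
    }
  }
  md <- do.call(rbind, meta)
  ord <- order(match(md$gecko_id, ids), match(md$body_part, BODY_PARTS),
               md$replicate)
  list(images = images[md$image[ord]],
       metadata = transform(md[ord, ], image = seq_along(ord)),
       truth = do.call(rbind, truth), latents = latents)
}

#' Measure a list of region images
#'
#' Runs binarize -> extract_spots -> compute_indices on every image and
#' appends replicate-averaged rows per gecko x body part (flagged
#' `averaged = TRUE`; a replicate-averaged row qualifies only when all its
#' replicates qualify).
#'
#' @param images list of `region_image`.
#' @param config a [run_config()] list (threshold/cleaning/index options).
#' @return data.frame in the indices-table layout (see
#'   [as.data.frame.pattern_indices()]).
#' @export
measure_dataset <- function(images, config = run_config()) {
  rows <- vector("list", length(images))
  per_key <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    type <- body_part_type(img$body_part)
    pat <- binarize(img, artifact_action = config$artifact_action,
                    k = config$niblack_k[[type]],
                    floor = config$threshold_floor,
                    cap = if (type == "trunk") config$trunk_cap else NA_real_)
    ss <- extract_spots(pat, img, min_spot_px = config$min_spot_px,
                        smooth_iterations = config$smooth_iterations,
                        qualify_min = config$qualify_min)
    ind <- compute_indices(ss, pat, img,
                           ee_convention = config$ee_convention)
    rows[[i]] <- as.data.frame(ind)
    key <- paste(img$gecko_id, img$body_part)
    per_key[[key]] <- c(per_key[[key]], list(ind))
  }
  avg <- lapply(per_key, function(reps)
    as.data.frame(average_replicates(reps)))
  out <- do.call(rbind, c(rows, avg))
  rownames(out) <- NULL
  out
}
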