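# Run configuration: every tunable of the pipeline with the defaults that
# reproduce the published extraction rules (Niblack factors 0.85 for
# limbs/trunk/tail and 0.50 for the head, threshold floor 60, trunk cap
# 108, 350-px minimum spot size, qualifying minima 4/6/0, two smoothing
# iterations).

#' Build a run configuration
#'
#' @param min_spot_px minimum spot size in pixels (default 350).
#' @param smooth_iterations contour-smoothing iterations (default 2).
#' @param artifact_action shadow/glare handling in [binarize()].
#' @param ee_convention spot ellipticity convention in
#'   [compute_indices()].
#' @param niblack_k named vector of Niblack factors per morphological
#'   type.
#' @param threshold_floor,trunk_cap threshold bounds (0-255 scale).
#' @param qualify_min named vector of minimum interior-spot counts.
#' @param n_perm permutations for statistical tests (default 10000).
#' @param seed RNG seed recorded in outputs.
#' @return list of class `run_config`.
#' @export
run_config <- function(min_spot_px = 350L,
                       smooth_iterations = 2L,
                       artifact_action = "exclude_stats",
                       ee_convention = "ratio",
                       niblack_k = c(limb = 0.85, head = 0.50,
                                     trunk = 0.85, tail = 0.85),
                       threshold_floor = 60,
                       trunk_cap = 108,
                       qualify_min = c(limb = 4L, head = 0L,
                                       trunk = 6L, tail = 6L),
                       n_perm = 10000L,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' @keywords internal
validate_run_config <- function(cfg) {
  stopifnot(cfg$min_spot_px >= 1L, cfg$smooth_iterations >= 0L,
            cfg$artifact_action %in% c("exclude_stats", "exclude_dark",
                                       "none"),
            cfg$ee_convention %in% c("ratio", "eccentricity"),
            all(c("limb", "head", "trunk", "tail") %in%
                  names(cfg$niblack_k)),
            cfg$threshold_floor >= 0, cfg$threshold_floor <= 255,
            cfg$n_perm >= 1L)
  invisible(cfg)
}

#' Write a run configuration to JSON
#' @param cfg a `run_config`.
#' @param path output file.
#' @export
write_run_config <- function(cfg, path) {
  out <- lapply(unclass(cfg), function(x)
    if (!is.null(names(x))) as.list(x) else x)   # keep element names
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path JSON file written by [write_run_config()] (or a subset of
#'   its fields; unspecified fields take their defaults).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- run_config()
  for (nm in intersect(names(raw), names(base))) {
    v <- unlist(raw[[nm]])
    if (is.integer(base[[nm]])) v[] <- as.integer(v)  # keep names
    storage.mode(v) <- storage.mode(base[[nm]])
    base[[nm]] <- v
  }
  validate_run_config(base)
  base
}
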