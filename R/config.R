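#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file with (all optional unless a stage that
#' needs them is run) sections \code{camera} (offset_counts,
#' counts_per_photon, read_noise_counts), \code{detection}
#' (threshold_photons, fit_window_px, min_photons, max_precision_nm,
#' min_sigma_nm, max_sigma_nm), \code{cluster} (preset or radius_nm +
#' min_neighbors), \code{render} (target_pixel_nm, mode),
#' \code{simulation} (scene and acquisition parameters) and top-level
#' \code{pixel_size_nm}, \code{seed}, \code{stages}, \code{out_dir}.
#' Every numeric value is validated against its type's invariants at load
#' time; violations raise an error naming the offending key.
#'
#' @param path Path to a YAML config file.
#' @return A named list of class \code{pipeline_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg A raw configuration list (as from \code{yaml::read_yaml}).
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  need_pos <- function(section, key, default = NULL, strict = TRUE) {
    v <- cfg[[section]][[key]]
    if (is.null(v)) {
      if (is.null(default))
        stop(sprintf("config missing required key: %s.%s", section, key))
      return(default)
    }
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) ||
        (strict && v <= 0) || (!strict && v < 0))
      stop(sprintf("config key %s.%s must be a %s number", section, key,
                   if (strict) "positive" else "nonnegative"))
    v
  }
  if (!is.null(cfg$camera)) {
    cfg$camera <- camera_model(
      offset_counts = need_pos("camera", "offset_counts", 100, strict = FALSE),
      counts_per_photon = need_pos("camera", "counts_per_photon"),
      read_noise_counts = need_pos("camera", "read_noise_counts", 2,
                                   strict = FALSE))
  } else cfg$camera <- camera_model()
  det <- cfg$detection
  cfg$detection <- detection_params(
    threshold_photons = if (is.null(det$threshold_photons)) NA_real_
                        else need_pos("detection", "threshold_photons"),
    fit_window_px = if (is.null(det$fit_window_px)) 7L
                    else as.integer(need_pos("detection", "fit_window_px")),
    min_photons = need_pos("detection", "min_photons", 200),
    max_precision_nm = need_pos("detection", "max_precision_nm", 50),
    min_sigma_nm = need_pos("detection", "min_sigma_nm", 50),
    max_sigma_nm = need_pos("detection", "max_sigma_nm", 300))
  cl <- cfg$cluster
  cfg$cluster <- if (!is.null(cl$radius_nm) || !is.null(cl$min_neighbors)) {
    cluster_params(radius_nm = need_pos("cluster", "radius_nm"),
                   min_neighbors = as.integer(need_pos("cluster", "min_neighbors")))
  } else {
    cluster_params(preset = if (is.null(cl$preset)) "results" else cl$preset)
  }
  rn <- cfg$render
  cfg$render <- list(
    target_pixel_nm = need_pos("render", "target_pixel_nm", 10),
    mode = if (is.null(rn$mode)) "gaussian" else match.arg(rn$mode,
                                                           c("gaussian", "histogram")))
  if (is.null(cfg$pixel_size_nm)) cfg$pixel_size_nm <- 100
  if (cfg$pixel_size_nm <= 0) stop("config key pixel_size_nm must be a positive number")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = c("pipeline_config", "list"))
}
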