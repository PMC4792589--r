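#' Run the analysis pipeline
#'
#' Executes the requested stages in order — simulate, localize, render,
#' cluster, segment, coloc — communicating only through files so each stage
#' is independently inspectable, and writes a JSON run manifest recording
#' the package version, seed, a parameter hash and every output path. The
#' global seed drives every stochastic stage, so identical config + seed
#' gives byte-identical outputs.
#'
#' Simulation parameters (config \code{simulation}): \code{layout}
#' ("thomas", "csr" or "nanoruler") with its scene parameters,
#' \code{n_frames}, \code{p_on_per_frame}, \code{mean_photons},
#' \code{psf_sigma_nm}, \code{background_photons_per_px},
#' \code{region_um = c(width, height)} and \code{shape_px}.
#'
#' @param config A \code{pipeline_config} (see \code{\link{read_config}}),
#'   or a path to a YAML config file.
#' @param out_dir Output directory (created if missing); overrides
#'   \code{config$out_dir}.
#' @param seed Integer seed; overrides \code{config$seed}.
#' @param stages Character vector of stages to run; overrides
#'   \code{config$stages}. Stages after "simulate" require either the
#'   simulate stage or existing input files named in the config
#'   (\code{stack}, \code{locs}, \code{mask}, \code{gfp}).
#' @return The manifest (named list), invisibly written to
#'   \code{manifest.json} in \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL, stages = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  if (is.null(out_dir)) out_dir <- if (!is.null(config$out_dir)) config$out_dir else "."
  if (is.null(seed)) seed <- config$seed
  seed <- as.integer(seed)
  if (is.null(stages)) stages <- config$stages
  if (is.null(stages)) {
    stages <- c("simulate", "localize", "render", "cluster", "segment")
    # co-localization needs a GFP wide-field channel
    if (!is.null(config$gfp)) stages <- c(stages, "coloc")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sim <- config$simulation
  a <- config$pixel_size_nm

  stack <- NULL; table <- NULL; regions <- NULL; gfp <- NULL; gfp_origin <- c(0, 0)

  if ("simulate" %in% stages) run_stage("simulate", function() {
    if (is.null(sim)) stop("config has no simulation section")
    region_um <- if (is.null(sim$region_um)) c(10, 10) else sim$region_um
    region <- c(0, 0, region_um[1] * 1000, region_um[2] * 1000)
    layout <- if (is.null(sim$layout)) "thomas" else sim$layout
    scene <- switch(layout,
      csr = sample_csr(sim$n_points, region, seed = seed),
      thomas = sample_thomas(
        n_parents = if (is.null(sim$n_parents)) 10 else sim$n_parents,
        mean_offspring = if (is.null(sim$mean_offspring)) 20 else sim$mean_offspring,
        cluster_sigma_nm = if (is.null(sim$cluster_sigma_nm)) 50 else sim$cluster_sigma_nm,
        background_n = if (is.null(sim$background_n)) 50 else sim$background_n,
        region = region, seed = seed),
      nanoruler = make_nanoruler(
        n_pairs = if (is.null(sim$n_pairs)) 100 else sim$n_pairs,
        separation_nm = if (is.null(sim$separation_nm)) 35 else sim$separation_nm,
        region = region, seed = seed),
      stop("unknown simulation layout: ", layout))
    n_frames <- if (is.null(sim$n_frames)) 500 else sim$n_frames
    scene <- make_blink_schedule(
      scene, n_frames,
      p_on_per_frame = if (is.null(sim$p_on_per_frame)) 0.01 else sim$p_on_per_frame,
      mean_photons = if (is.null(sim$mean_photons)) 2000 else sim$mean_photons,
      seed = seed + 1L)
    shape <- if (is.null(sim$shape_px))
      c(n_frames, ceiling(region_um[2] * 1000 / a),
        ceiling(region_um[1] * 1000 / a))
    else c(n_frames, sim$shape_px[1], sim$shape_px[2])
    stack <<- render_frames(
      scene, config$camera,
      psf_sigma_nm = if (is.null(sim$psf_sigma_nm)) 130 else sim$psf_sigma_nm,
      stack_shape = shape, pixel_size_nm = a,
      background_photons_per_px = if (is.null(sim$background_photons_per_px)) 1
                                  else sim$background_photons_per_px,
      seed = seed + 2L)
    p <- file.path(out_dir, "stack.tif")
    write_stack(stack, p)
    outputs$stack <<- p
    # companion compartment mask covering the field of view
    w <- region_um[1] * 1000; h <- region_um[2] * 1000
    regions <<- make_compartment_masks(
      region,
      nucleus_ellipse = list(cx = w * 0.45, cy = h * 0.5, rx = w * 0.15, ry = h * 0.12),
      cell_ellipse = list(cx = w * 0.5, cy = h * 0.5, rx = w * 0.35, ry = h * 0.3),
      mask_pixel_nm = a)
    pm <- file.path(out_dir, "mask.tif")
    write_mask(regions, pm)
    outputs$mask <<- pm
  })

  if ("localize" %in% stages) run_stage("localize", function() {
    if (is.null(stack)) {
      if (is.null(config$stack)) stop("no stack to localize (missing 'stack' input)")
      stack <<- read_stack(config$stack, pixel_size_nm = a)
    }
    table <<- localize_stack(stack, config$camera, config$detection)
    p <- file.path(out_dir, "localizations.csv")
    write_localizations(table, p)
    outputs$localizations <<- p
  })

  need_table <- function() {
    if (is.null(table)) {
      if (!is.null(outputs$localizations)) table <<- read_localizations(outputs$localizations)
      else if (!is.null(config$locs)) table <<- read_localizations(config$locs)
      else stop("no localization table available")
    }
  }

  if ("render" %in% stages) run_stage("render", function() {
    need_table()
    img <- render_smlm(table, render_params(
      target_pixel_nm = config$render$target_pixel_nm,
      mode = config$render$mode))
    p <- file.path(out_dir, "sr.tif")
    write_float_image(img, p)
    outputs$sr_image <<- p
  })

  if ("cluster" %in% stages) run_stage("cluster", function() {
    need_table()
    res <- density_cluster(table, config$cluster)
    met <- cluster_metrics(res, table)
    p <- file.path(out_dir, "clusters.csv")
    write.csv(met, p, row.names = FALSE)
    outputs$clusters <<- p
    area <- if (!is.null(regions)) region_area_um2(regions) else {
      b <- loc_bounds(table)
      (b[3] - b[1]) * (b[4] - b[2]) / 1e6
    }
    summ <- cell_summary(res, area)
    pj <- file.path(out_dir, "clusters_summary.json")
    jsonlite::write_json(summ, pj, auto_unbox = TRUE, digits = NA)
    outputs$cluster_summary <<- pj
  })

  if ("segment" %in% stages) run_stage("segment", function() {
    need_table()
    if (is.null(regions)) {
      if (!is.null(outputs$mask)) regions <<- read_mask(outputs$mask, a)
      else if (!is.null(config$mask)) regions <<- read_mask(config$mask, a)
      else stop("no compartment mask available")
    }
    cc <- assign_compartments(table, regions)
    p <- file.path(out_dir, "compartments.json")
    jsonlite::write_json(list(n_nucleus = cc$n_nucleus,
                              n_cytoplasm = cc$n_cytoplasm,
                              n_extracellular = cc$n_extracellular,
                              fractions = as.list(cc$fractions)),
                         p, auto_unbox = TRUE, digits = NA)
    outputs$compartments <<- p
  })

  if ("coloc" %in% stages) run_stage("coloc", function() {
    need_table()
    if (is.null(gfp)) {
      if (!is.null(config$gfp)) gfp <<- read_image(config$gfp)
      else stop("no GFP wide-field image available")
    }
    spots <- detect_exosome_spots(gfp, pixel_size_nm = a, origin_nm = gfp_origin)
    co <- coloc_counts(table, spots,
                       match_radius_nm = if (is.null(config$match_radius_nm)) 50
                                         else config$match_radius_nm)
    p <- file.path(out_dir, "coloc.json")
    jsonlite::write_json(list(n_spots = spots$n_spots,
                              n_colocalized = co$n_colocalized,
                              coloc_fraction = co$coloc_fraction,
                              mean_per_exosome = co$mean_per_exosome,
                              per_spot = co$per_spot),
                         p, auto_unbox = TRUE, digits = NA)
    outputs$coloc <<- p
  })

  manifest <- list(
    package = "mirloc",
    version = as.character(utils::packageVersion("mirloc")),
    seed = seed,
    stages = stages,
    parameter_hash = config_hash(config),
    outputs = outputs)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  manifest$path <- mp
  invisible(manifest)
}

# stable hash of the (serialized) configuration
config_hash <- function(config) {
  raw <- serialize(unclass(config), connection = NULL, version = 2,
                   xdr = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(raw, f)
  unname(tools::md5sum(f))
}

#' Human-readable summary of a pipeline run
#'
#' Recomputes the headline numbers from the manifest's output files —
#' localization count, mean/median precision, cluster count and density,
#' compartment fractions — and prints them.
#'
#' @param manifest A manifest list from \code{\link{run_pipeline}} or the
#'   path to a \code{manifest.json}.
#' @return The summary lines, invisibly (also printed).
#' @export
pipeline_report <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  out <- manifest$outputs
  lines <- character(0)
  push <- function(...) lines <<- c(lines, sprintf(...))
  if (!is.null(out$localizations)) {
    tab <- read_localizations(out$localizations)
    s <- summarize_localizations(tab)
    push("localizations: n = %d", s$n)
    if (s$n > 0) {
      push("mean precision = %.2f nm", s$mean_precision_nm)
      push("median precision = %.2f nm", s$median_precision_nm)
    } else {
      push("no localizations: precision statistics undefined")
    }
  }
  if (!is.null(out$cluster_summary)) {
    cs <- jsonlite::read_json(out$cluster_summary)
    push("clusters: n = %d", cs$n_clusters)
    push("cluster density = %.3f per um^2 (area %.2f um^2)",
         cs$cluster_density_per_um2, cs$cell_area_um2)
  }
  if (!is.null(out$compartments)) {
    cc <- jsonlite::read_json(out$compartments)
    push("compartments: nucleus %d / cytoplasm %d / extracellular %d",
         cc$n_nucleus, cc$n_cytoplasm, cc$n_extracellular)
  }
  if (!is.null(out$coloc)) {
    co <- jsonlite::read_json(out$coloc)
    push("exosome spots: %d, colocalized molecules: %d (mean %.2f per exosome)",
         co$n_spots, co$n_colocalized,
         if (is.null(co$mean_per_exosome)) NA_real_ else co$mean_per_exosome)
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
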