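#' Synthetic SMLM scene
#'
#' Ground-truth emitter layout for simulating an acquisition: emitter
#' positions (nm), cluster memberships (-1 for background), an optional
#' blinking schedule, and optional compartment / exosome geometry. Every
#' downstream stage can be validated against the retained ground truth.
#'
#' @param positions n x 2 numeric matrix of emitter positions (x_nm, y_nm).
#' @param labels Integer cluster labels, -1 for background points.
#' @param region \code{c(xmin, ymin, xmax, ymax)} nm.
#' @param schedule Optional blink schedule data frame
#'   (\code{emitter, frame, photons}); see \code{\link{make_blink_schedule}}.
#' @param regions Optional \code{\link{region_set}} compartment masks.
#' @param exosome_centers Optional m x 2 matrix of exosome spot centers (nm).
#' @return An object of class \code{synthetic_scene}.
#' @export
synthetic_scene <- function(positions, labels = NULL, region,
                            schedule = NULL, regions = NULL,
                            exosome_centers = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 2,
                      dimnames = list(NULL, c("x_nm", "y_nm")))
  if (is.null(labels)) labels <- rep(-1L, nrow(positions))
  stopifnot(length(labels) == nrow(positions), length(region) == 4)
  region <- as.numeric(region)
  if (region[3] <= region[1] || region[4] <= region[2])
    stop("region must have positive area")
  if (nrow(positions) > 0 &&
      (any(positions[, 1] < region[1] - 1e-9) ||
       any(positions[, 1] > region[3] + 1e-9) ||
       any(positions[, 2] < region[2] - 1e-9) ||
       any(positions[, 2] > region[4] + 1e-9)))
    stop("emitters outside region")
  structure(list(positions = positions, labels = as.integer(labels),
                 region = region, schedule = schedule, regions = regions,
                 exosome_centers = exosome_centers),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d emitters (%d clustered), region %g x %g um%s\n",
              nrow(x$positions), sum(x$labels >= 0),
              (x$region[3] - x$region[1]) / 1000,
              (x$region[4] - x$region[2]) / 1000,
              if (is.null(x$schedule)) "" else
                sprintf(", %d blink events", nrow(x$schedule))))
  invisible(x)
}

#' Sample a completely spatially random (CSR) scene
#'
#' n points independent and uniform over the region — the homogeneous
#' Poisson (binomial) null model against which clustering is tested.
#'
#' @param n Number of points (>= 0).
#' @param region \code{c(xmin, ymin, xmax, ymax)} nm.
#' @param seed Integer seed; identical seeds give identical scenes.
#' @return A \code{\link{synthetic_scene}} with all labels -1.
#' @export
sample_csr <- function(n, region, seed = NULL) {
  if (n < 0) stop("n must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  pos <- cbind(runif(n, region[1], region[3]),
               runif(n, region[2], region[4]))
  synthetic_scene(pos, rep(-1L, n), region)
}

#' Sample a Thomas cluster process
#'
#' Poisson-cluster model: \code{n_parents} cluster centers uniform in the
#' region; each center receives \code{Poisson(mean_offspring)} offspring
#' scattered with an isotropic Gaussian of sd \code{cluster_sigma_nm}
#' (offspring falling outside the region are redrawn, i.e. the Gaussian is
#' truncated to the region); \code{background_n} CSR points labeled -1 are
#' added. Cluster labels are the parent index (0-based).
#'
#' @param n_parents Number of cluster centers.
#' @param mean_offspring Mean points per cluster.
#' @param cluster_sigma_nm Gaussian scatter sd (nm).
#' @param background_n Number of CSR background points.
#' @param region \code{c(xmin, ymin, xmax, ymax)} nm.
#' @param seed Integer seed.
#' @return A \code{\link{synthetic_scene}}.
#' @export
sample_thomas <- function(n_parents, mean_offspring, cluster_sigma_nm,
                          background_n, region, seed = NULL) {
  stopifnot(n_parents >= 0, mean_offspring >= 0, cluster_sigma_nm > 0,
            background_n >= 0)
  if (!is.null(seed)) set.seed(seed)
  parents <- cbind(runif(n_parents, region[1], region[3]),
                   runif(n_parents, region[2], region[4]))
  counts <- if (n_parents > 0) rpois(n_parents, mean_offspring) else integer(0)
  pos_list <- vector("list", n_parents)
  for (p in seq_len(n_parents)) {
    m <- counts[p]
    pts <- matrix(numeric(0), ncol = 2)
    while (nrow(pts) < m) {
      cand <- cbind(rnorm(m, parents[p, 1], cluster_sigma_nm),
                    rnorm(m, parents[p, 2], cluster_sigma_nm))
      ok <- cand[, 1] >= region[1] & cand[, 1] <= region[3] &
            cand[, 2] >= region[2] & cand[, 2] <= region[4]
      pts <- rbind(pts, cand[ok, , drop = FALSE])
    }
    pos_list[[p]] <- pts[seq_len(m), , drop = FALSE]
  }
  pos <- do.call(rbind, c(pos_list,
                          list(cbind(runif(background_n, region[1], region[3]),
                                     runif(background_n, region[2], region[4])))))
  labels <- c(rep(seq_len(n_parents) - 1L, counts), rep(-1L, background_n))
  synthetic_scene(pos, labels, region)
}

#' Nanoruler pair layout
#'
#' Emulates a DNA-origami calibration standard: fluorophore pairs at a fixed
#' design separation. Anchors are placed uniformly with a minimum mutual
#' distance of 5x the separation (dart throwing); each pair sits at
#' anchor +/- (separation/2) along a uniformly random orientation in
#' [0, pi). Labels give the pair index for both members.
#'
#' @param n_pairs Number of fluorophore pairs.
#' @param separation_nm Design pair separation (> 0), e.g. the 35 nm of a
#'   commercial LM35 standard.
#' @param region \code{c(xmin, ymin, xmax, ymax)} nm.
#' @param seed Integer seed.
#' @return A \code{\link{synthetic_scene}} with 2 * n_pairs emitters.
#' @export
make_nanoruler <- function(n_pairs, separation_nm, region, seed = NULL) {
  if (separation_nm <= 0) stop("separation_nm must be > 0")
  if (!is.null(seed)) set.seed(seed)
  min_dist <- 5 * separation_nm
  margin <- separation_nm / 2
  lo <- c(region[1] + margin, region[2] + margin)
  hi <- c(region[3] - margin, region[4] - margin)
  if (any(hi <= lo))
    stop("region too small for the requested pair separation")
  anchors <- matrix(NA_real_, n_pairs, 2)
  max_tries <- 1000L * max(n_pairs, 1L)
  tries <- 0L
  placed <- 0L
  while (placed < n_pairs) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("region too small to place ", n_pairs,
           " pairs at mutual distance >= ", min_dist, " nm")
    cand <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
    if (placed == 0L ||
        min(sqrt((anchors[seq_len(placed), 1] - cand[1])^2 +
                 (anchors[seq_len(placed), 2] - cand[2])^2)) >= min_dist) {
      placed <- placed + 1L
      anchors[placed, ] <- cand
    }
  }
  theta <- runif(n_pairs, 0, pi)
  dx <- cos(theta) * separation_nm / 2
  dy <- sin(theta) * separation_nm / 2
  pos <- rbind(cbind(anchors[, 1] + dx, anchors[, 2] + dy),
               cbind(anchors[, 1] - dx, anchors[, 2] - dy))
  ord <- rep(seq_len(n_pairs), 2)
  pos <- pos[order(ord), , drop = FALSE]
  labels <- rep(seq_len(n_pairs) - 1L, each = 2)
  sc <- synthetic_scene(pos, labels, region)
  sc$anchors <- anchors
  sc$pair_orientation <- theta
  sc$separation_nm <- separation_nm
  sc
}

#' Attach a blinking schedule to a scene
#'
#' Memoryless photoswitching: each emitter independently turns on in each
#' frame with probability \code{p_on_per_frame} (at most one event per
#' emitter per frame); event photon counts follow an exponential law of
#' mean \code{mean_photons} truncated at >= 10 photons.
#'
#' @param scene A \code{\link{synthetic_scene}}.
#' @param n_frames Number of acquisition frames (e.g. 3000 for a full
#'   acquisition; smaller for tests).
#' @param p_on_per_frame Per-frame on probability, in (0, 1) (0 allowed and
#'   gives an empty schedule).
#' @param mean_photons Mean photons per blink event (> 0).
#' @param seed Integer seed.
#' @return The scene with \code{$schedule}: data frame
#'   \code{emitter} (0-based), \code{frame} (0-based), \code{photons}.
#' @export
make_blink_schedule <- function(scene, n_frames, p_on_per_frame,
                                mean_photons, seed = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"),
            p_on_per_frame >= 0, p_on_per_frame < 1, mean_photons > 0,
            n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_em <- nrow(scene$positions)
  if (n_em == 0 || p_on_per_frame == 0) {
    scene$schedule <- data.frame(emitter = integer(0), frame = integer(0),
                                 photons = numeric(0))
    scene$n_frames <- as.integer(n_frames)
    return(scene)
  }
  on <- which(matrix(runif(n_em * n_frames) < p_on_per_frame,
                     n_em, n_frames), arr.ind = TRUE)
  # truncation at >= 10 photons; the exponential is memoryless so the
  # truncated law is 10 + Exp(mean_photons)
  photons <- 10 + rexp(nrow(on), 1 / mean_photons)
  scene$schedule <- data.frame(emitter = as.integer(on[, 1] - 1L),
                               frame = as.integer(on[, 2] - 1L),
                               photons = photons)
  scene$n_frames <- as.integer(n_frames)
  scene
}

# pixel-integrated symmetric Gaussian masses over pixels [lo, lo+1), ...
# centered at u (px units), sd s (px); returns masses for pixels lo..hi
integrated_gauss_1d <- function(u, s, lo, hi) {
  edges <- seq(lo, hi + 1)
  diff(pnorm((edges - u) / s))
}

#' Render camera frames from a scene's blink schedule
#'
#' Forward model of the acquisition: each blink event deposits a
#' pixel-integrated isotropic 2D Gaussian (sd \code{psf_sigma_nm}, total
#' mass = event photons) on its frame's expected photon image; a constant
#' background photon rate is added; counts are then
#' \code{offset + counts_per_photon * Poisson(expected photons) +
#' Gaussian(0, read_noise)}, rounded and clipped at 0. Events whose center
#' falls outside the frame are dropped; the number dropped is attached as
#' attribute \code{n_dropped} with a warning.
#'
#' @param scene A scene with a blink schedule.
#' @param camera A \code{\link{camera_model}}.
#' @param psf_sigma_nm PSF standard deviation (nm), > 0.
#' @param stack_shape \code{c(n_frames, height_px, width_px)}; frames beyond
#'   the schedule are pure background.
#' @param pixel_size_nm Object-plane pixel pitch (nm).
#' @param background_photons_per_px Expected background photons per pixel
#'   per frame.
#' @param integration_time_ms Frame integration time (metadata only).
#' @param noise If \code{FALSE}, expected counts are returned without shot
#'   or read noise (for oracle tests).
#' @param seed Integer seed.
#' @return An \code{\link{image_stack}} in counts.
#' @export
render_frames <- function(scene, camera, psf_sigma_nm, stack_shape,
                          pixel_size_nm = 100, background_photons_per_px = 0,
                          integration_time_ms = 50, noise = TRUE,
                          seed = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(camera, "camera_model"),
            psf_sigma_nm > 0, length(stack_shape) == 3)
  if (is.null(scene$schedule))
    stop("scene has no blink schedule; call make_blink_schedule() first")
  if (!is.null(seed)) set.seed(seed)
  nt <- stack_shape[1]; nh <- stack_shape[2]; nw <- stack_shape[3]
  s_px <- psf_sigma_nm / pixel_size_nm
  # 7 sigma support: the tail mass left out is ~1e-12, so photon
  # conservation holds to numerical precision for interior emitters
  half <- ceiling(7 * s_px)
  expected <- array(background_photons_per_px, dim = c(nt, nh, nw))
  sched <- scene$schedule
  sched <- sched[sched$frame < nt, , drop = FALSE]
  n_dropped <- 0L
  for (e in seq_len(nrow(sched))) {
    em <- sched$emitter[e] + 1L
    u <- scene$positions[em, 1] / pixel_size_nm  # continuous px, x = col
    v <- scene$positions[em, 2] / pixel_size_nm  # y = row
    if (u < 0 || u >= nw || v < 0 || v >= nh) {
      n_dropped <- n_dropped + 1L
      next
    }
    jc <- floor(u); ic <- floor(v)
    j0 <- max(0, jc - half); j1 <- min(nw - 1, jc + half)
    i0 <- max(0, ic - half); i1 <- min(nh - 1, ic + half)
    gx <- integrated_gauss_1d(u, s_px, j0, j1)
    gy <- integrated_gauss_1d(v, s_px, i0, i1)
    t <- sched$frame[e] + 1L
    expected[t, (i0:i1) + 1L, (j0:j1) + 1L] <-
      expected[t, (i0:i1) + 1L, (j0:j1) + 1L] +
      sched$photons[e] * outer(gy, gx)
  }
  if (n_dropped > 0)
    warning(n_dropped, " blink event(s) outside frame bounds dropped")
  counts <- if (noise) {
    ph <- array(rpois(length(expected), expected), dim = dim(expected))
    round(pmax(camera$offset_counts + camera$counts_per_photon * ph +
                 array(rnorm(length(expected), 0, camera$read_noise_counts),
                       dim = dim(expected)), 0))
  } else {
    # noiseless oracle mode: expected counts, kept continuous so the
    # photon conversion inverts the forward model exactly
    camera$offset_counts + camera$counts_per_photon * expected
  }
  out <- image_stack(counts, pixel_size_nm = pixel_size_nm,
                     integration_time_ms = integration_time_ms)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Elliptical compartment masks
#'
#' Builds a \code{\link{region_set}} with label 1 inside the nucleus
#' ellipse, 2 inside the cell ellipse but outside the nucleus, and 0
#' elsewhere. The nucleus must lie entirely inside the cell.
#'
#' @param region \code{c(xmin, ymin, xmax, ymax)} nm covered by the mask.
#' @param nucleus_ellipse,cell_ellipse Lists \code{list(cx, cy, rx, ry)} in
#'   nm (center and semi-axes).
#' @param mask_pixel_nm Mask resolution (nm per mask pixel).
#' @return A \code{\link{region_set}}.
#' @export
make_compartment_masks <- function(region, nucleus_ellipse, cell_ellipse,
                                   mask_pixel_nm = 100) {
  ang <- seq(0, 2 * pi, length.out = 720)
  bx <- nucleus_ellipse$cx + nucleus_ellipse$rx * cos(ang)
  by <- nucleus_ellipse$cy + nucleus_ellipse$ry * sin(ang)
  if (any(((bx - cell_ellipse$cx) / cell_ellipse$rx)^2 +
          ((by - cell_ellipse$cy) / cell_ellipse$ry)^2 > 1))
    stop("nucleus ellipse not contained in the cell ellipse")
  nh <- ceiling((region[4] - region[2]) / mask_pixel_nm)
  nw <- ceiling((region[3] - region[1]) / mask_pixel_nm)
  xc <- region[1] + (seq_len(nw) - 0.5) * mask_pixel_nm
  yc <- region[2] + (seq_len(nh) - 0.5) * mask_pixel_nm
  X <- matrix(xc, nh, nw, byrow = TRUE)
  Y <- matrix(yc, nh, nw)
  in_cell <- ((X - cell_ellipse$cx) / cell_ellipse$rx)^2 +
             ((Y - cell_ellipse$cy) / cell_ellipse$ry)^2 <= 1
  in_nuc <- ((X - nucleus_ellipse$cx) / nucleus_ellipse$rx)^2 +
            ((Y - nucleus_ellipse$cy) / nucleus_ellipse$ry)^2 <= 1
  mask <- matrix(0L, nh, nw)
  mask[in_cell] <- 2L
  mask[in_nuc] <- 1L
  region_set(mask, mask_pixel_nm, origin_nm = region[1:2])
}

#' Render a wide-field image of diffraction-limited spots
#'
#' Convenience generator for GFP-exosome reference channels: each center
#' receives a pixel-integrated Gaussian blob of the given total intensity
#' on a constant background, with optional Poisson noise.
#'
#' @param centers_nm m x 2 matrix of spot centers (nm).
#' @param shape_px \code{c(height_px, width_px)}.
#' @param pixel_size_nm Pixel pitch (nm).
#' @param spot_sigma_nm Blob sd (nm).
#' @param intensity Total counts per blob.
#' @param background Constant background counts per pixel.
#' @param noise Add Poisson noise?
#' @param seed Integer seed.
#' @return An intensity matrix.
#' @export
render_widefield_spots <- function(centers_nm, shape_px, pixel_size_nm = 100,
                                   spot_sigma_nm = 200, intensity = 5000,
                                   background = 50, noise = TRUE,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nh <- shape_px[1]; nw <- shape_px[2]
  img <- matrix(background, nh, nw)
  s_px <- spot_sigma_nm / pixel_size_nm
  half <- ceiling(4 * s_px)
  centers_nm <- matrix(centers_nm, ncol = 2)
  for (m in seq_len(nrow(centers_nm))) {
    u <- centers_nm[m, 1] / pixel_size_nm
    v <- centers_nm[m, 2] / pixel_size_nm
    jc <- floor(u); ic <- floor(v)
    j0 <- max(0, jc - half); j1 <- min(nw - 1, jc + half)
    i0 <- max(0, ic - half); i1 <- min(nh - 1, ic + half)
    if (j1 < j0 || i1 < i0) next
    img[(i0:i1) + 1L, (j0:j1) + 1L] <- img[(i0:i1) + 1L, (j0:j1) + 1L] +
      intensity * outer(integrated_gauss_1d(v, s_px, i0, i1),
                        integrated_gauss_1d(u, s_px, j0, j1))
  }
  if (noise) img <- matrix(rpois(length(img), img), nh, nw)
  img
}
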