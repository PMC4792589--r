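#' Spot detection and fit filtering parameters
#'
#' @param threshold_photons Peak threshold above the local (frame median)
#'   background, in photons. \code{NA} (default) selects an automatic
#'   threshold of 5x the robust standard deviation (1.4826 * MAD) of each
#'   differential frame.
#' @param fit_window_px Side of the square fitting window (odd, >= 5).
#' @param min_photons Minimum fitted photon count to keep a localization.
#' @param max_precision_nm Maximum estimated precision to keep.
#' @param min_sigma_nm,max_sigma_nm Accepted fitted PSF sd range (nm).
#' @return An object of class \code{detection_params}.
#' @export
detection_params <- function(threshold_photons = NA_real_, fit_window_px = 7L,
                             min_photons = 200, max_precision_nm = 50,
                             min_sigma_nm = 50, max_sigma_nm = 300) {
  fit_window_px <- as.integer(fit_window_px)
  if (fit_window_px %% 2L != 1L || fit_window_px < 5L)
    stop("fit_window_px must be odd and >= 5")
  stopifnot(min_sigma_nm > 0, max_sigma_nm > min_sigma_nm,
            min_photons > 0, max_precision_nm > 0)
  structure(list(threshold_photons = threshold_photons,
                 fit_window_px = fit_window_px,
                 min_photons = min_photons,
                 max_precision_nm = max_precision_nm,
                 min_sigma_nm = min_sigma_nm,
                 max_sigma_nm = max_sigma_nm),
            class = "detection_params")
}

#' Convert camera counts to photons
#'
#' \code{photons = max(0, counts - offset) / counts_per_photon}, applied
#' elementwise.
#'
#' @param stack An \code{\link{image_stack}} in counts.
#' @param camera A \code{\link{camera_model}}.
#' @return An \code{\link{image_stack}} with units "photons".
#' @export
counts_to_photons <- function(stack, camera) {
  stopifnot(inherits(stack, "image_stack"), inherits(camera, "camera_model"))
  ph <- pmax(stack$frames - camera$offset_counts, 0) / camera$counts_per_photon
  image_stack(ph, pixel_size_nm = stack$pixel_size_nm,
              integration_time_ms = stack$integration_time_ms,
              units = "photons")
}

#' Differential stack
#'
#' Frame-to-frame subtraction that isolates blinking transitions:
#' \code{D[t] = F[t] - F[t+1]} for t = 0..T-2 (a succeeding frame is
#' subtracted from the preceding one). A positive peak in \code{D[t]} marks
#' a molecule whose emission ended with frame t; a negative peak is the
#' mirror of an emission starting at t+1.
#'
#' @param stack An \code{\link{image_stack}} with at least 2 frames
#'   (typically the photon-converted stack).
#' @return A signed T-1 x H x W array.
#' @export
differential_stack <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  f <- stack$frames
  nt <- dim(f)[1]
  if (nt < 2) stop("differential stack requires at least 2 frames")
  f[seq_len(nt - 1), , , drop = FALSE] - f[2:nt, , , drop = FALSE]
}

#' Detect candidate spots in one differential frame
#'
#' Local maxima (8-neighborhood) of the positive part of the frame whose
#' value exceeds the frame median by at least the photon threshold, then
#' non-maximum suppressed so surviving candidates are at least
#' \code{fit_window_px} pixels apart (strongest first).
#'
#' @param diff_frame Signed H x W matrix (one frame of
#'   \code{\link{differential_stack}}).
#' @param params A \code{\link{detection_params}}.
#' @return Integer matrix with columns \code{i, j} (0-based row/col pixel
#'   coordinates); zero rows when nothing is found.
#' @export
detect_spots <- function(diff_frame, params = detection_params()) {
  stopifnot(is.matrix(diff_frame))
  pos <- pmax(diff_frame, 0)
  med <- median(diff_frame)
  thr <- params$threshold_photons
  if (is.na(thr)) {
    sigma <- mad(diff_frame)
    thr <- 5 * max(sigma, .Machine$double.eps)
  }
  nh <- nrow(pos); nw <- ncol(pos)
  if (nh < 3 || nw < 3) return(matrix(integer(0), 0, 2,
                                      dimnames = list(NULL, c("i", "j"))))
  core <- pos[2:(nh - 1), 2:(nw - 1)]
  is_max <- core >= thr + med
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & core >= pos[2:(nh - 1) + di, 2:(nw - 1) + dj]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(integer(0), 0, 2,
                                    dimnames = list(NULL, c("i", "j"))))
  cand <- cbind(i = idx[, 1], j = idx[, 2])  # 0-based thanks to core offset
  vals <- core[idx]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    prev <- cand[keep, , drop = FALSE]
    if (nrow(prev) == 0 ||
        min(sqrt((prev[, 1] - cand[r, 1])^2 + (prev[, 2] - cand[r, 2])^2)) >=
        params$fit_window_px)
      keep[r] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  colnames(out) <- c("i", "j")
  out
}

#' Fit a pixel-integrated 2D Gaussian to a photon window
#'
#' Least-squares fit of \code{b + N * G(i, j; x0, y0, s)} by
#' Levenberg-Marquardt, where \code{G} is the symmetric 2D Gaussian
#' integrated over each pixel so the model matches a diffraction-limited
#' spot sampled by the camera exactly. Parameters are the continuous pixel
#' position \code{(x0, y0)} (column/row units, pixel j covering [j, j+1)),
#' the total photon count N, the PSF sd s (px) and a flat background b
#' (photons/px). The fit is declared non-converged if Levenberg-Marquardt
#' fails, the iteration cap (100) is hit, or the solution sits on a bound
#' (position outside the window, s outside the configured range).
#'
#' @param window Square photon matrix (the fitting window).
#' @param pixel_size_nm Pixel pitch, used to express results in nm.
#' @param init Optional named list of starting values
#'   (\code{x0_px, y0_px, photons, sigma_px, background}); a moment-based
#'   guess is used when omitted.
#' @param params \code{\link{detection_params}} supplying the sigma bounds.
#' @param weighting "poisson" (default) minimizes Pearson-weighted squares
#'   \code{(y - m)^2 / m}, matching photon shot noise; "none" is plain
#'   unweighted least squares.
#' @return A list of class \code{fit_result}: \code{x0_nm, y0_nm} (window
#'   coordinates), \code{photons}, \code{amplitude_photons_per_px},
#'   \code{psf_sigma_nm}, \code{background_photons_per_px},
#'   \code{converged}, \code{n_iterations}, \code{residual_norm}.
#' @export
fit_gaussian_2d <- function(window, pixel_size_nm = 100, init = NULL,
                            params = detection_params(),
                            weighting = c("poisson", "none")) {
  weighting <- match.arg(weighting)
  if (!is.matrix(window) || nrow(window) != ncol(window))
    stop("fit window must be square")
  w <- nrow(window)
  min_s_px <- params$min_sigma_nm / pixel_size_nm
  max_s_px <- params$max_sigma_nm / pixel_size_nm
  if (is.null(init)) {
    b0 <- median(window)
    excess <- pmax(window - b0, 0)
    tot <- sum(excess)
    if (tot <= 0) {
      cx <- w / 2; cy <- w / 2; tot <- 1
    } else {
      cx <- sum(excess * matrix(seq_len(w) - 0.5, w, w, byrow = TRUE)) / tot
      cy <- sum(excess * matrix(seq_len(w) - 0.5, w, w)) / tot
    }
    init <- list(x0_px = cx, y0_px = cy, photons = max(tot, 1),
                 sigma_px = sqrt(min_s_px * max_s_px), background = max(b0, 0))
  }
  model <- function(p) {
    gx <- integrated_gauss_1d(p[1], p[4], 0, w - 1)
    gy <- integrated_gauss_1d(p[2], p[4], 0, w - 1)
    p[5] + p[3] * outer(gy, gx)
  }
  # Pearson-weighted residuals: minimizing sum (y - m)^2 / m matches the
  # Poisson shot-noise statistics of photon counts and is asymptotically
  # efficient, unlike unweighted least squares which overweights the bright
  # central pixels
  resid_fn <- if (weighting == "poisson") {
    function(p) {
      m <- model(p)
      as.vector((window - m) / sqrt(pmax(m, 0.25)))
    }
  } else {
    function(p) as.vector(window - model(p))
  }
  lower <- c(0, 0, 1e-3, min_s_px, 0)
  upper <- c(w, w, Inf, max_s_px, Inf)
  start <- pmin(pmax(c(init$x0_px, init$y0_px, init$photons,
                       init$sigma_px, init$background), lower),
                c(w, w, 1e12, max_s_px, 1e9))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                       upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(x0_nm = NA_real_, y0_nm = NA_real_,
                          photons = NA_real_,
                          amplitude_photons_per_px = NA_real_,
                          psf_sigma_nm = NA_real_,
                          background_photons_per_px = NA_real_,
                          converged = FALSE, n_iterations = 0L,
                          residual_norm = NA_real_),
                     class = "fit_result"))
  }
  p <- fit$par
  eps <- 1e-6
  on_bound <- p[1] <= eps || p[1] >= w - eps ||
              p[2] <= eps || p[2] >= w - eps ||
              p[4] <= min_s_px + eps || p[4] >= max_s_px - eps
  converged <- fit$info %in% 1:4 && fit$niter < 100 && !on_bound &&
               p[3] > 0 && p[4] > 0
  structure(list(
    x0_nm = p[1] * pixel_size_nm,
    y0_nm = p[2] * pixel_size_nm,
    photons = p[3],
    amplitude_photons_per_px = p[3] / (2 * pi * p[4]^2),
    psf_sigma_nm = p[4] * pixel_size_nm,
    background_photons_per_px = p[5],
    converged = converged,
    n_iterations = fit$niter,
    residual_norm = sqrt(sum(fit$fvec^2))),
    class = "fit_result")
}

#' Theoretical localization precision
#'
#' Standard error of a fitted single-molecule position for a Gaussian PSF
#' of sd \code{s} sampled on pixels of pitch \code{a} with \code{N} signal
#' photons over a background of \code{b} photons per pixel:
#' \deqn{\sigma_{loc}^2 = \frac{s^2 + a^2/12}{N}
#'   + \frac{8 \pi s^4 b^2}{a^2 N^2}}
#' (photon-noise term with pixelation correction plus background term).
#'
#' @param N Photon count(s), > 0.
#' @param s PSF sd (nm).
#' @param a Pixel pitch (nm).
#' @param b Background photons per pixel.
#' @return Precision sigma_loc in nm (vectorized).
#' @export
localization_precision <- function(N, s, a, b = 0) {
  if (any(N <= 0)) stop("photon count N must be > 0")
  sqrt((s^2 + a^2 / 12) / N + 8 * pi * s^4 * b^2 / (a^2 * N^2))
}

#' Localize a full image stack
#'
#' The complete reconstruction chain: photon conversion, differential
#' stack, per-frame positive-peak detection, pixel-integrated Gaussian fits
#' on the original photon frame at the detected frame index (a positive
#' differential peak in D[t] means the emission ended with frame t),
#' precision estimation, and filtering by photon count, precision and PSF
#' width. Candidates too close to the frame border for a full fitting
#' window are skipped.
#'
#' @param stack An \code{\link{image_stack}} in counts.
#' @param camera A \code{\link{camera_model}}.
#' @param params A \code{\link{detection_params}}.
#' @return A \code{\link{localization_table}} in nm.
#' @export
localize_stack <- function(stack, camera = camera_model(),
                           params = detection_params()) {
  stopifnot(inherits(stack, "image_stack"))
  a <- stack$pixel_size_nm
  photons <- counts_to_photons(stack, camera)
  D <- differential_stack(photons)
  nt <- dim(D)[1]
  nh <- dim(D)[2]; nw <- dim(D)[3]
  hw <- params$fit_window_px %/% 2L
  rows <- list()
  for (t in seq_len(nt)) {
    cand <- detect_spots(D[t, , ], params)
    for (r in seq_len(nrow(cand))) {
      ic <- cand[r, 1]; jc <- cand[r, 2]      # 0-based
      if (ic < hw || ic >= nh - hw || jc < hw || jc >= nw - hw) next
      win <- photons$frames[t, (ic - hw):(ic + hw) + 1L,
                            (jc - hw):(jc + hw) + 1L]
      fit <- fit_gaussian_2d(win, pixel_size_nm = a, params = params)
      if (!fit$converged) next
      if (fit$photons < params$min_photons) next
      if (fit$psf_sigma_nm < params$min_sigma_nm ||
          fit$psf_sigma_nm > params$max_sigma_nm) next
      prec <- localization_precision(fit$photons, fit$psf_sigma_nm, a,
                                     fit$background_photons_per_px)
      if (prec > params$max_precision_nm) next
      rows[[length(rows) + 1L]] <- data.frame(
        frame = t - 1L,
        x_nm = (jc - hw) * a + fit$x0_nm,
        y_nm = (ic - hw) * a + fit$y0_nm,
        photons = fit$photons,
        psf_sigma_nm = fit$psf_sigma_nm,
        background = fit$background_photons_per_px,
        precision_nm = prec)
    }
  }
  df <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  localization_table(df,
                     bounds = c(0, 0, nw * a, nh * a),
                     provenance = list(n_frames = dim(stack$frames)[1],
                                       pixel_size_nm = a,
                                       params = unclass(params)))
}
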