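#' Super-resolution rendering parameters
#'
#' @param target_pixel_nm Rendering pixel size (nm), default 10 (matching a
#'   localization precision of order 10 nm).
#' @param mode "gaussian": each localization contributes a unit-mass
#'   isotropic Gaussian of sd equal to its own precision, integrated over
#'   the target pixels (truncated at 4 sd). "histogram": a unit count in
#'   the containing pixel.
#' @param normalize Scale the image to a maximum of 1 after accumulation.
#' @return An object of class \code{render_params}.
#' @export
render_params <- function(target_pixel_nm = 10,
                          mode = c("gaussian", "histogram"),
                          normalize = FALSE) {
  mode <- match.arg(mode)
  if (target_pixel_nm <= 0) stop("target_pixel_nm must be > 0")
  structure(list(target_pixel_nm = target_pixel_nm, mode = mode,
                 normalize = normalize),
            class = "render_params")
}

#' Render a super-resolution image from a localization table
#'
#' Each localization is blurred by a Gaussian whose width equals its own
#' estimated localization precision, so the rendering directly visualizes
#' positional uncertainty. Total image mass equals the number of
#' localizations (up to kernel truncation below 0.1%, and before any
#' normalization).
#'
#' @param table A \code{\link{localization_table}}.
#' @param params A \code{\link{render_params}}.
#' @param bounds Optional \code{c(xmin, ymin, xmax, ymax)} nm; defaults to
#'   the table's bounding region.
#' @return A numeric matrix with attributes \code{pixel_size_nm} and
#'   \code{origin_nm}.
#' @export
render_smlm <- function(table, params = render_params(), bounds = NULL) {
  stopifnot(inherits(table, "localization_table"))
  if (is.null(bounds)) bounds <- loc_bounds(table)
  px <- params$target_pixel_nm
  nw <- max(1L, ceiling((bounds[3] - bounds[1]) / px))
  nh <- max(1L, ceiling((bounds[4] - bounds[2]) / px))
  img <- matrix(0, nh, nw)
  if (nrow(table) > 0) {
    u <- (table$x_nm - bounds[1]) / px
    v <- (table$y_nm - bounds[2]) / px
    if (params$mode == "histogram") {
      j <- pmin(pmax(floor(u), 0), nw - 1)
      i <- pmin(pmax(floor(v), 0), nh - 1)
      for (r in seq_along(u))
        img[i[r] + 1L, j[r] + 1L] <- img[i[r] + 1L, j[r] + 1L] + 1
    } else {
      s <- table$precision_nm / px
      for (r in seq_along(u)) {
        half <- ceiling(4 * s[r])
        jc <- floor(u[r]); ic <- floor(v[r])
        j0 <- max(0, jc - half); j1 <- min(nw - 1, jc + half)
        i0 <- max(0, ic - half); i1 <- min(nh - 1, ic + half)
        if (j1 < j0 || i1 < i0) next
        img[(i0:i1) + 1L, (j0:j1) + 1L] <- img[(i0:i1) + 1L, (j0:j1) + 1L] +
          outer(integrated_gauss_1d(v[r], s[r], i0, i1),
                integrated_gauss_1d(u[r], s[r], j0, j1))
      }
    }
  }
  if (params$normalize && max(img) > 0) img <- img / max(img)
  attr(img, "pixel_size_nm") <- px
  attr(img, "origin_nm") <- bounds[1:2]
  img
}

# bilinear sample of img (matrix, pixel pitch a, origin o) at nm points;
# pixel centers at ((j+0.5)a, (i+0.5)a) + origin; clamped at the edges
bilinear_sample <- function(img, a, origin, x_nm, y_nm) {
  u <- (x_nm - origin[1]) / a - 0.5
  v <- (y_nm - origin[2]) / a - 0.5
  nh <- nrow(img); nw <- ncol(img)
  u <- pmin(pmax(u, 0), nw - 1)
  v <- pmin(pmax(v, 0), nh - 1)
  j0 <- pmin(floor(u), nw - 2 + (nw == 1)); j1 <- pmin(j0 + 1, nw - 1)
  i0 <- pmin(floor(v), nh - 2 + (nh == 1)); i1 <- pmin(i0 + 1, nh - 1)
  fu <- u - j0; fv <- v - i0
  img[cbind(i0 + 1, j0 + 1)] * (1 - fu) * (1 - fv) +
    img[cbind(i0 + 1, j1 + 1)] * fu * (1 - fv) +
    img[cbind(i1 + 1, j0 + 1)] * (1 - fu) * fv +
    img[cbind(i1 + 1, j1 + 1)] * fu * fv
}

#' Overlay a wide-field channel on a super-resolution image
#'
#' Resamples the wide-field image onto the super-resolution grid by
#' bilinear interpolation so both channels share pixel coordinates (e.g. a
#' GFP-exosome channel on top of the reconstruction).
#'
#' @param widefield Intensity matrix of the wide-field channel.
#' @param wf_pixel_nm Wide-field pixel pitch (nm).
#' @param wf_origin_nm \code{c(x, y)} nm of the wide-field top-left corner.
#' @param sr_image A rendering from \code{\link{render_smlm}} (carries its
#'   own georeference attributes).
#' @return List with \code{sr} and \code{widefield}, two aligned matrices
#'   on the SR grid.
#' @export
overlay_widefield <- function(widefield, wf_pixel_nm, wf_origin_nm = c(0, 0),
                              sr_image) {
  a_sr <- attr(sr_image, "pixel_size_nm")
  o_sr <- attr(sr_image, "origin_nm")
  if (is.null(a_sr) || is.null(o_sr))
    stop("sr_image lacks georeference attributes (use render_smlm output)")
  wf_xmax <- wf_origin_nm[1] + ncol(widefield) * wf_pixel_nm
  wf_ymax <- wf_origin_nm[2] + nrow(widefield) * wf_pixel_nm
  sr_xmax <- o_sr[1] + ncol(sr_image) * a_sr
  sr_ymax <- o_sr[2] + nrow(sr_image) * a_sr
  if (wf_xmax <= o_sr[1] || wf_origin_nm[1] >= sr_xmax ||
      wf_ymax <= o_sr[2] || wf_origin_nm[2] >= sr_ymax)
    stop("wide-field and super-resolution extents do not overlap")
  nh <- nrow(sr_image); nw <- ncol(sr_image)
  xc <- o_sr[1] + (seq_len(nw) - 0.5) * a_sr
  yc <- o_sr[2] + (seq_len(nh) - 0.5) * a_sr
  X <- matrix(xc, nh, nw, byrow = TRUE)
  Y <- matrix(yc, nh, nw)
  wf_res <- matrix(bilinear_sample(widefield, wf_pixel_nm, wf_origin_nm,
                                   as.vector(X), as.vector(Y)), nh, nw)
  list(sr = sr_image, widefield = wf_res)
}
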