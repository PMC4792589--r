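#' Image stack of camera frames
#'
#' A T x H x W array of nonnegative camera counts (or photons, after
#' conversion) with the object-plane pixel pitch and integration time.
#' Frame \code{t} is \code{frames(stack)[t, , ]}.
#'
#' @param frames Numeric array with dim \code{c(T, H, W)}, all values >= 0,
#'   or a single H x W matrix (treated as T = 1).
#' @param pixel_size_nm Object-plane pixel pitch in nm (> 0).
#' @param integration_time_ms Per-frame integration time in ms.
#' @param units Either "counts" or "photons".
#' @return An object of class \code{image_stack}.
#' @export
image_stack <- function(frames, pixel_size_nm = 100, integration_time_ms = 50,
                        units = c("counts", "photons")) {
  units <- match.arg(units)
  if (is.matrix(frames))
    frames <- array(frames, dim = c(1L, nrow(frames), ncol(frames)))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a T x H x W array")
  if (dim(frames)[1] < 1L)
    stop("stack must contain at least one frame")
  if (anyNA(frames) || any(frames < 0))
    stop("frame values must be nonnegative and finite")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be > 0")
  structure(list(frames = frames,
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 integration_time_ms = as.numeric(integration_time_ms),
                 units = units),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frame(s) of %d x %d px (%s), pixel %g nm, %g ms/frame\n",
              d[1], d[2], d[3], x$units, x$pixel_size_nm, x$integration_time_ms))
  invisible(x)
}

#' @rdname image_stack
#' @param stack An \code{image_stack}.
#' @export
n_frames <- function(stack) dim(stack$frames)[1]

#' Read a multi-page grayscale TIFF as an image stack
#'
#' Pages are loaded in file order as acquisition frames. Pixel values are
#' returned as raw integer counts.
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @param pixel_size_nm Object-plane pixel pitch in nm (TIFF files written by
#'   \code{\link{write_stack}} do not carry it; supply or keep the default).
#' @param integration_time_ms Per-frame integration time in ms.
#' @return An \code{\link{image_stack}}.
#' @export
read_stack <- function(path, pixel_size_nm = 100, integration_time_ms = 50) {
  if (!file.exists(path))
    stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) != 2L)
      stop("not a grayscale TIFF (multi-channel page found): ", path)
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("ragged TIFF pages (frame sizes differ): ", path)
  arr <- array(0, dim = c(length(pages), dims[1, 1], dims[2, 1]))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]
  image_stack(arr, pixel_size_nm = pixel_size_nm,
              integration_time_ms = integration_time_ms)
}

#' Write an image stack as a 16-bit multi-page grayscale TIFF
#'
#' @param stack An \code{\link{image_stack}} with integer-valued counts in
#'   [0, 65535]; values are rounded to the nearest integer.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  fr <- round(stack$frames)
  if (any(fr < 0) || any(fr > 65535))
    stop("counts outside the 16-bit range [0, 65535]")
  pages <- lapply(seq_len(dim(fr)[1]), function(t) fr[t, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read / write a single-frame grayscale image (TIFF or PNG)
#'
#' Wide-field reference images and label masks travel as single-page
#' grayscale TIFF or PNG. Values are returned as raw integers.
#'
#' @param path Input path; format chosen by extension (.tif/.tiff/.png).
#' @return An integer-valued matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    round(png::readPNG(path) * 65535)
  } else {
    tiff::readTIFF(path, as.is = TRUE)
  }
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1]
  if (length(dim(img)) != 2L)
    stop("not a single-channel grayscale image: ", path)
  img
}

#' @rdname read_image
#' @param img Integer-valued matrix in [0, 65535].
#' @export
write_image <- function(img, path) {
  stopifnot(is.matrix(img))
  img <- round(img)
  if (any(img < 0) || any(img > 65535))
    stop("values outside the 16-bit range [0, 65535]")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 65535, path)
  } else {
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Write / read a float image as 32-bit TIFF
#'
#' 32-bit float TIFF storage (as written here) holds values in [0, 1], so
#' the image is stored divided by its maximum (linear scaling only);
#' \code{read_float_image} returns the normalized image. Quantitative
#' values live in the in-memory matrices and the CSV/JSON outputs.
#'
#' @param img Numeric matrix (e.g. a super-resolution rendering).
#' @param path Output path.
#' @export
write_float_image <- function(img, path) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  scale <- max(img, 0)
  if (scale == 0) scale <- 1
  tiff::writeTIFF(pmax(img, 0) / scale, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_float_image
#' @export
read_float_image <- function(path) {
  tiff::readTIFF(path)
}
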