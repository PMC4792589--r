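#' EMCCD camera model
#'
#' Describes how camera counts relate to detected photons on an
#' electron-multiplying CCD: \code{counts = offset + counts_per_photon *
#' photons + noise}. \code{counts_per_photon} is the combined EM gain times
#' the analog-to-digital conversion, so a single number covers the gain
#' range the acquisition used.
#'
#' @param offset_counts Camera baseline (counts), >= 0.
#' @param counts_per_photon Combined gain x conversion (counts/photon), > 0.
#' @param read_noise_counts Gaussian readout noise sd (counts), >= 0.
#' @return An object of class \code{camera_model}.
#' @examples
#' cam <- camera_model(offset_counts = 100, counts_per_photon = 10)
#' @export
camera_model <- function(offset_counts = 100, counts_per_photon = 10,
                         read_noise_counts = 2) {
  stopifnot(is.numeric(offset_counts), length(offset_counts) == 1L,
            is.numeric(counts_per_photon), length(counts_per_photon) == 1L,
            is.numeric(read_noise_counts), length(read_noise_counts) == 1L)
  if (counts_per_photon <= 0)
    stop("counts_per_photon must be > 0")
  if (offset_counts < 0)
    stop("offset_counts must be >= 0")
  if (read_noise_counts < 0)
    stop("read_noise_counts must be >= 0")
  structure(list(offset_counts = as.numeric(offset_counts),
                 counts_per_photon = as.numeric(counts_per_photon),
                 read_noise_counts = as.numeric(read_noise_counts)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> offset=%g counts, gain=%g counts/photon, read noise=%g counts\n",
              x$offset_counts, x$counts_per_photon, x$read_noise_counts))
  invisible(x)
}
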