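#' Compartment label masks
#'
#' A label image partitioning the field of view into extracellular (0),
#' nucleus (1) and cytoplasm+membrane (2), with the mapping from nm
#' coordinates to mask pixels. Any nm point outside the mask footprint maps
#' to label 0 (extracellular).
#'
#' @param mask Integer matrix with values in \{0, 1, 2\}.
#' @param pixel_size_nm Mask pixel pitch in nm (> 0).
#' @param origin_nm \code{c(x, y)} nm position of the mask's top-left corner.
#' @return An object of class \code{region_set}.
#' @export
region_set <- function(mask, pixel_size_nm, origin_nm = c(0, 0)) {
  stopifnot(is.matrix(mask), length(origin_nm) == 2)
  if (!all(mask %in% c(0, 1, 2)))
    stop("mask labels must be in {0, 1, 2}")
  if (pixel_size_nm <= 0)
    stop("pixel_size_nm must be > 0")
  structure(list(mask = matrix(as.integer(mask), nrow(mask), ncol(mask)),
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 origin_nm = as.numeric(origin_nm)),
            class = "region_set")
}

#' Look up compartment labels at nm positions
#'
#' @param regions A \code{\link{region_set}}.
#' @param x_nm,y_nm Coordinates in nm.
#' @return Integer labels (0 extracellular, 1 nucleus, 2 cytoplasm+membrane);
#'   points outside the mask footprint get 0.
#' @export
region_label_at <- function(regions, x_nm, y_nm) {
  stopifnot(inherits(regions, "region_set"))
  a <- regions$pixel_size_nm
  j <- floor((x_nm - regions$origin_nm[1]) / a)
  i <- floor((y_nm - regions$origin_nm[2]) / a)
  lab <- integer(length(x_nm))
  inside <- i >= 0 & i < nrow(regions$mask) & j >= 0 & j < ncol(regions$mask)
  lab[inside] <- regions$mask[cbind(i[inside] + 1L, j[inside] + 1L)]
  lab
}

#' Area of a region set's cellular footprint
#'
#' @param regions A \code{\link{region_set}}.
#' @param labels Labels counted as "cell" (default nucleus plus cytoplasm).
#' @return Area in square micrometers.
#' @export
region_area_um2 <- function(regions, labels = c(1L, 2L)) {
  stopifnot(inherits(regions, "region_set"))
  sum(regions$mask %in% labels) * (regions$pixel_size_nm / 1000)^2
}

#' Read / write a compartment mask image
#'
#' Masks are stored as single-page grayscale TIFF or PNG holding the raw
#' labels 0/1/2.
#'
#' @param path Image path (.tif/.tiff/.png).
#' @param pixel_size_nm,origin_nm Georeference of the mask (not stored in
#'   the image file).
#' @export
read_mask <- function(path, pixel_size_nm, origin_nm = c(0, 0)) {
  region_set(read_image(path), pixel_size_nm, origin_nm)
}

#' @rdname read_mask
#' @param regions A \code{\link{region_set}}.
#' @export
write_mask <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  write_image(regions$mask, path)
}
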