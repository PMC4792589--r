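#' Upscale a label mask by bilinear interpolation
#'
#' Each label's indicator image is bilinearly interpolated by an integer
#' factor and every output pixel takes the label whose interpolated
#' indicator is largest (ties go to the lower label), which smooths
#' compartment boundaries drawn on a coarse wide-field grid. Factor 1 is
#' the identity.
#'
#' @param mask Integer label matrix (values in \{0, 1, 2\}).
#' @param factor Integer upscale factor, >= 1.
#' @return An upscaled label matrix of size \code{dim(mask) * factor}.
#' @export
upscale_mask <- function(mask, factor) {
  stopifnot(is.matrix(mask))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(mask)
  nh <- nrow(mask) * factor
  nw <- ncol(mask) * factor
  # output pixel centers in input pixel units (input pixel pitch = 1)
  xo <- (seq_len(nw) - 0.5) / factor
  yo <- (seq_len(nh) - 0.5) / factor
  X <- matrix(xo, nh, nw, byrow = TRUE)
  Y <- matrix(yo, nh, nw)
  labels <- sort(unique(as.vector(mask)))
  best_val <- matrix(-Inf, nh, nw)
  best_lab <- matrix(labels[1], nh, nw)
  for (l in labels) {
    ind <- matrix(as.numeric(mask == l), nrow(mask), ncol(mask))
    val <- matrix(bilinear_sample(ind, 1, c(0, 0), as.vector(X), as.vector(Y)),
                  nh, nw)
    better <- val > best_val  # strict: ties keep the lower (earlier) label
    best_val[better] <- val[better]
    best_lab[better] <- l
  }
  storage.mode(best_lab) <- "integer"
  best_lab
}

#' Assign localizations to compartments
#'
#' Labels every localization by the compartment mask pixel containing it
#' (points outside the mask footprint count as extracellular) and tallies
#' the three compartments. Counts always sum to the table size.
#'
#' @param table A \code{\link{localization_table}}.
#' @param regions A \code{\link{region_set}}.
#' @return A list of class \code{compartment_counts}: \code{labels}
#'   (0 extracellular / 1 nucleus / 2 cytoplasm per localization),
#'   \code{n_nucleus}, \code{n_cytoplasm}, \code{n_extracellular},
#'   \code{fractions} (named, summing to 1 for a nonempty table).
#' @export
assign_compartments <- function(table, regions) {
  stopifnot(inherits(table, "localization_table"),
            inherits(regions, "region_set"))
  lab <- region_label_at(regions, table$x_nm, table$y_nm)
  n <- nrow(table)
  counts <- c(extracellular = sum(lab == 0L),
              nucleus = sum(lab == 1L),
              cytoplasm = sum(lab == 2L))
  structure(list(labels = lab,
                 n_nucleus = unname(counts["nucleus"]),
                 n_cytoplasm = unname(counts["cytoplasm"]),
                 n_extracellular = unname(counts["extracellular"]),
                 fractions = if (n > 0) counts / n else counts * NA_real_),
            class = "compartment_counts")
}

#' @export
print.compartment_counts <- function(x, ...) {
  cat(sprintf("<compartment_counts> nucleus=%d cytoplasm=%d extracellular=%d\n",
              x$n_nucleus, x$n_cytoplasm, x$n_extracellular))
  invisible(x)
}

# 8-connected component labeling of a logical matrix (iterative flood fill)
connected_components <- function(bin) {
  nh <- nrow(bin); nw <- ncol(bin)
  comp <- matrix(0L, nh, nw)
  cur <- 0L
  todo <- which(bin)
  for (start in todo) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    comp[start] <- cur
    while (length(stack) > 0) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- (p - 1L) %% nh + 1L
      j <- (p - 1L) %/% nh + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1L || ii > nh || jj < 1L || jj > nw) next
        q <- (jj - 1L) * nh + ii
        if (bin[q] && comp[q] == 0L) {
          comp[q] <- cur
          stack <- c(stack, q)
        }
      }
    }
  }
  comp
}

#' Detect exosome spots in a wide-field GFP image
#'
#' Thresholds the image at \code{median + threshold_sigmas * robust sd}
#' (robust sd = 1.4826 * MAD), takes 8-connected components of at least
#' \code{min_area_px} pixels, and reports each component's
#' intensity-weighted centroid (background-subtracted weights) and
#' equivalent-circle radius.
#'
#' @param gfp_image Intensity matrix.
#' @param pixel_size_nm Pixel pitch (nm).
#' @param origin_nm \code{c(x, y)} nm of the image top-left corner.
#' @param threshold_sigmas Threshold in robust sds above the median.
#' @param min_area_px Minimum component area in pixels.
#' @return A list of class \code{exosome_spots}: \code{centers_nm} (m x 2),
#'   \code{radii_nm}, \code{areas_px}, \code{n_spots}.
#' @export
detect_exosome_spots <- function(gfp_image, pixel_size_nm = 100,
                                 origin_nm = c(0, 0), threshold_sigmas = 5,
                                 min_area_px = 4) {
  stopifnot(is.matrix(gfp_image))
  med <- median(gfp_image)
  sigma <- mad(gfp_image)
  thr <- med + threshold_sigmas * max(sigma, .Machine$double.eps)
  comp <- connected_components(gfp_image > thr)
  ncomp <- max(comp)
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  areas <- integer(0)
  for (cid in seq_len(ncomp)) {
    idx <- which(comp == cid, arr.ind = TRUE)
    if (nrow(idx) < min_area_px) next
    w <- gfp_image[idx] - med
    w <- pmax(w, .Machine$double.eps)
    # pixel centers: ((j - 0.5) * a, (i - 0.5) * a) for 1-based (i, j)
    cx <- origin_nm[1] + sum((idx[, 2] - 0.5) * w) / sum(w) * pixel_size_nm
    cy <- origin_nm[2] + sum((idx[, 1] - 0.5) * w) / sum(w) * pixel_size_nm
    centers <- rbind(centers, c(cx, cy))
    radii <- c(radii, sqrt(nrow(idx) / pi) * pixel_size_nm)
    areas <- c(areas, nrow(idx))
  }
  structure(list(centers_nm = centers, radii_nm = radii, areas_px = areas,
                 n_spots = nrow(centers)),
            class = "exosome_spots")
}

#' Co-localization of localizations with exosome spots
#'
#' A localization co-localizes with a spot when it lies within
#' \code{spot radius + match_radius_nm} of the spot center; each
#' co-localized molecule is assigned to the nearest qualifying spot. The
#' per-fraction readout is the total number of co-localized molecule
#' signals normalized to the number of detected exosome spots.
#'
#' @param table A \code{\link{localization_table}}.
#' @param spots An \code{\link{detect_exosome_spots}} result.
#' @param match_radius_nm Matching tolerance beyond the spot radius (nm).
#' @return List with \code{per_spot} (counts per spot),
#'   \code{n_colocalized}, \code{coloc_fraction} (of the table),
#'   \code{mean_per_exosome} (NA when there are no spots), and
#'   \code{assignment} (per-localization spot index, 0 when unassigned).
#' @export
coloc_counts <- function(table, spots, match_radius_nm = 50) {
  stopifnot(inherits(table, "localization_table"),
            inherits(spots, "exosome_spots"))
  if (match_radius_nm <= 0) stop("match_radius_nm must be > 0")
  n <- nrow(table)
  m <- spots$n_spots
  if (m == 0) {
    return(list(per_spot = integer(0), n_colocalized = 0L,
                coloc_fraction = if (n > 0) 0 else NA_real_,
                mean_per_exosome = NA_real_,
                assignment = integer(n)))
  }
  assignment <- integer(n)
  if (n > 0) {
    dx <- outer(table$x_nm, spots$centers_nm[, 1], "-")
    dy <- outer(table$y_nm, spots$centers_nm[, 2], "-")
    d <- sqrt(dx^2 + dy^2)
    lim <- matrix(spots$radii_nm + match_radius_nm, n, m, byrow = TRUE)
    qual <- d <= lim
    for (r in seq_len(n)) {
      ok <- which(qual[r, ])
      if (length(ok) > 0)
        assignment[r] <- ok[which.min(d[r, ok])]
    }
  }
  per_spot <- tabulate(assignment[assignment > 0], nbins = m)
  n_col <- sum(assignment > 0)
  list(per_spot = per_spot, n_colocalized = n_col,
       coloc_fraction = if (n > 0) n_col / n else NA_real_,
       mean_per_exosome = n_col / m,
       assignment = assignment)
}
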