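#' Measure fluorophore-pair separations from localizations
#'
#' Resolution validation against a nanoruler standard: repeated
#' localizations of each fluorophore are grouped into binding sites by
#' density clustering with a small radius, each site is summarized by its
#' centroid, and sites are paired by mutual nearest neighbours (a site pairs
#' with its nearest other site only if the choice is reciprocal and within
#' \code{max_separation_nm}). The mean measured separation over mutual
#' pairs estimates the design separation of the standard; the measurement
#' uses only the localization table, never the simulated ground truth.
#'
#' @param table A \code{\link{localization_table}} from a nanoruler
#'   acquisition.
#' @param group_radius_nm Clustering radius used to group repeated
#'   localizations of one fluorophore (nm); should be well below the design
#'   separation and above the localization precision.
#' @param group_min_neighbors Minimum neighbours for the grouping (sites
#'   need at least \code{group_min_neighbors + 1} localizations).
#' @param max_separation_nm Pairs farther apart than this are not
#'   considered mutual partners.
#' @return List with \code{separations_nm} (one per mutual pair),
#'   \code{mean_separation_nm}, \code{n_pairs}, \code{n_sites}, and
#'   \code{site_centers_nm}.
#' @export
measure_pair_separations <- function(table, group_radius_nm = 15,
                                     group_min_neighbors = 1,
                                     max_separation_nm = 100) {
  stopifnot(inherits(table, "localization_table"))
  res <- density_cluster(table, cluster_params(group_radius_nm,
                                               group_min_neighbors))
  ids <- sort(unique(res$labels[res$labels >= 0L]))
  if (length(ids) < 2)
    return(list(separations_nm = numeric(0), mean_separation_nm = NA_real_,
                n_pairs = 0L, n_sites = length(ids),
                site_centers_nm = matrix(numeric(0), 0, 2)))
  centers <- t(vapply(ids, function(id) {
    m <- res$labels == id
    c(mean(table$x_nm[m]), mean(table$y_nm[m]))
  }, numeric(2)))
  d <- as.matrix(dist(centers))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  seps <- numeric(0)
  for (i in seq_along(ids)) {
    j <- nn[i]
    if (j > i && nn[j] == i && d[i, j] <= max_separation_nm)
      seps <- c(seps, d[i, j])
  }
  list(separations_nm = seps,
       mean_separation_nm = if (length(seps)) mean(seps) else NA_real_,
       n_pairs = length(seps), n_sites = length(ids),
       site_centers_nm = centers)
}
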