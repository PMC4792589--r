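# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's code paths: full distance matrices,
# union-find, and direct definitions.

# O(n^2) DBSCAN oracle: neighbour counts from the full distance matrix,
# union-find over core points, border points to the nearest core.
# Returns labels -1/-0-based ids ordered by smallest member index.
oracle_dbscan <- function(x, y, eps, k) {
  n <- length(x)
  if (n == 0) return(integer(0))
  d <- as.matrix(dist(cbind(x, y)))
  nbr <- d <= eps
  diag(nbr) <- FALSE
  core <- rowSums(nbr) >= k

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in which(core)) {
    for (j in which(nbr[i, ] & core)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  labels <- rep(-1L, n)
  roots <- vapply(seq_len(n), function(i) if (core[i]) find(i) else NA_integer_,
                  integer(1))
  for (i in which(!core)) {
    cand <- which(nbr[i, ] & core)
    if (length(cand) > 0) {
      j <- cand[order(d[i, cand], cand)][1]
      roots[i] <- roots[j]
    }
  }
  seen <- integer(0)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (is.na(roots[i])) next
    pos <- match(roots[i], seen)
    if (is.na(pos)) {
      seen <- c(seen, roots[i])
      pos <- length(seen)
    }
    labels[i] <- pos - 1L
  }
  labels
}

# brute-force point-in-mask compartment oracle
oracle_compartment <- function(mask, a, origin, x_nm, y_nm) {
  vapply(seq_along(x_nm), function(r) {
    j <- floor((x_nm[r] - origin[1]) / a) + 1
    i <- floor((y_nm[r] - origin[2]) / a) + 1
    if (i < 1 || i > nrow(mask) || j < 1 || j > ncol(mask)) 0L
    else as.integer(mask[i, j])
  }, integer(1))
}

# render a pixel-integrated 2D Gaussian window directly from its definition
# (pnorm differences), independent of the package's internals
oracle_gauss_window <- function(w, x0, y0, N, s, b) {
  gx <- diff(pnorm((0:w - x0) / s))
  gy <- diff(pnorm((0:w - y0) / s))
  b + N * outer(gy, gx)
}

# small helper: a rendered stack with known ground truth, emitters inset
# from the frame border so every event admits a full fitting window
make_test_stack <- function(n_emitters, n_frames, mean_photons,
                            p_on = 0.01, field_px = 50, margin_nm = 500,
                            background = 1, seed = 1) {
  a <- 100
  fov <- field_px * a
  region <- c(margin_nm, margin_nm, fov - margin_nm, fov - margin_nm)
  scene <- sample_csr(n_emitters, region, seed = seed)
  scene <- make_blink_schedule(scene, n_frames, p_on, mean_photons,
                               seed = seed + 1L)
  stack <- render_frames(scene, camera_model(), psf_sigma_nm = 130,
                         stack_shape = c(n_frames, field_px, field_px),
                         pixel_size_nm = a,
                         background_photons_per_px = background,
                         seed = seed + 2L)
  list(scene = scene, stack = stack)
}

# distance from each localization to its nearest true emitter
match_to_truth <- function(table, positions) {
  vapply(seq_len(nrow(table)), function(r) {
    min(sqrt((positions[, 1] - table$x_nm[r])^2 +
             (positions[, 2] - table$y_nm[r])^2))
  }, numeric(1))
}
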