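region5 <- c(0, 0, 5000, 5000)

test_that("CSR sampling is uniform, bounded and reproducible", {
  expect_equal(nrow(sample_csr(0, region5, seed = 1)$positions), 0L)

  sc <- sample_csr(100, region5, seed = 1)
  expect_equal(nrow(sc$positions), 100L)
  expect_true(all(sc$positions[, 1] >= 0 & sc$positions[, 1] <= 5000))
  expect_true(all(sc$positions[, 2] >= 0 & sc$positions[, 2] <= 5000))
  expect_identical(sc$positions, sample_csr(100, region5, seed = 1)$positions)
  expect_error(sample_csr(-1, region5), ">= 0")

  # quadrant occupancy of 1e4 points is compatible with uniformity
  big <- sample_csr(1e4, region5, seed = 7)
  qx <- big$positions[, 1] > 2500
  qy <- big$positions[, 2] > 2500
  counts <- table(factor(paste(qx, qy), levels = c("FALSE FALSE", "FALSE TRUE",
                                                   "TRUE FALSE", "TRUE TRUE")))
  p <- chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.001)
})

test_that("Thomas process obeys its construction", {
  # no parents: pure background, all labels -1
  sc <- sample_thomas(0, 20, 50, background_n = 50, region5, seed = 1)
  expect_equal(nrow(sc$positions), 50L)
  expect_true(all(sc$labels == -1L))

  # Monte-Carlo total count: 10 parents x Poisson(20) offspring, mean 200
  totals <- vapply(1:200, function(s)
    nrow(sample_thomas(10, 20, 50, 0, region5, seed = s)$positions),
    numeric(1))
  # per-scene total ~ Poisson(200); mean of 200 replicates has sd
  # sqrt(200/200) = 1, so a 3-sigma band is +/- 3
  expect_lt(abs(mean(totals) - 200), 3 * sqrt(200 / 200))

  # tight clusters stay tight: sigma 1 nm, well-separated parents
  n_ok <- 0L; n_tot <- 0L
  for (s in 1:20) {
    sc <- sample_thomas(4, 20, 1, 0, c(0, 0, 2e4, 2e4), seed = 100 + s)
    for (id in unique(sc$labels)) {
      pts <- sc$positions[sc$labels == id, , drop = FALSE]
      if (nrow(pts) < 2) next
      n_tot <- n_tot + 1L
      if (max(dist(pts)) < 20) n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok / n_tot, 0.99)
})

test_that("nanoruler pairs sit at the exact design separation", {
  one <- make_nanoruler(1, 35, region5, seed = 1)
  expect_equal(nrow(one$positions), 2L)
  expect_equal(as.numeric(dist(one$positions)), 35, tolerance = 1e-9)

  many <- make_nanoruler(100, 35, c(0, 0, 2e4, 2e4), seed = 2)
  expect_equal(nrow(many$positions), 200L)
  seps <- vapply(seq_len(100), function(p) {
    pts <- many$positions[many$labels == p - 1L, , drop = FALSE]
    as.numeric(dist(pts))
  }, numeric(1))
  expect_equal(seps, rep(35, 100), tolerance = 1e-9)
  # anchors respect the minimum mutual distance
  expect_gte(min(dist(many$anchors)), 5 * 35)
  expect_error(make_nanoruler(100, 35, c(0, 0, 500, 500)), "too small")
})

test_that("pair orientations are uniform on [0, pi)", {
  sc <- make_nanoruler(3000, 35, c(0, 0, 3e5, 3e5), seed = 3)
  p <- suppressWarnings(ks.test(sc$pair_orientation / pi, "punif"))$p.value
  expect_gt(p, 0.001)
})

test_that("blink schedules have binomial event counts and the stated photon law", {
  sc <- sample_csr(100, region5, seed = 1)
  none <- make_blink_schedule(sc, 1000, 0, 2000, seed = 2)
  expect_equal(nrow(none$schedule), 0L)

  on <- make_blink_schedule(sc, 1000, 0.01, 2000, seed = 3)
  # 1e5 Bernoulli trials at p = 0.01: 1000 +/- 3*sqrt(1000)
  expect_lt(abs(nrow(on$schedule) - 1000), 3 * sqrt(1000))
  expect_true(all(on$schedule$photons >= 10))
  expect_true(all(on$schedule$frame >= 0 & on$schedule$frame < 1000))

  # photon mean within 5% at ~1e4 events (truncation adds 10)
  big <- make_blink_schedule(sample_csr(1000, region5, seed = 4),
                             1000, 0.01, 1000, seed = 5)
  expect_gt(nrow(big$schedule), 8000)
  expect_lt(abs(mean(big$schedule$photons) - 1000) / 1000, 0.05)

  # determinism
  again <- make_blink_schedule(sc, 1000, 0.01, 2000, seed = 3)
  expect_identical(on$schedule, again$schedule)
})

test_that("frame rendering reproduces offset, centroid and photon mass", {
  cam <- camera_model(offset_counts = 100, counts_per_photon = 10,
                      read_noise_counts = 0)
  sc <- sample_csr(1, c(1000, 1000, 4000, 4000), seed = 1)

  # empty schedule, no background, no noise: every pixel equals the offset
  empty <- make_blink_schedule(sc, 3, 0, 2000)
  st0 <- render_frames(empty, cam, 130, c(3, 50, 50), noise = FALSE)
  expect_true(all(st0$frames == 100))

  # one huge noiseless event: centroid within 0.02 px of the true position
  sc$schedule <- data.frame(emitter = 0L, frame = 0L, photons = 1e6)
  st1 <- render_frames(sc, cam, 130, c(1, 50, 50), noise = FALSE)
  ph <- (st1$frames[1, , ] - 100) / 10
  jj <- matrix(seq_len(50) - 0.5, 50, 50, byrow = TRUE)
  ii <- matrix(seq_len(50) - 0.5, 50, 50)
  cx <- sum(ph * jj) / sum(ph) * 100
  cy <- sum(ph * ii) / sum(ph) * 100
  expect_lt(abs(cx - sc$positions[1, 1]), 0.02 * 100)
  expect_lt(abs(cy - sc$positions[1, 2]), 0.02 * 100)

  # Poisson photon conservation: total recovered photons match expectation
  sc$schedule <- data.frame(emitter = 0L, frame = 0L, photons = 5000)
  stn <- render_frames(sc, cam, 130, c(1, 50, 50),
                       background_photons_per_px = 2, seed = 9)
  tot <- sum((stn$frames[1, , ] - 100) / 10)
  expectation <- 5000 + 50 * 50 * 2
  expect_lt(abs(tot - expectation), 3 * sqrt(expectation))

  # events outside the frame are dropped with a warning
  far <- synthetic_scene(matrix(c(9e4, 9e4), 1), region = c(0, 0, 1e5, 1e5))
  far$schedule <- data.frame(emitter = 0L, frame = 0L, photons = 1000)
  expect_warning(st <- render_frames(far, cam, 130, c(1, 20, 20)), "dropped")
  expect_equal(attr(st, "n_dropped"), 1L)
})

test_that("compartment masks follow the ellipse geometry", {
  region <- c(0, 0, 4000, 4000)
  nuc <- list(cx = 2000, cy = 2000, rx = 500, ry = 400)
  cell <- list(cx = 2000, cy = 2000, rx = 1500, ry = 1200)
  rs <- make_compartment_masks(region, nuc, cell, mask_pixel_nm = 10)
  expect_identical(region_label_at(rs, 2000, 2000), 1L)
  expect_identical(region_label_at(rs, 100, 100), 0L)
  expect_identical(region_label_at(rs, 2000, 900), 2L)

  # area fractions match the analytic ellipse areas within 1% at 10 nm
  n_px <- length(rs$mask)
  a_nuc <- pi * 500 * 400 / (4000 * 4000)
  a_cell <- pi * 1500 * 1200 / (4000 * 4000)
  expect_lt(abs(mean(rs$mask == 1L) - a_nuc) / a_nuc, 0.01)
  expect_lt(abs(mean(rs$mask %in% c(1L, 2L)) - a_cell) / a_cell, 0.01)

  expect_error(make_compartment_masks(region,
    list(cx = 2000, cy = 2000, rx = 1600, ry = 400), cell), "contained")
})
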