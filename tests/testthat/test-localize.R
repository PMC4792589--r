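test_that("photon conversion inverts the camera model", {
  cam <- camera_model(offset_counts = 100, counts_per_photon = 10,
                      read_noise_counts = 0)
  # counts equal to the offset everywhere -> zero photons
  st <- image_stack(array(100, dim = c(2, 4, 4)))
  expect_true(all(counts_to_photons(st, cam)$frames == 0))
  # forced arithmetic: (200 - 100) / 10 = 10 photons
  st2 <- image_stack(array(200, dim = c(1, 2, 2)))
  expect_true(all(counts_to_photons(st2, cam)$frames == 10))

  # noiseless forward model is recovered exactly (emitters deep inside the
  # frame so no PSF mass is clipped at the border)
  sc <- sample_csr(3, c(1500, 1500, 3500, 3500), seed = 1)
  sc$schedule <- data.frame(emitter = 0:2, frame = c(0L, 1L, 1L),
                            photons = c(3000, 2000, 1500))
  stn <- render_frames(sc, cam, 130, c(2, 50, 50),
                       background_photons_per_px = 1.5, noise = FALSE)
  ph <- counts_to_photons(stn, cam)$frames
  tot <- sum(sc$schedule$photons) + 2 * 50 * 50 * 1.5
  expect_lt(abs(sum(ph) - tot) / tot, 1e-9)
})

test_that("differential stack subtracts succeeding from preceding frames", {
  cam <- camera_model(read_noise_counts = 0)
  const <- image_stack(array(5, dim = c(4, 3, 3)), )
  expect_true(all(differential_stack(const) == 0))
  expect_error(differential_stack(image_stack(matrix(1, 3, 3))), "2 frames")

  # an emitter lit only in frame 1 (0-based) of 3 shows up negative in D[0]
  # and positive in D[1] at its pixels
  f <- array(0, dim = c(3, 9, 9))
  f[2, 4:6, 4:6] <- 10
  st <- image_stack(f, pixel_size_nm = 100)
  D <- differential_stack(st)
  expect_true(all(D[1, 4:6, 4:6] == -10))
  expect_true(all(D[2, 4:6, 4:6] == 10))

  # telescoping: sum over t of D[t] = F[0] - F[T-1], elementwise
  set.seed(3)
  rnd <- image_stack(array(runif(5 * 6 * 6, 0, 50), dim = c(5, 6, 6)))
  D <- differential_stack(rnd)
  expect_equal(apply(D, c(2, 3), sum),
               rnd$frames[1, , ] - rnd$frames[5, , ], tolerance = 1e-12)
})

test_that("spot detection finds isolated peaks and suppresses close pairs", {
  expect_equal(nrow(detect_spots(matrix(0, 20, 20))), 0L)

  cam <- camera_model(read_noise_counts = 0)
  sc <- synthetic_scene(matrix(c(2050, 2450), 1), region = c(0, 0, 5000, 5000))
  sc$schedule <- data.frame(emitter = 0L, frame = 0L, photons = 5000)
  st <- render_frames(sc, cam, 130, c(2, 50, 50), noise = FALSE)
  D <- differential_stack(counts_to_photons(st, cam))
  cand <- detect_spots(D[1, , ], detection_params(threshold_photons = 50))
  expect_equal(nrow(cand), 1L)
  # true pixel: x 2050 nm -> column 20, y 2450 nm -> row 24 (0-based)
  expect_lte(max(abs(cand[1, ] - c(24, 20))), 1)

  # two spots 2 px apart with a 7 px window: suppression leaves one
  two <- synthetic_scene(matrix(c(2050, 2250, 2450, 2450), 2),
                         region = c(0, 0, 5000, 5000))
  two$schedule <- data.frame(emitter = 0:1, frame = 0L, photons = 5000)
  st2 <- render_frames(two, cam, 130, c(2, 50, 50), noise = FALSE)
  D2 <- differential_stack(counts_to_photons(st2, cam))
  cand2 <- detect_spots(D2[1, , ], detection_params(threshold_photons = 50))
  expect_equal(nrow(cand2), 1L)
})

test_that("2D Gaussian fitting recovers noiseless parameters", {
  truth <- list(x0 = 3.37, y0 = 3.81, N = 2500, s = 1.3, b = 2)
  win <- oracle_gauss_window(7, truth$x0, truth$y0, truth$N, truth$s, truth$b)
  fit <- fit_gaussian_2d(win, pixel_size_nm = 100)
  expect_true(fit$converged)
  expect_lt(abs(fit$x0_nm / 100 - truth$x0), 1e-4)
  expect_lt(abs(fit$y0_nm / 100 - truth$y0), 1e-4)
  expect_lt(abs(fit$photons - truth$N) / truth$N, 1e-4)
  expect_lt(abs(fit$psf_sigma_nm / 100 - truth$s), 1e-4)
  expect_lt(abs(fit$background_photons_per_px - truth$b), 1e-4)
  expect_equal(fit$amplitude_photons_per_px,
               fit$photons / (2 * pi * (fit$psf_sigma_nm / 100)^2))

  # mirrored window: x reflects about the window center, y unchanged
  mir <- win[, ncol(win):1]
  fm <- fit_gaussian_2d(mir, pixel_size_nm = 100)
  expect_equal(fm$x0_nm / 100, 7 - truth$x0, tolerance = 1e-4)
  expect_equal(fm$y0_nm / 100, truth$y0, tolerance = 1e-4)

  # flat window: no spot survives (non-convergence or negligible photons)
  flat <- fit_gaussian_2d(matrix(2, 7, 7), pixel_size_nm = 100)
  expect_true(!flat$converged || flat$photons < 200)

  expect_error(fit_gaussian_2d(matrix(0, 5, 7)), "square")
})

test_that("localization precision follows the photon/background law", {
  # direct arithmetic: N=1e4, s=130 nm, a=100 nm, b=0
  expect_equal(localization_precision(1e4, 130, 100, 0),
               sqrt((130^2 + 100^2 / 12) / 1e4), tolerance = 1e-12)
  expect_equal(localization_precision(1e4, 130, 100, 0), 1.332,
               tolerance = 1e-3)
  # b = 0, vanishing pixel: sigma -> s / sqrt(N)
  expect_equal(localization_precision(400, 130, 1e-6, 0), 130 / 20,
               tolerance = 1e-9)
  # strictly decreasing in N
  Ns <- c(100, 300, 1000, 3000, 1e4)
  prec <- localization_precision(Ns, 130, 100, 2)
  expect_true(all(diff(prec) < 0))
  expect_error(localization_precision(0, 130, 100), "> 0")
})

test_that("stack localization recovers sparse blinking events", {
  sim <- make_test_stack(20, 150, 3000, p_on = 0.01, field_px = 40, seed = 21)
  tab <- localize_stack(sim$stack, camera_model(),
                        detection_params(min_photons = 300))
  sched <- sim$scene$schedule
  usable <- sched[sched$photons >= 1000 & sched$frame < 149, ]
  expect_gt(nrow(tab), 0)

  # localizations land on true emitters
  d <- match_to_truth(tab, sim$scene$positions)
  expect_lt(median(d), 15)

  # detection-frame convention: each localization's frame carries a
  # scheduled event of the emitter nearest to it
  frames_ok <- vapply(seq_len(nrow(tab)), function(r) {
    em <- which.min((sim$scene$positions[, 1] - tab$x_nm[r])^2 +
                    (sim$scene$positions[, 2] - tab$y_nm[r])^2) - 1L
    any(sched$emitter == em & sched$frame == tab$frame[r])
  }, logical(1))
  expect_gt(mean(frames_ok), 0.9)

  # large events are nearly all recovered
  rec <- vapply(seq_len(nrow(usable)), function(e) {
    em <- usable$emitter[e] + 1L
    any(tab$frame == usable$frame[e] &
        sqrt((tab$x_nm - sim$scene$positions[em, 1])^2 +
             (tab$y_nm - sim$scene$positions[em, 2])^2) < 100)
  }, logical(1))
  expect_gte(mean(rec), 0.9)
})

test_that("a noise-only stack yields almost no false localizations", {
  sc <- sample_csr(0, c(0, 0, 4000, 4000), seed = 1)
  sc <- make_blink_schedule(sc, 100, 0.01, 2000, seed = 2)
  st <- render_frames(sc, camera_model(), 130, c(100, 40, 40),
                      background_photons_per_px = 1, seed = 3)
  tab <- localize_stack(st, camera_model(), detection_params())
  expect_lte(nrow(tab), 1)
})

test_that("localization summaries are exact sample statistics", {
  tab <- localization_table(data.frame(
    frame = 0:2, x_nm = 1:3, y_nm = 1:3, photons = rep(1000, 3),
    psf_sigma_nm = rep(130, 3), background = rep(1, 3),
    precision_nm = c(10, 12, 14)))
  s <- summarize_localizations(tab)
  expect_equal(s$n, 3L)
  expect_equal(s$mean_precision_nm, 12)
  expect_equal(s$median_precision_nm, 12)

  empty <- summarize_localizations(localization_table())
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean_precision_nm))

  set.seed(8)
  prec <- runif(1e5, 1, 40)
  big <- localization_table(data.frame(
    frame = 0L, x_nm = runif(1e5), y_nm = runif(1e5), photons = 1000,
    psf_sigma_nm = 130, background = 1, precision_nm = prec))
  s2 <- summarize_localizations(big)
  expect_lt(abs(s2$mean_precision_nm - sum(prec) / 1e5), 1e-9)
  sorted <- sort(prec)
  expect_lt(abs(s2$median_precision_nm - (sorted[5e4] + sorted[5e4 + 1]) / 2),
            1e-9)
})
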