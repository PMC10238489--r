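test_that("camera background subtraction clips at zero and runs once", {
  fr <- list(matrix(100, 10, 10), matrix(100, 10, 10))
  mv <- time_lapse_movie(fr, 0.16, 20, 1)
  out <- subtract_camera_background(mv, 100)
  expect_true(all(out$frames[[1]] == 0))
  expect_true(out$background_subtracted)
  expect_error(subtract_camera_background(out, 100), "already")
  # offset 0 is the identity
  same <- subtract_camera_background(mv, 0)
  expect_identical(same$frames, mv$frames)
  expect_error(subtract_camera_background(mv, -1), ">= 0")
})

test_that("subtracting the true offset zeroes the extracellular mode", {
  p <- quick_params(n_frames = 4, midbody_frame = 4, ingression_onset_frame = 2,
                    anaphase_onset_frame = 1, read_noise_sd = 0, seed = 3)
  sim <- simulate_division(p)
  mv <- subtract_camera_background(sim$movie, p$camera_offset)
  border <- mv$frames[[2]][1:3, ]        # guaranteed extracellular margin
  tab <- table(round(border))
  expect_equal(as.numeric(names(tab)[which.max(tab)]), 0)
})

test_that("trace_contour recovers the phantom outline to a pixel", {
  p <- quick_params(read_noise_sd = 0, shot_noise = FALSE, seed = 2,
                    n_frames = 10, midbody_frame = 9)
  sim <- simulate_division(p)
  mv <- subtract_camera_background(sim$movie, p$camera_offset)
  for (f in c(1, 2, 3)) {          # pre-ingression: smooth convex outline
    ct <- trace_contour(mv$frames[[f]])
    d <- divquant:::dist_to_polyline(ct$points[, 1], ct$points[, 2],
                                     sim$truth$contours[[f]])$dist
    expect_lt(max(d), 1)   # Hausdorff, traced -> truth
  }
  # at the furrow fold the iso-contour rounds the sharp corners: the bound
  # there is ~2 px, which none of the linescan-based readouts depend on
  ct7 <- trace_contour(mv$frames[[7]])
  d7 <- divquant:::dist_to_polyline(ct7$points[, 1], ct7$points[, 2],
                                    sim$truth$contours[[7]])$dist
  expect_lt(max(d7), 2)
  expect_error(trace_contour(matrix(0, 40, 40)), "no cell found")
})

test_that("trace_contour on a rendered disk puts the poles a diameter apart", {
  circ <- disk_polygon(c(40, 40), 22)
  fr <- render_frame(circ, c(80, 80), cytoplasm = 120, cortex = 240,
                     band_width_px = 3)
  ct <- trace_contour(fr)
  pole_dist <- sqrt(sum((ct$points[ct$apical, ] - ct$points[ct$basal, ])^2))
  expect_lt(abs(pole_dist - 44), 1)
  # more than one cell-sized region is rejected with the count
  two <- fr
  two[3:15, 55:67] <- 200
  expect_error(trace_contour(two), "2 cell-sized")
})

test_that("pole-to-pole profiles track the rendered cortex model", {
  p <- quick_params(read_noise_sd = 0, shot_noise = FALSE, seed = 6,
                    n_frames = 20, midbody_frame = 18,
                    ingression_onset_frame = 4)
  sim <- simulate_division(p)
  mv <- subtract_camera_background(sim$movie, p$camera_offset)
  f <- 12
  ct <- trace_contour(mv$frames[[f]])
  prof <- pole_to_pole_profile(mv$frames[[f]], ct, side = "right")
  expect_s3_class(prof, "cortical_profile")
  expect_true(all(diff(prof$arclength) > 0))
  expect_gte(length(prof$intensity), 16)
  # argmax of the profile sits at the ring: within 2 samples of the true
  # furrow point on that side
  tfur <- sim$truth$furrow_points[[f]]
  pr <- ct$points[prof$indices, , drop = FALSE]
  d2 <- (pr[, 1] - tfur[2, 1])^2 + (pr[, 2] - tfur[2, 2])^2
  expect_lte(abs(which.max(prof$intensity) - which.min(d2)), 2)
  # width 1 and width 2 agree inside a band wider than 2 px; checked on a
  # uniform-band phantom (no ring bump) where the band is locally flat
  pu <- quick_params(read_noise_sd = 0, shot_noise = FALSE, seed = 6,
                     ring_amplitude = 0, cortical_band_width = 0.8,
                     psf_sigma = 0.05, n_frames = 4, midbody_frame = 4,
                     ingression_onset_frame = 2, anaphase_onset_frame = 1)
  simu <- simulate_division(pu)
  fru <- simu$movie$frames[[2]] - pu$camera_offset
  ctu <- trace_contour(fru)
  p2 <- pole_to_pole_profile(fru, ctu, side = "right", width_px = 2)
  p1 <- pole_to_pole_profile(fru, ctu, side = "right", width_px = 1)
  sel <- seq(round(0.1 * length(p1$intensity)), round(0.9 * length(p1$intensity)))
  expect_lt(max(abs(p1$intensity[sel] - p2$intensity[sel]) /
                  pmax(p2$intensity[sel], 1)), 0.05)
})

test_that("a uniform cortical band gives a flat profile", {
  circ <- disk_polygon(c(40, 40), 22)
  fr <- render_frame(circ, c(80, 80), cytoplasm = 0, cortex = 300,
                     band_width_px = 4)
  ct <- trace_contour(fr)
  prof <- pole_to_pole_profile(fr, ct, side = "left")
  cv <- stats::sd(prof$intensity) / mean(prof$intensity)
  expect_lt(cv, 0.05)
})

test_that("cytoplasm mean reads the generator level inside the eroded mask", {
  p <- quick_params(read_noise_sd = 0, shot_noise = FALSE, seed = 4,
                    cytoplasm_intensity = 50, n_frames = 4, midbody_frame = 4,
                    ingression_onset_frame = 2, anaphase_onset_frame = 1)
  sim <- simulate_division(p)
  mv <- subtract_camera_background(sim$movie, p$camera_offset)
  ct <- trace_contour(mv$frames[[2]])
  expect_lt(abs(cytoplasm_mean(mv$frames[[2]], ct) - 50), 1)
  # zero frame inside the same contour
  expect_equal(cytoplasm_mean(matrix(0, 66, 66), ct), 0)
  # cortex-only phantom: erosion keeps the estimate below 5% of the band
  circ <- disk_polygon(c(33, 33), 20)
  fr0 <- render_frame(circ, c(66, 66), cytoplasm = 0, cortex = 400,
                      band_width_px = 3)
  ct0 <- trace_contour(fr0, threshold = 100)
  expect_lt(cytoplasm_mean(fr0, ct0), 0.05 * 400)
  expect_error(cytoplasm_mean(fr0, ct0, erode_px = 60), "empty")
})

test_that("normalize_profile follows subtract / max-normalise / smooth", {
  mk <- function(v) structure(list(arclength = seq(0, 1, length.out = length(v)),
                                   intensity = v, side = "left", width_px = 2,
                                   state = "raw"), class = "cortical_profile")
  cyto <- 10
  prof <- mk(cyto + c(1, 2, 4, 2, 1))
  out <- normalize_profile(prof, cyto, smooth_k = 0)
  expect_equal(out$intensity, c(0.25, 0.5, 1, 0.5, 0.25))
  expect_equal(max(out$intensity_normalized), 1)
  # smoothing oracle: direct 3-point convolution of the normalised trace
  tri <- mk(cyto + c(1, 2, 3, 4, 5, 4, 3, 2, 1))
  out1 <- normalize_profile(tri, cyto, smooth_k = 1)
  ref <- normalize_profile(tri, cyto, smooth_k = 0)$intensity
  for (i in 2:8) expect_equal(out1$intensity[i], mean(ref[(i - 1):(i + 1)]))
  # flat profile at the cytoplasm level is rejected
  expect_error(normalize_profile(mk(rep(cyto, 20)), cyto), "not positive")
  expect_error(normalize_profile(out, cyto), "already")
})

test_that("cortical enrichment is the ratio-form index and gain invariant", {
  expect_equal(cortical_enrichment(2, 1), 1)
  expect_equal(cortical_enrichment(1, 1), 0)
  expect_error(cortical_enrichment(2, 0), "positive")
  for (gain in c(0.5, 3, 10)) {
    expect_equal(cortical_enrichment(gain * 180, gain * 60),
                 cortical_enrichment(180, 60))
  }
})

test_that("measured enrichment increases with the polar pulse amplitude", {
  # 2-point version of the amplitude sweep (the full sweep is an acceptance
  # criterion); same pipeline, E = 0 vs E = 1
  idx <- vapply(c(0, 1), function(E) {
    p <- quick_params(polar_enrichment_amplitude = E, n_frames = 20,
                      midbody_frame = 18, ingression_onset_frame = 4,
                      seed = 21 + round(E))
    sim <- simulate_division(p)
    mv <- subtract_camera_background(sim$movie, p$camera_offset)
    measure_cortical_enrichment(mv)$index
  }, numeric(1))
  expect_gt(idx[2], idx[1])
})

test_that("cortex-to-furrow ratio handles flat, furrow-bright and ordering cases", {
  mk <- function(v) structure(list(arclength = seq(0, 1, length.out = length(v)),
                                   intensity = v, side = "left", width_px = 2,
                                   state = "raw"), class = "cortical_profile")
  flat <- mk(rep(5, 50))
  expect_equal(cortex_to_furrow_ratio(flat, c(0.4, 0.6)), 1)
  furrowy <- mk(c(rep(1, 20), rep(2, 11), rep(1, 19)))
  expect_equal(cortex_to_furrow_ratio(furrowy, c(0.39, 0.61)), 0.5,
               tolerance = 0.05)
  expect_error(cortex_to_furrow_ratio(flat, c(0.9, 0.1)), "interval")
  expect_error(cortex_to_furrow_ratio(mk(rep(0, 50)), c(0.4, 0.6)),
               "not positive")
  # generator ordering: ring-focused vs spread cortex
  ratio_for <- function(E, amp) {
    p <- quick_params(polar_enrichment_amplitude = E, ring_amplitude = amp,
                      n_frames = 20, midbody_frame = 18,
                      ingression_onset_frame = 4, seed = 5)
    sim <- simulate_division(p)
    mv <- subtract_camera_background(sim$movie, p$camera_offset)
    f <- 16
    ct <- trace_contour(mv$frames[[f]])
    prof <- pole_to_pole_profile(mv$frames[[f]], ct, side = "left")
    seg <- furrow_segment(ct, side = "left")
    cortex_to_furrow_ratio(prof, seg, cyto = cytoplasm_mean(mv$frames[[f]], ct))
  }
  expect_gt(ratio_for(E = 1, amp = 200), ratio_for(E = 0, amp = 400))
})

test_that("left and right profiles of the mirror-symmetric phantom agree", {
  # uniform band (no ring focus): isolates the sampling machinery from arc
  # misalignment on the steep ring-bump slopes
  p <- quick_params(read_noise_sd = 0, shot_noise = FALSE, seed = 8,
                    psf_sigma = 0.11, ring_amplitude = 0,
                    n_frames = 12, midbody_frame = 11,
                    ingression_onset_frame = 3)
  sim <- simulate_division(p)
  mv <- subtract_camera_background(sim$movie, p$camera_offset)
  ct <- trace_contour(mv$frames[[8]])
  pl <- pole_to_pole_profile(mv$frames[[8]], ct, side = "left")
  pr <- pole_to_pole_profile(mv$frames[[8]], ct, side = "right")
  # compare on a common arclength grid
  common <- seq(0.05, 0.95, by = 0.01)
  sm <- function(pp) divquant:::moving_average(pp$intensity, 3)
  il <- approx(pl$arclength, sm(pl), common)$y
  ir <- approx(pr$arclength, sm(pr), common)$y
  expect_lt(stats::median(abs(il - ir) / pmax(il, 1)), 0.02)
})
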