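test_that("percent constriction is anchored, affine and unit invariant", {
  expect_equal(percent_constriction(10, 10, 0.5), 0)
  expect_equal(percent_constriction(0.5, 10, 0.5), 100)
  expect_equal(percent_constriction(5.25, 10, 0.5), 50)
  # affine in d
  d <- seq(0.5, 10, length.out = 7)
  pc <- percent_constriction(d, 10, 0.5)
  expect_equal(diff(pc) / diff(d), rep(-100 / 9.5, 6))
  # consistent unit change (um -> px at 0.16 um/px)
  expect_equal(percent_constriction(5.25 / 0.16, 10 / 0.16, 0.5 / 0.16),
               percent_constriction(5.25, 10, 0.5))
  expect_error(percent_constriction(1, 0.5, 10), "exceed")
  expect_error(percent_constriction(20, 10, 0.5), "tolerance")
  # small overshoots are clipped
  expect_equal(percent_constriction(10.01, 10, 0.5), 0)
})

test_that("convex contours carry no furrow", {
  circ <- as_cell_contour(disk_polygon(c(50, 50), 30, n = 150))
  expect_false(detect_furrow(circ)$detected)
  th <- seq(0, 2 * pi, length.out = 151)[-151]
  ell <- as_cell_contour(cbind(50 + 30 * cos(th), 50 + 15 * sin(th)))
  expect_false(detect_furrow(ell)$detected)
  tiny <- as_cell_contour(disk_polygon(c(5, 5), 2, n = 8))
  expect_error(detect_furrow(tiny), "degenerate")
})

test_that("two-lobe phantom furrow matches the brute-force curvature oracle", {
  for (cfg in list(list(r1 = 25, r2 = 15, gap = 32),
                   list(r1 = 28, r2 = 12, gap = 33),
                   list(r1 = 22, r2 = 18, gap = 30))) {
    tl <- two_lobe_contour(r1 = cfg$r1, r2 = cfg$r2, gap = cfg$gap, n = 200)
    fur <- detect_furrow(tl$contour)
    expect_true(fur$detected)
    pts <- tl$contour$points
    n <- nrow(pts)
    # oracle: most concave sample per lateral half by Menger curvature
    kap <- oracle_curvature(pts, span = 4)
    leftish <- which(pts[, 2] < tl$contour$centroid[2])
    rightish <- which(pts[, 2] >= tl$contour$centroid[2])
    o_l <- leftish[which.min(kap[leftish])]
    o_r <- rightish[which.min(kap[rightish])]
    circ_dist <- function(i, j) min(abs(i - j), n - abs(i - j))
    expect_lte(circ_dist(fur$left_index, o_l), 1)
    expect_lte(circ_dist(fur$right_index, o_r), 1)
    # and both agree with the true neck to within a sample's arc
    arc_per_sample <- divquant:::poly_arclength(pts)$total / n
    expect_lt(sqrt(sum((fur$left - c(tl$neck$row, tl$neck$left))^2)),
              1.5 * arc_per_sample)
    expect_lt(sqrt(sum((fur$right - c(tl$neck$row, tl$neck$right))^2)),
              1.5 * arc_per_sample)
  }
})

test_that("ingression onset is the first frame with a two-sided furrow", {
  p <- quick_params(n_frames = 16, ingression_onset_frame = 6,
                    midbody_frame = 15, seed = 9)
  sim <- simulate_division(p)
  mv <- subtract_camera_background(sim$movie, p$camera_offset)
  contours <- lapply(mv$frames, function(f)
    tryCatch(trace_contour(f), error = function(e) NULL))
  onset <- detect_ingression_onset(contours)
  # the schedule leaves the ring at d0 through frame 6; the first visible
  # pinch is frame 7
  expect_true(onset %in% c(7, 8))
  # all-convex movie: the distinguished no-ingression result
  circs <- replicate(3, as_cell_contour(disk_polygon(c(40, 40), 25, 150)),
                     simplify = FALSE)
  expect_identical(detect_ingression_onset(circs), NA_integer_)
  # ingression already under way in frame 1
  tl <- two_lobe_contour()
  expect_identical(detect_ingression_onset(list(tl$contour, tl$contour)), 1L)
  expect_error(detect_ingression_onset(list(NULL, NULL)), "at least 2")
})

test_that("constriction curves recover a linear schedule", {
  p <- sim_params(seed = 11, read_noise_sd = 0, shot_noise = FALSE)
  sim <- simulate_division(p)
  mv <- subtract_camera_background(sim$movie, p$camera_offset)
  cc <- constriction_curve(mv)
  err <- cc$percent - 100 * sim$truth$constriction
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 3)
  expect_equal(min(cc$percent, na.rm = TRUE), 0)
  expect_gt(max(cc$percent, na.rm = TRUE), 99)
  expect_false(attr(cc, "incomplete"))
  # monotone after isotonic cleanup
  expect_true(all(diff(cc$percent[!is.na(cc$percent)]) >= -1e-9))
  # time axis anchored on anaphase onset
  expect_equal(cc$t_s[p$anaphase_onset_frame], 0)
  # ring diameter tracks the truth within a pixel through mid-constriction
  mid <- which(sim$truth$constriction > 0.15 & sim$truth$constriction < 0.9)
  d_err <- abs(cc$ring_diameter_um[mid] - sim$truth$ring_diameter[mid])
  expect_lt(max(d_err, na.rm = TRUE), p$pixel_size * 1.6)
})

test_that("a movie without ingression is rejected, truncated rings flagged", {
  p <- quick_params(n_frames = 6, ingression_onset_frame = 5, midbody_frame = 6,
                    seed = 13)
  sim <- simulate_division(p)
  mv <- subtract_camera_background(sim$movie, p$camera_offset)
  # drop everything past the first pinch: constriction can never complete
  mv$frames <- mv$frames[1:5]
  short <- time_lapse_movie(mv$frames, mv$pixel_size, mv$frame_interval,
                            mv$anaphase_onset, background_subtracted = TRUE)
  res <- tryCatch(constriction_curve(short), error = function(e) e)
  expect_true(inherits(res, "error") || isTRUE(attr(res, "incomplete")))
  flat <- time_lapse_movie(sim$movie$frames[1:4], 0.2, 20, 2,
                           background_subtracted = TRUE)
  expect_error(constriction_curve(flat), "no ingression")
})

test_that("the cohort average of two identical cells equals either curve", {
  p <- quick_params(seed = 14, n_frames = 14, midbody_frame = 13)
  sim <- simulate_division(p)
  mv <- subtract_camera_background(sim$movie, p$camera_offset)
  cc <- constriction_curve(mv)
  avg <- average_constriction(list(cc, cc), smooth_k = 0)
  keep <- !is.na(cc$percent)
  expect_equal(avg$percent, cc$percent[keep][match(avg$t_s, cc$t_s[keep])])
})

test_that("furrow basal distance is the axial projection in um", {
  tl <- two_lobe_contour(r1 = 25, r2 = 15, gap = 32, z1 = 35)
  fur <- detect_furrow(tl$contour)
  mid <- (fur$left + fur$right) / 2
  bd <- furrow_basal_distance(tl$contour, mid, pixel_size = 0.2)
  truth <- (tl$contour$points[tl$contour$basal, 1] - tl$neck$row) * 0.2
  expect_lt(abs(bd - truth), 0.2)
  # furrow at the basal pole itself projects to zero
  expect_equal(furrow_basal_distance(tl$contour,
                                     tl$contour$points[tl$contour$basal, ], 0.2), 0)
  # flipping the phantom swaps the pole the distance is measured from
  flipped <- tl$contour$points
  flipped[, 1] <- max(flipped[, 1]) + min(flipped[, 1]) - flipped[, 1]
  ctf <- as_cell_contour(flipped[nrow(flipped):1, ])
  furf <- detect_furrow(ctf)
  midf <- (furf$left + furf$right) / 2
  bdf <- furrow_basal_distance(ctf, midf, pixel_size = 0.2)
  truthf <- (ctf$points[ctf$basal, 1] - midf[1]) * 0.2
  expect_lt(abs(bdf - truthf), 0.05)
})

test_that("pipeline recovers the initial furrow basal distance", {
  p <- quick_params(initial_furrow_basal_distance = 2.0, seed = 9)
  sim <- simulate_division(p)
  m <- measure_division(sim$movie, camera_offset = p$camera_offset)
  expect_lt(abs(m$initial_basal_distance_um - 2.0), 0.2)
})

test_that("furrow segment obeys the tangent-angle rule", {
  p <- quick_params(seed = 5, n_frames = 20, midbody_frame = 18,
                    ingression_onset_frame = 4)
  sim <- simulate_division(p)
  mv <- subtract_camera_background(sim$movie, p$camera_offset)
  ct <- trace_contour(mv$frames[[16]])
  seg <- furrow_segment(ct, side = "left", angle_threshold = 30)
  expect_true(seg[1] >= 0 && seg[2] <= 1 && seg[2] > seg[1])
  # the segment contains the furrow point
  fur <- detect_furrow(ct)
  expect_true(fur$left_index %in% attr(seg, "indices"))
  # tighter thresholds shrink the segment toward the furrow point
  seg5 <- furrow_segment(ct, side = "left", angle_threshold = 5)
  expect_lte(diff(seg5), diff(seg))
  expect_error(furrow_segment(ct, side = "left", angle_threshold = 95),
               "between 0 and 90")
  expect_error(furrow_segment(ct, side = "left", angle_threshold = 0),
               "between 0 and 90")
})

test_that("neck elongation widens the furrow readout", {
  # tube-furrow phantom (long parallel-walled throat) vs sharp neck at the
  # same ring diameter schedule
  widths <- vapply(c(0.1, 0.35), function(nt) {
    p <- quick_params(neck_throat = nt, seed = 8, n_frames = 20,
                      midbody_frame = 18, ingression_onset_frame = 4)
    sim <- simulate_division(p)
    mv <- subtract_camera_background(sim$movie, p$camera_offset)
    furrow_width(trace_contour(mv$frames[[14]]), p$pixel_size)
  }, numeric(1))
  expect_gt(widths[2], widths[1])
})
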