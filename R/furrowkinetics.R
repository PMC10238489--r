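# Furrow detection, ingression timing and constriction kinetics.
#
# The furrow is located as the point of maximal concave (inward) membrane
# curvature on each lateral side of the long axis; ingression onset is the
# first frame where both sides carry such a point; ring constriction is
# expressed as a percentage between the anaphase-onset chord (0%) and the
# midbody diameter (100%).

# Signed discrete curvature (1/px) at every contour sample, by algebraic
# (Kasa) circle fit over a centred window. Sign convention: convex (bulging
# outward, like the poles) positive; concave (the furrow neck) negative.
# A light circular moving average (span `presmooth`) suppresses the
# subpixel jitter of refined contours before fitting.
contour_curvature <- function(pts, window = 11, presmooth = 2) {
  n <- nrow(pts)
  if (presmooth > 0) {
    idx <- outer(seq_len(n), -presmooth:presmooth, "+")
    idx <- (idx - 1L) %% n + 1L
    pts <- cbind(rowMeans(matrix(pts[idx, 1], n)),
                 rowMeans(matrix(pts[idx, 2], n)))
  }
  half <- window %/% 2
  kappa <- numeric(n)
  ccw <- poly_signed_area(pts) > 0
  for (i in seq_len(n)) {
    idx <- ((i - half - 1L):(i + half - 1L)) %% n + 1L
    x <- pts[idx, 1]; y <- pts[idx, 2]
    mx <- mean(x); my <- mean(y)
    x <- x - mx; y <- y - my
    A <- cbind(x, y, 1)
    b <- x^2 + y^2
    fit <- tryCatch(qr.solve(A, b), error = function(e) NULL)
    if (is.null(fit)) { kappa[i] <- 0; next }
    cx <- fit[1] / 2; cy <- fit[2] / 2
    r2 <- fit[3] + cx^2 + cy^2
    if (!is.finite(r2) || r2 <= 0) { kappa[i] <- 0; next }
    k <- 1 / sqrt(r2)
    # orientation: tangent x (centre - point) tells which side the centre is on
    tx <- pts[idx[length(idx)], 1] - pts[idx[1], 1]
    ty <- pts[idx[length(idx)], 2] - pts[idx[1], 2]
    px <- pts[i, 1] - mx; py <- pts[i, 2] - my
    cross <- tx * (cy - py) - ty * (cx - px)
    s <- sign(cross)
    if (!ccw) s <- -s
    kappa[i] <- s * k
  }
  kappa
}

#' Detect the cleavage furrow on a cell contour
#'
#' Computes signed discrete curvature (circle fit over `window` samples) and
#' returns, on each lateral side of the long axis, the sample of maximal
#' concave (inward) curvature, provided it exceeds the concavity threshold;
#' a convex contour (circle, ellipse, pre-ingression cell) yields no furrow.
#'
#' @param contour a [trace_contour()] result.
#' @param window circle-fit window (samples).
#' @param kappa_threshold concavity threshold in 1/px; a side qualifies when
#'   its most concave curvature is below `-kappa_threshold`.
#' @return list with `left`, `right` (furrow point coordinates or NULL),
#'   `left_index`, `right_index` (contour sample indices or NULL), and
#'   `detected` (TRUE when both sides carry a furrow point).
#' @export
detect_furrow <- function(contour, window = 11, kappa_threshold = 0.05) {
  stopifnot(inherits(contour, "cell_contour"))
  pts <- contour$points
  if (nrow(pts) <= 8) stop("degenerate contour: 8 or fewer samples")
  n <- nrow(pts)
  kappa <- contour_curvature(pts, window = window)
  # contiguous concave runs on the closed contour (clusters closer than one
  # fit window are merged); the furrow = the two strongest clusters, one on
  # each lateral wall. Axis-free: robust to the ill-conditioned principal
  # axis of a nearly isotropic dumbbell.
  conc <- which(kappa < -kappa_threshold)
  empty <- list(left = NULL, right = NULL, left_index = NULL,
                right_index = NULL, detected = FALSE)
  if (!length(conc)) return(empty)
  clusters <- split(conc, cumsum(c(0, as.numeric(diff(conc) > window))))
  # wrap-around: merge first and last cluster if circularly adjacent
  if (length(clusters) > 1) {
    first <- clusters[[1]]; last <- clusters[[length(clusters)]]
    if ((n - max(last)) + min(first) <= window) {
      clusters[[1]] <- c(last - n, first)   # negative indices, mod later
      clusters[[length(clusters)]] <- NULL
    }
  }
  # single-sample clusters are indistinguishable from curvature noise
  clusters <- Filter(function(cl) length(cl) >= 2, clusters)
  if (!length(clusters)) return(empty)
  # a tube neck traces as two concave corners bridged by a straight throat;
  # the cluster median sits at the throat centre (= the furrow plane), and
  # for a single fold it is the fold centre
  centre <- function(cl) (round(stats::median(cl)) - 1L) %% n + 1L
  strength <- vapply(clusters, function(cl)
    min(kappa[(cl - 1L) %% n + 1L]), numeric(1))
  ord <- order(strength)
  i1 <- centre(clusters[[ord[1]]])
  if (length(clusters) == 1) {
    out <- empty
    if (pts[i1, 2] <= mean(pts[, 2])) {
      out$left <- pts[i1, ]; out$left_index <- i1
    } else {
      out$right <- pts[i1, ]; out$right_index <- i1
    }
    return(out)
  }
  i2 <- centre(clusters[[ord[2]]])
  il <- if (pts[i1, 2] <= pts[i2, 2]) i1 else i2
  ir <- if (pts[i1, 2] <= pts[i2, 2]) i2 else i1
  list(left = pts[il, ], right = pts[ir, ],
       left_index = il, right_index = ir, detected = TRUE)
}

#' Ring diameter from an intensity linescan across the furrow
#'
#' Extracts the intensity profile along the furrow chord (the line through
#' the two furrow points) and returns the separation of the two outermost
#' half-maximum edges -- the outer faces of the cortical band on each wall,
#' i.e. the neck width. The measurement is repeated at small axial offsets
#' (+/- `axial_window` px along the chord perpendicular) and the minimum
#' taken, absorbing the axial localisation error of the curvature maxima.
#' Robust to band merging at late constriction, when the two walls are
#' closer than twice the band width and no cytoplasmic dip remains.
#'
#' @param frame background-subtracted intensity matrix.
#' @param furrow a [detect_furrow()] result with both sides detected (or any
#'   list with `left` and `right` points on the two walls).
#' @param axial_window half-width (px) of the axial scan.
#' @param step profile sampling step (px).
#' @return diameter in pixel units.
#' @export
ring_diameter_px <- function(frame, furrow, axial_window = 1.5, step = 0.25) {
  if (!is.null(furrow$detected) && !isTRUE(furrow$detected))
    stop("furrow not detected on both sides")
  mid <- (furrow$left + furrow$right) / 2
  dir <- furrow$right - furrow$left
  nrm <- sqrt(sum(dir^2))
  if (nrm == 0) return(0)
  dir <- dir / nrm
  perp <- c(-dir[2], dir[1])
  tmax <- nrm / 2 + 8
  ts <- seq(-tmax, tmax, by = step)
  n <- length(ts)
  ext_n <- max(4L, round(3 / step))         # outermost ~3 px = exterior level
  width_at <- function(anchor) {
    v <- bilinear(frame, anchor[1] + ts * dir[1], anchor[2] + ts * dir[2])
    edge <- function(vv) {
      # vv runs from outside toward the midpoint; first rise through the
      # half level between the exterior and the wall peak, constrained to
      # within 4 px of the expected wall position
      ext <- mean(vv[seq_len(ext_n)])
      lvl <- (max(vv) + ext) / 2
      k <- which(vv[-length(vv)] < lvl & vv[-1] >= lvl)
      k <- k[abs((ts[1] + (k - 1) * step) + nrm / 2) <= 4]
      if (!length(k)) return(NA_real_)
      k <- k[1]
      k + (lvl - vv[k]) / (vv[k + 1] - vv[k]) - 1
    }
    eR <- edge(rev(v))                       # from the right end inward
    eL <- edge(v)                            # from the left end inward
    if (is.na(eR) || is.na(eL)) return(NA_real_)
    tR <- ts[n] - eR * step
    tL <- ts[1] + eL * step
    tR - tL
  }
  w <- vapply(seq(-axial_window, axial_window, by = 0.5), function(o)
    width_at(mid + o * perp), numeric(1))
  if (all(is.na(w))) return(nrm)
  min(w, na.rm = TRUE)
}

#' First frame showing inward membrane curvature on both sides
#'
#' @param contours list of [trace_contour()] results (or NULL for frames
#'   where tracing failed), one per movie frame.
#' @param ... passed to [detect_furrow()].
#' @return the 1-based frame index of ingression onset, or `NA_integer_`
#'   (the distinguished "no ingression" result) when no frame qualifies.
#' @export
detect_ingression_onset <- function(contours, ...) {
  valid <- Filter(Negate(is.null), contours)
  if (length(valid) < 2) stop("need valid contours for at least 2 frames")
  for (f in seq_along(contours)) {
    if (is.null(contours[[f]])) next
    if (detect_furrow(contours[[f]], ...)$detected) return(f)
  }
  NA_integer_
}

#' Percentage of ring constriction
#'
#' 0% at the anaphase-onset diameter `d0`, 100% at the midbody diameter
#' `d_mb`, linear in between: 100 (d0 - d) / (d0 - d_mb). `d` slightly
#' outside [d_mb, d0] (within `clip_tol` of the span) is clipped.
#'
#' @param d current ring diameter.
#' @param d0 diameter at anaphase onset.
#' @param d_mb midbody diameter (default convention: 4 px times the pixel
#'   size, the midpoint of the 3-5 px midbody).
#' @param clip_tol clipping tolerance as a fraction of d0 - d_mb.
#' @export
percent_constriction <- function(d, d0, d_mb, clip_tol = 0.05) {
  if (d0 <= d_mb) stop("d0 must exceed the midbody diameter")
  span <- d0 - d_mb
  if (any(d > d0 + clip_tol * span | d < d_mb - clip_tol * span))
    stop("diameter outside [d_mb, d0] beyond the clipping tolerance")
  d <- pmin(pmax(d, d_mb), d0)
  100 * (d0 - d) / span
}

# Chord width of the contour along the line through `point` with direction
# `direction` (defaults to the perpendicular of the long axis): distance
# between the two boundary crossings of that line.
chord_width_at <- function(contour, point, direction = NULL) {
  pts <- contour$points
  if (is.null(direction))
    direction <- c(-contour$long_axis[2], contour$long_axis[1])
  direction <- direction / sqrt(sum(direction^2))
  # signed perpendicular offset of each vertex from the chord line
  s <- (pts[, 1] - point[1]) * direction[2] - (pts[, 2] - point[2]) * direction[1]
  n <- length(s)
  nxt <- c(2:n, 1)
  crossing <- which(s * s[nxt] < 0)
  if (length(crossing) < 2) stop("no chord at the requested axial position")
  cross_pts <- t(vapply(crossing, function(i) {
    j <- nxt[i]
    f <- s[i] / (s[i] - s[j])
    pts[i, ] + f * (pts[j, ] - pts[i, ])
  }, numeric(2)))
  max(stats::dist(cross_pts))
}

# Locate the contractile-ring plane on a pre-ingression frame from the
# cortical intensity maxima (the ring bump) on each lateral side. Returns
# list(left, right) contour points, or NULL when there is no clear ring
# contrast (max < contrast_min x the side's median intensity).
ring_plane_by_intensity <- function(frame, contour, width_px = 2,
                                    smooth_k = 5, contrast_min = 1.2) {
  pts <- contour$points
  n <- nrow(pts)
  idx <- seq_len(n)
  nor <- path_inward_normals(contour, idx)
  offs <- 1.5 + seq_len(width_px) - (width_px + 1) / 2
  acc <- 0
  for (o in offs)
    acc <- acc + bilinear(frame, pts[, 1] + o * nor[, 1], pts[, 2] + o * nor[, 2])
  # circular smoothing over the closed contour
  sm <- outer(idx, -smooth_k:smooth_k, "+")
  sm <- (sm - 1L) %% n + 1L
  v <- rowMeans(matrix((acc / width_px)[sm], n))
  al <- poly_arclength(pts)
  base_lvl <- stats::median(v)
  i1 <- which.max(v)
  if (v[i1] < contrast_min * base_lvl) return(NULL)
  # second wall: intensity maximum at least a quarter perimeter away
  darc <- pmin(abs(al$cum - al$cum[i1]), al$total - abs(al$cum - al$cum[i1]))
  far <- which(darc > al$total / 4)
  i2 <- far[which.max(v[far])]
  if (v[i2] < contrast_min * base_lvl) return(NULL)
  refine <- function(i) {
    # iterated intensity-weighted centroid of the bump in arc (recentring
    # the window makes the estimate independent of noise on the argmax),
    # interpolated back to a point on the contour
    ci <- i
    for (it in 1:3) {
      win <- round(ci) + (-15:15)
      winw <- (win - 1L) %% n + 1L
      wts <- pmax(v[winw] - base_lvl, 0)
      if (sum(wts) == 0) break
      ci <- sum(win * wts) / sum(wts)
    }
    k1 <- (floor(ci) - 1L) %% n + 1L
    k2 <- k1 %% n + 1L
    pts[k1, ] + (ci - floor(ci)) * (pts[k2, ] - pts[k1, ])
  }
  list(left = refine(i1), right = refine(i2))
}

#' Ring constriction curve of a movie
#'
#' Traces the cell in every frame, detects the furrow, converts the
#' furrow-point separation to a ring diameter and expresses it as percent
#' constriction from anaphase onset. `d0` is measured geometrically at the
#' anaphase-onset frame as the cell chord at the eventual furrow axial
#' position (the ring does not exist yet at 0%). The per-cell curve is made
#' monotone by isotonic regression and smoothed with a `smooth_k`-neighbour
#' moving average ("4 neighbours" display convention: `smooth_k = 2`).
#'
#' @param movie a [time_lapse_movie()].
#' @param contours optional pre-traced contours (list, NULL entries allowed).
#' @param midbody_px midbody diameter in pixels (default 4).
#' @param smooth_k smoothing neighbours per side.
#' @param ... passed to [detect_furrow()].
#' @return data.frame with columns `frame`, `t_s` (seconds since anaphase
#'   onset), `ring_diameter_um` (NA before onset), `percent_raw`, `percent`;
#'   attributes `d0_um`, `onset_frame`, `incomplete`.
#' @export
constriction_curve <- function(movie, contours = NULL, midbody_px = 4,
                               smooth_k = 2, ...) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  nf <- length(movie$frames)
  if (is.null(contours))
    contours <- lapply(movie$frames, function(f)
      tryCatch(trace_contour(f), error = function(e) NULL))
  furrows <- lapply(contours, function(ct)
    if (is.null(ct)) NULL else detect_furrow(ct, ...))
  onset <- NA_integer_
  for (f in seq_len(nf)) {
    if (!is.null(furrows[[f]]) && furrows[[f]]$detected) { onset <- f; break }
  }
  if (is.na(onset)) stop("no ingression detected in any frame")
  px <- movie$pixel_size
  if (is.null(contours[[movie$anaphase_onset]]))
    stop("anaphase-onset frame could not be traced")
  # 0% anchor: cell width at the (static) ring plane, located through the
  # nascent ring's intensity maxima and measured on every pre-ingression
  # frame; the median over frames suppresses anchor jitter. No axial
  # minimisation: the pre-furrow cell tapers basally, so the width is wanted
  # exactly at the ring plane. Falls back on the onset furrow points when
  # the ring has no intensity contrast.
  d0_frames <- movie$anaphase_onset:max(movie$anaphase_onset, onset - 1L)
  d0_est <- c()
  for (f0 in d0_frames) {
    if (is.null(contours[[f0]])) next
    r0 <- ring_plane_by_intensity(movie$frames[[f0]], contours[[f0]])
    if (is.null(r0)) next
    d0_est <- c(d0_est, ring_diameter_px(movie$frames[[f0]], r0,
                                         axial_window = 0))
  }
  d0 <- if (length(d0_est)) stats::median(d0_est) * px
  else ring_diameter_px(movie$frames[[movie$anaphase_onset]],
                        list(left = furrows[[onset]]$left,
                             right = furrows[[onset]]$right),
                        axial_window = 0) * px
  d_mb <- midbody_px * px
  d_um <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    fur <- furrows[[f]]
    if (!is.null(fur) && fur$detected)
      d_um[f] <- ring_diameter_px(movie$frames[[f]], fur) * px
  }
  pct <- rep(NA_real_, nf)
  pct[seq_len(nf) < onset] <- 0
  meas <- which(!is.na(d_um))
  pct[meas] <- 100 * pmin(pmax((d0 - d_um[meas]) / (d0 - d_mb), 0), 1)
  known <- which(!is.na(pct))
  iso <- stats::isoreg(known, pct[known])
  pct_mono <- rep(NA_real_, nf)
  pct_mono[known] <- iso$yf
  out <- data.frame(frame = seq_len(nf),
                    t_s = (seq_len(nf) - movie$anaphase_onset) * movie$frame_interval,
                    ring_diameter_um = d_um,
                    percent_raw = pct,
                    percent = NA_real_)
  out$percent[known] <- moving_average(pct_mono[known], smooth_k)
  attr(out, "d0_um") <- d0
  attr(out, "onset_frame") <- onset
  reached <- pct_mono[!is.na(pct_mono)]
  attr(out, "incomplete") <- !length(reached) || max(reached) < 99
  out
}

#' Average a cohort of constriction curves
#'
#' Curves are aligned on time since anaphase onset; the cohort mean is taken
#' at time points shared by all cells and smoothed like the per-cell curves.
#'
#' @param curves list of [constriction_curve()] data frames.
#' @param smooth_k smoothing neighbours per side.
#' @export
average_constriction <- function(curves, smooth_k = 2) {
  stopifnot(length(curves) >= 1)
  common <- Reduce(intersect, lapply(curves, function(d) d$t_s[!is.na(d$percent)]))
  if (!length(common)) stop("curves share no time points")
  common <- sort(common)
  m <- vapply(curves, function(d)
    d$percent[match(common, d$t_s)], numeric(length(common)))
  data.frame(t_s = common,
             percent = moving_average(rowMeans(as.matrix(m)), smooth_k))
}

#' Furrow-to-basal-pole distance
#'
#' Projection of (basal pole - furrow midpoint) onto the apical -> basal
#' long axis, converted to micrometres.
#'
#' @param contour a [trace_contour()] result.
#' @param midpoint furrow midpoint (row, col) in pixel coordinates.
#' @param pixel_size um per pixel.
#' @export
furrow_basal_distance <- function(contour, midpoint, pixel_size) {
  stopifnot(inherits(contour, "cell_contour"))
  b <- contour$points[contour$basal, ]
  sum((b - midpoint) * contour$long_axis) * pixel_size
}

#' Furrow segment by the tangent-angle rule
#'
#' The maximal contiguous run of contour samples around the furrow point
#' whose tangent makes an angle below `angle_threshold` degrees with the
#' long axis of the cell (the furrow walls run nearly parallel to the axis).
#'
#' @param contour a [trace_contour()] result with a detectable furrow.
#' @param side lateral side, "left" or "right".
#' @param angle_threshold degrees, in (0, 90).
#' @param ... passed to [detect_furrow()].
#' @return numeric c(lo, hi): the segment as arclength fractions of the
#'   apical -> basal path on that side; attributes `indices` (contour sample
#'   indices) and `width_um` is left to [furrow_width()].
#' @export
furrow_segment <- function(contour, side = c("left", "right"),
                           angle_threshold = 30, ...) {
  side <- match.arg(side)
  if (angle_threshold <= 0 || angle_threshold >= 90)
    stop("angle_threshold must be strictly between 0 and 90 degrees")
  fur <- detect_furrow(contour, ...)
  fi <- fur[[paste0(side, "_index")]]
  if (is.null(fi)) stop("no furrow detected on the ", side, " side")
  # division axis from the furrow chord when both sides are detected (the
  # principal axis of a round cell is unstable); else the contour long axis
  axis <- if (fur$detected) {
    dirf <- fur$right - fur$left
    c(-dirf[2], dirf[1]) / sqrt(sum(dirf^2))
  } else contour$long_axis
  paths <- contour_side_paths(contour)
  idx <- paths[[side]]
  if (!fi %in% idx) idx <- paths[[setdiff(c("left", "right"), side)]]
  pos <- match(fi, idx)
  p <- contour$points[idx, , drop = FALSE]
  n <- length(idx)
  # tangents over a +/-2 sample baseline: single-sample tangents of traced
  # contours are too jittery for a threshold rule
  prev <- p[pmax(seq_len(n) - 2L, 1L), , drop = FALSE]
  nxt <- p[pmin(seq_len(n) + 2L, n), , drop = FALSE]
  tang <- nxt - prev
  len <- sqrt(rowSums(tang^2)); len[len == 0] <- 1
  cosang <- abs((tang[, 1] * axis[1] + tang[, 2] * axis[2]) / len)
  ok <- acos(pmin(cosang, 1)) * 180 / pi < angle_threshold
  lo <- pos; hi <- pos
  if (!ok[pos]) {
    # the furrow sample itself sits at the inflection; keep a point segment
    lo <- hi <- pos
  } else {
    while (lo > 1 && ok[lo - 1]) lo <- lo - 1
    while (hi < n && ok[hi + 1]) hi <- hi + 1
  }
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  out <- c(s[lo], s[hi]) / max(s)
  attr(out, "indices") <- idx[lo:hi]
  attr(out, "path_length_px") <- max(s)
  out
}

#' Arclength width of the furrow
#'
#' Mean arclength extent (um) of the tangent-angle furrow segment over the
#' two lateral sides; the "widened furrow" readout.
#'
#' @inheritParams furrow_segment
#' @param pixel_size um per pixel.
#' @export
furrow_width <- function(contour, pixel_size, angle_threshold = 30, ...) {
  w <- vapply(c("left", "right"), function(s) {
    seg <- furrow_segment(contour, side = s, angle_threshold = angle_threshold, ...)
    diff(seg) * attr(seg, "path_length_px")
  }, numeric(1))
  mean(w) * pixel_size
}
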