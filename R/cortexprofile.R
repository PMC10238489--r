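# Cortical linescan extraction and enrichment indices.
#
# The measurement path mirrors the standard Fiji workflow for cortical
# myosin: camera background subtraction, a 2-pixel wide pole-to-pole line
# along the cortex, cytoplasm subtraction, max normalisation, neighbour
# averaging, and the ratio indices (cortex - cyto)/cyto and
# cortex/furrow built from mean grey values.

#' Subtract the constant camera background from a movie
#'
#' Every pixel is reduced by `offset` and clipped at zero. Refuses to run
#' twice on the same movie.
#'
#' @param movie a [time_lapse_movie()].
#' @param offset camera offset (a.u., >= 0).
#' @return the movie with `background_subtracted = TRUE`.
#' @export
subtract_camera_background <- function(movie, offset) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  if (movie$background_subtracted)
    stop("movie background has already been subtracted")
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset) || offset < 0)
    stop("offset must be a single finite number >= 0")
  movie$frames <- lapply(movie$frames, function(f) pmax(f - offset, 0))
  movie$background_subtracted <- TRUE
  movie
}

#' Trace the cell outline in one frame
#'
#' Finds the largest closed iso-contour of the frame at `threshold`
#' (Otsu's threshold when NULL), lightly smooths it, resamples it to
#' uniform arclength spacing and assigns the apical and basal poles as the
#' two contour points extremal along the principal axis of the enclosed
#' region (apical = the pole nearer row 1).
#'
#' @param frame intensity matrix.
#' @param threshold iso-level separating cell from background; NULL for Otsu.
#' @param n_samples number of uniformly spaced contour samples.
#' @param smooth_span half-width of the circular moving average applied to
#'   the traced coordinates (samples); tames marching-squares jaggies.
#' @param min_area_px closed contours enclosing less area than this are
#'   treated as noise speckles.
#' @param refine if TRUE (default), move each contour sample along its
#'   normal to the subpixel crossing of the local half-maximum edge level,
#'   removing the step-edge localisation bias of the pixel-grid iso-contour.
#' @return object of class `cell_contour`: `points` (n x 2, row/col pixel
#'   coords, counterclockwise), `apical`, `basal` (indices), `long_axis`
#'   (unit vector apical -> basal), `centroid`.
#' @export
trace_contour <- function(frame, threshold = NULL, n_samples = 200,
                          smooth_span = 1, min_area_px = 100, refine = TRUE) {
  stopifnot(is.matrix(frame))
  thr <- if (is.null(threshold)) auto_cell_threshold(frame) else threshold
  cl <- grDevices::contourLines(x = seq_len(nrow(frame)),
                                y = seq_len(ncol(frame)),
                                z = frame, levels = thr)
  closed <- Filter(function(k) {
    length(k$x) > 3 && k$x[1] == k$x[length(k$x)] && k$y[1] == k$y[length(k$y)]
  }, cl)
  areas <- vapply(closed, function(k)
    poly_area(cbind(k$x[-length(k$x)], k$y[-length(k$y)])), numeric(1))
  big <- which(areas >= min_area_px)
  if (length(big) == 0) stop("no cell found above threshold")
  if (length(big) > 1) {
    # a bright band around a dim interior yields nested iso-contours: inner
    # ones are holes of the same region, not extra cells
    outer_of <- function(i) {
      p0 <- c(closed[[i]]$x[1], closed[[i]]$y[1])
      !any(vapply(setdiff(big, i), function(j)
        points_in_polygon(p0[1], p0[2],
                          cbind(closed[[j]]$x, closed[[j]]$y)), logical(1)))
    }
    big <- big[vapply(big, outer_of, logical(1))]
    if (length(big) > 1)
      stop(length(big), " cell-sized regions found above threshold; expected 1")
  }
  k <- closed[[big]]
  pts <- cbind(k$x[-length(k$x)], k$y[-length(k$y)])
  if (smooth_span > 0) {
    n <- nrow(pts)
    idx <- outer(seq_len(n), -smooth_span:smooth_span, "+")
    idx <- (idx - 1L) %% n + 1L
    pts <- cbind(rowMeans(matrix(pts[idx, 1], n)),
                 rowMeans(matrix(pts[idx, 2], n)))
  }
  pts <- resample_closed(pts, n_samples)
  if (poly_signed_area(pts) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  if (refine) pts <- refine_contour_edges(frame, pts)
  mom <- poly_moments(pts)
  ev <- eigen(mom$cov, symmetric = TRUE)
  axis <- ev$vectors[, 1]
  t_proj <- (pts[, 1] - mom$centroid[1]) * axis[1] +
    (pts[, 2] - mom$centroid[2]) * axis[2]
  i_lo <- which.min(t_proj); i_hi <- which.max(t_proj)
  if (pts[i_lo, 1] <= pts[i_hi, 1]) {
    apical <- i_lo; basal <- i_hi
  } else {
    apical <- i_hi; basal <- i_lo
  }
  la <- pts[basal, ] - pts[apical, ]
  la <- la / sqrt(sum(la^2))
  structure(list(points = pts, apical = apical, basal = basal,
                 long_axis = la, centroid = mom$centroid),
            class = "cell_contour")
}

# Midpoint between the extracellular background (median of the frame
# border) and the intracellular level (median of clearly supra-background
# pixels, dominated by the cytoplasm). Robust to a cortex much brighter
# than the cytoplasm, where Otsu would split the cell interior instead.
auto_cell_threshold <- function(frame) {
  border <- c(frame[1:2, ], frame[nrow(frame) - 1:0, ],
              frame[, 1:2], frame[, ncol(frame) - 1:0])
  bg <- stats::median(border)
  spread <- stats::mad(border)
  fg_px <- frame[frame > bg + max(5 * spread, 1e-6)]
  if (!length(fg_px)) stop("no cell found above threshold")
  (bg + stats::median(fg_px)) / 2
}

# Subpixel edge refinement: slide each vertex along its outward normal to
# the crossing of the local half-maximum level between the interior plateau
# (sampled 1-2 px inward) and the extracellular level (2-3 px outward).
refine_contour_edges <- function(frame, pts, search_out = 3, search_in = 2,
                                 step = 0.25) {
  n <- nrow(pts)
  cen <- colMeans(pts)
  prev <- pts[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- pts[c(2:n, 1), , drop = FALSE]
  tang <- nxt - prev
  len <- sqrt(rowSums(tang^2)); len[len == 0] <- 1
  nor <- cbind(-tang[, 2], tang[, 1]) / len
  flip <- (nor[, 1] * (cen[1] - pts[, 1]) + nor[, 2] * (cen[2] - pts[, 2])) > 0
  nor[flip, ] <- -nor[flip, ]                      # now pointing outward
  ts <- seq(-search_in, search_out, by = step)
  prof <- vapply(ts, function(t)
    bilinear(frame, pts[, 1] + t * nor[, 1], pts[, 2] + t * nor[, 2]),
    numeric(n))
  # interior reference = local peak (handles both the dim cytoplasm edge and
  # the bright cortical band); exterior reference = outermost samples
  ins <- apply(prof[, ts <= 0, drop = FALSE], 1, max)
  out <- rowMeans(prof[, ts >= search_out - 1, drop = FALSE])
  lvl <- (ins + out) / 2
  start <- max(which(ts <= -1))
  for (i in seq_len(n)) {
    if (ins[i] <= out[i]) next                     # no outward edge here
    v <- prof[i, ]
    kk <- which(v[-length(v)] >= lvl[i] & v[-1] < lvl[i])
    kk <- kk[kk >= start]
    if (!length(kk)) next
    k <- kk[1]
    fr <- (v[k] - lvl[i]) / (v[k] - v[k + 1])
    tstar <- ts[k] + fr * step
    pts[i, ] <- pts[i, ] + tstar * nor[i, ]
  }
  pts
}

# Contour sample indices of the two pole-to-pole lateral paths.
# Returns list(left = indices, right = indices), each running apical->basal.
contour_side_paths <- function(contour) {
  n <- nrow(contour$points)
  a <- contour$apical; b <- contour$basal
  fwd <- if (a <= b) a:b else c(a:n, 1:b)
  bwd <- if (a <= b) c(a:1, n:b) else a:b
  side_sign <- function(idx) {
    p <- contour$points[idx, , drop = FALSE]
    ap <- contour$points[contour$apical, ]
    s <- contour$long_axis[1] * (p[, 2] - ap[2]) -
      contour$long_axis[2] * (p[, 1] - ap[1])
    mean(s)
  }
  if (side_sign(fwd) >= 0) list(right = fwd, left = bwd)
  else list(right = bwd, left = fwd)
}

# Inward unit normals at given contour sample indices along a path.
path_inward_normals <- function(contour, idx) {
  pts <- contour$points
  n <- length(idx)
  prev <- pts[idx[pmax(seq_len(n) - 1L, 1L)], , drop = FALSE]
  nxt <- pts[idx[pmin(seq_len(n) + 1L, n)], , drop = FALSE]
  tang <- nxt - prev
  len <- sqrt(rowSums(tang^2)); len[len == 0] <- 1
  tang <- tang / len
  nor <- cbind(-tang[, 2], tang[, 1])
  p <- pts[idx, , drop = FALSE]
  to_c <- cbind(contour$centroid[1] - p[, 1], contour$centroid[2] - p[, 2])
  flip <- rowSums(nor * to_c) < 0
  nor[flip, ] <- -nor[flip, ]
  nor
}

#' Pole-to-pole cortical intensity profile
#'
#' Samples the frame along one lateral side of the contour from the apical
#' to the basal pole. At each contour sample the intensity is the mean of
#' `width_px` bilinear samples taken at 0.5, 1.5, ... px along the inward
#' normal, i.e. a `width_px`-pixel wide line hugging the inside of the
#' cortex. Arclength is normalised to [0, 1] (0 = apical pole).
#'
#' @param frame background-subtracted intensity matrix.
#' @param contour a [trace_contour()] result.
#' @param side "left", "right", or "auto" (the side with the higher mean
#'   signal, the default).
#' @param width_px line width in pixels (default 2).
#' @return object of class `cortical_profile` with fields `arclength`,
#'   `intensity`, `side`, `width_px`, `state` ("raw"), `indices` (contour
#'   sample indices) and `path_length_px`.
#' @export
pole_to_pole_profile <- function(frame, contour, side = c("auto", "left", "right"),
                                 width_px = 2) {
  side <- match.arg(side)
  paths <- contour_side_paths(contour)
  sample_path <- function(idx) {
    if (length(idx) < 16) stop("side path has fewer than 16 samples")
    p <- contour$points[idx, , drop = FALSE]
    nor <- path_inward_normals(contour, idx)
    # line centred 1.5 px inside the boundary regardless of width: solidly
    # within the cortical band, clear of the blurred edge ramp
    offs <- 1.5 + seq_len(width_px) - (width_px + 1) / 2
    acc <- 0
    for (o in offs)
      acc <- acc + bilinear(frame, p[, 1] + o * nor[, 1], p[, 2] + o * nor[, 2])
    inten <- acc / width_px
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    structure(list(arclength = s / max(s), intensity = inten, side = NA,
                   width_px = width_px, state = "raw", indices = idx,
                   path_length_px = max(s)),
              class = "cortical_profile")
  }
  if (side == "auto") {
    pl <- sample_path(paths$left); pr <- sample_path(paths$right)
    out <- if (mean(pl$intensity) >= mean(pr$intensity)) {
      pl$side <- "left"; pl
    } else {
      pr$side <- "right"; pr
    }
    return(out)
  }
  out <- sample_path(paths[[side]])
  out$side <- side
  out
}

#' Mean cytoplasmic intensity inside an eroded cell mask
#'
#' Averages the frame over pixels inside the contour whose distance to the
#' boundary is at least `erode_px`, keeping the estimate clear of the
#' cortical band (choose `erode_px` >= cortical band width + 2 px).
#'
#' @param frame intensity matrix.
#' @param contour a [trace_contour()] result (or a raw two-column polygon).
#' @param erode_px erosion depth in pixels (default 5).
#' @export
cytoplasm_mean <- function(frame, contour, erode_px = 5) {
  pts <- if (inherits(contour, "cell_contour")) contour$points else as.matrix(contour)
  rr <- range(pts[, 1]); cc <- range(pts[, 2])
  ri <- max(1, floor(rr[1])):min(nrow(frame), ceiling(rr[2]))
  ci <- max(1, floor(cc[1])):min(ncol(frame), ceiling(cc[2]))
  gr <- as.numeric(outer(ri, rep(1, length(ci))))
  gc <- as.numeric(outer(rep(1, length(ri)), ci))
  inside <- points_in_polygon(gr, gc, pts)
  if (!any(inside)) stop("eroded cytoplasm region is empty")
  d <- dist_to_polyline(gr[inside], gc[inside], pts)$dist
  keep <- d >= erode_px
  if (!any(keep)) stop("eroded cytoplasm region is empty")
  mean(frame[cbind(gr[inside][keep], gc[inside][keep])])
}

#' Normalise a cortical profile for plotting
#'
#' Subtracts the cytoplasm mean, divides by the post-subtraction maximum
#' (so the maximum is exactly 1 before smoothing), then applies a centred
#' moving average with `smooth_k` neighbours per side. Negative values
#' after cytoplasm subtraction are retained.
#'
#' @param profile a raw `cortical_profile`.
#' @param cyto cytoplasm mean intensity to subtract.
#' @param smooth_k neighbours per side in the moving average; 3 reproduces a
#'   7-point ("6 neighbours") average, 0 disables smoothing.
#' @return the profile with `intensity` smoothed-normalised, the
#'   pre-smoothing trace in `intensity_normalized`, and `state` updated.
#' @export
normalize_profile <- function(profile, cyto, smooth_k = 3) {
  stopifnot(inherits(profile, "cortical_profile"))
  if (profile$state != "raw")
    stop("profile has already been normalised (state: ", profile$state, ")")
  v <- profile$intensity - cyto
  m <- max(v)
  if (m <= 0) stop("profile maximum is not positive after cytoplasm subtraction")
  v <- v / m
  profile$intensity_normalized <- v
  profile$intensity <- moving_average(v, smooth_k)
  profile$state <- sprintf("max-normalized+smoothed(%d)", smooth_k)
  profile
}

#' Cortical enrichment index
#'
#' The ratio-form index (cortex - cyto) / cyto computed from the mean grey
#' value of the (polar) cortex and of the cytoplasm; invariant under any
#' positive gain applied to the whole frame.
#'
#' @param cortex_mean,cyto_mean mean intensities (a.u.); `cyto_mean` > 0.
#' @export
cortical_enrichment <- function(cortex_mean, cyto_mean) {
  if (!is.finite(cyto_mean) || cyto_mean <= 0)
    stop("cyto_mean must be positive")
  (cortex_mean - cyto_mean) / cyto_mean
}

#' Measure the polar cortical enrichment index of a movie
#'
#' Runs the full index pipeline: for every candidate frame, traces the cell,
#' samples the cortex with a `width_px`-wide inward line, excludes the
#' furrow segment (tangent within `angle_threshold` degrees of the long
#' axis around the detected furrow points), and takes the polar-cortex mean;
#' the index is computed at the frame where that mean peaks (the moment of
#' maximal polar signal, ~80% ingression for a pulsed phantom), as
#' (cortex - cyto)/cyto with the cytoplasm mean from the same frame.
#'
#' @param movie a background-subtracted [time_lapse_movie()].
#' @param frames candidate frame indices (default: anaphase onset onward).
#' @param cells "both" to average the polar cortex of both nascent cells,
#'   "neuroblast" to restrict to the apical (neuroblast) side of the furrow.
#' @param width_px,erode_px,angle_threshold see
#'   [pole_to_pole_profile()], [cytoplasm_mean()], [furrow_segment()].
#' @return list: `index`, `frame`, `cortex_mean`, `cyto_mean`.
#' @export
measure_cortical_enrichment <- function(movie, frames = NULL,
                                        cells = c("both", "neuroblast"),
                                        width_px = 2, erode_px = 5,
                                        angle_threshold = 30) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  if (!movie$background_subtracted)
    stop("subtract the camera background first")
  cells <- match.arg(cells)
  if (is.null(frames)) frames <- movie$anaphase_onset:length(movie$frames)
  res_all <- lapply(frames, function(f) {
    tryCatch({
      ct <- trace_contour(movie$frames[[f]])
      r <- polar_cortex_mean(movie$frames[[f]], ct, cells = cells,
                             width_px = width_px,
                             angle_threshold = angle_threshold)
      r$frame <- f
      r
    }, error = function(e) NULL)
  })
  res_all <- Filter(Negate(is.null), res_all)
  # read the index during ingression (frames with a detected furrow, where
  # the ring signal can be excluded); pre-onset frames only as a fallback
  with_fur <- Filter(function(r) isTRUE(r$furrow_detected), res_all)
  if (length(with_fur)) res_all <- with_fur
  best <- list(mean = -Inf)
  for (r in res_all) if (r$mean > best$mean) best <- r
  if (!is.finite(best$mean)) stop("no frame could be quantified")
  cyto <- cytoplasm_mean(movie$frames[[best$frame]], best$contour,
                         erode_px = erode_px)
  list(index = cortical_enrichment(best$mean, cyto), frame = best$frame,
       cortex_mean = best$mean, cyto_mean = cyto)
}

# Mean cortical intensity away from the furrow: excludes the tangent-rule
# furrow segment plus an arc neighbourhood of each furrow point (the
# ring-focused signal has Gaussian tails well beyond the geometric furrow),
# optionally restricted to the neuroblast (apical) side.
polar_cortex_mean <- function(frame, contour, cells = "both", width_px = 2,
                              angle_threshold = 30, ring_exclusion = 0.12) {
  n <- nrow(contour$points)
  fur <- detect_furrow(contour)
  excl <- rep(FALSE, n)
  al <- poly_arclength(contour$points)
  for (s in c("left", "right")) {
    fi <- fur[[paste0(s, "_index")]]
    if (is.null(fi)) next
    seg <- tryCatch(furrow_segment(contour, side = s,
                                   angle_threshold = angle_threshold),
                    error = function(e) NULL)
    if (!is.null(seg)) excl[attr(seg, "indices")] <- TRUE
    darc <- pmin(abs(al$cum - al$cum[fi]), al$total - abs(al$cum - al$cum[fi]))
    excl[darc < ring_exclusion * al$total] <- TRUE
  }
  if (cells == "neuroblast" && !is.null(fur$left) && !is.null(fur$right)) {
    mid <- (fur$left + fur$right) / 2
    t_mid <- sum((mid - contour$points[contour$apical, ]) * contour$long_axis)
    t_all <- (contour$points[, 1] - contour$points[contour$apical, 1]) * contour$long_axis[1] +
      (contour$points[, 2] - contour$points[contour$apical, 2]) * contour$long_axis[2]
    excl[t_all > t_mid] <- TRUE
  }
  keep <- which(!excl)
  if (!length(keep)) stop("furrow exclusion left no polar cortex samples")
  nor <- path_inward_normals(contour, seq_len(n))
  offs <- 1.5 + seq_len(width_px) - (width_px + 1) / 2
  acc <- 0
  p <- contour$points[keep, , drop = FALSE]
  for (o in offs)
    acc <- acc + bilinear(frame, p[, 1] + o * nor[keep, 1],
                          p[, 2] + o * nor[keep, 2])
  list(mean = mean(acc / width_px), contour = contour,
       furrow_detected = fur$detected)
}

#' Cortex-to-furrow intensity ratio
#'
#' Ratio of the mean cytoplasm-subtracted profile intensity outside the
#' furrow segment to the mean inside it. Values below 1 indicate a
#' furrow-focused distribution; values near or above 1 indicate cortical
#' spreading.
#'
#' @param profile a `cortical_profile` (raw).
#' @param furrow_segment numeric c(lo, hi) arclength interval in [0, 1]
#'   marking the furrow along the profile (e.g. from [furrow_segment()]).
#' @param cyto cytoplasm mean to subtract (default 0 for pre-subtracted
#'   profiles).
#' @export
cortex_to_furrow_ratio <- function(profile, furrow_segment, cyto = 0) {
  stopifnot(inherits(profile, "cortical_profile"))
  fs <- as.numeric(furrow_segment)
  if (length(fs) != 2 || fs[1] >= fs[2] || fs[1] < 0 || fs[2] > 1)
    stop("furrow_segment must be a nonempty interval within [0, 1]")
  v <- profile$intensity - cyto
  inside <- profile$arclength >= fs[1] & profile$arclength <= fs[2]
  if (!any(inside) || !any(!inside))
    stop("furrow segment leaves no samples on one side")
  mf <- mean(v[inside])
  if (mf <= 0) stop("furrow mean is not positive")
  mean(v[!inside]) / mf
}
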