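# Daughter-cell (GMC) morphometrics: pixel-count area and area/major-axis
# roundness, plus the contour split that isolates the GMC at the end of
# furrow ingression.

#' GMC cross-section area
#'
#' Pixel count times pixel area. Accepts either a logical/numeric region
#' mask or a closed contour polygon (rasterised at pixel centres).
#'
#' @param region logical or 0/1 matrix, or a two-column (row, col) polygon.
#' @param pixel_size um per pixel.
#' @return area in um^2.
#' @export
gmc_area <- function(region, pixel_size) {
  stopifnot(pixel_size > 0)
  if (is.matrix(region) && ncol(region) != 2) {
    n <- sum(region != 0)
    if (n == 0) stop("region is empty")
    return(n * pixel_size^2)
  }
  pts <- as.matrix(region)
  if (nrow(pts) < 3) stop("region is empty")
  rr <- floor(min(pts[, 1])):ceiling(max(pts[, 1]))
  cc <- floor(min(pts[, 2])):ceiling(max(pts[, 2]))
  gr <- as.numeric(outer(rr, rep(1, length(cc))))
  gc <- as.numeric(outer(rep(1, length(rr)), cc))
  n <- sum(points_in_polygon(gr, gc, pts))
  if (n == 0) stop("region is empty")
  n * pixel_size^2
}

#' Roundness from area and major-axis length
#'
#' 4 A / (pi L^2), with L the maximal chord of the region: 1 for a disk,
#' b/a for an ellipse with semi-axes a >= b.
#'
#' @param area region area (um^2).
#' @param length major-axis length (um).
#' @export
gmc_roundness <- function(area, length) {
  stopifnot(area > 0, length > 0)
  4 * area / (pi * length^2)
}

#' Major-axis length of a region
#'
#' Maximal pairwise distance between boundary points (exact scan over the
#' convex hull).
#'
#' @param pts two-column boundary points (pixel coords).
#' @param pixel_size um per pixel.
#' @export
region_major_axis <- function(pts, pixel_size = 1) {
  pts <- as.matrix(pts)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  max(stats::dist(pts[h, , drop = FALSE])) * pixel_size
}

#' Split a dividing-cell contour at the furrow into the GMC sub-polygon
#'
#' Walks the contour between the two furrow points along the side containing
#' the basal pole and closes it with the furrow chord, yielding the nascent
#' GMC outline.
#'
#' @param contour a [trace_contour()] result.
#' @param furrow a [detect_furrow()] result with both sides detected.
#' @return two-column polygon (pixel coords) of the GMC region.
#' @export
gmc_polygon <- function(contour, furrow) {
  if (!isTRUE(furrow$detected)) stop("furrow not detected on both sides")
  n <- nrow(contour$points)
  i1 <- furrow$left_index; i2 <- furrow$right_index
  walk <- function(a, b) if (a <= b) a:b else c(a:n, 1:b)
  p1 <- walk(i1, i2); p2 <- walk(i2, i1)
  # the GMC is the basal lobe; apical renders toward row 1, so basal = the
  # sub-polygon with the larger mean row (robust where the principal-axis
  # pole labels of a nearly isotropic dumbbell are not)
  r1 <- mean(contour$points[p1, 1]); r2 <- mean(contour$points[p2, 1])
  poly_idx <- if (r1 >= r2) p1 else p2
  contour$points[poly_idx, , drop = FALSE]
}

#' Measure one division end to end
#'
#' Convenience pipeline over a single movie: traces every frame, detects
#' ingression onset, measures the furrow basal distance at onset, the
#' constriction curve, and the GMC area and roundness at the final frame;
#' optionally the polar enrichment index.
#'
#' @param movie a [time_lapse_movie()]; the camera background is subtracted
#'   with `camera_offset` if not done yet.
#' @param camera_offset offset to subtract when needed (a.u.).
#' @param enrichment also compute [measure_cortical_enrichment()] (slower).
#' @param midbody_px midbody diameter in pixels.
#' @param ... passed to [detect_furrow()].
#' @return one-row data.frame of division metrics; the constriction curve is
#'   attached as attribute `curve`.
#' @export
measure_division <- function(movie, camera_offset = 0, enrichment = FALSE,
                             midbody_px = 4, ...) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  if (!movie$background_subtracted && camera_offset > 0)
    movie <- subtract_camera_background(movie, camera_offset)
  contours <- lapply(movie$frames, function(f)
    tryCatch(trace_contour(f), error = function(e) NULL))
  curve <- constriction_curve(movie, contours = contours,
                              midbody_px = midbody_px, ...)
  onset <- attr(curve, "onset_frame")
  fur_on <- detect_furrow(contours[[onset]], ...)
  # anchor the furrow plane at onset on the ring's intensity maxima when the
  # ring has contrast (more accurate axially than the shallow-pinch
  # curvature maxima); fall back on the curvature points
  ring_on <- ring_plane_by_intensity(movie$frames[[onset]], contours[[onset]])
  anchor <- if (!is.null(ring_on)) ring_on else fur_on
  mid_on <- (anchor$left + anchor$right) / 2
  # division axis = perpendicular of the furrow chord; the principal axis of
  # a nearly round cell is ill-conditioned, the furrow chord is not
  dir_on <- anchor$right - anchor$left
  dir_on <- dir_on / sqrt(sum(dir_on^2))
  axis_ref <- c(-dir_on[2], dir_on[1])
  ct_onset <- contours[[onset]]
  t_on <- (ct_onset$points[, 1] - mid_on[1]) * axis_ref[1] +
    (ct_onset$points[, 2] - mid_on[2]) * axis_ref[2]
  # basal pole = contour extreme on the furrow-proximal (GMC) side
  basal_dist <- min(abs(min(t_on)), abs(max(t_on))) * movie$pixel_size
  # end of ingression = the last frame with a furrow on both sides (at the
  # midbody stage the neck can fall below the tracing resolution)
  detected <- which(vapply(seq_along(contours), function(f)
    !is.null(contours[[f]]) &&
      detect_furrow(contours[[f]], ...)$detected, logical(1)))
  last <- max(detected)
  ct_last <- contours[[last]]
  fur_last <- detect_furrow(ct_last, ...)
  gmc <- gmc_polygon(ct_last, fur_last)
  area <- gmc_area(gmc, movie$pixel_size)
  roundness <- gmc_roundness(area, region_major_axis(gmc, movie$pixel_size))
  enr <- if (enrichment) measure_cortical_enrichment(movie)$index else NA_real_
  out <- data.frame(onset_frame = onset,
                    initial_basal_distance_um = basal_dist,
                    gmc_area_um2 = area,
                    gmc_roundness = roundness,
                    enrichment_index = enr,
                    constriction_complete = !attr(curve, "incomplete"))
  attr(out, "curve") <- curve
  out
}
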