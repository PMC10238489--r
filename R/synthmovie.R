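# Synthetic dividing-neuroblast phantom generator.
#
# The cell is modelled on a single sagittal plane as a mother circle of
# radius R (apical pole toward row 1, basal pole toward the last row) whose
# outline is pinched at the cleavage-furrow plane. The outline is a
# half-width profile w(z) of the axial coordinate z:
#
#   w(z) = W(z) - (W(zf) - d(t)/2) * phi((z - zf)/sigma_side)
#
# with W(z) the mother-circle half chord, zf the furrow plane, d(t) the ring
# diameter schedule and phi(u) = (1 - u^2)^2 a smooth compact-support bump
# (sigma differs apically/basally, giving the shallow neuroblast shoulder
# and the sharp cap edge of the GMC). The geometry gives closed-form control
# of ring diameter and furrow position and an exact 1-D quadrature for the
# ground-truth GMC area.

#' Simulation parameters for the dividing-neuroblast phantom
#'
#' Builds and validates the parameter set for [simulate_division()]. All
#' lengths are in micrometres, times in seconds, intensities in arbitrary
#' camera units. Defaults emulate a larval neuroblast just above the 11 um
#' diameter observation cut-off, imaged at 20 s per frame on an EMCCD-class
#' camera with constant offset, Poisson shot noise and Gaussian read noise.
#'
#' @param neuroblast_radius mother-cell radius (um); default 5.5 (11 um cell).
#' @param initial_furrow_basal_distance delta0, axial distance from the basal
#'   pole to the furrow plane at ingression onset (um).
#' @param midbody_diameter ring diameter at 100% constriction (um); default
#'   4 pixels (midpoint of the 3-5 px midbody convention).
#' @param n_frames number of frames in the movie.
#' @param frame_interval seconds between frames; default 20.
#' @param pixel_size um per pixel; default 0.16 (100x EMCCD assumption).
#' @param anaphase_onset_frame frame index (1-based) of anaphase onset, the
#'   time origin and the 0% constriction anchor.
#' @param ingression_onset_frame last frame at which the ring is still at its
#'   initial diameter; the diameter then falls linearly to the midbody value.
#' @param midbody_frame frame at which the ring reaches the midbody diameter.
#' @param cortical_band_width width of the cortical myosin band (um).
#' @param neck_sigma_apical,neck_sigma_basal axial half-support of the furrow
#'   pinch on the neuroblast / GMC side (um).
#' @param neck_throat parallel-walled throat half-length as a fraction of
#'   the pinch depth: deep furrows become tubes rather than V grooves, and
#'   larger values give the elongated "tube furrow" phenotype.
#' @param ring_focus_sigma arclength sigma of the ring-focused intensity bump,
#'   as a fraction of the cell perimeter.
#' @param ring_amplitude peak intensity of the ring bump above the cortical
#'   base band (a.u.).
#' @param polar_enrichment_amplitude E, amplitude of the transient polar
#'   myosin enrichment (dimensionless multiple of the base band; 0 disables).
#' @param polar_peak_constriction constriction fraction at which the polar
#'   pulse peaks; default 0.80.
#' @param polar_sigma width of the polar pulse in constriction-fraction units.
#' @param cytoplasm_intensity,cortex_base_intensity,camera_offset intensity
#'   levels (a.u.).
#' @param psf_sigma Gaussian point-spread-function sigma (um); emulates
#'   diffraction blur (default 0.11 um, ~0.7 px at the default pixel size).
#'   0 renders aliased hard edges.
#' @param read_noise_sd Gaussian read-noise s.d. (a.u.); 0 disables.
#' @param shot_noise logical; apply Poisson shot noise to the signal.
#' @param correction_on logical; if TRUE the furrow plane drifts during
#'   constriction so that the final GMC area equals `target_gmc_area`
#'   regardless of delta0 (the wild-type correction); if FALSE the plane
#'   stays at delta0 and GMC size tracks the initial furrow position.
#' @param target_gmc_area target GMC cross-section area (um^2) under
#'   correction; default: the model area for a furrow at 2.5 um.
#' @param margin extracellular margin around the cell (um).
#' @param n_contour number of samples on the ground-truth contour.
#' @param seed integer RNG seed; identical parameter sets and seeds give
#'   byte-identical movies.
#' @return object of class `sim_params` (a validated named list).
#' @export
sim_params <- function(neuroblast_radius = 5.5,
                       initial_furrow_basal_distance = 2.5,
                       midbody_diameter = NULL,
                       n_frames = 30,
                       frame_interval = 20,
                       pixel_size = 0.16,
                       anaphase_onset_frame = 2,
                       ingression_onset_frame = 5,
                       midbody_frame = n_frames - 2,
                       cortical_band_width = 0.5,
                       neck_sigma_apical = 1.2,
                       neck_sigma_basal = 0.35,
                       neck_throat = 0.25,
                       ring_focus_sigma = 0.04,
                       ring_amplitude = 400,
                       polar_enrichment_amplitude = 1,
                       polar_peak_constriction = 0.80,
                       polar_sigma = 0.15,
                       cytoplasm_intensity = 100,
                       cortex_base_intensity = 250,
                       camera_offset = 100,
                       psf_sigma = 0.11,
                       read_noise_sd = 5,
                       shot_noise = TRUE,
                       correction_on = FALSE,
                       target_gmc_area = NULL,
                       margin = 1.0,
                       n_contour = 240,
                       seed = 1L) {
  p <- list(neuroblast_radius = neuroblast_radius,
            initial_furrow_basal_distance = initial_furrow_basal_distance,
            midbody_diameter = if (is.null(midbody_diameter)) 4 * pixel_size else midbody_diameter,
            n_frames = as.integer(n_frames),
            frame_interval = frame_interval,
            pixel_size = pixel_size,
            anaphase_onset_frame = as.integer(anaphase_onset_frame),
            ingression_onset_frame = as.integer(ingression_onset_frame),
            midbody_frame = as.integer(midbody_frame),
            cortical_band_width = cortical_band_width,
            neck_sigma_apical = neck_sigma_apical,
            neck_sigma_basal = neck_sigma_basal,
            neck_throat = neck_throat,
            ring_focus_sigma = ring_focus_sigma,
            ring_amplitude = ring_amplitude,
            polar_enrichment_amplitude = polar_enrichment_amplitude,
            polar_peak_constriction = polar_peak_constriction,
            polar_sigma = polar_sigma,
            cytoplasm_intensity = cytoplasm_intensity,
            cortex_base_intensity = cortex_base_intensity,
            camera_offset = camera_offset,
            psf_sigma = psf_sigma,
            read_noise_sd = read_noise_sd,
            shot_noise = isTRUE(shot_noise),
            correction_on = isTRUE(correction_on),
            target_gmc_area = target_gmc_area,
            margin = margin,
            n_contour = as.integer(n_contour),
            seed = as.integer(seed))
  num <- p[!names(p) %in% c("shot_noise", "correction_on", "target_gmc_area")]
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  lens <- c("pixel_size", "neuroblast_radius",
            "initial_furrow_basal_distance", "midbody_diameter",
            "cortical_band_width", "neck_sigma_apical", "neck_sigma_basal",
            "margin")
  for (nm in lens) if (p[[nm]] <= 0) stop("parameter '", nm, "' must be > 0")
  if (p$polar_enrichment_amplitude < 0)
    stop("parameter 'polar_enrichment_amplitude' must be >= 0")
  if (p$neck_throat < 0)
    stop("parameter 'neck_throat' must be >= 0")
  if (p$polar_peak_constriction < 0 || p$polar_peak_constriction > 1)
    stop("parameter 'polar_peak_constriction' must be in [0, 1]")
  if (p$initial_furrow_basal_distance >= 2 * p$neuroblast_radius)
    stop("initial furrow basal distance exceeds the cell length")
  d0 <- initial_ring_diameter(p)
  if (p$midbody_diameter >= d0)
    stop("midbody_diameter must be smaller than the initial ring diameter (",
         signif(d0, 4), " um)")
  if (!(p$anaphase_onset_frame >= 1 && p$anaphase_onset_frame <= p$ingression_onset_frame &&
        p$ingression_onset_frame < p$midbody_frame && p$midbody_frame <= p$n_frames))
    stop("frame indices must satisfy 1 <= anaphase <= ingression onset < midbody <= n_frames")
  if (p$n_frames < 2) stop("parameter 'n_frames' must be >= 2")
  if (is.null(p$target_gmc_area)) {
    p$target_gmc_area <- gmc_model_area(p, delta = 2.5, d = p$midbody_diameter)
  } else if (!is.finite(p$target_gmc_area) || p$target_gmc_area <= 0) {
    stop("parameter 'target_gmc_area' must be a single finite positive number")
  }
  class(p) <- "sim_params"
  p
}

#' Initial ring diameter implied by the geometry
#'
#' The chord of the mother circle at the furrow plane: the ring diameter at
#' 0% constriction, measured at the anaphase-onset frame.
#' @param params a `sim_params` object (or plain list with the same fields).
#' @return diameter in um.
#' @export
initial_ring_diameter <- function(params) {
  R <- params$neuroblast_radius
  delta <- params$initial_furrow_basal_distance
  2 * sqrt(2 * R * delta - delta^2)
}

# Half-width profile w(z) of the pinched cell, all in um. z is axial
# distance from the apical image edge; the cell spans [margin, margin + 2R].
cell_halfwidth <- function(z, params, delta, d) {
  R <- params$neuroblast_radius
  zc <- params$margin + R
  zb <- params$margin + 2 * R
  zf <- zb - delta
  W <- sqrt(pmax(R^2 - (z - zc)^2, 0))
  Wf <- sqrt(max(R^2 - (zf - zc)^2, 0))
  depth <- max(Wf - d / 2, 0)
  if (depth == 0) return(W)
  # parallel-walled throat of half-length growing with pinch depth: deep
  # furrows are tubes, not V grooves (the <30 degree tangent rule relies on it)
  lt <- params$neck_throat * depth
  sig <- ifelse(z < zf, params$neck_sigma_apical, params$neck_sigma_basal)
  u <- pmax(abs(z - zf) - lt, 0) / sig
  phi <- ifelse(u < 1, (1 - u^2)^2, 0)
  w <- pmax(W - depth * phi, 0)
  # within the throat the width is the ring half-diameter exactly
  w[abs(z - zf) <= lt] <- pmin(W[abs(z - zf) <= lt], d / 2)
  w
}

#' Ground-truth GMC cross-section area of the model
#'
#' Integrates the half-width profile basally of the furrow plane. With the
#' pinch fully open (d at its initial value) this equals the circular-segment
#' area of the mother circle at delta.
#' @keywords internal
gmc_model_area <- function(params, delta, d, n_grid = 4000L) {
  R <- params$neuroblast_radius
  zb <- params$margin + 2 * R
  zf <- zb - delta
  z <- seq(zf, zb, length.out = n_grid)
  w <- cell_halfwidth(z, params, delta, d)
  2 * sum((w[-1] + w[-n_grid]) / 2) * (z[2] - z[1])
}

# Ring-diameter schedule d(f), um: flat at d0 through the ingression-onset
# frame, linear to the midbody diameter, flat after.
ring_schedule <- function(params) {
  d0 <- initial_ring_diameter(params)
  f <- seq_len(params$n_frames)
  on <- params$ingression_onset_frame
  mb <- params$midbody_frame
  d <- rep(d0, params$n_frames)
  mid <- f > on & f <= mb
  d[mid] <- d0 + (params$midbody_diameter - d0) * (f[mid] - on) / (mb - on)
  d[f > mb] <- params$midbody_diameter
  d
}

#' Furrow axial trajectory
#'
#' Per-frame axial position of the furrow plane, expressed as distance from
#' the basal pole (um). Without correction the plane stays at delta0, so the
#' final GMC area is a strictly increasing function of delta0. With
#' correction the plane drifts in proportion to the constriction fraction
#' toward the position whose model GMC area equals `target_gmc_area`, making
#' the final area independent of delta0.
#'
#' @param params a [sim_params()] object.
#' @return numeric vector of length `n_frames` (distance from basal pole, um).
#' @export
furrow_trajectory <- function(params) {
  delta0 <- params$initial_furrow_basal_distance
  R <- params$neuroblast_radius
  if (delta0 >= 2 * R) stop("initial furrow basal distance exceeds the cell length")
  d <- ring_schedule(params)
  d0 <- initial_ring_diameter(params)
  cfrac <- (d0 - d) / (d0 - params$midbody_diameter)
  if (!params$correction_on) return(rep(delta0, params$n_frames))
  target <- params$target_gmc_area
  obj <- function(delta) gmc_model_area(params, delta, params$midbody_diameter) - target
  lo <- max(params$neck_sigma_basal + 0.05, 0.2)
  hi <- 2 * R - 0.2
  delta_target <- stats::uniroot(obj, c(lo, hi), tol = 1e-4)$root
  delta0 + (delta_target - delta0) * cfrac
}

# Ground-truth contour for one frame, closed polyline in continuous pixel
# coordinates (row, col), counterclockwise, apical pole toward row 1.
model_contour <- function(params, delta, d) {
  R <- params$neuroblast_radius
  zc <- params$margin + R
  # dense sampling uniform in mother-circle angle resolves the poles; extra
  # uniform-z samples resolve the neck
  theta <- seq(0, pi, length.out = 400L)
  z <- zc - R * cos(theta)
  zb <- params$margin + 2 * R
  zf <- zb - delta
  zneck <- seq(max(params$margin, zf - params$neck_sigma_apical),
               min(zb, zf + params$neck_sigma_basal), length.out = 200L)
  z <- sort(unique(c(z, zneck)))
  w <- cell_halfwidth(z, params, delta, d)
  px <- params$pixel_size
  ccol <- (params$margin + R) / px
  right <- cbind(z / px, ccol + w / px)
  left <- cbind(rev(z) / px, ccol - rev(w) / px)
  pts <- rbind(right, left[-1, , drop = FALSE])
  pts <- pts[!duplicated(round(pts, 9)), , drop = FALSE]
  pts <- resample_closed(pts, params$n_contour)
  if (poly_signed_area(pts) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  pts
}

# Per-vertex cortical intensity along a contour: base band raised uniformly
# by the polar pulse, plus a ring-focused Gaussian bump in arclength around
# the two furrow-plane vertices.
cortex_vertex_values <- function(pts, params, zf_px, E_f) {
  al <- poly_arclength(pts)
  P <- al$total
  sig <- params$ring_focus_sigma * P
  # the two vertices closest to the furrow plane, one on each lateral side
  ccol <- mean(range(pts[, 2]))
  right <- which(pts[, 2] >= ccol)
  left <- which(pts[, 2] < ccol)
  fr <- right[which.min(abs(pts[right, 1] - zf_px))]
  fl <- left[which.min(abs(pts[left, 1] - zf_px))]
  ds <- function(i0) pmin(abs(al$cum - al$cum[i0]), P - abs(al$cum - al$cum[i0]))
  dmin <- pmin(ds(fr), ds(fl))
  base <- params$cortex_base_intensity * (1 + E_f)
  base + params$ring_amplitude * exp(-dmin^2 / (2 * sig^2))
}

# Apply the camera model: Poisson shot noise on the signal, constant offset,
# Gaussian read noise. Consumes the current RNG stream.
apply_camera_noise <- function(signal, params) {
  v <- as.numeric(signal)
  if (params$shot_noise) v <- stats::rpois(length(v), pmax(v, 0))
  v <- v + params$camera_offset
  if (params$read_noise_sd > 0)
    v <- v + stats::rnorm(length(v), 0, params$read_noise_sd)
  matrix(pmax(v, 0), nrow = nrow(signal))
}

# Fast noiseless renderer for model frames. Exploits the half-width
# parameterisation: O(n_pixels) with an exact circle distance away from the
# neck and a local polyline distance inside the pinch window.
render_model_signal <- function(params, pts, delta, d, E_f, dims, ss = 2L) {
  px <- params$pixel_size
  R <- params$neuroblast_radius
  nr <- dims[1]; nc <- dims[2]
  # supersampled grid: ss x ss subpixel centres per pixel (anti-aliasing)
  stopifnot(ss %in% c(1L, 2L))
  rowc <- (seq_len(nr * ss) - 0.5) / ss + 0.5
  colc <- (seq_len(nc * ss) - 0.5) / ss + 0.5
  nrs <- nr * ss; ncs <- nc * ss
  zc_px <- (params$margin + R) / px
  ccol <- (params$margin + R) / px
  zb <- params$margin + 2 * R
  zf <- zb - delta
  zf_px <- zf / px
  band_px <- params$cortical_band_width / px
  z_um <- rowc * px
  w_px <- cell_halfwidth(z_um, params, delta, d) / px

  X <- abs(outer(rep(1, nrs), colc) - ccol)         # |col offset|
  Wm <- outer(w_px, rep(1, ncs))
  inside <- X < Wm & Wm > 0
  Ri <- outer(rowc, rep(1, ncs))
  dcirc <- R / px - sqrt((Ri - zc_px)^2 + X^2)      # distance to mother circle
  dist <- dcirc

  # ring bump via mother-circle arc distance (valid outside the pinch window)
  theta <- atan2(X, zc_px - Ri)
  Wf <- sqrt(max(R^2 - (zf - (params$margin + R))^2, 0))
  theta_f <- acos(pmin(pmax(((params$margin + R) - zf) / R, -1), 1))
  arc <- (R / px) * abs(theta - theta_f)
  pts_al <- poly_arclength(pts)
  sig_px <- params$ring_focus_sigma * pts_al$total
  base_val <- params$cortex_base_intensity * (1 + E_f)
  val <- base_val + params$ring_amplitude * exp(-arc^2 / (2 * sig_px^2))

  depth <- max(Wf - d / 2, 0)
  if (depth > 0) {
    win_um <- max(params$neck_sigma_apical, params$neck_sigma_basal) +
      params$cortical_band_width + 2 * px
    rows <- which(abs(z_um - zf) <= win_um)
    if (length(rows)) {
      sel <- which(inside[rows, , drop = FALSE], arr.ind = TRUE)
      if (nrow(sel)) {
        ir <- rows[sel[, 1]]; ic <- sel[, 2]
        keep <- abs(pts[, 1] - zf_px) <= (win_um + 2 * px) / px
        sub <- pts[keep, , drop = FALSE]
        vv <- cortex_vertex_values(pts, params, zf_px, E_f)[keep]
        dp <- dist_to_polyline(rowc[ir], colc[ic], sub)
        # open polyline chains: distances from dist_to_polyline close the
        # loop over the subset; harmless, closing segments lie off-cortex
        ii <- cbind(ir, ic)
        dist[ii] <- dp$dist
        val[ii] <- vv[dp$nearest]
      }
    }
  }

  signal <- matrix(0, nrs, ncs)
  signal[inside] <- params$cytoplasm_intensity
  band <- inside & dist <= band_px
  signal[band] <- pmax(val[band], params$cytoplasm_intensity)
  if (ss > 1L) {
    # box-average ss x ss subpixels into each pixel
    signal <- (signal[seq(1, nrs, by = ss), ] + signal[seq(2, nrs, by = ss), ]) / 2
    signal <- (signal[, seq(1, ncs, by = ss)] + signal[, seq(2, ncs, by = ss)]) / 2
  }
  signal
}

#' Simulate a dividing-neuroblast time-lapse movie with ground truth
#'
#' Renders an asymmetrically dividing cell over `n_frames` frames: a
#' cortical myosin band, a contractile ring focused at the furrow that
#' constricts from the initial chord to the midbody diameter, an optional
#' transient polar enrichment pulse E(t) = E exp(-(c(t) - c_peak)^2 /
#' (2 sigma_E^2)) peaking near 80% constriction, camera offset, Poisson shot
#' noise and Gaussian read noise. Identical parameters and seed give
#' byte-identical movies.
#'
#' @param params a [sim_params()] object.
#' @return list with components `movie` (a [time_lapse_movie()]) and `truth`
#'   (class `ground_truth`): per-frame contours (pixel coords), furrow points,
#'   ring diameter (um), constriction fraction, polar pulse value, furrow
#'   basal distance (um), plus `d0`, `delta0` and `final_gmc_area` (um^2).
#' @export
simulate_division <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  px <- params$pixel_size
  R <- params$neuroblast_radius
  nr <- ceiling((2 * R + 2 * params$margin) / px)
  nc <- ceiling((2 * R + 2 * params$margin) / px)
  d <- ring_schedule(params)
  d0 <- initial_ring_diameter(params)
  cfrac <- (d0 - d) / (d0 - params$midbody_diameter)
  delta <- furrow_trajectory(params)
  E_t <- params$polar_enrichment_amplitude *
    exp(-(cfrac - params$polar_peak_constriction)^2 / (2 * params$polar_sigma^2))
  zb <- params$margin + 2 * R

  contours <- vector("list", params$n_frames)
  furrows <- vector("list", params$n_frames)
  frames <- vector("list", params$n_frames)
  with_seed(params$seed, {
    for (f in seq_len(params$n_frames)) {
      pts <- model_contour(params, delta[f], d[f])
      contours[[f]] <- pts
      zf <- zb - delta[f]
      h <- d[f] / 2
      Wf <- sqrt(max(R^2 - (zf - (params$margin + R))^2, 0))
      furrows[[f]] <- if (d[f] < d0 - 1e-9) {
        rbind(left = c(zf / px, (params$margin + R - h) / px),
              right = c(zf / px, (params$margin + R + h) / px))
      } else NULL
      signal <- render_model_signal(params, pts, delta[f], d[f], E_t[f],
                                    c(nr, nc))
      if (params$psf_sigma > 0)
        signal <- gaussian_blur(signal, params$psf_sigma / px)
      frames[[f]] <- apply_camera_noise(signal, params)
    }
  })
  movie <- time_lapse_movie(frames, pixel_size = px,
                            frame_interval = params$frame_interval,
                            anaphase_onset = params$anaphase_onset_frame)
  truth <- structure(list(
    contours = contours,
    furrow_points = furrows,
    ring_diameter = d,
    constriction = cfrac,
    polar_pulse = E_t,
    furrow_basal_distance = delta,
    d0 = d0,
    delta0 = params$initial_furrow_basal_distance,
    final_gmc_area = gmc_model_area(params, delta[params$n_frames],
                                    d[params$n_frames]),
    params = params), class = "ground_truth")
  list(movie = movie, truth = truth)
}

#' Render a single frame from an arbitrary closed contour
#'
#' Generic (geometry-agnostic) rasteriser used for validation and custom
#' phantoms: pixels strictly inside the contour receive the cytoplasm
#' intensity, pixels inside and within `band_width_px` of the boundary
#' receive the cortical intensity (a scalar or one value per contour
#' vertex), everything is offset by `camera_offset`, then the optional
#' camera noise model is applied. Deterministic under a fixed seed.
#'
#' @param contour closed polyline (two-column matrix, row/col pixel coords),
#'   or NULL for an empty frame.
#' @param dim frame dimensions c(nrow, ncol).
#' @param cytoplasm,cortex,band_width_px,camera_offset intensity model.
#' @param shot_noise,read_noise_sd camera noise model.
#' @param seed optional integer; when given, the caller's RNG state is left
#'   untouched.
#' @param check if TRUE (default) reject self-intersecting contours.
#' @return intensity matrix `dim[1]` x `dim[2]`.
#' @export
render_frame <- function(contour, dim, cytoplasm = 100, cortex = 250,
                         band_width_px = 3, camera_offset = 0,
                         shot_noise = FALSE, read_noise_sd = 0,
                         seed = NULL, check = TRUE) {
  nr <- dim[1]; nc <- dim[2]
  np <- list(shot_noise = shot_noise, read_noise_sd = read_noise_sd,
             camera_offset = camera_offset)
  if (is.null(contour) || NROW(contour) == 0) {
    out <- with_seed(seed, apply_camera_noise(matrix(0, nr, nc), np))
    return(out)
  }
  contour <- as.matrix(contour)
  if (nrow(contour) < 3) stop("contour must have at least 3 vertices")
  if (check && polyline_self_intersects(contour))
    stop("contour is self-intersecting")
  grid_r <- as.numeric(outer(1:nr, rep(1, nc)))
  grid_c <- as.numeric(outer(rep(1, nr), 1:nc))
  inside <- points_in_polygon(grid_r, grid_c, contour)
  signal <- matrix(0, nr, nc)
  signal[inside] <- cytoplasm
  if (any(inside)) {
    dp <- dist_to_polyline(grid_r[inside], grid_c[inside], contour)
    cval <- if (length(cortex) == 1L) rep(cortex, nrow(contour)) else cortex
    if (length(cval) != nrow(contour))
      stop("cortex must be a scalar or one value per contour vertex")
    band <- dp$dist <= band_width_px
    sig_ins <- signal[inside]
    sig_ins[band] <- pmax(cval[dp$nearest[band]], cytoplasm)
    signal[inside] <- sig_ins
  }
  with_seed(seed, apply_camera_noise(signal, np))
}

# Brute-force segment pair intersection test (bounding-box prefiltered).
polyline_self_intersects <- function(pts) {
  n <- nrow(pts)
  p1 <- pts
  p2 <- pts[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    if (i == 1L) j <- j[j != n]           # skip edges adjacent to edge i
    if (!length(j)) next
    # bounding box reject
    bb <- pmax(pmin(p1[j, 1], p2[j, 1]), min(p1[i, 1], p2[i, 1])) <=
      pmin(pmax(p1[j, 1], p2[j, 1]), max(p1[i, 1], p2[i, 1])) &
      pmax(pmin(p1[j, 2], p2[j, 2]), min(p1[i, 2], p2[i, 2])) <=
      pmin(pmax(p1[j, 2], p2[j, 2]), max(p1[i, 2], p2[i, 2]))
    j <- j[bb]
    if (!length(j)) next
    a <- p1[i, ]; b <- p2[i, ]
    d1 <- (b[1] - a[1]) * (p1[j, 2] - a[2]) - (b[2] - a[2]) * (p1[j, 1] - a[1])
    d2 <- (b[1] - a[1]) * (p2[j, 2] - a[2]) - (b[2] - a[2]) * (p2[j, 1] - a[1])
    c1 <- (p2[j, 1] - p1[j, 1]) * (a[2] - p1[j, 2]) -
      (p2[j, 2] - p1[j, 2]) * (a[1] - p1[j, 1])
    c2 <- (p2[j, 1] - p1[j, 1]) * (b[2] - p1[j, 2]) -
      (p2[j, 2] - p1[j, 2]) * (b[1] - p1[j, 1])
    if (any(d1 * d2 < 0 & c1 * c2 < 0)) return(TRUE)
  }
  FALSE
}
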