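# Shared phantom builders and independent oracles. Everything here is
# generated in code at test time; no stored fixtures.

# Small, fast phantom: coarser pixels and fewer frames than the defaults,
# otherwise the same stated world.
quick_params <- function(...) {
  args <- list(...)
  defaults <- list(pixel_size = 0.2, n_frames = 16,
                   ingression_onset_frame = 3, midbody_frame = 14,
                   polar_enrichment_amplitude = 0, seed = 1L)
  do.call(sim_params, utils::modifyList(defaults, args))
}

# Wrap an arbitrary closed polyline into a cell_contour object, assigning
# poles along the principal axis exactly as trace_contour does.
as_cell_contour <- function(pts) {
  mom <- divquant:::poly_moments(pts)
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
  structure(list(points = pts, apical = apical, basal = basal,
                 long_axis = la / sqrt(sum(la^2)), centroid = mom$centroid),
            class = "cell_contour")
}

# Two overlapping circles stacked along the row axis (the classic two-lobe
# dividing-cell phantom): returns the union contour plus the true neck.
# Centres at rows z1 (radius r1) and z2 (radius r2), common column ccol.
two_lobe_contour <- function(r1 = 25, r2 = 15, gap = 32, ccol = 45,
                             z1 = 35, n = 200) {
  z2 <- z1 + gap
  stopifnot(gap < r1 + r2, gap > abs(r1 - r2))
  # true neck row: where the two circles intersect
  z_star <- (r1^2 - r2^2 + z2^2 - z1^2) / (2 * (z2 - z1))
  w_star <- sqrt(r1^2 - (z_star - z1)^2)
  z <- seq(z1 - r1, z2 + r2, length.out = 2000)
  w1 <- sqrt(pmax(r1^2 - (z - z1)^2, 0))
  w2 <- sqrt(pmax(r2^2 - (z - z2)^2, 0))
  w <- pmax(w1, w2)
  keep <- w > 0
  z <- z[keep]; w <- w[keep]
  right <- cbind(z, ccol + w)
  left <- cbind(rev(z), ccol - rev(w))
  pts <- rbind(right, left)
  pts <- pts[!duplicated(round(pts, 9)), , drop = FALSE]
  pts <- divquant:::resample_closed(pts, n)
  if (divquant:::poly_signed_area(pts) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  list(contour = as_cell_contour(pts),
       neck = list(row = z_star, left = ccol - w_star, right = ccol + w_star,
                   diameter = 2 * w_star))
}

# Independent discrete-curvature oracle: Menger curvature (circumradius of
# the triangle over points i - span, i, i + span), signed by the local turn.
# Deliberately different from the package's windowed circle fit.
oracle_curvature <- function(pts, span = 5) {
  n <- nrow(pts)
  ccw <- divquant:::poly_signed_area(pts) > 0
  vapply(seq_len(n), function(i) {
    a <- pts[(i - span - 1) %% n + 1, ]
    b <- pts[i, ]
    c <- pts[(i + span - 1) %% n + 1, ]
    cross <- (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
    la <- sqrt(sum((b - a)^2)); lb <- sqrt(sum((c - b)^2))
    lc <- sqrt(sum((c - a)^2))
    if (la * lb * lc == 0) return(0)
    k <- 2 * abs(cross) / (la * lb * lc)
    s <- sign(cross)
    if (!ccw) s <- -s
    s * k
  }, numeric(1))
}

# Disk polygon, for rasterisation checks.
disk_polygon <- function(centre, radius, n = 200) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(centre[1] + radius * cos(th), centre[2] + radius * sin(th))
}

# Seeded evaluation without disturbing the suite RNG stream.
with_seed_helper <- function(seed, code) divquant:::with_seed(seed, code)
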