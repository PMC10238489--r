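# Low-level polygon / raster helpers shared by the generator and the
# measurement pipeline. Coordinates are continuous pixel units: the centre
# of matrix element [i, j] sits at (row = i, col = j); rows increase basally.

#' Signed area of a closed polygon (shoelace)
#'
#' @param pts two-column matrix (row, col) of vertices; the polygon is closed
#'   implicitly (last vertex joins the first).
#' @return Signed area; positive when vertices run counterclockwise in the
#'   (row, col) right-handed sense used throughout the package.
#' @keywords internal
poly_signed_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

poly_area <- function(pts) abs(poly_signed_area(pts))

#' Perimeter and cumulative arclength of a closed polyline
#' @keywords internal
poly_arclength <- function(pts) {
  d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
  list(seg = d, cum = cumsum(c(0, d[-length(d)])), total = sum(d))
}

#' Resample a closed polyline to n points at uniform arclength spacing
#' @keywords internal
resample_closed <- function(pts, n) {
  al <- poly_arclength(pts)
  s <- al$cum
  total <- al$total
  target <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  # segment index for each target arclength
  idx <- findInterval(target, s)
  p0 <- pts[idx, , drop = FALSE]
  p1 <- pts[c(2:nrow(pts), 1), , drop = FALSE][idx, , drop = FALSE]
  seg <- al$seg[idx]
  frac <- ifelse(seg > 0, (target - s[idx]) / seg, 0)
  p0 + (p1 - p0) * frac
}

#' Centroid and second moments of a polygon interior (Green's theorem)
#' @keywords internal
poly_moments <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  cx <- sum((x + x2) * cr) / (6 * a)
  cy <- sum((y + y2) * cr) / (6 * a)
  # central second moments
  ixx <- sum((x^2 + x * x2 + x2^2) * cr) / (12 * a) - cx^2
  iyy <- sum((y^2 + y * y2 + y2^2) * cr) / (12 * a) - cy^2
  ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / (24 * a) - cx * cy
  list(area = abs(a), centroid = c(cx, cy),
       cov = matrix(c(ixx, ixy, ixy, iyy), 2, 2))
}

#' Even-odd point-in-polygon test for many points at once
#'
#' @param pr,pc numeric vectors of point rows / cols.
#' @param pts closed polygon vertices.
#' @return logical vector, TRUE strictly inside.
#' @keywords internal
points_in_polygon <- function(pr, pc, pts) {
  n <- nrow(pts)
  inside <- logical(length(pr))
  x1 <- pts[, 1]; y1 <- pts[, 2]
  x2 <- pts[c(2:n, 1), 1]; y2 <- pts[c(2:n, 1), 2]
  for (k in seq_len(n)) {
    a1 <- y1[k]; a2 <- y2[k]
    if (a1 == a2) next
    cross <- (pc > pmin(a1, a2)) & (pc <= pmax(a1, a2))
    if (!any(cross)) next
    xint <- x1[k] + (pc - a1) / (a2 - a1) * (x2[k] - x1[k])
    inside <- xor(inside, cross & (pr < xint))
  }
  inside
}

#' Minimum distance from points to a closed polyline, with nearest vertex
#'
#' @return list(dist, nearest) where nearest is the index of the polygon
#'   vertex starting the closest segment (used to look up per-vertex
#'   intensity along the cortex).
#' @keywords internal
dist_to_polyline <- function(pr, pc, pts) {
  n <- nrow(pts)
  best <- rep(Inf, length(pr))
  nearest <- integer(length(pr))
  x1 <- pts[, 1]; y1 <- pts[, 2]
  x2 <- pts[c(2:n, 1), 1]; y2 <- pts[c(2:n, 1), 2]
  for (k in seq_len(n)) {
    dx <- x2[k] - x1[k]; dy <- y2[k] - y1[k]
    L2 <- dx * dx + dy * dy
    if (L2 == 0) {
      d2 <- (pr - x1[k])^2 + (pc - y1[k])^2
    } else {
      t <- ((pr - x1[k]) * dx + (pc - y1[k]) * dy) / L2
      t <- pmin(1, pmax(0, t))
      d2 <- (pr - (x1[k] + t * dx))^2 + (pc - (y1[k] + t * dy))^2
    }
    upd <- d2 < best
    if (any(upd)) {
      best[upd] <- d2[upd]
      nearest[upd] <- k
    }
  }
  list(dist = sqrt(best), nearest = nearest)
}

#' Bilinear interpolation of a matrix at continuous (row, col) positions
#' @keywords internal
bilinear <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Centered moving average with k neighbours per side
#'
#' Edge windows shrink to the available samples (no padding), matching the
#' neighbour-averaging used for linescan and constriction-curve display.
#' @keywords internal
moving_average <- function(x, k) {
  if (k <= 0) return(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - k); hi <- min(n, i + k)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Otsu threshold of an intensity matrix
#'
#' Maximises between-class variance over a 256-bin histogram; used to
#' separate the extracellular background from the cell.
#' @keywords internal
otsu_threshold <- function(m) {
  v <- as.numeric(m)
  rng <- range(v)
  if (diff(rng) == 0) stop("cannot threshold a constant frame")
  br <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = 256)
  w <- cumsum(h)
  mids <- (br[-1] + br[-257]) / 2
  mu <- cumsum(h * mids)
  wt <- w[256]; mt <- mu[256]
  w1 <- w[-256]; mu1 <- mu[-256]
  w2 <- wt - w1
  ok <- w1 > 0 & w2 > 0
  bc <- rep(-Inf, 255)
  bc[ok] <- (mt * w1[ok] / wt - mu1[ok])^2 / (w1[ok] * w2[ok])
  mids[which.max(bc)]
}

#' Area of a circular segment of radius R cut at height h from the pole
#'
#' The planar cross-section of a spherical cap: the region of a disk of
#' radius \code{R} beyond a chord at distance \code{h} from the nearest
#' point of the circle (0 < h <= 2R).
#' @keywords internal
circle_segment_area <- function(R, h) {
  stopifnot(h > 0, h <= 2 * R)
  R^2 * acos((R - h) / R) - (R - h) * sqrt(2 * R * h - h^2)
}

#' Separable Gaussian blur of a matrix (replicate-padded edges)
#' @keywords internal
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- ceiling(3 * sigma)
  x <- (-k):k
  w <- exp(-x^2 / (2 * sigma^2)); w <- w / sum(w)
  pad_conv <- function(mm) {
    top <- mm[rep(1, k), , drop = FALSE]
    bot <- mm[rep(nrow(mm), k), , drop = FALSE]
    mp <- rbind(top, mm, bot)
    out <- stats::filter(mp, w, sides = 2)
    out[(k + 1):(k + nrow(mm)), , drop = FALSE]
  }
  t(pad_conv(t(pad_conv(m))))
}

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
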