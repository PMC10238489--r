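# Cohort statistics for division metrics: exact two-tailed Mann-Whitney,
# Pearson correlation with R^2, median +/- IQR summaries, and the in-silico
# furrow-position-correction experiment.

#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test
#'
#' U is computed with half credit for ties. The two-sided p value is exact
#' (full enumeration of all label arrangements of the pooled sample) when
#' the combined size is at most 20 and there are no ties; otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction is used. p = min(1, 2 x smaller tail), tail probabilities
#' including the observed point.
#'
#' @param x,y numeric samples (each nonempty).
#' @return list of class `stat_result`: `method`, `statistic` (U of `x`),
#'   `p_value`, `n` (c(n_x, n_y)), `exact` (TRUE when fully enumerated).
#' @export
mann_whitney_two_tailed <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (!has_ties && nx + ny <= 20) {
    cmb <- utils::combn(nx + ny, nx)
    rs <- matrix(r[cmb], nrow = nx)
    Us <- colSums(rs) - nx * (nx + 1) / 2
    m <- length(Us)
    p <- min(1, 2 * min(sum(Us <= U), sum(Us >= U)) / m)
    exact <- TRUE
  } else {
    mu <- nx * ny / 2
    t_tab <- table(pooled)
    tie_corr <- sum(t_tab^3 - t_tab) / ((nx + ny) * (nx + ny - 1))
    sigma2 <- nx * ny / 12 * ((nx + ny + 1) - tie_corr)
    if (sigma2 <= 0) return(structure(list(method = "Mann-Whitney two-tailed",
                                           statistic = U, p_value = 1,
                                           n = c(nx, ny), exact = FALSE),
                                      class = "stat_result"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(method = "Mann-Whitney two-tailed", statistic = U,
                 p_value = p, n = c(nx, ny), exact = exact),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, p = %.4g (n = %s, %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = "/"),
              if (x$exact) "exact" else "approximate"))
  invisible(x)
}

#' Pearson correlation with R^2 and two-tailed p
#'
#' Product-moment r, its square, and the two-tailed p value from the
#' t-transform t = r sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#'
#' @param x,y paired numeric samples, n >= 3, each with nonzero variance.
#' @return list: `r`, `r_squared`, `p_value`, `n`.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0) stop("zero variance in x or y")
  r <- sum(dx * dy) / sqrt(sx * sy)
  r <- min(1, max(-1, r))
  p <- if (abs(r) == 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, r_squared = r^2, p_value = p, n = n)
}

#' Median and interquartile range
#'
#' Linear-interpolation (type 7) quantiles at 0.25, 0.5, 0.75 — the
#' convention behind "median +/- interquartile range" bars.
#'
#' @param x nonempty numeric sample.
#' @return named numeric: `median`, `q1`, `q3`.
#' @export
median_iqr <- function(x) {
  if (!length(x)) stop("empty sample")
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' In-silico furrow-position-correction experiment
#'
#' Simulates two cohorts of dividing cells whose initial furrow basal
#' distance delta0 is drawn uniformly from `delta0_range`: one with the
#' furrow-position correction active (final GMC size clamped to the target,
#' the wild-type behaviour) and one without (GMC size tracks delta0, the
#' uncorrected behaviour). Each movie is quantified with the full
#' measurement pipeline (contour tracing, furrow detection, onset timing,
#' basal-distance and end-of-ingression GMC area measurement); the report
#' gives, per cohort, the Pearson correlation of measured initial basal
#' distance vs final GMC area, and the Mann-Whitney comparison of the two
#' cohorts' GMC areas.
#'
#' @param n_cells cells per cohort (>= 5).
#' @param delta0_range range (um) of the initial furrow basal distance.
#' @param seed integer seed driving delta0 draws and all rendering noise.
#' @param params_fn optional function(delta0, correction_on, seed) returning
#'   a [sim_params()] object, to override phantom defaults.
#' @return list of class `correction_report`: per-cohort `corrected` /
#'   `uncorrected` (each with `r`, `r_squared`, `p_value`, `basal_distance`,
#'   `gmc_area`), and `area_test` (Mann-Whitney of areas across cohorts).
#' @export
correlation_experiment <- function(n_cells = 30, delta0_range = c(1.5, 3.5),
                                   seed = 1L, params_fn = NULL) {
  if (n_cells < 5) stop("need at least 5 cells per cohort")
  if (is.null(params_fn))
    params_fn <- function(delta0, correction_on, seed)
      sim_params(initial_furrow_basal_distance = delta0,
                 correction_on = correction_on,
                 pixel_size = 0.20, n_frames = 16,
                 ingression_onset_frame = 3, midbody_frame = 14,
                 polar_enrichment_amplitude = 0, seed = seed)
  run_cohort <- function(correction_on, offset_seed) {
    delta0 <- with_seed(offset_seed,
                        stats::runif(n_cells, delta0_range[1], delta0_range[2]))
    bd <- area <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      p <- params_fn(delta0[i], correction_on, offset_seed + i)
      sim <- simulate_division(p)
      m <- measure_division(sim$movie, camera_offset = p$camera_offset)
      bd[i] <- m$initial_basal_distance_um
      area[i] <- m$gmc_area_um2
    }
    c(pearson_r2(bd, area),
      list(basal_distance = bd, gmc_area = area, delta0 = delta0))
  }
  base <- as.integer(seed) %% 100000L
  corrected <- run_cohort(TRUE, base * 10000L + 1L)
  uncorrected <- run_cohort(FALSE, base * 10000L + 5001L)
  structure(list(corrected = corrected, uncorrected = uncorrected,
                 area_test = mann_whitney_two_tailed(corrected$gmc_area,
                                                     uncorrected$gmc_area),
                 n_cells = n_cells),
            class = "correction_report")
}

#' @export
print.correction_report <- function(x, ...) {
  cat(sprintf("furrow-position correction experiment (n = %d per cohort)\n",
              x$n_cells))
  for (g in c("uncorrected", "corrected")) {
    cat(sprintf("  %-11s r = %+.3f, R^2 = %.3f, p = %.3g\n", g,
                x[[g]]$r, x[[g]]$r_squared, x[[g]]$p_value))
  }
  cat(sprintf("  GMC areas: Mann-Whitney U = %g, p = %.3g\n",
              x$area_test$statistic, x$area_test$p_value))
  invisible(x)
}
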