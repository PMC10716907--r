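# Circular torsion-angle distributions: 5-degree binned histograms,
# wrapped-Gaussian kernel density estimates, and r2 comparison between
# density profiles.

#' Build a circular torsion histogram
#'
#' Bins angles on \[0, 360) with half-open bins `[b*step, (b+1)*step)`.
#' The default 5-degree step gives 72 bins.
#'
#' @param angles numeric vector of angles in degrees in \[0, 360).
#' @param step bin width in degrees; must divide 360.
#' @param pattern_id optional pattern id recorded in the result.
#' @return object of class `qt_histogram`: list with `pattern_id`, `step`,
#'   `edges` (length nbins + 1), `mids`, `counts`, `n`.
#' @export
build_histogram <- function(angles, step = 5, pattern_id = NA_integer_) {
  if (360 %% step != 0) stop("step must divide 360")
  angles <- as.numeric(angles)
  if (any(!is.finite(angles))) stop("non-finite angles")
  if (any(angles < 0 | angles >= 360)) stop("angles must lie in [0, 360)")
  nbins <- as.integer(360 / step)
  idx <- floor(angles / step) + 1L
  counts <- tabulate(idx, nbins)
  structure(list(pattern_id = pattern_id, step = step,
                 edges = seq(0, 360, by = step),
                 mids = seq(step / 2, 360 - step / 2, by = step),
                 counts = as.integer(counts), n = length(angles)),
            class = "qt_histogram")
}

#' @export
print.qt_histogram <- function(x, ...) {
  cat(sprintf("<qt_histogram: %d bins of %g deg, n = %d>\n",
              length(x$counts), x$step, x$n))
  invisible(x)
}

# wrapped Gaussian kernel evaluated for all grid points x observation pairs,
# summed over +-n_images periodic images
.wrapped_gauss_matrix <- function(grid, centers, sigma, n_images = 3L) {
  out <- matrix(0, length(grid), length(centers))
  for (k in -n_images:n_images) {
    d <- outer(grid, centers + 360 * k, "-")
    out <- out + exp(-d^2 / (2 * sigma^2))
  }
  out / (sigma * sqrt(2 * pi))
}

#' Circular kernel density estimate of a torsion distribution
#'
#' Wrapped-Gaussian KDE on a regular grid over \[0, 360): each observation
#' contributes a Gaussian kernel summed over +-3 periodic images, so the
#' density is seam-continuous at 0/360. The profile is normalized so its
#' periodic trapezoidal integral is exactly 1.
#'
#' @param angles numeric angles in degrees in \[0, 360); alternatively a
#'   `qt_histogram`, in which case bin mid-points weighted by counts are
#'   smoothed (the histogram entry point).
#' @param bandwidth kernel standard deviation in degrees (default 5,
#'   matching the histogram step).
#' @param grid_step grid spacing in degrees (default 1).
#' @return object of class `qt_density`: list with `grid`, `density`
#'   (per-degree units), and metadata.
#' @export
kde_profile <- function(angles, bandwidth = 5, grid_step = 1) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  weights <- NULL
  if (inherits(angles, "qt_histogram")) {
    h <- angles
    if (h$n == 0) stop("empty histogram")
    keep <- h$counts > 0
    weights <- h$counts[keep] / h$n
    angles <- h$mids[keep]
  } else {
    angles <- as.numeric(angles)
    if (length(angles) == 0) stop("no angles")
    if (any(angles < 0 | angles >= 360)) stop("angles must lie in [0, 360)")
    weights <- rep(1 / length(angles), length(angles))
  }
  grid <- seq(0, 360 - grid_step, by = grid_step)
  mat <- .wrapped_gauss_matrix(grid, angles, bandwidth)
  dens <- as.vector(mat %*% weights)
  # periodic trapezoid on a regular grid is mean * period
  dens <- dens / (mean(dens) * 360)
  structure(list(grid = grid, density = dens, bandwidth = bandwidth,
                 grid_step = grid_step), class = "qt_density")
}

#' @export
print.qt_density <- function(x, ...) {
  cat(sprintf("<qt_density: %d grid points, step %g deg>\n",
              length(x$grid), x$grid_step))
  invisible(x)
}

# periodic trapezoidal integral of a density profile over [0, 360)
density_integral <- function(profile) {
  mean(profile$density) * 360
}

#' Squared Pearson correlation between two density profiles
#'
#' The standard way to compare two torsion preference profiles where the
#' peak magnitudes may differ but the relative intensities should agree.
#'
#' @param a,b `qt_density` objects on identical grids.
#' @return r-squared in \[0, 1\].
#' @export
kde_r2 <- function(a, b) {
  if (length(a$grid) != length(b$grid) || any(a$grid != b$grid))
    stop("density grids differ")
  if (stats::sd(a$density) == 0 || stats::sd(b$density) == 0)
    stop("constant density profile: correlation undefined")
  cor(a$density, b$density)^2
}

#' Summarize a set of per-pattern correlation results
#'
#' @param pairs data.frame with columns `pattern_id`, `r2`, and
#'   `support_count` (number of torsion observations behind the pattern).
#' @param high_threshold r2 above which a pattern counts as well
#'   correlated (default 0.8).
#' @param low_threshold r2 below which a pattern counts as poorly
#'   correlated (default 0.2).
#' @return list with `median_r2`, `n_high` (count of r2 >
#'   `high_threshold`), `n_low`, and `median_support_low` (median support
#'   of poorly correlated patterns; `NA` if none).
#' @export
summarize_correlations <- function(pairs, high_threshold = 0.8,
                                   low_threshold = 0.2) {
  if (nrow(pairs) == 0) stop("no correlation records")
  low <- pairs$r2 < low_threshold
  list(median_r2 = median(pairs$r2),
       n_high = sum(pairs$r2 > high_threshold),
       n_low = sum(low),
       median_support_low = if (any(low)) median(pairs$support_count[low])
                            else NA_real_)
}
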