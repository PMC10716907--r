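# Fitting torsion distributions: Boltzmann inversion of histogram
# probabilities to relative energies, cosine-series fits in energy space
# (fixed-phase ETKDG convention and free-phase), and wrapped Gaussian
# mixture fits in probability space.

#' Boltzmann-invert histogram probabilities to relative energies
#'
#' Empty bins are floored before the log transform so the energy stays
#' finite: p_i = max(count_i / n, floor), E_i = -ln(p_i / max p) in kT
#' units, so the most probable bin sits at E = 0.
#'
#' @param hist a `qt_histogram` with `n > 0`.
#' @param floor probability floor for empty bins (default 1e-4).
#' @return object of class `qt_energy_profile`: list with `grid` (bin
#'   mid-points, degrees), `energy` (kT units, min 0), `floor`.
#' @export
probabilities_to_energies <- function(hist, floor = 1e-4) {
  if (hist$n == 0) stop("empty histogram")
  p <- pmax(hist$counts / hist$n, floor)
  e <- -log(p / max(p))
  structure(list(grid = hist$mids, energy = e, floor = floor),
            class = "qt_energy_profile")
}

#' @export
print.qt_energy_profile <- function(x, ...) {
  cat(sprintf("<qt_energy_profile: %d points, max %.3f kT>\n",
              length(x$grid), max(x$energy)))
  invisible(x)
}

#' Fit a cosine series to a torsion energy profile
#'
#' Least-squares fit of `E(theta) = c + sum_n K_n [1 + cos(n theta - d_n)]`
#' for orders n = 1..`max_order`. In `fixed_phase` mode each phase d_n is
#' restricted to 0 or pi (the ETKDG convention); in `free_phase` mode d_n
#' varies continuously. Both problems are solved exactly: the model is
#' linear in (K_n cos d_n, K_n sin d_n), so ordinary least squares yields
#' the global optimum (free phase uses both the cosine and sine regressors;
#' fixed phase uses cosines only and reads the phase off the coefficient
#' sign). Because the fixed-phase solution lies inside the free-phase
#' parameter space, the free-phase residual never exceeds the fixed-phase
#' residual.
#'
#' @param profile a `qt_energy_profile`.
#' @param max_order highest cosine order (1..6, default 6).
#' @param mode `"fixed_phase"` or `"free_phase"`.
#' @return object of class `qt_cosine_fit`: list with `terms` (data.frame
#'   `n`, `K` in kT, `d` in radians), `offset`, `mode`, `residual` (sum of
#'   squared errors), `fitted`.
#' @export
fit_cosine_series <- function(profile, max_order = 6,
                              mode = c("free_phase", "fixed_phase")) {
  mode <- match.arg(mode)
  if (max_order < 1 || max_order > 6) stop("max_order must be in 1..6")
  th <- profile$grid * pi / 180
  y <- profile$energy
  orders <- seq_len(max_order)
  X <- do.call(cbind, lapply(orders, function(n) cos(n * th)))
  colnames(X) <- paste0("a", orders)
  if (mode == "free_phase") {
    S <- do.call(cbind, lapply(orders, function(n) sin(n * th)))
    colnames(S) <- paste0("b", orders)
    X <- cbind(X, S)
  }
  dat <- data.frame(y = y, X)
  fit <- lm(y ~ ., data = dat)
  cf <- coef(fit)
  a <- cf[paste0("a", orders)]
  b <- if (mode == "free_phase") cf[paste0("b", orders)] else rep(0, max_order)
  # K cos d = a, K sin d = b  (model contributes +K cos(n th - d))
  K <- sqrt(a^2 + b^2)
  d <- atan2(b, a) %% (2 * pi)
  if (mode == "fixed_phase") d <- ifelse(a >= 0, 0, pi)
  resid <- sum(fit$residuals^2)
  offset <- unname(cf[1]) - sum(K) # c in E = c + sum K [1 + cos(.)]
  structure(list(
    terms = data.frame(n = orders, K = unname(K), d = unname(d)),
    offset = offset, mode = mode, residual = resid,
    fitted = unname(fit$fitted.values), grid = profile$grid
  ), class = "qt_cosine_fit")
}

#' @export
print.qt_cosine_fit <- function(x, ...) {
  cat(sprintf("<qt_cosine_fit (%s): %d terms, SSE %.4g>\n", x$mode,
              nrow(x$terms), x$residual))
  invisible(x)
}

# evaluate a cosine-series energy model on a grid (degrees)
.cosine_energy <- function(fit, grid) {
  th <- grid * pi / 180
  e <- rep(fit$offset, length(grid))
  for (r in seq_len(nrow(fit$terms))) {
    e <- e + fit$terms$K[r] *
      (1 + cos(fit$terms$n[r] * th - fit$terms$d[r]))
  }
  e
}

#' Convert a cosine-series energy fit to a normalized density
#'
#' Boltzmann weighting of the fitted energy: density proportional to
#' exp(-E(theta)), normalized to unit periodic integral on the grid. This
#' puts energy-space fits on the same footing as probability-space fits so
#' their quality can be compared against the same histogram.
#'
#' @param fit a `qt_cosine_fit`.
#' @param grid evaluation grid in degrees (default 1-degree grid).
#' @return a `qt_density`.
#' @export
cosine_to_density <- function(fit, grid = seq(0, 359, by = 1)) {
  e <- .cosine_energy(fit, grid)
  dens <- exp(-(e - min(e)))
  dens <- dens / (mean(dens) * 360)
  step <- if (length(grid) > 1) grid[2] - grid[1] else 1
  structure(list(grid = grid, density = dens, bandwidth = NA_real_,
                 grid_step = step), class = "qt_density")
}

# wrapped sum-of-Gaussians model evaluated at angles (degrees)
.gauss_mix_eval <- function(theta, amp, mean, sigma, baseline,
                            n_images = 3L) {
  out <- rep(baseline, length(theta))
  for (j in seq_along(amp)) {
    for (k in -n_images:n_images) {
      out <- out + amp[j] * exp(-(theta - mean[j] + 360 * k)^2 /
                                  (2 * sigma[j]^2))
    }
  }
  out
}

# deterministic peak-picking initialization on a KDE of the histogram
.pick_peaks <- function(hist, k) {
  prof <- kde_profile(hist, bandwidth = 5, grid_step = 1)
  d <- prof$density
  n <- length(d)
  prv <- c(d[n], d[-n]); nxt <- c(d[-1], d[1])
  is_max <- d >= prv & d > nxt
  peaks <- data.frame(angle = prof$grid[is_max], height = d[is_max])
  peaks <- peaks[order(-peaks$height), , drop = FALSE]
  if (nrow(peaks) >= k) return(peaks[seq_len(k), , drop = FALSE])
  # pad with equally spaced fillers at low density if too few maxima
  extra <- k - nrow(peaks)
  fill <- data.frame(angle = (peaks$angle[1] + 360 * seq_len(extra) /
                                (extra + 1)) %% 360,
                     height = rep(min(d), extra))
  rbind(peaks, fill)
}

#' Fit a wrapped Gaussian mixture to a torsion histogram
#'
#' Fits bin probabilities with `baseline + sum_j A_j G(theta; mu_j,
#' sigma_j)` where each Gaussian is wrapped over +-3 periodic images, by
#' bounded Levenberg-Marquardt least squares (minpack.lm). The number of
#' peaks is chosen by fitting k = 1..`max_peaks` and keeping the smallest
#' k whose multinomial BIC (bin counts as multinomial draws from the
#' modelled bin probabilities) is within 2 of the best. Initialization is
#' deterministic peak-picking on a 5-degree-bandwidth KDE of the histogram,
#' so the fit is reproducible.
#'
#' @param hist a `qt_histogram` with at least two populated bins.
#' @param max_peaks maximum number of Gaussian components (1..6).
#' @return object of class `qt_gaussian_fit`: list with `peaks`
#'   (data.frame `amplitude`, `mean` in \[0,360), `sigma` > 0, `weight`),
#'   `baseline`, `residual`, `bic`, `k`.
#' @export
fit_gaussian_mixture <- function(hist, max_peaks = 6) {
  if (hist$n == 0) stop("empty histogram")
  if (sum(hist$counts > 0) < 2) stop("too few populated bins to fit")
  theta <- hist$mids
  p <- hist$counts / hist$n
  m <- length(theta)
  fits <- list()
  for (k in seq_len(max_peaks)) {
    init <- .pick_peaks(hist, k)
    par0 <- c(amp = pmax(init$height * hist$step, 1e-3),
              mean = init$angle,
              sigma = rep(15, k),
              baseline = max(min(p) , 0))
    lower <- c(rep(0, k), rep(-360, k), rep(1, k), 0)
    upper <- c(rep(Inf, k), rep(720, k), rep(180, k), max(p))
    resid_fn <- function(par) {
      amp <- par[seq_len(k)]
      mu <- par[k + seq_len(k)]
      sg <- par[2 * k + seq_len(k)]
      bl <- par[3 * k + 1]
      .gauss_mix_eval(theta, amp, mu, sg, bl) - p
    }
    res <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    sse <- sum(res$fvec^2)
    npar <- 3 * k + 1
    # multinomial BIC: bin counts are multinomial draws from the modelled
    # bin probabilities, so spurious components that only chase binning
    # noise cannot pay for their parameters
    q <- .gauss_mix_eval(theta, res$par[seq_len(k)],
                         res$par[k + seq_len(k)],
                         res$par[2 * k + seq_len(k)], res$par[3 * k + 1])
    q <- pmax(q, 1e-12)
    q <- q / sum(q)
    bic <- -2 * sum(hist$counts * log(q)) + npar * log(hist$n)
    fits[[k]] <- list(res = res, sse = sse, bic = bic, k = k)
  }
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("Gaussian mixture fit failed to converge")
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  chosen <- fits[[which(bics <= min(bics) + 2)[1]]]
  par <- chosen$res$par
  k <- chosen$k
  amp <- unname(par[seq_len(k)])
  mu <- unname(par[k + seq_len(k)]) %% 360
  sg <- unname(par[2 * k + seq_len(k)])
  bl <- unname(par[3 * k + 1])
  # component weights: share of modelled probability mass per peak
  mass <- amp * sg * sqrt(2 * pi) / hist$step
  total <- sum(mass) + bl * length(theta)
  peaks <- data.frame(amplitude = amp, mean = mu, sigma = sg,
                      weight = mass / total)
  peaks <- peaks[order(-peaks$weight), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(peaks = peaks, baseline = bl, residual = chosen$sse,
                 bic = chosen$bic, k = k, step = hist$step),
            class = "qt_gaussian_fit")
}

#' @export
print.qt_gaussian_fit <- function(x, ...) {
  cat(sprintf("<qt_gaussian_fit: %d peak(s), SSE %.4g>\n", x$k, x$residual))
  for (r in seq_len(nrow(x$peaks)))
    cat(sprintf("  mean %6.1f deg  sigma %5.1f deg  weight %.3f\n",
                x$peaks$mean[r], x$peaks$sigma[r], x$peaks$weight[r]))
  invisible(x)
}

#' Evaluate a Gaussian-mixture fit as a normalized density
#'
#' @param fit a `qt_gaussian_fit`.
#' @param grid evaluation grid in degrees (default 1-degree grid).
#' @return a `qt_density` with unit periodic integral.
#' @export
gaussian_to_density <- function(fit, grid = seq(0, 359, by = 1)) {
  dens <- .gauss_mix_eval(grid, fit$peaks$amplitude, fit$peaks$mean,
                          fit$peaks$sigma, fit$baseline)
  dens <- dens / (mean(dens) * 360)
  step <- if (length(grid) > 1) grid[2] - grid[1] else 1
  structure(list(grid = grid, density = dens, bandwidth = NA_real_,
                 grid_step = step), class = "qt_density")
}

#' Fit quality as squared Pearson correlation against a histogram
#'
#' Evaluates the model density at the histogram bin centers and correlates
#' with the bin probabilities. Scale-invariant: what matters is the
#' relative intensity at each torsion angle, not absolute peak heights.
#'
#' @param model_density a `qt_density` whose grid covers the bin centers.
#' @param hist a `qt_histogram`.
#' @return r-squared in \[0, 1\].
#' @export
fit_quality_r2 <- function(model_density, hist) {
  at <- approx(c(model_density$grid, 360),
               c(model_density$density, model_density$density[1]),
               xout = hist$mids)$y
  p <- hist$counts / hist$n
  if (stats::sd(at) == 0 || stats::sd(p) == 0)
    stop("zero-variance input: correlation undefined")
  cor(at, p)^2
}
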