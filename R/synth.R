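# Synthetic data: wrapped-Gaussian-mixture torsion populations with known
# parameters (ground truth for fitting and sampling tests) and small toy
# molecule fixtures built in code.

#' Define a wrapped-Gaussian mixture of torsion angles
#'
#' @param means component means in degrees in \[0, 360).
#' @param sigmas component standard deviations in degrees (> 0).
#' @param weights component weights; must sum to 1 (default equal).
#' @return object of class `qt_mixture_spec`.
#' @export
mixture_spec <- function(means, sigmas, weights = NULL) {
  k <- length(means)
  if (k < 1 || k > 6) stop("1 to 6 components supported")
  if (length(sigmas) != k) stop("sigmas length mismatch")
  if (any(sigmas <= 0)) stop("sigmas must be positive")
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k) stop("weights length mismatch")
  if (any(weights <= 0)) stop("weights must be positive")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  structure(list(means = as.numeric(means) %% 360,
                 sigmas = as.numeric(sigmas),
                 weights = as.numeric(weights)),
            class = "qt_mixture_spec")
}

#' @export
print.qt_mixture_spec <- function(x, ...) {
  cat("<qt_mixture_spec>\n")
  for (j in seq_along(x$means))
    cat(sprintf("  w %.3f  mean %6.1f deg  sigma %5.1f deg\n",
                x$weights[j], x$means[j], x$sigmas[j]))
  invisible(x)
}

#' Draw torsion angles from a wrapped-Gaussian mixture
#'
#' Component chosen by weight, angle drawn from the component normal and
#' wrapped into \[0, 360). Reproducible for a fixed seed.
#'
#' @param spec a `qt_mixture_spec`.
#' @param n number of draws (>= 1).
#' @param seed optional integer seed (set locally).
#' @return numeric vector of angles in degrees in \[0, 360).
#' @export
generate_mixture_angles <- function(spec, n, seed = NULL) {
  if (!inherits(spec, "qt_mixture_spec")) stop("invalid mixture spec")
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  comp <- sample.int(length(spec$weights), n, replace = TRUE,
                     prob = spec$weights)
  (rnorm(n, mean = spec$means[comp], sd = spec$sigmas[comp])) %% 360
}

#' Analytic CDF of a wrapped-Gaussian mixture
#'
#' Closed-form CDF on \[0, 360) with the periodic image sum truncated at
#' +-3 wraps; the independent oracle for sampling fidelity tests.
#'
#' @param spec a `qt_mixture_spec`.
#' @param angle angles in degrees in \[0, 360\].
#' @return cumulative probabilities; `analytic_mixture_cdf(spec, 0) == 0`
#'   and the value at 360 approaches 1.
#' @export
analytic_mixture_cdf <- function(spec, angle) {
  vapply(angle, function(a) {
    tot <- 0
    for (j in seq_along(spec$weights)) {
      # at least +-3 wraps; very wide components need more images to cover
      # their tails
      ni <- max(3, ceiling(4 * spec$sigmas[j] / 360))
      s <- 0
      for (k in -ni:ni) {
        s <- s + pnorm((a - spec$means[j] + 360 * k) / spec$sigmas[j]) -
          pnorm((0 - spec$means[j] + 360 * k) / spec$sigmas[j])
      }
      tot <- tot + spec$weights[j] * s
    }
    min(max(tot, 0), 1)
  }, numeric(1))
}

#' Analytic density of a wrapped-Gaussian mixture
#'
#' @param spec a `qt_mixture_spec`.
#' @param grid evaluation grid in degrees (default 1-degree grid).
#' @return a `qt_density` (per-degree units, unit periodic integral).
#' @export
mixture_density <- function(spec, grid = seq(0, 359, by = 1)) {
  dens <- numeric(length(grid))
  for (j in seq_along(spec$weights)) {
    for (k in -3:3) {
      dens <- dens + spec$weights[j] *
        exp(-(grid - spec$means[j] + 360 * k)^2 / (2 * spec$sigmas[j]^2)) /
        (spec$sigmas[j] * sqrt(2 * pi))
    }
  }
  dens <- dens / (mean(dens) * 360)
  step <- if (length(grid) > 1) grid[2] - grid[1] else 1
  structure(list(grid = grid, density = dens, bandwidth = NA_real_,
                 grid_step = step), class = "qt_density")
}

#' Draw a random mixture specification
#'
#' Generates the study conditions for the synthetic fitting battery: 1-4
#' components with means pairwise at least 60 degrees apart on the circle
#' (rotameric wells are separated by torsional barriers), sigmas uniform
#' in \[8, 25\] degrees (typical torsion peak widths), and weights uniform
#' on the simplex floored at 0.1 and renormalized.
#'
#' @param n_components number of components, or `NULL` to draw uniformly
#'   from 1..4.
#' @param min_separation minimum circular distance between component means
#'   in degrees (default 60).
#' @return a `qt_mixture_spec`.
#' @export
random_mixture_spec <- function(n_components = NULL, min_separation = 60) {
  k <- if (is.null(n_components)) sample.int(4, 1) else as.integer(n_components)
  circ_dist <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  means <- numeric(0)
  tries <- 0L
  while (length(means) < k) {
    cand <- runif(1, 0, 360)
    if (all(circ_dist(cand, means) >= min_separation)) {
      means <- c(means, cand)
    }
    tries <- tries + 1L
    if (tries > 10000L) stop("could not place component means")
  }
  sigmas <- runif(k, 8, 25)
  w <- runif(k)
  w <- pmax(w / sum(w), 0.1)
  w <- w / sum(w)
  mixture_spec(means, sigmas, w)
}

# zig-zag heavy-atom chain along x with tetrahedral-ish 111-degree angles
.chain_coords <- function(n, bond = 1.53, angle_deg = 111) {
  half <- (180 - angle_deg) / 2 * pi / 180
  dx <- bond * cos(half); dy <- bond * sin(half)
  x <- cumsum(c(0, rep(dx, n - 1)))
  y <- rep(c(0, dy), length.out = n)
  cbind(x, y, 0)
}

.hexagon <- function(center, radius = 1.396, phase_deg = 0) {
  ang <- (phase_deg + seq(0, 300, by = 60)) * pi / 180
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang),
        center[3])
}

#' Built-in toy molecule fixtures
#'
#' Deterministic small molecules with valid geometry, built in code:
#' \describe{
#'   \item{`butane`}{n-butane heavy-atom skeleton (implicit hydrogens),
#'     anti conformation; exactly one rotatable bond (C2-C3).}
#'   \item{`salt_pair`}{heptylammonium chloride: an 8-heavy-atom cation
#'     and a single-atom counterion, for fragment-stripping tests.}
#'   \item{`bimodal_biaryl`}{2,2'-dimethylbiphenyl with the inter-ring
#'     torsion set near 90 degrees, mimicking a sterically constrained
#'     biaryl.}
#' }
#'
#' @param name one of `"butane"`, `"salt_pair"`, `"bimodal_biaryl"`.
#' @return a `qt_mol` with one conformer.
#' @export
make_toy_molecule <- function(name = c("butane", "salt_pair",
                                       "bimodal_biaryl")) {
  name <- match.arg(name)
  if (name == "butane") {
    coords <- .chain_coords(4)
    bonds <- data.frame(a1 = 0:2, a2 = 1:3, order = 1L)
    return(qt_mol(rep("C", 4), bonds, coords = coords, id = "butane"))
  }
  if (name == "salt_pair") {
    coords <- rbind(.chain_coords(8), c(10, 5, 0))
    bonds <- data.frame(a1 = 0:6, a2 = 1:7, order = 1L)
    elements <- c(rep("C", 7), "N", "Cl")
    charges <- c(rep(0L, 7), 1L, -1L)
    return(qt_mol(elements, bonds, coords = coords, charges = charges,
                  id = "salt_pair"))
  }
  # 2,2'-dimethylbiphenyl with ~90 degree inter-ring twist
  ringA <- .hexagon(c(0, 0, 0))                    # atoms 0..5, link atom 0
  cB <- c(1.396 + 1.49 + 1.396, 0, 0)
  ringB <- .hexagon(cB, phase_deg = 180)           # atoms 6..11, link atom 6
  # twist ring B by 90 degrees about the x axis (the inter-ring bond axis)
  ringB <- cbind(ringB[, 1], -ringB[, 3], ringB[, 2])
  # ortho methyls on atom 1 (ring A) and atom 7 (ring B)
  meA <- ringA[2, ] * (1.396 + 1.5) / 1.396
  dirB <- ringB[2, ] - cB
  meB <- cB + dirB * (1.396 + 1.5) / 1.396
  coords <- rbind(ringA, ringB, meA, meB)
  ring_bonds <- function(offset) data.frame(
    a1 = offset + c(0:4, 5), a2 = offset + c(1:5, 0),
    order = rep(c(1L, 2L), 3))
  bonds <- rbind(ring_bonds(0L), ring_bonds(6L),
                 data.frame(a1 = 0L, a2 = 6L, order = 1L),
                 data.frame(a1 = 1L, a2 = 12L, order = 1L),
                 data.frame(a1 = 7L, a2 = 13L, order = 1L))
  qt_mol(c(rep("C", 12), "C", "C"), bonds, coords = coords,
         id = "bimodal_biaryl")
}
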