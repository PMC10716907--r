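# Inverse-CDF sampling tables built from fitted torsion densities, and
# torsion driving: applying sampled angles to conformers by rigid rotation
# about acyclic central bonds.

#' Build an inverse-CDF sampling table from a density profile
#'
#' Accumulates the density across all angles from 0 to 360 degrees at a
#' fixed angular resolution, normalizes the cumulative sum to \[0, 1\], and
#' inverts it by monotone linear interpolation, so that pushing a uniform
#' random quantile through the table yields a torsion angle distributed by
#' the source density.
#'
#' @param density a `qt_density` (nonnegative, positive total mass).
#' @param resolution angular resolution of the CDF in degrees (default
#'   0.5).
#' @param pattern_id optional pattern id carried in the table.
#' @return object of class `qt_sampling_table`: list with `quantile_grid`
#'   (strictly increasing, from 0 to 1) and `angle_at_quantile` (degrees,
#'   nondecreasing, in \[0, 360\]).
#' @export
build_sampling_table <- function(density, resolution = 0.5,
                                 pattern_id = NA_integer_) {
  if (any(density$density < -1e-12)) stop("negative density")
  grid <- seq(0, 360 - resolution, by = resolution)
  d <- approx(c(density$grid, 360),
              c(density$density, density$density[1]),
              xout = grid)$y
  d <- pmax(d, 0)
  total <- sum(d)
  if (total <= 0) stop("density has zero total mass")
  cdf <- cumsum(d) / total
  angles <- c(0, grid + resolution)  # right edges; CDF(0) = 0
  q <- c(0, cdf)
  # collapse zero-density plateaus so the quantile grid stays strictly
  # increasing: interior/trailing plateaus map to their left edge, and the
  # leading zero plateau anchors at its right edge (the start of support)
  keep <- c(TRUE, diff(q) > 1e-15)
  zero_run <- which(q <= 1e-15)
  qk <- q[keep]; angles_k <- angles[keep]
  if (length(zero_run) > 1) angles_k[1] <- angles[max(zero_run)]
  q <- qk; angles <- angles_k
  q[length(q)] <- 1
  structure(list(pattern_id = pattern_id, quantile_grid = q,
                 angle_at_quantile = angles, resolution = resolution),
            class = "qt_sampling_table")
}

#' @export
print.qt_sampling_table <- function(x, ...) {
  cat(sprintf("<qt_sampling_table: %d knots, resolution %g deg>\n",
              length(x$quantile_grid), x$resolution))
  invisible(x)
}

#' Map uniform quantiles through a sampling table
#'
#' @param table a `qt_sampling_table`.
#' @param u numeric quantiles in \[0, 1\].
#' @return angles in degrees in \[0, 360).
#' @export
quantile_to_angle <- function(table, u) {
  if (any(u < 0 | u > 1)) stop("quantiles must lie in [0, 1]")
  a <- approx(table$quantile_grid, table$angle_at_quantile, xout = u,
              ties = "ordered")$y
  a %% 360
}

#' Draw torsion angles from a sampling table
#'
#' Inverse-transform sampling: n uniform random quantiles pushed through
#' the table. Reproducible for a fixed seed.
#'
#' @param table a `qt_sampling_table`.
#' @param n number of draws.
#' @param seed optional integer seed (set locally; the caller's RNG state
#'   is restored).
#' @return numeric vector of n angles in degrees in \[0, 360).
#' @export
sample_angles <- function(table, n, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  quantile_to_angle(table, runif(n))
}

# Rodrigues rotation of points about unit axis through origin
.rotate_about <- function(points, axis, angle_rad) {
  k <- axis / sqrt(sum(axis^2))
  ct <- cos(angle_rad); st <- sin(angle_rad)
  t(apply(points, 1, function(v) {
    v * ct + .cross(k, v) * st + k * sum(k * v) * (1 - ct)
  }))
}

# 0-based atom indices on the p3 side of the bond p2-p3 (excluding p2);
# errors if the bond is in a ring
.distal_side <- function(mol, a2, a3) {
  adj <- .adj_list(mol)
  seen <- logical(n_atoms(mol))
  seen[a2 + 1L] <- TRUE
  queue <- a3
  seen[a3 + 1L] <- TRUE
  side <- a3
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v + 1L]]) {
      if (w == a2 && v == a3) next
      if (w == a2) stop("central bond lies in a ring: torsion driving undefined")
      if (!seen[w + 1L]) {
        seen[w + 1L] <- TRUE
        queue <- c(queue, w)
        side <- c(side, w)
      }
    }
  }
  side
}

#' Set a dihedral angle by rigid rotation
#'
#' Rotates every atom on the distal side of the acyclic central bond
#' rigidly about the bond axis so the measured dihedral of the quadruple
#' equals the target. Bond lengths and angles are untouched.
#'
#' @param mol a `qt_mol` (used for connectivity).
#' @param coords N x 3 conformer coordinates.
#' @param quad integer quadruple of 0-based atom indices (a1, a2, a3, a4);
#'   the central bond a2-a3 must be acyclic.
#' @param target target dihedral in degrees.
#' @return new N x 3 coordinate matrix.
#' @export
set_dihedral <- function(mol, coords, quad, target) {
  coords <- as.matrix(coords)
  a <- as.integer(quad)
  k <- which((mol$bonds$a1 == a[2] & mol$bonds$a2 == a[3]) |
             (mol$bonds$a1 == a[3] & mol$bonds$a2 == a[2]))
  if (length(k) == 0) stop("central pair is not bonded")
  if (mol$ring_bond[k[1]]) stop("central bond lies in a ring: torsion driving undefined")
  current <- .dihedral_idx(coords, a)
  delta <- (target - current) %% 360
  if (delta > 180) delta <- delta - 360
  # rotating the distal side by +delta about the p2->p3 axis (right-hand
  # rule) advances the measured dihedral by +delta under the atan2
  # convention of measure_dihedral()
  side <- setdiff(.distal_side(mol, a[2], a[3]), a[3])
  axis <- coords[a[3] + 1L, ] - coords[a[2] + 1L, ]
  origin <- coords[a[2] + 1L, ]
  if (length(side) > 0) {
    rot_idx <- side + 1L
    moved <- .rotate_about(sweep(coords[rot_idx, , drop = FALSE], 2, origin),
                           axis, delta * pi / 180)
    coords[rot_idx, ] <- sweep(moved, 2, origin, "+")
  }
  coords
}

#' Drive all matched acyclic torsions of a molecule
#'
#' Matches the pattern library against the molecule, then sets each
#' matched acyclic torsion to an angle drawn from that pattern's sampling
#' table, in a deterministic order (ascending central-bond atom indices).
#' Ring torsions are left untouched; matched torsions without a table fall
#' back to a uniform draw.
#'
#' @param mol a `qt_mol` with coordinates.
#' @param library a `qt_pattern_library`.
#' @param tables named list of `qt_sampling_table`, keyed by pattern id
#'   (as character).
#' @param seed integer seed for the angle draws.
#' @return list with `coords` (driven conformer) and `torsions` (the
#'   observation table with the sampled target angles in column
#'   `target_angle`).
#' @export
drive_molecule <- function(mol, library, tables = list(), seed = 1L) {
  obs <- match_torsions(mol, library)
  coords <- mol$coords
  obs <- obs[obs$kind == "acyclic", , drop = FALSE]
  if (nrow(obs) == 0)
    return(list(coords = coords, torsions = obs))
  ord <- order(pmin(obs$a2, obs$a3), pmax(obs$a2, obs$a3))
  obs <- obs[ord, , drop = FALSE]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  targets <- numeric(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    key <- as.character(obs$pattern_id[i])
    u <- runif(1)
    targets[i] <- if (!is.null(tables[[key]]))
      quantile_to_angle(tables[[key]], u) else 360 * u
    coords <- set_dihedral(mol, coords,
                           c(obs$a1[i], obs$a2[i], obs$a3[i], obs$a4[i]),
                           targets[i])
  }
  obs$target_angle <- targets
  list(coords = coords, torsions = obs)
}
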