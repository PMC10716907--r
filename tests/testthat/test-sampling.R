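# Inverse-CDF sampling tables and torsion driving.

uniform_density <- function() {
  structure(list(grid = seq(0, 359), density = rep(1 / 360, 360),
                 bandwidth = NA_real_, grid_step = 1),
            class = "qt_density")
}

test_that("sampling table inverts the CDF", {
  tab <- build_sampling_table(uniform_density())
  expect_equal(tab$quantile_grid[1], 0)
  expect_equal(tab$quantile_grid[length(tab$quantile_grid)], 1)
  expect_true(all(diff(tab$quantile_grid) > 0))
  expect_true(all(diff(tab$angle_at_quantile) >= 0))
  # uniform: u -> 360 u within half a resolution step
  u <- c(0, 0.1, 0.25, 0.5, 0.9)
  expect_true(all(abs(quantile_to_angle(tab, u) - 360 * u) <= 0.25 + 1e-9))
  expect_equal(quantile_to_angle(tab, 0.5), 180, tolerance = 0.25)

  # all mass in one 5-degree window
  d <- uniform_density()
  d$density <- ifelse(d$grid >= 90 & d$grid < 95, 1, 0)
  tab2 <- build_sampling_table(d)
  # smearing by at most the table resolution plus grid interpolation
  a <- quantile_to_angle(tab2, seq(0.01, 0.99, by = 0.07))
  expect_true(all(a >= 89.5 & a <= 95.5))

  # two equal point masses at 60 and 240
  d2 <- uniform_density()
  d2$density <- rep(0, 360)
  d2$density[d2$grid == 60] <- 1
  d2$density[d2$grid == 240] <- 1
  tab3 <- build_sampling_table(d2)
  expect_equal(quantile_to_angle(tab3, 0.25), 60, tolerance = 1.0)
  expect_equal(quantile_to_angle(tab3, 0.75), 240, tolerance = 1.0)

  zero <- uniform_density()
  zero$density <- rep(0, 360)
  expect_error(build_sampling_table(zero), "zero total mass")
})

test_that("pushing the quantile grid through the CDF is the identity", {
  set.seed(14)
  spec <- random_mixture_spec()
  tab <- build_sampling_table(mixture_density(spec))
  ang <- tab$angle_at_quantile
  q <- tab$quantile_grid
  # forward CDF at the table's own angles (analytic oracle)
  fwd <- analytic_mixture_cdf(spec, pmin(ang, 360 - 1e-12))
  expect_lt(max(abs(fwd - q)), 5e-3) # resolution-limited round trip
})

test_that("sampled angles reproduce the analytic mixture distribution", {
  spec <- mixture_spec(c(60, 180, 300), c(12, 15, 10), c(0.3, 0.45, 0.25))
  tab <- build_sampling_table(mixture_density(spec))
  s1 <- sample_angles(tab, 1000, seed = 7)
  s2 <- sample_angles(tab, 1000, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 < 360))

  s <- sort(sample_angles(tab, 1e5, seed = 8))
  ks <- max(abs(analytic_mixture_cdf(spec, s) -
                (seq_along(s) - 0.5) / length(s)))
  expect_lt(ks, 0.01)

  # histogram of draws correlates with the source density
  h <- build_histogram(s)
  src <- mixture_density(spec)
  at <- approx(c(src$grid, 360), c(src$density, src$density[1]),
               xout = h$mids)$y
  expect_gt(cor(at, h$counts / h$n)^2, 0.99)
})

test_that("set_dihedral is exact, rigid, and ring-protected", {
  bu <- make_toy_molecule("butane")
  # no-op: setting the current angle leaves coordinates unchanged
  cur <- qtdg:::.dihedral_idx(bu$coords, 0:3)
  same <- set_dihedral(bu, bu$coords, 0:3, cur)
  expect_lt(max(abs(same - bu$coords)), 1e-9)

  for (target in c(0, 60, 180, 243.7, 359.5)) {
    moved <- set_dihedral(bu, bu$coords, 0:3, target)
    got <- qtdg:::.dihedral_idx(moved, 0:3)
    d <- min(abs(got - target), 360 - abs(got - target))
    expect_lt(d, 1e-6)
    # rigidity: all pairwise bonded distances preserved
    for (k in seq_len(nrow(bu$bonds))) {
      i <- bu$bonds$a1[k] + 1L; j <- bu$bonds$a2[k] + 1L
      expect_equal(sqrt(sum((moved[i,] - moved[j,])^2)),
                   sqrt(sum((bu$coords[i,] - bu$coords[j,])^2)),
                   tolerance = 1e-9)
    }
  }

  # intra-side distances are preserved exactly (isometry on each side)
  bb <- make_toy_molecule("bimodal_biaryl")
  moved <- set_dihedral(bb, bb$coords, c(1, 0, 6, 7), 45)
  sideB <- c(6:11, 13) + 1L
  dist0 <- as.matrix(dist(bb$coords[sideB, ]))
  dist1 <- as.matrix(dist(moved[sideB, ]))
  expect_lt(max(abs(dist0 - dist1)), 1e-9)
  # ring bonds refuse to drive
  expect_error(set_dihedral(bb, bb$coords, c(0, 1, 2, 3), 90), "ring")
})

test_that("driving applies sampled angles to every matched acyclic torsion", {
  lib <- load_pattern_library()
  bu <- make_toy_molecule("butane")
  # table concentrated at 180 degrees -> anti conformer
  d <- uniform_density()
  d$density <- exp(-(d$grid - 180)^2 / (2 * 0.5^2))
  anti_tab <- build_sampling_table(d)
  obs <- match_torsions(bu, lib)
  tabs <- setNames(list(anti_tab), as.character(obs$pattern_id[1]))
  res <- drive_molecule(bu, lib, tabs, seed = 3)
  got <- qtdg:::.dihedral_idx(res$coords, 0:3)
  expect_lt(min(abs(got - 180), 360 - abs(got - 180)), 2)

  # determinism
  res2 <- drive_molecule(bu, lib, tabs, seed = 3)
  expect_identical(res$coords, res2$coords)

  # molecule with no acyclic matched torsion: unchanged
  ringA <- .subset_mol_for_test(make_toy_molecule("bimodal_biaryl"), 0:5)
  r <- drive_molecule(ringA, lib, seed = 1)
  expect_identical(r$coords, ringA$coords)

  # biaryl: the inter-ring torsion is driven, ring torsions untouched
  bb <- make_toy_molecule("bimodal_biaryl")
  rb <- drive_molecule(bb, lib, tables = list(), seed = 9)
  expect_equal(nrow(rb$torsions), 1L)
  ring_quad <- c(0, 1, 2, 3)
  expect_equal(qtdg:::.dihedral_idx(rb$coords, ring_quad),
               qtdg:::.dihedral_idx(bb$coords, ring_quad), tolerance = 1e-9)
})
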