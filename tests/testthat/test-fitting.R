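# Boltzmann inversion, cosine-series fits, Gaussian-mixture fits, and fit
# scoring.

test_that("probability-to-energy transform follows -ln(p/pmax)", {
  # uniform -> all zero
  h <- build_histogram(rep(seq(2.5, 357.5, by = 5), each = 2))
  e <- probabilities_to_energies(h)
  expect_true(all(abs(e$energy) < 1e-12))

  # two populated bins, counts 100 and 10 -> gap of ln(10)
  ang <- c(rep(2, 100), rep(12, 10))
  h2 <- build_histogram(ang)
  e2 <- probabilities_to_energies(h2)
  expect_equal(e2$energy[3] - e2$energy[1], log(10), tolerance = 1e-12)
  expect_equal(min(e2$energy), 0)

  # empty bin with floor 1e-4 when pmax = 0.5 -> ln(5000)
  h3 <- build_histogram(c(rep(2, 5), rep(12, 5)))
  e3 <- probabilities_to_energies(h3, floor = 1e-4)
  expect_equal(max(e3$energy), log(0.5 / 1e-4), tolerance = 1e-12)

  empty <- build_histogram(numeric(0))
  expect_error(probabilities_to_energies(empty), "empty")
})

test_that("energy round-trip reproduces floored probabilities", {
  set.seed(31)
  ang <- generate_mixture_angles(mixture_spec(c(70, 200), c(10, 20)), 5e3)
  h <- build_histogram(ang)
  e <- probabilities_to_energies(h, floor = 1e-4)
  p_floor <- pmax(h$counts / h$n, 1e-4)
  back <- exp(-e$energy) * max(p_floor)
  expect_lt(max(abs(back - p_floor)), 1e-9)
})

test_that("cosine fit recovers noiseless single-term profiles", {
  grid <- seq(2.5, 357.5, by = 5)
  # K1 = 1, d1 = 0
  prof <- structure(list(grid = grid,
                         energy = 1 + cos(grid * pi / 180), floor = 1e-4),
                    class = "qt_energy_profile")
  fit <- fit_cosine_series(prof, mode = "free_phase")
  expect_equal(fit$terms$K[1], 1, tolerance = 1e-6)
  d1 <- fit$terms$d[1]
  expect_lt(min(d1, 2 * pi - d1), 1e-6)
  expect_true(all(fit$terms$K[-1] < 1e-8))
  expect_lt(fit$residual, 1e-12)

  # K3 = 2, d3 = pi/4: free phase recovers it, fixed phase cannot
  prof3 <- structure(list(grid = grid,
                          energy = 2 * (1 + cos(3 * grid * pi / 180 - pi / 4)),
                          floor = 1e-4),
                     class = "qt_energy_profile")
  free <- fit_cosine_series(prof3, mode = "free_phase")
  fixed <- fit_cosine_series(prof3, mode = "fixed_phase")
  expect_equal(free$terms$K[3], 2, tolerance = 1e-6)
  expect_equal(free$terms$d[3], pi / 4, tolerance = 1e-6)
  expect_lt(free$residual, 1e-12)
  expect_gt(fixed$residual, free$residual + 1)

  # flat profile -> all force constants vanish
  flat <- structure(list(grid = grid, energy = rep(0, length(grid)),
                         floor = 1e-4), class = "qt_energy_profile")
  ffit <- fit_cosine_series(flat, mode = "free_phase")
  expect_true(all(ffit$terms$K < 1e-10))
})

test_that("free-phase residual never exceeds fixed-phase residual", {
  set.seed(19)
  for (rep in 1:10) {
    spec <- random_mixture_spec()
    ang <- generate_mixture_angles(spec, 2000)
    e <- probabilities_to_energies(build_histogram(ang))
    free <- fit_cosine_series(e, mode = "free_phase")
    fixed <- fit_cosine_series(e, mode = "fixed_phase")
    expect_lte(free$residual, fixed$residual + 1e-9)
    # fixed phases are 0 or pi only
    expect_true(all(fixed$terms$d %in% c(0, pi)))
  }
})

test_that("cosine density is the Boltzmann weight of the fitted energy", {
  grid <- seq(2.5, 357.5, by = 5)
  flat <- structure(list(grid = grid, energy = rep(0, length(grid)),
                         floor = 1e-4), class = "qt_energy_profile")
  d0 <- cosine_to_density(fit_cosine_series(flat, mode = "free_phase"))
  expect_lt(diff(range(d0$density)), 1e-9) # uniform
  expect_equal(qtdg:::density_integral(d0), 1, tolerance = 1e-9)

  # single-minimum term: density mode at the energy minimum (180 deg)
  prof <- structure(list(grid = grid,
                         energy = 1.5 * (1 + cos(grid * pi / 180)),
                         floor = 1e-4), class = "qt_energy_profile")
  d1 <- cosine_to_density(fit_cosine_series(prof, mode = "free_phase"))
  expect_equal(d1$grid[which.max(d1$density)], 180)
})

test_that("Gaussian mixture recovers known components", {
  # one wrapped component
  ang <- generate_mixture_angles(mixture_spec(90, 10), 1e4, seed = 41)
  fit <- fit_gaussian_mixture(build_histogram(ang))
  expect_equal(fit$k, 1L)
  expect_lt(abs(fit$peaks$mean[1] - 90), 1)
  expect_lt(abs(fit$peaks$sigma[1] - 10) / 10, 0.1)

  # two well-separated equal components
  ang2 <- generate_mixture_angles(mixture_spec(c(60, 180), c(10, 10)),
                                  1e4, seed = 42)
  fit2 <- fit_gaussian_mixture(build_histogram(ang2))
  expect_equal(fit2$k, 2L)
  means <- sort(fit2$peaks$mean)
  expect_lt(abs(means[1] - 60), 2)
  expect_lt(abs(means[2] - 180), 2)
  expect_true(all(abs(fit2$peaks$weight - 0.5) < 0.05))

  # component straddling the 0/360 seam
  ang3 <- generate_mixture_angles(mixture_spec(355, 8), 1e4, seed = 43)
  fit3 <- fit_gaussian_mixture(build_histogram(ang3))
  d <- abs(fit3$peaks$mean[1] - 355) %% 360
  expect_lt(min(d, 360 - d), 2)

  expect_error(fit_gaussian_mixture(build_histogram(numeric(0))), "empty")
  expect_error(fit_gaussian_mixture(build_histogram(rep(2, 10))), "few")
})

test_that("fit-quality r2 is scale-invariant and discriminating", {
  set.seed(55)
  ang <- generate_mixture_angles(mixture_spec(c(60, 240), c(10, 12)), 1e4)
  h <- build_histogram(ang)
  # model equal to the histogram itself (as a density) scores 1
  self <- structure(list(grid = h$mids, density = h$counts / h$n / h$step,
                         bandwidth = NA_real_, grid_step = h$step),
                    class = "qt_density")
  expect_equal(fit_quality_r2(self, h), 1.0, tolerance = 1e-12)
  scaled <- self
  scaled$density <- self$density * 3
  expect_equal(fit_quality_r2(scaled, h), 1.0, tolerance = 1e-12)
  # uniform model against a strongly bimodal histogram: undefined (zero
  # variance) -> error, and a slightly perturbed uniform scores near zero
  uni <- self
  uni$density <- rep(1 / 360, 72)
  expect_error(fit_quality_r2(uni, h), "zero-variance")
  set.seed(56)
  near_uni <- self
  near_uni$density <- 1 / 360 + rnorm(72, sd = 1e-6)
  expect_lt(fit_quality_r2(near_uni, h), 0.2)
})
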