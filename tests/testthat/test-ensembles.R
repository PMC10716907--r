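# Ensemble preprocessing and geometry-comparison statistics.

make_butane_ensemble <- function(angles = c(180, 60, 300),
                                 energies = c(0, 0.9, 0.95)) {
  bu <- make_toy_molecule("butane")
  coords <- lapply(angles, function(a) set_dihedral(bu, bu$coords, 0:3, a))
  qt_ensemble(bu, coords, energies = energies)
}

test_that("energy window keeps conformers within the window of the minimum", {
  ens <- make_butane_ensemble(angles = c(180, 60, 300, 90),
                              energies = c(0, 3, 5.9, 6.1))
  expect_length(energy_window_filter(ens, 6)$coords, 3L)
  expect_length(energy_window_filter(ens, 0)$coords, 1L)
  all_equal <- make_butane_ensemble(energies = c(1, 1, 1))
  expect_length(energy_window_filter(all_equal, 0)$coords, 3L)
  # nesting: smaller window is a subset of larger
  k2 <- energy_window_filter(ens, 3)$labels
  k6 <- energy_window_filter(ens, 6)$labels
  expect_true(all(k2 %in% k6))
  noE <- qt_ensemble(make_toy_molecule("butane"),
                     list(make_toy_molecule("butane")$coords))
  expect_error(energy_window_filter(noE), "no energies")
})

test_that("lowest-energy conformer selection and tie-break", {
  ens <- make_butane_ensemble(energies = c(2.0, 0.5, 1.1))
  expect_equal(lowest_energy_conformer(ens)$index, 2L)
  tie <- make_butane_ensemble(angles = c(60, 300), energies = c(0.5, 0.5))
  expect_equal(lowest_energy_conformer(tie)$label, "conf1")
})

test_that("minimum heavy RMSD is zero for self and rigid copies", {
  ens <- make_butane_ensemble()
  ref <- ens$coords[[1]]
  expect_equal(min_heavy_rmsd(ens, ref), 0, tolerance = 1e-6)
  rotated <- random_rigid_transform(ref, seed = 5)
  expect_equal(min_heavy_rmsd(ens, rotated), 0, tolerance = 1e-6)
  expect_error(min_heavy_rmsd(ens, ref[1:2, ]), "mismatch")
})

test_that("Kabsch RMSD matches a brute-force rigid-body minimisation", {
  # 3-atom toy with one displaced atom; oracle = direct minimisation over
  # Euler angles + translation
  a <- matrix(c(0,0,0, 1.5,0,0, 0.7,1.2,0), 3, 3, byrow = TRUE)
  b <- a; b[3, ] <- b[3, ] + c(0.2, -0.15, 0.1)
  oracle <- function(par) {
    ca <- cos(par[1]); sa <- sin(par[1])
    cb <- cos(par[2]); sb <- sin(par[2])
    cg <- cos(par[3]); sg <- sin(par[3])
    Rz <- matrix(c(ca,-sa,0, sa,ca,0, 0,0,1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cb,0,sb, 0,1,0, -sb,0,cb), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1,0,0, 0,cg,-sg, 0,sg,cg), 3, 3, byrow = TRUE)
    moved <- b %*% t(Rz %*% Ry %*% Rx)
    moved <- sweep(moved, 2, par[4:6], "+")
    sqrt(mean(rowSums((moved - a)^2)))
  }
  best <- Inf
  set.seed(2)
  for (k in 1:40) {
    r <- optim(c(runif(3, -pi, pi), rnorm(3, sd = 0.1)), oracle,
               method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    r2 <- optim(r$par, oracle, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, r$value, r2$value)
  }
  mol <- qt_mol(c("C", "C", "C"),
                data.frame(a1 = c(0L, 1L), a2 = c(1L, 2L), order = 1L),
                coords = a, id = "tri")
  ens <- qt_ensemble(mol, list(b), energies = 0)
  expect_equal(min_heavy_rmsd(ens, a), best, tolerance = 1e-5)
})

test_that("RMSD is invariant to rigid transforms of either side", {
  ens <- make_butane_ensemble()
  ref <- ens$coords[[2]]
  base <- min_heavy_rmsd(ens, ens$coords[[1]] + 0) # deterministic baseline
  moved_ens <- qt_ensemble(ens$mol,
                           lapply(seq_along(ens$coords), function(i)
                             random_rigid_transform(ens$coords[[i]], seed = i)),
                           energies = ens$energies)
  expect_equal(min_heavy_rmsd(moved_ens, ens$coords[[1]]), base,
               tolerance = 1e-6)
  expect_equal(min_heavy_rmsd(ens, random_rigid_transform(ens$coords[[1]],
                                                          seed = 42)),
               base, tolerance = 1e-6)
})

test_that("symmetry-aware RMSD finds equivalent atom orderings", {
  # 2-methylbutane skeleton: swapping the two C2 methyls is a graph
  # automorphism but geometrically a reflection, which no proper rotation
  # can undo -- so naive correspondence reports a spurious RMSD
  t3 <- 1.5 / sqrt(3)
  coords <- rbind(c(t3, t3, t3),     # 0: methyl a
                  c(0, 0, 0),        # 1: CH
                  c(t3, -t3, -t3),   # 2: methyl b
                  c(-t3, t3, -t3),   # 3: CH2
                  c(-t3 - 1.2, t3 + 0.6, -t3 - 0.9)) # 4: terminal methyl
  mol <- qt_mol(rep("C", 5),
                data.frame(a1 = c(0L, 1L, 1L, 3L), a2 = c(1L, 2L, 3L, 4L),
                           order = 1L),
                coords = coords, id = "isopentane")
  perm <- c(2L, 1L, 0L, 3L, 4L) # swap the equivalent methyls
  ens <- qt_ensemble(mol, list(coords[perm + 1L, ]), energies = 0)
  plain <- min_heavy_rmsd(ens, coords)
  sym <- min_heavy_rmsd(ens, coords, symmetry = TRUE)
  expect_gt(plain, 0.1)
  expect_equal(sym, 0, tolerance = 1e-6)
})

test_that("radius of gyration matches hand-computed values", {
  expect_equal(radius_of_gyration(matrix(c(0, 0, 0), 1, 3)), 0)
  two <- matrix(c(0,0,0, 2,0,0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 1.0)
  square <- matrix(c(0,0,0, 1,0,0, 1,1,0, 0,1,0), 4, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(square), sqrt(0.5))
  # translation/rotation invariant, scales linearly
  moved <- random_rigid_transform(square, seed = 8)
  expect_equal(radius_of_gyration(moved), sqrt(0.5), tolerance = 1e-9)
  expect_equal(radius_of_gyration(square * 3), 3 * sqrt(0.5))
  # hydrogens excluded when elements given
  withH <- rbind(two, c(50, 50, 50))
  expect_equal(radius_of_gyration(withH, elements = c("C", "C", "H")), 1.0)
})

test_that("Rg ratio behaves as a ratio", {
  sq <- matrix(c(0,0,0, 1,0,0, 1,1,0, 0,1,0), 4, 3, byrow = TRUE)
  expect_equal(rg_ratio(sq, sq), 1.0)
  expect_equal(rg_ratio(sq, sq * 2), 0.5)
  expect_error(rg_ratio(sq, matrix(c(1, 1, 1), 1, 3)), "zero")
})

test_that("rotatable bonds: terminal, ring and amide bonds excluded", {
  expect_equal(rotatable_bond_count(read_smiles("CC")), 0L)
  expect_equal(rotatable_bond_count(read_smiles("CCCC")), 1L)
  expect_equal(rotatable_bond_count(read_smiles("c1ccccc1")), 0L)
  # N-methylacetamide: the amide C-N bond does not count
  expect_equal(rotatable_bond_count(read_smiles("CC(=O)NC")), 0L)
  # pentane: 2
  expect_equal(rotatable_bond_count(read_smiles("CCCCC")), 2L)
})

test_that("RMSD-vs-rotors regression matches closed-form OLS", {
  rec <- data.frame(n_rotatable_bonds = c(0, 2, 4),
                    min_rmsd = c(0.1, 0.5, 0.9))
  fit <- rmsd_vs_rotors_regression(rec)
  expect_equal(fit$slope, 0.2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)
  flat <- data.frame(n_rotatable_bonds = c(0, 2, 4), min_rmsd = c(1, 1, 1))
  expect_equal(rmsd_vs_rotors_regression(flat)$slope, 0, tolerance = 1e-12)
  two <- data.frame(n_rotatable_bonds = c(1, 3), min_rmsd = c(0.2, 0.8))
  f2 <- rmsd_vs_rotors_regression(two)
  expect_equal(f2$intercept + 1 * f2$slope, 0.2, tolerance = 1e-12)
  degen <- data.frame(n_rotatable_bonds = c(2, 2), min_rmsd = c(0.1, 0.2))
  expect_error(rmsd_vs_rotors_regression(degen), "degenerate")
})

test_that("RMSD summaries are correct and monotone in threshold", {
  s <- rmsd_summary(c(0.1, 0.3, 0.7), thresholds = 0.5)
  expect_equal(unname(s$fraction_within), 2 / 3)
  expect_equal(s$median, 0.3)
  one <- rmsd_summary(0.42)
  expect_equal(one$median, 0.42)
  expect_equal(one$mean, 0.42)
  set.seed(9)
  x <- runif(50)
  fr <- rmsd_summary(x, thresholds = seq(0, 1, by = 0.1))$fraction_within
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 1))
})
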