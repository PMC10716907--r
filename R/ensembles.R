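# Conformer-ensemble container, preprocessing (fragment stripping, identity
# checks, energy windows) and geometry-comparison statistics (minimum
# heavy-atom RMSD, radius of gyration, rotatable-bond regression).

#' Construct a conformer ensemble
#'
#' @param mol a `qt_mol` carrying the shared connectivity (its own
#'   coordinates, if any, are ignored).
#' @param coords list of N x 3 coordinate matrices, one per conformer.
#' @param energies numeric vector of conformer energies in kcal/mol, or
#'   `NULL` when absent (energies must be present or absent as a block).
#' @param labels conformer labels (default `conf1..confK`).
#' @return an object of class `qt_ensemble`.
#' @export
qt_ensemble <- function(mol, coords, energies = NULL, labels = NULL) {
  stopifnot(inherits(mol, "qt_mol"))
  if (!is.list(coords) || length(coords) == 0) stop("no conformers")
  n <- n_atoms(mol)
  coords <- lapply(coords, function(x) {
    x <- as.matrix(x); dimnames(x) <- NULL
    if (nrow(x) != n || ncol(x) != 3) stop("conformer shape mismatch")
    x
  })
  if (!is.null(energies)) {
    energies <- as.numeric(energies)
    if (length(energies) != length(coords)) stop("energy count mismatch")
    if (any(!is.finite(energies))) stop("non-finite energies")
  }
  if (is.null(labels)) labels <- sprintf("conf%d", seq_along(coords))
  structure(list(mol = mol, coords = coords, energies = energies,
                 labels = as.character(labels)), class = "qt_ensemble")
}

#' @export
print.qt_ensemble <- function(x, ...) {
  cat(sprintf("<qt_ensemble %s: %d conformers, %d atoms%s>\n", x$mol$id,
              length(x$coords), n_atoms(x$mol),
              if (is.null(x$energies)) "" else sprintf(
                ", E range %.2f kcal/mol",
                diff(range(x$energies)))))
  invisible(x)
}

#' Read a multi-record SDF as a conformer ensemble
#'
#' All records must share the atom count and connectivity. Energies are
#' taken from an SDF property tag (default `energy_kcal`) or from a
#' two-column sidecar CSV (`label,energy`).
#'
#' @param path SDF path.
#' @param energy_tag SDF property tag holding the conformer energy in
#'   kcal/mol; ignored when `energy_csv` is given.
#' @param energy_csv optional sidecar CSV with columns `label`, `energy`.
#' @return a `qt_ensemble` (energies `NULL` when no source provides them).
#' @export
read_sdf_ensemble <- function(path, energy_tag = "energy_kcal",
                              energy_csv = NULL) {
  mols <- read_sdf(path)
  ref <- mols[[1]]
  for (m in mols[-1]) {
    if (n_atoms(m) != n_atoms(ref) ||
        !identical(m$elements, ref$elements) ||
        !identical(m$bonds, ref$bonds))
      stop("SDF records do not share connectivity; not an ensemble")
  }
  labels <- vapply(seq_along(mols),
                   function(i) sprintf("conf%d", i), character(1))
  energies <- NULL
  if (!is.null(energy_csv)) {
    tab <- read.csv(energy_csv, stringsAsFactors = FALSE)
    energies <- tab$energy[match(labels, tab$label)]
    if (any(is.na(energies))) stop("sidecar CSV missing energies for some conformers")
  } else {
    vals <- vapply(mols, function(m) {
      d <- attr(m, "data")
      if (!is.null(d) && energy_tag %in% names(d))
        suppressWarnings(as.numeric(d[[energy_tag]])) else NA_real_
    }, numeric(1))
    if (all(is.finite(vals))) energies <- vals
  }
  qt_ensemble(ref, lapply(mols, `[[`, "coords"), energies = energies,
              labels = labels)
}

#' Keep the largest disconnected fragment
#'
#' Salts and solvent are dropped by keeping the component with the most
#' heavy atoms; ties go to the larger total atom count, then to the
#' lexicographically smallest canonical identifier.
#'
#' @param mol a `qt_mol`, possibly multi-component.
#' @return single-component `qt_mol`.
#' @export
strip_to_largest_fragment <- function(mol) {
  comps <- .components(mol)
  if (length(comps) == 1) return(mol)
  heavy <- vapply(comps, function(c0) sum(mol$elements[c0 + 1L] != "H"),
                  integer(1))
  total <- lengths(comps)
  keep <- which(heavy == max(heavy))
  if (length(keep) > 1) keep <- keep[total[keep] == max(total[keep])]
  if (length(keep) > 1) {
    ids <- vapply(keep, function(k) .mol_to_inchi(.subset_mol(mol, comps[[k]])),
                  character(1))
    keep <- keep[order(ids)][1]
  } else keep <- keep[1]
  .subset_mol(mol, comps[[keep]])
}

#' Check whether two molecules are the same compound
#'
#' Connectivity-level identity via canonical InChI (coordinates are
#' irrelevant). Used to exclude systems where conformer generation produced
#' a different compound than the input.
#'
#' @param a,b `qt_mol` objects with full connectivity.
#' @return `TRUE` iff the canonical identifiers match.
#' @export
identity_check <- function(a, b) {
  .mol_to_inchi(a) == .mol_to_inchi(b)
}

#' Filter conformers by relative energy window
#'
#' @param ensemble a `qt_ensemble` with energies.
#' @param window window width in kcal/mol above the ensemble minimum
#'   (default 6).
#' @return filtered `qt_ensemble`; the minimum-energy conformer always
#'   survives.
#' @export
energy_window_filter <- function(ensemble, window = 6) {
  if (is.null(ensemble$energies)) stop("ensemble has no energies")
  keep <- which(ensemble$energies - min(ensemble$energies) <= window)
  qt_ensemble(ensemble$mol, ensemble$coords[keep],
              energies = ensemble$energies[keep],
              labels = ensemble$labels[keep])
}

#' Lowest-energy conformer of an ensemble
#'
#' @param ensemble a `qt_ensemble` with energies.
#' @return list with `coords`, `energy`, `label`, `index`. Ties go to the
#'   first label in order.
#' @export
lowest_energy_conformer <- function(ensemble) {
  if (length(ensemble$coords) == 0) stop("empty ensemble")
  if (is.null(ensemble$energies)) stop("ensemble has no energies")
  i <- which.min(ensemble$energies)
  list(coords = ensemble$coords[[i]], energy = ensemble$energies[i],
       label = ensemble$labels[i], index = i)
}

# heavy-atom RMSD after Kabsch superposition (bio3d does the fit; the RMSD
# is computed here at full precision, bio3d::rmsd rounds its output)
.kabsch_rmsd <- function(a, b) {
  idx <- seq_len(3 * nrow(a))
  fitted <- bio3d::fit.xyz(as.vector(t(b)), as.vector(t(a)),
                           fixed.inds = idx, mobile.inds = idx)
  sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - b)^2)))
}

# graph automorphisms of the heavy-atom skeleton (element-labelled), as a
# matrix of 0-based permutations (rows); capped to avoid blow-ups
.heavy_automorphisms <- function(mol, cap = 5000L) {
  h0 <- heavy_idx(mol)
  sub <- .subset_mol(mol, h0)
  # self-match: query graph = molecule graph with element/degree constraints
  nq <- n_atoms(sub)
  atoms <- lapply(seq_len(nq), function(i) list(list(
    list(type = "element", value = list(sym = sub$elements[i],
                                        arom = sub$aromatic_atom[i]),
         negate = FALSE))))
  bonds <- lapply(seq_len(nrow(sub$bonds)), function(k) list(
    a1 = sub$bonds$a1[k] + 1L, a2 = sub$bonds$a2[k] + 1L,
    expr = list(list(list(type = "~", negate = FALSE)))))
  q <- structure(list(smarts = "<self>", atoms = atoms,
                      maps = integer(nq), bonds = bonds),
                 class = "qt_smarts")
  perms <- smarts_match(q, sub)
  # filter to bond-order-preserving permutations
  key <- paste(pmin(sub$bonds$a1, sub$bonds$a2),
               pmax(sub$bonds$a1, sub$bonds$a2))
  ord <- setNames(sub$bonds$order, key)
  ok <- apply(perms, 1, function(p) {
    all(ord[paste(pmin(p[sub$bonds$a1 + 1L], p[sub$bonds$a2 + 1L]),
                  pmax(p[sub$bonds$a1 + 1L], p[sub$bonds$a2 + 1L]))] ==
        sub$bonds$order)
  })
  perms <- perms[ok, , drop = FALSE]
  if (nrow(perms) > cap) perms <- perms[seq_len(cap), , drop = FALSE]
  perms
}

#' Minimum heavy-atom RMSD between an ensemble and a reference
#'
#' For each conformer, hydrogens are dropped and the conformer is optimally
#' superposed on the reference (Kabsch); the smallest RMSD over the
#' ensemble is returned. Atom correspondence is by stored atom order;
#' `symmetry = TRUE` additionally minimizes over element- and
#' bond-preserving graph automorphisms of the heavy-atom skeleton.
#'
#' @param ensemble a `qt_ensemble`.
#' @param reference N x 3 coordinate matrix in the ensemble's atom order.
#' @param symmetry minimize over graph automorphisms (slower).
#' @return minimum RMSD in Angstrom.
#' @export
min_heavy_rmsd <- function(ensemble, reference, symmetry = FALSE) {
  reference <- as.matrix(reference)
  if (nrow(reference) != n_atoms(ensemble$mol))
    stop("reference atom count mismatch")
  h1 <- heavy_idx(ensemble$mol) + 1L
  ref_h <- reference[h1, , drop = FALSE]
  perms <- if (symmetry) .heavy_automorphisms(ensemble$mol)
           else matrix(seq_along(h1) - 1L, nrow = 1)
  best <- Inf
  for (cf in ensemble$coords) {
    cf_h <- cf[h1, , drop = FALSE]
    for (r in seq_len(nrow(perms))) {
      p <- perms[r, ] + 1L
      val <- .kabsch_rmsd(cf_h[p, , drop = FALSE], ref_h)
      if (val < best) best <- val
    }
  }
  best
}

#' Radius of gyration of a structure
#'
#' Unweighted root-mean-square distance of heavy atoms from their centroid:
#' sqrt(sum |r_i - rbar|^2 / N). Hydrogens are excluded when element
#' symbols are supplied.
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param elements optional element symbols; rows with `"H"` are dropped.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords, elements = NULL) {
  coords <- as.matrix(coords)
  if (!is.null(elements)) coords <- coords[elements != "H", , drop = FALSE]
  if (nrow(coords) == 0) stop("no atoms")
  ctr <- colMeans(coords)
  sqrt(sum(sweep(coords, 2, ctr)^2) / nrow(coords))
}

#' Ratio of conformer to reference radius of gyration
#'
#' @param conformer,reference N x 3 coordinate matrices (heavy atoms or
#'   with `elements` passed through to [radius_of_gyration()]).
#' @param elements optional element symbols applied to both.
#' @return dimensionless ratio Rg(conformer) / Rg(reference).
#' @export
rg_ratio <- function(conformer, reference, elements = NULL) {
  rr <- radius_of_gyration(reference, elements)
  if (rr <= 0) stop("reference radius of gyration is zero")
  radius_of_gyration(conformer, elements) / rr
}

#' Count rotatable bonds
#'
#' A rotatable bond is an acyclic single bond between two non-terminal
#' heavy atoms (each end bonded to at least one further heavy atom),
#' excluding amide C-N bonds (carbon double-bonded to oxygen and singly
#' bonded to the nitrogen).
#'
#' @param mol a `qt_mol`.
#' @return integer count.
#' @export
rotatable_bond_count <- function(mol) {
  if (nrow(mol$bonds) == 0) return(0L)
  heavy_deg <- integer(n_atoms(mol))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    if (mol$elements[j + 1L] != "H") heavy_deg[i + 1L] <- heavy_deg[i + 1L] + 1L
    if (mol$elements[i + 1L] != "H") heavy_deg[j + 1L] <- heavy_deg[j + 1L] + 1L
  }
  is_amide_cn <- function(i, j) {
    # i carbon, j nitrogen (or swapped): C has a double bond to O
    for (ord in list(c(i, j), c(j, i))) {
      ci <- ord[1]; nj <- ord[2]
      if (mol$elements[ci + 1L] == "C" && mol$elements[nj + 1L] == "N") {
        dbl_o <- any(mol$bonds$order == 2L &
          ((mol$bonds$a1 == ci & mol$elements[mol$bonds$a2 + 1L] == "O") |
           (mol$bonds$a2 == ci & mol$elements[mol$bonds$a1 + 1L] == "O")))
        if (dbl_o) return(TRUE)
      }
    }
    FALSE
  }
  count <- 0L
  for (k in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[k] != 1L || mol$aromatic_bond[k] || mol$ring_bond[k])
      next
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    if (mol$elements[i + 1L] == "H" || mol$elements[j + 1L] == "H") next
    if (heavy_deg[i + 1L] < 2L || heavy_deg[j + 1L] < 2L) next
    if (is_amide_cn(i, j)) next
    count <- count + 1L
  }
  count
}

#' Regression of minimum RMSD on rotatable-bond count
#'
#' Ordinary least squares of `min_rmsd` against `n_rotatable_bonds`,
#' matching the best-fit-line summaries used when comparing ensembles
#' against reference geometries across a data set.
#'
#' @param records data.frame with columns `n_rotatable_bonds` and
#'   `min_rmsd` (e.g. built from [min_heavy_rmsd()] results).
#' @return list with `slope` (Angstrom per rotor), `intercept` (Angstrom),
#'   and the underlying `lm` fit.
#' @export
rmsd_vs_rotors_regression <- function(records) {
  if (nrow(records) < 2) stop("need at least two records")
  if (length(unique(records$n_rotatable_bonds)) < 2)
    stop("degenerate design: all rotor counts equal")
  fit <- lm(min_rmsd ~ n_rotatable_bonds, data = records)
  cf <- coef(fit)
  list(slope = unname(cf[2]), intercept = unname(cf[1]), fit = fit)
}

#' Summary statistics over minimum RMSD records
#'
#' @param records data.frame with a `min_rmsd` column (or a bare numeric
#'   vector of RMSDs).
#' @param thresholds RMSD thresholds in Angstrom for coverage fractions
#'   (default `c(0.2, 0.5, 1.0)`).
#' @return list with `median`, `mean`, and `fraction_within` (named numeric
#'   vector, one entry per threshold).
#' @export
rmsd_summary <- function(records, thresholds = c(0.2, 0.5, 1.0)) {
  x <- if (is.data.frame(records)) records$min_rmsd else as.numeric(records)
  if (length(x) == 0) stop("no records")
  fr <- vapply(thresholds, function(t) mean(x <= t), numeric(1))
  names(fr) <- sprintf("%.3g", thresholds)
  list(median = median(x), mean = mean(x), fraction_within = fr)
}
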