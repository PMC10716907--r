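# Shared fixtures, built in code.

# two-pattern mini-library hitting the butane central bond at different
# hierarchy ranks (rank 0 = more specific methyl-terminated pattern)
mini_library <- function(smarts = c(
  "[CX4H3:1][CX4H2:2]!@[CX4H2:3][CX4H3:4]",
  "[!#1:1][CX4:2]!@[CX4:3][!#1:4]"),
  kind = rep("acyclic", length(smarts))) {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    library = "test", version = "test",
    patterns = lapply(seq_along(smarts), function(i)
      list(smarts = smarts[i], kind = kind[i]))),
    tmp, auto_unbox = TRUE)
  load_pattern_library(tmp)
}

# rigid-body transform helper: random rotation (from QR) plus translation
random_rigid_transform <- function(coords, seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(coords %*% R, 2, rnorm(3, sd = 5), "+")
}

.subset_mol_for_test <- function(mol, keep0) qtdg:::.subset_mol(mol, keep0)

# amide/aromatic test molecule: phenylacetyl-N-methylamide
# atoms: 0-5 benzene ring, 6 CH2, 7 C(=O), 8 O, 9 N, 10 CH3
amide_mol <- function() {
  read_smiles("c1ccccc1CC(=O)NC", id = "amide")
}
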