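# Molecule and ensemble I/O. SDF parsing is delegated to ChemmineR; SMILES
# and InChI go through the Open Babel bindings in ChemmineOB.

.mol_from_chemmine_sdf <- function(sdf, id = "mol") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  bonds <- if (length(bb) == 0 || nrow(bb) == 0) {
    data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    data.frame(a1 = as.integer(bb[, 1]) - 1L, a2 = as.integer(bb[, 2]) - 1L,
               order = as.integer(bb[, 3]))
  }
  # V2000 charge codes in atom-block column 5: 0 none, 1:+3 .. 3:+1,
  # 5:-1 .. 7:-3 (4 is a radical, ignored here)
  charges <- integer(length(elements))
  if (ncol(ab) >= 5) {
    code <- as.integer(ab[, 5])
    charges <- ifelse(code %in% 1:3, 4L - code,
                      ifelse(code %in% 5:7, 4L - code, 0L))
  }
  qt_mol(elements, bonds, coords = coords, charges = charges, id = id)
}

#' Read molecules from an SDF file
#'
#' Each record becomes a `qt_mol`. Records sharing connectivity can be
#' combined into a conformer ensemble with [read_sdf_ensemble()].
#'
#' @param path path to a V2000 SDF file.
#' @return list of `qt_mol` objects; each carries a `data` attribute with
#'   the record's property tags.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sdfset <- ChemmineR::read.SDFset(path)
  chg <- .parse_mchg_blocks(path)
  out <- vector("list", length(sdfset))
  for (i in seq_along(sdfset)) {
    sdf <- sdfset[[i]]
    id <- ChemmineR::sdfid(sdfset)[i]
    if (is.na(id) || id == "") id <- sprintf("mol%03d", i)
    m <- .mol_from_chemmine_sdf(sdf, id = id)
    if (length(chg) >= i && length(chg[[i]]) > 0) {
      charges <- integer(n_atoms(m))
      charges[chg[[i]][, 1]] <- chg[[i]][, 2]
      m <- qt_mol(m$elements, m$bonds, coords = m$coords,
                  charges = charges, id = m$id)
    }
    attr(m, "data") <- ChemmineR::datablock(sdf)
    out[[i]] <- m
  }
  out
}

# "M  CHG" properties per record (ChemmineR drops them); returns a list of
# two-column matrices (1-based atom index, charge)
.parse_mchg_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  marks <- grep("^\\$\\$\\$\\$", lines)
  if (length(marks) == 0) marks <- length(lines)
  starts <- c(1L, head(marks, -1) + 1L)
  lapply(seq_along(marks), function(i) {
    block <- lines[starts[i]:marks[i]]
    rows <- grep("^M  CHG", block, value = TRUE)
    if (length(rows) == 0) return(matrix(integer(), 0, 2))
    do.call(rbind, lapply(rows, function(r) {
      v <- as.integer(strsplit(trimws(sub("^M  CHG\\s*\\d+", "", r)),
                               "\\s+")[[1]])
      matrix(v, ncol = 2, byrow = TRUE)
    }))
  })
}

#' Write molecules to an SDF file
#'
#' @param mols a `qt_mol` or list of them; conformer ensembles are written
#'   as one record per conformer.
#' @param path output path.
#' @param data optional named character vector (or list of them) of property
#'   tags per record.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, data = NULL) {
  if (inherits(mols, "qt_mol")) mols <- list(mols)
  if (!is.null(data) && !is.list(data)) data <- list(data)
  lines <- character()
  for (i in seq_along(mols)) {
    mol <- mols[[i]]
    if (is.null(mol$coords)) stop("cannot write molecule without coordinates")
    n <- n_atoms(mol); nb <- nrow(mol$bonds)
    lines <- c(lines, mol$id, "  qtdg", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    for (a in seq_len(n)) {
      lines <- c(lines, sprintf(
        "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        mol$coords[a, 1], mol$coords[a, 2], mol$coords[a, 3],
        mol$elements[a]))
    }
    for (k in seq_len(nb)) {
      lines <- c(lines, sprintf("%3d%3d%3d  0",
                                mol$bonds$a1[k] + 1L, mol$bonds$a2[k] + 1L,
                                mol$bonds$order[k]))
    }
    chg <- which(mol$charges != 0)
    if (length(chg) > 0) {
      lines <- c(lines, sprintf("M  CHG%3d%s", length(chg),
                                paste(sprintf("%4d%4d", chg,
                                              mol$charges[chg]),
                                      collapse = "")))
    }
    lines <- c(lines, "M  END")
    tags <- if (!is.null(data) && length(data) >= i) data[[i]] else NULL
    if (!is.null(tags)) {
      for (nm in names(tags))
        lines <- c(lines, paste0("> <", nm, ">"), as.character(tags[[nm]]), "")
    }
    lines <- c(lines, "$$$$")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a SMILES string into a connectivity-only molecule
#'
#' Open Babel generates the graph (and 2D placeholder coordinates, which are
#' dropped); use this for operations that need connectivity only, such as
#' identity checks or rotatable-bond counts.
#'
#' @param smiles a SMILES string.
#' @param id molecule identifier.
#' @return a `qt_mol` without coordinates.
#' @export
read_smiles <- function(smiles, id = smiles) {
  sdfset <- ChemmineR::smiles2sdf(smiles)
  m <- .mol_from_chemmine_sdf(sdfset[[1]], id = id)
  m$coords <- NULL
  m
}

#' Read a multi-frame XYZ file as a list of coordinate matrices
#'
#' XYZ carries no connectivity; frames are returned as bare N x 3 matrices
#' with element symbols in the `elements` attribute, suitable for attaching
#' to an existing molecule as conformers.
#'
#' @param path path to an XYZ file (one or more concatenated frames).
#' @return list of N x 3 coordinate matrices.
#' @export
read_xyz_frames <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i])) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ frame header at line ", i)
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    coords <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    attr(coords, "elements") <- vapply(toks, `[`, character(1), 1L)
    attr(coords, "comment") <- lines[i + 1L]
    frames[[length(frames) + 1L]] <- coords
    i <- i + 2L + n
  }
  frames
}

# canonical identifier via Open Babel; used by identity_check()
.mol_to_inchi <- function(mol) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  m <- mol
  if (is.null(m$coords)) m$coords <- matrix(0, n_atoms(m), 3)
  write_sdf(m, tmp)
  out <- tryCatch(
    ChemmineOB::convertFormatFile("SDF", "INCHI", tmp, paste0(tmp, ".inchi")),
    error = function(e) NULL)
  res <- tryCatch(readLines(paste0(tmp, ".inchi"), warn = FALSE),
                  error = function(e) character())
  unlink(paste0(tmp, ".inchi"))
  res <- res[grepl("^InChI=", res)]
  if (length(res) == 0) stop("InChI generation failed for ", mol$id)
  res[1]
}
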