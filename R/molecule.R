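#' @importFrom stats approx coef lm median runif rnorm setNames cor pnorm
#' @importFrom utils head read.csv write.csv
NULL

# Standard valences used to infer implicit hydrogen counts from a kekulized
# bond block. Where an element supports several valence states the smallest
# one accommodating the explicit bond-order sum is used.
.default_valences <- list(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1,
  Si = 4, P = c(3, 5), S = c(2, 4, 6), Cl = 1, Br = 1, I = 1
)

#' Construct a molecule object
#'
#' A lightweight molecular graph with optional 3D coordinates: element
#' symbols, a kekulized bond table, formal charges, and perceived ring and
#' aromaticity flags. All atom indices are 0-based internally; SDF 1-based
#' indices are converted at the I/O boundary.
#'
#' @param elements character vector of element symbols.
#' @param bonds data.frame with integer columns `a1`, `a2` (0-based) and
#'   `order` (1, 2, 3, or 4 for an explicitly aromatic bond).
#' @param coords numeric N x 3 matrix of Cartesian coordinates in Angstrom,
#'   or `NULL` for connectivity-only molecules.
#' @param charges integer vector of formal charges (default all zero).
#' @param id molecule identifier string.
#' @return An object of class `qt_mol`.
#' @export
qt_mol <- function(elements, bonds, coords = NULL, charges = NULL,
                   id = "mol") {
  n <- length(elements)
  if (n == 0L) stop("molecule has no atoms")
  if (is.null(charges)) charges <- integer(n)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3)
      stop("coords must be an N x 3 matrix matching the atom count")
    dimnames(coords) <- NULL
  }
  if (nrow(bonds) > 0) {
    bonds <- data.frame(a1 = as.integer(bonds$a1), a2 = as.integer(bonds$a2),
                        order = as.integer(bonds$order))
    if (any(bonds$a1 < 0 | bonds$a1 >= n | bonds$a2 < 0 | bonds$a2 >= n))
      stop("bond atom index out of range")
    if (any(bonds$a1 == bonds$a2)) stop("self-bond")
  } else {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  mol <- structure(list(
    id = id, elements = as.character(elements), bonds = bonds,
    coords = coords, charges = as.integer(charges)
  ), class = "qt_mol")
  mol <- .perceive(mol)
  mol
}

#' @export
print.qt_mol <- function(x, ...) {
  cat(sprintf("<qt_mol %s: %d atoms (%d heavy), %d bonds%s>\n",
              x$id, length(x$elements), sum(x$elements != "H"),
              nrow(x$bonds),
              if (is.null(x$coords)) ", no coordinates" else ""))
  invisible(x)
}

n_atoms <- function(mol) length(mol$elements)

heavy_idx <- function(mol) which(mol$elements != "H") - 1L

# adjacency list, 0-based in and out
.adj_list <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      adj[[i + 1L]] <- c(adj[[i + 1L]], j)
      adj[[j + 1L]] <- c(adj[[j + 1L]], i)
    }
  }
  adj
}

# ring-bond perception (a bond is in a ring iff its endpoints stay connected
# after its removal) and aromatic perception: explicit order-4 bonds, plus
# 5/6-membered cycles of C/N/O/S with alternating single/double kekule orders
.perceive <- function(mol) {
  nb <- nrow(mol$bonds)
  ring_bond <- logical(nb)
  adj <- .adj_list(mol)
  if (nb > 0) {
    for (k in seq_len(nb)) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      ring_bond[k] <- .connected_without(adj, i, j)
    }
  }
  mol$ring_bond <- ring_bond
  ring_atom <- logical(n_atoms(mol))
  if (any(ring_bond)) {
    ra <- unique(c(mol$bonds$a1[ring_bond], mol$bonds$a2[ring_bond]))
    ring_atom[ra + 1L] <- TRUE
  }
  mol$ring_atom <- ring_atom

  arom_bond <- mol$bonds$order == 4L
  arom_atom <- logical(n_atoms(mol))
  for (cyc in .find_cycles(adj, max_len = 6L)) {
    if (!all(mol$elements[cyc + 1L] %in% c("C", "N", "O", "S"))) next
    m <- length(cyc)
    orders <- integer(m)
    bidx <- integer(m)
    ok <- TRUE
    for (t in seq_len(m)) {
      i <- cyc[t]; j <- cyc[if (t == m) 1L else t + 1L]
      k <- which((mol$bonds$a1 == i & mol$bonds$a2 == j) |
                 (mol$bonds$a1 == j & mol$bonds$a2 == i))[1]
      if (is.na(k)) { ok <- FALSE; break }
      orders[t] <- mol$bonds$order[k]; bidx[t] <- k
    }
    if (!ok) next
    aromatic <- all(orders == 4L) ||
      (m == 6L && all(orders %in% c(1L, 2L)) && sum(orders == 2L) == 3L &&
       all(abs(diff(orders)) == 1L))
    if (aromatic) {
      arom_bond[bidx] <- TRUE
      arom_atom[cyc + 1L] <- TRUE
    }
  }
  mol$aromatic_bond <- arom_bond
  mol$aromatic_atom <- arom_atom

  # implicit H from smallest standard valence >= kekule bond-order sum
  n <- n_atoms(mol)
  bsum <- numeric(n)
  if (nb > 0) {
    for (k in seq_len(nb)) {
      o <- mol$bonds$order[k]
      ov <- if (o == 4L) 1.5 else o
      bsum[mol$bonds$a1[k] + 1L] <- bsum[mol$bonds$a1[k] + 1L] + ov
      bsum[mol$bonds$a2[k] + 1L] <- bsum[mol$bonds$a2[k] + 1L] + ov
    }
  }
  imp <- integer(n)
  for (i in seq_len(n)) {
    vals <- .default_valences[[mol$elements[i]]]
    if (is.null(vals)) { imp[i] <- 0L; next }
    # formal charge shifts valence for the common organic set
    # (N+ -> 4, O- -> 1, etc.)
    if (mol$elements[i] %in% c("N", "P", "O", "S", "F", "Cl", "Br", "I"))
      vals <- pmax(0, vals + mol$charges[i])
    need <- ceiling(bsum[i] - 1e-9)
    v <- vals[vals >= need]
    imp[i] <- if (length(v) == 0) 0L else as.integer(max(0, min(v) - round(bsum[i])))
  }
  mol$implicit_h <- imp
  # total H count and total connectivity per atom (SMARTS H and X primitives)
  adj <- .adj_list(mol)
  exp_h <- vapply(seq_len(n), function(i)
    sum(mol$elements[adj[[i]] + 1L] == "H"), integer(1))
  mol$total_h <- exp_h + imp
  mol$degree <- vapply(adj, length, integer(1))
  mol$connectivity <- mol$degree + imp
  mol
}

.connected_without <- function(adj, i, j) {
  # BFS from i to j with the direct i-j edge removed
  n <- length(adj)
  seen <- logical(n)
  seen[i + 1L] <- TRUE
  queue <- i
  first <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v + 1L]]) {
      if (first && v == i && w == j) next
      if (w == j && v != i) return(TRUE)
      if (w == j && v == i) next
      if (!seen[w + 1L]) { seen[w + 1L] <- TRUE; queue <- c(queue, w) }
    }
    first <- FALSE
  }
  seen[j + 1L] && FALSE
}

# enumerate simple cycles up to max_len (unique by atom set); molecules here
# are small so a DFS over paths is adequate
.find_cycles <- function(adj, max_len = 6L) {
  n <- length(adj)
  cycles <- list()
  seen_keys <- character()
  path <- integer(max_len)
  dfs <- function(start, v, depth, inpath) {
    for (w in adj[[v + 1L]]) {
      if (w == start && depth >= 3L) {
        cyc <- path[seq_len(depth)]
        key <- paste(sort(cyc), collapse = ",")
        if (!(key %in% seen_keys)) {
          seen_keys <<- c(seen_keys, key)
          cycles[[length(cycles) + 1L]] <<- cyc
        }
      } else if (depth < max_len && !inpath[w + 1L] && w > start) {
        path[depth + 1L] <<- w
        inpath[w + 1L] <- TRUE
        dfs(start, w, depth + 1L, inpath)
        inpath[w + 1L] <- FALSE
      }
    }
  }
  for (s in 0:(n - 1L)) {
    inpath <- logical(n)
    inpath[s + 1L] <- TRUE
    path[1] <- s
    dfs(s, s, 1L, inpath)
  }
  cycles
}

# connected components of the molecular graph; returns list of 0-based
# atom-index vectors
.components <- function(mol) {
  adj <- .adj_list(mol)
  n <- n_atoms(mol)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]] + 1L) {
        if (is.na(comp[w])) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  lapply(seq_len(cur), function(k) which(comp == k) - 1L)
}

# subset a molecule to a 0-based atom index vector (keeps order given)
.subset_mol <- function(mol, keep0) {
  keep1 <- keep0 + 1L
  remap <- setNames(seq_along(keep0) - 1L, keep0)
  b <- mol$bonds[mol$bonds$a1 %in% keep0 & mol$bonds$a2 %in% keep0, ,
                 drop = FALSE]
  b$a1 <- unname(remap[as.character(b$a1)])
  b$a2 <- unname(remap[as.character(b$a2)])
  qt_mol(mol$elements[keep1], b,
         coords = if (is.null(mol$coords)) NULL else
           mol$coords[keep1, , drop = FALSE],
         charges = mol$charges[keep1], id = mol$id)
}
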