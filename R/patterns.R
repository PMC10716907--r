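# Hierarchical torsion SMARTS library: loading, central-bond classification,
# and extraction of one torsion observation per matched central bond.

#' Load a torsion SMARTS pattern library
#'
#' Reads a JSON library of dihedral SMARTS patterns (each with four mapped
#' atoms and an acyclic/ring kind annotation). Patterns keep file order;
#' hierarchy rank is the position within each kind (lower rank = more
#' specific, wins when several patterns hit the same bond).
#'
#' The library bundled with the package
#' (`torsion_patterns_synthetic_v1.json`) is a synthetic stand-in
#' reproducing the class structure of the ETKDG-style hierarchical set:
#' 387 acyclic and 105 ring patterns, with acyclic central bonds C-C (168),
#' C-O (56), C-S (16), N-C (131), N-S (4), S-S (1) and 11 further acyclic
#' patterns with other central bonds.
#'
#' @param path path to the JSON library; defaults to the bundled library.
#' @return data.frame of class `qt_pattern_library` with columns `id`
#'   (0-based file order), `smarts`, `kind`, `name`, `rank`,
#'   `central_bond`, plus a `query` list-column of parsed SMARTS.
#' @export
load_pattern_library <- function(path = system.file(
  "extdata", "torsion_patterns_synthetic_v1.json", package = "qtdg")) {
  if (!nzchar(path) || !file.exists(path)) stop("pattern library not found: ", path)
  doc <- jsonlite::read_json(path)
  recs <- doc$patterns
  if (is.null(recs) || length(recs) == 0) stop("empty pattern library: ", path)
  smarts <- vapply(recs, function(r) as.character(r$smarts), character(1))
  kind <- vapply(recs, function(r) as.character(r$kind), character(1))
  name <- vapply(recs, function(r)
    if (is.null(r$name)) NA_character_ else as.character(r$name), character(1))
  if (!all(kind %in% c("acyclic", "ring")))
    stop("pattern kind must be 'acyclic' or 'ring'")
  queries <- vector("list", length(smarts))
  for (i in seq_along(smarts)) {
    q <- tryCatch(parse_smarts(smarts[i]), error = function(e) e)
    if (inherits(q, "error"))
      stop("invalid SMARTS at library record ", i, ": ", conditionMessage(q))
    if (!setequal(q$maps[q$maps > 0], 1:4))
      stop("library record ", i,
           " must carry exactly four mapped atoms :1-:4 (got '",
           smarts[i], "')")
    queries[[i]] <- q
  }
  rank <- integer(length(smarts))
  for (k in unique(kind)) rank[kind == k] <- seq_len(sum(kind == k)) - 1L
  lib <- data.frame(id = seq_along(smarts) - 1L, smarts = smarts,
                    kind = kind, name = name, rank = rank,
                    stringsAsFactors = FALSE)
  lib$central_bond <- vapply(queries, .central_bond_label, character(1))
  lib$query <- queries
  class(lib) <- c("qt_pattern_library", "data.frame")
  lib
}

# element of a mapped query atom, from the first non-negated element/atomic
# number primitive of its first OR alternative; NA when unconstrained
.query_atom_element <- function(query, map) {
  q <- which(query$maps == map)[1]
  if (is.na(q)) return(NA_character_)
  syms <- names(.atomic_numbers)
  for (p in query$atoms[[q]][[1]]) {
    if (p$negate) next
    if (p$type == "element") return(p$value$sym)
    if (p$type == "anum") {
      hit <- syms[.atomic_numbers == p$value]
      if (length(hit)) return(hit[1])
    }
  }
  NA_character_
}

.known_bond_labels <- c("C C" = "C-C", "C O" = "C-O", "C S" = "C-S",
                        "C N" = "N-C", "N S" = "N-S", "S S" = "S-S")

.central_bond_label <- function(query) {
  e2 <- .query_atom_element(query, 2L)
  e3 <- .query_atom_element(query, 3L)
  if (is.na(e2) || is.na(e3)) return("other")
  key <- paste(sort(c(e2, e3)), collapse = " ")
  lbl <- .known_bond_labels[key]
  if (is.na(lbl)) "other" else unname(lbl)
}

#' Classify the central bond of a torsion pattern
#'
#' Returns the unordered element-pair label of the two central mapped atoms
#' (maps :2 and :3), one of `"C-C"`, `"C-O"`, `"C-S"`, `"N-C"`, `"N-S"`,
#' `"S-S"`, or `"other"` when either central atom is not constrained to a
#' single element of that set.
#'
#' @param pattern a SMARTS string, a parsed `qt_smarts`, or one row of a
#'   `qt_pattern_library`.
#' @return character label.
#' @export
classify_central_bond <- function(pattern) {
  q <- if (inherits(pattern, "qt_smarts")) pattern
       else if (is.character(pattern)) parse_smarts(pattern)
       else if (is.list(pattern) && !is.null(pattern$query[[1]])) pattern$query[[1]]
       else stop("cannot interpret pattern")
  .central_bond_label(q)
}

#' Measure a dihedral angle from four points
#'
#' Signed dihedral by the atan2 convention, mapped into \[0, 360). With
#' b1 = p2 - p1, b2 = p3 - p2, b3 = p4 - p3 the angle is
#' `atan2((n1 x n2) . b2 / |b2|, n1 . n2)` where n1 = b1 x b2 and
#' n2 = b2 x b3. Under this convention the quadruple
#' (0,1,0), (0,0,0), (1,0,0), (1,0,1) measures 90 degrees.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees in \[0, 360).
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b2^2)) < 1e-12) stop("central atoms coincide")
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("collinear atoms: dihedral undefined")
  x <- sum(n1 * n2)
  y <- sum(.cross(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  ang %% 360
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# dihedral for 0-based atom-index quadruple on a coordinate matrix
.dihedral_idx <- function(coords, quad0) {
  measure_dihedral(coords[quad0[1] + 1L, ], coords[quad0[2] + 1L, ],
                   coords[quad0[3] + 1L, ], coords[quad0[4] + 1L, ])
}

#' Extract torsion observations from a molecule
#'
#' Runs the hierarchical pattern library over one conformer. For every
#' central bond hit by at least one pattern, exactly one observation is
#' emitted: the highest-priority (lowest-rank) matching pattern wins, and
#' among that pattern's matches on the bond the lexicographically smallest
#' atom-index quadruple is kept as the representative. Ties between an
#' acyclic and a ring pattern on the same bond (possible only if the library
#' leaves the central bond's ring membership unconstrained) go to the
#' acyclic pattern.
#'
#' @param mol a `qt_mol` with 3D coordinates.
#' @param library a `qt_pattern_library`.
#' @param coords optional N x 3 matrix overriding `mol$coords` (e.g. one
#'   conformer of an ensemble).
#' @param conformer_id label recorded in the output.
#' @return data.frame with columns `molecule_id`, `conformer_id`,
#'   `pattern_id`, `kind`, `a1..a4` (0-based atom indices), `angle`
#'   (degrees in \[0, 360)).
#' @export
match_torsions <- function(mol, library, coords = NULL,
                           conformer_id = "conf0") {
  if (is.null(coords)) coords <- mol$coords
  if (is.null(coords)) stop("molecule has no coordinates")
  empty <- data.frame(molecule_id = character(), conformer_id = character(),
                      pattern_id = integer(), kind = character(),
                      a1 = integer(), a2 = integer(), a3 = integer(),
                      a4 = integer(), angle = numeric())
  best <- list() # key: central bond "i-j" -> list(rank, kind, pattern_id, quads)
  for (i in seq_len(nrow(library))) {
    q <- library$query[[i]]
    hits <- smarts_match(q, mol)
    if (nrow(hits) == 0) next
    mcols <- vapply(1:4, function(m) which(q$maps == m), integer(1))
    quads <- hits[, mcols, drop = FALSE]
    for (r in seq_len(nrow(quads))) {
      quad <- quads[r, ]
      key <- paste(min(quad[2], quad[3]), max(quad[2], quad[3]), sep = "-")
      rank <- library$rank[i]
      kind <- library$kind[i]
      cur <- best[[key]]
      if (is.null(cur)) {
        best[[key]] <- list(rank = rank, kind = kind,
                            pattern_id = library$id[i], quads = list(quad))
      } else {
        better <- rank < cur$rank ||
          (rank == cur$rank && kind == "acyclic" && cur$kind == "ring")
        if (library$id[i] == cur$pattern_id) {
          cur$quads[[length(cur$quads) + 1L]] <- quad
          best[[key]] <- cur
        } else if (better) {
          best[[key]] <- list(rank = rank, kind = kind,
                              pattern_id = library$id[i], quads = list(quad))
        }
      }
    }
  }
  if (length(best) == 0) return(empty)
  rows <- lapply(best, function(b) {
    qm <- do.call(rbind, b$quads)
    ord <- do.call(order, as.data.frame(qm))
    quad <- qm[ord[1], ]
    data.frame(molecule_id = mol$id, conformer_id = conformer_id,
               pattern_id = b$pattern_id, kind = b$kind,
               a1 = quad[1], a2 = quad[2], a3 = quad[3], a4 = quad[4],
               angle = .dihedral_idx(coords, quad))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$a2, out$a3), , drop = FALSE]
}
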