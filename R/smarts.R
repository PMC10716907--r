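# Restricted SMARTS query engine. Torsion pattern libraries use a small,
# well-defined slice of SMARTS; this engine implements that slice over the
# qt_mol graph and exposes full atom-index match maps, which are required
# to extract dihedral quadruples.
#
# Supported atom primitives: element symbols (uppercase aliphatic, lowercase
# c/n/o/s/p aromatic), *, a, A, #<n> (atomic number), X<n> (total
# connectivity), H<n> (total hydrogen count), R / R0 (ring membership),
# +<n> / -<n> (formal charge), ! negation, juxtaposition or & for AND,
# ',' for OR, trailing :<n> atom map. Bond primitives: - = # : ~ @ with !
# negation and juxtaposition AND / ',' OR; an omitted bond means
# "single or aromatic". Branches with parentheses are supported.

.atomic_numbers <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                     P = 15, S = 16, Cl = 17, Br = 35, I = 53)

#' Parse a SMARTS pattern
#'
#' Parses the supported SMARTS subset into a query graph used by
#' [smarts_match()]. See the package vignette for the exact dialect.
#'
#' @param smarts the SMARTS string.
#' @return an object of class `qt_smarts` with query atoms, bonds, and the
#'   atom-map labels.
#' @export
parse_smarts <- function(smarts) {
  s <- smarts
  pos <- 1L
  nc <- nchar(s)
  peek <- function() if (pos <= nc) substr(s, pos, pos) else ""
  advance <- function(k = 1L) pos <<- pos + k
  fail <- function(msg) stop("SMARTS parse error in '", smarts, "' at position ",
                             pos, ": ", msg, call. = FALSE)

  atoms <- list()    # each: list of OR-alternatives; alternative = list of prims
  maps <- integer()
  bonds <- list()    # list(a1, a2, expr)
  stack <- integer() # branch stack of 1-based atom indices
  prev <- 0L         # last atom index (1-based), 0 = none
  pending_bond <- NULL

  read_uint <- function() {
    d <- ""
    while (grepl("[0-9]", peek())) { d <- paste0(d, peek()); advance() }
    if (d == "") NA_integer_ else as.integer(d)
  }

  read_atom_primitive <- function() {
    ch <- peek()
    if (ch == "!") {
      advance()
      p <- read_atom_primitive()
      p$negate <- !p$negate
      return(p)
    }
    prim <- function(type, value = NULL) list(type = type, value = value,
                                              negate = FALSE)
    if (ch == "*") { advance(); return(prim("any")) }
    if (ch == "#") {
      advance(); v <- read_uint()
      if (is.na(v)) fail("expected atomic number after #")
      return(prim("anum", v))
    }
    if (ch == "X") {
      advance(); v <- read_uint()
      if (is.na(v)) fail("expected digit after X")
      return(prim("connectivity", v))
    }
    if (ch == "H") {
      # bare H in a bracket is an element only at expression start; treat
      # 'H' followed by optional digit as hydrogen-count primitive unless the
      # whole expression is just "H"
      advance(); v <- read_uint()
      if (is.na(v)) v <- 1L
      return(prim("hcount", v))
    }
    if (ch == "R") {
      advance(); v <- read_uint()
      if (!is.na(v) && v == 0L) return(prim("ring", FALSE))
      return(prim("ring", TRUE))
    }
    if (ch == "+") {
      advance(); v <- read_uint(); if (is.na(v)) v <- 1L
      return(prim("charge", v))
    }
    if (ch == "-") {
      advance(); v <- read_uint(); if (is.na(v)) v <- 1L
      return(prim("charge", -v))
    }
    if (ch == "a") { advance(); return(prim("aromatic", TRUE)) }
    if (ch == "A") { advance(); return(prim("aromatic", FALSE)) }
    # two-letter elements first
    two <- if (pos + 1L <= nc) substr(s, pos, pos + 1L) else ""
    if (two %in% c("Cl", "Br", "Si")) { advance(2L); return(prim("element", list(sym = two, arom = FALSE))) }
    if (ch %in% c("B", "C", "N", "O", "F", "P", "S", "I")) {
      advance(); return(prim("element", list(sym = ch, arom = FALSE)))
    }
    if (ch %in% c("c", "n", "o", "p", "s")) {
      advance(); return(prim("element", list(sym = toupper(ch), arom = TRUE)))
    }
    fail(paste0("unsupported atom primitive '", ch, "'"))
  }

  read_bracket_atom <- function() {
    advance() # consume '['
    alts <- list()
    cur <- list()
    map <- 0L
    repeat {
      ch <- peek()
      if (ch == "") fail("unterminated bracket atom")
      if (ch == "]") { advance(); break }
      if (ch == ",") {
        if (length(cur) == 0) fail("empty OR alternative")
        alts[[length(alts) + 1L]] <- cur
        cur <- list()
        advance(); next
      }
      if (ch == "&" || ch == ";") { advance(); next }
      if (ch == ":") {
        advance(); v <- read_uint()
        if (is.na(v)) fail("expected digits after :")
        map <- v; next
      }
      cur[[length(cur) + 1L]] <- read_atom_primitive()
    }
    if (length(cur) > 0) alts[[length(alts) + 1L]] <- cur
    if (length(alts) == 0) fail("empty bracket atom")
    list(alts = alts, map = map)
  }

  read_bare_atom <- function() {
    two <- if (pos + 1L <= nc) substr(s, pos, pos + 1L) else ""
    prim <- NULL
    if (two %in% c("Cl", "Br", "Si")) {
      advance(2L)
      prim <- list(type = "element", value = list(sym = two, arom = FALSE),
                   negate = FALSE)
    } else {
      ch <- peek()
      if (ch == "*") { advance(); prim <- list(type = "any", value = NULL, negate = FALSE) }
      else if (ch == "a") { advance(); prim <- list(type = "aromatic", value = TRUE, negate = FALSE) }
      else if (ch == "A") { advance(); prim <- list(type = "aromatic", value = FALSE, negate = FALSE) }
      else if (ch %in% c("B", "C", "N", "O", "F", "P", "S", "I")) {
        advance()
        prim <- list(type = "element", value = list(sym = ch, arom = FALSE),
                     negate = FALSE)
      } else if (ch %in% c("c", "n", "o", "p", "s")) {
        advance()
        prim <- list(type = "element", value = list(sym = toupper(ch), arom = TRUE),
                     negate = FALSE)
      } else fail(paste0("unexpected character '", ch, "'"))
    }
    list(alts = list(list(prim)), map = 0L)
  }

  read_bond_expr <- function() {
    # returns NULL if no explicit bond symbols present
    alts <- list()
    cur <- list()
    has <- FALSE
    repeat {
      ch <- peek()
      neg <- FALSE
      if (ch == "!") {
        nxt <- if (pos + 1L <= nc) substr(s, pos + 1L, pos + 1L) else ""
        if (!(nxt %in% c("-", "=", "#", ":", "~", "@"))) break
        advance(); neg <- TRUE; ch <- peek()
      }
      if (ch %in% c("-", "=", "#", ":", "~", "@")) {
        advance()
        cur[[length(cur) + 1L]] <- list(type = ch, negate = neg)
        has <- TRUE
      } else if (ch == "," && has) {
        alts[[length(alts) + 1L]] <- cur; cur <- list(); advance()
      } else if (ch == "&" && has) {
        advance()
      } else break
    }
    if (!has) return(NULL)
    if (length(cur) > 0) alts[[length(alts) + 1L]] <- cur
    alts
  }

  while (pos <= nc) {
    ch <- peek()
    if (ch == "(") {
      advance()
      if (prev == 0L) fail("branch before any atom")
      stack <- c(stack, prev)
      next
    }
    if (ch == ")") {
      advance()
      if (length(stack) == 0) fail("unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      next
    }
    b <- read_bond_expr()
    ch <- peek()
    atom <- if (ch == "[") read_bracket_atom() else read_bare_atom()
    atoms[[length(atoms) + 1L]] <- atom$alts
    maps <- c(maps, atom$map)
    cur <- length(atoms)
    if (prev != 0L) {
      bonds[[length(bonds) + 1L]] <- list(a1 = prev, a2 = cur, expr = b)
    } else if (!is.null(b)) fail("bond with no preceding atom")
    prev <- cur
  }
  if (length(stack) != 0) fail("unbalanced '('")
  if (length(atoms) == 0) fail("no atoms")
  structure(list(smarts = smarts, atoms = atoms, maps = maps, bonds = bonds),
            class = "qt_smarts")
}

#' @export
print.qt_smarts <- function(x, ...) {
  cat(sprintf("<qt_smarts '%s': %d query atoms, %d bonds, %d mapped>\n",
              x$smarts, length(x$atoms), length(x$bonds), sum(x$maps > 0)))
  invisible(x)
}

.match_atom_expr <- function(alts, mol, i) {
  el <- mol$elements[i]
  for (conj in alts) {
    ok <- TRUE
    for (p in conj) {
      r <- switch(p$type,
        any = TRUE,
        element = el == p$value$sym &&
          mol$aromatic_atom[i] == p$value$arom,
        anum = !is.na(.atomic_numbers[el]) &&
          .atomic_numbers[[el]] == p$value,
        aromatic = mol$aromatic_atom[i] == p$value,
        connectivity = mol$connectivity[i] == p$value,
        hcount = mol$total_h[i] == p$value,
        ring = mol$ring_atom[i] == p$value,
        charge = mol$charges[i] == p$value,
        FALSE)
      if (p$negate) r <- !r
      if (!r) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

.match_bond_expr <- function(expr, mol, k) {
  ord <- mol$bonds$order[k]
  arom <- mol$aromatic_bond[k]
  ring <- mol$ring_bond[k]
  if (is.null(expr)) return((ord == 1L && !arom) || arom) # default bond
  for (conj in expr) {
    ok <- TRUE
    for (p in conj) {
      r <- switch(p$type,
        "-" = ord == 1L && !arom,
        "=" = ord == 2L && !arom,
        "#" = ord == 3L,
        ":" = arom,
        "~" = TRUE,
        "@" = ring,
        FALSE)
      if (p$negate) r <- !r
      if (!r) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Match a SMARTS query against a molecule
#'
#' Backtracking subgraph matching over the molecular graph. Every distinct
#' injective atom mapping is returned; callers deduplicate as appropriate
#' (e.g. per central bond for torsion extraction).
#'
#' @param query a `qt_smarts` (or SMARTS string, parsed on the fly).
#' @param mol a `qt_mol`.
#' @return integer matrix with one row per match and one column per query
#'   atom, holding 0-based molecule atom indices. Zero rows if no match.
#' @export
smarts_match <- function(query, mol) {
  if (is.character(query)) query <- parse_smarts(query)
  nq <- length(query$atoms)
  nm <- n_atoms(mol)
  out <- matrix(integer(), 0, nq)
  if (nm < nq) return(out)

  # bond lookup: key "i-j" (1-based query indices) -> expr
  qadj <- vector("list", nq)
  qexpr <- list()
  for (b in query$bonds) {
    qadj[[b$a1]] <- c(qadj[[b$a1]], b$a2)
    qadj[[b$a2]] <- c(qadj[[b$a2]], b$a1)
    qexpr[[paste(min(b$a1, b$a2), max(b$a1, b$a2))]] <- b$expr
  }
  # molecule bond index lookup
  mkey <- paste(pmin(mol$bonds$a1, mol$bonds$a2),
                pmax(mol$bonds$a1, mol$bonds$a2))
  mbond <- setNames(seq_along(mkey), mkey)
  madj <- .adj_list(mol)

  # query traversal order: DFS from atom 1 so each atom after the first has
  # a matched neighbor (torsion SMARTS are connected)
  order <- 1L
  seen <- logical(nq)
  seen[1] <- TRUE
  while (length(order) < nq) {
    nxt <- NA_integer_
    for (q in order) for (w in qadj[[q]]) if (!seen[w]) { nxt <- w; break }
    if (is.na(nxt)) stop("disconnected SMARTS query: ", query$smarts)
    seen[nxt] <- TRUE
    order <- c(order, nxt)
  }

  assign <- integer(nq) # 1-based mol index per query atom, 0 = unassigned
  results <- list()
  try_at <- function(depth) {
    if (depth > nq) {
      results[[length(results) + 1L]] <<- assign - 1L
      return(invisible(NULL))
    }
    q <- order[depth]
    anchored <- intersect(qadj[[q]], order[seq_len(depth - 1L)])
    cands <- if (length(anchored) == 0) seq_len(nm) else {
      madj[[assign[anchored[1]]]] + 1L
    }
    for (c1 in cands) {
      if (c1 %in% assign[assign > 0L]) next
      if (!.match_atom_expr(query$atoms[[q]], mol, c1)) next
      ok <- TRUE
      for (q2 in anchored) {
        k <- mbond[paste(min(c1 - 1L, assign[q2] - 1L),
                         max(c1 - 1L, assign[q2] - 1L))]
        if (is.na(k)) { ok <- FALSE; break }
        if (!.match_bond_expr(qexpr[[paste(min(q, q2), max(q, q2))]],
                              mol, k)) { ok <- FALSE; break }
      }
      if (!ok) next
      assign[q] <<- c1
      try_at(depth + 1L)
      assign[q] <<- 0L
    }
    invisible(NULL)
  }
  try_at(1L)
  if (length(results) == 0) return(out)
  mat <- do.call(rbind, results)
  colnames(mat) <- NULL
  # reorder columns to query-atom order (they already are: assign indexed by q)
  mat
}
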