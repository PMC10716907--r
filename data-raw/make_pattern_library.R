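# Generates inst/extdata/torsion_patterns_synthetic_v1.json: a synthetic
# stand-in torsion SMARTS library reproducing the class structure of the
# ETKDG-style hierarchical set (387 acyclic + 105 ring patterns; acyclic
# central bonds C-C 168, C-O 56, C-S 16, N-C 131, N-S 4, S-S 1, and 11
# further acyclic patterns with other central bonds). Within each central
# bond class, patterns run most-specific-first and finish with generic
# catch-alls (bare-element centrals, !#1 ends), so file order within a kind
# doubles as hierarchy rank. Run from the package root:
#   Rscript data-raw/make_pattern_library.R

ends <- c("CX4", "CX3", "C", "c", "N", "O", "F", "Cl", "*", "!#1")

central_variants <- list(
  C = c("CX4H2", "CX4H1", "CX4H3", "CX4", "CX3H1", "CX3", "CX2", "c"),
  N = c("NX3H1", "NX3", "NX2", "n"),
  O = c("OX2", "o"),
  S = c("SX2", "SX3", "SX4"),
  P = c("PX3", "PX4"),
  B = c("BX3"),
  Si = c("SiX4")
)

# generic fallbacks per class: bare-element centrals, any-heavy ends
generic_centrals <- list(
  "C C" = list(c("C", "C"), c("c", "C"), c("c", "c")),
  "C O" = list(c("C", "O"), c("c", "O")),
  "C S" = list(c("C", "S"), c("c", "S")),
  "N C" = list(c("N", "C"), c("N", "c")),
  "N S" = list(c("N", "S")),
  "S S" = list(c("S", "S"))
)

smarts_of <- function(x1, c1, bond, c2, x2)
  sprintf("[%s:1][%s:2]%s[%s:3][%s:4]", x1, c1, bond, c2, x2)

make_class <- function(e1, e2, n_needed, bond = "!@") {
  generics <- vapply(generic_centrals[[paste(e1, e2)]], function(cc)
    smarts_of("!#1", cc[1], bond, cc[2], "!#1"), character(1))
  budget <- n_needed - length(generics)
  if (budget <= 0) return(head(generics, n_needed))
  out <- character(0)
  seen <- character(0)
  c1s <- central_variants[[e1]]
  c2s <- central_variants[[e2]]
  # ends outer so every central pair appears early; dedup by reversed form
  for (x1 in ends) for (x2 in ends) for (c1 in c1s) for (c2 in c2s) {
    sm <- smarts_of(x1, c1, bond, c2, x2)
    rev <- smarts_of(x2, c2, bond, c1, x1)
    if (sm %in% seen || rev %in% seen) next
    seen <- c(seen, sm)
    out <- c(out, sm)
    if (length(out) >= budget) return(c(out, generics))
  }
  stop(sprintf("only %d/%d patterns for %s-%s", length(out), budget, e1, e2))
}

other_acyclic <- sprintf(
  "[%s:1][%s:2]!@[%s:3][%s:4]",
  c("!#1", "!#1", "C", "C", "!#1", "C", "!#1", "C", "!#1", "C", "!#1"),
  c("OX2", "NX3", "PX3", "PX3", "NX3", "BX3", "SiX4", "OX2",
    "NX3", "PX4", "SX4"),
  c("OX2", "NX3", "CX4", "OX2", "OX2", "CX4", "CX4", "SiX4",
    "PX3", "OX2", "OX2"),
  c("!#1", "!#1", "C", "C", "!#1", "C", "!#1", "C", "!#1", "C", "!#1"))

acyclic <- c(
  make_class("C", "C", 168),
  make_class("C", "O", 56),
  make_class("C", "S", 16),
  make_class("N", "C", 131),
  make_class("N", "S", 4),
  make_class("S", "S", 1),
  other_acyclic
)

ring_centrals <- list(
  c("c", "c"), c("CX4R", "CX4R"), c("CX4R", "CX3R"), c("CX3R", "CX3R"),
  c("CX4R", "NX3R"), c("c", "n"), c("CX4R", "OX2R"), c("CX4R", "SX2R"),
  c("n", "n"), c("NX3R", "NX3R"), c("CX3R", "NX2R"), c("CX4R", "NX2R")
)
ring_generics <- c(smarts_of("!#1", "C", "@", "C", "!#1"),
                   smarts_of("!#1", "c", "@", "C", "!#1"),
                   smarts_of("!#1", "c", "@", "c", "!#1"))
ring <- character(0)
seen <- character(0)
for (x1 in ends) for (x2 in ends) for (cc in ring_centrals) {
  sm <- smarts_of(x1, cc[1], "@", cc[2], x2)
  rev <- smarts_of(x2, cc[2], "@", cc[1], x1)
  if (sm %in% seen || rev %in% seen) next
  seen <- c(seen, sm)
  ring <- c(ring, sm)
}
ring <- c(ring[seq_len(105 - length(ring_generics))], ring_generics)

stopifnot(length(acyclic) == 387, length(ring) == 105,
          !anyDuplicated(c(acyclic, ring)))

recs <- c(
  lapply(acyclic, function(s) list(smarts = s, kind = "acyclic")),
  lapply(ring, function(s) list(smarts = s, kind = "ring"))
)
doc <- list(
  library = "synthetic torsion SMARTS pattern set",
  note = paste("Synthetic stand-in reproducing the class structure of the",
               "hierarchical ETKDG torsion pattern set (387 acyclic + 105",
               "ring; acyclic central bonds C-C 168, C-O 56, C-S 16,",
               "N-C 131, N-S 4, S-S 1, other 11). Not the original",
               "crystallographically derived patterns."),
  version = "1.0-synthetic",
  patterns = recs
)
out <- file.path("inst", "extdata", "torsion_patterns_synthetic_v1.json")
jsonlite::write_json(doc, out, auto_unbox = TRUE, pretty = FALSE)
cat("wrote", out, ":", length(recs), "patterns\n")
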