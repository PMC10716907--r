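---
title: "Torsion-angle priors from conformer ensembles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsion-angle priors from conformer ensembles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtdg)
```

## Overview

Conformer generators such as ETKDG bias their distance-geometry embedding
with torsion-angle preferences harvested from large structural databases:
every rotatable bond class, defined by a SMARTS pattern over the four
dihedral atoms, carries an empirical distribution of observed angles.
Traditionally those distributions come from crystal structures, which
restricts them to molecules that are stable, synthesizable, and
crystallizable. An alternative is to harvest them from quantum-computed
gas-phase conformer ensembles (e.g. CREST/GFN2-xTB output), which removes
the crystallization bottleneck — the QTDG idea. `qtdg` implements the
analysis layer of that program: it consumes conformers (SDF/XYZ) produced
by external engines and turns them into per-pattern torsion distributions,
parametric fits, and inverse-CDF sampling tables, together with the
ensemble-versus-reference geometry statistics used to validate such data.

## The extraction pipeline

**Pattern library.** A torsion pattern is a SMARTS expression with four
mapped atoms `:1`–`:4`; the dihedral is measured over the mapped quadruple
and the central bond is `:2`–`:3`. Patterns are classed `acyclic` or
`ring` and are hierarchical: within a kind, file order is the priority
rank, and when several patterns hit the same central bond the lowest rank
(most specific) wins. The library bundled with the package
(`inst/extdata/torsion_patterns_synthetic_v1.json`) is a *synthetic*
stand-in that reproduces the class structure of the ETKDG-style set — 387
acyclic and 105 ring patterns, with acyclic central bonds C–C (168), C–O
(56), C–S (16), N–C (131), N–S (4), S–S (1), plus 11 acyclic patterns
with other central bonds — but its individual SMARTS strings are generated
combinatorially (specific end-atom constraints first, generic
bare-element catch-alls last within each class), not derived from any
structural database. Counts are asserted at load time. Note the published
per-class figures sum to 376, not 387; the 11-pattern "other" class
absorbs that difference in the synthetic stand-in, and the discrepancy is
recorded rather than resolved.

**SMARTS dialect.** Because torsion extraction needs the *atom indices*
of each match, the package ships its own matcher for a restricted, fully
documented SMARTS subset: element symbols (uppercase aliphatic, lowercase
`c n o p s` aromatic), `*`, `a`, `A`, `#n`, `Xn` (total connectivity),
`Hn` (total hydrogen count), `R`/`R0`, charges `+n`/`-n`, `!` negation,
`&`/juxtaposition for AND and `,` for OR, bond primitives `- = # : ~ @`
with `!`, branches, and atom maps. An omitted bond means "single or
aromatic", as in standard SMARTS. The matcher is a backtracking subgraph
search over the molecular graph; the test suite pins its behaviour to
match sets computed independently with RDKit on fixed molecules.

**One observation per central bond.** For every central bond hit by at
least one pattern exactly one `TorsionObservation` is emitted, from the
highest-priority matching pattern; among that pattern's matches on the
bond the lexicographically smallest atom-index quadruple is the
representative. This mirrors per-bond torsion assignment in
distance-geometry codes and keeps histograms free of multiplicity
inflation (a symmetric pattern would otherwise contribute the same
physical torsion several times).

**Dihedral convention.** Angles are stored in [0°, 360°) everywhere;
folding to [0°, 180°] is a display concern only, since the sampling
tables span the full circle. The signed dihedral uses the standard
`atan2` convention with `b1 = p2-p1`, `b2 = p3-p2`, `b3 = p4-p3`,
`θ = atan2((n1×n2)·b̂2, n1·n2)`, negatives wrapped by +360°. The
convention is locked by a test: the quadruple (0,1,0), (0,0,0), (1,0,0),
(1,0,1) measures 90°, not 270°. Collinear `b1,b2` or `b2,b3` raise an
error (the dihedral is undefined).

## Distributions

Histograms bin on half-open intervals `[b·s, (b+1)·s)` with a default
step of s = 5°, i.e. 72 bins. Densities are estimated with a
wrapped-Gaussian kernel density estimate: each observation contributes a
Gaussian kernel (default bandwidth 5°, matching the bin width) summed
over ±3 periodic images, evaluated on a 1° grid, and normalized so the
periodic trapezoidal integral is exactly 1. Wrapping keeps the estimate
seam-continuous at 0°/360°, which matters for torsions peaked near 0°
(anti/syn populations). Three images cover ±1080°, ample for any
realistic bandwidth. Both raw angles and pre-binned histograms are
accepted as input, since either may be what an archive provides.

Two torsion profiles are compared by the squared Pearson correlation of
their densities on a common 1° grid (`kde_r2`). Pearson r² is used
because absolute peak heights vary with data volume; what should agree
between two sources is the *relative* intensity at each angle. A
constant profile has no defined correlation and raises an error rather
than returning a silent `NA`.

## Fitting torsion distributions

**Boltzmann inversion.** Energy-space fits need relative energies, not
probabilities: with bin probabilities `p_i` (floored at 1e-4 so empty
bins stay finite), `E_i = −ln(p_i / max p)` in units of kT, so the most
populated bin sits at E = 0. The floor is configurable; 1e-4 is roughly
one observation in ten thousand, below which a bin is treated as "seen
nothing".

**Cosine series.** The ETKDG-style potential is

  E(θ) = c + Σₙ Kₙ [1 + cos(nθ − dₙ)],  n = 1…6,

with force constants Kₙ (kT) and phases dₙ. In *fixed-phase* mode each
dₙ is restricted to {0, π} (the published convention); in *free-phase*
mode dₙ varies continuously. Both are solved exactly rather than by
iterative optimization: expanding the cosine gives
E = c′ + Σₙ aₙ cos nθ + bₙ sin nθ with aₙ = Kₙ cos dₙ, bₙ = Kₙ sin dₙ,
which is linear in (aₙ, bₙ). Ordinary least squares therefore yields the
*global* optimum of the identical least-squares problem — free phase uses
both regressor sets, fixed phase uses cosines only and reads dₙ ∈ {0, π}
off the coefficient sign. This replaces the multi-start nonlinear fit
one might otherwise write: it is deterministic, faster, and guarantees
the nesting property that the free-phase residual never exceeds the
fixed-phase residual (the fixed-phase solution lives inside the
free-phase parameter space at bₙ = 0). To score an energy-space fit
against a probability histogram it is Boltzmann-weighted back:
density ∝ exp(−E(θ)), normalized on the grid.

**Gaussian mixtures.** The alternative model fits bin probabilities
directly with `baseline + Σⱼ Aⱼ exp(−(θ−μⱼ)²/2σⱼ²)` (1–6 peaks, each
wrapped over ±3 images), by bounded Levenberg–Marquardt least squares
(`minpack.lm`). Fitting probability space rather than energy space is a
deliberate choice: the fitted density feeds the sampling-table
construction without a further transform, and peak parameters (position,
width, weight) are directly interpretable as conformer subpopulations.
Initialization is deterministic peak-picking on the 5°-bandwidth KDE of
the histogram (largest maxima first, equally spaced fillers if the KDE
has fewer maxima than requested peaks), so fits are reproducible without
randomness. The peak count is selected by fitting k = 1…6 and keeping the
smallest k whose BIC is within 2 of the best. The BIC uses the
*multinomial* likelihood of the bin counts given the modelled bin
probabilities, not a Gaussian residual likelihood: with 72 bins and 10⁴
observations, a Gaussian-residual BIC rewards components that chase pure
binning noise (halving an already noise-level SSE), whereas under the
multinomial likelihood a spurious component cannot pay for its three
parameters. Component weights are reported as each peak's share of the
modelled probability mass.

Fit quality for every family is the squared Pearson correlation between
the model density at bin centers and the bin probabilities
(`fit_quality_r2`) — again scale-invariant by design. On the synthetic
battery (below) the observed ordering is Gaussian ≥ free-phase cosine ≥
fixed-phase cosine, with the fixed-phase fits far behind: a phase
restricted to {0, π} forces minima onto a symmetric grid that arbitrary
multimodal distributions do not respect.

## Sampling tables and torsion driving

A fitted density becomes a sampling table by accumulating it across all
angles from 0° to 360° at 0.5° resolution, normalizing the cumulative sum
to [0, 1], and inverting by monotone linear interpolation, so a uniform
random quantile u maps to an angle with the fitted distribution.
Zero-density plateaus make the CDF flat; the table collapses them so the
quantile grid stays strictly increasing, mapping interior and trailing
plateaus to their left edge and anchoring the leading zero plateau at its
right edge (the start of the support). Sampling is plain inverse-transform
with a seeded uniform generator; determinism is part of the contract.

Driving applies a sampled angle to a conformer by rotating every atom on
the distal side of the central bond rigidly about the bond axis
(Rodrigues rotation); bond lengths and angles are untouched, and the
rotation direction is fixed by the same atan2 convention as measurement,
so set-then-measure round-trips to 1e-6°. Ring bonds refuse to drive:
ring torsions are strongly coupled to the other torsions of the same
ring, and setting one in isolation would distort the geometry. Ring
tables are still produced — they are meant for downstream
distance-geometry use, not for driving. `drive_molecule` processes the
matched acyclic torsions in ascending central-bond index order with one
uniform draw per torsion (falling back to a uniform angle when a pattern
has no table); no clash resolution is attempted.

## Ensemble statistics

The validation statistics used when comparing ensembles to reference
geometries:

* **Minimum heavy-atom RMSD** over the ensemble after optimal rigid-body
  (Kabsch) superposition, hydrogens excluded. Correspondence is by stored
  atom order by default; `symmetry = TRUE` additionally minimizes over
  element- and bond-preserving graph automorphisms of the heavy-atom
  skeleton, for molecules whose equivalent atoms (e.g. paired methyls)
  would otherwise report a spurious RMSD. The default is fast and
  deterministic; the flag exists because reference datasets differ in
  whether they account for symmetry.
* **Radius of gyration**: √(Σ‖rᵢ − r̄‖²/N) over heavy atoms, unweighted.
  Mass weighting is deliberately not applied — the choice is documented so
  comparisons stay consistent.
* **Rotatable bonds**: acyclic single bonds between two non-terminal
  heavy atoms, excluding amide C–N bonds (carbon double-bonded to
  oxygen). Conventions differ across the field; this one is fixed and
  tested.
* **Preprocessing**: multi-component inputs keep the largest fragment
  (most heavy atoms, then most total atoms, then smallest canonical
  identifier); compound identity between an input and a generated
  structure is checked at the connectivity level via canonical InChI
  (Open Babel); conformer sets are filtered to a relative energy window
  (default 6 kcal/mol, within which most ensembles concentrate) with the
  minimum-energy conformer always retained; energy ties break to the
  first conformer label.

## The synthetic generator, and what the tests do and do not show

`random_mixture_spec()` draws the study conditions for the fitting and
sampling batteries: 1–4 wrapped-Gaussian components whose means are
pairwise at least 60° apart on the circle, σ uniform in [8°, 25°], and
weights uniform on the simplex floored at 0.1. Those choices emulate
rotameric wells: torsional minima are separated by barriers (gauche/anti
wells sit 60°+ apart), populated wells in ensemble data have widths of
roughly 10–25°, and a well below ~10 % occupancy is near the resolution
of a 10⁴-observation histogram. The battery runs 50 such mixtures at
n = 10⁴ angles each; sampling fidelity is checked with 10⁵ draws against
the analytic wrapped-mixture CDF (image sums widened adaptively for very
broad components). These sizes keep the full suite in minutes on one
core while leaving statistical headroom on every criterion.

What passing these tests shows: the estimator recovers known mixtures,
the fit families rank as expected when the truth *is* a Gaussian
mixture, and the sampling tables reproduce their source density. What it
does not show: behaviour on real torsion archives, whose distributions
contain skewed and shouldered peaks, correlated torsion pairs, sparse
patterns with a handful of observations, and crystal-packing effects —
none of which the generator emulates. The toy molecules likewise cover
the geometric mechanics (one rotatable bond, a salt pair, a sterically
twisted biaryl near 90°), not chemical diversity.

## Degenerate inputs and numerical details

* Empty histograms, zero-mass densities, constant profiles, collinear
  dihedrals, ring central bonds in `set_dihedral`, missing energies, and
  atom-count mismatches all raise errors with specific messages; nothing
  silently returns `NA`.
* Gaussian-mixture σ is bounded to [1°, 180°] and means wrap into
  [0°, 360°) after fitting; a seam-straddling component (e.g. mean 355°)
  is recovered without artifacts because the model itself is wrapped.
* The energy floor, KDE bandwidth, grid steps, CDF resolution, BIC
  window, and energy window are all arguments with the defaults stated
  above.
* All randomness (mixture draws, sampling, driving) is seeded through
  function arguments; fits contain no randomness at all.

## Limitations

The bundled pattern library is a synthetic stand-in: counts and class
structure match the published hierarchy, but the SMARTS strings are
generated, so per-pattern chemistry does not correspond to the original
crystallographically derived set — swap in a real library file via
`load_pattern_library(path)` for production use. The SMARTS dialect is a
subset (no recursive SMARTS, no stereo, no component-level grouping).
Torsion driving is sequential and clash-blind, and no distance-geometry
embedding is performed; ring-torsion tables are produced but never
applied. Two-dimensional (correlated) torsion distributions are out of
scope.
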