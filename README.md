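# qtdg

Torsion-angle distributions, fits, and sampling tables for quantum-derived
conformer ensembles.

Conformer generators bias their search with torsion priors: for each class
of rotatable bond, described by a SMARTS pattern over the four dihedral
atoms, an empirical distribution of observed angles. Those priors are
traditionally harvested from crystal structures, which limits them to
molecules that can be made and crystallized. Harvesting them instead from
quantum-computed gas-phase conformer ensembles (CREST/GFN2-xTB and
similar) removes that bottleneck — the QTDG (quantum torsion distance
geometry) idea. `qtdg` is the analysis layer for that workflow, aimed at
cheminformatics developers building or evaluating torsion priors. It
consumes conformers produced by external engines and provides:

* **Extraction** — a hierarchical torsion SMARTS library (387 acyclic +
  105 ring patterns; a synthetic stand-in library is bundled), a
  restricted SMARTS matcher exposing atom-index maps, and one torsion
  observation per matched central bond.
* **Distributions** — 5°-binned circular histograms, wrapped-Gaussian
  KDE on [0°, 360°), and r² comparison between torsion profiles.
* **Fitting** — Boltzmann inversion `E_i = −ln(p_i / p_max)` (kT units),
  then either the ETKDG-style cosine series

  `E(θ) = c + Σₙ Kₙ [1 + cos(nθ − dₙ)]`, n = 1…6,

  with phases fixed to {0, π} or free (both solved exactly by linear
  least squares in `(Kₙ cos dₙ, Kₙ sin dₙ)`), or a wrapped Gaussian
  mixture of up to six peaks fitted to bin probabilities, with the peak
  count chosen by multinomial BIC.
* **Sampling** — inverse-CDF tables (cumulative density 0→360° at 0.5°,
  normalized, inverted), seeded angle draws, and rigid torsion driving of
  conformers (`set_dihedral`, `drive_molecule`).
* **Ensemble comparison** — largest-fragment stripping, InChI identity
  checks, energy-window filtering (default 6 kcal/mol), minimum
  heavy-atom RMSD by Kabsch superposition (optionally
  graph-automorphism-aware), radius of gyration, rotatable-bond counts,
  and RMSD-vs-rotors regression summaries.

## Worked example

Extract a torsion, fit a synthetic three-well distribution, and sample
from the fitted table:

```r
library(qtdg)

lib <- load_pattern_library()        # bundled synthetic stand-in library
bu  <- make_toy_molecule("butane")
match_torsions(bu, lib)
#>   molecule_id conformer_id pattern_id    kind a1 a2 a3 a4 angle
#> 1      butane        conf0          0 acyclic  0  1  2  3   180
```

Butane's single rotatable bond matches pattern 0
(`[CX4:1][CX4H2:2]!@[CX4H2:3][CX4:4]`) and sits at the anti angle, 180°.

```r
spec   <- mixture_spec(means = c(60, 180, 300), sigmas = c(12, 15, 10),
                       weights = c(0.30, 0.45, 0.25))
angles <- generate_mixture_angles(spec, n = 1e4, seed = 7)
h      <- build_histogram(angles)            # 72 bins of 5 degrees
fit    <- fit_gaussian_mixture(h)
fit
#> <qt_gaussian_fit: 3 peak(s), SSE 6.217e-05>
#>   mean  180.3 deg  sigma  15.3 deg  weight 0.446
#>   mean   59.8 deg  sigma  11.9 deg  weight 0.306
#>   mean  300.4 deg  sigma  10.3 deg  weight 0.246
fit_quality_r2(gaussian_to_density(fit), h)
#> [1] 0.9974
```

The three generating wells (60°/180°/300°, weights 0.30/0.45/0.25) are
recovered within a fraction of a degree and a few thousandths in weight;
r² measures the squared Pearson correlation between the fitted density
and the bin probabilities. The cosine-series fits of the same histogram
score 0.9695 (free phase) and 0.9684 (fixed phase) here — on broader
batteries of random mixtures the fixed-phase family falls far behind
(median r² ≈ 0.35), because phases restricted to {0, π} cannot place
minima at arbitrary angles.

```r
tab <- build_sampling_table(gaussian_to_density(fit))
sample_angles(tab, 5, seed = 1)
#> [1]  73.4 164.5 184.3 304.0  65.0
set_dihedral(bu, bu$coords, quad = 0:3, target = 73.4) |>
  (\(m) measure_dihedral(m[1, ], m[2, ], m[3, ], m[4, ]))()
#> [1] 73.4
```

Uniform quantiles pushed through the inverted CDF give angles from the
fitted distribution, and `set_dihedral` rotates the distal side of the
bond rigidly so the measured dihedral hits the target exactly.

A command-line front end wrapping these functions
(`extract`, `compare`, `hist`, `corr`, `fit`, `sample`, `synth`) is
installed at `system.file("cli", "qtdg.R", package = "qtdg")`.

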