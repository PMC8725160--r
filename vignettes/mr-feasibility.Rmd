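---
title: "Judging molecular-replacement feasibility with the expected log-likelihood gain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Judging molecular-replacement feasibility with the expected log-likelihood gain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrellg)
```

## The problem

Molecular replacement (MR) phases a crystal by placing a structurally
similar model in the unit cell and borrowing its phases. Whether a given
model can succeed depends on three quantities: the coordinate error of the
model relative to the target (its r.m.s.d.), the fraction of the total
scattering of the asymmetric unit that the model represents
(`fm`), and the resolution of the diffraction data. With accurate predicted
models now routinely available, the practical questions are *how good does a
model have to be* for a given crystal, and *how should a predicted model be
prepared* (trimmed, weighted) to maximize its chance of success. `mrellg`
implements the quantitative machinery for both questions, together with the
structural scores used to describe model quality and a classifier for
surveying how phasing practice has shifted over time.

## The sigma-A curve

The central parameter is `sigmaA(d)`, the resolution-dependent correlation
between normalized model and target structure factors. For a model with
scattering fraction `fm` whose coordinates carry isotropic Gaussian errors of
r.m.s. magnitude `rmsd`,

    sigmaA(d) = sqrt(fm) * (1 - fsol * exp(-bsol / (4 d^2)))
                         * exp(-(2 pi^2 / 3) * rmsd^2 / d^2)

The `sqrt(fm)` factor is the correlation cost of the missing scattering; the
exponential factor is the Debye-Waller factor `exp(-B s^2/4)` (with
`s = 1/d`) for the B value equivalent to a positional error `Delta`,

    B = 8 pi^2 Delta^2 / 3,

so the two conversions used throughout the package are one relationship seen
from two sides. The Babinet-style bulk-solvent pair `(fsol, bsol)` only
affects resolutions lower than about 8 angstroms and is **off by default**
(`fsol = 0`); it is exposed for low-resolution studies.

```{r sigmaa}
p <- sigmaa_params(rmsd = 1.0, fm = 0.8)
sigma_a(p, d = c(8, 4, 2.5, 2))
```

## The expected LLG

The likelihood of a placed model is the probability of the observed
amplitudes given the calculated ones: the Rice distribution for acentric
reflections and the Woolfson (folded-normal) distribution for centric ones,
both parameterized by `sigmaA`. The log-likelihood gain (LLG) subtracts the
Wilson (random-atom) baseline. Before structure solution the LLG a correctly
placed model *would* achieve can be estimated: the expected LLG (eLLG) per
reflection is the expectation of the per-reflection LLG over the joint
`(E_obs, E_calc)` distribution at that `sigmaA`, and the total eLLG is its
sum over all reflections.

That expectation has no elementary closed form. For small `sigmaA` it
approaches `sigmaA^4 / 2` per acentric reflection -- the classic result that
makes the eLLG grow linearly with the number of reflections and steeply with
model quality -- and it diverges as `sigmaA -> 1` (a perfect, complete model
pins the data exactly). `ellg_per_reflection()` therefore evaluates the
expectation by deterministic two-dimensional Gauss-Legendre quadrature
(96-point rules, the inner window tracking the location and width of the
conditional so that sharp high-`sigmaA` conditionals stay resolved), cached
on a fine `sigmaA` grid with a monotone (Hyman) spline. The quadrature is
converged to well below 1e-7, far inside every tolerance used in the tests.
The package's independent check of this engine is `expected_llg_mc()`, which
samples the same expectation by Monte Carlo; the two routes agree within
Monte-Carlo error across the whole `sigmaA` range, centric and acentric.

At `sigmaA = 1` the per-reflection eLLG returns `+Inf` with a warning, and
`total_ellg()` propagates it: the divergent perfect-model limit is reported
honestly rather than clamped.

```{r ellg}
cell <- unit_cell(30, 30, 30)
refl <- generate_reflections(cell, space_group_ops("P1"), dmin = 3)
total_ellg(sigmaa_params(rmsd = 1.2, fm = 0.8), refl)
```

The inverse question -- how accurate must a model of given completeness be to
reach a target eLLG -- is answered by `solve_required_rmsd()`, a bisection on
the monotone map from r.m.s.d. to total eLLG (tolerance 1e-8 angstroms on a
`[0, 10]` angstrom bracket). An unreachable target returns `NA` with a
warning rather than a silent clamp. `ellg_grid()` tabulates totals over
r.m.s.d. and `fm` axes for contour plots of feasibility.

## The synthetic diffraction laboratory

To verify the theory end to end the package simulates crystals it fully
controls:

* **Targets** are random structures: four point atoms per residue placed
  uniformly in the cell with a 1.5 angstrom minimum-distance guard. The
  guard keeps Wilson statistics clean; realistic stereochemistry is
  deliberately not modelled, because the likelihood theory under test only
  sees structure-factor statistics. Real data differ in ways that do not
  matter here (bonded geometry, solvent, anisotropy) and in ways that are
  explicitly out of scope (twinning, translational NCS, coiled-coil
  modulations).
* **Scattering factors** are constant `f = Z` (point atoms). The likelihood
  operates on normalized amplitudes, where the resolution fall-off of the
  form factor divides out shell by shell; constant `f` keeps the independent
  per-atom test oracle exact.
* **Models** retain a random subset of target atoms chosen so the retained
  `sum((occ f)^2)` is the requested fraction of the total (fm is a
  *scattering* fraction, not an atom count), then each retained atom is
  displaced by an isotropic Gaussian perturbation rescaled so the realized
  r.m.s.d. equals the request exactly -- this makes the simulation contract
  deterministic and testable to 1e-9.
* **Observed amplitudes** are the target amplitudes, optionally perturbed by
  seeded multiplicative Gaussian noise clipped at zero.

Structure factors come from direct summation
`F(h) = sum_j occ_j f_j exp(-B_j s^2/4) exp(2 pi i h.x_j)`, checked to 1e-10
against an independently coded scalar loop. Normalization divides epsilon
factors into per-shell scales; in empirical mode the mean epsilon-corrected
`E^2` is exactly 1 per equal-count shell.

## VRMS refinement and pose significance

`refine_vrms()` treats the model r.m.s.d. entering the sigma-A curve as a
likelihood parameter (the "VRMS", or effective r.m.s.d.) and maximizes the
total LLG over it by bounded Brent search on `[0.01, 5]` angstroms. The
initial value defaults to **1.2 angstroms**, the standard starting VRMS for
posed predicted models, and the returned optimum never scores below the
initial point. On simulated noise-free pairs with about 2000 reflections the
refined VRMS recovers the true coordinate error within a few percent
(the test suite requires 15%).

A pose whose LLG strictly exceeds a space-group-class threshold -- 60 in
nonpolar space groups, 50 in polar ones, 30 in P1 -- is classified as
probably correct by `classify_pose()`. Probable correctness is *not* the
same as solvability: downstream building and refinement also depend on model
completeness and resolution, which is why these thresholds are exposed as a
classifier and nothing more.

## Weighting by estimated coordinate error

Predicted models carry a per-residue error estimate `Delta` (CASP-style
models store it directly in the B column; depositions store pLDDT, which
`plddt_to_delta()` converts by a documented monotone approximation,
`Delta = 1.5 exp(4 (0.7 - pLDDT/100))`). Converting `Delta` to a per-atom B
via `B = 8 pi^2 Delta^2/3` down-weights unreliable atoms at high resolution
exactly as the Debye-Waller factor prescribes. `weighting_benefit()` makes
the qualitative claim -- accurate error estimates improve the LLG -- testable:
it scores the same model twice, once with per-atom converted Bs and once with
the best single uniform B, refining the VRMS in both runs so that the
comparison isolates the weighting itself. On two-error-level synthetic
models the weighted LLG exceeds the uniform one by a wide margin; with
homogeneous errors the two coincide; with deliberately shuffled (wrong)
error assignments the benefit disappears.

Model preparation follows the same error estimates: `trim_by_error()`
removes residues whose predicted error exceeds a threshold (thresholds in
the 0.7-1.2 angstrom range are typical in practice), is idempotent, and is
monotone in the threshold. Per-residue errors are taken from the residue's
CA atom and applied to all its atoms; a per-atom variant would be a
straightforward extension but per-residue matches how the estimates are
published. Ensembles of consistently-predicted models superpose so tightly
that divergence-based trimming only marks anything at exceptionally small
thresholds (of order 0.1 angstroms); `ensemble_divergence_trim()` implements
it anyway (superpose all members on the first over the common core, drop
residues whose maximum pairwise CA divergence exceeds the threshold), since
for heterogeneous ensembles it remains useful.

## Structural scores

`superpose()` is the least-squares (Kabsch) fit; degenerate (collinear)
geometry is refused rather than silently resolved. `gdt()` scores, for each
distance cutoff, the maximal fraction of CA pairs that any candidate
superposition brings within the cutoff; candidates come from an iterative
seed-and-extend search (seed windows of 3/5/7 residues, refined by
re-superposing on inliers) and are shared across cutoffs, which guarantees
GDT_HA (cutoffs 0.5/1/2/4) never exceeds GDT_TS (1/2/4/8). This is a
simplification of the full LGA search; with a user-fixed superposition GDT
reduces to exact distance counting. `lcs()` finds the longest contiguous
window whose own superposition fits under an r.m.s.d. cutoff, via
prefix-sum accumulation that makes each window's minimized r.m.s.d. O(1);
the tests verify it against an exhaustive window-by-window oracle. The
LGA_S-style combination `lga_s()` is a weighted mean of GDT and LCS with a
default weight of 0.75 toward GDT -- the exact combination inside LGA is not
published, so the weight is configurable and the default is documented as an
approximation. Pairing is strictly sequence-dependent (1:1 by residue
index); sequence-independent alignment is out of scope.

Helix geometry uses the Sugeta-Miyazawa local-axis construction on
four-CA windows; the bending angle compares local axes one turn apart
(offset 4 by default). Class boundaries -- kinked at a maximum bend of 20
degrees or more, linear below 5 degrees, curved between -- place a 7.4 degree
maximum bend on the curved side and a 25.7 degree bend on the kinked side,
matching how such helices are described in practice. Inter-helix angles are
reported unsigned in `[0, 180]` degrees, with a signed convention (sign of
`det[axis1, axis2, reference]`) exposed because published angle lists use
varying conventions.

## The phasing-method survey

Free-text "structure determination method" strings are normalized by an
alias dictionary over canonicalized text and resolved by seniority:
MIRAS > MIR > MAD > SIRAS > SIR > SAD > MR > Fourier synthesis. "SAD with
molecular replacement" is SAD; "SIRAS/MAD" is MAD. Ab-initio/direct-methods
entries are excluded from shares (they are rare and mostly denote fragment
or substructure methods), and empty or unrecognized strings are dropped as
null. The dictionary is best-effort by construction -- the historical field
was free format -- and is extensible via a config file.

Dating PDB-style entries is ambiguous (deposition, release and revision
dates can be years apart; revision dates are dominated by archive-wide
edits), so binning uses five-year windows starting at 2000 and requires
*both* deposition and release dates inside the same window; straddling
records are counted nowhere, revision dates are ignored, and only entity-1
rows enter. Shares are reported either over the three broad strategies
(experimental phasing combined, MR, Fourier synthesis) or within
experimental phasing, and sum to 100 per window by construction.
`generate_survey_fixture()` produces seeded synthetic metadata with known
composition and a controllable straddle fraction, so the whole pipeline is
testable round-trip.

## Numerical choices and problem sizes

* eLLG quadrature: 96-point Gauss-Legendre per dimension; spline cache on a
  grid up to `sigmaA = 0.9985`, direct quadrature beyond.
* VRMS search: Brent on `[0.01, 5]` angstroms, tolerance 1e-6.
* Required-rmsd inversion: root-finding to 1e-12 on the bracket.
* Simulated verification crystals use a 30 angstrom cubic P1 cell with data
  to 3 angstroms (about 2100 unique reflections) and 60-residue targets --
  large enough for stable Wilson statistics and parameter recovery, small
  enough that the full suite runs in about a minute.
* Degenerate inputs fail loudly: empty reflection sets, all-residues-trimmed
  models, collinear superpositions, unknown space-group classes and
  unreachable eLLG targets all raise informative errors.

## Limitations

The package deliberately stops short of running molecular replacement:
rotation/translation searches, packing, map correlation, density
modification and MR-SAD are out of scope, as are anisotropy, twinning and
translational NCS in the simulator, and experimental amplitude-error
inflation in the likelihood (the forms here are noise-free; a documented
inflation hook would slot into the normalization). Passing tests on the
synthetic laboratory demonstrate the internal consistency of the theory and
its implementation, not performance on real crystals with real pathologies.
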