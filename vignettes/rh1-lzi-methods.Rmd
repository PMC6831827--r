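---
title: "Methods: idealized modelling and SAXS analysis of the RH1-LZI tandem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: idealized modelling and SAXS analysis of the RH1-LZI tandem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jiptandem)
```

This vignette is the package's own account of what it computes, which
assumptions those computations rest on, and where the idealizations are
known to bite. Nothing stated here goes beyond what the test suite and the
acceptance script themselves compute.

## The system and the modelling strategy

The N-terminal region of the JIP3/JIP4 motor adaptors is a dimeric tandem:
a small RH1 domain — a four-helix bundle built from two antiparallel
helices per protomer (JIP3 α1 26–43, α2 50–73) — followed, through a short
helical hinge (74–77), by the ~14-heptad Leucine Zipper I parallel coiled
coil. The package rebuilds this architecture from annotated sequence alone,
as an idealized Cα-trace model:

* **One center per residue.** Every consumer of coordinates in the package
  is per-residue — Debye scattering with per-residue weights, P(r)
  histograms, one-bead-per-residue hydrodynamics, clash checks — so the
  model keeps exactly one Cα-like center per residue. Backbone N/C/O atoms
  would triple the bookkeeping without entering any downstream formula;
  side chains are represented implicitly by per-residue masses, a residue
  excluded-volume form factor, and bead radii.
* **Ideal α-helices**: 1.5 Å rise per residue, 3.6 residues/turn, 2.3 Å
  radius. Consecutive Cα–Cα distances come out at 3.75–3.85 Å.
* **Crick coiled coil**: a minor helix of radius 2.26 Å wound on a
  left-handed superhelix (radius 4.9 Å, pitch 190 Å), 1.485 Å axial rise
  per residue, chains related by a 180° rotation about the superhelical
  axis. The minor-helix rotation is parameterized *in the rotating
  superhelical frame*, default 3.5 residues/turn — exactly two turns per
  heptad, which is what makes a heptad-repeat coiled coil close on itself.
  With the default pitch this corresponds to a laboratory-frame
  periodicity of ≈3.6. Had we used a lab-frame 3.62 directly, the a/d seam
  would drift ≈4° per heptad and leave the dimer interface entirely over
  14 heptads; the knob-distance checks in the test suite (inter-chain
  Cα–Cα at a/d positions within 5.0–7.5 Å at every core position) pin this
  choice down.
* **Bundle geometry**: the four helix axes sit on the corners of a square
  of side 10.5 Å; α1 runs up, α2 runs down, the second protomer is the
  two-fold image about the bundle axis. The α1–α2 loop (44–49) is a
  quadratic-arc coil, sampled uniformly in arc length; its consecutive
  spacings (~3.3 Å) are looser than helical geometry, as befits a loop
  modelled without side-chain detail. The hinge and the C-terminal
  residues 181–187 continue the coiled-coil geometry, so the bundle axis
  is collinear with the coil axis and the tandem is straight.

The assembled dimer comes out ≈211 Å long and ≈19 Å thick with the LZI
contributing ≈153 Å — the acceptance checks hold these against 210, 20 and
150 Å with ±10, ±3 and ±8 Å bands. Residue numbering follows the
full-length protein; the Gly-Ser-His expression-tag remnant is numbered
19–21.

Where the published domain annotations (RH1 22–73, LZI 74–177) and the
modelling ranges (α2 ending at 73, coil built from 78, hinge 74–77)
disagree in detail, the package builds with the modelling ranges and keeps
the domain-level ranges as annotations (`jip_regions()`); a possible
Pro57 kink in α2 is deliberately not modelled — the idealized bundle
absorbs it within its ±4 Å length tolerance.

## Sequence fixtures

The packaged JIP3/JIP4 records are **synthetic stand-ins**, constructed —
not transcribed — to satisfy every residue-level constraint stated for the
real sequences: the named interface and core residues of the RH1 domain,
the ⁷²ENQEHE⁷⁷ linker, tryptophan at the LZI construct boundary, absence
of Gly/Pro in the coil, a hydrophobic a/d core across all 14 heptads
(90% Ile/Leu/Val/Met occupancy at the designed register), construct masses
of 20.3/14.8/6.4 kDa (with the GSH remnant, human and mouse K→R variant
alike), and 84.6% ungapped RH1 identity between the two homologs. The
manifest in `inst/extdata/` records this provenance and pins the file by
checksum. Tests that depend only on these constraints transfer to the real
sequences; tests of residue-specific detail beyond them would not.

## Forward scattering model

`debye_intensity()` evaluates the Debye double sum over residue centers
with average residue masses as default weights. Two numerical choices
matter:

* **Histogram acceleration.** Pair distances are binned at 0.25 Å and each
  occupied bin is represented by its *weight-averaged* distance, which
  makes the approximation first-order exact; the relative deviation from
  the exact double sum stays below 0.5% out to q = 0.5 Å⁻¹ (the exact sum
  is retained as the test oracle).
* **Residue form factor.** For simulated measurements the default is a
  hard-sphere amplitude per residue with radius 3.17 Å — the radius of a
  sphere with the mean residue volume (1.21 Å³/Da at v̄ = 0.73 mL/g). This
  represents the excluded volume that a point model lacks: it leaves I(0)
  untouched, adds <0.3% to the apparent Rg, and gives the intensity a
  physically shaped high-q decay, which the Porod-volume mass estimate
  needs. `form_factor = "none"` recovers the bare point-Debye contract
  `I(0) = (Σf)²`.

## Inverse analyses

**Guinier.** Weighted regression of ln I on q², either on a fixed window
or automatically (grow from the lowest q while qRg ≤ 1.3 and r² ≥ 0.99,
iterating Rg to 0.1 Å). A caveat the package states rather than hides: for
a 210 Å rod the Guinier window is already outside its validity regime at
qRg ≈ 1, and the fitted Rg under-reads the true radius of gyration by
3–9% depending on the window. The property tests therefore assert the 2%
recovery on compact (globular) bead clouds, where the expansion holds, and
the elongated-particle bias is exercised knowingly in the beamline-like
integration test. This same physics is visible in the published numbers
for the real protein, where the Guinier estimate sits below the
P(r)-derived one.

**Dimensionless Kratky.** `(qRg)² I/I₀` against qRg with the global
maximum located below qRg = 10. For a pure Guinier-law curve the peak is
analytically at (√3, 3/e) ≈ (1.73, 1.10) — the compact-particle landmark,
reproduced to 0.01 — while the rod-like tandem model peaks near (9, 5),
far past it. Note the coarse Cα model peaks higher and later than an
all-atom, hydration-shell calculation of the same shape would (its
cross-section is thinner); the published model curve peaks near (7.4,
4.1). This is a known coarse-grain limitation, not a target of the test
suite.

**P(r).** From coordinates, a weighted pair-distance histogram (1 Å bins
by default), optionally smeared by the residue-sphere width (2.46 Å
Gaussian) so that the discrete Cα distance spectrum turns into the smooth
distribution a continuous particle would show; the smeared P(r) of the
assembled model peaks at ≈16 Å (the rod thickness signature) and its
second moment reproduces the coordinate Rg within 1%. From data,
`ift_pr()` solves the regularized indirect transform: non-negative p on
101 grid points with pinned endpoints, χ² plus a second-difference
curvature penalty, L-BFGS-B with analytic gradients on intensities
normalized to unit scale. The smoothness weight is chosen by a
multiplicative sweep (8 decades around the scale where the two terms
balance), keeping the *largest* α whose χ² stays within 10% of the best —
i.e. the smoothest solution the data support. Round-trip recovery of a
known sphere P(r) is within 0.7% L2 at realistic noise; a warning is
raised when a too-small Dmax shows up as boundary pile-up with poor χ².

**Porod-volume mass.** `porod_mow_mass()` integrates q²I to
q_m = 0.5 Å⁻¹ (Guinier-extrapolated below the first data point), forms
V′ = 2π²I₀/Q and converts with 1/1.21 Da/Å³. The truncation at finite q_m
biases V′ upward by roughly 6/(π·R_eq) relative — about +10% for a 20 Å
sphere, ~3% once the window extends well past the particle's Porod region
(the sphere test uses q_m = 1 for exactly this reason). The published
web-tool calibration coefficients for this correction are not printed in
the text, so the default linear calibration is the identity and the
coefficients are exposed as arguments; on the simulated dimer curve the
estimate lands at ≈39 kDa against the 40.6 kDa sequence dimer, within the
10% class accuracy this method is credited with.

**χ².** Reduced, σ-weighted, with the multiplicative scale fit
analytically; invariant to rescaling either curve.

## Hydrodynamics

One bead per residue at the Cα position, radius 3.8 + 1.1 Å (base plus
hydration shell — frozen constants checked once against the single-sphere
and two-bead closed forms, never adjusted per structure), weight equal to
the residue mass.

* `rg_from_beads()` adds the (3/5)a² single-bead term; on the assembled
  dimer it gives 63.0 Å, matching the ~64 Å full-hydrodynamics prediction
  for the published model within the ±3 Å band.
* `kirkwood_rh()` evaluates the orientationally preaveraged double sum
  `1/R_h = (1/N²)[Σ1/aᵢ + Σ_{i≠j}1/rᵢⱼ]`. **Known, quantified
  limitation:** this approximation cannot see bead volume in the
  interaction term and underestimates friction systematically — on a
  solid sphere of volume-filling beads it returns ≈0.85 R (checked in the
  prototype against the exact result), and on overlapping bead strings the
  fine discretization inflates Σ1/r further. For the 211 × 19 Å tandem it
  returns 3.32 nm (3.49 nm with the optional Rotne–Prager overlap
  correction, `overlap = "rpy"`), whereas a full bead-shell
  hydrodynamics treatment of an atomistic, hydrated model of the same
  shape gives 4.4 nm — consistent with a cylinder-theory R_h of ≈4.4 nm at
  an effective hydrated diameter of ~28 Å. The package reports the
  double-sum value honestly and documents the gap instead of rescaling
  toward the literature number; the corresponding acceptance check is
  expected to fail under this estimator, and the pipeline's s (≈2.9 S) and
  f/f₀ (≈1.5) inherit the same bias. The Svedberg and frictional-ratio
  *formulas* themselves are validated independently at the published
  operating point (40.6 kDa, v̄ 0.73 mL/g, R_h 4.4 nm → 2.2 S, f/f₀ 1.94).
* Solvent defaults are water at 20 °C (η = 1.002 mPa·s, ρ = 0.9982 g/mL),
  the temperature of the sedimentation experiments; v̄ is fixed at
  0.73 mL/g rather than computed from composition.

## Refinement and ensemble analysis

The flexibility mask follows the published protocol: RH1 (26–66) and the
coil (78–176) rigid; the N-terminus (GSH + 22–25), the linker with a few
preceding residues (67–77) and the C-terminus (177–187) mobile. Moves are
rigid-body: terminal tails rotate about their anchor residue with
two-fold-conjugated rotations on the two chains (these preserve the dimer
symmetry *exactly*, as the property tests assert); linker moves bend the
entire upstream unit — the RH1 bundle travels as one intact body — about a
pivot at the downstream anchor and re-thread the 11 linker residues as a
helix through the two anchor points (twist snapped to a divisor of a full
turn so the helix passes through both anchors; radius set for 3.8 Å
steps). A bend of the shared bundle necessarily breaks the *global*
two-fold by the bend angle: exact C2 and an asymmetric hinge bend are
mutually exclusive for a domain that spans both chains, which is as true
of the published refined models as it is here. Conformers with non-bonded
contacts under 2.5 Å are resampled (up to 50 draws).

`refine_against_saxs()` wraps these moves in an elitist evolutionary
search (default population 24, 60 generations, 10° mutation scale, elite
quarter), scored by reduced χ² with per-evaluation scale refit; five
independent runs by default, best run reported, ties broken toward the
smaller Rg excursion then run order. Elitism makes the best-so-far trace
non-increasing by construction, and every run is bit-reproducible from
its seed. `generate_pool()`/`select_ensemble()` implement the
flexibility characterization: a linker-only pool (default 1000 conformers,
bend amplitude up to 90°; 10,000 at the published protocol's scale) and genetic selection of
an equal-weight 20-member sub-ensemble (5 runs × 20 cycles desk-scale,
100 cycles at the published scale), guaranteed never to score worse than the best
single conformer.

Identifiability deserves a plain statement: a hinge bend changes the
distance spectrum of this rod only mildly (a 20° bend shifts Rg by
≈0.4 Å), so recovery experiments are run on linker-only masks — the decoy
differs from the start in exactly that degree of freedom — and at
signal-to-noise 1000–2000 at q_min, the precision class of well-averaged
SEC-SAXS frames (and the regime where a wrong-by-20° model scores χ² ≈ 2.7
while the truth scores ≈1, mirroring the published 2.1 → 1.3 contrast).
At the generator's default SNR of 100 the same 20° bend is statistically
invisible (χ² excess ≈ 0.2); with full masks, tail moves can absorb part
of a hinge signal. Under the documented conditions the bend magnitude is
recovered to within 10° and χ² drops ≥2-fold.

## Synthetic measurements

`simulate_curve()` evaluates the forward model on a linear 500-point grid
over q = 0.008–0.5 Å⁻¹ (the configured SWING-like window; the
energy/distance-to-q conversion is available as `q_from_geometry()`), adds
independent Gaussian noise with
σ(q) = √[(k√I)² + (0.01·I)²], k set so the counting term's
signal-to-noise at q_min equals the `snr` parameter (default 100), and
emits the σ column. There is no inter-point correlation, no beam smearing,
no buffer-subtraction artefact; consequently χ² of the generating model
against its own curve is ≈1 by construction, and passing tests on
simulated data demonstrate the mathematics, not robustness to real
beamline systematics.

## Problem sizes and determinism

The shipped tests and the acceptance script run everything at desk scale:
the 338-center dimer, 40-point oracle grids, pools of 150–300 conformers,
refinement populations of 8–16 over 5–25 generations, two or three
independent runs. The full-scale settings (pool 10,000, 100 selection
cycles, population 24 × 60 generations × 5 runs) are plain parameter
changes. All stochastic steps consume explicit integer seeds; the pipeline
derives per-stage seeds from one global seed by fixed offsets, so each
stage is independently reproducible and two runs with the same
configuration are identical.
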