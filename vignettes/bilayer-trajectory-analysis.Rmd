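---
title: "Analysing polyphilic additives in a lipid bilayer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing polyphilic additives in a lipid bilayer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayerlab)
```

## The system and the questions

bilayerlab analyses molecular-dynamics trajectories of a planar
phospholipid (DPPC-like) bilayer doped with a small number of
trans-bilayer polyphilic molecules — rigid aromatic backbones spanning
both leaflets, with polar end groups in the headgroup regions and one
alkyl plus one perfluoroalkyl side chain buried in the aliphatic core.
The reference system the defaults emulate is a 288-lipid bilayer (144
per leaflet) hosting 6 such additives in a 98 × 98 × 68 Å orthorhombic
cell, sampled every 0.1 ns.

Five questions drive the five analysis stages:

1. How mobile are lipids and additives in the bilayer plane
   (`compute_msd`, `fit_diffusion`, `block_diffusion`)?
2. Do the additives associate laterally, and at what spacings
   (`compute_rdf`, `find_peaks`)?
3. How are the backbones oriented and bent (`backbone_angles`,
   `side_chain_angle`, `angle_histogram`)?
4. Where along the bilayer normal do the side-chain terminal groups sit
   (`z_profile`, `bilayer_thickness`, `midplane_ratio`, `flip_events`)?
5. Is cluster formation transient, and on what timescale
   (`cluster_timeseries`, `characteristic_timescale`)?

Every estimator is validated by *parameter recovery*: a seeded
generator (`gen_*`) produces data whose ground truth is known, the
estimator must get it back, and the test suite asserts that it does.

## Units, conventions, degenerate inputs

* Lengths in Å, times in ns throughout. Diffusion coefficients are
  reported in 10⁻¹² m²/s; the single conversion constant
  1 × 10⁻¹² m²/s = 0.01 Å²/ns is applied in exactly two places
  (`gen_brownian2d` forward, `fit_diffusion` when reporting) so double
  conversion cannot occur.
* Cells are orthorhombic only; a non-orthorhombic DCD cell raises an
  explicit unsupported-format error rather than a silent wrong answer.
* Particle indices are 1-based inside R. Group files declare their own
  `index_base` (default 0, the common convention of simulation tools)
  and are converted on read, so off-by-one errors fail loudly at
  validation rather than silently shifting atoms.
* The bilayer normal is fixed to +z; there is no normal estimation.
* Unwrapping accumulates per-frame minimum-image displacements, valid
  while no particle moves half a box length between stored frames; a
  violation warns with the frame and particle concerned. A single-frame
  trajectory is returned unchanged.
* Masses are optional. When absent, centres of mass are plain
  centroids; when present they are mass-weighted by default
  (`weighted = FALSE` forces centroids).

## Lateral diffusion

The mean squared displacement uses all time origins,

MSD(τ) = ⟨|r(t₀+τ) − r(t₀)|²⟩,

with the collective motion of a *reference group* removed first, so
drift of the whole phase (or the water layer dragging the bilayer)
does not inflate the estimate. The default reference is the lipid
population, for additives as well as lipids, so both are measured in
the same co-moving frame. The Einstein relation D = slope/(2d) with
d = 2 (in-plane) converts the fitted slope.

Implementation notes:

* With `origin_stride = 1` the per-particle MSD is computed with the
  FFT autocorrelation identity (O(N log N) per coordinate); the test
  suite pins it to a brute-force double loop at 10⁻¹⁰ Å². Strided
  origins use the direct sum.
* The fit window defaults to 10–50% of the largest lag: below that the
  curve is not yet diffusive and poorly sampled statistics dominate
  above it. It is configurable and always recorded in the output.
* Uncertainty: the trajectory is cut into 5 contiguous blocks, each
  fitted independently; the quoted uncertainty is 3 × the standard
  error of the mean over blocks. A three-sigma convention is used
  because per-molecule spreads would be far larger than the
  uncertainties one wants to attach to an ensemble mean; the convention
  is stored with the estimate.
* Subtracting the COM of the measured group itself biases D down by a
  factor (1 − 1/N). For N = 288 lipids this is negligible (0.3%); for
  a 6-molecule additive set it would be a 17% artefact, which is why
  additives are referenced to the lipid COM, never to their own.

## Pair correlation and peak detection

g(r) is the probability of a pair at separation r relative to a random
arrangement at the same density, computed from minimum-image distances
and normalised per frame. Two modes exist because the two uses differ:

* **lateral** (default for molecular centres): xy distances, annulus
  normalisation 2πr·dr against the areal density. Trans-bilayer
  molecules share one z-band, and their association is an in-plane
  phenomenon.
* **3d** (default for terminal groups): full distances, shell
  normalisation 4πr²·dr — terminal-group contacts are genuinely
  three-dimensional.

The molecular centre (COR) is the centroid of the central aromatic
ring's atoms. Intramolecular pairs can be excluded
(`exclude_same_index`) so a molecule's own two side chains do not
masquerade as intermolecular structure.

Peak detection smooths with a 5-bin moving average and filters local
maxima by two criteria:

* *prominence*, by default 0.1 of the smoothed maximum. A relative
  threshold is used because the absolute scale of g(r) from a handful
  of molecules is set by the tiny ideal-gas denominator, not by order
  unity.
* *Poisson significance*: the excess of raw pair counts over the
  ideal-gas expectation, summed across the smoothing window, must
  exceed 5 standard deviations. At small r the expected count per bin
  is far below one, so a single background pair lands a g spike of 2–3
  that survives any height- or prominence-based cut; but such spikes
  carry z ≈ 2–3, whereas a shell populated every frame carries z ≳ 30.
  With ~150 bins scanned, 3σ excursions are routine and 5σ is the
  sensible detection floor. Curves constructed without count
  information skip this filter; `min_significance = 0` disables it.

`first_minimum` returns the lowest smoothed point between the first two
peaks — the standard first-coordination-shell boundary — and feeds the
cluster stage's cutoff; 9.5 Å (midway between the 7 Å and 12 Å shells)
is the documented fallback when no RDF is available.

## Orientation and axial structure

The backbone is reduced to three points: end A, ring centre, end B.
α₁ and α₂ are the angles of the two half-backbone vectors against +z
(both against +z, so a straight trans-bilayer rod reads α₁ = 0,
α₂ = 180°) and β is the angle between the half-backbone vectors, with
β = 180° meaning unbent. This sign convention makes the collinear case
an identity (β = 180, α₂ = 180 − α₁) that the tests exploit. Side-chain
angles measure terminal → ring-centre vectors against +z: 90° means the
terminal group lies between the leaflets in the bilayer plane.

z-profiles histogram group z relative to the per-frame reference-group
COM (default: the whole system), normalised to unit area, in bins
symmetric about z = 0 (1 Å default). Bilayer thickness is the
peak-to-peak distance of the headgroup profile's two leaflet maxima.
`midplane_ratio` reports mean central density over the profile maximum
— the quantity behind statements like "the occurrence at the bilayer
centre is an order of magnitude below the main peak". Flip events use
two bands at ±10 Å (midway between centre and the ±20 Å headgroup
planes); a flip requires entering the *opposite* band, so midplane
excursions that retreat are not counted, and dwell times are the gaps
between flips.

## Cluster kinetics

Molecules are adjacent when their lateral minimum-image COR distance is
within the cutoff; clusters are connected components (labelled
deterministically by lowest member index). The per-frame trimer
indicator — any component of size ≥ 3 — is a two-state process. Its
characteristic time is the lag at which the normalised autocovariance
first crosses 1/e, linearly interpolated between bracketing lags. The
e-folding definition was chosen because it is estimator-light, matches
the exponential memory of a two-state Markov process exactly, and can
be validated against a generator with analytically known correlation
time; mean on/off dwell times are reported alongside. Membership
exchange events (the cluster swapping molecules between consecutive
trimer frames) are counted separately.

## What the generators emulate — and what they do not

* `gen_brownian2d`: independent 2D Gaussian walkers (per-axis step
  variance 2·D·dt) with optional collective drift, optionally two
  populations (lipid-like + additive-like) so the cross-referenced COM
  correction is exercised. No interactions, no subdiffusive short-time
  regime, no hydrodynamics: passing recovery shows the estimator chain
  is unbiased for ideal diffusion, not that real lipid MSDs are linear
  everywhere.
* `gen_cluster_frames`: one rigid trimer triangle with sides
  (7, 7, 12 Å) — apex angle 118.2° by the law of cosines — jittered,
  rotated and placed at random, plus uniform background molecules.
  Static geometry: it validates the RDF/peak machinery, not cluster
  formation dynamics.
* `gen_terminal_pairs`: point pairs at the 3 Å (CH3-like) or 5 Å
  (CF3-like) contact spacing with 0.3 Å jitter plus background.
* `gen_rod_frames`: three-point backbones with prescribed arm tilts and
  Gaussian polar-angle noise (not full spherical diffusion — adequate
  for distribution-recovery tests, not a physical rotor model).
* `gen_bilayer_slab`: headgroup planes at ±thickness/2 (default 40 Å,
  144 markers per leaflet) with Gaussian roughness (2.5 Å in the
  recovery tests), plus optional terminal particles drawn from a
  user-specified Gaussian z-mixture.
* `gen_telegraph`: stationary two-state Markov chain with exactly
  exponential autocorrelation e^(−lag/τ); τ = 100 ns and dt = 0.1 ns in
  the recovery condition. Generated by alternating geometric dwell
  times, which is exact because the chain is memoryless.

All generators take a `seed` and are bit-reproducible; R's default RNG
is seeded per call, so a generator call is a pure function of its
arguments.

## Problem sizes and numerical tolerances

The recovery conditions mirror the reference system: diffusion uses
288 + 6 walkers × 9800 frames (980 ns at 0.1 ns), RDF and slab
recovery use 500 frames, the telegraph series 10⁶ steps. These run in
seconds on one core thanks to the FFT MSD and vectorised generators.
Oracle equalities are asserted at 10⁻¹⁰ (MSD vs brute force) or
10⁻¹²–10⁻¹³ (symmetries, drift cancellation — exact up to floating
rounding of the COM); statistical recoveries use 3-standard-error
bands or the estimator's own 3σ uncertainty; the timescale estimator
is held to 15% (its bias at finite series length is O(dt/τ) but its
variance at 10⁴ correlation times dominates).

## Known limitations

* No triclinic cells, no trajectory alignment/RMSD fitting, no leaflet
  auto-detection, no anomalous-diffusion exponents, no finite-size
  hydrodynamic corrections to D, no lipid order parameters.
* XTC input is not supported (no reader available in the R stack this
  package builds on); DCD and the plain-text XYZ interchange format
  are.
* Peak positions are reported at bin centres; sub-bin interpolation is
  deliberately not attempted (one 0.2 Å bin is the stated resolution).
* The autocorrelation timescale assumes an (at least approximately)
  stationary indicator; non-recurrent, one-off aggregation would need
  survival analysis instead.
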