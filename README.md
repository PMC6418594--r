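# bilayerlab

Trajectory analysis for planar lipid bilayers doped with trans-bilayer
polyphilic additives — rigid-backbone amphiphiles whose aromatic core
spans both leaflets while an alkyl and a perfluoroalkyl side chain sit
in the membrane interior. The package is aimed at simulators of
membrane/additive systems who need the standard post-processing
observables as tested, scriptable R functions rather than one-off
analysis scripts.

Five analysis stages, each validated by parameter recovery on built-in
seeded generators:

| stage | observable | core functions |
|---|---|---|
| diffusion | lateral self-diffusion from MSD | `compute_msd`, `fit_diffusion`, `block_diffusion` |
| pair correlation | g(r) of molecular centres / terminal groups, peak detection | `compute_rdf`, `find_peaks`, `first_minimum` |
| orientation | backbone tilt α₁, α₂ and bending β, side-chain angles | `backbone_angles`, `side_chain_angle`, `angle_histogram` |
| axial structure | z-profiles, bilayer thickness, midplane occupancy, flips | `z_profile`, `bilayer_thickness`, `midplane_ratio`, `flip_events` |
| cluster kinetics | distance-cutoff clusters, trimer indicator, characteristic time | `cluster_timeseries`, `characteristic_timescale` |

## The statistics at the core

**Diffusion.** The multiple-time-origin mean squared displacement,
after removing the lipid-phase centre-of-mass motion, is fitted with
the Einstein relation

&nbsp;&nbsp;MSD(τ) = ⟨|r(t₀+τ) − r(t₀)|²⟩,&nbsp;&nbsp;D = (1/2d) · dMSD/dτ,&nbsp;&nbsp;d = 2 (in-plane),

over 10–50% of the lag range; uncertainty is 3× the standard error of
the mean over 5 trajectory blocks. D is reported in 10⁻¹² m²/s
(1 × 10⁻¹² m²/s = 0.01 Å²/ns).

**Pair correlation.** g(r) is normalised against the ideal-gas
expectation at the same density (lateral annulus 2πr·dr for molecular
centres, 3D shell 4πr²·dr for terminal contacts), with minimum-image
distances. Peaks must pass a relative-prominence cut *and* a Poisson
significance cut on raw counts, which makes detection reliable for
sparse ensembles (a handful of molecules) where shot noise otherwise
fakes small-r peaks.

**Cluster kinetics.** Frame-wise connected components under a
first-shell distance cutoff (default: first minimum of the
centre–centre g(r), fallback 9.5 Å) yield a binary
"trimer present" indicator; its characteristic time is the 1/e
crossing of the normalised autocorrelation, interpolated between lags.

## Worked example

Generate a doped-bilayer analogue — 288 lipid-like walkers at
D = 13.9 × 10⁻¹² m²/s plus 6 additive-like walkers at 10.7 — and
recover both diffusivities:

```r
library(bilayerlab)

sim <- gen_brownian2d(n_walkers = 288, d_true = 13.9, dt = 0.1,
                      n_steps = 9800, box = 98,
                      n_additives = 6, d_additive = 10.7, seed = 1)
un  <- unwrap(sim$trajectory)

block_diffusion(un, sim$groups$lipids, sim$groups$lipids,
                n_blocks = 5, max_lag = 100, fit_window = c(10, 50))
#> <DiffusionEstimate> D = 14.1 +/- 0.78 x 1e-12 m^2/s (d = 2, fit 10-50 ns)

block_diffusion(un, sim$groups$additives, sim$groups$lipids,
                n_blocks = 5, max_lag = 100, fit_window = c(10, 50))
#> <DiffusionEstimate> D = 8.95 +/- 3.03 x 1e-12 m^2/s (d = 2, fit 10-50 ns)
```

Both generator inputs are recovered within the quoted 3σ bands; the
6-molecule estimate carries the wide uncertainty a six-particle
ensemble deserves. Lateral association shows up as g(r) peaks of the
molecular centres:

```r
cl  <- gen_cluster_frames(pair_distance = 7, third_distance = 12,
                          jitter_sigma = 0.5, n_frames = 500, seed = 1)
rdf <- compute_rdf(cor_positions(cl$trajectory, cl$groups),
                   box = cl$trajectory$box[1, ], mode = "lateral")
find_peaks(rdf)
#> <PeakSet> 2 peak(s) at 6.90, 11.90 A
first_minimum(rdf)
#> [1] 9.7
```

The two shells at ~7 Å (adjacent molecules) and ~12 Å (a third
molecule closing a triangle) are the signature of trimer formation;
the first minimum between them is the natural cluster cutoff. The
whole chain can also be driven from a YAML config via `run_pipeline()`
or the wrapper script `inst/scripts/bilayerlab.R`.

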