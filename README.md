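# punctatrack

Quantification of Myddosome assembly kinetics and morphology from
fluorescence imaging.

When Toll-like receptor 4 on a macrophage is triggered — by
lipopolysaccharide or by amyloid-beta aggregates — the adaptor MyD88
oligomerises into the Myddosome, visible as a diffraction-limited
fluorescent punctum. `punctatrack` measures, for people doing this kind of
innate-immunity imaging, the three quantities that characterise the
response:

1. **When the first punctum forms** after stimulation (live-cell 4D
   light-sheet stacks);
2. **How long each punctum lives**, with the lifetime distribution fitted
   by a two-step degradation model;
3. **How large and how round** the assembled clusters are (fixed-cell
   super-resolution reconstructions).

## The model at the core

Punctum disassembly is modelled as two sequential first-order steps with
rate constants k₁ and k₂, so the lifetime τ is hypoexponential:

    P(τ) = k₁k₂/(k₂ − k₁) · (e^(−k₁τ) − e^(−k₂τ)),   ⟨τ⟩ = (k₁ + k₂)/(k₁k₂)

with the Erlang-2 limit k²τe^(−kτ) as k₁ → k₂. `fit_two_step()` fits it by
maximum likelihood (default) or by least squares to the normalised
lifetime histogram. Cluster circularity uses the shape factor 4πA/p²
(1 for a circle), cluster size the relation FWHM = 2√(2 ln 2)·d ≈ 2.355·d
applied to a 1D Gaussian fit of the intensity profile.

The live-cell chain is: rolling-ball background subtraction (radius
80 px) → 3D Gaussian blur (σ 1 px) → brightest-point z-projection →
prominence-based maxima detection (20 counts) → frame-to-frame linking
with gap closing (search range 8 px = 0.85 µm, memory 6 frames, minimum
track 2 frames) → exclusion of pre-formed puncta → cell segmentation,
drift correction, and membrane/cytoplasm classification at 1.4 µm from the
cell boundary.

A fully seeded synthetic-data generator renders ground-truthed 4D stacks
(Poisson nucleation after a delay, hypoexponential lifetimes,
membrane-biased placement, Poisson + read noise) and cluster masks with
analytically known morphometry, so every stage is validated by parameter
recovery. See the methods vignette
(`vignettes/punctatrack-methods.Rmd`) for the full model description and
design choices.

## Worked example

```r
library(punctatrack)

# simulate one stimulated cell (compact design: 120 frames, 12 z-slices)
cfg <- simulation_config(n_t = 120, n_z = 12, n_y = 88, n_x = 88,
                         cell_radius = 4, nucleation_rate = 0.02,
                         formation_delay = 100, k1 = 0.005, k2 = 0.02,
                         membrane_fraction = 0.9, photon_amplitude = 100,
                         background_level = 50, rng_seed = 7)
ds  <- simulate_dataset(cfg)
res <- run_live_pipeline(ds, output_dir = "myddosome_run")

res$first_formation_s
#> [1] 110
res$stage_counts$tracks_membrane_initiated
#> [1] 18
fit_two_step(res$lifetimes)
#> Two-step lifetime fit (mle, n = 18)
#>   k1 = 0.0058065 /s, k2 = 0.033332 /s, <tau> = 202.2 s

# fixed-cell branch: 200 synthetic clusters, 60% circular
cs    <- simulate_cluster_masks(200, circular_fraction = 0.6, seed = 7)
morph <- run_fixed_pipeline(cs)
morph$spherical_fraction
#> [1] 0.6
```

The cell was simulated with a 100 s formation delay and nucleation rate
0.02 events/s, so the first recovered formation at 110 s is one
frame-interval past the expected first birth; the fitted rates bracket the
generating values (0.005, 0.02 s⁻¹) at this small track count, and the
mean lifetime ⟨τ⟩ follows exactly from the fitted rates. The morphometry
branch recovers the configured 60% circular fraction from the rasterised
masks. `run_live_pipeline()` also writes `trajectories.csv`, `tracks.csv`,
`counts.csv` (membrane/cytoplasm counts per frame), `results.json` and a
provenance `manifest.json` into the output directory, byte-identically on
re-runs with the same seed.

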