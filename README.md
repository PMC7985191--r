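# cryodose

Electron-beam radiation damage is the silent failure mode of high-dose
single-particle cryo-EM: redox-sensitive sites — disulfide bridges and
metal clusters such as the Mn4CaO5 oxygen-evolving complex of
photosystem II — are chemically reduced long before global resolution
suffers. Because exposures are recorded as dose-fractionated movies, maps
reconstructed from only the earliest frames trade a little resolution for
far less damage. `cryodose` packages that analysis for structural
biologists: it quantifies damage as a function of accumulated dose and
provides a fully synthetic test bed so every estimator can be validated
against planted ground truth without any microscope data.

## What it computes

- **Dose bookkeeping.** Fluence `F` (e⁻ Å⁻²) converts to absorbed dose
  `D = 3.7 F` MGy at 300 kV, compared against the Henderson limit
  (20 MGy). The first `k = round(F_target / F_total · n)` frames of a
  uniformly fractionated movie realize a target dose.
- **Resolution.** Gold-standard Fourier shell correlation between
  half-maps, `FSC(s) = Re Σ F₁F₂* / √(Σ|F₁|² Σ|F₂|²)` per shell, with the
  resolution read at the 0.143 crossing; Rosenthal–Henderson B-factors
  from the slope of `1/d²` against `ln N` (`B = 2/slope`).
- **Site assignment.** Metals from the strongest map peaks (26-neighbour
  maxima, subvoxel quadratic refinement), then oxygens and waters from the
  metal-subtracted map at 7 σ within bonding distance (1.7–3.0 Å) of a
  metal — the standard workflow for clusters whose light atoms are
  swallowed by adjacent heavy-atom density.
- **Restrained refinement.** Cluster positions maximize
  `Σᵢ wᵢ ρ(xᵢ)/σ_map − Σᵣ ((dᵣ−tᵣ)/σᵣ)²` under distance restraints taken
  from the initial assignment, iterated with a tightening
  σ = 0.1 → 0.05 Å schedule until the distances converge; pairs falling
  below 1.7 Å are fixed at 1.8 Å. Reported distances average the final
  four refinement steps (half-up rounding at one decimal).
- **Damage metrics.** Bond integrity (minimum density along the bond vs a
  4 σ contour), occupancy proxies from metal peak heights, and distance
  elongations against a damage-free reference geometry, tabulated per
  dose.
- **Synthetic ground truth.** A toy complex (Mn4CaO5-like cluster embedded
  from a published damage-free distance table, a disulfide pair, and a
  protein-like scaffold) rendered as occupancy- and B-weighted Gaussian
  atoms, degraded by a parametric damage process: occupancy
  `exp(−D/Dc)`, linear ADP inflation, saturating coordinate drift
  `Δmax(1 − exp(−D/Dd))`, and disulfide cleavage beyond a break dose.

I/O covers MRC/CCP4 2014 volumes (mode 2, arbitrary header axis order)
and PDB-style coordinate files.

## Worked example

```r
library(cryodose)

# dose ladder of a 50-frame, 83 e-/A^2 exposure
sel <- frames_for_dose(83, 50, target_fluence = 3.3)
dose_to_gray(sel$realized_fluence)
#>   fluence dose_mgy henderson_limit exceeds_henderson
#> 1    3.32   12.284              20             FALSE

# simulate a dose-fractionated exposure of the toy metalloprotein complex
spec <- toy_complex_spec(seed = 1)
stack <- simulate_dose_series(spec, damage_model(), n_frames = 10,
                              total_fluence = 83, seed = 1)
high <- sum_frames(stack, c(1, 10))    # full exposure
low  <- sum_frames(stack, c(1, 1))     # first frame only

# metals from the strongest peaks, then light atoms in the carved map
peaks  <- find_peaks(high, threshold_sigma = 17)
metals <- label_sites_by_reference(assign_metals(peaks), stack$model)
carved <- carve_spheres(high, model_coords(metals), radius = 1.3)
lights <- assign_light_atoms(carved, metals, threshold_sigma = 7)
nrow(peaks)   #> 5   (the four Mn and one Ca)
nrow(lights)  #> 8
head(lights[, c("height_sigma", "nearest_metal", "distance")], 3)
#>   height_sigma nearest_metal distance
#> 1     10.95068           Mn3 2.155532
#> 2     10.66319           Mn4 2.094993
#> 3     10.65461           Mn2 1.700648

# disulfide integrity at both doses (4 sigma contour)
ss <- model_coords(stack$model)[stack$model$selections$disulfide, ]
bond_integrity(low,  ss[1, ], ss[2, ])$intact   #> TRUE
bond_integrity(high, ss[1, ], ss[2, ])$intact   #> FALSE

# Rosenthal-Henderson B-factor from a particle-count series
rosenthal_henderson_fit(simulate_rh_dataset(rh_dataset_spec()))
#> <rh_fit> B = 43.300 A^2 (slope 0.046189, intercept -0.2943)
```

At five of the ten frames' dose the disulfide is already cleaved (its
break dose of 20 MGy equals roughly 5.4 e⁻ Å⁻²), while the first-frame
map retains it — the low-dose rescue the method is built to demonstrate.
`run_pipeline(pipeline_config())` chains all of the above over the full
dose ladder 3.3/5/10/20/40/83 e⁻ Å⁻² and writes per-dose reports,
per-step distance tables, and deltas against the damage-free reference
geometry. A thin command-line wrapper over the same functions is
installed at `inst/cli/cryodose.R`.

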