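# cortexpci

Simultaneous quantification of calcified cortical bone microstructure and
the intracortical vasculature from propagation-based phase contrast-enhanced
CT — as a fully simulated, testable R pipeline.

## The problem

Blood vessels in cortical bone run inside intracortical canals, deeply
encased in mineralised tissue. Absorption micro-CT resolves the canals (as
the *negative imprint* of the mineralised matrix) but not the soft tissue
inside them, so canal-based indices cannot say whether a canal actually
contains a vessel. Propagation-based phase contrast imaging fixes this: with
a coherent beam and an appropriate sample-to-detector distance `D`, the
object-induced phase shift is converted by free-space interference into
intensity fringes at soft-tissue boundaries, making the vessel inside a
canal visible without any contrast agent.

Because real synchrotron scans of this kind are not publicly deposited,
`cortexpci` ships the whole measurement chain in software:

1. **Phantom** — a voxelised murine-cortex analogue (annular cortex along z,
   tubular canals with coaxial thin-walled vessels, ellipsoidal osteocyte
   lacunae) with exact ground-truth morphometry from its construction
   registry.
2. **Imaging** — projection approximation (`phi = -(2*pi/lambda) * integral
   of delta ds`, `mu = (4*pi/lambda) * integral of beta ds`), Fresnel
   transfer function `H(f) = exp(-i*pi*lambda*D*|f|^2)`, Gaussian detector
   PSF, Poisson photon noise, ring-artefact correction, and slice-wise
   parallel-beam filtered backprojection with a band-limited ramp filter.
3. **Segmentation** — Otsu threshold (with robust midpoint refinement) of
   the near-absorption reconstruction, pore extraction by morphological
   closing, canal/lacuna classification by component volume and elongation,
   and automated vessel detection from the phase-sensitive reconstruction
   (fringe threshold + ring-geometry gate + a model-referenced canal-content
   gate).
4. **Morphometry** — the five standard indices: canal volume density (%),
   mean canal diameter (local thickness, um), osteocyte lacunar density
   (1/mm^3), canal occupancy (%), vascular space (%).
5. **Statistics** — exact two-sided Mann-Whitney U (full enumeration via
   dynamic programming with midranks) for comparing occupancy between
   modalities, and mean/SD aggregation across datasets.

## Worked example

```r
library(cortexpci)

cfg <- pipeline_config(grid_n = 192L, cortex_outer_radius_um = 60,
                       cortex_inner_radius_um = 28, n_canals = 8L,
                       canal_orientation_jitter_deg = 2,
                       occupancy_fraction = 0.9,
                       vessel_fill_fraction = 0.85,
                       photons_per_pixel = 1e4, seed = 2L,
                       verbose = FALSE)
res <- run_pipeline(cfg)
print(res$recovery, digits = 4)
```

```
                    index ground_truth  estimate
1        canal_volume_pct        4.600     4.808
2       canal_diameter_um        8.023     7.863
3 lacunar_density_per_mm3    40299.831 40202.348
4     canal_occupancy_pct       87.500    87.500
5      vascular_space_pct       64.632    67.632
```

Each row compares the phantom's exact ground truth with what the imaging +
segmentation pipeline recovered at 10^4 photons/pixel: ~8 um canals
measured to a fifth of a voxel, lacunar density to 0.3%, occupancy (the
fraction of canal cross-sections containing a detected vessel — 7 of the 8
canals drew one) exactly, and vascular space (vessel area over canal area
on 60 inspected slices) within ~3 points.

Compare occupancy between two modalities exactly as a validation study
would:

```r
mann_whitney_exact(c(95.0, 97.5, 94.1, 96.5), c(71.4, 90.0, 88.9, 97.4))
#> Mann-Whitney U = 13 (n1 = 4, n2 = 4), two-sided p = 0.2 [exact]
```

## Command line

Every stage is scriptable via the wrapper in `inst/cli/`:

```sh
cortexpci generate  --config inst/extdata/demo_config.ini --out ph/
cortexpci simulate  --phantom ph/ --distance-mm 25 --out sino25/
cortexpci reconstruct --sino sino25/ --out rec25/
cortexpci segment   --recon-abs rec5/ --recon-phase rec25/ --out seg/
cortexpci pipeline  --config inst/extdata/demo_config.ini --out run/
```

Volumes are exchanged as uncompressed multipage TIFF plus JSON sidecars.

## Documentation

The methods vignette (`vignettes/cortical-vasculature-pci.Rmd`) describes
the physical model, every tunable parameter with units and defaults, what
the synthetic data do and do not emulate, and the numerical design
decisions.
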