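---
title: "Quantifying cortical bone microstructure and intracortical vessels from simulated phase contrast-enhanced CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical bone microstructure and intracortical vessels from simulated phase contrast-enhanced CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`cortexpci` reproduces, end to end and in software, the workflow by which
propagation-based phase contrast-enhanced CT quantifies calcified cortical
bone microstructure together with the soft tissue comprising the
intracortical vasculature: phantom → two-distance coherent tomography →
filtered backprojection → bone/pore segmentation → canal/lacuna
classification → intra-canal vessel detection → five morphometric indices →
between-modality statistics.

The imaging model is parallel-beam, fully coherent and monochromatic (the
synchrotron case: no beam hardening, negligible source blur at these
distances). Under the projection approximation a ray accumulates

* phase: $\varphi = -\tfrac{2\pi}{\lambda}\int \delta\, ds$
* absorption exponent: $\mu_p = \tfrac{4\pi}{\lambda}\int \beta\, ds$

with $n = 1-\delta+i\beta$ the complex refractive index, giving the exit
field $T = e^{-\mu_p/2 + i\varphi}$. Free-space propagation over a distance
$D$ applies the Fresnel transfer function
$H(f)=\exp(-i\pi\lambda D |f|^2)$ in frequency space; the detector records
$|U_D|^2$, optionally blurred by a Gaussian PSF and corrupted by Poisson
noise. Volumes are reconstructed slice by slice from $-\log I$ with a
band-limited Ram–Lak filter and backprojection; the result is an effective
linear attenuation coefficient in 1/µm (equal to $4\pi\beta/\lambda$ for
pure absorption at the contact plane).

The characteristic transverse fringe scale is $\sqrt{\lambda D}$ — about
1.2 µm at 21 keV and $D = 25$ mm — which is why a near distance
("standard" tomography) and a far distance (phase-sensitive imaging) of the
*same* object look qualitatively different at soft-tissue boundaries. Both
distances are simulated by the same operator; the near distance is not
artificially fringe-free.

## The phantom and what it does (not) emulate

`phantom_spec()` describes a desk-scale analogue of a murine
tibiofibular-junction cortex: an annular cortical cylinder along *z*
containing

* straight, gently tilted tubular canals (truncated-normal diameters,
  default mean 8 µm, SD 0.7 µm, tilt ≤ 5° from the long axis),
* coaxial thin-walled vessels (default wall 1 µm) inside a Bernoulli
  fraction of canals (default occupancy 0.96; vessel outer diameter
  defaults to 0.92 of the canal diameter so the coaxial *area* fraction
  matches the ~85 % vascular space typical of murine cortex),
* non-overlapping ellipsoidal osteocyte lacunae (default 9 × 4 × 4 µm, long
  axis along *z*) at a literature-typical density of 4·10⁴ per mm³ of bone.
  (Published tables occasionally print lacunar densities several orders of
  magnitude higher; we treat those as unit misprints and keep the
  literature scale. The value is configurable.)

Rasterisation is voxel-centre-in-analytic-solid, axis order (z, y, x), and
bit-reproducible for a fixed seed. The construction registry makes every
downstream index exactly computable (`ground_truth_indices()`), which is
the oracle for all recovery tests.

Deliberately **not** emulated: branching vascular trees,
Haversian/Volkmann topology, mineral-density gradients, eccentric or wavy
vessels (vessels are coaxial tubes), cone-beam geometry, detector
scintillator physics, and phase retrieval. A green recovery test therefore
establishes that the pipeline measures what it claims on geometrically
simple, well-separated structures at the stated noise level — not that it
would segment arbitrary real anatomy.

### Optical constants

Default $(\delta, \beta)$ at 21 keV are computed from standard relations
($\delta = r_e\lambda^2\rho_e/2\pi$; $\beta = \mu\lambda/4\pi$ with
tabulated attenuation): mineralised bone (9.8·10⁻⁷, 1.8·10⁻⁹), soft-tissue
vessel wall (5.5·10⁻⁷, 3.5·10⁻¹⁰), aqueous vessel lumen and lacunar fluid
(5.2·10⁻⁷, 3.4·10⁻¹⁰). The free canal space is **air**: the emulated
specimens are fixed, ethanol-stored, unperfused bones mounted and scanned
in air, whose open canal network drains — this is precisely what gives the
soft-tissue vessel its strong single edge fringe at the phase-sensitive
distance while leaving it invisible in pure absorption contrast. All values
are configurable through `material_table()`.

### Detector PSF

`beam_config(psf_fwhm_px = )` applies a Gaussian OTF to the recorded
intensities (default 0 = ideal detector; the pipeline default is 1 px).
Real detector systems of this class resolve ~2–3× their pixel size; a
sub-voxel PSF also suppresses the aliasing of sub-pixel interference detail
that a literal ideal-coherent sampling would fold back into the image.

## Segmentation choices

* **Bone**: Otsu's between-class criterion on the mildly smoothed
  (σ = 0.8 voxel) near-absorption reconstruction, refined by iterating the
  threshold to the midpoint of the two class *medians*. The refinement
  matters: with asymmetric fringe/noise tails the raw Otsu split sits off
  the edge midpoint and systematically dilates pores. The binary mask is
  then regularised (Gaussian-blur + 0.5 re-cut, a smooth majority vote,
  σ = 0.8 voxel) to remove symmetric photon-noise boundary wobble, and
  closed with a 1-voxel ball to fill noise pinholes. The largest
  26-connected component is kept as the cortex.
* **Pores**: morphological closing of the bone mask with a ball of radius
  3 × the expected canal diameter (must exceed half the widest pore; both
  the medullary cavity radius and the air margin around the cortex must
  exceed it, or closing floods them — `extract_pores()` warns when the
  closed cortex reaches the volume corners). Pores touching the outer
  surface are discarded and counted.
* **Classification**: 26-connected components are canals when volume
  > 2000 µm³ OR elongation (principal-axis ratio with a 1/12 voxel²
  quantisation floor) > 5, else lacunae. Components below `min_size_vox`
  (pipeline default 27 = a 3×3×3 cube, ~3× below the smallest real lacuna
  at 1 µm voxels) are dropped as speckle.

## Vessel detection

A vessel announces itself at the phase-sensitive distance as a bright
fringe ring in the outer part of the canal cross-section. Detection is per
slice and per canal component:

1. threshold: lumen voxels deviating from the lumen median by more than
   `max(k_sigma * sigma, contrast_floor * m_bone)`, with σ the 1.4826·MAD
   of the eroded bone interior and `m_bone` the bone attenuation scale —
   the histogram *mode* of the bone voxels (fringe residue lives in the
   distribution tails), taken from the near-absorption reconstruction when
   available because its residual fringe bias is an order of magnitude
   smaller. The contrast floor (default 1 × bone attenuation) encodes that
   phase fringes characteristically *exceed* the attenuation of
   mineralised tissue while absorption-only detail never does — so
   detection fails, by design, on a contact-plane reconstruction;
2. geometry: 8-connected groups (pooled over non-speckle fragments) must
   cover ≥ `min_extent_vox` voxels and be ring-like (mean radius ≥ 0.5 of
   the equivalent cross-section radius). The ring gate rejects the axial
   focusing artefact of an *empty* air canal, whose rim fringe train
   converges on the canal axis as a compact central blob;
3. content: per canal, the slice-aggregated lumen median (normalised by
   `m_bone`) must exceed half the *empty-canal reference* — obtained by
   pushing a tiny synthetic air-canal cross-section of the same radius
   (bracketed by ± half a voxel) through the identical
   projection/propagation/PSF/FBP chain and normalising by the model's
   exact nominal bone attenuation. This self-calibrates the detector
   across distances, pixel sizes and blur.

The same reference machinery sizes the vessel. Because the bipolar fringes
are nearly zero-mean over the lumen, the lumen *mean* interpolates linearly
between the empty (air) and tissue-filled model references with the vessel
area fraction; the vessel is reported as the filled disk of that area about
the cross-section centroid. The absolute depth of reconstructed canal
statistics varies between datasets (porosity-dependent rectification bias
of the log transform, azimuthal angular-sampling blur of off-axis canals)
in ways a centred single-canal model cannot reproduce, so whenever the
dataset contains at least one canal gated as *empty*, the model levels are
rescaled to match the observed empty-canal level (the tissue/empty ratio is
retained from the model). This attenuation-mixing estimator is unbiased
where any support-edge rule is resolution-limited (the wall and the canal
boundary are separated by less than a fringe width at realistic fill
fractions), and it makes the mask independent of `k_sigma`, so raising the
threshold can only remove voxels (the documented monotonicity property).

The corresponding real-data workflow segmented vessels manually; the
automated rule exists so the pipeline is unit-testable. Its occupancy flags
equal the phantom registry exactly on noiseless data.

## Morphometry definitions

* canal volume density (%) = canal-class voxels (including enclosed vessel)
  / total cortical voxels (bone + all pores) × 100. The denominator *reads
  "total cortical tissue volume" as bone plus pore space*; this is a
  documented reading of an ambiguous definition.
* mean canal diameter (µm) = model-independent 3D local thickness
  (largest-inscribed-sphere diameter via the Euclidean distance transform
  and sphere painting, Hildebrand-style), averaged over canal voxels.
* lacunar density (1/mm³) = lacuna component count / mineralised bone
  volume.
* canal occupancy (%) — counted per canal cross-section per slice on
  `n_slices` (default 60) evenly spaced slices spanning the canal-bearing
  range; a cross-section is occupied when it contains ≥ 1 vessel voxel.
* vascular space (%) = vessel voxels / canal voxels over the sampled
  slices.

## Numerical choices

* −log is taken on intensities clipped at `log_floor` (default 10⁻⁹).
* Ramp filter: band-limited spatial-domain Ram–Lak kernel, FFT-applied with
  power-of-two zero padding; optional Hann apodisation (default off);
  π/n_angles backprojection weighting.
* Line integrals by in-plane resampling at voxel steps with bilinear
  interpolation (accuracy/speed trade-off; quadratic order would halve the
  rim error at ~2× cost).
* The Fresnel transfer function warns when aliased
  (λD > N·pixel² along any non-degenerate axis).
* Exact Mann–Whitney: the permutation distribution of U is enumerated by
  dynamic programming over midrank tie groups (exact integer counts in
  doubles up to n₁+n₂ = 40); two-sided p doubles the smaller tail, capped
  at 1. The exact path is used whenever n₁·n₂ ≤ 400.
* Seeds: every stochastic stage consumes a private RNG stream
  (`rng_seed` fields; the pipeline derives noise seeds as seed+1, seed+2)
  and restores the caller's RNG state, so identical configurations
  reproduce every artifact bit-exactly.

## Known limitations

* At 1 µm voxels the vessel wall (≈1 µm) and the wall-to-canal gap are at
  or below the resolution/fringe scale; occupancy and vascular space are
  recovered through the model-referenced gates, but wall thickness and the
  two vessel surfaces are not resolvable — matching the stated limitation
  of the real measurement.
* The empty-canal reference assumes near-circular canal cross-sections and
  nominal bone optical constants; strongly elliptical canals or grossly
  different mineralisation would need re-calibration.
* Vascular space is measured to a few points whenever the dataset contains
  at least one unoccupied canal (the usual case at physiological occupancy),
  which anchors the self-calibration. In a fully occupied dataset the
  estimator falls back to the uncalibrated model references and can
  overestimate vessel area by 10–20 points — the occupancy flags themselves
  remain correct.
* Local tomography truncation, partial coherence and scintillator physics
  are out of scope.
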