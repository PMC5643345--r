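Package: cortexpci
Title: Simulated Phase Contrast-Enhanced CT of Cortical Bone and Its
    Intracortical Vasculature
Version: 0.1.0
Authors@R:
    person("cortexpci", "developers", email = "cortexpci@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the simultaneous quantification of calcified
    cortical bone microstructure and the soft tissue comprising the
    intracortical vasculature from propagation-based phase contrast-enhanced
    computed tomography. Provides a voxel phantom generator for murine
    cortical bone with embedded vascular canals, thin-walled vessels and
    osteocyte lacunae with exact ground-truth morphometry; a coherent
    parallel-beam imaging simulator (projection approximation, Fresnel
    free-space propagation, Poisson noise, ring-artefact correction,
    filtered backprojection); segmentation of mineralised tissue, extraction
    of cortical porosity as a negative imprint, canal/lacuna classification
    and fringe-based intracortical vessel detection; the five standard
    morphometric indices (canal volume density, mean canal diameter,
    lacunar density, canal occupancy, vascular space); and an exact
    Mann-Whitney comparison of occupancy between modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
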