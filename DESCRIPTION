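Package: cortmd
Title: Surface-Based Cortical Mean Diffusivity Quantification and Mixed-Effects Group Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies cortical mean diffusivity (cMD) from diffusion-weighted MRI by
    fitting the diffusion tensor per voxel, sampling the mean-diffusivity map at the
    cortical mid-ribbon (the per-vertex midpoint between white and pial surfaces), and
    aggregating to the 68 Desikan-Killiany atlas regions alongside cortical thickness.
    Provides the staged statistical comparison of cMD against cortical thickness used in
    genetic frontotemporal dementia research: linear mixed-effects models with site (and
    individual-within-site) random intercepts, Benjamini-Hochberg false-discovery-rate
    control across regions, chi-square comparison of spatial extents, clinical-stage
    contrasts, and baseline-imaging by time interaction models of longitudinal clinical
    decline. Includes synthetic generators for diffusion phantoms with known tensors,
    toy cortical surface bundles, and cohort tables with the assumed generative
    structure, so the whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
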