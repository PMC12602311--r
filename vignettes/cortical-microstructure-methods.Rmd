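---
title: "Quantifying cortical mean diffusivity and comparing it with cortical thickness: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical mean diffusivity and comparing it with cortical thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortmd)
```

## The scientific problem

Cortical thinning (CTh, mm) is the standard MRI marker of neurodegeneration,
but it is a late, macrostructural sign. Cortical mean diffusivity (cMD,
mm²/s) — the orientation-averaged water diffusion within cortical grey
matter, `MD = trace(D)/3` for the diffusion tensor `D` — rises when cellular
membranes and synapses break down, and may therefore flag injury before
measurable atrophy. In genetic frontotemporal dementia (mutations in
*C9orf72*, *GRN* or *MAPT*), carriers can be studied decades before symptom
onset, which makes the cMD-vs-CTh comparison a sharp test of which marker
moves first and which better predicts clinical decline.

`cortmd` implements the full analysis chain for that comparison:

1. **Tensor fitting** (`fit_tensor`, `md_map`): per-voxel log-linear
   least-squares fit of `log S_i = log S0 − b_i g_i' D g_i`, then
   `MD = trace(D)/3`.
2. **Mid-ribbon sampling** (`midthickness`, `sample_volume_at_vertices`):
   the MD volume is sampled at the per-vertex midpoint between the white and
   pial surfaces, away from CSF and white matter, and aggregated to the 68
   Desikan-Killiany regions (`aggregate_rois`, `global_measure`), alongside
   a simplified vertex-pair thickness (`vertex_thickness`).
3. **Staged statistics** (`fit_interaction_model`, `fit_group_contrast`,
   `fit_longitudinal_model`, `fit_joint_global_model`, `run_aim`):
   region-wise linear mixed-effects models with BH-FDR across regions and a
   χ² comparison of the spatial extents of significant cMD vs CTh findings
   (`extent_chi_square`).
4. **Synthetic data** (`make_phantom`, `make_surface_bundle`,
   `simulate_cohort`, `simulate_longitudinal`): generators with known ground
   truth for every input, so each stage is testable without patient data.

## The statistical models

All models are fitted by REML with `nlme::lme`, the same estimator family
used in the multicentre studies this pipeline mirrors. Outcomes and
continuous covariates are z-transformed (mean-centred, unit variance) within
the analysis sample, after a single mean ± 3 SD outlier exclusion per
variable; coefficients are therefore standardised effect sizes.

**Cross-sectional, status × age interaction** (aim 1), per region and
modality, carriers of one mutation type plus all non-carriers:

    outcome ~ status + age + status:age + sex + (1 | site)

The `status:age` coefficient asks whether the outcome's age trajectory is
steeper in carriers.

**Cross-sectional group contrasts** (aims 2–3):

    outcome ~ group + age + sex + (1 | site)

with `group` contrasting presymptomatic or symptomatic carriers against
non-carriers (aim 2), or carrier disease stages — GENFI-CDR 0, 0.5, and ≥ 1
pooled (`classify_stage`) — against non-carriers (aim 3).

**Longitudinal prediction** (aim 4), within carriers of one mutation type:

    clinical score ~ imaging + time + imaging:time + age + sex + education
                     + (1 | site/individual)

where `imaging` is a baseline regional or global cMD/CTh value and time is
years from baseline. The main effect is the association with the score
level; the interaction is the moderation of the rate of decline. A joint
variant enters global cMD and global CTh (and both interactions) together.

**Multiplicity and extent.** Within each family of 68 regional tests (one
mutation type × one modality × one contrast), p-values are BH-adjusted
(`bh_fdr`, q < 0.05 two-sided). The paired counts of significant regions for
cMD and CTh are then compared with a Pearson χ² on the 2×2 table
`[[k_cMD, 68 − k_cMD], [k_CTh, 68 − k_CTh]]` *without* continuity
correction — the variant that reproduces the published statistics from their
printed regional percentages — with equal or empty margins reported as
χ² = 0, p = 1 and flagged degenerate.

## What the generators emulate — and what they do not

`simulate_cohort` draws regional values from exactly the linear structure
the cross-sectional models assume (fixed effects on the z-scale, Gaussian
site intercepts and residuals), then maps them affinely into natural units
(cMD ≈ 0.8×10⁻³ mm²/s ± 5×10⁻⁵ per z; CTh ≈ 2.5 mm ± 0.15 per z), which the
downstream z-scoring undoes. Defaults mirror the published study design
where stated: three carrier groups plus a pooled non-carrier arm,
round-robin multi-site assignment (10 sites by default; the cohort scripts
use 12 of the study's 24 to keep per-site counts realistic at desk scale),
ages uniform over 20–80 years, education ≈ 14 ± 3 years, balanced sex,
carrier staging probabilities of 0.6 / 0.2 / 0.2 for CDR 0 / 0.5 / ≥ 1. The
published work reports no presymptomatic effect sizes usable as defaults,
so effect magnitudes are explicit arguments, not baked-in claims.
`simulate_longitudinal` mirrors the aim-4 model: visit counts and follow-up
drawn from configurable ranges (defaults 2–5 visits over 1–5 years,
consistent with the reported 2.8 ± 1.6-year CBI-R follow-up), scores built
from the baseline imaging predictor with site and subject-within-site
intercepts, and clamped natural-scale CBI-R (0–180) and CDR-SOB (0–27)
copies alongside the unclamped z-scale columns.

What passing tests on these generators show is that the *pipeline* is
correct: the estimators recover the coefficients that generated the data,
type-I error is nominal, FDR is controlled. What they cannot show is
robustness to everything real data add — spatially correlated regional
values, skewed floor-effect clinical scores, scanner differences beyond an
additive site intercept, partial-volume contamination, attrition that
correlates with severity. Phantoms are rectangular grids with analytic
tensors (Gaussian noise by default, Rician available); surfaces are spheres,
because the sampling mathematics is geometry-agnostic and spheres give exact
ground truth (every white/pial pair exactly `thickness` apart).

## Numerical choices

- **Tensor fit**: ordinary (unweighted) log-linear least squares, closed
  form via the normal equations, vectorised over voxels. Non-positive
  signals are clamped to `1e-6 ×` the voxel's mean b = 0 signal before the
  log; voxels with fewer than 7 positive measurements (or outside the brain
  mask) are flagged invalid and propagate NaN — no negative-eigenvalue
  repair, since repairs would shift MD silently.
- **Interpolation**: trilinear, exact for affine fields — which is the test
  oracle; vertices outside the grid or touching NaN neighbours give NaN, and
  regional means exclude NaN vertices (warning above 5% per region).
- **Coordinates**: world mm (RAS); voxel indices 0-based; the affine maps
  index → world. Regional aggregation happens in subject space — equivalent
  to template space for regional means, so no spherical registration is
  needed.
- **Degrees of freedom**: `nlme`'s containment convention, as in the
  published tables. With fewer than two sites the model falls back to a
  fixed-intercept fit with a warning.
- **REML at a variance boundary**: with a true site variance of zero, REML
  returns a small positive estimate rather than collapsing to the boundary,
  so the package's OLS-equivalence check is calibrated to what the estimator
  delivers (site SD ≤ 0.15 z-units, fixed effects within 0.02 z-units of
  OLS at n = 400), not to machine precision.
- **Standardisation switch**: `standardize` can name which of outcome /
  imaging / time to z-score. The pipeline default transforms everything (as
  published); parameter-recovery tests disable outcome scaling so generating
  and fitted coefficients live on the same scale — legitimate because the
  transform is affine and the model equivariant.
- **Seeding**: every generator takes an explicit integer seed, or
  `seed = NULL` to consume the current RNG stream; replication studies seed
  once and stream, rather than reseeding per replicate.

## Design decisions where the published description was open

- **Residual covariance**: the published methods mention an unstructured
  residual covariance, which is unidentifiable in cross-sectional
  region-wise models with one observation per subject; the package uses
  random intercepts plus iid residuals throughout.
- **FDR family**: 68 tests per mutation type, per modality, per contrast —
  each brain map is one family. (The published text fixes the
  per-mutation-type stratification; per-modality is this package's choice.)
- **Covariates**: age + sex in the cross-sectional models, age + sex +
  education in the longitudinal ones, following the printed model
  structures; education can be added to the cross-sectional models via the
  model functions if desired.
- **Aim-4 regional maps** are keyed on the baseline-imaging main effect
  (the "association" that the negative control in non-carriers refers to);
  the imaging × time interaction is always reported and can be selected as
  the map term via `run_aim`'s config.
- **Stage pooling**: GENFI-CDR 1, 2 and 3 are pooled into one "≥ 1" stage;
  all non-carriers form one control group regardless of their own rating.

## Problem sizes used by the test-suite

The suite validates the models at sizes chosen to balance statistical power
against desk-scale runtimes: parameter recovery at n = 400 per analysis
(100 replicates, every generating coefficient within 3 SE in ≥ 95%), type-I
error at n = 140 per replicate (500 replicates per model form, band
0.03–0.07), FDR control on full 68-region null maps (40 replicates), and
the non-carrier negative control on 97 controls with 2–4 visits
(60 replicates). One distributional fact matters when reading that last
check: under a global null, BH makes at least one discovery with probability
exactly q = 0.05 (the Simes identity), so about one null map in twenty
*should* contain a spurious survivor; the test verifies the clean-replicate
fraction is consistent with the nominal 95% within Monte-Carlo error, and
the replicate count was sized so that check has ~98% power.

## Known limitations

- The simplified thickness (white-to-pial vertex distance) assumes exact
  vertex correspondence; it is a stand-in for reconstruction-based thickness
  and is only meaningful on meshes built with that correspondence.
- Mid-ribbon sampling does not model partial-volume effects; on real data
  the NaN policy only guards against out-of-volume and masked voxels.
- Site effects are additive intercepts; no scanner-specific variance or
  covariance harmonisation is attempted.
- Clinical scores are modelled as Gaussian on the z-scale; real CBI-R
  distributions are floor-heavy in presymptomatic carriers and non-carriers.
- Regional values are simulated independently across regions (given site
  and subject effects), so spatial smoothness of real cortical maps is not
  reproduced.
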