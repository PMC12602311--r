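#!/usr/bin/env Rscript
# End-to-end per-subject quantification on synthetic geometry: a constant-MD
# phantom and a linear-gradient MD field are sampled at the mid-ribbon of a
# toy surface bundle and aggregated to the 68 atlas regions. The constant
# field checks exactness; the gradient field shows regional variation driven
# purely by geometry. Writes results/surface_quantification.csv.

library(cortmd)
dir.create("results", showWarnings = FALSE)

grads <- make_gradient_scheme(12, b = 1000)
d_iso <- 0.9e-3
ph <- make_phantom(phantom_spec(c(16, 16, 16), 2, isotropic_tensor(d_iso),
                                noise_sigma = 0), grads)
md <- md_map(fit_tensor(ph$dwi, grads))
bundle <- make_surface_bundle(4000, 68, thickness = 2.5, radius = 10,
                              center = c(15, 15, 15), seed = 2)
q_const <- quantify_subject(md, bundle)

# linear MD field along x: analytic regional means
idx <- expand.grid(x = 0:31, y = 0:31, z = 0:31)
grad_field <- list(
  data = array(0.7e-3 + 1e-5 * idx$x, dim = c(32, 32, 32)),
  affine = diag(c(2, 2, 2, 1)))
bundle2 <- make_surface_bundle(4000, 68, thickness = 2.5, radius = 20,
                               center = c(31, 31, 31), seed = 2)
mid2 <- midthickness(bundle2)
grad_vals <- sample_volume_at_vertices(grad_field, mid2)
q_grad <- aggregate_rois(grad_vals, bundle2$parcellation)

out <- data.frame(
  roi = dk_roi_names(),
  cmd_constant_field = unname(q_const$cmd_roi),
  cth = unname(q_const$cth_roi),
  cmd_gradient_field = unname(q_grad))
write.csv(out, "results/surface_quantification.csv", row.names = FALSE)

cat("Constant-MD phantom: max |ROI cMD -", d_iso, "| =",
    max(abs(out$cmd_constant_field - d_iso)), "\n")
cat("Thickness recovered:  max |ROI CTh - 2.5 mm| =",
    max(abs(out$cth - 2.5)), "\n")
cat("Gradient field: regional cMD spans",
    paste(signif(range(out$cmd_gradient_field), 4), collapse = " .. "),
    "mm^2/s across the 68 regions, following the imposed spatial gradient.\n")
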