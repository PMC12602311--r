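#!/usr/bin/env Rscript
# Validates the imaging core on synthetic ground truth: simulates a DWI
# phantom with known per-voxel tensors, refits them, and summarises the
# recovery error of the tensor components and the mean-diffusivity map at
# three noise levels. Writes results/phantom_recovery.csv.

library(cortmd)
dir.create("results", showWarnings = FALSE)
set.seed(1)

grads <- make_gradient_scheme(12, b = 1000)
tensor_rule <- function(i, j, k) {
  R <- rotation_matrix(c(i, j, k), 0.15 * (i + 2 * j + 3 * k))
  anisotropic_tensor(c(1.7, 0.5, 0.3) * 1e-3, R)
}

rows <- lapply(c(0, 5, 20), function(sigma) {
  ph <- make_phantom(phantom_spec(c(16, 16, 16), 2, tensor_rule, s0 = 1000,
                                  noise_sigma = sigma, seed = NULL), grads)
  tf <- fit_tensor(ph$dwi, grads)
  md_hat <- md_map(tf)$data
  md_true <- (ph$truth[, , , 1] + ph$truth[, , , 2] + ph$truth[, , , 3]) / 3
  data.frame(noise_sigma = sigma,
             pct_noise = 100 * sigma / 1000,
             n_voxels = length(md_true),
             max_rel_err_tensor = max(abs(tf$comp - ph$truth)) /
               max(abs(ph$truth)),
             md_rmse = sqrt(mean((md_hat - md_true)^2)),
             md_max_rel_err = max(abs(md_hat - md_true) / md_true))
})
out <- do.call(rbind, rows)
write.csv(out, "results/phantom_recovery.csv", row.names = FALSE)

cat("Phantom tensor/MD recovery (16^3 voxels, 12 directions + b0):\n")
print(out, row.names = FALSE, digits = 3)
cat("\nNoiseless recovery is exact to numerical precision;",
    "MD error scales with the noise level.\n")
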