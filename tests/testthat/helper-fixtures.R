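# shared fixtures, all generated in code

default_grads <- function(n_dir = 12, b = 1000) make_gradient_scheme(n_dir, b)

# cohort on the generator (z) scale so model coefficients are directly
# comparable to the generating values
zscale_cohort_spec <- function(...) {
  cohort_spec(..., loc = c(cMD = 0, CTh = 0), scale = c(cMD = 1, CTh = 1))
}

# a small linear scalar field volume: f(x, y, z) = a + b x + c y + d z
affine_field_volume <- function(coefs = c(2, 0.1, -0.05, 0.2),
                                dims = c(33, 33, 33), affine = diag(4)) {
  idx <- expand.grid(x = seq_len(dims[1]) - 1, y = seq_len(dims[2]) - 1,
                     z = seq_len(dims[3]) - 1)
  world <- cbind(as.matrix(idx), 1) %*% t(affine)
  vals <- coefs[1] + coefs[2] * world[, 1] + coefs[3] * world[, 2] +
    coefs[4] * world[, 3]
  list(data = array(vals, dim = dims), affine = affine)
}

affine_field_truth <- function(pts, coefs = c(2, 0.1, -0.05, 0.2)) {
  coefs[1] + coefs[2] * pts[, 1] + coefs[3] * pts[, 2] + coefs[4] * pts[, 3]
}
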