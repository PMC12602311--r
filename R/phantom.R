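#' Specification of a synthetic DWI phantom
#'
#' Describes a rectangular grid of voxels, a rule assigning a ground-truth
#' diffusion tensor to every voxel, the baseline (b=0) signal and the noise
#' level. [make_phantom()] turns the specification into a 4D signal stack via
#' the single-tensor forward model `S_i = s0 * exp(-b_i * g_i' D g_i)`.
#'
#' @param grid_shape Integer vector of length 3, voxels per axis.
#' @param voxel_size Numeric length 3 (or scalar), mm per axis.
#' @param tensor_fun Either a single 3x3 symmetric positive semi-definite tensor
#'   (mm^2/s) used everywhere, or `function(i, j, k)` returning such a tensor
#'   for the 1-based voxel index.
#' @param s0 Baseline signal, > 0.
#' @param noise_sigma Noise scale in signal units, >= 0.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param seed Integer seed making the noise draw reproducible, or NULL to
#'   draw from the current RNG stream.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(8, 8, 8), voxel_size = c(2, 2, 2),
                         tensor_fun = isotropic_tensor(0.8e-3), s0 = 1000,
                         noise_sigma = 0, noise_model = c("gaussian", "rician"),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1))
    stop("grid_shape must be 3 positive integers")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (s0 <= 0) stop("s0 must be > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  noise_model <- match.arg(noise_model)
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 tensor_fun = tensor_fun, s0 = s0, noise_sigma = noise_sigma,
                 noise_model = noise_model,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "phantom_spec")
}

#' Convenience tensor constructors
#'
#' `isotropic_tensor(d)` is `d * I`. `anisotropic_tensor(evals, rotation)` is
#' `R diag(evals) R'` for a rotation matrix `R` (defaults to identity).
#' `rotation_matrix(axis, angle)` builds a 3D rotation via Rodrigues' formula.
#'
#' @param d Diffusivity (mm^2/s).
#' @return A 3x3 symmetric tensor (or rotation matrix).
#' @export
isotropic_tensor <- function(d) diag(rep(d, 3))

#' @param evals Length-3 eigenvalues (mm^2/s).
#' @param rotation 3x3 rotation matrix.
#' @rdname isotropic_tensor
#' @export
anisotropic_tensor <- function(evals, rotation = diag(3)) {
  stopifnot(length(evals) == 3)
  rotation %*% diag(evals) %*% t(rotation)
}

#' @param axis Rotation axis (length 3, need not be unit).
#' @param angle Rotation angle in radians.
#' @rdname isotropic_tensor
#' @export
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# order of the 6 unique tensor components used throughout: xx, yy, zz, xy, xz, yz
TENSOR_COMP <- c("xx", "yy", "zz", "xy", "xz", "yz")

tensor_to_comp <- function(D) {
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

comp_to_tensor <- function(v) {
  matrix(c(v[1], v[4], v[5], v[4], v[2], v[6], v[5], v[6], v[3]), 3, 3)
}

check_psd <- function(D, tol = 1e-12) {
  if (max(abs(D - t(D))) > 1e-12 * max(1, max(abs(D))))
    stop("tensor rule produced a non-symmetric tensor")
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1))
    stop("tensor rule produced a non-positive-semi-definite tensor ",
         "(min eigenvalue ", format(min(ev)), ")")
  invisible(TRUE)
}

#' 4D diffusion-weighted stack container
#'
#' @param data 4D numeric array (x, y, z, volume).
#' @param affine 4x4 voxel-index (0-based) to world-mm (RAS) transform.
#' @param brain_mask Optional 3D logical array; voxels outside are not fitted.
#' @return An object of class `dwi_stack`.
#' @export
dwi_stack <- function(data, affine = NULL, brain_mask = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 4L) stop("data must be a 4D array")
  if (is.null(affine)) affine <- diag(4)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix")
  if (!is.null(brain_mask)) {
    brain_mask <- as.array(brain_mask)
    if (!all(dim(brain_mask) == dim(data)[1:3]))
      stop("brain_mask dimensions must match the first three data dimensions")
    storage.mode(brain_mask) <- "logical"
  }
  structure(list(data = data, affine = affine, brain_mask = brain_mask),
            class = "dwi_stack")
}

#' Simulate a DWI phantom with known tensors
#'
#' Evaluates the monoexponential tensor forward model on every voxel of the
#' grid and adds measurement noise, returning both the signal stack and the
#' ground-truth tensor field so that fitting code can be validated against it.
#' Gaussian noise is added directly to the signal; Rician noise replaces the
#' signal with the magnitude of a complex Gaussian perturbation.
#'
#' @param spec A [phantom_spec()].
#' @param grads A [gradient_scheme()] with >= 1 b=0 volume and >= 6
#'   non-collinear weighted directions.
#' @return List with `dwi` (a [dwi_stack()], affine = diag(voxel size)) and
#'   `truth` (array `grid_shape x 6` of tensor components in xx, yy, zz, xy,
#'   xz, yz order).
#' @export
make_phantom <- function(spec, grads) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(grads, "gradient_scheme"))
  B <- tensor_design(grads)          # n_vol x 6, errors if design-deficient
  shp <- spec$grid_shape
  nvox <- prod(shp)
  nvol <- length(grads$bvals)

  # per-voxel tensor components
  comp <- matrix(0, nvox, 6)
  if (is.function(spec$tensor_fun)) {
    idx <- arrayInd(seq_len(nvox), shp)
    for (v in seq_len(nvox)) {
      D <- spec$tensor_fun(idx[v, 1], idx[v, 2], idx[v, 3])
      check_psd(D)
      comp[v, ] <- tensor_to_comp(D)
    }
  } else {
    D <- as.matrix(spec$tensor_fun)
    check_psd(D)
    comp <- matrix(tensor_to_comp(D), nvox, 6, byrow = TRUE)
  }

  # signal: S = s0 * exp(-b g' D g) = s0 * exp(-(B %*% comp))
  expo <- comp %*% t(B)              # nvox x nvol
  sig <- spec$s0 * exp(-expo)
  if (spec$noise_sigma > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    if (spec$noise_model == "gaussian") {
      sig <- sig + stats::rnorm(length(sig), 0, spec$noise_sigma)
    } else {
      re <- sig + stats::rnorm(length(sig), 0, spec$noise_sigma)
      im <- stats::rnorm(length(sig), 0, spec$noise_sigma)
      sig <- sqrt(re^2 + im^2)
    }
  }

  data <- array(sig, dim = c(shp, nvol))
  affine <- diag(c(spec$voxel_size, 1))
  list(dwi = dwi_stack(data, affine),
       truth = array(comp, dim = c(shp, 6L),
                     dimnames = c(rep(list(NULL), 3), list(TENSOR_COMP))))
}

#' Read / write DWI and scalar volumes as NIfTI-1
#'
#' Thin wrappers over RNifti keeping the package's convention: the affine maps
#' 0-based voxel indices to world mm (RAS).
#'
#' @param path NIfTI file path.
#' @param bval_path,bvec_path Optional FSL gradient files read alongside.
#' @return `read_dwi()`: list with `dwi` ([dwi_stack()]) and `grads` (or NULL).
#' @export
read_dwi <- function(path, bval_path = NULL, bvec_path = NULL) {
  img <- RNifti::readNifti(path)
  grads <- if (!is.null(bval_path)) read_gradients(bval_path, bvec_path)
  list(dwi = dwi_stack(as.array(img), affine = RNifti::xform(img)),
       grads = grads)
}

#' @param volume 3D array (e.g. an MD map) or a `dwi_stack`.
#' @param affine 4x4 affine for a bare array.
#' @rdname read_dwi
#' @export
write_volume <- function(volume, path, affine = NULL) {
  if (inherits(volume, "dwi_stack")) {
    affine <- volume$affine
    volume <- volume$data
  }
  if (is.null(affine)) affine <- diag(4)
  img <- RNifti::asNifti(volume, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
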