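#' Diffusion-weighting design matrix
#'
#' Builds the n_vol x 6 matrix `B` with rows
#' `b * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)` so that the log-signal
#' model is `log S = log S0 - B %*% d` with `d` the six unique tensor
#' components (xx, yy, zz, xy, xz, yz). Errors if the full design
#' `[1, -B]` is rank-deficient (fewer than 6 independent weighted directions).
#'
#' @param grads A [gradient_scheme()].
#' @return n_vol x 6 numeric matrix.
#' @keywords internal
tensor_design <- function(grads) {
  g <- grads$bvecs
  b <- grads$bvals
  B <- b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                 2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  colnames(B) <- TENSOR_COMP
  X <- cbind(1, -B)
  if (qr(X)$rank < 7L)
    stop("design-deficient gradient scheme: need at least 6 non-collinear ",
         "diffusion-weighted directions plus b=0 (design rank ",
         qr(X)$rank, " < 7)")
  B
}

#' Fit the diffusion tensor per voxel
#'
#' Ordinary (unweighted) log-linear least squares: for each voxel the model
#' `log S_i = log S0 - b_i g_i' D g_i` is solved in closed form over all
#' volumes. Non-positive signals are clamped to a floor of `1e-6` times the
#' voxel's mean b=0 signal before taking logs; voxels with fewer than 7
#' strictly positive measurements are flagged invalid, as are voxels outside
#' the brain mask.
#'
#' @param stack A [dwi_stack()].
#' @param grads The matching [gradient_scheme()].
#' @return An object of class `tensor_field`: list with `comp` (array
#'   `x,y,z,6`, NaN where invalid), `log_s0` (3D array), `valid` (3D logical),
#'   and the source `affine`.
#' @export
fit_tensor <- function(stack, grads) {
  stopifnot(inherits(stack, "dwi_stack"), inherits(grads, "gradient_scheme"))
  dims <- dim(stack$data)
  nvol <- dims[4]
  if (nvol != length(grads$bvals))
    stop("stack has ", nvol, " volumes but gradient scheme describes ",
         length(grads$bvals))
  B <- tensor_design(grads)
  X <- cbind(log_s0 = 1, -B)                       # n_vol x 7
  XtX_inv_Xt <- solve(crossprod(X), t(X))          # 7 x n_vol

  nvox <- prod(dims[1:3])
  S <- matrix(stack$data, nvox, nvol)              # voxels x volumes
  fit_mask <- if (is.null(stack$brain_mask)) rep(TRUE, nvox)
              else as.vector(stack$brain_mask)

  usable <- rowSums(S > 0)
  valid <- fit_mask & usable >= 7L

  b0 <- grads$bvals == 0
  s0_est <- rowMeans(S[, b0, drop = FALSE])
  s0_est[!(s0_est > 0)] <- 1
  floor_eps <- 1e-6 * s0_est
  Sc <- pmax(S, floor_eps)                         # clamp, recycled by column

  coef <- matrix(NA_real_, nvox, 7)
  if (any(valid))
    coef[valid, ] <- log(Sc[valid, , drop = FALSE]) %*% t(XtX_inv_Xt)

  comp <- array(coef[, 2:7], dim = c(dims[1:3], 6L),
                dimnames = c(rep(list(NULL), 3), list(TENSOR_COMP)))
  comp[!is.finite(comp)] <- NaN
  log_s0 <- array(coef[, 1], dim = dims[1:3])

  structure(list(comp = comp, log_s0 = log_s0,
                 valid = array(valid, dim = dims[1:3]),
                 affine = stack$affine),
            class = "tensor_field")
}

#' Extract one voxel's tensor as a 3x3 matrix
#'
#' @param field A `tensor_field`.
#' @param i,j,k 1-based voxel indices.
#' @return 3x3 symmetric matrix (NaN entries if the voxel is invalid).
#' @export
tensor_at <- function(field, i, j, k) {
  comp_to_tensor(field$comp[i, j, k, ])
}

#' Mean diffusivity map
#'
#' MD = trace(D)/3 = (Dxx + Dyy + Dzz)/3, equal to the mean of the tensor's
#' eigenvalues. Invalid voxels propagate NaN.
#'
#' @param field A `tensor_field` from [fit_tensor()].
#' @return An object of class `md_volume`: list with `data` (3D array, mm^2/s)
#'   and `affine`.
#' @export
md_map <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  md <- (field$comp[, , , 1] + field$comp[, , , 2] + field$comp[, , , 3]) / 3
  md <- array(md, dim = dim(field$comp)[1:3])
  md[!field$valid] <- NaN
  structure(list(data = md, affine = field$affine), class = "md_volume")
}

#' @export
print.md_volume <- function(x, ...) {
  cat("<md_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels; MD range ",
      paste(signif(range(x$data, na.rm = TRUE), 4), collapse = " .. "),
      " mm^2/s; ", sum(is.nan(x$data)), " invalid\n", sep = "")
  invisible(x)
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", paste(dim(x$valid), collapse = " x "),
      " voxels; ", sum(x$valid), " valid\n", sep = "")
  invisible(x)
}
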