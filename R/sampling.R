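#' Mid-thickness (mid-ribbon) surface
#'
#' The per-vertex arithmetic midpoint between corresponding white and pial
#' vertices. Sampling scalar maps here rather than at either boundary reduces
#' partial-volume contamination from CSF (outside the pial surface) and white
#' matter (inside the white surface).
#'
#' @param bundle A `surface_bundle`.
#' @return n x 3 matrix of mid-surface vertex coordinates (world mm).
#' @export
midthickness <- function(bundle) {
  validate_bundle(bundle)
  (bundle$white + bundle$pial) / 2
}

#' Simplified vertex-wise cortical thickness
#'
#' Euclidean distance between corresponding white and pial vertices. This is a
#' simplified measure relying on index correspondence (synthetic bundles are
#' built with exact correspondence); it is not the full reconstruction-based
#' thickness of surface pipelines.
#'
#' @param bundle A `surface_bundle`.
#' @return Numeric vector of per-vertex thickness (mm).
#' @export
vertex_thickness <- function(bundle) {
  validate_bundle(bundle)
  sqrt(rowSums((bundle$pial - bundle$white)^2))
}

#' Sample a scalar volume at world-space points
#'
#' Maps world coordinates to (0-based) voxel coordinates through the inverse
#' affine and interpolates trilinearly. Trilinear interpolation reproduces
#' affine fields `a + bx + cy + dz` exactly, which the test-suite uses as an
#' analytic oracle. Points falling outside the voxel grid, or whose 8
#' neighbouring voxels include a NaN, yield NaN; the number of out-of-volume
#' points is reported via the `n_outside` attribute.
#'
#' @param volume An `md_volume` (or any list with 3D `data` and 4x4 `affine`).
#' @param vertices n x 3 matrix of world-mm coordinates.
#' @return Numeric vector of sampled values with attribute `n_outside`.
#' @export
sample_volume_at_vertices <- function(volume, vertices) {
  vol <- volume$data
  dims <- dim(vol)
  vertices <- as.matrix(vertices)
  n <- nrow(vertices)
  # world -> 0-based continuous voxel coordinates
  vox <- cbind(vertices, 1) %*% t(solve(volume$affine))[, 1:3]

  inside <- vox[, 1] >= 0 & vox[, 1] <= dims[1] - 1 &
            vox[, 2] >= 0 & vox[, 2] <= dims[2] - 1 &
            vox[, 3] >= 0 & vox[, 3] <= dims[3] - 1
  inside[is.na(inside)] <- FALSE
  # lower corner of the interpolation cell; points exactly on the upper
  # boundary use the last full cell with fractional offset 1
  i0 <- pmin(floor(vox), matrix(dims - 2, n, 3, byrow = TRUE))
  i0 <- pmax(i0, 0)
  frac <- vox - i0

  out <- rep(NaN, n)
  if (any(inside)) {
    ii <- i0[inside, , drop = FALSE]
    ff <- frac[inside, , drop = FALSE]
    corner <- function(dx, dy, dz) {
      idx <- cbind(ii[, 1] + dx + 1, ii[, 2] + dy + 1, ii[, 3] + dz + 1)
      vol[idx]
    }
    w <- function(dx, dy, dz) {
      (if (dx == 1) ff[, 1] else 1 - ff[, 1]) *
      (if (dy == 1) ff[, 2] else 1 - ff[, 2]) *
      (if (dz == 1) ff[, 3] else 1 - ff[, 3])
    }
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
      acc <- acc + w(dx, dy, dz) * corner(dx, dy, dz)
    out[inside] <- acc
  }
  attr(out, "n_outside") <- sum(!inside)
  out
}

#' Aggregate per-vertex values to ROI means
#'
#' Unweighted mean of the per-vertex values over each parcellation label, in
#' the fixed ROI-dictionary order. NaN vertices are excluded from the mean; an
#' ROI whose valid fraction drops below 95% triggers a warning, and an ROI
#' with no valid vertex yields NaN. The `"unknown"` label is never aggregated.
#'
#' @param values Numeric per-vertex vector.
#' @param parcellation Character per-vertex labels.
#' @param roi_names Ordered ROI dictionary (default: the 68 Desikan-Killiany
#'   names).
#' @param nan_warn_frac Warn when an ROI has more than this fraction of NaN
#'   vertices.
#' @return Named numeric vector, one entry per `roi_names`.
#' @export
aggregate_rois <- function(values, parcellation, roi_names = dk_roi_names(),
                           nan_warn_frac = 0.05) {
  if (length(values) != length(parcellation))
    stop("values and parcellation lengths differ")
  out <- stats::setNames(rep(NaN, length(roi_names)), roi_names)
  for (roi in roi_names) {
    v <- values[parcellation == roi]
    if (length(v) == 0) {
      warning("ROI '", roi, "' has no vertices")
      next
    }
    bad <- !is.finite(v)
    if (mean(bad) > nan_warn_frac)
      warning("ROI '", roi, "' has ", sum(bad), "/", length(v),
              " NaN vertices")
    if (all(bad)) {
      warning("ROI '", roi, "' has no valid vertices; mean is NaN")
      next
    }
    out[roi] <- mean(v[!bad])
  }
  out
}

#' Global cortical measure
#'
#' Arithmetic mean of the 68 regional values. With the default `"propagate"`
#' policy a NaN region makes the global value NaN; `"omit"` averages the
#' remaining regions instead (the choice is logged via a message).
#'
#' @param roi_values Numeric vector of length 68 (or `length(roi_names)`).
#' @param na_policy `"propagate"` (default) or `"omit"`.
#' @param n_expected Expected number of regions.
#' @return Scalar.
#' @export
global_measure <- function(roi_values, na_policy = c("propagate", "omit"),
                           n_expected = 68) {
  na_policy <- match.arg(na_policy)
  if (length(roi_values) != n_expected)
    stop("expected ", n_expected, " regional values, got ", length(roi_values))
  if (any(!is.finite(roi_values)) && na_policy == "omit") {
    message(sum(!is.finite(roi_values)),
            " NaN region(s) omitted from global mean")
    return(mean(roi_values[is.finite(roi_values)]))
  }
  mean(roi_values)
}

#' Quantify one subject: regional cMD and CTh from volume + surfaces
#'
#' Runs the full per-subject quantification: mid-ribbon construction, trilinear
#' MD sampling, simplified vertex thickness, and ROI aggregation of both
#' measures.
#'
#' @param md An `md_volume`.
#' @param bundle A `surface_bundle`.
#' @param na_policy Passed to [global_measure()].
#' @return List with `cmd_roi`, `cth_roi` (named 68-vectors), `global_cmd`,
#'   `global_cth`, and `n_outside` (vertices outside the MD volume).
#' @export
quantify_subject <- function(md, bundle, na_policy = "propagate") {
  mid <- midthickness(bundle)
  md_vert <- sample_volume_at_vertices(md, mid)
  th_vert <- vertex_thickness(bundle)
  cmd <- aggregate_rois(md_vert, bundle$parcellation, bundle$roi_names)
  cth <- aggregate_rois(th_vert, bundle$parcellation, bundle$roi_names)
  n_roi <- length(bundle$roi_names)
  list(cmd_roi = cmd, cth_roi = cth,
       global_cmd = global_measure(cmd, na_policy, n_expected = n_roi),
       global_cth = global_measure(cth, na_policy, n_expected = n_roi),
       n_outside = attr(md_vert, "n_outside"))
}
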