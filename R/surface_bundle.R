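# split n items into k positive integer parts (n >= k), optionally weighted
split_sizes <- function(n, k, weights = NULL) {
  if (k > n) stop("cannot split ", n, " items into ", k, " non-empty parts")
  if (is.null(weights)) weights <- rep(1, k)
  sizes <- pmax(1L, floor(weights / sum(weights) * n))
  excess <- sum(sizes) - n
  ord <- order(sizes, decreasing = excess > 0)
  i <- 1
  while (excess != 0) {
    v <- ord[(i - 1) %% k + 1]
    if (excess > 0 && sizes[v] > 1L) { sizes[v] <- sizes[v] - 1L; excess <- excess - 1 }
    if (excess < 0) { sizes[v] <- sizes[v] + 1L; excess <- excess + 1 }
    i <- i + 1
  }
  sizes
}

# triangle strip between two vertex rings of (possibly) different sizes
stitch_rings <- function(ring_a, ring_b) {
  m <- length(ring_a); n <- length(ring_b)
  faces <- matrix(0L, 0, 3)
  i <- 0L; j <- 0L
  while (i < m || j < n) {
    adv_a <- i < m && (j >= n || (i + 1) / m <= (j + 1) / n)
    if (adv_a) {
      faces <- rbind(faces, c(ring_a[i %% m + 1L], ring_a[(i + 1L) %% m + 1L],
                              ring_b[j %% n + 1L]))
      i <- i + 1L
    } else {
      faces <- rbind(faces, c(ring_a[i %% m + 1L], ring_b[(j + 1L) %% n + 1L],
                              ring_b[j %% n + 1L]))
      j <- j + 1L
    }
  }
  faces
}

#' Build a synthetic cortical surface bundle
#'
#' Constructs a closed spherical "white" mesh with exactly `n_vertices`
#' vertices (two poles plus latitude rings, triangulated), displaces each
#' vertex outward along its (radial) normal by `thickness` to obtain the
#' "pial" mesh, and partitions the vertices into `n_rois` contiguous,
#' non-empty parcels (latitude bands split into azimuthal sectors). Vertex
#' correspondence between white and pial surfaces is by index, matching the
#' convention of paired cortical reconstructions. The spherical geometry gives
#' analytic ground truth: every white/pial vertex pair is exactly `thickness`
#' apart, so the simplified thickness measure is known by construction.
#'
#' @param n_vertices Total vertex count (>= `n_rois`).
#' @param n_rois Number of parcels; 68 (default) uses the Desikan-Killiany
#'   name dictionary, other values get generic `roi<k>` names.
#' @param thickness White-to-pial displacement in mm.
#' @param radius White-surface radius in mm.
#' @param center Sphere centre in world mm.
#' @param seed Integer (or NULL to use the current RNG stream); applies a
#'   seeded random rotation to the sphere so different seeds give different
#'   vertex placements.
#' @return An object of class `surface_bundle`: list with `white`, `pial`
#'   (n x 3 matrices, world mm), `faces` (m x 3 integer, 1-based),
#'   `parcellation` (character vector of ROI labels), `roi_names`.
#' @export
make_surface_bundle <- function(n_vertices = 2000, n_rois = 68,
                                thickness = 2.5, radius = 60,
                                center = c(0, 0, 0), seed = 1L) {
  n_vertices <- as.integer(n_vertices)
  if (n_rois > n_vertices)
    stop("n_rois (", n_rois, ") exceeds n_vertices (", n_vertices, ")")
  if (thickness <= 0) stop("thickness must be > 0")
  if (n_vertices < 5) stop("need at least 5 vertices for a closed mesh")

  # poles + latitude rings sized ~ sin(theta)
  n_interior <- n_vertices - 2L
  n_rings <- max(1L, round(sqrt(n_interior / 2)))
  n_rings <- min(n_rings, n_interior)
  theta <- pi * seq_len(n_rings) / (n_rings + 1)
  ring_sizes <- split_sizes(n_interior, n_rings, weights = sin(theta))

  pts <- matrix(0, n_vertices, 3)
  pts[1, ] <- c(0, 0, 1)
  pts[n_vertices, ] <- c(0, 0, -1)
  rings <- vector("list", n_rings)
  off <- 1L
  for (r in seq_len(n_rings)) {
    m <- ring_sizes[r]
    phi <- 2 * pi * (seq_len(m) - 1) / m + (r %% 2) * pi / m
    rings[[r]] <- off + seq_len(m)
    pts[rings[[r]], ] <- cbind(sin(theta[r]) * cos(phi),
                               sin(theta[r]) * sin(phi),
                               rep(cos(theta[r]), m))
    off <- off + m
  }

  faces <- do.call(rbind, c(
    list(stitch_rings(rep(1L, 2), rings[[1]])[, c(1, 3, 2), drop = FALSE]),
    if (n_rings > 1)
      lapply(seq_len(n_rings - 1), function(r)
        stitch_rings(rings[[r]], rings[[r + 1]])),
    list(stitch_rings(rings[[n_rings]], rep(n_vertices, 2L)))
  ))
  faces <- faces[faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
                 faces[, 1] != faces[, 3], , drop = FALSE]

  # seeded rotation, then scale/translate into world coordinates
  if (!is.null(seed)) set.seed(seed)
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  unit <- pts %*% t(R)
  white <- sweep(unit * radius, 2, center, `+`)
  pial <- sweep(unit * (radius + thickness), 2, center, `+`)

  parcellation <- parcellate_sphere(unit, n_rois)

  structure(list(white = white, pial = pial, faces = faces,
                 parcellation = parcellation$labels,
                 roi_names = parcellation$roi_names),
            class = "surface_bundle")
}

# contiguous parcellation of unit-sphere points: latitude bands x azimuth sectors
parcellate_sphere <- function(unit, n_rois) {
  n <- nrow(unit)
  roi_names <- if (n_rois == 68) dk_roi_names() else paste0("roi", seq_len(n_rois))
  n_bands <- max(1L, round(sqrt(n_rois / 2)))
  n_bands <- min(n_bands, n_rois)
  sectors_per_band <- split_sizes(n_rois, n_bands)
  band_sizes <- split_sizes(n, n_bands, weights = sectors_per_band)

  z_order <- order(unit[, 3], decreasing = TRUE)
  labels <- character(n)
  roi_i <- 1L
  pos <- 1L
  for (b in seq_len(n_bands)) {
    band_idx <- z_order[pos:(pos + band_sizes[b] - 1L)]
    pos <- pos + band_sizes[b]
    k <- sectors_per_band[b]
    az <- atan2(unit[band_idx, 2], unit[band_idx, 1])
    sec_sizes <- split_sizes(length(band_idx), k)
    az_order <- band_idx[order(az)]
    p <- 1L
    for (s in seq_len(k)) {
      labels[az_order[p:(p + sec_sizes[s] - 1L)]] <- roi_names[roi_i]
      p <- p + sec_sizes[s]
      roi_i <- roi_i + 1L
    }
  }
  list(labels = labels, roi_names = roi_names)
}

#' @export
print.surface_bundle <- function(x, ...) {
  cat("<surface_bundle> ", nrow(x$white), " vertices, ", nrow(x$faces),
      " faces, ", length(x$roi_names), " ROIs\n", sep = "")
  invisible(x)
}

validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "surface_bundle"))
  n <- nrow(bundle$white)
  if (nrow(bundle$pial) != n)
    stop("white and pial surfaces have different vertex counts (",
         n, " vs ", nrow(bundle$pial), ")")
  if (length(bundle$parcellation) != n)
    stop("parcellation length does not match vertex count")
  if (nrow(bundle$faces) > 0 &&
      (min(bundle$faces) < 1 || max(bundle$faces) > n))
    stop("faces reference vertices outside 1..", n)
  invisible(bundle)
}
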