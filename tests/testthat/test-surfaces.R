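test_that("bundle construction: exact thickness, full parcellation", {
  b <- make_surface_bundle(1500, 68, thickness = 2.5, radius = 50, seed = 2)
  expect_equal(nrow(b$white), 1500)
  expect_equal(nrow(b$pial), 1500)
  d <- sqrt(rowSums((b$pial - b$white)^2))
  expect_lt(max(abs(d - 2.5)), 1e-9)
  labs <- table(b$parcellation)
  expect_setequal(names(labs), dk_roi_names())
  expect_true(all(labs > 0))
  # faces reference valid vertices and cover the mesh
  expect_gte(min(b$faces), 1)
  expect_lte(max(b$faces), 1500)
  expect_setequal(sort(unique(as.vector(b$faces))), 1:1500)
})

test_that("label histogram is invariant under vertex-order permutation", {
  b <- make_surface_bundle(800, 20, thickness = 2, seed = 9)
  set.seed(1)
  perm <- sample(nrow(b$white))
  h1 <- table(b$parcellation)
  h2 <- table(b$parcellation[perm])
  expect_identical(as.vector(h1[names(h1)]), as.vector(h2[names(h1)]))
})

test_that("degenerate bundle requests error", {
  expect_error(make_surface_bundle(50, 68), "exceeds")
  expect_error(make_surface_bundle(100, 68, thickness = 0), "thickness")
})

test_that("mid-thickness is the exact vertex midpoint and behaves affinely", {
  b <- make_surface_bundle(400, 10, thickness = 3, seed = 4)
  mid <- midthickness(b)
  expect_equal(mid, (b$white + b$pial) / 2)
  # hand case
  b2 <- b
  b2$white[1, ] <- c(0, 0, 0); b2$pial[1, ] <- c(2, 0, 0)
  expect_equal(midthickness(b2)[1, ], c(1, 0, 0))
  # white == pial -> mid == white, thickness 0
  b3 <- b; b3$pial <- b3$white
  expect_equal(midthickness(b3), b3$white)
  expect_equal(vertex_thickness(b3), rep(0, 400))
  # linearity under an affine map applied to both surfaces
  set.seed(5)
  A <- matrix(rnorm(9), 3, 3); t0 <- rnorm(3)
  b4 <- b
  b4$white <- sweep(b$white %*% t(A), 2, t0, `+`)
  b4$pial <- sweep(b$pial %*% t(A), 2, t0, `+`)
  expect_equal(midthickness(b4), sweep(mid %*% t(A), 2, t0, `+`),
               tolerance = 1e-12)
})

test_that("vertex thickness is rigid-motion invariant", {
  b <- make_surface_bundle(300, 5, thickness = 1.7, seed = 6)
  th <- vertex_thickness(b)
  R <- rotation_matrix(c(0.3, 1, -2), 0.9); t0 <- c(10, -4, 2)
  br <- b
  br$white <- sweep(b$white %*% t(R), 2, t0, `+`)
  br$pial <- sweep(b$pial %*% t(R), 2, t0, `+`)
  expect_equal(vertex_thickness(br), th, tolerance = 1e-10)
  # mismatched vertex counts error
  bb <- b; bb$pial <- bb$pial[-1, ]
  expect_error(vertex_thickness(bb), "vertex counts")
})

test_that("surfaces round-trip through FreeSurfer binary and text formats", {
  b <- make_surface_bundle(200, 5, thickness = 2, seed = 8)
  for (fmt in c("freesurfer", "text")) {
    f <- tempfile()
    write_surface(b$white, b$faces, f, format = fmt)
    rt <- read_surface(f)
    tol <- if (fmt == "freesurfer") 1e-4 else 1e-9  # float32 storage
    expect_equal(rt$vertices, b$white, tolerance = tol, ignore_attr = TRUE)
    expect_equal(rt$faces, b$faces, ignore_attr = TRUE)
  }
})

test_that("parcellations round-trip through .annot and text formats", {
  b <- make_surface_bundle(250, 68, thickness = 2, seed = 10)
  for (fmt in c("annot", "text")) {
    f <- tempfile()
    write_annot(b$parcellation, f, format = fmt)
    expect_identical(read_annot(f, 250), b$parcellation)
  }
})

test_that("whole bundles round-trip via a path prefix", {
  b <- make_surface_bundle(300, 68, thickness = 2.2, seed = 11)
  for (fmt in c("freesurfer", "text")) {
    prefix <- file.path(tempdir(), paste0("bundle_", fmt))
    write_surface_bundle(b, prefix, format = fmt)
    rt <- read_surface_bundle(prefix, format = fmt)
    expect_equal(rt$white, b$white, tolerance = 1e-4, ignore_attr = TRUE)
    expect_equal(rt$pial, b$pial, tolerance = 1e-4, ignore_attr = TRUE)
    expect_identical(rt$parcellation, b$parcellation)
    expect_identical(rt$roi_names, dk_roi_names())
  }
})
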