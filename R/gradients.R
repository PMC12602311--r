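#' Diffusion gradient scheme
#'
#' Bundles the b-values and unit gradient directions of a DWI acquisition.
#' At least one b=0 volume is required; for diffusion-weighted volumes the
#' direction vectors must be unit length to within 1e-3 (the FSL bvec
#' convention). The zero vector is allowed (and conventional) for b=0 entries.
#'
#' @param bvals Numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs Numeric matrix of gradient directions, either 3 x n or n x 3.
#' @return An object of class `gradient_scheme`: a list with `bvals` (length n)
#'   and `bvecs` (n x 3 matrix, rows are directions).
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3L)
    stop("bvecs must be a 3 x n or n x 3 matrix of directions")
  if (length(bvals) != nrow(bvecs))
    stop("bvals and bvecs describe different numbers of volumes (",
         length(bvals), " vs ", nrow(bvecs), ")")
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative")
  if (!any(bvals == 0))
    stop("gradient scheme must contain at least one b=0 volume")
  norms <- sqrt(rowSums(bvecs^2))
  bad <- bvals > 0 & abs(norms - 1) >= 1e-3
  if (any(bad))
    stop(sum(bad), " diffusion-weighted direction(s) are not unit length")
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("<gradient_scheme> ", length(x$bvals), " volumes (",
      sum(x$bvals == 0), " b=0; shells: ",
      paste(sort(unique(x$bvals[x$bvals > 0])), collapse = ", "),
      " s/mm^2)\n", sep = "")
  invisible(x)
}

#' Read / write FSL-style bval and bvec files
#'
#' `read_gradients()` parses the standard FSL text pair: `bval` holds one row of
#' whitespace-separated b-values, `bvec` three rows (x, y, z components).
#' `write_gradients()` writes the same layout.
#'
#' @param bval_path,bvec_path Paths to the text files.
#' @return `read_gradients()` returns a [gradient_scheme()].
#' @export
read_gradients <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- readLines(bvec_path)
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != 3L)
    stop("bvec file must contain exactly 3 rows, found ", length(rows))
  bvecs <- do.call(rbind, lapply(rows, function(r)
    scan(text = r, quiet = TRUE)))
  gradient_scheme(bvals, bvecs)
}

#' @param grads A [gradient_scheme()].
#' @rdname read_gradients
#' @export
write_gradients <- function(grads, bval_path, bvec_path) {
  stopifnot(inherits(grads, "gradient_scheme"))
  writeLines(paste(format(grads$bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(t(grads$bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Evenly spread diffusion directions
#'
#' Deterministic direction set built from the spherical Fibonacci lattice,
#' suitable for synthetic acquisitions. Returns a full scheme with `n_b0`
#' leading b=0 volumes followed by `n_dir` weighted directions at `b`.
#'
#' @param n_dir Number of diffusion-weighted directions (>= 6).
#' @param b b-value for the weighted volumes (s/mm^2).
#' @param n_b0 Number of b=0 volumes.
#' @return A [gradient_scheme()].
#' @export
make_gradient_scheme <- function(n_dir = 12, b = 1000, n_b0 = 1) {
  if (n_dir < 6) stop("need at least 6 diffusion-weighted directions")
  if (n_dir == 6) {
    # the classic dual-gradient 6-direction set; the 6-point Fibonacci
    # lattice is degenerate for tensor estimation
    dirs <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
                  c(1, -1, 0), c(1, 0, -1), c(0, 1, -1)) / sqrt(2)
  } else {
    i <- seq_len(n_dir) - 0.5
    phi <- pi * (1 + sqrt(5)) * i
    z <- 1 - 2 * i / n_dir
    r <- sqrt(pmax(0, 1 - z^2))
    dirs <- cbind(r * cos(phi), r * sin(phi), z)
  }
  g <- gradient_scheme(
    bvals = c(rep(0, n_b0), rep(b, n_dir)),
    bvecs = rbind(matrix(0, n_b0, 3), dirs)
  )
  tensor_design(g)   # errors early if the direction set is degenerate
  g
}
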