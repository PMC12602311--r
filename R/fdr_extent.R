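#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over a family of tests (here typically the 68
#' regional tests of one modality within one mutation type). Adjusted values
#' satisfy `q >= p` elementwise and are monotone non-decreasing in p.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (NA allowed, propagated).
#' @return Vector of adjusted q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Chi-square comparison of spatial extents
#'
#' Compares the number of significant regions found for two modalities (e.g.
#' cMD vs CTh) out of a common total, using the Pearson chi-square statistic
#' on the 2x2 table `[[sig_a, n - sig_a], [sig_b, n - sig_b]]` without
#' continuity correction (df = 1, two-sided). Degenerate tables (both counts
#' 0 or both equal to `n_total`) are reported as chi-square 0, p = 1, with a
#' `degenerate` flag.
#'
#' @param n_sig_a,n_sig_b Significant-region counts for the two modalities.
#' @param n_total Total number of regions (default 68).
#' @return List of class `extent_comparison`: `n_sig_a`, `n_sig_b`, `n_total`,
#'   `chi2`, `p`, `degenerate`.
#' @export
extent_chi_square <- function(n_sig_a, n_sig_b, n_total = 68) {
  if (n_sig_a < 0 || n_sig_b < 0 || n_sig_a > n_total || n_sig_b > n_total)
    stop("counts must lie in 0..n_total")
  tab <- matrix(c(n_sig_a, n_total - n_sig_a,
                  n_sig_b, n_total - n_sig_b), 2, 2, byrow = TRUE)
  degenerate <- any(colSums(tab) == 0)
  if (degenerate || n_sig_a == n_sig_b) {
    chi2 <- 0
    p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic)
    p <- unname(ct$p.value)
  }
  structure(list(n_sig_a = n_sig_a, n_sig_b = n_sig_b, n_total = n_total,
                 chi2 = chi2, p = p, degenerate = degenerate),
            class = "extent_comparison")
}

#' @export
print.extent_comparison <- function(x, ...) {
  cat(sprintf(
    "<extent_comparison> %d/%d vs %d/%d regions: chi2 = %.2f, p = %.3g%s\n",
    x$n_sig_a, x$n_total, x$n_sig_b, x$n_total, x$chi2, x$p,
    if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
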