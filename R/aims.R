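aim_contrasts <- function(aim) {
  switch(as.character(aim),
    "1" = data.frame(contrast = "interaction", group_a = NA, group_b = NA),
    "2" = data.frame(contrast = c("pMC_vs_NC", "sMC_vs_NC", "sMC_vs_pMC"),
                     group_a = c("pMC", "sMC", "sMC"),
                     group_b = c("NC", "NC", "pMC")),
    "3" = data.frame(contrast = c("CDR0_vs_NC", "CDR0.5_vs_NC",
                                  "CDR1plus_vs_NC"),
                     group_a = c("CDR0", "CDR0.5", "CDR1plus"),
                     group_b = "NC"),
    "4" = data.frame(contrast = "imaging_x_progression",
                     group_a = NA, group_b = NA),
    stop("aim must be 1, 2, 3 or 4"))
}

#' Run one analysis aim across regions, modalities and mutation groups
#'
#' Orchestrates the regional statistical analysis for one of the four aims:
#' \describe{
#'   \item{Aim 1}{carrier-status by age interaction ([fit_interaction_model()]),
#'     all carriers of a mutation type plus all non-carriers.}
#'   \item{Aim 2}{pairwise contrasts pMC vs NC, sMC vs NC and sMC vs pMC
#'     ([fit_group_contrast()]).}
#'   \item{Aim 3}{disease-stage contrasts CDR = 0, 0.5, >= 1 vs non-carriers.}
#'   \item{Aim 4}{baseline imaging association with longitudinal clinical
#'     scores ([fit_longitudinal_model()]) within carriers of each type.}
#' }
#' For every mutation group, contrast and modality, the per-ROI models are
#' fitted, p-values of the key term are BH-adjusted within the 68-test family
#' (one family per mutation type, per modality, per contrast), significance is
#' flagged at `q < 0.05`, and the spatial extents of significant cMD and CTh
#' findings are compared with [extent_chi_square()]. Per-ROI fit failures are
#' recorded (with NA statistics), not fatal.
#'
#' @param cohort List with `records` and `table` (see [simulate_cohort()]).
#' @param aim 1, 2, 3 or 4.
#' @param visits Visit table, required for aim 4.
#' @param config Optional list overriding defaults: `rois` (ROI subset),
#'   `modalities`, `mutation_groups`, `q_threshold` (0.05), `outcome`
#'   (`"cbi_r"`; aim 4), `aim4_term` (`"imaging"`, the mapped association
#'   term, or `"imaging:time"`), `standardize`, `screen_outliers`.
#' @return List of class `aim_result`: `roi_results` (one row per group x
#'   contrast x modality x ROI: beta, se, df, t, p, q, significant) and
#'   `extent` (one row per group x contrast: significant counts per modality,
#'   chi-square, p, degeneracy flag).
#' @export
run_aim <- function(cohort, aim, visits = NULL, config = list()) {
  records <- cohort$records
  table <- cohort$table
  cfg <- utils::modifyList(list(
    rois = dk_roi_names(), modalities = c("cMD", "CTh"),
    mutation_groups = intersect(MUTATION_GROUPS,
                                unique(records$mutation_group)),
    q_threshold = 0.05, outcome = "cbi_r", aim4_term = "imaging",
    standardize = TRUE, screen_outliers = TRUE), config)
  if (aim == 4 && is.null(visits))
    stop("aim 4 requires a visit table")
  contrasts <- aim_contrasts(aim)

  key_term <- switch(as.character(aim),
    "1" = "status:age", "2" = "group", "3" = "group", "4" = cfg$aim4_term)

  rows <- list()
  for (g in cfg$mutation_groups) {
    for (ci in seq_len(nrow(contrasts))) {
      for (mod in cfg$modalities) {
        for (roi in cfg$rois) {
          res <- tryCatch({
            fit <- switch(as.character(aim),
              "1" = fit_interaction_model(table, records, mod, roi, g,
                                          cfg$standardize,
                                          cfg$screen_outliers),
              "2" = ,
              "3" = fit_group_contrast(table, records, mod, roi,
                                       contrasts$group_a[ci],
                                       contrasts$group_b[ci], g,
                                       cfg$standardize, cfg$screen_outliers),
              "4" = fit_longitudinal_model(
                      visits, table,
                      records[records$carrier &
                              records$mutation_group == g, , drop = FALSE],
                      cfg$outcome, roi, mod, cfg$standardize,
                      cfg$screen_outliers))
            fixed_effect(fit, key_term)
          }, error = function(e) {
            warning("fit failed for ", g, "/", mod, "/", roi, ": ",
                    conditionMessage(e))
            data.frame(term = key_term, estimate = NA_real_, se = NA_real_,
                       df = NA_real_, t = NA_real_, p = NA_real_,
                       ci_lo = NA_real_, ci_hi = NA_real_)
          })
          rows[[length(rows) + 1]] <- data.frame(
            aim = aim, mutation_group = g,
            contrast = contrasts$contrast[ci], modality = mod, roi = roi,
            beta = res$estimate, se = res$se, df = res$df, t = res$t,
            p = res$p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  roi_results <- do.call(rbind, rows)

  # BH-FDR within each (mutation type, contrast, modality) family
  roi_results$q <- NA_real_
  fam <- interaction(roi_results$mutation_group, roi_results$contrast,
                     roi_results$modality, drop = TRUE)
  for (f in levels(fam)) {
    i <- fam == f
    roi_results$q[i] <- bh_fdr(roi_results$p[i])
  }
  roi_results$significant <- !is.na(roi_results$q) &
    roi_results$q < cfg$q_threshold

  ext <- list()
  if (all(c("cMD", "CTh") %in% cfg$modalities)) {
    for (g in cfg$mutation_groups) {
      for (con in contrasts$contrast) {
        sel <- roi_results$mutation_group == g & roi_results$contrast == con
        n_a <- sum(roi_results$significant[sel & roi_results$modality == "cMD"])
        n_b <- sum(roi_results$significant[sel & roi_results$modality == "CTh"])
        ec <- extent_chi_square(n_a, n_b, length(cfg$rois))
        ext[[length(ext) + 1]] <- data.frame(
          aim = aim, mutation_group = g, contrast = con,
          n_sig_cMD = n_a, n_sig_CTh = n_b, n_total = length(cfg$rois),
          chi2 = ec$chi2, p = ec$p, degenerate = ec$degenerate,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(roi_results = roi_results,
                 extent = if (length(ext)) do.call(rbind, ext)),
            class = "aim_result")
}

#' @export
print.aim_result <- function(x, ...) {
  cat("<aim_result> aim ", x$roi_results$aim[1], ": ",
      nrow(x$roi_results), " ROI fits, ",
      sum(x$roi_results$significant), " significant (q < 0.05)\n", sep = "")
  if (!is.null(x$extent)) print(x$extent, row.names = FALSE)
  invisible(x)
}
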