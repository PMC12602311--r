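#' Validate a pipeline run configuration
#'
#' A run configuration is a nested list (typically read from YAML): `seed`,
#' `out_dir`, `cohort` (arguments to [cohort_spec()]), `longitudinal`
#' (arguments to [longitudinal_spec()]), `aims` (subset of 1:4), `thresholds`
#' (`alpha`, `q`, `outlier_sd`), and `stats` overrides passed to [run_aim()]
#' (e.g. `rois`, `outcome`, `truncate_years`). Validation is fail-fast:
#' thresholds must lie in (0, 1), the outlier multiple must be positive, and
#' referenced input paths must exist.
#'
#' @param config List or path to a YAML file.
#' @return The validated config (invisibly usable by [run_pipeline()]).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(list(
    seed = 1L, out_dir = "cortmd_run",
    cohort = list(), longitudinal = list(), aims = c(1, 2, 3),
    thresholds = list(alpha = 0.05, q = 0.05, outlier_sd = 3),
    stats = list()), config)
  th <- config$thresholds
  if (th$alpha <= 0 || th$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (th$q <= 0 || th$q >= 1) stop("q must lie in (0, 1)")
  if (th$outlier_sd <= 0) stop("outlier_sd must be positive")
  if (!all(config$aims %in% 1:4)) stop("aims must be a subset of 1:4")
  for (p in config$inputs)
    if (!file.exists(p)) stop("configured input does not exist: ", p)
  config
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Executes the stages in order: simulate a cross-sectional cohort, simulate
#' longitudinal clinical visits (when aim 4 is requested), run the configured
#' aims, and write all outputs under `config$out_dir`: regional results and
#' the cohort tables as CSV, extent comparisons and global-model fits as
#' JSON, a human-readable markdown report, and a reproducibility manifest
#' (config hash, seeds, input checksums, per-stage record counts). Identical
#' configuration and seeds give identical outputs.
#'
#' @param config List or YAML path; see [validate_config()].
#' @return Invisibly, a list with `cohort`, `visits`, `aim_results`,
#'   `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- simulate_cohort(do.call(cohort_spec,
    utils::modifyList(list(seed = config$seed), config$cohort)))
  utils::write.csv(cohort$records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$table, file.path(out_dir, "regional_table.csv"),
                   row.names = FALSE)

  visits <- NULL
  if (4 %in% config$aims) {
    visits <- simulate_longitudinal(do.call(longitudinal_spec,
      utils::modifyList(list(seed = config$seed + 1),
                        config$longitudinal)), cohort)
    if (!is.null(config$stats$truncate_years))
      visits <- truncate_followup(visits, config$stats$truncate_years)
    utils::write.csv(visits, file.path(out_dir, "visits.csv"),
                     row.names = FALSE)
  }

  stats_cfg <- utils::modifyList(
    list(q_threshold = config$thresholds$q), config$stats)
  stats_cfg$truncate_years <- NULL
  aim_results <- lapply(config$aims, function(a)
    run_aim(cohort, a, visits = visits, config = stats_cfg))
  names(aim_results) <- paste0("aim", config$aims)

  all_roi <- do.call(rbind, lapply(aim_results, `[[`, "roi_results"))
  utils::write.csv(all_roi, file.path(out_dir, "roi_results.csv"),
                   row.names = FALSE)
  all_ext <- do.call(rbind, lapply(aim_results, `[[`, "extent"))
  jsonlite::write_json(all_ext, file.path(out_dir, "extent_comparisons.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cortmd")),
    seed = config$seed,
    config_hash = unname(hash_object(config)),
    counts = list(
      subjects = nrow(cohort$records),
      sites = length(unique(cohort$records$site_id)),
      visits = if (is.null(visits)) 0L else nrow(visits),
      roi_fits = nrow(all_roi),
      roi_fit_failures = sum(is.na(all_roi$p)),
      extent_records = if (is.null(all_ext)) 0L else nrow(all_ext)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(write_report(aim_results), file.path(out_dir, "report.md"))

  invisible(list(cohort = cohort, visits = visits,
                 aim_results = aim_results, manifest = manifest,
                 out_dir = out_dir))
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

#' Format aim results as a markdown report
#'
#' One section per aim; for every mutation group and contrast, the percentage
#' of significant regions per modality, the chi-square extent comparison and
#' its p-value, in the reporting style of regional neuroimaging studies.
#' ROI names must belong to the atlas dictionary.
#'
#' @param aim_results List of `aim_result` objects (as in
#'   [run_pipeline()]'s output).
#' @return Character vector of markdown lines.
#' @export
write_report <- function(aim_results) {
  if (length(aim_results) == 0) {
    warning("no results to report")
    return("# cortmd report\n\n(no results)")
  }
  lines <- c("# Regional cMD vs CTh analysis report", "")
  for (res in aim_results) {
    bad <- setdiff(unique(res$roi_results$roi),
                   c(dk_roi_names(), "global"))
    if (length(bad))
      stop("unknown ROI name(s) in results: ", paste(bad, collapse = ", "))
    lines <- c(lines, paste0("## Aim ", res$roi_results$aim[1]), "")
    if (is.null(res$extent)) next
    for (i in seq_len(nrow(res$extent))) {
      e <- res$extent[i, ]
      pct <- function(n) sprintf("%.0f%%", 100 * n / e$n_total)
      lines <- c(lines, sprintf(
        "- %s, %s: cMD %s vs CTh %s significant regions (chi2 = %.1f, p = %.2g)%s",
        e$mutation_group, e$contrast, pct(e$n_sig_cMD), pct(e$n_sig_CTh),
        e$chi2, e$p, if (e$degenerate) " [degenerate]" else ""))
    }
    lines <- c(lines, "")
  }
  lines
}
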