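# run_aim checks use an ROI subset to keep model counts manageable; the
# full 68-ROI behaviour is exercised in the acceptance suite

test_that("aim orchestration finds planted regional effects", {
  rois <- dk_roi_names()[1:12]
  eff_cmd <- rep(0, 68); eff_cmd[1:8] <- 1.2     # 8 affected cMD regions
  eff_cth <- rep(0, 68); eff_cth[1:3] <- -1.2    # 3 affected CTh regions
  co <- simulate_cohort(zscale_cohort_spec(
    n_per_group = 80, n_noncarrier = 80, n_sites = 8,
    beta = list(cMD = list(status = eff_cmd), CTh = list(status = eff_cth)),
    sigma_site = 0.1, sigma_resid = 0.6, seed = 80))
  res <- run_aim(co, 2, config = list(rois = rois,
                                      mutation_groups = "C9orf72"))
  rr <- res$roi_results
  expect_equal(nrow(rr), 3 * 2 * 12)   # 3 contrasts x 2 modalities x 12 ROIs
  smc <- rr[rr$contrast == "sMC_vs_NC", ]
  hit_cmd <- smc$significant[smc$modality == "cMD"]
  expect_gte(sum(hit_cmd[1:8]), 6)
  expect_lte(sum(hit_cmd[9:12]), 1)
  ext <- res$extent[res$extent$contrast == "sMC_vs_NC", ]
  expect_gt(ext$n_sig_cMD, ext$n_sig_CTh)
  # q-values respect the per-family BH relation
  expect_true(all(rr$q >= rr$p, na.rm = TRUE))
})

test_that("interaction aim flags only the modality with the planted effect", {
  rois <- dk_roi_names()[1:6]
  eff <- rep(0, 68); eff[1:6] <- 0.8
  co <- simulate_cohort(zscale_cohort_spec(
    n_per_group = 120, n_noncarrier = 120, n_sites = 8,
    beta = list(cMD = list(status_age = eff)),
    sigma_site = 0.1, sigma_resid = 0.7, seed = 81))
  res <- run_aim(co, 1, config = list(rois = rois,
                                      mutation_groups = "GRN"))
  rr <- res$roi_results
  expect_gte(sum(rr$significant[rr$modality == "cMD"]), 4)
  expect_lte(sum(rr$significant[rr$modality == "CTh"]), 1)
})

test_that("stage contrasts emit one stratum per requested group", {
  co <- simulate_cohort(zscale_cohort_spec(n_per_group = 60,
                                           n_noncarrier = 60, seed = 82))
  res <- run_aim(co, 3, config = list(rois = dk_roi_names()[1:3],
                                      mutation_groups = "MAPT"))
  expect_setequal(unique(res$roi_results$contrast),
                  c("CDR0_vs_NC", "CDR0.5_vs_NC", "CDR1plus_vs_NC"))
  expect_setequal(unique(res$roi_results$mutation_group), "MAPT")
})

test_that("aim 4 requires visits and reports the association term", {
  co <- simulate_cohort(zscale_cohort_spec(n_per_group = 60,
                                           n_noncarrier = 60, seed = 83))
  expect_error(run_aim(co, 4), "visit")
  vis <- simulate_longitudinal(
    longitudinal_spec(visits_per_subject = c(3, 3),
                      beta = list(imaging = 0.5, time = 0.2,
                                  imaging_time = 0.15),
                      predictor = "cMD_lh_bankssts", seed = 84), co)
  res <- run_aim(co, 4, visits = vis,
                 config = list(rois = c("lh_bankssts", "rh_insula"),
                               mutation_groups = "C9orf72",
                               outcome = "cbi_r_z"))
  rr <- res$roi_results
  expect_equal(nrow(rr), 4)
  b <- rr[rr$roi == "lh_bankssts" & rr$modality == "cMD", ]
  expect_lt(b$p, 0.05)
})

test_that("pipeline runs end to end, deterministically, with a manifest", {
  cfg <- list(seed = 11, out_dir = file.path(tempdir(), "run1"),
              cohort = list(n_per_group = 40, n_noncarrier = 40,
                            n_sites = 5),
              aims = c(2, 4),
              longitudinal = list(visits_per_subject = c(2, 3)),
              stats = list(rois = dk_roi_names()[1:4],
                           outcome = "cbi_r"))
  out1 <- run_pipeline(cfg)
  files <- list.files(cfg$out_dir)
  expect_true(all(c("records.csv", "regional_table.csv", "visits.csv",
                    "roi_results.csv", "extent_comparisons.json",
                    "manifest.json", "report.md") %in% files))
  expect_equal(out1$manifest$counts$subjects, 160)
  expect_equal(out1$manifest$counts$roi_fit_failures, 0)
  # determinism: identical config + seed give byte-identical tables
  cfg2 <- cfg; cfg2$out_dir <- file.path(tempdir(), "run2")
  run_pipeline(cfg2)
  for (f in c("records.csv", "regional_table.csv", "roi_results.csv")) {
    expect_identical(readLines(file.path(cfg$out_dir, f)),
                     readLines(file.path(cfg2$out_dir, f)))
  }
  # 3 groups x (3 aim-2 contrasts + 1 aim-4 record) extent records
  ext <- jsonlite::read_json(file.path(cfg$out_dir,
                                       "extent_comparisons.json"))
  expect_equal(length(ext), 3 * 4)
})

test_that("config validation is fail-fast", {
  expect_error(validate_config(list(thresholds = list(alpha = 1.5, q = 0.05,
                                                      outlier_sd = 3))),
               "alpha")
  expect_error(validate_config(list(aims = c(1, 7))), "aims")
  expect_error(validate_config(list(inputs = "no/such/file.csv")),
               "does not exist")
})

test_that("reports format extents and reject unknown ROI names", {
  fake <- structure(list(
    roi_results = data.frame(aim = 2, mutation_group = "C9orf72",
                             contrast = "sMC_vs_NC",
                             modality = rep(c("cMD", "CTh"), each = 2),
                             roi = rep(dk_roi_names()[1:2], 2),
                             beta = 1, se = 0.1, df = 10, t = 10, p = 0.001,
                             q = 0.004, significant = TRUE),
    extent = data.frame(aim = 2, mutation_group = "C9orf72",
                        contrast = "sMC_vs_NC", n_sig_cMD = 68,
                        n_sig_CTh = 38, n_total = 68, chi2 = 38.5,
                        p = 5e-10, degenerate = FALSE)), class = "aim_result")
  rep_lines <- write_report(list(aim2 = fake))
  expect_true(any(grepl("100% vs CTh 56%", rep_lines)))
  expect_true(any(grepl("38.5", rep_lines)))
  bad <- fake
  bad$roi_results$roi[1] <- "lh_atlantis"
  expect_error(write_report(list(bad)), "unknown ROI")
  expect_warning(write_report(list()), "no results")
})
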