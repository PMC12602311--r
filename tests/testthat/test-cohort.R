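test_that("degenerate spec: no noise, all effects zero gives the intercept", {
  sp <- zscale_cohort_spec(n_per_group = 5, n_noncarrier = 5, n_sites = 2,
                           beta = list(cMD = list(intercept = 1.25),
                                       CTh = list(intercept = -0.5)),
                           sigma_site = 0, sigma_resid = 0, seed = 1)
  co <- simulate_cohort(sp)
  expect_true(all(co$table$cMD_lh_insula == 1.25))
  expect_true(all(co$table$CTh_rh_cuneus == -0.5))
  expect_equal(co$table$global_cMD, rep(1.25, 20))
})

test_that("simulated moments match the spec at large n", {
  sp <- zscale_cohort_spec(n_per_group = 100, n_noncarrier = 9700,
                           n_sites = 4, sigma_site = 0, sigma_resid = 1,
                           seed = 2)
  co <- simulate_cohort(sp)
  vals <- co$table$cMD_lh_bankssts
  n <- length(vals)
  expect_equal(sd(vals), 1, tolerance = 3 / sqrt(2 * n))   # 3 MC SEs
  expect_equal(mean(vals), 0, tolerance = 3 / sqrt(n))
})

test_that("cohort tables are deterministic and schema-valid", {
  sp <- cohort_spec(n_per_group = 10, n_noncarrier = 12, n_sites = 3,
                    seed = 5)
  a <- simulate_cohort(sp)
  b <- simulate_cohort(sp)
  expect_identical(a, b)
  rec <- a$records
  expect_equal(nrow(rec), 42)
  expect_setequal(unique(rec$mutation_group),
                  c("C9orf72", "GRN", "MAPT", "non-carrier"))
  # invariants: non-carriers have NA symptom status; carriers a stage
  expect_true(all(is.na(rec$symptom_status[!rec$carrier])))
  expect_true(all(rec$symptom_status[rec$carrier] %in% c("pMC", "sMC")))
  # global equals the mean over the 68 regional columns
  cmd_cols <- paste0("cMD_", dk_roi_names())
  expect_equal(a$table$global_cMD, rowMeans(a$table[, cmd_cols]))
  # natural units plausible: cMD ~ 1e-3 mm^2/s, CTh ~ 2.5 mm
  expect_true(all(a$table[, cmd_cols] > 0))
  expect_true(all(a$table[, paste0("CTh_", dk_roi_names())] > 1))
})

test_that("per-ROI status effects land on the designated regions", {
  eff <- rep(0, 68); eff[1:10] <- 1.5
  sp <- zscale_cohort_spec(n_per_group = 300, n_noncarrier = 300,
                           n_sites = 5,
                           beta = list(cMD = list(status = eff)),
                           sigma_site = 0, sigma_resid = 0.3, seed = 6)
  co <- simulate_cohort(sp)
  carrier <- co$records$carrier
  diffs <- sapply(dk_roi_names(), function(r) {
    x <- co$table[[paste0("cMD_", r)]]
    mean(x[carrier]) - mean(x[!carrier])
  })
  expect_equal(unname(diffs[1:10]), rep(1.5, 10), tolerance = 0.1)
  expect_equal(unname(diffs[11:68]), rep(0, 58), tolerance = 0.1)
})

test_that("longitudinal visits honour schedule and noiseless slopes", {
  co <- simulate_cohort(zscale_cohort_spec(n_per_group = 10,
                                           n_noncarrier = 10, seed = 3))
  sp <- longitudinal_spec(visits_per_subject = c(3, 3),
                          followup_years = c(2, 2),
                          beta = list(time = 1),
                          sigma_site = 0, sigma_subject = 0, sigma_resid = 0,
                          seed = 4)
  vis <- simulate_longitudinal(sp, co)
  expect_equal(nrow(vis), 40 * 3)
  base <- vis[vis$visit == 1, ]
  expect_true(all(base$time_from_baseline == 0))
  # slope exactly 1 z-unit per year for every subject
  for (s in unique(vis$subject_id)[1:5]) {
    v <- vis[vis$subject_id == s, ]
    expect_equal(unname(coef(lm(cbi_r_z ~ time_from_baseline, v))[2]), 1,
                 tolerance = 1e-10)
  }
  expect_identical(vis, simulate_longitudinal(sp, co))
  expect_error(longitudinal_spec(visits_per_subject = c(1, 1)), ">= 2")
})

test_that("subject random intercepts produce the expected ICC", {
  co <- simulate_cohort(zscale_cohort_spec(n_per_group = 400,
                                           n_noncarrier = 400, seed = 7))
  sp <- longitudinal_spec(visits_per_subject = c(4, 4),
                          followup_years = c(2, 2), sigma_site = 0,
                          sigma_subject = 0.8, sigma_resid = 0.6, seed = 8)
  vis <- simulate_longitudinal(sp, co)
  # moment estimate of the ICC from between/within subject variances
  m <- tapply(vis$cbi_r_z, vis$subject_id, mean)
  wthn <- tapply(vis$cbi_r_z, vis$subject_id, var)
  s2_w <- mean(wthn)
  s2_b <- var(m) - s2_w / 4
  icc_hat <- s2_b / (s2_b + s2_w)
  icc_true <- 0.8^2 / (0.8^2 + 0.6^2)
  expect_equal(icc_hat, icc_true, tolerance = 0.05)
})

test_that("clinical scores stay within instrument ranges", {
  co <- simulate_cohort(cohort_spec(n_per_group = 30, seed = 9))
  vis <- simulate_longitudinal(longitudinal_spec(seed = 10), co)
  expect_true(all(vis$cbi_r >= 0 & vis$cbi_r <= 180))
  expect_true(all(vis$cdr_sob >= 0 & vis$cdr_sob <= 27))
  expect_true(all(vis$time_from_baseline >= 0))
})
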