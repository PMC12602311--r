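# moderate-replicate model checks; the full-scale recovery and error-rate
# studies live in test-acceptance.R

sim_cross <- function(seed, beta_cmd = list(), n = 100, n_sites = 10,
                      sigma_site = 0.2, sigma_resid = 1) {
  simulate_cohort(zscale_cohort_spec(
    n_per_group = n, n_noncarrier = n, n_sites = n_sites,
    beta = list(cMD = beta_cmd), sigma_site = sigma_site,
    sigma_resid = sigma_resid, seed = seed))
}

test_that("status-by-age interaction is recovered within its CI", {
  hits <- sapply(1:20, function(s) {
    co <- sim_cross(s, list(status = 0.3, age = 0.2, status_age = 0.5,
                            sex = 0.1), n = 130)
    f <- fit_interaction_model(co$table, co$records, "cMD", "lh_bankssts",
                               "C9orf72", standardize = FALSE)
    e <- fixed_effect(f, "status:age")
    abs(e$estimate - 0.5) <= 3 * e$se
  })
  expect_gte(mean(hits), 0.9)
})

test_that("zero site variance approaches ordinary least squares", {
  # REML estimates a small positive site SD when the truth is zero, so the
  # comparison is in absolute units on the z-scale, not machine tolerance
  co <- sim_cross(21, list(status = 0.4), n = 200, sigma_site = 0)
  f <- fit_interaction_model(co$table, co$records, "cMD", "lh_cuneus",
                             "GRN", standardize = FALSE)
  expect_lte(f$random_sd[["site"]], 0.15)
  d <- cortmd:::cross_sectional_frame(
    co$table,
    co$records[!co$records$carrier |
               co$records$mutation_group == "GRN", ],
    "cMD", "lh_cuneus", standardize = FALSE)
  ols <- lm(y ~ status * age + sex, d)
  expect_lt(abs(fixed_effect(f, "status:age")$estimate -
                coef(ols)["status:age"]), 0.02)
  expect_lt(abs(fixed_effect(f, "status")$estimate -
                coef(ols)["status"]), 0.05)
  expect_lt(abs(fixed_effect(f, "status:age")$se /
                sqrt(diag(vcov(ols)))["status:age"] - 1), 0.1)
})

test_that("group contrasts estimate the simulated shift and respect nulls", {
  co <- sim_cross(22, list(status = 1.0), n = 150)
  f <- fit_group_contrast(co$table, co$records, "cMD", "lh_insula",
                          "pMC", "NC", "C9orf72", standardize = FALSE)
  e <- fixed_effect(f, "group")
  expect_lt(abs(e$estimate - 1.0), 3 * e$se)
  # null symmetry: no simulated effect, estimates centred on zero
  ests <- sapply(23:32, function(s) {
    co0 <- sim_cross(s, list(), n = 80)
    fixed_effect(fit_group_contrast(co0$table, co0$records, "cMD",
                                    "lh_insula", "sMC", "NC", "MAPT",
                                    standardize = FALSE),
                 "group")$estimate
  })
  expect_lt(abs(mean(ests)), 2 * sd(ests) / sqrt(length(ests)) + 0.1)
})

test_that("age adjustment removes an age confound a t-test would inherit", {
  # carriers simulated older with a pure age effect, no true group effect
  set.seed(33)
  reps <- lapply(1:15, function(s) {
    co <- sim_cross(100 + s, list(age = 0.8), n = 120)
    rec <- co$records
    # shift carrier ages upward to confound age with carrier status
    rec$age[rec$carrier] <- rec$age[rec$carrier] + 15
    # regenerate the outcome with the shifted ages: y = 0.8 * age_z + noise
    age_z <- as.numeric(scale(rec$age))
    set.seed(200 + s)
    y <- 0.8 * age_z + rnorm(nrow(rec))
    tab <- co$table
    tab$cMD_lh_insula <- y
    sel <- !rec$carrier | rec$mutation_group == "C9orf72"
    f <- fit_group_contrast(tab, rec, "cMD", "lh_insula", "pMC", "NC",
                            "C9orf72", standardize = FALSE)
    tt <- t.test(y[sel & rec$carrier & rec$symptom_status %in% "pMC"],
                 y[sel & !rec$carrier])
    c(adj_p = fixed_effect(f, "group")$p, raw_p = tt$p.value)
  })
  adj <- sapply(reps, `[[`, "adj_p")
  raw <- sapply(reps, `[[`, "raw_p")
  expect_gt(mean(raw < 0.05), mean(adj < 0.05))  # unadjusted test inflated
  expect_lte(mean(adj < 0.05), 0.3)
})

test_that("fewer than two sites falls back to a fixed-intercept model", {
  co <- sim_cross(40, list(status = 0.5), n = 30, n_sites = 1)
  expect_warning(
    f <- fit_interaction_model(co$table, co$records, "cMD", "lh_bankssts",
                               "C9orf72", standardize = FALSE),
    "fixed-intercept")
  expect_equal(f$method, "OLS")
  expect_true(is.finite(fixed_effect(f, "status:age")$p))
})

test_that("empty analysis groups error cleanly", {
  co <- sim_cross(41, n = 10)
  co$records$symptom_status[co$records$carrier] <- "pMC"
  expect_error(fit_group_contrast(co$table, co$records, "cMD", "lh_insula",
                                  "sMC", "NC", "GRN"), "empty")
})

sim_long <- function(seed, beta = list(), n = 100, ...) {
  co <- simulate_cohort(zscale_cohort_spec(n_per_group = n, n_noncarrier = n,
                                           n_sites = 10, seed = seed))
  vis <- simulate_longitudinal(
    longitudinal_spec(visits_per_subject = c(3, 3), followup_years = c(1, 4),
                      beta = beta, seed = seed + 5000, ...), co)
  list(co = co, vis = vis)
}

test_that("longitudinal interaction and main effects are recovered", {
  hits <- sapply(1:15, function(s) {
    d <- sim_long(s, list(imaging = 0.5, time = 0.3, imaging_time = 0.2))
    f <- fit_longitudinal_model(d$vis, d$co$table, d$co$records, "cbi_r_z",
                                "global", "cMD", standardize = "imaging")
    c(abs(fixed_effect(f, "imaging")$estimate - 0.5) <=
        3 * fixed_effect(f, "imaging")$se,
      abs(fixed_effect(f, "imaging:time")$estimate - 0.2) <=
        3 * fixed_effect(f, "imaging:time")$se,
      abs(fixed_effect(f, "time")$estimate - 0.3) <=
        3 * fixed_effect(f, "time")$se)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("null longitudinal generator centres both key terms on zero", {
  ests <- sapply(31:40, function(s) {
    d <- sim_long(s)
    f <- fit_longitudinal_model(d$vis, d$co$table, d$co$records, "cbi_r_z",
                                "global", "cMD", standardize = "imaging")
    c(fixed_effect(f, "imaging")$estimate,
      fixed_effect(f, "imaging:time")$estimate)
  })
  expect_lt(abs(mean(ests[1, ])), 0.1)
  expect_lt(abs(mean(ests[2, ])), 0.05)
})

test_that("joint model separates a cMD-only signal and flags collinearity", {
  d <- sim_long(50, list(imaging = 0.6, time = 0.2, imaging_time = 0.25),
                n = 150)
  f <- fit_joint_global_model(d$vis, d$co$table, d$co$records, "cbi_r_z",
                              standardize = "imaging")
  expect_lt(fixed_effect(f, "cmd:time")$p, 0.05)
  expect_gt(fixed_effect(f, "cth:time")$p, 0.05)
  # identical predictors flagged
  d$co$table$global_CTh <- d$co$table$global_cMD
  f2 <- suppressWarnings(
    try(fit_joint_global_model(d$vis, d$co$table, d$co$records, "cbi_r_z",
                               standardize = "imaging"), silent = TRUE))
  if (!inherits(f2, "try-error"))
    expect_match(paste(f2$notes, collapse = " "), "collinear")
})

test_that("single-visit subjects are dropped with a warning", {
  d <- sim_long(60, n = 30)
  vis <- d$vis[!(d$vis$subject_id == d$vis$subject_id[1] & d$vis$visit > 1), ]
  expect_warning(
    fit_longitudinal_model(vis, d$co$table, d$co$records, "cbi_r_z",
                           "global", "cMD"),
    "single visit")
})

test_that("interaction grid slopes follow the fitted coefficients exactly", {
  d <- sim_long(70, list(imaging = 0.4, time = 0.3, imaging_time = 0.15))
  f <- fit_longitudinal_model(d$vis, d$co$table, d$co$records, "cbi_r_z",
                              "global", "cMD", standardize = "imaging")
  b_time <- fixed_effect(f, "time")$estimate
  b_int <- fixed_effect(f, "imaging:time")$estimate
  grid <- predict_interaction_grid(f, levels = c(-1, 0, 1),
                                   time_grid = c(0, 1, 2))
  s <- unique(grid[, c("level", "slope")])
  expect_equal(s$slope[s$level == 0], b_time)
  expect_equal(s$slope[s$level == 1], b_time + b_int)
  expect_equal(mean(s$slope[s$level %in% c(-1, 1)]), s$slope[s$level == 0])
  # bands widen away from the data centre and contain the point estimate
  expect_true(all(grid$ci_lo <= grid$predicted & grid$predicted <= grid$ci_hi))
  # slope consistency with finite differences of predictions
  p0 <- grid$predicted[grid$level == 1 & grid$time == 1]
  p1 <- grid$predicted[grid$level == 1 & grid$time == 2]
  expect_equal(p1 - p0, b_time + b_int, tolerance = 1e-10)
  expect_error(predict_interaction_grid(f, terms = c(predictor = "nope",
                                                     time = "time",
                                                     interaction = "x")),
               "no")
})
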