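pkg_env <- new.env(parent = emptyenv())

# standardise helper: covariates (age, education) are always z-scored within
# the analysis sample; the outcome / imaging predictor / time follow the
# `standardize` setting, which is TRUE (all), FALSE (none) or a character
# vector naming which of "y", "imaging", "time" to z-score
zcol <- function(x, active = TRUE) {
  if (active) z_transform(x) else x
}

std_on <- function(standardize, var) {
  if (is.character(standardize)) var %in% standardize
  else isTRUE(standardize)
}

# assemble a tidy fixed-effects table + variance components from an nlme::lme
# fit (or an lm fallback when the data hold fewer than two sites)
lmem_fit <- function(fit, formula_str, n_obs, n_groups) {
  if (inherits(fit, "lme")) {
    tt <- summary(fit)$tTable
    fixed <- data.frame(
      term = rownames(tt), estimate = tt[, "Value"],
      se = tt[, "Std.Error"], df = tt[, "DF"], t = tt[, "t-value"],
      p = tt[, "p-value"], row.names = NULL, stringsAsFactors = FALSE)
    vc <- nlme::VarCorr(fit)
    sds <- suppressWarnings(as.numeric(vc[, "StdDev"]))
    names(sds) <- rownames(vc)
    # nested fits interleave group-header rows (NA); relabel intercept SDs by
    # their grouping factor, outermost first
    keep_sd <- !is.na(sds)
    grp <- names(fit$groups)
    lbl <- names(sds)[keep_sd]
    lbl[lbl == "(Intercept)"] <- grp[seq_len(sum(lbl == "(Intercept)"))]
    sds <- stats::setNames(sds[keep_sd], lbl)
    vcov_fixed <- fit$varFix
    method <- fit$method
  } else {
    sm <- summary(fit)$coefficients
    fixed <- data.frame(
      term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
      df = fit$df.residual, t = sm[, 3], p = sm[, 4],
      row.names = NULL, stringsAsFactors = FALSE)
    sds <- c(Residual = summary(fit)$sigma)
    vcov_fixed <- stats::vcov(fit)
    method <- "OLS"
  }
  tcrit <- stats::qt(0.975, fixed$df)
  fixed$ci_lo <- fixed$estimate - tcrit * fixed$se
  fixed$ci_hi <- fixed$estimate + tcrit * fixed$se
  structure(list(fixed = fixed, random_sd = sds, vcov_fixed = vcov_fixed,
                 method = method, formula = formula_str,
                 n_obs = n_obs, n_groups = n_groups, notes = character()),
            class = "lmem_fit")
}

#' @export
print.lmem_fit <- function(x, digits = 3, ...) {
  cat("<lmem_fit> ", x$formula, "  [", x$method, ", n = ", x$n_obs, "]\n",
      sep = "")
  print(cbind(x$fixed[1], round(x$fixed[-1], digits)), row.names = FALSE)
  cat("random-effect SDs:",
      paste(names(x$random_sd), signif(x$random_sd, 3), collapse = ", "), "\n")
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Extract one fixed-effect row from an `lmem_fit`
#' @param fit An `lmem_fit`.
#' @param term Term name (e.g. `"status:age"`, `"imaging:time"`).
#' @return One-row data frame (estimate, se, df, t, p, ci_lo, ci_hi).
#' @export
fixed_effect <- function(fit, term) {
  row <- fit$fixed[fit$fixed$term == term, , drop = FALSE]
  if (nrow(row) != 1)
    stop("term '", term, "' not found in fit (terms: ",
         paste(fit$fixed$term, collapse = ", "), ")")
  row
}

fit_lme_or_lm <- function(fixed_formula, data, random, label) {
  n_grp <- length(unique(data$site))
  if (n_grp < 2) {
    warning("fewer than 2 sites in ", label,
            "; falling back to a fixed-intercept model")
    fit <- stats::lm(fixed_formula, data = data)
  } else {
    fit <- nlme::lme(fixed_formula, random = random, data = data,
                     method = "REML", na.action = stats::na.omit,
                     control = nlme::lmeControl(opt = "optim",
                                                returnObject = TRUE))
  }
  lmem_fit(fit, paste(deparse(fixed_formula), collapse = ""),
           n_obs = nrow(data), n_groups = n_grp)
}

# build the per-subject analysis frame for one modality/ROI outcome
cross_sectional_frame <- function(table, records, modality, roi,
                                  standardize = TRUE,
                                  screen_outliers = TRUE) {
  col <- if (roi == "global") paste0("global_", modality)
         else paste0(modality, "_", roi)
  if (!col %in% names(table)) stop("no column '", col, "' in regional table")
  y <- table[[col]][match(records$subject_id, table$subject_id)]
  keep <- if (screen_outliers) exclude_outliers(y) else is.finite(y)
  d <- data.frame(
    subject_id = records$subject_id,
    y = y,
    status = as.numeric(records$carrier),
    age = as.numeric(zcol(records$age)),
    sex = factor(records$sex, levels = c("female", "male")),
    site = factor(records$site_id),
    education = as.numeric(zcol(records$education)),
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  d$y <- as.numeric(zcol(d$y, std_on(standardize, "y")))
  d
}

#' Carrier-status by age interaction model (cross-sectional)
#'
#' Fits, for one ROI (or the global measure) of one modality, the linear
#' mixed-effects model
#' `outcome ~ status + age + status:age + sex + (1 | site)`
#' by REML, restricted to the named mutation group's carriers plus all
#' non-carriers. The status-by-age interaction coefficient tests whether the
#' outcome's association with age differs between carriers and non-carriers.
#' The outcome is screened for mean +/- 3 SD outliers and z-transformed by
#' default; age is always z-scored within the analysis sample.
#'
#' @param table Regional table from [simulate_cohort()] (or equivalent CSV).
#' @param records Subject records.
#' @param modality `"cMD"` or `"CTh"`.
#' @param roi ROI name, or `"global"`.
#' @param mutation_group One of `"C9orf72"`, `"GRN"`, `"MAPT"`, or `NULL` for
#'   all carriers pooled.
#' @param standardize z-transform the outcome (and, in longitudinal models,
#'   the imaging predictor and time). TRUE (default) transforms everything,
#'   FALSE nothing, or a character subset of `c("y", "imaging", "time")`.
#'   Age and education covariates are always z-scored within the analysis
#'   sample.
#' @param screen_outliers Apply the mean +/- 3 SD exclusion first.
#' @return An `lmem_fit`; the interaction row has term `"status:age"`.
#' @export
fit_interaction_model <- function(table, records, modality, roi,
                                  mutation_group = NULL, standardize = TRUE,
                                  screen_outliers = TRUE) {
  sel <- !records$carrier |
    (if (is.null(mutation_group)) records$carrier
     else records$mutation_group == mutation_group)
  records <- records[sel, , drop = FALSE]
  if (!any(records$carrier))
    stop("no carriers", if (!is.null(mutation_group))
      paste0(" in group ", mutation_group))
  d <- cross_sectional_frame(table, records, modality, roi,
                             standardize, screen_outliers)
  fit_lme_or_lm(y ~ status * age + sex, d, ~ 1 | site,
                paste0(modality, "_", roi))
}

# subject selectors for the pairwise contrasts
subjects_in_group <- function(records, label, mutation_group = NULL) {
  in_mut <- if (is.null(mutation_group)) records$carrier
            else records$carrier & records$mutation_group == mutation_group
  stage <- classify_stage(records$carrier, records$genfi_cdr)
  switch(label,
    NC = !records$carrier,
    pMC = in_mut & records$symptom_status %in% "pMC",
    sMC = in_mut & records$symptom_status %in% "sMC",
    CDR0 = in_mut & stage == "CDR0",
    CDR0.5 = in_mut & stage == "CDR0.5",
    CDR1plus = in_mut & stage == "CDR1plus",
    stop("unknown group label '", label, "'")
  )
}

#' Pairwise group contrast model (cross-sectional)
#'
#' Fits `outcome ~ group + age + sex + (1 | site)` for one ROI and modality,
#' comparing two participant groups: presymptomatic or symptomatic carriers
#' vs non-carriers, carrier disease stages (by GENFI-CDR) vs non-carriers, or
#' symptomatic vs presymptomatic carriers. The group coefficient is the
#' adjusted difference (`group_a` minus `group_b`) on the outcome scale.
#'
#' @inheritParams fit_interaction_model
#' @param group_a,group_b Group labels among
#'   `{NC, pMC, sMC, CDR0, CDR0.5, CDR1plus}`.
#' @param mutation_group Mutation type defining carrier membership for the
#'   carrier-side group(s).
#' @return An `lmem_fit`; the contrast row has term `"group"`.
#' @export
fit_group_contrast <- function(table, records, modality, roi,
                               group_a, group_b = "NC",
                               mutation_group = NULL, standardize = TRUE,
                               screen_outliers = TRUE) {
  in_a <- subjects_in_group(records, group_a, mutation_group)
  in_b <- subjects_in_group(records, group_b, mutation_group)
  if (!any(in_a)) stop("group '", group_a, "' is empty")
  if (!any(in_b)) stop("group '", group_b, "' is empty")
  if (any(in_a & in_b)) stop("groups overlap")
  records <- records[in_a | in_b, , drop = FALSE]
  records$group01 <- as.numeric(in_a[in_a | in_b])
  d <- cross_sectional_frame(table, records, modality, roi,
                             standardize, screen_outliers)
  d$group <- records$group01[match(d$subject_id, records$subject_id)]
  fit_lme_or_lm(y ~ group + age + sex, d, ~ 1 | site,
                paste0(modality, "_", roi, " ", group_a, " vs ", group_b))
}

# visit-level frame joining clinical scores with baseline imaging + covariates
longitudinal_frame <- function(visits, table, records, outcome,
                               predictor_col, standardize = TRUE,
                               screen_outliers = TRUE) {
  keep_subj <- records$subject_id
  v <- visits[visits$subject_id %in% keep_subj, , drop = FALSE]
  n_visits <- table(v$subject_id)
  singles <- names(n_visits)[n_visits < 2]
  if (length(singles)) {
    warning(length(singles), " subject(s) with a single visit dropped")
    v <- v[!v$subject_id %in% singles, , drop = FALSE]
  }
  if (nrow(v) == 0) stop("no subjects with >= 2 visits in the analysis set")
  m <- match(v$subject_id, records$subject_id)
  mt <- match(v$subject_id, table$subject_id)
  img <- table[[predictor_col]][mt]
  y <- v[[outcome]]
  # imaging is a baseline (per-subject) variable: screen it at subject level
  subj <- unique(v$subject_id)
  img_subj <- table[[predictor_col]][match(subj, table$subject_id)]
  img_ok_subj <- if (screen_outliers) exclude_outliers(img_subj)
                 else is.finite(img_subj)
  keep <- (if (screen_outliers) exclude_outliers(y) else is.finite(y)) &
          img_ok_subj[match(v$subject_id, subj)]
  d <- data.frame(
    subject_id = v$subject_id,
    y = y,
    imaging = img,
    time = v$time_from_baseline,
    age = records$age[m],
    sex = factor(records$sex[m], levels = c("female", "male")),
    education = records$education[m],
    site = factor(records$site_id[m]),
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  d$y <- as.numeric(zcol(d$y, std_on(standardize, "y")))
  d$imaging <- as.numeric(zcol(d$imaging, std_on(standardize, "imaging")))
  d$time <- as.numeric(zcol(d$time, std_on(standardize, "time")))
  d$age <- as.numeric(zcol(d$age))
  d$education <- as.numeric(zcol(d$education))
  d
}

#' Baseline imaging by time model of longitudinal clinical decline
#'
#' Fits the longitudinal linear mixed-effects model
#' `clinical score ~ imaging + time + imaging:time + age + sex + education
#'  + (1 | site/individual)`
#' by REML, where `imaging` is a baseline regional or global cMD/CTh value and
#' time is measured in years from baseline. With `standardize = TRUE` (the
#' default) the outcome, imaging predictor and time are z-transformed within
#' the analysis sample, as are age and education. The imaging main effect
#' (term `"imaging"`) is the cross-sectional association with the score, and
#' the interaction (term `"imaging:time"`) is the moderation of the rate of
#' clinical change by baseline imaging. Subjects with fewer than two visits
#' are dropped with a warning.
#'
#' @param visits Visit table (`subject_id`, `time_from_baseline`, outcome).
#' @param table Baseline regional table.
#' @param records Subject records defining the analysis subset (e.g. carriers
#'   of one mutation type).
#' @param outcome Column of `visits` to model (e.g. `"cbi_r"`, `"cdr_sob"`).
#' @param predictor ROI name or `"global"`.
#' @param modality `"cMD"` or `"CTh"`.
#' @inheritParams fit_interaction_model
#' @return An `lmem_fit`.
#' @export
fit_longitudinal_model <- function(visits, table, records, outcome,
                                   predictor = "global", modality = "cMD",
                                   standardize = TRUE,
                                   screen_outliers = TRUE) {
  predictor_col <- if (predictor == "global") paste0("global_", modality)
                   else paste0(modality, "_", predictor)
  d <- longitudinal_frame(visits, table, records, outcome, predictor_col,
                          standardize, screen_outliers)
  fit_lme_or_lm(y ~ imaging * time + age + sex + education, d,
                ~ 1 | site / subject_id,
                paste0(outcome, " ~ ", predictor_col))
}

#' Joint model with both global predictors
#'
#' As [fit_longitudinal_model()] but entering global cMD and global CTh (and
#' both their interactions with time) together in one model, to compare their
#' independent predictive contributions. If the two predictors are nearly
#' collinear (|r| > 0.99) a note is attached to the fit.
#'
#' @inheritParams fit_longitudinal_model
#' @return An `lmem_fit` with terms `"cmd"`, `"cth"`, `"cmd:time"`,
#'   `"cth:time"` (among others).
#' @export
fit_joint_global_model <- function(visits, table, records, outcome,
                                   standardize = TRUE,
                                   screen_outliers = TRUE) {
  d1 <- longitudinal_frame(visits, table, records, outcome, "global_cMD",
                           standardize, screen_outliers)
  cth <- table$global_CTh[match(d1$subject_id, table$subject_id)]
  d1$cmd <- d1$imaging
  d1$cth <- as.numeric(zcol(cth, std_on(standardize, "imaging")))
  r <- stats::cor(d1$cmd, d1$cth)
  fit <- fit_lme_or_lm(y ~ cmd + cth + time + cmd:time + cth:time +
                         age + sex + education,
                       d1, ~ 1 | site / subject_id,
                       paste0(outcome, " ~ global cMD + global CTh"))
  if (is.finite(r) && abs(r) > 0.99)
    fit$notes <- c(fit$notes,
                   sprintf("predictors nearly collinear (r = %.3f)", r))
  fit
}

#' Predicted clinical trajectories at discrete predictor levels
#'
#' Converts a fitted imaging-by-time interaction model into predicted
#' trajectories (with 95% confidence bands from the fixed-effect covariance)
#' at discrete baseline-imaging levels, conventionally mean and mean +/- 1 SD
#' of the standardised predictor. The slope at level `l` is
#' `beta_time + l * beta_interaction`; covariates are held at zero (their
#' sample means on the z-scale) and sex at the reference level.
#'
#' @param fit An `lmem_fit` containing `imaging`, `time` and `imaging:time`
#'   terms (names configurable).
#' @param levels Predictor levels in SD units (default -1, 0, +1).
#' @param time_grid Time points (same scale as the fitted time variable).
#' @param terms Names of the predictor, time and interaction terms.
#' @return Data frame: `level`, `time`, `predicted`, `ci_lo`, `ci_hi`,
#'   `slope` (the level's slope per unit time).
#' @export
predict_interaction_grid <- function(fit, levels = c(-1, 0, 1),
                                     time_grid = seq(0, 2, by = 0.5),
                                     terms = c(predictor = "imaging",
                                               time = "time",
                                               interaction = "imaging:time")) {
  for (t in terms)
    if (!t %in% fit$fixed$term)
      stop("fit has no '", t, "' term; is the interaction model fitted?")
  all_terms <- fit$fixed$term
  est <- stats::setNames(fit$fixed$estimate, all_terms)
  V <- fit$vcov_fixed
  idx <- match(all_terms, colnames(V))
  df_int <- fixed_effect(fit, terms[["interaction"]])$df
  tcrit <- stats::qt(0.975, df_int)

  grid <- expand.grid(level = levels, time = time_grid)
  X <- matrix(0, nrow(grid), length(all_terms),
              dimnames = list(NULL, all_terms))
  if ("(Intercept)" %in% all_terms) X[, "(Intercept)"] <- 1
  X[, terms[["predictor"]]] <- grid$level
  X[, terms[["time"]]] <- grid$time
  X[, terms[["interaction"]]] <- grid$level * grid$time
  pred <- as.numeric(X %*% est)
  se <- sqrt(rowSums((X %*% V[idx, idx]) * X))
  data.frame(level = grid$level, time = grid$time, predicted = pred,
             ci_lo = pred - tcrit * se, ci_hi = pred + tcrit * se,
             slope = est[terms[["time"]]] +
               grid$level * est[terms[["interaction"]]])
}
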