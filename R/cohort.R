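#' Specification of a simulated cross-sectional cohort
#'
#' Describes the generative model behind the regional imaging tables: for each
#' ROI and modality, the value on the standardised scale is
#' `b0 + b_status*carrier + b_age*age_z + b_int*carrier*age_z + b_sex*sex
#'  + site intercept + residual`,
#' with Gaussian site intercepts and residuals — the same linear structure the
#' cross-sectional mixed models assume. Values are then mapped to natural
#' units via a per-modality location/scale so the tables look like real cMD
#' (mm^2/s) and thickness (mm) measurements; the mapping is affine and thus
#' invisible to the downstream z-scored analysis.
#'
#' @param n_per_group Carriers per mutation group (C9orf72, GRN, MAPT).
#' @param n_noncarrier Size of the pooled non-carrier group (default
#'   `n_per_group`).
#' @param n_sites Number of acquisition sites (round-robin assignment).
#' @param beta Named list per modality (`cMD`, `CTh`), each a list with
#'   elements `intercept`, `status`, `age`, `status_age`, `sex`, each a scalar
#'   or length-68 vector (per-ROI), and optionally `stage`, a named list
#'   (`CDR0`, `CDR0.5`, `CDR1plus`) of additional carrier effects by stage.
#' @param sigma_site Site random-intercept SD (z-scale).
#' @param sigma_resid Residual SD (z-scale).
#' @param age_range Age range in years (uniform draw).
#' @param stage_probs Probabilities of carrier GENFI-CDR stage 0 / 0.5 / >=1.
#' @param loc,scale Named numeric (per modality) affine mapping from the
#'   z-scale to natural units.
#' @param seed Integer seed, or NULL to draw from the current RNG stream.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 40, n_noncarrier = n_per_group,
                        n_sites = 10,
                        beta = list(), sigma_site = 0.2, sigma_resid = 1,
                        age_range = c(20, 80),
                        stage_probs = c(CDR0 = 0.6, CDR0.5 = 0.2,
                                        CDR1plus = 0.2),
                        loc = c(cMD = 0.8e-3, CTh = 2.5),
                        scale = c(cMD = 5e-5, CTh = 0.15),
                        seed = 1L) {
  if (n_per_group < 1 || n_noncarrier < 1)
    stop("every group needs at least one subject")
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (sigma_site < 0 || sigma_resid < 0) stop("SDs must be >= 0")
  beta <- utils::modifyList(
    list(cMD = default_beta(), CTh = default_beta()),
    beta)
  for (m in c("cMD", "CTh"))
    beta[[m]] <- utils::modifyList(default_beta(), beta[[m]])
  stopifnot(all(abs(sum(stage_probs) - 1) < 1e-8))
  structure(list(n_per_group = as.integer(n_per_group),
                 n_noncarrier = as.integer(n_noncarrier),
                 n_sites = as.integer(n_sites), beta = beta,
                 sigma_site = sigma_site, sigma_resid = sigma_resid,
                 age_range = age_range, stage_probs = stage_probs,
                 loc = loc, scale = scale,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "cohort_spec")
}

default_beta <- function() {
  list(intercept = 0, status = 0, age = 0, status_age = 0, sex = 0,
       stage = NULL)
}

as_roi_vec <- function(x, n_roi) {
  if (is.null(x)) return(rep(0, n_roi))
  if (length(x) == 1) rep(as.numeric(x), n_roi)
  else if (length(x) == n_roi) as.numeric(x)
  else stop("coefficient must be scalar or length ", n_roi)
}

MUTATION_GROUPS <- c("C9orf72", "GRN", "MAPT")

#' Simulate a cross-sectional cohort with regional imaging tables
#'
#' Draws subject records (demographics, mutation group, carrier status,
#' GENFI-CDR stage, site) and a regional table of 68 cMD and 68 CTh values per
#' subject following the generative structure in [cohort_spec()]. Carrier and
#' sex assignment are balanced by construction; sites are assigned
#' round-robin. Fully deterministic given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `records` (one row per subject: `subject_id`, `site_id`,
#'   `mutation_group`, `carrier`, `symptom_status`, `genfi_cdr`, `age`, `sex`,
#'   `education`) and `table` (one row per subject: `subject_id`, 68
#'   `cMD_<roi>` columns, 68 `CTh_<roi>` columns, `global_cMD`, `global_CTh`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rois <- dk_roi_names()
  n_roi <- length(rois)

  groups <- c(rep(MUTATION_GROUPS, each = spec$n_per_group),
              rep("non-carrier", spec$n_noncarrier))
  n <- length(groups)
  carrier <- groups != "non-carrier"
  records <- data.frame(
    subject_id = sprintf("sub%04d", seq_len(n)),
    site_id = sprintf("site%02d", (seq_len(n) - 1) %% spec$n_sites + 1),
    mutation_group = groups,
    carrier = carrier,
    age = stats::runif(n, spec$age_range[1], spec$age_range[2]),
    # alternate sex across site-assignment cycles so that every site
    # receives both sexes (round-robin sites + within-pair alternation
    # would confound sex with site)
    sex = c("female", "male")[(seq_len(n) - 1) %/% spec$n_sites %% 2 + 1],
    education = pmin(pmax(stats::rnorm(n, 14.1, 3.3), 6), 22),
    stringsAsFactors = FALSE
  )
  # carrier staging by GENFI-CDR; non-carriers are rated but pooled as controls
  stage <- character(n)
  stage[carrier] <- sample(names(spec$stage_probs), sum(carrier),
                           replace = TRUE, prob = spec$stage_probs)
  cdr <- numeric(n)
  cdr[carrier] <- ifelse(stage[carrier] == "CDR0", 0,
                  ifelse(stage[carrier] == "CDR0.5", 0.5,
                         sample(c(1, 2, 3), sum(carrier), replace = TRUE)))
  cdr[!carrier] <- sample(c(0, 0.5), sum(!carrier), replace = TRUE,
                          prob = c(0.9, 0.1))
  records$genfi_cdr <- cdr
  records$symptom_status <- ifelse(!carrier, NA_character_,
                                   ifelse(cdr >= 1, "sMC", "pMC"))

  age_z <- as.numeric(scale(records$age))
  sex01 <- as.numeric(records$sex == "male")
  table <- data.frame(subject_id = records$subject_id,
                      stringsAsFactors = FALSE)
  for (mod in c("cMD", "CTh")) {
    b <- spec$beta[[mod]]
    b0 <- as_roi_vec(b$intercept, n_roi)
    bs <- as_roi_vec(b$status, n_roi)
    ba <- as_roi_vec(b$age, n_roi)
    bi <- as_roi_vec(b$status_age, n_roi)
    bx <- as_roi_vec(b$sex, n_roi)
    site_eff <- stats::rnorm(spec$n_sites, 0, spec$sigma_site)
    site_idx <- (seq_len(n) - 1) %% spec$n_sites + 1
    lp <- outer(rep(1, n), b0) +
      outer(as.numeric(carrier), bs) +
      outer(age_z, ba) +
      outer(as.numeric(carrier) * age_z, bi) +
      outer(sex01, bx)
    if (!is.null(b$stage)) {
      for (st in names(b$stage)) {
        sel <- carrier & stage == st
        if (any(sel))
          lp[sel, ] <- lp[sel, ] +
            outer(rep(1, sum(sel)), as_roi_vec(b$stage[[st]], n_roi))
      }
    }
    z <- lp + site_eff[site_idx] +
      matrix(stats::rnorm(n * n_roi, 0, spec$sigma_resid), n, n_roi)
    vals <- spec$loc[[mod]] + spec$scale[[mod]] * z
    colnames(vals) <- paste0(mod, "_", rois)
    table <- cbind(table, as.data.frame(vals))
  }
  table$global_cMD <- rowMeans(table[, paste0("cMD_", rois)])
  table$global_CTh <- rowMeans(table[, paste0("CTh_", rois)])
  list(records = records, table = table)
}

#' Specification of simulated longitudinal clinical follow-up
#'
#' Visit-level clinical scores follow the longitudinal interaction model: on
#' the standardised scale,
#' `b0 + b1*imaging_z + b2*time + b3*imaging_z*time + b4*age_z + b5*sex
#'  + b6*education_z + site intercept + subject intercept + residual`,
#' with time in years from baseline and the subject intercept nested within
#' site. Both CBI-R-like and CDR-SOB-like scores are generated with this
#' structure (independent random-effect and residual draws); the standardised
#' scores are kept alongside clamped natural-scale versions.
#'
#' @param visits_per_subject Integer range (min, max) of visits, min >= 2.
#' @param followup_years Range of total follow-up in years.
#' @param beta Named list: `intercept`, `imaging`, `time`, `imaging_time`,
#'   `age`, `sex`, `education` (scalars, z-scale; `time` per year).
#' @param sigma_site,sigma_subject,sigma_resid Random-effect and residual SDs.
#' @param predictor Column of the baseline table used as the imaging
#'   predictor (default the global cMD).
#' @param seed Integer seed, or NULL to draw from the current RNG stream.
#' @return Object of class `longitudinal_spec`.
#' @export
longitudinal_spec <- function(visits_per_subject = c(2, 5),
                              followup_years = c(1, 5),
                              beta = list(), sigma_site = 0.1,
                              sigma_subject = 0.5, sigma_resid = 0.5,
                              predictor = "global_cMD", seed = 1L) {
  if (visits_per_subject[1] < 2)
    stop("visits_per_subject must be >= 2 (baseline plus follow-up)")
  if (any(c(sigma_site, sigma_subject, sigma_resid) < 0))
    stop("SDs must be >= 0")
  beta <- utils::modifyList(
    list(intercept = 0, imaging = 0, time = 0, imaging_time = 0,
         age = 0, sex = 0, education = 0), beta)
  structure(list(visits_per_subject = as.integer(visits_per_subject),
                 followup_years = followup_years, beta = beta,
                 sigma_site = sigma_site, sigma_subject = sigma_subject,
                 sigma_resid = sigma_resid, predictor = predictor,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "longitudinal_spec")
}

#' Simulate longitudinal clinical visits from a baseline cohort
#'
#' Every subject in the baseline cohort receives a baseline visit (time 0) and
#' at least one follow-up, with visit count and total follow-up drawn from the
#' spec's ranges and visits evenly spaced. Deterministic given the spec seed.
#'
#' @param spec A [longitudinal_spec()].
#' @param baseline The list returned by [simulate_cohort()] (or any list with
#'   compatible `records` and `table`).
#' @return Data frame of visit records: `subject_id`, `visit`,
#'   `time_from_baseline` (years), standardised scores `cbi_r_z`,
#'   `cdr_sob_z`, and natural-scale `cbi_r` (0-180), `cdr_sob` (0-27).
#' @export
simulate_longitudinal <- function(spec, baseline) {
  stopifnot(inherits(spec, "longitudinal_spec"))
  records <- baseline$records
  table <- baseline$table
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- nrow(records)

  img_z <- as.numeric(scale(table[[spec$predictor]]))
  age_z <- as.numeric(scale(records$age))
  edu_z <- as.numeric(scale(records$education))
  sex01 <- as.numeric(records$sex == "male")

  visit_choices <- seq(spec$visits_per_subject[1], spec$visits_per_subject[2])
  n_visits <- visit_choices[sample.int(length(visit_choices), n,
                                       replace = TRUE)]
  total_fu <- stats::runif(n, spec$followup_years[1], spec$followup_years[2])

  sites <- unique(records$site_id)
  b <- spec$beta
  out <- vector("list", 2)
  names(out) <- c("cbi_r", "cdr_sob")
  times <- lapply(seq_len(n), function(i)
    seq(0, total_fu[i], length.out = n_visits[i]))
  for (sc in names(out)) {
    u_site <- stats::setNames(stats::rnorm(length(sites), 0, spec$sigma_site),
                              sites)
    u_subj <- stats::rnorm(n, 0, spec$sigma_subject)
    out[[sc]] <- lapply(seq_len(n), function(i) {
      t <- times[[i]]
      b$intercept + b$imaging * img_z[i] + b$time * t +
        b$imaging_time * img_z[i] * t + b$age * age_z[i] +
        b$sex * sex01[i] + b$education * edu_z[i] +
        u_site[[records$site_id[i]]] + u_subj[i] +
        stats::rnorm(length(t), 0, spec$sigma_resid)
    })
  }
  visits <- data.frame(
    subject_id = rep(records$subject_id, n_visits),
    visit = unlist(lapply(n_visits, seq_len)),
    time_from_baseline = unlist(times),
    cbi_r_z = unlist(out$cbi_r),
    cdr_sob_z = unlist(out$cdr_sob),
    stringsAsFactors = FALSE
  )
  # natural-scale versions on the instruments' ranges (clamped)
  visits$cbi_r <- pmin(pmax(30 + 25 * visits$cbi_r_z, 0), 180)
  visits$cdr_sob <- pmin(pmax(4 + 3 * visits$cdr_sob_z, 0), 27)
  visits
}
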