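#' Specify a synthetic longitudinal cohort
#'
#' A `cohort_spec` describes the data-generating model for a longitudinal
#' gray-matter-volume (GMV) cohort with planted group structure: healthy
#' controls (HC) plus one or more latent patient subtypes, each with its own
#' per-region mean annual rate of GMV change. Each subject's regional
#' trajectory is a line, `intercept + rate * time`, with subject-level
#' Gaussian deviations of intercept and slope around the group profile, a
#' per-subject global slope factor shared across regions (atrophy rates are
#' strongly correlated across the brain within a subject), fixed covariate
#' effects, and within-visit Gaussian noise. Clinical scores follow
#' independent per-group linear trajectory models.
#'
#' @param n_hc number of healthy controls.
#' @param n_patients_per_subtype integer vector, one entry per latent patient
#'   subtype.
#' @param n_roi number of regions of interest (ROIs).
#' @param roi_names optional character vector of ROI identifiers
#'   (length `n_roi`).
#' @param roi_intercepts per-ROI mean baseline volume (volume units, e.g.
#'   cm^3), length `n_roi`. Recycled if scalar.
#' @param hc_rate_profile per-ROI true mean annual GMV change for controls
#'   (volume units/year; negative = atrophy). Recycled if scalar.
#' @param subtype_rate_profiles list of per-ROI rate vectors, one per
#'   subtype, in the order of `n_patients_per_subtype`.
#' @param visit_schedule list with `max_years` (last nominal annual visit),
#'   `dropout` (per-visit probability of dropping out; dropout is absorbing,
#'   so the baseline visit is never lost), `dropout_start` (first nominal
#'   visit at which dropout can occur; the default 4 emulates a cohort that
#'   already passed a minimum-follow-up inclusion rule, every subject
#'   retaining visits 0-3), and `jitter_years` (half-width of the uniform
#'   timing jitter applied to follow-up visits).
#' @param random_effect_sd named numeric vector with `intercept` and `slope`
#'   standard deviations of the per-ROI subject deviations and their
#'   correlation `corr`.
#' @param global_slope_sd SD of the per-subject global slope factor added to
#'   every ROI's slope (volume units/year). Set to 0 for independent ROIs.
#' @param residual_sd within-visit measurement noise SD (volume units).
#' @param covariate_model list of covariate distributions and their fixed
#'   effects on GMV; see [ppmi_like_spec()] for the default shape.
#' @param clinical_score_model data frame with one row per score and group
#'   (columns `score_name`, `group`, `intercept`, `slope`, `intercept_sd`,
#'   `slope_sd`, `residual_sd`), or `NULL` for no clinical table.
#' @param seed integer seed owned by the spec; generation is a pure function
#'   of the spec.
#'
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()], [ppmi_like_spec()]
#' @export
cohort_spec <- function(n_hc,
                        n_patients_per_subtype,
                        n_roi = 254,
                        roi_names = NULL,
                        roi_intercepts = 5,
                        hc_rate_profile = 0,
                        subtype_rate_profiles = list(),
                        visit_schedule = list(max_years = 5, dropout = 0.35,
                                              dropout_start = 4,
                                              jitter_years = 0.1),
                        random_effect_sd = c(intercept = 0.3, slope = 0.004,
                                             corr = -0.2),
                        global_slope_sd = 0.004,
                        residual_sd = 0.05,
                        covariate_model = default_covariate_model(),
                        clinical_score_model = NULL,
                        seed = 1L) {
  n_hc <- as.integer(n_hc)
  n_pat <- as.integer(n_patients_per_subtype)
  if (n_hc < 0 || any(n_pat < 0)) stop_ac("subject counts must be nonnegative")
  n_roi <- as.integer(n_roi)
  if (n_roi < 1) stop_ac("n_roi must be positive")

  expand_profile <- function(x, what) {
    if (length(x) == 1) x <- rep(x, n_roi)
    if (length(x) != n_roi) {
      stop_ac(sprintf("%s has length %d but n_roi = %d", what, length(x), n_roi))
    }
    as.numeric(x)
  }
  roi_intercepts <- expand_profile(roi_intercepts, "roi_intercepts")
  hc_rate_profile <- expand_profile(hc_rate_profile, "hc_rate_profile")
  if (length(subtype_rate_profiles) != length(n_pat)) {
    stop_ac("need one rate profile per patient subtype")
  }
  subtype_rate_profiles <- lapply(seq_along(subtype_rate_profiles), function(i) {
    expand_profile(subtype_rate_profiles[[i]],
                   sprintf("subtype_rate_profiles[[%d]]", i))
  })

  if (is.null(roi_names)) {
    roi_names <- sprintf("roi_%03d", seq_len(n_roi))
  }
  stopifnot(length(roi_names) == n_roi, !anyDuplicated(roi_names))

  re <- random_effect_sd
  if (is.null(names(re))) names(re) <- c("intercept", "slope", "corr")
  if (re[["intercept"]] < 0 || re[["slope"]] < 0) {
    stop_ac("random-effect SDs must be nonnegative")
  }
  if (abs(re[["corr"]]) > 1) stop_ac("intercept-slope correlation must lie in [-1, 1]")
  if (global_slope_sd < 0 || residual_sd < 0) stop_ac("SDs must be nonnegative")
  check_prob(visit_schedule$dropout, "visit_schedule$dropout")
  stopifnot(visit_schedule$max_years >= 1)

  structure(
    list(n_hc = n_hc,
         n_patients_per_subtype = n_pat,
         n_roi = n_roi,
         roi_names = roi_names,
         roi_intercepts = roi_intercepts,
         hc_rate_profile = hc_rate_profile,
         subtype_rate_profiles = subtype_rate_profiles,
         visit_schedule = visit_schedule,
         random_effect_sd = re,
         global_slope_sd = global_slope_sd,
         residual_sd = residual_sd,
         covariate_model = covariate_model,
         clinical_score_model = clinical_score_model,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Default covariate distributions and GMV fixed effects
#'
#' Covariates are generated per subject: age ~ Normal(60, 10) years, sex
#' Bernoulli(0.65 male), a two-level race factor, years of education ~
#' Normal(15.5, 3), site uniform over `n_sites` scanning sites, total
#' intracranial volume (TIV) ~ Normal(1450, 120) cm^3. Effects on GMV are
#' applied to centered covariates so ROI intercepts keep their meaning for a
#' reference subject.
#'
#' @param n_sites number of scanning sites.
#' @return a list consumed by [cohort_spec()].
#' @export
default_covariate_model <- function(n_sites = 10) {
  list(age_mean = 60, age_sd = 10,
       p_male = 0.65,
       p_race_b = 0.1,
       educ_mean = 15.5, educ_sd = 3,
       n_sites = n_sites,
       tiv_mean = 1450, tiv_sd = 120,
       beta = c(age = -0.003, sexM = 0.15, raceB = 0.05,
                education_years = 0.005, tiv = 3e-4),
       site_effect_sd = 0.03)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("cohort_spec:", x$n_hc, "HC +",
      paste(x$n_patients_per_subtype, collapse = "/"),
      "patients,", x$n_roi, "ROIs, visits 0..",
      x$visit_schedule$max_years, "y, seed", x$seed, "\n")
  invisible(x)
}

# Clinical trajectory models for the default cohort: per-group intercepts
# (baseline characteristics table) and annual slopes (longitudinal change
# table) of the score battery, with per-score noise calibrated so that a
# per-group slope standard error at n = 63 over a full annual schedule
# matches the reported one (se63). slope_sd = se63*sqrt(63/2) splits half of
# the slope information into between-subject slope variance, the rest into
# residual noise via Sxx = 17.5 (visits 0..5).
default_clinical_models <- function() {
  rows <- list(
    #             int_hc sd_hc  int1   int2   sd1    slope_hc slope1 slope2 se63
    updrs1     = c(2.89, 3.06, 4.03, 5.567, 2.90, 0.05, 0.63, 1.26, 0.10),
    updrs2     = c(0.43, 1.00, 4.56, 5.98, 2.96, 0.02, 0.71, 1.34, 0.11),
    updrs3     = c(1.18, 2.25, 18.95, 23.05, 9.07, 0.05, 1.92, 1.84, 0.32),
    updrs_total = c(4.44, 4.53, 27.54, 34.59, 11.78, 0.10, 3.20, 4.10, 0.45),
    rbdsq      = c(2.87, 2.24, 3.57, 4.86, 2.12, 0.00, 0.19, 0.25, 0.06),
    gds        = c(1.24, 2.10, 2.06, 1.98, 2.29, 0.00, -0.01, 0.26, 0.06),
    scopa_aut  = c(5.77, 3.80, 7.71, 10.28, 5.00, 0.05, 0.56, 1.15, 0.13),
    ess        = c(5.50, 3.47, 5.62, 6.66, 3.11, 0.05, 0.39, 0.62, 0.15),
    quip       = c(0.26, 0.72, 0.25, 0.25, 0.59, 0.00, 0.02, 0.05, 0.02),
    stai       = c(56.70, 13.63, 62.48, 65.98, 16.16, 0.00, -0.29, 0.68, 0.31),
    moca       = c(28.26, 1.10, 27.98, 27.11, 1.87, 0.00, 0.04, -0.20, 0.05),
    sem_fluency = c(51.68, 11.18, 51.56, 46.16, 10.97, 0.10, 0.39, -0.02, 0.22),
    hvlt_ir    = c(26.10, 4.62, 26.92, 23.95, 4.71, 0.00, 0.03, -0.32, 0.10),
    hvlt_disc  = c(10.06, 2.89, 10.42, 8.59, 2.15, 0.00, 0.20, 0.27, 0.06),
    hvlt_ret   = c(0.90, 0.19, 0.88, 0.83, 0.18, 0.000, 0.008, -0.023, 0.004))
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    v <- rows[[nm]]
    se63 <- v[9]
    slope_sd <- se63 * sqrt(63 / 2)
    resid_sd <- se63 * sqrt(63 * 17.5 / 2)
    data.frame(
      score_name = nm,
      group = c("HC", "subtype_1", "subtype_2"),
      intercept = c(v[1], v[3], v[4]),
      slope = c(v[6], v[7], v[8]),
      intercept_sd = c(v[2], v[5], v[5]),
      slope_sd = slope_sd,
      residual_sd = resid_sd,
      stringsAsFactors = FALSE)
  }))
  tibble::as_tibble(out)
}

# ROI naming: 200 cortical parcels tagged by lobe plus 54 subcortical
# structures, mirroring a 200 + 54 atlas parcellation. Tags drive the
# default subtype rate profiles (lateral temporal excess etc.).
default_roi_table <- function() {
  cort <- c(prefrontal = 34, orbitofrontal = 14, motor = 22, parietal = 32,
            occipital = 26, lateral_temporal = 30, medial_temporal = 16,
            cingulate = 16, insula = 10)
  stopifnot(sum(cort) == 200)
  sub <- c(hippocampus = 8, amygdala = 6, thalamus = 10, caudate = 6,
           putamen = 6, pallidum = 6, accumbens = 4, brainstem = 8)
  stopifnot(sum(sub) == 54)
  lobe <- c(rep(names(cort), cort), rep(names(sub), sub))
  tibble::tibble(
    roi_id = sprintf("%s_%02d", lobe,
                     unlist(lapply(c(cort, sub), seq_len), use.names = FALSE)),
    lobe = lobe,
    cortical = rep(c(TRUE, FALSE), c(200, 54)))
}

#' Default cohort specification mirroring a PPMI-like study
#'
#' Returns a [cohort_spec()] shaped like the study population this pipeline
#' targets: 161 healthy controls and 107 patients split into two latent
#' subtypes of 63 and 44, with 254 ROIs (200 cortical + 54 subcortical),
#' baseline plus annual visits to year 5 with timing jitter and absorbing
#' dropout (mean follow-up about 4 years). Subtype 1 shows moderate atrophy
#' concentrated in prefrontal and lateral temporal regions; subtype 2 is
#' globally faster with the strongest excess in the lateral temporal lobe
#' and pronounced medial temporal, hippocampal, and thalamic loss. Clinical
#' scores follow per-group linear trajectories whose intercepts and slopes
#' are set to the reference study's baseline characteristics and annual
#' rates of change.
#'
#' @param seed integer seed stored in the spec.
#' @return a `cohort_spec`.
#' @examples
#' spec <- ppmi_like_spec()
#' spec$n_roi                        # 254
#' sum(spec$n_patients_per_subtype)  # 107
#' @export
ppmi_like_spec <- function(seed = 1L) {
  roi <- default_roi_table()
  n_roi <- nrow(roi)

  # Baseline regional volumes (cm^3): a fixed smooth spread over parcels;
  # magnitudes are order-of-magnitude realistic, not atlas-calibrated.
  roi_int <- 3 + 6 * (1 + sin(seq_len(n_roi) / 7)) / 2

  hc_rate <- rep(-0.003, n_roi)

  s1 <- rep(-0.008, n_roi)
  s1[roi$lobe %in% c("prefrontal", "lateral_temporal")] <- -0.020

  # subtype 2: globally faster than subtype 1, strongest excess laterally
  # temporal, plus marked medial temporal / hippocampus / thalamus loss
  s2 <- s1 - 0.025
  s2[roi$lobe == "lateral_temporal"] <- s2[roi$lobe == "lateral_temporal"] - 0.020
  s2[roi$lobe %in% c("medial_temporal", "hippocampus", "thalamus")] <-
    s2[roi$lobe %in% c("medial_temporal", "hippocampus", "thalamus")] - 0.010

  cohort_spec(
    n_hc = 161,
    n_patients_per_subtype = c(63, 44),
    n_roi = n_roi,
    roi_names = roi$roi_id,
    roi_intercepts = roi_int,
    hc_rate_profile = hc_rate,
    subtype_rate_profiles = list(s1, s2),
    visit_schedule = list(max_years = 5, dropout = 0.35, dropout_start = 4,
                          jitter_years = 0.1),
    random_effect_sd = c(intercept = 0.3, slope = 0.004, corr = -0.2),
    global_slope_sd = 0.004,
    residual_sd = 0.05,
    covariate_model = default_covariate_model(),
    clinical_score_model = default_clinical_models(),
    seed = seed)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a long-format GMV table and a clinical score table from the
#' generating model described by a [cohort_spec()]. The GMV value for
#' subject i, ROI j at time t is
#' `intercept_j + b0_ij + covariate effects + (rate_gj + b1_ij + g_i) * t + noise`
#' where `(b0_ij, b1_ij)` are correlated Gaussian subject-by-ROI deviations,
#' `g_i` is the subject's global slope factor, and `rate_gj` is the group or
#' subtype mean rate for ROI j. Identical specs (including seed) give
#' identical tables. The global random-number state is preserved.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `gmv` (tibble: `subject_id`, `group`,
#'   `true_subtype`, `visit_time`, `age_baseline`, `sex`, `race`,
#'   `education_years`, `site`, `tiv`, `roi_id`, `gmv`) and `clinical`
#'   (tibble: `subject_id`, `visit_time`, `score_name`, `value`; `NULL` when
#'   the spec has no clinical model). `true_subtype` is the planted label;
#'   analysis functions never consume it.
#' @examples
#' spec <- cohort_spec(n_hc = 2, n_patients_per_subtype = c(3, 3), n_roi = 4,
#'                     subtype_rate_profiles = list(rep(-0.02, 4), rep(-0.06, 4)))
#' cohort <- generate_cohort(spec)
#' head(cohort$gmv)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  n_sub <- length(spec$n_patients_per_subtype)
  n_pat <- sum(spec$n_patients_per_subtype)
  n <- spec$n_hc + n_pat
  subject_id <- sprintf("S%04d", seq_len(n))
  group <- rep(c("HC", "PD"), c(spec$n_hc, n_pat))
  true_subtype <- c(rep(NA_integer_, spec$n_hc),
                    rep(seq_len(n_sub), spec$n_patients_per_subtype))

  cm <- spec$covariate_model
  age <- rnorm(n, cm$age_mean, cm$age_sd)
  sex <- ifelse(rbinom(n, 1, cm$p_male) == 1, "M", "F")
  race <- ifelse(rbinom(n, 1, cm$p_race_b) == 1, "B", "A")
  educ <- round(pmax(8, rnorm(n, cm$educ_mean, cm$educ_sd)))
  site <- sprintf("site_%02d", sample.int(cm$n_sites, n, replace = TRUE))
  tiv <- rnorm(n, cm$tiv_mean, cm$tiv_sd)
  site_eff <- setNames(rnorm(cm$n_sites, 0, cm$site_effect_sd),
                       sprintf("site_%02d", seq_len(cm$n_sites)))
  b <- cm$beta
  cov_eff <- b[["age"]] * (age - cm$age_mean) +
    b[["sexM"]] * (sex == "M") +
    b[["raceB"]] * (race == "B") +
    b[["education_years"]] * (educ - cm$educ_mean) +
    b[["tiv"]] * (tiv - cm$tiv_mean) +
    site_eff[site]

  # visit times: baseline exact, annual follow-ups with jitter; dropout is
  # absorbing so the first missed visit truncates the subject's schedule
  vs <- spec$visit_schedule
  ds <- vs$dropout_start %||% 1
  nominal <- 0:vs$max_years
  # per-visit dropout hazard: zero before dropout_start, constant after
  hazard <- ifelse(seq_len(vs$max_years) >= ds, vs$dropout, 0)
  keep_until <- if (vs$dropout > 0) {
    drop_at <- matrix(rbinom(n * vs$max_years, 1,
                             rep(hazard, each = n)) == 1, nrow = n)
    apply(drop_at, 1, function(d) if (any(d)) which(d)[1] else vs$max_years + 1L)
  } else rep(vs$max_years + 1L, n)
  visit_list <- lapply(seq_len(n), function(i) {
    v <- nominal[seq_len(keep_until[i])]
    tt <- v + c(0, runif(length(v) - 1, -vs$jitter_years, vs$jitter_years))
    tt
  })
  n_vis <- lengths(visit_list)

  # subject x ROI random effects: correlated (intercept, slope) pairs plus a
  # per-subject global slope factor shared across ROIs
  re <- spec$random_effect_sd
  b0 <- matrix(rnorm(n * spec$n_roi, 0, re[["intercept"]]), n, spec$n_roi)
  z <- matrix(rnorm(n * spec$n_roi), n, spec$n_roi)
  z0 <- if (re[["intercept"]] > 0) b0 / re[["intercept"]] else
    matrix(rnorm(n * spec$n_roi), n, spec$n_roi)
  b1 <- re[["slope"]] * (re[["corr"]] * z0 + sqrt(1 - re[["corr"]]^2) * z)
  g <- rnorm(n, 0, spec$global_slope_sd)

  rate_mat <- matrix(0, n, spec$n_roi)
  if (spec$n_hc > 0) rate_mat[group == "HC", ] <-
      matrix(spec$hc_rate_profile, spec$n_hc, spec$n_roi, byrow = TRUE)
  for (s in seq_len(n_sub)) {
    idx <- which(!is.na(true_subtype) & true_subtype == s)
    rate_mat[idx, ] <- matrix(spec$subtype_rate_profiles[[s]],
                              length(idx), spec$n_roi, byrow = TRUE)
  }

  si <- rep(seq_len(n), n_vis)            # subject index per subject-visit row
  tv <- unlist(visit_list, use.names = FALSE)
  nsv <- length(tv)

  # gmv matrix: subject-visit rows x ROI columns
  inter <- matrix(spec$roi_intercepts, nsv, spec$n_roi, byrow = TRUE) +
    b0[si, , drop = FALSE] + cov_eff[si]
  slope <- rate_mat[si, , drop = FALSE] + b1[si, , drop = FALSE] + g[si]
  gmat <- inter + slope * tv
  if (spec$residual_sd > 0) {
    gmat <- gmat + rnorm(nsv * spec$n_roi, 0, spec$residual_sd)
  }

  gmv <- tibble::tibble(
    subject_id = rep(subject_id[si], each = spec$n_roi),
    group = rep(group[si], each = spec$n_roi),
    true_subtype = rep(true_subtype[si], each = spec$n_roi),
    visit_time = rep(tv, each = spec$n_roi),
    age_baseline = rep(age[si], each = spec$n_roi),
    sex = rep(sex[si], each = spec$n_roi),
    race = rep(race[si], each = spec$n_roi),
    education_years = rep(educ[si], each = spec$n_roi),
    site = rep(site[si], each = spec$n_roi),
    tiv = rep(tiv[si], each = spec$n_roi),
    roi_id = rep(spec$roi_names, nsv),
    gmv = as.vector(t(gmat)))

  clinical <- NULL
  if (!is.null(spec$clinical_score_model)) {
    csm <- spec$clinical_score_model
    grp_label <- ifelse(group == "HC", "HC",
                        sprintf("subtype_%d", true_subtype))
    scores <- unique(csm$score_name)
    cl <- vector("list", length(scores))
    for (k in seq_along(scores)) {
      sub_csm <- csm[csm$score_name == scores[k], ]
      m <- match(grp_label, sub_csm$group)
      if (anyNA(m)) stop_ac(sprintf(
        "clinical_score_model for '%s' lacks groups: %s", scores[k],
        paste(unique(grp_label[is.na(m)]), collapse = ", ")))
      ic <- sub_csm$intercept[m] + rnorm(n, 0, sub_csm$intercept_sd[m])
      sl <- sub_csm$slope[m] + rnorm(n, 0, sub_csm$slope_sd[m])
      val <- ic[si] + sl[si] * tv +
        rnorm(nsv, 0, sub_csm$residual_sd[m][si])
      cl[[k]] <- tibble::tibble(
        subject_id = subject_id[si],
        visit_time = tv,
        score_name = scores[k],
        value = val)
    }
    clinical <- dplyr::bind_rows(cl)
  }

  list(gmv = gmv, clinical = clinical)
}
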