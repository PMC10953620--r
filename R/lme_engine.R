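#' Specify a longitudinal mixed-effects model
#'
#' The three model families used throughout the pipeline share one random
#' structure — a random intercept and random follow-up-time slope per
#' subject — and differ only in the outcome and fixed terms:
#' GMV models adjust for age, sex, race, education, site and total
#' intracranial volume plus follow-up time; group-comparison models add a
#' group-by-time interaction; clinical-score models drop TIV.
#'
#' @param outcome name of the outcome column.
#' @param covariates character vector of fixed-effect covariate columns.
#' @param group_by_time if `TRUE`, fixed effects include
#'   `group + time:group` (differential progression model).
#' @param group name of the grouping column (used when `group_by_time`).
#' @param time,subject names of the follow-up-time (years) and subject-id
#'   columns. The random structure is always `(1 + time | subject)`.
#' @param reml fit by REML (default) or ML.
#' @return an object of class `lme_model_spec`.
#' @seealso [fit_lme()]
#' @export
lme_model_spec <- function(outcome,
                           covariates = c("age_baseline", "sex", "race",
                                          "education_years", "site", "tiv"),
                           group_by_time = FALSE,
                           group = "group",
                           time = "visit_time",
                           subject = "subject_id",
                           reml = TRUE) {
  stopifnot(is.character(outcome), length(outcome) == 1)
  structure(list(outcome = outcome, covariates = covariates,
                 group_by_time = isTRUE(group_by_time), group = group,
                 time = time, subject = subject, reml = isTRUE(reml)),
            class = "lme_model_spec")
}

fixed_rhs <- function(spec) {
  terms <- c(spec$covariates, spec$time)
  if (spec$group_by_time) {
    terms <- c(terms, spec$group, paste0(spec$time, ":", spec$group))
  }
  paste(c("1", terms), collapse = " + ")
}

# Classify fixed-design columns for the between-within degrees-of-freedom
# split: "between" columns are constant within subject, "slope" columns are
# time multiplied by a between-subject column (including time itself), and
# everything else is "within". Slope-level contrasts carry subject-level
# information only, so their Wald t gets n_subjects - (#slope columns) df;
# residual df would overstate the information and makes slope tests
# anticonservative.
classify_columns <- function(mm, subject, time_vals) {
  n_sub <- length(unique(subject))
  apply_const <- function(v) {
    r <- tapply(v, subject, function(x) max(x) - min(x))
    all(r < 1e-10)
  }
  vapply(seq_len(ncol(mm)), function(j) {
    v <- mm[, j]
    if (apply_const(v)) return("between")
    ok <- abs(time_vals) > 1e-12
    if (all(abs(v[!ok]) < 1e-10)) {
      ratio <- v[ok] / time_vals[ok]
      full <- rep(NA_real_, length(v))
      full[ok] <- ratio
      r <- tapply(full, subject, function(x) {
        x <- x[!is.na(x)]
        if (!length(x)) 0 else max(x) - min(x)
      })
      if (all(r < 1e-8)) return("slope")
    }
    "within"
  }, character(1))
}

wald_df <- function(mm, subject, time_vals, n_obs, rank) {
  cls <- classify_columns(mm, subject, time_vals)
  n_sub <- length(unique(subject))
  df <- numeric(length(cls))
  df[cls == "between"] <- max(1, n_sub - sum(cls == "between"))
  df[cls == "slope"] <- max(1, n_sub - sum(cls == "slope"))
  df[cls == "within"] <- max(1, n_obs - rank)
  df
}

wald_table <- function(term, beta, se, df) {
  t <- beta / se
  p <- 2 * pt(-abs(t), df)
  crit <- qt(0.975, df)
  tibble::tibble(term = term, estimate = beta, se = se, df = df,
                 t = t, p = p,
                 ci_lo = beta - crit * se, ci_hi = beta + crit * se)
}

#' Fit a random-intercept, random-slope mixed model
#'
#' Fits the Gaussian linear mixed model defined by an [lme_model_spec()] by
#' (restricted) maximum likelihood, with `(1 + time | subject)` random
#' structure. Fixed-effect inference uses Wald t statistics with a
#' between-within degrees-of-freedom split (see Details). Rows with missing
#' values in any modelled column are dropped listwise.
#'
#' @details Degrees of freedom: coefficients of subject-level covariates use
#' `n_subjects - (number of subject-level coefficients)`; coefficients on
#' follow-up time and its interactions with subject-level factors use
#' `n_subjects - (number of such slope coefficients)`; any purely
#' within-subject term uses residual df. A rank-deficient fixed design is an
#' error naming the aliased columns. When the optimizer fails even after
#' restarts from perturbed starting values, the fit is returned with
#' `converged = FALSE` rather than silently wrong numbers; variance
#' components may legitimately sit on the boundary (`boundary = TRUE`), in
#' which case subject slope predictions shrink to the fixed slope.
#'
#' @param data long-format data frame with one row per subject-visit.
#' @param spec an [lme_model_spec()].
#' @return object of class `lme_fit`: list with `fixed_effects` (tibble of
#'   term, estimate, se, df, t, p, 95% CI), `vcov_random` (2x2 covariance of
#'   intercept and slope deviations), `residual_variance`, `subject_effects`
#'   (tibble of subject_id, intercept_dev, slope_dev), `loglik`, `reml`,
#'   `converged`, `boundary`, `n_obs`, `n_subjects`, the fitted `model`
#'   (merMod) and the `spec`.
#' @examples
#' spec <- cohort_spec(n_hc = 0, n_patients_per_subtype = 20, n_roi = 1,
#'                     subtype_rate_profiles = list(-0.05),
#'                     random_effect_sd = c(intercept = .3, slope = .02, corr = 0))
#' d <- generate_cohort(spec)$gmv
#' fit <- fit_lme(d, lme_model_spec("gmv"))
#' fit$fixed_effects[fit$fixed_effects$term == "visit_time", ]
#' @export
fit_lme <- function(data, spec) {
  stopifnot(inherits(spec, "lme_model_spec"))
  need <- unique(c(spec$outcome, spec$covariates, spec$time, spec$subject,
                   if (spec$group_by_time) spec$group))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_ac("missing columns: ", paste(miss, collapse = ", "))
  d <- as.data.frame(data)[, need, drop = FALSE]
  cc <- complete.cases(d)
  if (!all(cc)) {
    message(sum(!cc), " rows with missing values dropped")
    d <- d[cc, , drop = FALSE]
  }
  for (v in need) if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
  d[[spec$subject]] <- factor(d[[spec$subject]])

  subj <- d[[spec$subject]]
  if (nlevels(subj) < 2) stop_ac("need at least 2 subjects")
  visits_per <- table(subj)
  if (max(visits_per) < 2) {
    stop_ac("all subjects have a single visit; the time slope is not identifiable")
  }

  fform <- stats::as.formula(paste(spec$outcome, "~", fixed_rhs(spec)))
  mm <- model.matrix(fform, d)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop_ac("rank-deficient fixed-effect design; aliased columns: ",
            paste(aliased, collapse = ", "))
  }

  full <- stats::as.formula(paste(
    spec$outcome, "~", fixed_rhs(spec),
    sprintf("+ (1 + %s | %s)", spec$time, spec$subject)))

  fit_once <- function(start = NULL) {
    warned <- FALSE
    m <- withCallingHandlers(
      suppressMessages(lme4::lmer(full, data = d, REML = spec$reml,
                                  start = start)),
      warning = function(w) {
        msg <- conditionMessage(w)
        if (grepl("unidentifiable|rescale", msg, ignore.case = TRUE)) {
          # scaling advisories, common on near-degenerate noise-free data;
          # not an optimizer failure
          invokeRestart("muffleWarning")
        } else if (grepl("converge|gradient|Hessian", msg,
                         ignore.case = TRUE)) {
          warned <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    list(model = m, converged = !warned)
  }
  res <- fit_once()
  if (!res$converged) {
    th <- lme4::getME(res$model, "theta")
    for (i in 1:3) {
      pert <- list(theta = pmax(th * (1 + 0.3 * i) + 0.05 * i, 1e-3))
      res2 <- try(fit_once(start = pert), silent = TRUE)
      if (!inherits(res2, "try-error") && res2$converged) {
        res <- res2
        break
      }
    }
  }
  m <- res$model

  beta <- lme4::fixef(m)
  se <- sqrt(diag(as.matrix(vcov(m))))
  df <- wald_df(mm, subj, d[[spec$time]], nrow(d), qr_mm$rank)
  fe <- wald_table(names(beta), unname(beta), unname(se), df)

  vc <- lme4::VarCorr(m)[[spec$subject]]
  vcr <- matrix(as.numeric(vc), 2, 2,
                dimnames = list(c("intercept", "slope"),
                                c("intercept", "slope")))
  re <- lme4::ranef(m)[[spec$subject]]
  subject_effects <- tibble::tibble(
    subject_id = rownames(re),
    intercept_dev = re[[1]],
    slope_dev = re[[2]])

  interaction_term <- NULL
  if (spec$group_by_time) {
    cand <- grep(paste0("^", spec$time, ":", spec$group, "|^",
                        spec$group, ".*:", spec$time),
                 fe$term, value = TRUE)
    interaction_term <- cand
  }

  structure(list(
    fixed_effects = fe,
    vcov_random = vcr,
    residual_variance = stats::sigma(m)^2,
    subject_effects = subject_effects,
    loglik = as.numeric(stats::logLik(m)),
    reml = spec$reml,
    converged = res$converged,
    boundary = lme4::isSingular(m),
    n_obs = nrow(d),
    n_subjects = nlevels(subj),
    interaction_term = interaction_term,
    model = m,
    spec = spec), class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("lme_fit: %s, %d obs / %d subjects, %s logLik = %.2f%s%s\n",
              x$spec$outcome, x$n_obs, x$n_subjects,
              if (x$reml) "REML" else "ML", x$loglik,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$boundary) " [boundary]" else ""))
  print(as.data.frame(x$fixed_effects), digits = 4)
  invisible(x)
}

#' Per-subject GMV-loss rates from a fitted model
#'
#' Each subject's atrophy rate is the fixed follow-up-time coefficient plus
#' the best linear unbiased prediction (BLUP) of the subject's slope
#' deviation — the conditional mean of that subject's slope. When the
#' random-slope variance is estimated at the boundary (zero), every subject
#' receives the fixed slope.
#'
#' @param fit an [fit_lme()] result with `converged = TRUE`.
#' @return named numeric vector, one rate per subject (volume units/year).
#' @export
subject_slopes <- function(fit) {
  stopifnot(inherits(fit, "lme_fit"))
  if (!fit$converged) stop_ac("model did not converge; rates unavailable")
  slope <- fit$fixed_effects$estimate[fit$fixed_effects$term == fit$spec$time]
  setNames(slope + fit$subject_effects$slope_dev,
           fit$subject_effects$subject_id)
}

#' Wald test of the group-by-time interaction
#'
#' Extracts the differential-progression contrast — the difference in
#' outcome slopes between groups — from a model fit with `group_by_time`.
#'
#' @param fit an [fit_lme()] result from a spec with `group_by_time = TRUE`.
#' @param level confidence level for the interval.
#' @return list with `term`, `beta`, `se`, `df`, `t`, `p`, `ci` (length-2).
#' @export
interaction_test <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "lme_fit"))
  if (is.null(fit$interaction_term) || !length(fit$interaction_term)) {
    stop_ac("model was not fit with a group-by-time interaction term")
  }
  term <- fit$interaction_term[1]
  row <- fit$fixed_effects[fit$fixed_effects$term == term, ]
  if (!nrow(row)) stop_ac("interaction term absent from fixed effects: ", term)
  crit <- qt(1 - (1 - level) / 2, row$df)
  list(term = term, beta = row$estimate, se = row$se, df = row$df,
       t = row$t, p = row$p,
       ci = c(row$estimate - crit * row$se, row$estimate + crit * row$se))
}
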