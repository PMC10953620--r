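#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1). Thin validating
#' wrapper over [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values, same length.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.na(p) & (p < 0 | p > 1))) {
    stop_ac("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Cohen's d effect size
#'
#' `(mean(b) - mean(a)) / pooled SD`, pooled with n-1 weights. The sign
#' convention is b minus a (e.g. subtype 2 minus subtype 1).
#'
#' @param values_a,values_b numeric vectors with at least 2 values each.
#' @return the effect size.
#' @export
cohens_d <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) stop_ac("need at least 2 values per group")
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop_ac("zero pooled SD; effect size undefined")
  (mean(b) - mean(a)) / sqrt(sp2)
}

# subject -> subtype labels as a named character vector "subtype_<i>"
normalize_labels <- function(labels) {
  if (inherits(labels, "cluster_solution")) labels <- labels$labels
  if (is.null(names(labels))) stop_ac("labels must be named by subject id")
  setNames(ifelse(grepl("^subtype_", as.character(labels)),
                  as.character(labels),
                  sprintf("subtype_%s", labels)), names(labels))
}

# attach a group column (HC or subtype_<i>) to a long table
attach_group <- function(tab, labels) {
  lab <- normalize_labels(labels)
  grp <- unname(lab[tab$subject_id])
  if ("group" %in% names(tab)) {
    grp[is.na(grp) & tab$group == "HC"] <- "HC"
  }
  tab$cmp_group <- grp
  tab[!is.na(tab$cmp_group), , drop = FALSE]
}

#' Per-ROI group-by-time GMV contrasts
#'
#' For each group pair and each ROI, fits the group-comparison GMV model
#' (covariates + TIV + time x group with `(1 + time | subject)` random
#' structure) on the two groups' data and reports the interaction contrast
#' (difference in annual GMV-loss rates, second group minus first).
#' Benjamini-Hochberg FDR is applied per pair across ROIs.
#'
#' @param gmv long GMV table covering HC and patients.
#' @param labels patient subtype labels ([ward_cluster()] solution or named
#'   vector). HC rows keep the `"HC"` group.
#' @param pairs list of length-2 character vectors naming ordered group
#'   pairs; default compares HC against each subtype and subtype 1 vs 2.
#' @param covariates fixed-effect covariates (TIV included: GMV outcome).
#' @param fdr_threshold significance threshold on q.
#' @return object of class `contrast_table`: tibble with one row per
#'   pair x ROI (`target`, `contrast`, `beta`, `se`, `df`, `t`, `p`, `q`,
#'   `significant`), plus skipped-pair records in `attr(, "skipped")`.
#' @export
gmv_group_contrasts <- function(gmv, labels,
                                pairs = NULL,
                                covariates = c("age_baseline", "sex", "race",
                                               "education_years", "site", "tiv"),
                                fdr_threshold = 0.05) {
  tab <- attach_group(gmv, labels)
  groups <- sort(unique(tab$cmp_group))
  subtypes <- setdiff(groups, "HC")
  if (is.null(pairs)) {
    pairs <- c(lapply(subtypes, function(s) c("HC", s)),
               if (length(subtypes) >= 2)
                 utils::combn(subtypes, 2, simplify = FALSE))
  }

  out <- list()
  skipped <- character()
  for (pr in pairs) {
    sub <- tab[tab$cmp_group %in% pr, , drop = FALSE]
    sub$cmp_group <- factor(sub$cmp_group, levels = pr)
    if (length(unique(sub$subject_id[sub$cmp_group == pr[1]])) < 2 ||
        length(unique(sub$subject_id[sub$cmp_group == pr[2]])) < 2) {
      skipped <- c(skipped, paste(pr, collapse = " vs "))
      warning("pair skipped (fewer than 2 subjects per group): ",
              paste(pr, collapse = " vs "))
      next
    }
    design_cols <- unique(c("subject_id", "visit_time", "cmp_group", covariates))
    wide <- pivot_gmv_wide(sub, design_cols)
    covs <- covariates[vapply(covariates, function(v)
      length(unique(wide$frame[[v]])) > 1, logical(1))]
    rhs <- paste(c("1", covs, "visit_time * cmp_group"), collapse = " + ")
    bf <- lme_batch(wide$frame, wide$Y, rhs, want_blups = FALSE)
    iterm <- grep("^visit_time:cmp_group", bf$terms, value = TRUE)[1]
    beta <- bf$beta[iterm, ]
    se <- bf$se[iterm, ]
    dfree <- bf$df[match(iterm, bf$terms)]
    wt <- wald_table(names(beta), unname(beta), unname(se), dfree)
    q <- fdr_adjust(wt$p)
    out[[length(out) + 1L]] <- tibble::tibble(
      target = wide$rois,
      contrast = paste(pr[2], "vs", pr[1]),
      beta = wt$estimate, se = wt$se, df = wt$df, t = wt$t, p = wt$p,
      q = q, significant = q < fdr_threshold)
  }
  if (!length(out)) stop_ac("no group pair could be contrasted")
  res <- dplyr::bind_rows(out)
  attr(res, "skipped") <- skipped
  class(res) <- c("contrast_table", class(res))
  res
}

#' Clinical progression contrasts between subtypes
#'
#' For each clinical score, fits the clinical progression model (score on
#' age, sex, race, education, site, time x group with subject random
#' intercept and slope; no TIV for non-GMV outcomes) on the two subtypes'
#' data and reports each subtype's annual slope with its SE plus the
#' group-by-time interaction p, FDR-corrected across the score battery.
#'
#' @param clinical long clinical table (`subject_id`, `visit_time`,
#'   `score_name`, `value`).
#' @param labels patient subtype labels.
#' @param covariates per-subject covariate table (one row per subject with
#'   `subject_id` plus the adjustment columns), e.g. from
#'   [baseline_covariates()].
#' @param scores score names to model (default: all present); absent scores
#'   are listed in `attr(, "omitted")`.
#' @param contrast length-2 character vector of subtype labels to compare
#'   (default: the two largest).
#' @param adjust_for adjustment covariate columns.
#' @param fdr_threshold significance threshold on q.
#' @return `contrast_table` tibble with one row per score: `target`,
#'   `contrast`, `slope1`, `slope1_se`, `slope2`, `slope2_se`, `beta`
#'   (interaction = slope2 - slope1), `se`, `p`, `q`, `significant`.
#' @export
clinical_progression_contrasts <- function(clinical, labels, covariates,
                                           scores = NULL,
                                           contrast = NULL,
                                           adjust_for = c("age_baseline", "sex",
                                                          "race", "education_years",
                                                          "site"),
                                           fdr_threshold = 0.05) {
  lab <- normalize_labels(labels)
  if (is.null(contrast)) {
    sizes <- sort(table(lab), decreasing = TRUE)
    contrast <- names(sizes)[1:2]
  }
  have <- unique(clinical$score_name)
  if (is.null(scores)) scores <- have
  omitted <- setdiff(scores, have)
  scores <- intersect(scores, have)
  if (!length(scores)) stop_ac("none of the requested scores are present")

  cl <- clinical[clinical$subject_id %in% names(lab)[lab %in% contrast], ,
                 drop = FALSE]
  covariates <- covariates[setdiff(names(covariates), "group")]
  cl <- dplyr::left_join(cl, covariates, by = "subject_id")
  cl$group <- factor(unname(lab[cl$subject_id]), levels = contrast)

  rows <- lapply(scores, function(sc) {
    d <- cl[cl$score_name == sc, , drop = FALSE]
    adj <- adjust_for[vapply(adjust_for, function(v)
      length(unique(d[[v]])) > 1, logical(1))]
    spec <- lme_model_spec("value", covariates = adj, group_by_time = TRUE,
                           group = "group")
    fit <- fit_lme(d, spec)
    it <- interaction_test(fit)
    fe <- fit$fixed_effects
    b_time <- fe[fe$term == "visit_time", ]
    vc <- as.matrix(vcov(fit$model))
    i1 <- which(colnames(vc) == "visit_time")
    i2 <- which(colnames(vc) == it$term)
    slope2_se <- sqrt(vc[i1, i1] + vc[i2, i2] + 2 * vc[i1, i2])
    tibble::tibble(
      target = sc,
      contrast = paste(contrast[2], "vs", contrast[1]),
      slope1 = b_time$estimate, slope1_se = b_time$se,
      slope2 = b_time$estimate + it$beta, slope2_se = slope2_se,
      beta = it$beta, se = it$se, df = it$df, t = it$t, p = it$p,
      converged = fit$converged)
  })
  res <- dplyr::bind_rows(rows)
  res$q <- fdr_adjust(res$p)
  res$significant <- res$q < fdr_threshold
  attr(res, "omitted") <- omitted
  class(res) <- c("contrast_table", class(res))
  res
}

#' Per-subject baseline covariates from a long GMV table
#'
#' @param gmv long GMV (or any subject-visit) table carrying the covariate
#'   columns.
#' @param columns covariate columns to extract.
#' @return tibble with one row per subject.
#' @export
baseline_covariates <- function(gmv,
                                columns = c("age_baseline", "sex", "race",
                                            "education_years", "site", "tiv",
                                            "group")) {
  columns <- intersect(columns, names(gmv))
  first <- !duplicated(gmv$subject_id)
  tibble::as_tibble(gmv[first, c("subject_id", columns), drop = FALSE])
}

#' Baseline comparison of subtypes
#'
#' Continuous variables are compared between two subtypes by
#' covariate-adjusted regression (variable on group + adjusters; Wald t on
#' the group coefficient), categorical variables (e.g. sex) by Pearson
#' chi-squared on the contingency table. FDR correction is applied across
#' all compared variables.
#'
#' @param baseline one row per subject: `subject_id` plus variables.
#' @param labels patient subtype labels.
#' @param continuous,categorical variable names to compare.
#' @param adjust_for adjustment covariates for continuous variables (a
#'   variable is never adjusted for itself).
#' @param contrast length-2 subtype pair (default: the two largest).
#' @param fdr_threshold significance threshold on q.
#' @return `contrast_table` tibble: `target`, `type` (t or chisq),
#'   `statistic`, `p`, `q`, `significant`; skipped zero-variance variables
#'   in `attr(, "skipped")`.
#' @export
baseline_comparison <- function(baseline, labels,
                                continuous,
                                categorical = "sex",
                                adjust_for = c("age_baseline", "sex",
                                               "education_years"),
                                contrast = NULL,
                                fdr_threshold = 0.05) {
  lab <- normalize_labels(labels)
  if (is.null(contrast)) {
    sizes <- sort(table(lab), decreasing = TRUE)
    contrast <- names(sizes)[1:2]
  }
  d <- baseline[baseline$subject_id %in% names(lab)[lab %in% contrast], ,
                drop = FALSE]
  d <- as.data.frame(d)
  d$cmp_group <- factor(unname(lab[d$subject_id]), levels = contrast)

  rows <- list()
  skipped <- character()
  for (v in continuous) {
    x <- d[[v]]
    if (sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      skipped <- c(skipped, v)
      next
    }
    adj <- setdiff(adjust_for, v)
    adj <- adj[vapply(adj, function(a) length(unique(d[[a]])) > 1, logical(1))]
    f <- stats::as.formula(paste(v, "~ cmp_group",
                                 if (length(adj)) paste("+", paste(adj, collapse = " + ")) else ""))
    m <- lm(f, data = d)
    cf <- summary(m)$coefficients
    gr <- grep("^cmp_group", rownames(cf))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      target = v, type = "t", statistic = cf[gr, "t value"],
      estimate = cf[gr, "Estimate"], p = cf[gr, "Pr(>|t|)"])
  }
  for (v in categorical) {
    tabv <- table(d[[v]], d$cmp_group)
    if (nrow(tabv) < 2) {
      skipped <- c(skipped, v)
      next
    }
    ct <- suppressWarnings(chisq.test(tabv, correct = FALSE))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      target = v, type = "chisq", statistic = unname(ct$statistic),
      estimate = NA_real_, p = ct$p.value)
  }
  if (!length(rows)) stop_ac("nothing to compare")
  res <- dplyr::bind_rows(rows)
  res$q <- fdr_adjust(res$p)
  res$significant <- res$q < fdr_threshold
  attr(res, "skipped") <- skipped
  class(res) <- c("contrast_table", class(res))
  res
}

#' Cohen's d effect sizes per score and visit
#'
#' Tabulates the between-subtype effect size of each clinical score at each
#' nominal visit: Cohen's d (second subtype minus first, pooled SD), group
#' means and SDs, and group sizes. By default d is computed on raw values;
#' with `adjust_for` and a covariate table, values are residualized on the
#' covariates first.
#'
#' @inheritParams clinical_progression_contrasts
#' @param adjust_for optional covariate columns to residualize on before
#'   computing d.
#' @return tibble with one row per score x visit: `score_name`, `visit`,
#'   `d`, `mean1`, `sd1`, `n1`, `mean2`, `sd2`, `n2`.
#' @export
effect_size_table <- function(clinical, labels, covariates = NULL,
                              scores = NULL, contrast = NULL,
                              adjust_for = NULL) {
  lab <- normalize_labels(labels)
  if (is.null(contrast)) {
    sizes <- sort(table(lab), decreasing = TRUE)
    contrast <- names(sizes)[1:2]
  }
  if (is.null(scores)) scores <- unique(clinical$score_name)
  cl <- clinical[clinical$subject_id %in% names(lab)[lab %in% contrast] &
                   clinical$score_name %in% scores, , drop = FALSE]
  cl$cmp_group <- factor(unname(lab[cl$subject_id]), levels = contrast)
  cl$visit <- round(cl$visit_time)
  if (length(adjust_for)) {
    if (is.null(covariates)) stop_ac("adjust_for requires a covariate table")
    covariates <- covariates[setdiff(names(covariates), "group")]
    cl <- dplyr::left_join(cl, covariates, by = "subject_id")
  }
  rows <- list()
  for (sc in unique(cl$score_name)) {
    for (vis in sort(unique(cl$visit[cl$score_name == sc]))) {
      d <- as.data.frame(cl[cl$score_name == sc & cl$visit == vis, ])
      v <- d$value
      if (length(adjust_for)) {
        adj <- adjust_for[vapply(adjust_for, function(a)
          length(unique(d[[a]])) > 1, logical(1))]
        if (length(adj)) {
          v <- stats::residuals(lm(stats::as.formula(
            paste("value ~", paste(adj, collapse = " + "))), data = d))
        }
      }
      a <- v[d$cmp_group == contrast[1]]
      b <- v[d$cmp_group == contrast[2]]
      if (length(a) < 2 || length(b) < 2) next
      dd <- tryCatch(cohens_d(a, b), error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        score_name = sc, visit = vis, d = dd,
        mean1 = mean(a), sd1 = sd(a), n1 = length(a),
        mean2 = mean(b), sd2 = sd(b), n2 = length(b))
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-visit cross-sectional contrasts
#'
#' Bins visits to nominal years, then at each visit compares the two
#' subtypes on each score by covariate-adjusted regression. FDR correction
#' is applied across visits within each score.
#'
#' The same machinery serves cross-sectional GMV comparisons: reshape the
#' GMV table to (`subject_id`, `visit_time`, `score_name = roi_id`,
#' `value = gmv`) and add `"tiv"` to `adjust_for`.
#'
#' @inheritParams clinical_progression_contrasts
#' @param min_per_group visits with fewer subjects than this in either group
#'   are skipped (recorded in `attr(, "skipped")`).
#' @return `contrast_table` tibble: `target` (score), `visit` (nominal
#'   year), `estimate` (group difference, second minus first), `t`, `p`,
#'   `q`, `significant`.
#' @export
per_visit_contrasts <- function(clinical, labels, covariates,
                                scores = NULL, contrast = NULL,
                                adjust_for = c("age_baseline", "sex",
                                               "education_years"),
                                min_per_group = 3,
                                fdr_threshold = 0.05) {
  lab <- normalize_labels(labels)
  if (is.null(contrast)) {
    sizes <- sort(table(lab), decreasing = TRUE)
    contrast <- names(sizes)[1:2]
  }
  if (is.null(scores)) scores <- unique(clinical$score_name)
  cl <- clinical[clinical$subject_id %in% names(lab)[lab %in% contrast] &
                   clinical$score_name %in% scores, , drop = FALSE]
  cl$cmp_group <- factor(unname(lab[cl$subject_id]), levels = contrast)
  cl$visit <- round(cl$visit_time)
  covariates <- covariates[setdiff(names(covariates), "group")]
  cl <- dplyr::left_join(cl, covariates, by = "subject_id")

  rows <- list()
  skipped <- character()
  for (sc in unique(cl$score_name)) {
    for (vis in sort(unique(cl$visit[cl$score_name == sc]))) {
      d <- cl[cl$score_name == sc & cl$visit == vis, , drop = FALSE]
      d <- as.data.frame(d)
      cnt <- table(d$cmp_group)
      if (length(cnt) < 2 || any(cnt < min_per_group)) {
        skipped <- c(skipped, sprintf("%s@%d", sc, vis))
        next
      }
      if (sd(d$value, na.rm = TRUE) == 0) {
        skipped <- c(skipped, sprintf("%s@%d", sc, vis))
        next
      }
      adj <- adjust_for[vapply(adjust_for, function(a)
        length(unique(d[[a]])) > 1, logical(1))]
      f <- stats::as.formula(paste("value ~ cmp_group",
                                   if (length(adj)) paste("+", paste(adj, collapse = " + ")) else ""))
      m <- lm(f, data = d)
      cf <- summary(m)$coefficients
      gr <- grep("^cmp_group", rownames(cf))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        target = sc, visit = vis,
        contrast = paste(contrast[2], "vs", contrast[1]),
        estimate = cf[gr, "Estimate"], t = cf[gr, "t value"],
        p = cf[gr, "Pr(>|t|)"])
    }
  }
  if (!length(rows)) stop_ac("no visit had enough subjects to compare")
  res <- dplyr::bind_rows(rows)
  res$q <- NA_real_
  for (sc in unique(res$target)) {
    i <- res$target == sc
    res$q[i] <- fdr_adjust(res$p[i])
  }
  res$significant <- res$q < fdr_threshold
  attr(res, "skipped") <- skipped
  class(res) <- c("contrast_table", class(res))
  res
}
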