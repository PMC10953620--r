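#' Per-ROI atrophy rates for the clustering feature space
#'
#' Fits the per-ROI rate model — outcome `gmv` on age, sex, race, education,
#' site, TIV and follow-up time with `(1 + time | subject)` random structure
#' — for every ROI over the patient subset, and extracts each patient's
#' atrophy rate (fixed slope + BLUP slope deviation). Raw rates are then
#' z-standardized per ROI across the patient population. ROIs whose fit
#' fails to converge are excluded from the standardized matrix (never
#' imputed) and recorded in the diagnostics.
#'
#' @param gmv long GMV table (see [generate_cohort()] / [read_cohort()]).
#'   Restricted to patients with `patients_only = TRUE` (default): rows with
#'   `group != "HC"` are used. The planted `true_subtype` column, if
#'   present, is ignored.
#' @param covariates fixed-effect covariates of the rate model.
#' @param patients_only standardize and fit over patients only (the
#'   clustering population). Set `FALSE` to include HC in both.
#' @param reml fit by REML (default) or ML.
#' @return object of class `rate_matrix`: list with `subjects`, `rois`,
#'   `raw_rates` and `z_rates` (subjects x ROIs matrices), and `diagnostics`
#'   (tibble with per-ROI `converged` and `boundary` flags).
#' @examples
#' spec <- cohort_spec(n_hc = 0, n_patients_per_subtype = c(8, 8), n_roi = 6,
#'                     subtype_rate_profiles = list(rep(-0.02, 6), rep(-0.08, 6)))
#' rm <- fit_rate_matrix(generate_cohort(spec)$gmv)
#' dim(rm$z_rates)
#' @export
fit_rate_matrix <- function(gmv,
                            covariates = c("age_baseline", "sex", "race",
                                           "education_years", "site", "tiv"),
                            patients_only = TRUE,
                            reml = TRUE) {
  if (patients_only && "group" %in% names(gmv)) {
    gmv <- gmv[gmv$group != "HC", , drop = FALSE]
  }
  if (length(unique(gmv$subject_id)) < 2) stop_ac("need at least 2 patients")
  design_cols <- unique(c("subject_id", "visit_time", covariates))
  miss <- setdiff(c(design_cols, "roi_id", "gmv"), names(gmv))
  if (length(miss)) stop_ac("missing columns: ", paste(miss, collapse = ", "))

  wide <- pivot_gmv_wide(gmv, design_cols)
  # covariates constant across a subject can alias the intercept when only
  # one level is present; drop such degenerate factors up front
  keep <- vapply(covariates, function(v) {
    x <- wide$frame[[v]]
    length(unique(x)) > 1
  }, logical(1))
  covariates <- covariates[keep]
  rhs <- paste(c("1", covariates, "visit_time"), collapse = " + ")

  bf <- lme_batch(wide$frame, wide$Y, rhs, reml = reml)
  slope_fixed <- bf$beta["visit_time", ]
  raw <- sweep(bf$slope_blups, 2, slope_fixed, `+`)

  ok <- bf$converged
  if (!any(ok)) stop_ac("no ROI fit converged; cannot build a rate matrix")
  if (!all(ok)) {
    warning(sum(!ok), " ROI fits failed to converge and were excluded from z_rates")
  }
  z <- raw
  z[] <- NA_real_
  z[, ok] <- standardize(raw[, ok, drop = FALSE])

  structure(list(
    subjects = rownames(raw),
    rois = wide$rois,
    raw_rates = raw,
    z_rates = z,
    diagnostics = tibble::tibble(roi_id = wide$rois,
                                 converged = bf$converged,
                                 boundary = bf$boundary)),
    class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("rate_matrix: %d subjects x %d ROIs (%d converged, %d boundary)\n",
              length(x$subjects), length(x$rois),
              sum(x$diagnostics$converged), sum(x$diagnostics$boundary)))
  invisible(x)
}

#' Z-standardize a rate matrix column-wise
#'
#' Centers and scales each column (ROI) to mean 0, sample SD 1 (n-1
#' denominator) across subjects — the population-level z-scoring applied to
#' atrophy rates before clustering.
#'
#' @param raw_rates numeric matrix, subjects x ROIs.
#' @return matrix of the same shape and dimnames.
#' @export
standardize <- function(raw_rates) {
  raw_rates <- as.matrix(raw_rates)
  if (nrow(raw_rates) < 2) stop_ac("need at least 2 subjects per column")
  mu <- colMeans(raw_rates)
  s <- apply(raw_rates, 2, sd)
  zero <- s <= 0 | !is.finite(s)
  if (any(zero)) {
    stop_ac("zero-variance (degenerate) columns: ",
            paste(colnames(raw_rates)[zero] %||% which(zero), collapse = ", "))
  }
  scale(raw_rates, center = mu, scale = s)[, , drop = FALSE]
}
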