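# Batch fitting of one mixed-model design over many response columns.
#
# Per-ROI models share a single fixed design (same subjects, visits and
# covariates); only the response changes. lme4's modular API lets us build
# the deviance function once and swap the response module between columns,
# skipping merMod construction entirely. This is what makes 254-ROI fits
# over many simulation replicates tractable on one CPU; results agree with
# full lmer() fits to optimizer precision (tested).

# frame: subject-visit design rows; Y: n_obs x m response matrix;
# rhs: fixed-effects right-hand side (character); returns per-column fixed
# effects, slope BLUPs, REML/ML criterion and convergence/boundary flags.
lme_batch <- function(frame, Y, rhs, subject = "subject_id",
                      time = "visit_time", reml = TRUE,
                      tol = 1e-6, want_blups = TRUE) {
  stopifnot(is.matrix(Y), nrow(frame) == nrow(Y))
  d <- as.data.frame(frame)
  for (v in names(d)) if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
  d[[subject]] <- factor(d[[subject]])
  d[[".y"]] <- Y[, 1]

  full <- stats::as.formula(sprintf(".y ~ %s + (1 + %s | %s)", rhs, time, subject))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  ff <- lme4::lFormula(full, data = d, REML = reml, control = ctrl)
  if (nrow(ff$X) != nrow(Y)) {
    stop_ac("missing values in design columns are not allowed in batch fits")
  }
  qr_mm <- qr(ff$X)
  if (qr_mm$rank < ncol(ff$X)) {
    aliased <- colnames(ff$X)[qr_mm$pivot[(qr_mm$rank + 1):ncol(ff$X)]]
    stop_ac("rank-deficient fixed-effect design; aliased columns: ",
            paste(aliased, collapse = ", "))
  }

  devfun <- do.call(lme4::mkLmerDevfun, ff)
  rho <- environment(devfun)
  lower <- rho$lower
  n <- nrow(ff$X)
  p <- ncol(ff$X)
  m <- ncol(Y)
  subj_levels <- levels(ff$reTrms$flist[[1]])
  n_sub <- length(subj_levels)

  df <- wald_df(ff$X, d[[subject]], d[[time]], n, qr_mm$rank)

  opt_ctrl <- list(xtol_abs = tol, ftol_abs = tol)
  beta_mat <- matrix(NA_real_, p, m, dimnames = list(colnames(ff$X), colnames(Y)))
  se_mat <- beta_mat
  crit <- numeric(m)
  conv <- logical(m)
  singular <- logical(m)
  blups <- if (want_blups) {
    matrix(NA_real_, n_sub, m, dimnames = list(subj_levels, colnames(Y)))
  } else NULL

  # every column restarts from lmer's default (unit variances, zero
  # correlation): warm starts from a neighbouring column's optimum can
  # stall BOBYQA on the variance boundary
  start <- rep(1, length(lower))
  start[lower < 0] <- 0
  for (j in seq_len(m)) {
    # swap the response in place: reassign the y field and null the cached
    # external pointer so the C++ response module is rebuilt on next use
    rho$resp$y <- Y[, j]
    rho$resp$Ptr <- methods::new("externalptr")
    opt <- lme4::nloptwrap(start, devfun, lower = lower,
                           upper = rep(Inf, length(lower)),
                           control = opt_ctrl)
    devfun(opt$par)  # sync pp/resp state at the optimum
    pp <- rho$pp
    beta_mat[, j] <- pp$beta(1)
    denom <- if (reml) n - p else n
    sigma2 <- (rho$resp$wrss() + pp$sqrL(1)) / denom
    se_mat[, j] <- sqrt(sigma2 * diag(tcrossprod(pp$RXi())))
    crit[j] <- opt$fval
    conv[j] <- opt$conv >= 0
    singular[j] <- any(opt$par[lower == 0] < 1e-4)
    if (want_blups) {
      u <- pp$b(1)
      blups[, j] <- u[seq(2, 2 * n_sub, by = 2)]
    }
  }

  list(beta = beta_mat, se = se_mat, df = df,
       slope_blups = blups, criterion = crit, loglik = -crit / 2,
       converged = conv, boundary = singular,
       n_obs = n, n_subjects = n_sub, terms = colnames(ff$X))
}

# Pivot a long GMV table to one subject-visit row per line with a response
# matrix of ROI columns; validates that every retained visit has the full
# ROI set.
pivot_gmv_wide <- function(gmv, design_cols) {
  rois <- sort(unique(gmv$roi_id))
  key <- paste(gmv$subject_id, gmv$visit_time, sep = "\r")
  rows <- !duplicated(key)
  frame <- as.data.frame(gmv[rows, design_cols, drop = FALSE])
  ukey <- key[rows]
  Y <- matrix(NA_real_, length(ukey), length(rois),
              dimnames = list(NULL, rois))
  Y[cbind(match(key, ukey), match(gmv$roi_id, rois))] <- gmv$gmv
  if (anyNA(Y)) {
    bad <- unique(frame$subject_id[rowSums(is.na(Y)) > 0])
    stop_ac("incomplete ROI set at some visits for subjects: ",
            paste(head(bad, 5), collapse = ", "))
  }
  list(frame = frame, Y = Y, rois = rois)
}
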