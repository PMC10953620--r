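# Independent oracles and small simulators used across the suite.

# REML log-likelihood of the random-intercept random-slope Gaussian model,
# computed directly from the marginal density with beta and sigma^2 profiled
# out. psi0, psi1, rho parameterize the RELATIVE (sigma^2-scaled) covariance
# of the subject (intercept, slope) deviations. Dense algebra, independent
# of lme4's penalized-least-squares path.
reml_oracle <- function(X, y, subject, time, psi0, psi1, rho) {
  n <- nrow(X)
  p <- ncol(X)
  Psi <- matrix(c(psi0^2, rho * psi0 * psi1, rho * psi0 * psi1, psi1^2), 2)
  W <- diag(n)
  for (s in unique(subject)) {
    i <- which(subject == s)
    Zi <- cbind(1, time[i])
    W[i, i] <- W[i, i] + Zi %*% Psi %*% t(Zi)
  }
  Wi <- solve(W)
  XtWiX <- t(X) %*% Wi %*% X
  beta <- solve(XtWiX, t(X) %*% Wi %*% y)
  r <- y - X %*% beta
  s2 <- drop(t(r) %*% Wi %*% r) / (n - p)
  -0.5 * as.numeric((n - p) * (1 + log(2 * pi * s2)) +
                      determinant(W)$modulus + determinant(XtWiX)$modulus)
}

# Coordinate zoom-grid maximization of the oracle over (psi0, psi1, rho):
# brute-force grid evaluation, shrinking the box around the argmax.
zoom_grid_max <- function(X, y, subject, time,
                          lower = c(0, 0, -0.99), upper = c(4, 4, 0.99),
                          n_grid = 7, iters = 7) {
  best <- -Inf
  best_par <- (lower + upper) / 2
  for (it in seq_len(iters)) {
    g1 <- seq(lower[1], upper[1], length.out = n_grid)
    g2 <- seq(lower[2], upper[2], length.out = n_grid)
    g3 <- seq(lower[3], upper[3], length.out = n_grid)
    for (a in g1) for (b in g2) for (cc in g3) {
      v <- reml_oracle(X, y, subject, time, a, b, cc)
      if (v > best) {
        best <- v
        best_par <- c(a, b, cc)
      }
    }
    span <- (upper - lower) / (n_grid - 1)
    lower <- pmax(c(0, 0, -0.99), best_par - span)
    upper <- pmin(c(Inf, Inf, 0.99), best_par + span)
  }
  list(value = best, par = best_par)
}

# Longitudinal two-group design with a balanced annual schedule.
make_long_design <- function(n1, n2, visits = 0:4,
                             group_names = c("subtype_1", "subtype_2")) {
  n <- n1 + n2
  d <- expand.grid(subject_id = sprintf("P%03d", seq_len(n)),
                   visit_time = visits, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  grp <- setNames(rep(group_names, c(n1, n2)), sprintf("P%03d", seq_len(n)))
  d$group <- factor(grp[d$subject_id], levels = group_names)
  d[order(d$subject_id, d$visit_time), ]
}

# Matrix of simulated outcomes for a two-group random-slope model: one
# column per replicate; group slopes slope1/slope2, random intercept and
# slope SDs, residual SD.
sim_two_group_y <- function(design, n_reps, slope1, slope2,
                            tau_int = 2.9, tau_slope = 0.561, sigma = 1.775,
                            intercept = 4) {
  ids <- unique(design$subject_id)
  n <- length(ids)
  si <- match(design$subject_id, ids)
  slope_g <- ifelse(design$group == levels(design$group)[1], slope1, slope2)
  t <- design$visit_time
  m <- nrow(design)
  vapply(seq_len(n_reps), function(j) {
    b0 <- rnorm(n, 0, tau_int)
    b1 <- rnorm(n, 0, tau_slope)
    intercept + b0[si] + (slope_g + b1[si]) * t + rnorm(m, 0, sigma)
  }, numeric(m))
}

# Well-separated Gaussian blobs for clustering tests.
make_blobs <- function(n_per, centers, sd = 1) {
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(rnorm(n_per * ncol(centers), mean = rep(centers[i, ], each = n_per),
                 sd = sd), n_per)
  }))
  rownames(x) <- sprintf("s%03d", seq_len(nrow(x)))
  list(x = x, truth = rep(seq_len(k), each = n_per))
}

# Adjusted Rand index via mclust (declared in Suggests; present in the
# test environment).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Patients-only cohort spec with two planted subtypes on the default
# 254-ROI layout; used by pipeline-level tests.
patients_only_spec <- function(seed, n1 = 63, n2 = 44) {
  spec <- ppmi_like_spec(seed = seed)
  spec$n_hc <- 0L
  spec$n_patients_per_subtype <- as.integer(c(n1, n2))
  spec$clinical_score_model <- NULL
  spec
}

# planted truth labels (named by subject) from a generated gmv table
planted_truth <- function(gmv) {
  first <- !duplicated(gmv$subject_id)
  setNames(gmv$true_subtype[first], gmv$subject_id[first])
}
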