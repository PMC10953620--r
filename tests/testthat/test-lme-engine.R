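make_tiny <- function(seed = 3, n_sub = 4, visits = 0:2) {
  set.seed(seed)
  d <- expand.grid(subject_id = sprintf("P%d", seq_len(n_sub)),
                   visit_time = visits, stringsAsFactors = FALSE)
  n <- nrow(d)
  d$x <- rnorm(n)
  b0 <- rnorm(n_sub, 0, 0.7)
  b1 <- rnorm(n_sub, 0, 0.3)
  si <- match(d$subject_id, unique(d$subject_id))
  d$y <- 5 + 0.4 * d$x - 0.5 * d$visit_time + b0[si] + b1[si] * d$visit_time +
    rnorm(n, 0, 0.4)
  d
}

test_that("REML optimum agrees with the zoomed grid-search oracle", {
  d <- make_tiny()
  spec <- lme_model_spec("y", covariates = "x")
  fit <- fit_lme(d, spec)
  X <- model.matrix(~ x + visit_time, d)

  # the reported log-likelihood equals the marginal Gaussian density at the
  # fitted relative covariance parameters
  psi <- fit$vcov_random / fit$residual_variance
  at_fit <- reml_oracle(X, d$y, d$subject_id, d$visit_time,
                        sqrt(psi[1, 1]), sqrt(psi[2, 2]),
                        psi[1, 2] / sqrt(psi[1, 1] * psi[2, 2]))
  expect_equal(at_fit, fit$loglik, tolerance = 1e-6)

  # and brute-force maximization over the parameter grid finds no better
  # optimum (nor a worse one, beyond tolerance)
  gr <- zoom_grid_max(X, d$y, d$subject_id, d$visit_time)
  expect_lt(abs(gr$value - fit$loglik), 1e-4)
})

test_that("degenerate-variance limit reduces to ordinary least squares", {
  # identical-slope noise-free lines: variance components hit the boundary
  # and the fixed slope equals the OLS slope exactly
  d <- expand.grid(subject_id = sprintf("P%d", 1:6), visit_time = 0:3,
                   stringsAsFactors = FALSE)
  ints <- setNames(seq(4, 9), sprintf("P%d", 1:6))
  d$y <- ints[d$subject_id] - 0.5 * d$visit_time
  fit <- suppressMessages(fit_lme(d, lme_model_spec("y", covariates = character())))
  slope <- fit$fixed_effects$estimate[fit$fixed_effects$term == "visit_time"]
  ols <- coef(lm(y ~ subject_id + visit_time, d))[["visit_time"]]
  expect_equal(slope, ols, tolerance = 1e-8)
  expect_equal(slope, -0.5, tolerance = 1e-8)
  expect_true(fit$boundary)
  # shrinkage-to-mean limit: every subject receives the fixed slope (up to
  # the optimizer's boundary precision)
  expect_equal(unname(subject_slopes(fit)), rep(slope, 6), tolerance = 1e-5)
})

test_that("subject slopes recover per-subject OLS in the no-shrinkage limit", {
  set.seed(7)
  n_sub <- 12
  d <- expand.grid(subject_id = sprintf("P%02d", seq_len(n_sub)),
                   visit_time = 0:4, stringsAsFactors = FALSE)
  si <- match(d$subject_id, unique(d$subject_id))
  b1 <- rnorm(n_sub, -0.3, 0.5)       # large slope heterogeneity
  b0 <- rnorm(n_sub, 5, 0.5)
  d$y <- b0[si] + b1[si] * d$visit_time + rnorm(nrow(d), 0, 1e-5)
  fit <- fit_lme(d, lme_model_spec("y", covariates = character()))
  rates <- subject_slopes(fit)
  ols <- vapply(split(d, d$subject_id), function(s)
    coef(lm(y ~ visit_time, s))[[2]], numeric(1))
  expect_equal(rates[names(ols)], ols, tolerance = 1e-6)
})

test_that("BLUP slope deviations are centered in a balanced design", {
  d <- make_tiny(seed = 19, n_sub = 8, visits = 0:3)
  fit <- fit_lme(d, lme_model_spec("y", covariates = character()))
  expect_lt(abs(mean(fit$subject_effects$slope_dev)),
            1e-6 * sd(fit$subject_effects$slope_dev))
  # population mean of returned rates equals the fixed slope
  slope <- fit$fixed_effects$estimate[fit$fixed_effects$term == "visit_time"]
  expect_equal(mean(subject_slopes(fit)), slope, tolerance = 1e-8)
})

test_that("interaction test is present only when requested, with Wald duality", {
  d <- make_long_design(10, 10)
  set.seed(21)
  d$y <- sim_two_group_y(d, 1, slope1 = 0, slope2 = 1.2,
                         tau_int = 1, tau_slope = 0.3, sigma = 0.8)[, 1]
  fit0 <- fit_lme(d, lme_model_spec("y", covariates = character()))
  expect_error(interaction_test(fit0), "interaction")

  fit1 <- fit_lme(d, lme_model_spec("y", covariates = character(),
                                    group_by_time = TRUE))
  it <- interaction_test(fit1)
  expect_true(it$p >= 0 && it$p <= 1)
  expect_equal((it$ci[1] > 0 | it$ci[2] < 0), it$p < 0.05)
  # CI brackets the estimate
  expect_true(it$ci[1] < it$beta && it$beta < it$ci[2])
})

test_that("rank-deficient designs and unidentifiable slopes error clearly", {
  d <- make_tiny()
  d$x2 <- 2 * d$x
  expect_error(fit_lme(d, lme_model_spec("y", covariates = c("x", "x2"))),
               "aliased.*x2")
  d1 <- d[d$visit_time == 0, ]
  expect_error(fit_lme(d1, lme_model_spec("y", covariates = "x")),
               "single visit")
  expect_error(fit_lme(d[d$subject_id == "P1", ],
                       lme_model_spec("y", covariates = "x")),
               "2 subjects")
})

test_that("fits are invariant to affine covariate reparameterization", {
  d <- make_tiny(seed = 13, n_sub = 8, visits = 0:3)
  sp_ml <- lme_model_spec("y", covariates = "x", reml = FALSE)
  f1 <- fit_lme(d, sp_ml)
  f1r <- fit_lme(d, lme_model_spec("y", covariates = "x"))
  d2 <- d
  d2$x <- 2 * d$x + 5
  f2 <- fit_lme(d2, sp_ml)
  f2r <- fit_lme(d2, lme_model_spec("y", covariates = "x"))
  # ML log-likelihood is invariant; the REML criterion shifts by exactly
  # log|det| of the reparameterization (here log 2), a known REML property
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-4)
  expect_equal(f1r$loglik - f2r$loglik, log(2), tolerance = 1e-4)
  b1 <- f1r$fixed_effects$estimate[f1r$fixed_effects$term == "x"]
  b2 <- f2r$fixed_effects$estimate[f2r$fixed_effects$term == "x"]
  expect_equal(b1, 2 * b2, tolerance = 1e-3)
  # t statistic of the reparameterized covariate is unchanged
  expect_equal(f1r$fixed_effects$t[f1r$fixed_effects$term == "x"],
               f2r$fixed_effects$t[f2r$fixed_effects$term == "x"],
               tolerance = 1e-4)
})

test_that("doubling the outcome doubles beta and SE, leaves t and p unchanged", {
  d <- make_tiny(seed = 17, n_sub = 8, visits = 0:3)
  f1 <- fit_lme(d, lme_model_spec("y", covariates = "x"))
  d$y <- 2 * d$y
  f2 <- fit_lme(d, lme_model_spec("y", covariates = "x"))
  expect_equal(f2$fixed_effects$estimate, 2 * f1$fixed_effects$estimate,
               tolerance = 1e-6)
  expect_equal(f2$fixed_effects$se, 2 * f1$fixed_effects$se, tolerance = 1e-6)
  expect_equal(f2$fixed_effects$t, f1$fixed_effects$t, tolerance = 1e-6)
  expect_equal(f2$fixed_effects$p, f1$fixed_effects$p, tolerance = 1e-6)
})

test_that("the batch fitter matches full lmer fits column by column", {
  set.seed(31)
  d <- make_long_design(8, 7, visits = 0:3)
  Y <- sim_two_group_y(d, 6, slope1 = -0.2, slope2 = 0.4,
                       tau_int = 1, tau_slope = 0.4, sigma = 0.7)
  colnames(Y) <- sprintf("out%d", 1:6)
  bf <- atrophyclust:::lme_batch(d, Y, "1 + visit_time * group", tol = 1e-8)
  for (j in 1:6) {
    dd <- d
    dd$y <- Y[, j]
    fit <- fit_lme(dd, lme_model_spec("y", covariates = character(),
                                      group_by_time = TRUE))
    expect_equal(unname(bf$beta[, j]), fit$fixed_effects$estimate,
                 tolerance = 1e-4)
    expect_equal(unname(bf$se[, j]), fit$fixed_effects$se, tolerance = 1e-3)
    expect_equal(bf$loglik[j], fit$loglik, tolerance = 1e-5)
    # slope BLUP deviations agree
    m <- match(rownames(bf$slope_blups), fit$subject_effects$subject_id)
    expect_equal(unname(bf$slope_blups[, j]),
                 fit$subject_effects$slope_dev[m], tolerance = 1e-4)
  }
})
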