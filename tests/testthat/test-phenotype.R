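test_that("Benjamini-Hochberg adjustment matches the hand-worked step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(fdr_adjust(0.123), 0.123)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone in the sorted p-values and capped at 1
  set.seed(32)
  p <- runif(50)
  q <- fdr_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q <= 1 & q >= p))
})

test_that("Cohen's d matches its definition and error paths", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cohens_d(c(0, 0), c(1, 1)), "pooled SD")
  expect_error(cohens_d(1, c(1, 2)), "2 values")
  # hand case: a=(0,2), b=(3,5): pooled var = 2, d = 3/sqrt(2)
  expect_equal(cohens_d(c(0, 2), c(3, 5)), 3 / sqrt(2), tolerance = 1e-12)
  set.seed(34)
  d <- cohens_d(rnorm(1000), rnorm(1000, 0.65))
  expect_lt(abs(d - 0.65), 0.1)
})

make_baseline <- function(counts) {
  # counts: matrix male/female x subtype_1/subtype_2
  sex <- rep(rep(c("M", "F"), 2), as.vector(counts))
  subtype <- rep(rep(1:2, each = 2), as.vector(counts))
  n <- length(sex)
  set.seed(36)
  tibble::tibble(subject_id = sprintf("P%03d", seq_len(n)),
                 sex = sex,
                 age_baseline = rnorm(n, 60, 8),
                 education_years = rnorm(n, 15, 2),
                 updrs3 = rnorm(n, 20, 5))
}

test_that("baseline chi-squared matches the direct Pearson formula", {
  counts <- matrix(c(39, 24, 36, 8), 2)  # male/female by subtype
  bl <- make_baseline(counts)
  lab <- setNames(rep(rep(1:2, each = 2), as.vector(counts)), bl$subject_id)
  res <- baseline_comparison(bl, lab, continuous = c("age_baseline", "updrs3"))
  chi <- res[res$type == "chisq", ]
  # independent oracle: sum (O - E)^2 / E on the 2x2 table
  tab <- matrix(c(39, 24, 36, 8), 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
  expect_true(all(res$q >= res$p - 1e-12))
  # chi-squared is invariant to group order
  lab_sw <- setNames(3 - lab, names(lab))
  res_sw <- baseline_comparison(bl, lab_sw,
                                continuous = c("age_baseline", "updrs3"))
  expect_equal(res_sw$statistic[res_sw$type == "chisq"], chi$statistic,
               tolerance = 1e-10)
})

test_that("identical group distributions give a null adjusted t", {
  n <- 20
  bl <- tibble::tibble(subject_id = sprintf("P%03d", 1:(2 * n)),
                       sex = rep(c("M", "F"), n),
                       age_baseline = rep(rnorm(n, 60, 5), 2),
                       education_years = rep(rnorm(n, 15, 2), 2),
                       score = rep(rnorm(n, 10, 2), 2))
  lab <- setNames(rep(1:2, each = n), bl$subject_id)
  res <- baseline_comparison(bl, lab, continuous = "score")
  expect_lt(abs(res$statistic[res$type == "t"]), 1e-8)
  # zero-variance variables are skipped with a record
  bl$flat <- 1
  res2 <- baseline_comparison(bl, lab, continuous = c("score", "flat"))
  expect_true("flat" %in% attr(res2, "skipped"))
})

sim_clinical <- function(slope1, slope2, noise = 0, seed = 38,
                         n1 = 10, n2 = 10, visits = 0:4) {
  set.seed(seed)
  d <- make_long_design(n1, n2, visits)
  ids <- unique(d$subject_id)
  lab <- setNames(ifelse(seq_along(ids) <= n1, 1, 2), ids)
  slope <- ifelse(lab[d$subject_id] == 1, slope1, slope2)
  base <- setNames(rnorm(length(ids), 10, 2), ids)
  clinical <- tibble::tibble(
    subject_id = d$subject_id, visit_time = d$visit_time,
    score_name = "score_a",
    value = base[d$subject_id] + slope * d$visit_time +
      rnorm(nrow(d), 0, noise))
  covs <- tibble::tibble(subject_id = ids,
                         age_baseline = rnorm(length(ids), 60, 8),
                         sex = sample(c("M", "F"), length(ids), TRUE),
                         race = "A",
                         education_years = round(rnorm(length(ids), 15, 2)),
                         site = sample(c("s1", "s2"), length(ids), TRUE))
  list(clinical = clinical, labels = lab, covs = covs)
}

test_that("noise-free clinical slopes are recovered exactly", {
  s <- sim_clinical(0.63, 1.26, noise = 1e-7)
  res <- clinical_progression_contrasts(s$clinical, s$labels, s$covs)
  expect_equal(res$slope1, 0.63, tolerance = 1e-6)
  expect_equal(res$slope2, 1.26, tolerance = 1e-6)
  expect_equal(res$beta, 0.63, tolerance = 1e-6)
})

test_that("contrast order flips the interaction sign but not its p-value", {
  s <- sim_clinical(0.2, 0.9, noise = 0.8)
  r12 <- clinical_progression_contrasts(s$clinical, s$labels, s$covs,
                                        contrast = c("subtype_1", "subtype_2"))
  r21 <- clinical_progression_contrasts(s$clinical, s$labels, s$covs,
                                        contrast = c("subtype_2", "subtype_1"))
  expect_equal(r12$beta, -r21$beta, tolerance = 1e-4)
  expect_equal(r12$p, r21$p, tolerance = 1e-4)
  # absent scores are recorded, not silently dropped
  r3 <- clinical_progression_contrasts(s$clinical, s$labels, s$covs,
                                       scores = c("score_a", "missing_score"))
  expect_equal(attr(r3, "omitted"), "missing_score")
})

test_that("progression contrasts recover the planted study operating point", {
  csm <- default_clinical_models()
  csm <- csm[csm$score_name == "updrs1", ]
  spec <- cohort_spec(n_hc = 0, n_patients_per_subtype = c(63, 44), n_roi = 2,
                      subtype_rate_profiles = list(rep(-0.02, 2), rep(-0.06, 2)),
                      clinical_score_model = csm, seed = 48)
  co <- generate_cohort(spec)
  truth <- planted_truth(co$gmv)
  res <- clinical_progression_contrasts(co$clinical, truth,
                                        baseline_covariates(co$gmv))
  # planted annual slopes 0.63 and 1.26 recovered within 3 SE
  expect_lt(abs(res$slope1 - 0.63), 3 * res$slope1_se)
  expect_lt(abs(res$slope2 - 1.26), 3 * res$slope2_se)
  # and the per-group slope SE sits near the calibrated operating point
  expect_lt(res$slope1_se, 0.2)
})

test_that("per-ROI contrasts carry the planted direction uniformly", {
  spec <- cohort_spec(n_hc = 6, n_patients_per_subtype = c(10, 10), n_roi = 8,
                      subtype_rate_profiles = list(rep(-0.02, 8), rep(-0.09, 8)),
                      visit_schedule = list(max_years = 4, dropout = 0,
                                            jitter_years = 0.05),
                      random_effect_sd = c(intercept = 0.3, slope = 0.005,
                                           corr = 0),
                      global_slope_sd = 0.005, residual_sd = 0.05, seed = 40)
  g <- generate_cohort(spec)$gmv
  truth <- planted_truth(g)
  lab <- truth[!is.na(truth)]
  res <- gmv_group_contrasts(g, lab)
  s21 <- res[res$contrast == "subtype_2 vs subtype_1", ]
  expect_equal(nrow(s21), 8)
  expect_true(all(s21$beta < 0))  # subtype 2 loses volume faster
  expect_true(all(res$q >= res$p - 1e-12))
  # reversing the pair flips beta, keeps p
  rev <- gmv_group_contrasts(g, lab, pairs = list(c("subtype_2", "subtype_1")))
  expect_equal(rev$beta, -s21$beta, tolerance = 1e-4)
  expect_equal(rev$p, s21$p, tolerance = 1e-3)
})

test_that("per-visit contrasts flag divergence only after it emerges", {
  # shared baseline, diverging slopes, tiny noise: significance cannot
  # precede the divergence
  s <- sim_clinical(0, 1, noise = 0.05, n1 = 8, n2 = 8)
  res <- per_visit_contrasts(s$clinical, s$labels, s$covs)
  expect_false(res$significant[res$visit == 0])
  expect_true(all(res$significant[res$visit >= 2]))
  # locality: removing a visit removes exactly its rows
  cl2 <- s$clinical[round(s$clinical$visit_time) != 3, ]
  res2 <- per_visit_contrasts(cl2, s$labels, s$covs)
  expect_setequal(res2$visit, setdiff(res$visit, 3))
  kept <- res$visit != 3
  expect_equal(res2$estimate, res$estimate[kept], tolerance = 1e-12)
})

test_that("effect sizes per visit follow the planted divergence", {
  s <- sim_clinical(0, 1, noise = 0.4, seed = 44, n1 = 12, n2 = 12)
  et <- effect_size_table(s$clinical, s$labels)
  expect_setequal(names(et), c("score_name", "visit", "d",
                               "mean1", "sd1", "n1", "mean2", "sd2", "n2"))
  expect_equal(et$n1, rep(12, 5))
  # divergence grows roughly linearly: |d| increases with visit
  expect_lt(abs(et$d[et$visit == 0]), 1)
  expect_gt(et$d[et$visit == 4], et$d[et$visit == 1])
  # hand check at one visit
  d3 <- s$clinical[round(s$clinical$visit_time) == 3, ]
  a <- d3$value[s$labels[d3$subject_id] == 1]
  b <- d3$value[s$labels[d3$subject_id] == 2]
  expect_equal(et$d[et$visit == 3], cohens_d(a, b), tolerance = 1e-12)
  # residualized variant runs and changes nothing when covariates are noise
  et2 <- effect_size_table(s$clinical, s$labels, covariates = s$covs,
                           adjust_for = "age_baseline")
  expect_equal(nrow(et2), nrow(et))
})

test_that("a shared trajectory yields no spurious per-visit flags", {
  s <- sim_clinical(0.5, 0.5, noise = 1, seed = 42, n1 = 15, n2 = 15)
  res <- per_visit_contrasts(s$clinical, s$labels, s$covs)
  expect_true(mean(res$significant) <= 0.2)
})
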