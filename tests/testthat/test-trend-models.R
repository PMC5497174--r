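test_that("trend estimates expose per-year and per-epoch odds ratios coherently", {
  tr <- trend_estimate(log(0.973), 0.0013)
  expect_equal(tr$odds_ratio_per_year, 0.973)
  expect_equal(tr$odds_ratio_per_epoch, 0.973^2)
  expect_equal(tr$relative_annual_decline_pct, 2.7, tolerance = 1e-10)
  expect_true(tr$ci95[1] <= tr$odds_ratio_per_year &&
                tr$odds_ratio_per_year <= tr$ci95[2])
})

test_that("the naive fit rejects risk sets without incident cases", {
  ref <- reference_rows()
  statuses <- ascertain_panel(ref)$statuses
  expect_error(fit_naive_trend(ref, statuses), "no incident dementia")
})

test_that("with no deaths the competing-risks fit reduces to the naive fit", {
  f <- small_dataset(42)
  p <- f$data$panel
  p$death_year <- NA_real_
  p$death_cause <- NA_character_
  st <- f$asc$statuses
  nv <- fit_naive_trend(p, st)
  cr <- fit_competing_risks_trend(p, st)
  expect_equal(cr$trend$odds_ratio_per_year, nv$trend$odds_ratio_per_year,
               tolerance = 1e-4)
})

test_that("epoch outcome categories partition the risk set", {
  f <- small_dataset(42)
  e <- demproj:::build_risk_epochs(f$data$panel, f$asc$statuses)
  expect_true(all(e$outcome %in% c("none", "dementia", "death", "dropout")))
  ## multinomial fitted probabilities sum to 1
  d <- e[e$outcome != "dropout", ]
  d$outcome <- factor(d$outcome, levels = c("none", "dementia", "death"))
  d$age_c <- (d$age - 75) / 10
  d$female <- as.integer(d$sex == "female")
  d$yr_c <- d$year - 2006
  fit <- nnet::multinom(outcome ~ age_c + female + yr_c, data = d, trace = FALSE)
  pr <- stats::predict(fit, type = "probs")
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-12)
})

test_that("joint model converges, improves on its start, and recovers null associations", {
  f <- small_dataset(42)
  jm <- suppressWarnings(fit_joint_model(f$data$panel, f$asc$statuses,
                                         f$asc$zscores))
  expect_true(jm$converged)
  expect_gte(jm$loglik, jm$loglik_start - 1e-6)
  ## associations must point the right way: worse and falling cognition
  ## raises the hazard
  expect_lt(jm$event$alpha_value, 0)
  expect_lt(jm$event$alpha_slope, 0)

  ## null-association generator: alpha coefficients' CIs cover zero.
  ## Ground-truth statuses are used because the operational case
  ## definition itself conditions on low scores, which would re-introduce
  ## an association no estimator should be asked to remove.
  cfg0 <- small_cohort_config(13, n_core = 1800L,
                              dropout_params = c(baseline = 0.07,
                                                 slope_increment = 0))
  cfg0$hazard_params$alpha_value <- 0
  cfg0$hazard_params$alpha_slope <- 0
  cfg0$hazard_params$intercept <- -4.6  # keep caseness in a realistic range
  d0 <- generate_cohort(cfg0)
  a0 <- ascertain_panel(d0)
  st0 <- truth_statuses(d0)
  jm0 <- suppressWarnings(fit_joint_model(d0$panel, st0, a0$zscores))
  se <- sqrt(diag(jm0$event$vcov))
  z_v <- jm0$event$alpha_value / se[["alpha_value"]]
  z_s <- jm0$event$alpha_slope / se[["alpha_slope"]]
  expect_lt(abs(z_v), 2.6)
  expect_lt(abs(z_s), 2.6)
})

test_that("predicted probabilities are valid, risk-graded and calibrated", {
  f <- small_dataset(42)
  jm <- suppressWarnings(fit_joint_model(f$data$panel, f$asc$statuses,
                                         f$asc$zscores))
  pr <- predict_dementia_probability(jm, f$data$panel, f$asc$statuses)
  expect_true(all(pr$p_dementia >= 0 & pr$p_dementia <= 1))
  ## dropouts keep contributing person-epochs
  expect_gt(sum(!pr$observed), 0)

  ## persons on steeply declining trajectories carry higher predicted risk
  tr <- f$data$truth
  b1 <- tr$b1[match(pr$person_id, tr$person_id)]
  steep <- pr$p_dementia[b1 <= stats::quantile(b1, 1 / 3)]
  flat <- pr$p_dementia[b1 >= stats::quantile(b1, 2 / 3)]
  expect_gt(mean(steep), mean(flat))

  ## calibration among observed epochs: mean prediction close to the
  ## observed incident fraction
  e <- demproj:::build_risk_epochs(f$data$panel, f$asc$statuses)
  obs_rate <- mean(e$outcome[e$interviewed | e$outcome == "dementia"] == "dementia")
  pred_rate <- mean(pr$p_dementia[pr$observed])
  expect_lt(abs(pred_rate - obs_rate) / obs_rate, 0.25)
})

test_that("calendar-trend extraction recovers a known log-linear structure", {
  grid <- expand.grid(age = 55:95, sex = c("male", "female"),
                      year = seq(2002, 2012, 2), stringsAsFactors = FALSE)
  b_true <- log(0.95)
  set.seed(5)
  lp <- -6 + 0.08 * (grid$age - 75) + 0.2 * (grid$sex == "female") +
    b_true * (grid$year - 2006) + stats::rnorm(nrow(grid), 0, 1e-4)
  grid$p_dementia <- stats::plogis(lp)
  tr <- extract_calendar_trend(grid)
  expect_equal(tr$odds_ratio_per_year, 0.95, tolerance = 1e-5)

  ## invariance to recentring calendar time
  grid2 <- grid; grid2$year <- grid2$year + 7
  tr2 <- extract_calendar_trend(grid2)
  expect_equal(tr2$odds_ratio_per_year, tr$odds_ratio_per_year,
               tolerance = 1e-10)

  ## probabilities at the boundary are clipped with a warning
  grid3 <- grid; grid3$p_dementia[1] <- 0
  expect_warning(extract_calendar_trend(grid3), "clipped")

  ## sex-specific estimates available on request
  trs <- extract_calendar_trend(grid, sex_specific = TRUE)
  expect_named(trs$sex_specific, c("female", "male"))
})

test_that("risk-factor adjustment reports the attenuation of the calendar effect", {
  f <- small_dataset(42)
  jm <- suppressWarnings(fit_joint_model(f$data$panel, f$asc$statuses,
                                         f$asc$zscores))
  pr <- predict_dementia_probability(jm, f$data$panel, f$asc$statuses)
  ## the default generator holds risk-factor prevalences calendar-constant,
  ## so adjustment attenuates (almost) nothing
  adj <- adjust_trend_for_risk_factors(pr, f$data$panel)
  expect_equal(adj$attenuation_pct,
               100 * (1 - adj$trend$log_or_per_year /
                        adj$unadjusted_trend$log_or_per_year),
               tolerance = 1e-10)
  expect_lt(abs(adj$attenuation_pct), 12)

  ## a collinear covariate is dropped with a warning
  p2 <- f$data$panel
  p2$dup_factor <- p2$obesity
  expect_warning(
    adjust_trend_for_risk_factors(pr, p2,
                                  risk_factors = c("obesity", "dup_factor")),
    "collinear")
})

test_that("a secular risk-factor improvement is partly attributed to risk factors", {
  cfg <- small_cohort_config(29, n_core = 5000L,
                             risk_factor_trends = c(obesity = 0, hypertension = 0,
                                                    diabetes = 0, smoking = -0.08,
                                                    inactive = -0.08),
                             true_incidence_trend_or = 0.985)
  cfg$hazard_params$rf_effects[c("smoking", "inactive")] <- c(0.5, 0.5)
  d <- generate_cohort(cfg)
  a <- ascertain_panel(d)
  jm <- suppressWarnings(fit_joint_model(d$panel, a$statuses, a$zscores))
  pr <- predict_dementia_probability(jm, d$panel, a$statuses)
  adj <- adjust_trend_for_risk_factors(pr, d$panel)
  expect_gt(adj$attenuation_pct, 0)
  expect_lt(adj$attenuation_pct, 100)
})

test_that("with non-informative dropout the naive and corrected estimators agree", {
  cfg <- small_cohort_config(31, n_core = 6000L,
                             dropout_params = c(baseline = 0.07,
                                                slope_increment = 0))
  d <- generate_cohort(cfg)
  a <- ascertain_panel(d)
  nv <- fit_naive_trend(d$panel, a$statuses)$trend
  jm <- suppressWarnings(fit_joint_model(d$panel, a$statuses, a$zscores))
  tr <- extract_calendar_trend(predict_dementia_probability(jm, d$panel, a$statuses))
  diff <- abs(tr$log_or_per_year - nv$log_or_per_year)
  expect_lt(diff, 1.96 * sqrt(nv$se_log_or^2 + tr$se_log_or^2) + 0.01)
})

test_that("trend-estimate precision improves with the square root of sample size", {
  se_at <- function(n, seed) {
    d <- generate_cohort(small_cohort_config(seed, n_core = n))
    a <- ascertain_panel(d)
    fit_naive_trend(d$panel, a$statuses)$trend$se_log_or
  }
  se_small <- se_at(1500L, 51)
  se_large <- se_at(6000L, 52)
  ## quadrupling the core sample should roughly halve the standard error
  expect_lt(se_large / se_small, 0.75)
  expect_gt(se_large / se_small, 0.3)
})
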