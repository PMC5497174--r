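#' Configuration for the synthetic ageing-panel generator
#'
#' Builds the full parameter set for [generate_cohort()]. Defaults emulate a
#' six-wave biennial panel of adults aged 50+ (2002-2012, with a seventh
#' wave in 2014 used only to resolve transient impairment at wave 6):
#' a core sample recruited at wave 1 plus refreshment cohorts at waves 3, 4
#' and 6, per-wave cognitive test scores driven by a one-dimensional latent
#' cognitive trajectory with person-level random intercepts and slopes,
#' activities-of-daily-living (ADL) impairment, informant (IQCODE) scores
#' for proxy interviews, doctor-diagnosis flags, cardiovascular disease,
#' cause-specific mortality with a secular decline, and dropout whose
#' hazard may depend on the latent rate of cognitive decline (informative
#' attrition).
#'
#' @param n_core number of participants recruited at wave 1.
#' @param wave_years calendar years of the biennial waves (strictly
#'   increasing, spacing 2).
#' @param recruitment_waves list of refreshment cohorts, each a list with
#'   elements `wave`, `age_range` (length 2) and `n`.
#' @param include_wave7 emit a seventh wave two years after the last
#'   analysis wave (cognition and ADL only used downstream, for wave-6
#'   transience).
#' @param true_incidence_trend_or true per-calendar-year odds ratio applied
#'   to the dementia-onset hazard (0.973 = 2.7\% relative annual decline).
#' @param dropout_params numeric: `baseline` per-epoch dropout probability
#'   and `slope_increment`, the log-odds increase in dropout per standard
#'   deviation of latent cognitive decline (0 = non-informative dropout).
#' @param risk_factor_prevalences named proportions for the binary risk
#'   factors and the three education levels.
#' @param risk_factor_trends per-year log-odds change in each risk factor's
#'   prevalence (0 = calendar-stationary risk factors).
#' @param trajectory_params latent-cognition fixed effects, random-effect
#'   SDs/correlation, residual SD and post-onset decline parameters.
#' @param hazard_params dementia-onset hazard coefficients: intercept,
#'   age terms (age centred at 80, per decade), sex, association with the
#'   latent value (`alpha_value`) and slope (`alpha_slope`), and risk-factor
#'   log-odds effects.
#' @param mortality_params baseline cause-specific mortality rates
#'   (Gompertz in age), per-year secular declines by sex and cause, and
#'   log-odds increments of death for CVD, dementia and functional
#'   impairment (`mortality_link`).
#' @param cvd_params CVD baseline prevalence/incidence coefficients; the
#'   CVD-incidence calendar trend is tied to the CVD mortality decline.
#' @param disability_params onset model for persistent non-dementia
#'   functional impairment and the transient single-wave ADL noise rate.
#' @param seed integer seed; required by [generate_cohort()].
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_core = 11400L,
                          wave_years = seq(2002L, 2012L, by = 2L),
                          recruitment_waves = list(
                            list(wave = 3L, age_range = c(50L, 55L), n = 1500L),
                            list(wave = 4L, age_range = c(50L, 74L), n = 3600L),
                            list(wave = 6L, age_range = c(50L, 55L), n = 1400L)
                          ),
                          include_wave7 = TRUE,
                          true_incidence_trend_or = 0.973,
                          dropout_params = c(baseline = 0.07, slope_increment = 0.9),
                          risk_factor_prevalences = c(
                            education_none = 0.45, education_intermediate = 0.35,
                            education_higher = 0.20,
                            obesity = 0.25, hypertension = 0.40, diabetes = 0.10,
                            smoking = 0.25, inactive = 0.30
                          ),
                          risk_factor_trends = c(obesity = 0, hypertension = 0,
                                                 diabetes = 0, smoking = 0,
                                                 inactive = 0),
                          trajectory_params = list(
                            intercept = 0.25, age_slope = -0.03,
                            education_effects = c(none = -0.45, intermediate = 0,
                                                  higher = 0.35),
                            re_sd = c(intercept = 0.75, slope = 0.045),
                            re_corr = -0.3,
                            resid_sd = 0.45,
                            onset_drop = 2.0, onset_extra_slope = 0.3
                          ),
                          hazard_params = list(
                            intercept = -3.45, age = 1.05, age2 = -0.05,
                            sex_female = 0.12,
                            alpha_value = -0.8, alpha_slope = -14,
                            rf_effects = c(obesity = 0.20, hypertension = 0.15,
                                           diabetes = 0.30, smoking = 0.20,
                                           inactive = 0.30),
                            pre_entry_epochs = 13L,
                            prevalent_survival_decay = 0.45
                          ),
                          mortality_params = list(
                            rate0 = c(cvd_male = 9.3e-4, cvd_female = 6.0e-4,
                                      noncvd_male = 1.76e-3, noncvd_female = 1.15e-3),
                            gompertz_b = c(cvd = 0.108, noncvd = 0.103),
                            trend = c(cvd_male = 0.045, cvd_female = 0.035,
                                      noncvd_male = 0.016, noncvd_female = 0.014),
                            mortality_link = list(
                              cvd = c(cvd = 0.80, dementia = 0.90, fi = 0.40),
                              noncvd = c(cvd = 0.15, dementia = 1.55, fi = 0.50)
                            )
                          ),
                          cvd_params = list(
                            prevalence_intercept = -3.4, prevalence_age = 0.05,
                            prevalence_male = 0.35,
                            incidence_intercept = -4.6, incidence_age = 0.055,
                            incidence_male = 0.40,
                            rf_effects = c(obesity = 0.25, hypertension = 0.35,
                                           diabetes = 0.40, smoking = 0.40,
                                           inactive = 0.25)
                          ),
                          disability_params = list(
                            prevalence_intercept = -4.2, prevalence_age = 0.06,
                            incidence_intercept = -6.0, incidence_age = 0.07,
                            transient_adl_rate = 0.015
                          ),
                          seed = NULL) {
  cfg <- list(
    n_core = as.integer(n_core), wave_years = as.integer(wave_years),
    recruitment_waves = recruitment_waves, include_wave7 = include_wave7,
    true_incidence_trend_or = true_incidence_trend_or,
    dropout_params = dropout_params,
    risk_factor_prevalences = risk_factor_prevalences,
    risk_factor_trends = risk_factor_trends,
    trajectory_params = trajectory_params, hazard_params = hazard_params,
    mortality_params = mortality_params, cvd_params = cvd_params,
    disability_params = disability_params, seed = seed
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_core <= 0L) stopf("n_core must be positive")
  wy <- cfg$wave_years
  if (length(wy) < 2L || any(diff(wy) != 2L)) {
    stopf("wave_years must be strictly increasing with spacing 2")
  }
  if (!is.numeric(cfg$true_incidence_trend_or) ||
      cfg$true_incidence_trend_or <= 0) {
    stopf("true_incidence_trend_or must be a positive odds ratio")
  }
  p0 <- cfg$dropout_params[["baseline"]]
  if (p0 < 0 || p0 > 1) stopf("baseline dropout probability must be in [0,1]")
  rf <- cfg$risk_factor_prevalences
  if (any(rf < 0 | rf > 1)) stopf("risk factor prevalences must be in [0,1]")
  edu <- rf[c("education_none", "education_intermediate", "education_higher")]
  if (abs(sum(edu) - 1) > 1e-8) stopf("education proportions must sum to 1")
  for (rw in cfg$recruitment_waves) {
    if (rw$n <= 0L) stopf("recruitment n must be positive")
    if (!(rw$wave %in% seq_along(wy))) stopf("recruitment wave outside panel")
  }
  invisible(cfg)
}

## Risk-factor status at a calendar year (vectorised over persons and,
## where needed, over per-person years): factor f is present when the
## person's persistent propensity falls below the year-specific prevalence.
rf_at_matrix <- function(rf_u, rfp, rft, year) {
  rf_names <- colnames(rf_u)
  out <- matrix(FALSE, nrow(rf_u), length(rf_names),
                dimnames = list(NULL, rf_names))
  for (f in rf_names) {
    p <- stats::plogis(stats::qlogis(rfp[[f]]) + rft[[f]] * (year - 2006))
    out[, f] <- rf_u[, f] < p
  }
  out
}

## Cause-specific mortality rate (deaths per person-year) used both by the
## cohort simulation and by generate_mortality_series(), so the panel and
## the mortality inputs share one secular structure.
base_mortality_rate <- function(age, sex, cause, year, mp) {
  key <- paste(cause, sex, sep = "_")
  ## trend is the relative annual decline: a 0.02 trend means rates fall
  ## by the factor 0.98 for each calendar year
  mp$rate0[key] * exp(mp$gompertz_b[cause] * (age - 50)) *
    (1 - mp$trend[key])^(year - 2006)
}

## Latent cognitive value at a given age; post-onset dementia accelerates
## decline on top of the linear age trajectory.
latent_cognition <- function(age, b0, b1, edu, tp, onset_age = NULL) {
  m <- tp$intercept + tp$age_slope * (age - 65) +
    tp$education_effects[edu] + b0 + b1 * (age - 65)
  if (!is.null(onset_age)) {
    post <- !is.na(onset_age) & age >= onset_age
    m[post] <- m[post] - tp$onset_drop -
      tp$onset_extra_slope * (age[post] - onset_age[post])
  }
  as.numeric(m)
}

#' Generate a synthetic longitudinal ageing panel with known ground truth
#'
#' Simulates the full panel described in [cohort_config()]: each person has
#' a latent linear cognitive trajectory (random intercept and slope on age),
#' observed domain scores equal to the latent value plus a domain shift and
#' measurement noise, a per-epoch dementia-onset hazard following the
#' configured calendar trend and depending on the latent value and slope,
#' cause-specific mortality with secular decline and elevated odds in
#' impaired states, cardiovascular incidence whose decline parallels CVD
#' mortality, persistent and transient functional impairment, and dropout
#' whose log-odds increase with the latent rate of decline. Deaths are
#' recorded for dropouts too (register linkage). Onsets that occur in an
#' epoch but are followed by death before the next interview remain
#' unobservable to downstream ascertainment, as in a real panel.
#'
#' @param config a [cohort_config()]; `config$seed` must be set.
#' @return an object of class `panel_dataset`: list with `panel` (one row
#'   per person-wave), `truth` (one row per person: random effects, true
#'   onset/death/CVD dates, dropout wave) and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) validate_cohort_config(config)
  if (is.null(config$seed)) stopf("config$seed is required for reproducibility")
  set.seed(config$seed)

  wy <- config$wave_years
  n_waves <- length(wy)
  all_wave_years <- if (isTRUE(config$include_wave7)) c(wy, max(wy) + 2L) else wy
  n_all_waves <- length(all_wave_years)
  tp <- config$trajectory_params
  hp <- config$hazard_params
  mp <- config$mortality_params
  cp <- config$cvd_params
  dp <- config$disability_params
  rfp <- config$risk_factor_prevalences
  rft <- config$risk_factor_trends
  log_or <- log(config$true_incidence_trend_or)

  ## ---- persons ----
  sample_entry_ages <- function(n, lo, hi) {
    ages <- lo:hi
    sample(ages, n, replace = TRUE, prob = exp(-0.055 * (ages - 50)))
  }
  persons <- data.frame(
    entry_wave = rep(1L, config$n_core),
    age_entry = sample_entry_ages(config$n_core, 50L, 89L)
  )
  for (rw in config$recruitment_waves) {
    persons <- rbind(persons, data.frame(
      entry_wave = rep(as.integer(rw$wave), rw$n),
      age_entry = sample_entry_ages(rw$n, rw$age_range[1L], rw$age_range[2L])
    ))
  }
  N <- nrow(persons)
  persons$person_id <- seq_len(N)
  persons$entry_year <- wy[persons$entry_wave]
  persons$sex <- ifelse(stats::runif(N) < 0.54, "female", "male")
  persons$education <- sample(c("none", "intermediate", "higher"), N,
                              replace = TRUE,
                              prob = rfp[c("education_none",
                                           "education_intermediate",
                                           "education_higher")])
  ## latent random effects
  sd_b <- tp$re_sd
  Sigma_b <- matrix(c(sd_b[1L]^2, tp$re_corr * prod(sd_b),
                      tp$re_corr * prod(sd_b), sd_b[2L]^2), 2L, 2L)
  b <- draw_mvn(N, c(0, 0), Sigma_b)
  persons$b0 <- b[, 1L]
  persons$b1 <- b[, 2L]
  persons$latent_slope <- tp$age_slope + persons$b1

  ## persistent propensities for time-varying risk factors: rf present at
  ## year y iff u < plogis(logit(p0) + trend * (y - 2006)); monotone within
  ## person when the trend is monotone.
  rf_names <- c("obesity", "hypertension", "diabetes", "smoking", "inactive")
  rf_u <- matrix(stats::runif(N * 5L), N, 5L, dimnames = list(NULL, rf_names))
  rf_at <- function(year) rf_at_matrix(rf_u, rfp, rft, year)

  ## ---- baseline conditions at entry ----
  female <- persons$sex == "female"
  male <- !female
  agee <- persons$age_entry

  ## Prevalent dementia arises from the same onset hazard run over the
  ## decades before recruitment, so the entry cross-section is at
  ## selection equilibrium with respect to the latent trajectory: the low
  ## tail of latent cognition at each age has already been depleted by
  ## prevalent caseness and by death with dementia, exactly as continued
  ## ascertainment depletes it in-study. Pre-entry onsets k epochs back
  ## survive to recruitment with probability exp(-decay * k); people who
  ## would have died with dementia before entry cannot appear in an alive
  ## sample, so their latent effects are redrawn (rejection sampling from
  ## the alive-at-entry population).
  K_pre <- as.integer(hp$pre_entry_epochs %||% 13L)
  decay <- hp$prevalent_survival_decay %||% 0.25
  rf_eff <- hp$rf_effects[c("obesity", "hypertension", "diabetes",
                            "smoking", "inactive")]
  onset_time <- rep(NA_real_, N)
  need <- rep(TRUE, N)
  for (iter in 1:25) {
    if (!any(need)) break
    idx <- which(need)
    onset_time[idx] <- NA_real_
    died_pre <- rep(FALSE, length(idx))
    for (kk in K_pre:1) {
      y_pre <- persons$entry_year[idx] - 2 * kk
      age_pre <- agee[idx] - 2 * kk
      at_risk <- is.na(onset_time[idx]) & !died_pre
      m_pre <- latent_cognition(age_pre, persons$b0[idx], persons$b1[idx],
                                persons$education[idx], tp, onset_age = NULL)
      rf_pre <- rf_at_matrix(rf_u[idx, , drop = FALSE], rfp, rft, y_pre)
      u <- (age_pre - 80) / 10
      eta <- hp$intercept + hp$age * u + hp$age2 * u^2 +
        hp$sex_female * female[idx] + log_or * (y_pre - 2006) +
        hp$alpha_value * m_pre + hp$alpha_slope * persons$latent_slope[idx] +
        as.vector(rf_pre %*% rf_eff)
      hit <- at_risk & stats::runif(length(idx)) < stats::plogis(eta)
      survives <- stats::runif(length(idx)) < exp(-decay * kk)
      onset_time[idx[hit & survives]] <-
        y_pre[hit & survives] + stats::runif(sum(hit & survives), 0, 2)
      died_pre[hit & !survives] <- TRUE
    }
    ## redraw latent effects for would-be pre-entry dementia deaths
    need[idx] <- died_pre
    nbad <- sum(died_pre)
    if (nbad) {
      bnew <- draw_mvn(nbad, c(0, 0), Sigma_b)
      bi <- idx[died_pre]
      persons$b0[bi] <- bnew[, 1L]
      persons$b1[bi] <- bnew[, 2L]
      persons$latent_slope[bi] <- tp$age_slope + bnew[, 2L]
    }
  }
  prevalent_dem <- !is.na(onset_time)

  p_cvd0 <- stats::plogis(cp$prevalence_intercept +
                            cp$prevalence_age * (agee - 50) +
                            cp$prevalence_male * male)
  cvd_time <- rep(NA_real_, N)
  has_cvd0 <- stats::runif(N) < p_cvd0
  cvd_time[has_cvd0] <- persons$entry_year[has_cvd0] -
    stats::runif(sum(has_cvd0), 0, 10)

  p_fi0 <- stats::plogis(dp$prevalence_intercept + dp$prevalence_age * (agee - 50))
  fi_time <- rep(NA_real_, N)
  has_fi0 <- stats::runif(N) < p_fi0
  fi_time[has_fi0] <- persons$entry_year[has_fi0] - stats::runif(sum(has_fi0), 0, 4)

  ## ---- epoch simulation ----
  death_time <- rep(Inf, N)
  death_cause <- rep(NA_character_, N)
  dropout_wave <- rep(NA_integer_, N)
  dx_ever <- prevalent_dem & stats::runif(N) < 0.60
  p0_drop <- config$dropout_params[["baseline"]]
  d_incr <- config$dropout_params[["slope_increment"]]
  decline_z <- -persons$b1 / sd_b[2L]  # SDs of latent decline (+ = faster decline)

  for (w in seq_len(n_all_waves - 1L)) {
    y <- all_wave_years[w]
    active <- persons$entry_wave <= w & death_time > y
    if (!any(active)) next
    idx <- which(active)
    age_s <- persons$age_entry[idx] + (y - persons$entry_year[idx])
    dem_s <- !is.na(onset_time[idx]) & onset_time[idx] <= y
    cvd_s <- !is.na(cvd_time[idx]) & cvd_time[idx] <= y
    fi_s <- (!is.na(fi_time[idx]) & fi_time[idx] <= y) | dem_s
    rf_now <- rf_at(y)[idx, , drop = FALSE]

    ## dementia onset hazard over [y, y+2)
    u <- (age_s - 80) / 10
    ## pre-onset latent value (hazard applies to the dementia-free only)
    m_s <- latent_cognition(age_s, persons$b0[idx], persons$b1[idx],
                            persons$education[idx], tp, onset_age = NULL)
    eta <- hp$intercept + hp$age * u + hp$age2 * u^2 +
      hp$sex_female * (persons$sex[idx] == "female") +
      log_or * (y - 2006) +
      hp$alpha_value * m_s + hp$alpha_slope * persons$latent_slope[idx] +
      as.vector(rf_now %*% hp$rf_effects[rf_names])
    p_on <- stats::plogis(eta)
    new_onset <- !dem_s & stats::runif(length(idx)) < p_on
    t_on <- rep(Inf, length(idx))
    t_on[new_onset] <- y + stats::runif(sum(new_onset), 0, 2)

    ## cause-specific death over the epoch
    q_c <- 1 - exp(-2 * base_mortality_rate(age_s, persons$sex[idx], "cvd", y, mp))
    q_n <- 1 - exp(-2 * base_mortality_rate(age_s, persons$sex[idx], "noncvd", y, mp))
    lk <- mp$mortality_link
    q_c <- stats::plogis(stats::qlogis(pmax(q_c, 1e-12)) +
                           lk$cvd["cvd"] * cvd_s + lk$cvd["dementia"] * dem_s +
                           lk$cvd["fi"] * (fi_s & !dem_s))
    q_n <- stats::plogis(stats::qlogis(pmax(q_n, 1e-12)) +
                           lk$noncvd["cvd"] * cvd_s + lk$noncvd["dementia"] * dem_s +
                           lk$noncvd["fi"] * (fi_s & !dem_s))
    p_die <- 1 - (1 - q_c) * (1 - q_n)
    dies <- stats::runif(length(idx)) < p_die
    cause <- ifelse(stats::runif(length(idx)) < q_c / (q_c + q_n), "cvd", "noncvd")
    t_de <- rep(Inf, length(idx))
    t_de[dies] <- y + stats::runif(sum(dies), 0, 2)

    ## competition within the epoch: onset stands only if it precedes death
    onset_ok <- new_onset & t_on < t_de
    oi <- idx[onset_ok]
    onset_time[oi] <- t_on[onset_ok]
    di <- idx[dies]
    death_time[di] <- t_de[dies]
    death_cause[di] <- cause[dies]

    ## CVD incidence (decline tied to CVD mortality trend)
    p_cvd <- stats::plogis(cp$incidence_intercept + cp$incidence_age * (age_s - 50) +
                             cp$incidence_male * (persons$sex[idx] == "male") -
                             mp$trend[paste0("cvd_", persons$sex[idx])] * (y - 2006) +
                             as.vector(rf_now %*% cp$rf_effects[rf_names]))
    new_cvd <- !cvd_s & stats::runif(length(idx)) < p_cvd
    ci <- idx[new_cvd]
    cvd_time[ci] <- pmin(y + stats::runif(length(ci), 0, 2), death_time[ci])

    ## persistent non-dementia functional impairment
    p_fi <- stats::plogis(dp$incidence_intercept + dp$incidence_age * (age_s - 50))
    new_fi <- !fi_s & stats::runif(length(idx)) < p_fi
    fi_time[idx[new_fi]] <- y + stats::runif(sum(new_fi), 0, 2)

    ## dropout: miss wave w+1 onwards (only for current attenders)
    attending <- is.na(dropout_wave[idx])
    p_do <- stats::plogis(stats::qlogis(p0_drop) + d_incr * decline_z[idx])
    drops <- attending & stats::runif(length(idx)) < p_do
    dropout_wave[idx[drops]] <- w + 1L

    ## doctor diagnosis accrues among (true) dementia cases
    dem_now <- !is.na(onset_time[idx]) & onset_time[idx] <= y + 2
    dx_new <- dem_now & !dx_ever[idx] & stats::runif(length(idx)) < 0.15
    dx_ever[idx[dx_new]] <- TRUE
  }

  ## ---- wave records ----
  records <- vector("list", n_all_waves)
  for (w in seq_len(n_all_waves)) {
    y <- all_wave_years[w]
    obs <- persons$entry_wave <= w & death_time > y &
      (is.na(dropout_wave) | dropout_wave > w)
    if (!any(obs)) next
    idx <- which(obs)
    n_w <- length(idx)
    age_w <- persons$age_entry[idx] + (y - persons$entry_year[idx])
    onset_age <- persons$age_entry[idx] + (onset_time[idx] - persons$entry_year[idx])
    m_w <- latent_cognition(age_w, persons$b0[idx], persons$b1[idx],
                            persons$education[idx], tp, onset_age = onset_age)
    dem_w <- !is.na(onset_time[idx]) & onset_time[idx] <= y
    cvd_w <- !is.na(cvd_time[idx]) & cvd_time[idx] <= y
    fi_w <- (!is.na(fi_time[idx]) & fi_time[idx] <= y) | dem_w

    ## proxy interviews: mostly for dementia cases (unable to take part)
    proxy <- (dem_w & stats::runif(n_w) < 0.40) |
      (!dem_w & stats::runif(n_w) < 0.005)
    iqcode <- rep(NA_real_, n_w)
    iqcode[proxy & dem_w] <- pmin(5, pmax(1, stats::rnorm(sum(proxy & dem_w), 4.05, 0.30)))
    iqcode[proxy & !dem_w] <- pmin(5, pmax(1, stats::rnorm(sum(proxy & !dem_w), 3.0, 0.25)))

    ## cognitive battery (missing for proxy interviews)
    noise <- function() stats::rnorm(n_w, 0, tp$resid_sd)
    sc <- data.frame(
      orientation = m_w + 0.00 + noise(),
      immediate_recall = m_w + 0.05 + noise(),
      delayed_recall = m_w - 0.05 + noise(),
      verbal_fluency = m_w + 0.02 + noise()
    )
    sc$numeracy <- if (w %in% c(1L, 4L, 6L)) m_w + noise() else NA_real_
    sc$literacy <- if (w == 6L) m_w + noise() else NA_real_
    ## a small fraction answer too few tests for a valid assessment
    short <- !proxy & stats::runif(n_w) < 0.02
    sc$delayed_recall[short] <- NA_real_
    sc$verbal_fluency[short] <- NA_real_
    sc$numeracy[short] <- NA_real_
    sc$literacy[short] <- NA_real_
    sc[proxy, ] <- NA_real_
    n_tests <- rowSums(!is.na(sc))

    ## ADL impairment count (0-7)
    adl <- integer(n_w)
    adl[dem_w] <- 1L + stats::rbinom(sum(dem_w), 6L, 0.55)
    pfi <- fi_w & !dem_w
    adl[pfi] <- 1L + stats::rbinom(sum(pfi), 6L, 0.25)
    trans <- !fi_w & !dem_w & stats::runif(n_w) < dp$transient_adl_rate
    adl[trans] <- 1L

    rf_now <- rf_at(y)[idx, , drop = FALSE]
    records[[w]] <- data.frame(
      person_id = persons$person_id[idx], wave = w, year = y, age = age_w,
      sex = persons$sex[idx], education = persons$education[idx],
      sc,
      n_tests_answered = n_tests,
      adl_impaired_count = adl,
      iqcode = iqcode,
      proxy_interview = proxy,
      doctor_dx_dementia = dx_ever[idx] & dem_w,
      cvd_status = cvd_w,
      obesity = rf_now[, "obesity"], hypertension = rf_now[, "hypertension"],
      diabetes = rf_now[, "diabetes"], smoking = rf_now[, "smoking"],
      inactive = rf_now[, "inactive"],
      weight = 1
    )
  }
  panel <- do.call(rbind, records)
  panel <- panel[order(panel$person_id, panel$wave), ]
  rownames(panel) <- NULL

  ## register linkage: vital status known for everyone, dropouts included
  panel$death_year <- death_time[panel$person_id]
  panel$death_year[!is.finite(panel$death_year)] <- NA_real_
  panel$death_cause <- death_cause[panel$person_id]
  panel$vital_status <- ifelse(is.na(panel$death_year), "alive", "dead")
  panel$dropped_out <- !is.na(dropout_wave[panel$person_id])

  truth <- data.frame(
    person_id = persons$person_id, sex = persons$sex,
    education = persons$education,
    entry_wave = persons$entry_wave, entry_year = persons$entry_year,
    age_entry = persons$age_entry,
    b0 = persons$b0, b1 = persons$b1, latent_slope = persons$latent_slope,
    prevalent_dementia = prevalent_dem,
    true_onset_year = onset_time,
    cvd_onset_year = cvd_time, fi_onset_year = fi_time,
    death_year = ifelse(is.finite(death_time), death_time, NA_real_),
    death_cause = death_cause,
    dropout_wave = dropout_wave,
    dropped_out = !is.na(dropout_wave)
  )

  structure(list(panel = panel, truth = truth, config = config,
                 wave_years = all_wave_years, analysis_waves = seq_len(n_waves)),
            class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("Synthetic panel: %d persons, %d person-waves, waves %s (%s)\n",
              nrow(x$truth), nrow(x$panel),
              paste(range(x$panel$wave), collapse = "-"),
              paste(range(x$panel$year), collapse = "-")))
  cat(sprintf("  true incidence trend OR/year: %.4f; dropout increment: %.2f\n",
              x$config$true_incidence_trend_or,
              x$config$dropout_params[["slope_increment"]]))
  invisible(x)
}

#' Generate an age-sex-cause mortality rate series
#'
#' Log-linear declining, Gompertz-graded cause-specific mortality rates in
#' five-year age bands, emulating national death-registration series. Uses
#' the same rate model as the cohort simulation.
#'
#' @param years calendar years covered (default 1990-2012).
#' @param mortality_params as in [cohort_config()]; `trend` entries are the
#'   per-year proportional declines by cause and sex.
#' @param age_bands lower edges of the 5-year bands from 35 to 100 (the last
#'   band is open, 100+).
#' @param state_mix_adjust scale the base (healthy) rates up by the
#'   expected state-specific mortality excess under rough age profiles of
#'   CVD, dementia and functional impairment, so the series represents
#'   population-average rates as a national registry would (default TRUE).
#' @return a tidy data.frame: year, sex, age_band, cause, value (deaths per
#'   person-year), of class `mortality_series`.
#' @export
generate_mortality_series <- function(years = 1990:2012,
                                      mortality_params = cohort_config(seed = 1)$mortality_params,
                                      age_bands = seq(35L, 100L, by = 5L),
                                      state_mix_adjust = TRUE) {
  if (length(years) < 1L) stopf("at least one year required")
  if (any(unlist(mortality_params$rate0) < 0)) stopf("negative baseline rate")
  grid <- expand.grid(year = years, sex = c("male", "female"),
                      age_lo = age_bands, cause = c("cvd", "noncvd"),
                      stringsAsFactors = FALSE)
  mid <- ifelse(grid$age_lo == 100L, 102, grid$age_lo + 2)
  grid$value <- base_mortality_rate(mid, grid$sex, grid$cause, grid$year,
                                    mortality_params)
  if (isTRUE(state_mix_adjust)) {
    ## a national series measures population-average rates: the healthy
    ## base rate times the expected state-specific excess, under rough
    ## age profiles of CVD, dementia and functional impairment
    pi_cvd <- stats::plogis(-3.4 + 0.05 * (mid - 50) +
                              0.35 * (grid$sex == "male"))
    pi_dem <- stats::plogis(-7.2 + 0.105 * (mid - 50))
    pi_fi <- stats::plogis(-4.2 + 0.06 * (mid - 50))
    lk <- mortality_params$mortality_link
    for (cause in c("cvd", "noncvd")) {
      i <- grid$cause == cause
      mult <- 1 + pi_cvd[i] * (exp(lk[[cause]]["cvd"]) - 1) +
        pi_dem[i] * (exp(lk[[cause]]["dementia"]) - 1) +
        pi_fi[i] * (exp(lk[[cause]]["fi"]) - 1)
      grid$value[i] <- grid$value[i] * mult
    }
  }
  grid$age_band <- ifelse(grid$age_lo == 100L, "100+",
                          paste(grid$age_lo, grid$age_lo + 4L, sep = "-"))
  out <- grid[order(grid$year, grid$sex, grid$cause, grid$age_lo),
              c("year", "sex", "age_band", "age_lo", "cause", "value")]
  rownames(out) <- NULL
  class(out) <- c("mortality_series", "data.frame")
  out
}

#' Generate the population structure inputs for the projection engine
#'
#' Returns the base-year population by single year of age (35 to 100+) and
#' sex, plus the series of 35-year-old entrants for each future calendar
#' year. Defaults synthesise an England-and-Wales-like structure: a fixed
#' entering cohort per sex with the base-year age profile given by survival
#' under the generator's 2006 mortality rates.
#'
#' @param base_counts optional data.frame (age, sex, count) for the base
#'   year; must cover every age 35-100 for both sexes.
#' @param entry_series optional data.frame (year, sex, count) of entrants at
#'   age 35; defaults to a constant cohort through `horizon_year`.
#' @param base_year first modelled year (default 2006).
#' @param horizon_year last year entrants are needed for (default 2040).
#' @param entry_size entrants per sex per year used when `entry_series` is
#'   NULL.
#' @param mortality_params rate model used to shape the default age profile.
#' @return an object of class `population_inputs`: list(base_year, base,
#'   entrants).
#' @export
generate_population_structure <- function(base_counts = NULL,
                                          entry_series = NULL,
                                          base_year = 2006L,
                                          horizon_year = 2040L,
                                          entry_size = 380000,
                                          mortality_params = cohort_config(seed = 1)$mortality_params) {
  ages <- 35:100
  if (is.null(base_counts)) {
    base_counts <- do.call(rbind, lapply(c("male", "female"), function(sx) {
      ## cohort survival: a person aged a lived most of their adult life
      ## under the (higher) historical rates, approximated by evaluating
      ## the rate at the mid-point year of their exposure
      yr_mid <- base_year - (ages - 35) / 2
      r <- base_mortality_rate(ages, sx, "cvd", yr_mid, mortality_params) +
        base_mortality_rate(ages, sx, "noncvd", yr_mid, mortality_params)
      surv <- exp(-cumsum(c(0, r[-length(r)])))
      data.frame(age = ages, sex = sx, count = entry_size * surv)
    }))
  }
  for (sx in c("male", "female")) {
    have <- base_counts$age[base_counts$sex == sx]
    if (!all(ages %in% have)) {
      stopf("base_counts missing age cells for sex %s", sx)
    }
  }
  if (any(base_counts$count < 0)) stopf("population counts must be non-negative")
  if (is.null(entry_series)) {
    entry_series <- expand.grid(year = base_year:horizon_year,
                                sex = c("male", "female"),
                                stringsAsFactors = FALSE)
    entry_series$count <- entry_size
  }
  structure(list(base_year = as.integer(base_year),
                 base = base_counts[order(base_counts$sex, base_counts$age), ],
                 entrants = entry_series),
            class = "population_inputs")
}

#' Write a panel dataset to CSV (panel + ground-truth sidecar)
#'
#' @param dataset a `panel_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_panel_csv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "panel.csv")
  tp <- file.path(dir, "truth.csv")
  utils::write.csv(dataset$panel, pp, row.names = FALSE)
  utils::write.csv(dataset$truth, tp, row.names = FALSE)
  invisible(c(panel = pp, truth = tp))
}
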