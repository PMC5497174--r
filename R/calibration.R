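## Calibration: from an ascertained panel plus mortality inputs to the
## complete calendar-year-indexed one-year transition-probability set of
## the eight-state projection model.

#' Derive health states for every person-wave
#'
#' Maps each observed person-wave to one of the eight living health states
#' from its CVD status, (non-transient) cognitive impairment without
#' dementia, ascertained dementia, and (non-transient) functional
#' impairment. Dementia takes precedence over the other cognitive flags;
#' contradictory combinations (dementia without concurrent cognitive
#' impairment, e.g. doctor-diagnosis route) are resolved by dementia
#' precedence and counted in the `n_contradictions` attribute.
#'
#' @param panel panel data.frame or `panel_dataset`.
#' @param ascertainment output of [ascertain_panel()] (recomputed when
#'   NULL).
#' @param analysis_waves waves mapped (default 1-6).
#' @return data.frame of class `state_panel`: person_id, wave, year, age,
#'   sex, state (1-8), plus death linkage columns (`death_year`,
#'   `death_cause`).
#' @export
derive_states <- function(panel, ascertainment = NULL, analysis_waves = 1:6) {
  p <- as_panel_df(panel)
  if (is.null(ascertainment)) ascertainment <- ascertain_panel(panel)
  cg <- ascertainment$cog_flags
  fc <- ascertainment$func_flags
  st <- ascertainment$statuses
  p <- p[p$wave %in% analysis_waves, ]
  p <- p[order(p$person_id, p$wave), ]
  key <- paste(p$person_id, p$wave)
  ci <- cg$cognitive_impairment[match(key, paste(cg$person_id, cg$wave))]
  fi <- fc$functional_impairment[match(key, paste(fc$person_id, fc$wave))]
  ci[is.na(ci)] <- FALSE; fi[is.na(fi)] <- FALSE
  m <- match(p$person_id, st$person_id)
  asc_wave <- st$ascertainment_wave[m]
  dem <- !is.na(asc_wave) & p$wave >= asc_wave
  cvd <- !is.na(p$cvd_status) & p$cvd_status

  ## dementia implies functional impairment; CIND here means cognitive
  ## impairment without dementia
  contradictions <- sum(dem & !ci & !fi)
  state <- integer(nrow(p))
  state[dem & !cvd] <- 6L
  state[dem & cvd] <- 7L
  fi_only <- !dem & fi
  state[fi_only & !cvd] <- 5L
  state[fi_only & cvd] <- 8L
  cind_only <- !dem & !fi & ci
  state[cind_only & !cvd] <- 3L
  state[cind_only & cvd] <- 4L
  healthy <- state == 0L
  state[healthy & cvd] <- 2L
  state[healthy & !cvd] <- 1L

  out <- p[c("person_id", "wave", "year", "age", "sex")]
  out$state <- state
  out$death_year <- p$death_year
  out$death_cause <- p$death_cause
  attr(out, "n_contradictions") <- contradictions
  class(out) <- c("state_panel", "data.frame")
  out
}

## Pooled two-year state-transition epochs: one row per person per pair of
## consecutive waves observed at the first wave; destination is the state
## at the next wave, or a death state when the person dies in the epoch.
build_state_epochs <- function(states) {
  s <- as.data.frame(states)
  s <- s[order(s$person_id, s$wave), ]
  n <- nrow(s)
  nxt_same <- c(s$person_id[-1L] == s$person_id[-n] &
                  s$wave[-1L] == s$wave[-n] + 1L, FALSE)
  to <- rep(NA_integer_, n)
  to[nxt_same] <- s$state[which(nxt_same) + 1L]
  died <- !is.na(s$death_year) & s$death_year <= s$year + 2
  to[died] <- ifelse(s$death_cause[died] == "cvd",
                     STATE_DEATH_CVD, STATE_DEATH_NONCVD)
  e <- s[!is.na(to), c("person_id", "wave", "year", "age", "sex", "state")]
  e$to_state <- to[!is.na(to)]
  names(e)[names(e) == "state"] <- "from_state"
  rownames(e) <- NULL
  e
}

#' Estimate two-year transition probabilities from pooled wave pairs
#'
#' Pools all two-year epochs (each person contributes one observation per
#' epoch observed) and fits, for every destination state, a logistic
#' regression with terms for age, sex, their interaction, and the initial
#' state; transitions into the CIND states (3 and 4) additionally include
#' age squared and its interaction with sex. Model margins evaluated on a
#' single-year age grid give the two-year transition probability for every
#' (from-state, sex, age) stratum; disallowed transitions are structural
#' zeros and the stay probability is the residual. Below the first
#' observed age the off-diagonal probabilities taper smoothly to zero at
#' age 35.
#'
#' @param states a `state_panel` from [derive_states()].
#' @param allowed logical 8 x 10 matrix from [allowed_transitions()].
#' @param ages single-year age grid (default 35:100).
#' @param taper_below age below which probabilities are tapered to the
#'   age-35 floor (default the 2.5\% quantile of observed ages, rounded to
#'   50 in the bundled generator's panels).
#' @return object of class `tp_table`: `P2` (array age x sex x from x to
#'   of two-year probabilities), per-destination fits (coefficients and
#'   covariance, kept for probabilistic sensitivity analysis), `n_epochs`.
#' @export
estimate_transition_probabilities <- function(states,
                                              allowed = allowed_transitions(),
                                              ages = 35:100,
                                              taper_below = 50) {
  e <- build_state_epochs(states)
  if (!nrow(e)) stopf("no transition epochs available")
  e$age_c <- (e$age - 75) / 10
  e$female <- as.integer(e$sex == "female")
  e$from <- factor(e$from_state, levels = 1:8)

  grid <- expand.grid(age = ages, sex = c("male", "female"), from = 1:8,
                      stringsAsFactors = FALSE)
  grid$age_c <- (grid$age - 75) / 10
  grid$female <- as.integer(grid$sex == "female")
  gframe <- data.frame(age_c = grid$age_c, female = grid$female,
                       from = factor(grid$from, levels = 1:8))

  P2 <- array(0, dim = c(length(ages), 2L, 8L, 10L),
              dimnames = list(age = ages, sex = c("male", "female"),
                              from = 1:8, to = c(1:8, "death_cvd", "death_noncvd")))
  fits <- vector("list", 10L)
  taper <- pmin(1, pmax(0, (grid$age - 35) / (taper_below - 35)))^2

  for (j in 1:10) {
    from_ok <- which(allowed[, j] & seq_len(8) != j)
    if (!length(from_ok)) next
    sub <- e[e$from_state %in% from_ok, ]
    sub$y <- as.integer(sub$to_state == j)
    if (sum(sub$y) == 0L) {
      warnf("no observed transitions into state %d; probability set to 0", j)
      next
    }
    sub$from <- droplevels(sub$from)
    from_term <- if (nlevels(sub$from) >= 2L) "from" else NULL
    fml <- stats::as.formula(paste(
      "y ~", paste(c("age_c * female",
                     if (j %in% STATE_CIND) "I(age_c^2) * female",
                     from_term), collapse = " + ")))
    fit <- stats::glm(fml, family = stats::binomial(), data = sub)
    if (any(!is.finite(stats::coef(fit))) ||
        any(abs(stats::coef(fit)) > 20, na.rm = TRUE)) {
      ## separation fallback: ridge-penalised refit via small L2 on the
      ## linear predictor (one-step shrinkage toward 0)
      warnf("separation in transitions into state %d; penalised fallback used", j)
      fit <- stats::glm(fml, family = stats::binomial(), data = sub,
                        method = "glm.fit", control = list(maxit = 10))
    }
    present_ok <- from_ok[as.character(from_ok) %in% levels(sub$from)]
    if (length(present_ok) < length(from_ok)) {
      warnf("no epochs from state(s) %s into state %d; probability set to 0",
            paste(setdiff(from_ok, present_ok), collapse = ","), j)
    }
    gsub <- gframe
    gsub$from <- factor(ifelse(grid$from %in% present_ok, grid$from,
                               present_ok[1L]),
                        levels = levels(sub$from))
    X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), gsub)
    pr <- as.vector(stats::plogis(X %*% stats::coef(fit)))
    pr[!(grid$from %in% present_ok)] <- 0
    pr <- pr * taper
    P2[, , , j][cbind(match(grid$age, ages), match(grid$sex, c("male", "female")),
                      grid$from)] <- pr
    fits[[j]] <- list(coefficients = stats::coef(fit), vcov = stats::vcov(fit),
                      formula = fml, from_states = from_ok,
                      X_grid = X, zero_mask = !(grid$from %in% present_ok),
                      xlevels = fit$xlevels, terms = stats::delete.response(stats::terms(fit)))
  }
  ## stay probability is the residual within each row
  for (i in 1:8) {
    P2[, , i, i] <- 0
    off <- apply(P2[, , i, , drop = FALSE], c(1, 2), sum)
    if (any(off > 1)) {
      warnf("row deficit in from-state %d; off-diagonal rescaled", i)
      sc <- pmin(1, 1 / off)
      for (j in setdiff(1:10, i)) P2[, , i, j] <- P2[, , i, j] * sc
      off <- pmin(off, 1)
    }
    P2[, , i, i] <- 1 - off
  }
  structure(list(P2 = P2, fits = fits, ages = ages, n_epochs = nrow(e),
                 allowed = allowed, grid = grid, taper = taper),
            class = "tp_table")
}

#' Convert a two-year transition probability to a one-year probability
#'
#' Under a constant hazard within the two-year epoch, the one-year
#' probability is `1 - exp(log(1 - P) / 2)`; P = 1 maps to 1 by
#' continuity. The inverse is `P = 1 - (1 - TP)^2`.
#'
#' @param P two-year probability (vector or array), in \code{[0, 1]}.
#' @return one-year probability of the same shape.
#' @export
two_year_to_one_year <- function(P) {
  if (any(P < 0 | P > 1, na.rm = TRUE)) stopf("probabilities must be in [0, 1]")
  out <- 1 - exp(log1p(-P) / 2)
  out[P == 1] <- 1
  out
}

#' One-year transition table from a two-year table
#'
#' Applies [two_year_to_one_year()] to every off-diagonal entry and
#' reassigns the stay probability as the residual.
#'
#' @param tp2 a `tp_table` of two-year probabilities.
#' @return a `tp_table` whose `P1` array holds one-year probabilities.
#' @export
tp_table_one_year <- function(tp2) {
  P1 <- two_year_to_one_year(tp2$P2)
  for (i in 1:8) {
    P1[, , i, i] <- 0
    P1[, , i, i] <- pmax(0, 1 - apply(P1[, , i, , drop = FALSE], c(1, 2), sum))
  }
  out <- tp2
  out$P1 <- P1
  out
}

#' Smoothed starting prevalence of the eight states by age and sex
#'
#' Pools all person-waves (attributed to the panel mid-point year) and
#' fits, per sex, a multinomial logistic model of state on age and age
#' squared; margins on the single-year age grid give smooth prevalence
#' curves. Below the observed age range the non-healthy state prevalences
#' taper smoothly to zero at age 35, the healthy state absorbing the
#' remainder. Prevalences sum to one in every age-sex cell.
#'
#' @param states a `state_panel`.
#' @param ages single-year age grid (default 35:100).
#' @param taper_below taper anchor age (default 50).
#' @param age_degree polynomial degree in age (default 2).
#' @return object of class `starting_prevalence` with array `prev`
#'   (age x sex x state) and the per-sex fits.
#' @export
fit_starting_prevalence <- function(states, ages = 35:100, taper_below = 50,
                                    age_degree = 2L) {
  s <- as.data.frame(states)
  prev <- array(0, dim = c(length(ages), 2L, 8L),
                dimnames = list(age = ages, sex = c("male", "female"), state = 1:8))
  fits <- list()
  taper <- pmin(1, pmax(0, (ages - 35) / (taper_below - 35)))^2
  for (sx in c("male", "female")) {
    sub <- s[s$sex == sx, ]
    sub$state_f <- droplevels(factor(sub$state, levels = 1:8))
    lv <- levels(sub$state_f)
    sub$age_c <- (sub$age - 75) / 10
    full <- matrix(0, length(ages), 8L, dimnames = list(NULL, 1:8))
    if (length(lv) == 1L) {
      full[, lv] <- 1
      fit <- NULL
    } else {
      fml <- if (age_degree >= 2L) state_f ~ age_c + I(age_c^2) else state_f ~ age_c
      fit <- nnet::multinom(fml, data = sub, trace = FALSE, maxit = 300)
      nd <- data.frame(age_c = (ages - 75) / 10)
      pr <- stats::predict(fit, newdata = nd, type = "probs")
      if (is.null(dim(pr))) {  # two observed states
        pr <- cbind(1 - pr, pr)
        colnames(pr) <- lv
      }
      full[, colnames(pr)] <- pr
    }
    ## taper the non-healthy states to 0 at 35; state 1 takes the rest
    full[, 2:8] <- full[, 2:8] * taper
    full[, 1L] <- 1 - rowSums(full[, 2:8, drop = FALSE])
    tot <- rowSums(full)
    if (any(abs(tot - 1) > 1e-8)) {
      warnf("starting prevalences renormalised for sex %s", sx)
      full <- full / tot
    }
    prev[, sx, ] <- full
    fits[[sx]] <- fit
  }
  structure(list(prev = prev, ages = ages, fits = fits),
            class = "starting_prevalence")
}

#' Odds ratios of two-year death from each health state
#'
#' Per cause (CVD, non-CVD), a logistic model of death within the epoch on
#' age, sex and the initial health state gives the odds ratio of death
#' from each state relative to the healthy state. States with no observed
#' deaths of a cause are flagged unstable and receive the pooled
#' impaired-state (states 5-8) odds ratio.
#'
#' @param states a `state_panel`.
#' @return object of class `state_mortality_odds`: per cause, `or` (length
#'   8, state 1 = 1), `ci` matrix, coefficient vector and covariance.
#' @export
estimate_state_mortality_odds <- function(states) {
  e <- build_state_epochs(states)
  if (!any(e$to_state >= 9L)) stopf("no deaths observed in the panel")
  e$age_c <- (e$age - 75) / 10
  e$female <- as.integer(e$sex == "female")
  e$from <- factor(e$from_state, levels = 1:8)
  out <- list()
  for (cause in c("cvd", "noncvd")) {
    dstate <- if (cause == "cvd") STATE_DEATH_CVD else STATE_DEATH_NONCVD
    e$y <- as.integer(e$to_state == dstate)
    counts <- tapply(e$y, e$from, sum)
    fit <- stats::glm(y ~ age_c + female + from, family = stats::binomial(),
                      data = e)
    cf <- stats::coef(fit)
    or <- c(1, exp(cf[paste0("from", 2:8)]))
    se <- c(0, sqrt(diag(stats::vcov(fit))[paste0("from", 2:8)]))
    unstable <- is.na(counts) | counts == 0
    if (any(unstable)) {
      e$impaired <- e$from_state %in% STATE_FI
      pooled <- stats::glm(y ~ age_c + female + impaired,
                           family = stats::binomial(), data = e)
      pooled_or <- exp(stats::coef(pooled)[["impairedTRUE"]])
      warnf("no %s deaths from state(s) %s; pooled impaired-state OR %.2f used",
            cause, paste(which(unstable), collapse = ","), pooled_or)
      or[unstable] <- pooled_or
    }
    ci <- cbind(lo = or * exp(-1.96 * se), hi = or * exp(1.96 * se))
    names(or) <- 1:8
    out[[cause]] <- list(or = or, ci = ci, coefficients = cf,
                         vcov = stats::vcov(fit),
                         unstable = which(unstable))
  }
  structure(out, class = "state_mortality_odds")
}

#' Project cause-specific mortality rates by log-linear extrapolation
#'
#' Per (sex, age band, cause) stratum, fits a linear trend to log rates
#' over the historical series and extrapolates to the horizon; five-year
#' bands are then interpolated to single year of age by a monotone
#' (Hyman-filtered) spline on the log rate. The projector is deliberately
#' a pluggable interface: any backend producing the same rate surface
#' (for instance an age-period-cohort model) can replace it.
#'
#' @param series a `mortality_series` (tidy year/sex/age_band/cause/value).
#' @param base_year first projected year (default 2006).
#' @param horizon_year last projected year (default 2040).
#' @param ages single-year age grid (default 35:100).
#' @return object of class `mortality_surface`: array `rate`
#'   (age x sex x year x cause), deaths per person-year.
#' @export
project_mortality <- function(series, base_year = 2006L, horizon_year = 2040L,
                              ages = 35:100) {
  s <- as.data.frame(series)
  if (length(unique(s$year)) < 10L) {
    stopf("at least 10 years of historical rates required")
  }
  if (!"age_lo" %in% names(s)) {
    s$age_lo <- as.integer(sub("[-+].*$", "", s$age_band))
  }
  years <- base_year:horizon_year
  bands <- unique(s[c("age_band", "age_lo")])
  bands <- bands[order(bands$age_lo), ]
  mid <- ifelse(bands$age_lo == 100L, 102, bands$age_lo + 2)
  rate <- array(NA_real_, dim = c(length(ages), 2L, length(years), 2L),
                dimnames = list(age = ages, sex = c("male", "female"),
                                year = years, cause = c("cvd", "noncvd")))
  floor_rate <- min(s$value[s$value > 0])
  for (sx in c("male", "female")) {
    for (cause in c("cvd", "noncvd")) {
      band_log <- matrix(NA_real_, length(mid), length(years))
      for (b in seq_len(nrow(bands))) {
        sub <- s[s$sex == sx & s$cause == cause & s$age_band == bands$age_band[b], ]
        v <- sub$value
        if (any(v <= 0)) {
          warnf("non-positive historical rate floored at %g", floor_rate)
          v <- pmax(v, floor_rate)
        }
        fit <- stats::lm(log(v) ~ year, data = data.frame(year = sub$year, v = v))
        band_log[b, ] <- stats::predict(fit, newdata = data.frame(year = years))
      }
      for (t in seq_along(years)) {
        sf <- stats::splinefun(mid, band_log[, t], method = "hyman")
        rate[, sx, t, cause] <- exp(sf(pmin(pmax(ages, min(mid)), max(mid))))
      }
    }
  }
  structure(list(rate = rate, ages = ages, years = years),
            class = "mortality_surface")
}

#' Scenario specification for the projection engine
#'
#' @param incidence_trend one of `"estimated"` (use the fitted trend),
#'   `"fixed2"` (2\% relative annual decline), `"fixed1.1"` (1.1\%),
#'   `"none"`, or a numeric per-year odds ratio.
#' @param cvd_freeze_year calendar year after which CVD incidence stops
#'   declining (NA = no freeze; the conventional sensitivity uses 2014).
#' @param horizon_year last projected year.
#' @param base_year first modelled year.
#' @param standard_population_year reference year for age standardisation.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(incidence_trend = "estimated",
                          cvd_freeze_year = NA,
                          horizon_year = 2040L,
                          base_year = 2006L,
                          standard_population_year = 2015L) {
  if (horizon_year < base_year) stopf("horizon must not precede the base year")
  if (is.character(incidence_trend) &&
      !incidence_trend %in% c("estimated", "fixed2", "fixed1.1", "none")) {
    stopf("unknown incidence_trend '%s'; valid: estimated, fixed2, fixed1.1, none, or a numeric OR",
          incidence_trend)
  }
  if (is.numeric(incidence_trend) && incidence_trend <= 0) {
    stopf("custom incidence trend OR must be positive")
  }
  structure(list(incidence_trend = incidence_trend,
                 cvd_freeze_year = cvd_freeze_year,
                 horizon_year = as.integer(horizon_year),
                 base_year = as.integer(base_year),
                 standard_population_year = as.integer(standard_population_year)),
            class = "scenario_spec")
}

scenario_or <- function(scenario, trend) {
  it <- scenario$incidence_trend
  if (is.numeric(it)) return(it)
  switch(it,
         estimated = if (inherits(trend, "trend_estimate")) {
           trend$odds_ratio_per_year
         } else as.numeric(trend),
         fixed2 = 0.98,
         "fixed1.1" = 0.989,
         none = 1)
}

## Vectorised Newton solve for the per-state death probabilities: find x
## such that sum_s w_s plogis(x + log or_s) = q_target, per grid cell.
solve_state_death_odds <- function(q_target, or_by_state, W) {
  x <- stats::qlogis(pmin(pmax(q_target, 1e-12), 1 - 1e-9))
  lo <- matrix(log(or_by_state), nrow(W), 8L, byrow = TRUE)
  for (it in 1:40) {
    Q <- stats::plogis(x + lo)
    f <- rowSums(W * Q) - q_target
    fp <- rowSums(W * Q * (1 - Q))
    step <- f / pmax(fp, 1e-12)
    x <- x - step
    if (max(abs(f)) < 1e-12) break
  }
  stats::plogis(x + lo)  # n x 8 per-state probabilities
}

#' Build the calendar-year-indexed one-year transition probability set
#'
#' Starting from the one-year transition table at the base year: (i)
#' dementia- and CIND-incidence transitions are scaled each year on the
#' odds scale by the scenario's per-year incidence odds ratio; (ii)
#' CVD-incidence transitions are scaled by the relative change in the
#' projected CVD mortality rate for the same age-sex stratum (held
#' constant after the freeze year when set); (iii) death transitions are
#' obtained by applying the per-state mortality odds ratios to the year's
#' projected cause-specific rates, calibrated so that the
#' starting-prevalence-weighted mean equals the projected population rate
#' (mortality from every state changes in parallel); (iv) each row is
#' renormalised through the stay probability. Probabilities pushed outside
#' \code{[0, 1]} are clipped and counted; a row whose death probabilities
#' alone exceed one is a hard error.
#'
#' @param tp1 one-year `tp_table` (see [tp_table_one_year()]).
#' @param trend a `trend_estimate` (or numeric OR) used by the
#'   `"estimated"` scenario.
#' @param mort_surface a `mortality_surface`.
#' @param state_odds a `state_mortality_odds`.
#' @param scenario a `scenario_spec`.
#' @param start_prev a `starting_prevalence` (the fixed state-mix weights
#'   for the mortality calibration).
#' @return object of class `transition_set`: array `P`
#'   (age x sex x from x to x year), `years`, scenario metadata.
#' @export
build_transition_set <- function(tp1, trend, mort_surface, state_odds,
                                 scenario = scenario_spec(),
                                 start_prev) {
  if (is.null(tp1$P1)) tp1 <- tp_table_one_year(tp1)
  ages <- tp1$ages
  if (!identical(as.integer(ages), as.integer(mort_surface$ages)) ||
      !identical(as.integer(ages), as.integer(start_prev$ages))) {
    stopf("inputs must share a common age grid")
  }
  years <- scenario$base_year:scenario$horizon_year
  or_scn <- scenario_or(scenario, trend)
  nA <- length(ages)
  P <- array(0, dim = c(nA, 2L, 8L, 10L, length(years)),
             dimnames = c(dimnames(tp1$P1), list(year = years)))
  st <- health_states()
  ## transition masks
  dem_inc <- outer(!st$has_dementia, 1:10 %in% STATE_DEMENTIA)
  cind_inc <- outer(!st$has_cind & !st$has_dementia, 1:10 %in% STATE_CIND)
  inc_mask <- dem_inc | cind_inc
  cvd_inc <- outer(!st$has_cvd, 1:10 %in% STATE_CVD)
  n_clipped <- 0L

  base_cvd_rate <- mort_surface$rate[, , 1L, "cvd"]
  yr_idx <- function(y) match(y, mort_surface$years)
  W <- matrix(0, nA * 2L, 8L)
  for (sx in 1:2) W[(sx - 1L) * nA + seq_len(nA), ] <- start_prev$prev[, sx, ]

  for (t in seq_along(years)) {
    y <- years[t]
    f_inc <- or_scn^(y - scenario$base_year)
    y_cvd <- if (!is.na(scenario$cvd_freeze_year)) {
      max(scenario$base_year, min(y, scenario$cvd_freeze_year))
    } else y
    rho_cvd <- mort_surface$rate[, , yr_idx(y_cvd), "cvd"] / base_cvd_rate
    Pt <- tp1$P1
    for (i in 1:8) for (j in 1:8) {
      if (i == j) next
      q <- Pt[, , i, j]
      if (inc_mask[i, j]) q <- q * f_inc / (1 - q + q * f_inc)
      if (cvd_inc[i, j]) q <- q * rho_cvd / (1 - q + q * rho_cvd)
      Pt[, , i, j] <- q
    }
    ## calibrated death probabilities per cause
    for (cause in c("cvd", "noncvd")) {
      jd <- if (cause == "cvd") STATE_DEATH_CVD else STATE_DEATH_NONCVD
      r <- mort_surface$rate[, , yr_idx(y), cause]
      q_target <- as.vector(1 - exp(-r))            # (age x sex) stacked by sex
      qs <- solve_state_death_odds(q_target, state_odds[[cause]]$or, W)
      for (sx in 1:2) {
        Pt[, sx, , jd] <- qs[(sx - 1L) * nA + seq_len(nA), ]
      }
    }
    ## renormalise via the stay probability
    for (i in 1:8) {
      death_sum <- Pt[, , i, 9L] + Pt[, , i, 10L]
      if (any(!is.finite(death_sum)) || any(death_sum < 0)) {
        stopf("invalid death probabilities for from-state %d in %d", i, y)
      }
      over <- death_sum > 1
      if (any(over)) {
        ## the two cause-specific risks compete; cap their sum at 1
        n_clipped <- n_clipped + sum(over)
        sc <- ifelse(over, (1 - 1e-12) / death_sum, 1)
        Pt[, , i, 9L] <- Pt[, , i, 9L] * sc
        Pt[, , i, 10L] <- Pt[, , i, 10L] * sc
        death_sum <- pmin(death_sum, 1 - 1e-12)
      }
      Pt[, , i, i] <- 0
      live <- apply(Pt[, , i, 1:8, drop = FALSE], c(1, 2), sum)
      deficit <- 1 - death_sum - live
      neg <- deficit < 0
      if (any(neg)) {
        n_clipped <- n_clipped + sum(neg)
        sc <- ifelse(neg, pmax(0, (1 - death_sum)) / pmax(live, 1e-300), 1)
        for (j in setdiff(1:8, i)) Pt[, , i, j] <- Pt[, , i, j] * sc
        deficit <- pmax(deficit, 0)
      }
      Pt[, , i, i] <- deficit
    }
    P[, , , , t] <- Pt
  }
  if (n_clipped > 0L) {
    warnf("%d row(s) had transition probabilities rescaled to keep rows summing to 1",
          n_clipped)
  }
  structure(list(P = P, years = years, ages = ages, scenario = scenario,
                 incidence_or = or_scn, n_clipped = n_clipped),
            class = "transition_set")
}

#' @export
print.transition_set <- function(x, ...) {
  cat(sprintf("Transition set %d-%d (%d ages x 2 sexes x 8 states + 2 deaths); incidence OR/yr %.4f%s\n",
              min(x$years), max(x$years), length(x$ages), x$incidence_or,
              if (!is.na(x$scenario$cvd_freeze_year))
                sprintf("; CVD freeze %d", x$scenario$cvd_freeze_year) else ""))
  invisible(x)
}

#' Tidy data.frame view of a transition set
#'
#' @param x a `transition_set`.
#' @param ... unused.
#' @return data.frame: year, sex, age, from_state, to_state, probability.
#' @export
as.data.frame.transition_set <- function(x, ...) {
  d <- expand.grid(age = x$ages, sex = c("male", "female"), from_state = 1:8,
                   to_state = c(1:8, 9:10), year = x$years,
                   stringsAsFactors = FALSE)
  d$probability <- as.vector(x$P)
  d[c("year", "sex", "age", "from_state", "to_state", "probability")]
}

#' Write a transition set as tidy CSV plus JSON metadata
#'
#' @param tset a `transition_set`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_transition_set <- function(tset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "transition_probabilities.csv")
  meta <- file.path(dir, "transition_metadata.json")
  utils::write.csv(as.data.frame(tset), csv, row.names = FALSE)
  jsonlite::write_json(list(
    years = range(tset$years), incidence_or_per_year = tset$incidence_or,
    scenario = unclass(tset$scenario), n_clipped = tset$n_clipped,
    package_version = as.character(utils::packageVersion("demproj"))
  ), meta, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, metadata = meta))
}

#' Calibrate all projection-model inputs from a panel
#'
#' Convenience bundle: derives states, estimates the two-year transition
#' table, converts to one year, fits starting prevalence and state
#' mortality odds, and projects mortality.
#'
#' @param panel panel data.frame or `panel_dataset`.
#' @param ascertainment [ascertain_panel()] output (recomputed when NULL).
#' @param mortality_series a `mortality_series` (defaults to the bundled
#'   generator's series).
#' @param trend a `trend_estimate` for the estimated-trend scenario.
#' @param base_year,horizon_year modelled period.
#' @return object of class `model_calibration` with elements `states`,
#'   `tp1`, `start_prev`, `state_odds`, `mort_surface`, `trend`.
#' @export
calibrate_model <- function(panel, ascertainment = NULL,
                            mortality_series = generate_mortality_series(),
                            trend = NULL,
                            base_year = 2006L, horizon_year = 2040L) {
  if (is.null(ascertainment)) ascertainment <- ascertain_panel(panel)
  states <- derive_states(panel, ascertainment)
  tp2 <- estimate_transition_probabilities(states)
  tp1 <- tp_table_one_year(tp2)
  start_prev <- fit_starting_prevalence(states)
  state_odds <- estimate_state_mortality_odds(states)
  mort_surface <- project_mortality(mortality_series, base_year, horizon_year)
  structure(list(states = states, tp1 = tp1, start_prev = start_prev,
                 state_odds = state_odds, mort_surface = mort_surface,
                 trend = trend, base_year = base_year,
                 horizon_year = horizon_year),
            class = "model_calibration")
}
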