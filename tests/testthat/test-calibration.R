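test_that("person-waves map to the eight-state labelling", {
  ref <- reference_rows()
  panel <- rbind(
    ref,
    make_panel_row(1, 1, 2002, 85),                          # healthy
    make_panel_row(2, 1, 2002, 85, cvd_status = TRUE),       # CVD only
    make_panel_row(3, 1, 2002, 85, orientation = -3,
                   immediate_recall = -3, delayed_recall = -3),  # CIND
    make_panel_row(4, 1, 2002, 85, adl_impaired_count = 2),  # FI, no CVD
    make_panel_row(5, 1, 2002, 85, doctor_dx_dementia = TRUE),            # dementia
    make_panel_row(6, 1, 2002, 85, doctor_dx_dementia = TRUE,
                   cvd_status = TRUE),                        # dementia + CVD
    make_panel_row(7, 1, 2002, 85, adl_impaired_count = 1, cvd_status = TRUE,
                   death_year = 2003.2, death_cause = "cvd")  # FI + CVD, dies
  )
  s <- derive_states(panel)
  g <- function(id) s$state[s$person_id == id]
  expect_equal(g(1), 1L); expect_equal(g(2), 2L); expect_equal(g(3), 3L)
  expect_equal(g(4), 5L); expect_equal(g(5), 6L); expect_equal(g(6), 7L)
  expect_equal(g(7), 8L)
  ## a death within the epoch becomes the cause-specific absorbing state
  e <- demproj:::build_state_epochs(s)
  expect_equal(e$to_state[e$person_id == 7], 9L)
  ## state attribute flags are internally consistent
  st <- health_states()
  expect_equal(st$state[st$has_dementia], c(6L, 7L))
  expect_equal(st$state[st$has_functional_impairment], 5:8)
  expect_true(all(st$has_functional_impairment[st$has_dementia]))
})

test_that("the two-year to one-year conversion satisfies the closed form", {
  expect_equal(two_year_to_one_year(0), 0)
  expect_equal(two_year_to_one_year(1), 1)
  ## 1 - P = 0.9^2 gives a one-year probability of exactly 0.10
  expect_equal(two_year_to_one_year(0.19), 0.10, tolerance = 1e-12)
  set.seed(1)
  P <- stats::runif(1000)
  TP <- two_year_to_one_year(P)
  expect_equal(1 - (1 - TP)^2, P, tolerance = 1e-12)
  expect_error(two_year_to_one_year(-0.1), "0, 1")
  expect_error(two_year_to_one_year(1.1), "0, 1")
})

test_that("a panel with no transitions yields zero off-diagonal probabilities", {
  states <- expand.grid(person_id = 1:200, wave = 1:4)
  states$year <- 2000 + 2 * states$wave
  states$age <- 60 + states$person_id %% 30 + 2 * states$wave
  states$sex <- ifelse(states$person_id %% 2 == 0, "male", "female")
  states$state <- 1L
  states$death_year <- NA_real_
  states$death_cause <- NA_character_
  tp <- suppressWarnings(estimate_transition_probabilities(states))
  off <- tp$P2
  for (i in 1:8) off[, , i, i] <- 0
  expect_true(all(off == 0))
  expect_true(all(tp$P2[, , 1, 1] == 1))
  rs <- apply(tp$P2, c(1, 2, 3), sum)
  expect_equal(max(abs(rs - 1)), 0, tolerance = 1e-10)
})

test_that("transition probabilities are recovered from a known generating process", {
  ## two-state process: 1 -> 2 with a logistic age-sex probability, plus
  ## a flat 5% death risk split across causes
  set.seed(77)
  n <- 15000
  p_true <- function(age_c, female) stats::plogis(-2 + 0.5 * age_c + 0.3 * female)
  rows <- list()
  for (pid in seq_len(n)) NULL  # (vectorised below)
  age0 <- sample(55:90, n, replace = TRUE)
  female <- stats::runif(n) < 0.5
  state <- rep(1L, n)
  alive <- rep(TRUE, n)
  for (w in 1:3) {
    yr <- 2000 + 2 * w
    age <- age0 + 2 * (w - 1)
    agec <- (age - 75) / 10
    move <- alive & state == 1L & stats::runif(n) < p_true(agec, female)
    die <- alive & stats::runif(n) < 0.05
    rows[[w]] <- data.frame(person_id = seq_len(n), wave = w, year = yr,
                            age = age, sex = ifelse(female, "female", "male"),
                            state = state,
                            death_year = ifelse(die & alive, yr + 1, NA),
                            death_cause = ifelse(die & alive, "noncvd", NA))
    rows[[w]] <- rows[[w]][alive, ]
    state[move] <- 2L
    alive <- alive & !die
  }
  states <- do.call(rbind, rows)
  ## keep only rows while alive at the wave
  tp <- suppressWarnings(estimate_transition_probabilities(states))
  for (probe_female in c(0, 1)) {
    sx <- if (probe_female == 1) "female" else "male"
    est <- tp$P2["75", sx, 1, 2]
    truth <- p_true(0, probe_female) * 0.95  # masked by death in the epoch
    expect_lt(abs(est - truth) / truth, 0.15)
  }
})

test_that("starting prevalence curves are smooth, normalised and monotone when the truth is", {
  ## all healthy
  states <- data.frame(person_id = 1:500, wave = 1, year = 2006,
                       age = sample(50:95, 500, replace = TRUE),
                       sex = rep(c("male", "female"), 250), state = 1L,
                       death_year = NA_real_, death_cause = NA_character_)
  sp <- fit_starting_prevalence(states)
  expect_true(all(sp$prev[, , 1] == 1))

  ## two states with a logistic-in-age split: the fitted curve must be
  ## monotone in age over the observed range
  set.seed(8)
  n <- 6000
  age <- sample(50:95, n, replace = TRUE)
  p2 <- stats::plogis(-6 + 0.08 * age)
  st2 <- data.frame(person_id = seq_len(n), wave = 1, year = 2006, age = age,
                    sex = rep(c("male", "female"), n / 2),
                    state = ifelse(stats::runif(n) < p2, 6L, 1L),
                    death_year = NA_real_, death_cause = NA_character_)
  sp2 <- fit_starting_prevalence(st2)
  curve <- sp2$prev[as.character(50:95), "female", 6]
  expect_true(all(diff(curve) > -1e-10))
  ## normalisation in every age-sex cell, and a taper to zero at 35
  tot <- apply(sp2$prev, c(1, 2), sum)
  expect_equal(max(abs(tot - 1)), 0, tolerance = 1e-10)
  expect_equal(sum(sp2$prev["35", , 2:8]), 0)
})

test_that("state-specific mortality odds are recovered", {
  set.seed(9)
  n <- 20000
  states <- data.frame(
    person_id = seq_len(n), wave = 1, year = 2006,
    age = sample(60:90, n, replace = TRUE),
    sex = rep(c("male", "female"), n / 2),
    state = sample(1:8, n, replace = TRUE)
  )
  ## equal mortality in all states
  q <- 0.10
  die <- stats::runif(n) < q
  states$death_year <- ifelse(die, 2007, NA)
  states$death_cause <- ifelse(die, ifelse(stats::runif(n) < 0.4, "cvd", "noncvd"), NA)
  ## a second wave (survivors only) so the epoch structure exists
  mk_w2 <- function(st) {
    w2 <- st[is.na(st$death_year), ]
    w2$wave <- 2; w2$year <- 2008; w2$age <- w2$age + 2
    w2
  }
  eq <- estimate_state_mortality_odds(rbind(states, mk_w2(states)))
  expect_true(all(eq$noncvd$or > 0))
  expect_true(all(abs(log(eq$noncvd$or)) < log(1.45)))

  ## doubled death odds in the dementia states
  odds <- q / (1 - q) * ifelse(states$state %in% 6:7, 2, 1)
  die2 <- stats::runif(n) < odds / (1 + odds)
  states$death_year <- ifelse(die2, 2007, NA)
  states$death_cause <- ifelse(die2, ifelse(stats::runif(n) < 0.4, "cvd", "noncvd"), NA)
  dbl <- estimate_state_mortality_odds(rbind(states, mk_w2(states)))
  for (s_dem in c("6", "7")) {
    expect_gt(dbl$noncvd$or[s_dem], 1.5)
    expect_lt(dbl$noncvd$or[s_dem], 2.7)
    expect_true(dbl$noncvd$ci[as.integer(s_dem), "lo"] <= 2 &&
                  2 <= dbl$noncvd$ci[as.integer(s_dem), "hi"])
  }
})

test_that("mortality projection extrapolates log-linear trends exactly", {
  mp <- cohort_config(seed = 1)$mortality_params
  mp$trend[] <- 0.02
  s <- generate_mortality_series(years = 1992:2012, mortality_params = mp)
  surf <- project_mortality(s, base_year = 2006, horizon_year = 2040)
  r <- surf$rate
  ## an exact 2%/year historical decline continues: rate(T+k) = rate(T) 0.98^k
  expect_equal(max(abs(r[, , "2030", ] / r[, , "2006", ] - 0.98^24)), 0,
               tolerance = 1e-8)
  expect_true(all(r > 0))

  mp0 <- mp; mp0$trend[] <- 0
  s0 <- generate_mortality_series(years = 1992:2012, mortality_params = mp0)
  surf0 <- project_mortality(s0, base_year = 2006, horizon_year = 2020)
  expect_equal(surf0$rate[, , "2020", ], surf0$rate[, , "2006", ],
               tolerance = 1e-10)

  expect_error(project_mortality(s[s$year > 2008, ]), "10 years")
})

test_that("the transition set applies calendar trends on the odds scale", {
  sc <- small_calibration(42)
  calib <- sc$calib

  tset_none <- suppressWarnings(build_transition_set(
    calib$tp1, 1, calib$mort_surface, calib$state_odds,
    scenario_spec("none"), calib$start_prev))
  ## with no incidence decline the dementia-incidence entries are frozen,
  ## apart from the CVD-linked scaling of transitions that also acquire CVD
  expect_equal(tset_none$P["80", "female", 1, 6, "2030"],
               tset_none$P["80", "female", 1, 6, "2006"], tolerance = 1e-12)

  tset_est <- suppressWarnings(build_transition_set(
    calib$tp1, trend_estimate(log(0.973), 0.001), calib$mort_surface,
    calib$state_odds, scenario_spec("estimated"), calib$start_prev))
  odds <- function(p) p / (1 - p)
  p0 <- tset_est$P["80", "female", 1, 6, "2006"]
  p10 <- tset_est$P["80", "female", 1, 6, "2016"]
  expect_equal(odds(p10) / odds(p0), 0.973^10, tolerance = 1e-10)
  expect_equal(0.973^10, 0.761, tolerance = 1e-3)

  ## every row of every year sums to one
  rs <- apply(tset_est$P, c(1, 2, 3, 5), sum)
  expect_equal(max(abs(rs - 1)), 0, tolerance = 1e-9)
})

test_that("stronger incidence declines give uniformly smaller incidence entries", {
  sc <- small_calibration(42)
  calib <- sc$calib
  or_levels <- c(1, 0.989, 0.98, 0.973)
  tsets <- lapply(or_levels, function(or) {
    suppressWarnings(build_transition_set(
      calib$tp1, or, calib$mort_surface, calib$state_odds,
      scenario_spec(or), calib$start_prev))
  })
  for (k in seq_len(length(or_levels) - 1L)) {
    a <- tsets[[k]]$P[, , 1, 6, -1]
    b <- tsets[[k + 1L]]$P[, , 1, 6, -1]
    expect_true(all(a - b >= -1e-15))
    expect_gt(sum(a - b), 0)
  }
})

test_that("the CVD freeze changes transitions only after the freeze year", {
  sc <- small_calibration(42)
  calib <- sc$calib
  base <- suppressWarnings(build_transition_set(
    calib$tp1, 0.973, calib$mort_surface, calib$state_odds,
    scenario_spec(0.973), calib$start_prev))
  frozen <- suppressWarnings(build_transition_set(
    calib$tp1, 0.973, calib$mort_surface, calib$state_odds,
    scenario_spec(0.973, cvd_freeze_year = 2014), calib$start_prev))
  pre <- as.character(2006:2014)
  post <- as.character(2020:2040)
  expect_equal(frozen$P[, , , , pre], base$P[, , , , pre], tolerance = 1e-12)
  expect_gt(sum(abs(frozen$P[, , 1, 2, post] - base$P[, , 1, 2, post])), 0)
  ## freezing the CVD decline keeps CVD incidence higher
  expect_true(all(frozen$P[, , 1, 2, post] - base$P[, , 1, 2, post] >= -1e-15))
})

test_that("odds scaling and the epoch-length conversion nearly commute below P = 0.3", {
  odds_scale <- function(p, f) p * f / (1 - p + p * f)
  P <- seq(0.001, 0.25, by = 0.001)
  a <- two_year_to_one_year(odds_scale(P, 0.9))
  b <- odds_scale(two_year_to_one_year(P), 0.9)
  expect_lt(max(abs(a - b)), 1e-3)
  ## the discrepancy grows towards P = 0.3 and with the cumulated scaling
  ## factor, but stays below 2.5e-3 at the ten-year factor
  P3 <- seq(0.001, 0.3, by = 0.001)
  f10 <- 0.973^10
  a10 <- two_year_to_one_year(odds_scale(P3, f10))
  b10 <- odds_scale(two_year_to_one_year(P3), f10)
  expect_lt(max(abs(a10 - b10)), 2.5e-3)
})

test_that("scenario specifications validate their inputs", {
  expect_error(scenario_spec("bogus"), "valid")
  expect_error(scenario_spec(-0.5), "positive")
  expect_error(scenario_spec("none", horizon_year = 2000), "precede")
  expect_equal(demproj:::scenario_or(scenario_spec("fixed2"), NULL), 0.98)
  expect_equal(demproj:::scenario_or(scenario_spec("fixed1.1"), NULL), 0.989)
  expect_equal(demproj:::scenario_or(scenario_spec("none"), NULL), 1)
})
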