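## Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

## A reduced cohort: same structure as the default study conditions,
## scaled down for unit tests.
small_cohort_config <- function(seed, n_core = 2200L, ...) {
  cohort_config(
    n_core = n_core,
    recruitment_waves = list(
      list(wave = 3L, age_range = c(50L, 55L), n = 300L),
      list(wave = 4L, age_range = c(50L, 74L), n = 700L),
      list(wave = 6L, age_range = c(50L, 55L), n = 280L)
    ),
    seed = seed, ...)
}

small_dataset <- function(seed = 42L) {
  cached(paste0("ds", seed), {
    d <- generate_cohort(small_cohort_config(seed))
    a <- ascertain_panel(d)
    list(data = d, asc = a)
  })
}

## A reduced but fully calibrated projection model shared across engine,
## uncertainty and acceptance tests.
small_calibration <- function(seed = 42L) {
  cached(paste0("calib", seed), {
    f <- small_dataset(seed)
    trend <- fit_naive_trend(f$data$panel, f$asc$statuses)$trend
    calib <- suppressWarnings(
      calibrate_model(f$data$panel, f$asc, trend = trend))
    pop <- generate_population_structure()
    list(calib = calib, pop = pop, trend = trend)
  })
}

## Hand-built panel rows with every column the case definition reads.
make_panel_row <- function(person_id, wave, year, age, sex = "female",
                           education = "intermediate",
                           orientation = 0, immediate_recall = 0,
                           delayed_recall = 0, verbal_fluency = 0,
                           numeracy = NA_real_, literacy = NA_real_,
                           n_tests_answered = 4L, adl_impaired_count = 0L,
                           iqcode = NA_real_, doctor_dx_dementia = FALSE,
                           cvd_status = FALSE, obesity = FALSE,
                           hypertension = FALSE, diabetes = FALSE,
                           smoking = FALSE, inactive = FALSE,
                           death_year = NA_real_,
                           death_cause = NA_character_,
                           dropped_out = FALSE, proxy_interview = FALSE) {
  data.frame(person_id = person_id, wave = wave, year = year, age = age,
             sex = sex, education = education, orientation = orientation,
             immediate_recall = immediate_recall,
             delayed_recall = delayed_recall,
             verbal_fluency = verbal_fluency, numeracy = numeracy,
             literacy = literacy, n_tests_answered = n_tests_answered,
             adl_impaired_count = adl_impaired_count, iqcode = iqcode,
             doctor_dx_dementia = doctor_dx_dementia,
             cvd_status = cvd_status, obesity = obesity,
             hypertension = hypertension, diabetes = diabetes,
             smoking = smoking, inactive = inactive, weight = 1,
             death_year = death_year, death_cause = death_cause,
             dropped_out = dropped_out, proxy_interview = proxy_interview)
}

## A reference stratum (ages 50-80, one education level) whose test means
## are 0 and SDs 1 by construction is appended so hand-built rows have a
## well-defined standardisation. Scores follow a fixed symmetric pattern.
reference_rows <- function(education = "intermediate", n = 20L,
                           start_id = 9000L) {
  vals <- stats::qnorm(seq(0.05, 0.95, length.out = n))
  vals <- (vals - mean(vals)) / stats::sd(vals)
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_panel_row(start_id + i, wave = 1L, year = 2002L,
                   age = 50L + (i %% 31L), education = education,
                   orientation = vals[i], immediate_recall = vals[i],
                   delayed_recall = vals[i], verbal_fluency = vals[i])
  }))
}

## Oracle statuses built from the generator's ground truth: every true
## onset is "ascertained" at the first analysis wave on or after it,
## independent of the measured scores.
truth_statuses <- function(dataset, analysis_waves = 1:6) {
  tr <- dataset$truth
  wy <- dataset$wave_years[analysis_waves]
  asc_wave <- vapply(tr$true_onset_year, function(on) {
    if (is.na(on)) return(NA_integer_)
    w <- which(wy >= on)
    if (!length(w)) NA_integer_ else as.integer(w[1L])
  }, integer(1))
  is_case <- !is.na(asc_wave)
  prevalent <- is_case & asc_wave <= tr$entry_wave
  asc_wave[is_case] <- pmax(asc_wave[is_case], tr$entry_wave[is_case])
  data.frame(person_id = tr$person_id, is_case = is_case,
             prevalent_at_entry = prevalent,
             onset_year = ifelse(is_case, tr$true_onset_year, NA_real_),
             route = ifelse(is_case, "ground-truth", NA_character_),
             ascertainment_wave = asc_wave,
             ascertainment_year = ifelse(is_case, wy[asc_wave], NA_real_))
}

## Toy transition set: every age and sex shares one 8x10 one-year matrix.
toy_transition_set <- function(P8x10, years = 2006:2040, ages = 35:100) {
  P <- array(0, dim = c(length(ages), 2L, 8L, 10L, length(years)),
             dimnames = list(age = ages, sex = c("male", "female"),
                             from = 1:8, to = c(1:8, "death_cvd", "death_noncvd"),
                             year = years))
  for (t in seq_along(years)) for (sx in 1:2) for (a in seq_along(ages)) {
    P[a, sx, , , t] <- P8x10
  }
  structure(list(P = P, years = years, ages = ages,
                 scenario = scenario_spec("none", horizon_year = max(years)),
                 incidence_or = 1, n_clipped = 0L),
            class = "transition_set")
}

## Simple survival kernel: stay alive with probability 1 - q in every
## state, death split evenly between the two causes.
survival_kernel <- function(q) {
  P <- matrix(0, 8L, 10L)
  diag(P[, 1:8]) <- 1 - q
  P[, 9L] <- q / 2
  P[, 10L] <- q / 2
  P
}
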