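## Operational dementia case definition: domain z-scores standardised
## against an age-50-80 reference within education strata, impairment in
## two or more cognitive domains, functional impairment as difficulty with
## one or more activities of daily living, transience rules, and the
## informant-questionnaire and doctor-diagnosis routes.

DOMAIN_TESTS <- list(
  concentration = "orientation",
  memory = c("immediate_recall", "delayed_recall"),
  executive = c("verbal_fluency", "numeracy", "literacy")
)

#' Standardise cognitive domain scores against a reference population
#'
#' Each test is z-scored against the mean and SD of the reference stratum
#' (participants aged `reference_ages[1]`-`reference_ages[2]`, pooled over
#' waves, within the same education level). Tests are then combined into
#' three domains -- concentration (orientation), memory (immediate +
#' delayed recall), executive function (verbal fluency plus numeracy and
#' literacy where administered) -- and each domain composite is re-scaled
#' to unit SD in the reference stratum so the impairment threshold has the
#' same meaning in every domain. Assessments with fewer than three answered
#' tests are flagged invalid.
#'
#' @param panel a panel data.frame (see [generate_cohort()]) or a
#'   `panel_dataset`.
#' @param reference_ages age range of the reference population (default
#'   c(50, 80)).
#' @param reference_waves waves pooled into the reference population
#'   (default 1-6: a trailing follow-up wave used only for transience
#'   must not shift the standardisation of earlier waves).
#' @return data.frame of class `domain_zscores`: one row per person-wave
#'   with `z_concentration`, `z_memory`, `z_executive`,
#'   `z_executive_no_numeracy`, `avg_z`, `n_domains_observed` and
#'   `valid_assessment`.
#' @export
standardize_domain_scores <- function(panel, reference_ages = c(50, 80),
                                      reference_waves = 1:6) {
  panel <- as_panel_df(panel)
  tests <- unique(unlist(DOMAIN_TESTS))
  missing_cols <- setdiff(tests, names(panel))
  if (length(missing_cols)) stopf("panel lacks test columns: %s",
                                  paste(missing_cols, collapse = ", "))
  ref <- panel$age >= reference_ages[1L] & panel$age <= reference_ages[2L] &
    panel$wave %in% reference_waves
  z <- panel[c("person_id", "wave", "year", "age", "sex", "education")]

  zt <- matrix(NA_real_, nrow(panel), length(tests),
               dimnames = list(NULL, tests))
  for (edu in unique(panel$education)) {
    in_edu <- panel$education == edu
    in_ref <- in_edu & ref
    if (!any(in_ref)) stopf("empty reference stratum (ages %d-%d, education '%s')",
                            reference_ages[1L], reference_ages[2L], edu)
    for (tn in tests) {
      x <- panel[[tn]]
      n_ref <- sum(!is.na(x[in_ref]))
      if (n_ref < 2L) next  # test not administered in this reference
      mu <- mean(x[in_ref], na.rm = TRUE)
      sg <- stats::sd(x[in_ref], na.rm = TRUE)
      if (!is.finite(sg) || sg <= 0) {
        stopf("zero SD for test '%s' in reference stratum (education '%s')",
              tn, edu)
      }
      zt[in_edu, tn] <- (x[in_edu] - mu) / sg
    }
  }

  domain_composite <- function(cols) rowMeans(zt[, cols, drop = FALSE], na.rm = TRUE)
  raw <- list(
    concentration = domain_composite(DOMAIN_TESTS$concentration),
    memory = domain_composite(DOMAIN_TESTS$memory),
    executive = domain_composite(DOMAIN_TESTS$executive),
    executive_no_numeracy = domain_composite(setdiff(DOMAIN_TESTS$executive, "numeracy"))
  )
  ## rescale composites to unit SD in the reference stratum, per education
  for (dn in names(raw)) {
    v <- raw[[dn]]
    v[is.nan(v)] <- NA_real_
    for (edu in unique(panel$education)) {
      in_edu <- panel$education == edu
      sg <- stats::sd(v[in_edu & ref], na.rm = TRUE)
      mu <- mean(v[in_edu & ref], na.rm = TRUE)
      if (is.finite(sg) && sg > 0) v[in_edu] <- (v[in_edu] - mu) / sg
    }
    z[[paste0("z_", dn)]] <- v
  }
  names(z)[names(z) == "z_executive_no_numeracy"] <- "z_executive_no_numeracy"

  dom <- c("z_concentration", "z_memory", "z_executive")
  z$n_domains_observed <- rowSums(!is.na(z[dom]))
  z$avg_z <- rowMeans(z[dom], na.rm = TRUE)
  z$avg_z[is.nan(z$avg_z)] <- NA_real_
  n_tests <- if ("n_tests_answered" %in% names(panel)) {
    panel$n_tests_answered
  } else {
    rowSums(!is.na(panel[tests]))
  }
  z$valid_assessment <- n_tests >= 3L
  class(z) <- c("domain_zscores", "data.frame")
  z
}

#' Classify cognitive impairment from domain z-scores
#'
#' A domain is impaired when its z-score is 1.5 SD below the reference mean
#' or lower (boundary inclusive). Cognitive impairment requires impairment
#' in two or more of the observed domains. Impairment is rescinded as
#' transient when the person's average standardised score improves by
#' `improvement_sd` (default 1 SD) or more at the consecutive wave;
#' transience at the last analysis wave is resolved with the following
#' wave's data when present.
#'
#' @param zscores output of [standardize_domain_scores()].
#' @param threshold impairment threshold on the z scale (default -1.5).
#' @param improvement_sd improvement rescinding impairment (default 1).
#' @return data.frame of class `impairment_flags` with per person-wave
#'   `cognitive_impairment` (transient already suppressed),
#'   `cognitive_impairment_raw`, `transient_cognitive`,
#'   `impaired_domain_count` and
#'   `cognitive_impairment_without_numeracy` (caseness had numeracy been
#'   unavailable; used for onset dating).
#' @export
classify_cognitive_impairment <- function(zscores,
                                          threshold = -1.5,
                                          improvement_sd = 1) {
  z <- as.data.frame(zscores)
  if (any(stats::ave(z$wave, z$person_id,
                     FUN = function(w) any(diff(w) <= 0)) == 1)) {
    stopf("waves must be strictly increasing within person")
  }
  z <- z[order(z$person_id, z$wave), ]
  dom <- cbind(z$z_concentration, z$z_memory, z$z_executive)
  imp <- dom <= threshold
  n_imp <- rowSums(imp, na.rm = TRUE)
  raw <- z$valid_assessment & n_imp >= 2L

  dom_nn <- cbind(z$z_concentration, z$z_memory, z$z_executive_no_numeracy)
  raw_nn <- z$valid_assessment & rowSums(dom_nn <= threshold, na.rm = TRUE) >= 2L

  ## transience: impairment at wave w is suppressed when the average score
  ## at wave w+1 (if observed) is at least improvement_sd higher
  nr <- nrow(z)
  nxt_same <- c(z$person_id[-1L] == z$person_id[-nr] &
                  z$wave[-1L] == z$wave[-nr] + 1L, FALSE)
  improve <- rep(NA_real_, nr)
  improve[nxt_same] <- z$avg_z[which(nxt_same) + 1L] - z$avg_z[which(nxt_same)]
  transient <- raw & !is.na(improve) & improve >= improvement_sd

  out <- z[c("person_id", "wave", "year")]
  out$impaired_domain_count <- n_imp
  out$cognitive_impairment_raw <- raw
  out$transient_cognitive <- transient
  out$cognitive_impairment <- raw & !transient
  out$cognitive_impairment_without_numeracy <- raw_nn & !transient
  out$partial_domains <- z$valid_assessment & z$n_domains_observed < 3L
  class(out) <- c("impairment_flags", "data.frame")
  out
}

#' Classify functional impairment from ADL counts
#'
#' Functional impairment is difficulty independently performing one or more
#' of the seven activities of daily living. Impairment reported at exactly
#' one wave, with full recovery at all later observed waves, is treated as
#' transient (transience at the last analysis wave uses the following
#' wave's data when present).
#'
#' @param panel panel data.frame or `panel_dataset` with
#'   `adl_impaired_count`.
#' @return data.frame of class `impairment_flags` with
#'   `functional_impairment` (transience suppressed),
#'   `functional_impairment_raw` and `transient_functional`.
#' @export
classify_functional_impairment <- function(panel) {
  p <- as_panel_df(panel)
  p <- p[order(p$person_id, p$wave), ]
  raw <- p$adl_impaired_count >= 1L
  ## transient = the person's only impaired wave, with a later observed wave
  ## showing recovery
  n_imp_person <- stats::ave(as.integer(raw), p$person_id, FUN = sum)
  last_wave <- stats::ave(p$wave, p$person_id, FUN = max)
  transient <- raw & n_imp_person == 1L & p$wave < last_wave

  out <- p[c("person_id", "wave", "year")]
  out$functional_impairment_raw <- raw
  out$transient_functional <- transient
  out$functional_impairment <- raw & !transient
  class(out) <- c("impairment_flags", "data.frame")
  out
}

#' Ascertain dementia caseness and onset dates
#'
#' A person is a dementia case at the first analysis wave at which any of
#' the three routes fires: (i) non-transient cognitive impairment together
#' with non-transient functional impairment at the same wave; (ii) an
#' informant-questionnaire (IQCODE) score at or above `iqcode_cut` together
#' with functional impairment; (iii) self- or proxy-reported doctor
#' diagnosis of dementia. The onset date is the mid-point between the
#' ascertainment wave and the latest previous assessment; when caseness
#' hinges solely on impairment in numeracy (administered at waves 1, 4 and
#' 6 only), the mid-point is taken between the two consecutive
#' numeracy-bearing waves. Cases at their first observed wave are flagged
#' prevalent at entry, with onset dated at that wave. Waves outside
#' `analysis_waves` (a trailing follow-up wave) contribute only to
#' transience resolution upstream, never to caseness.
#'
#' For reporting, one primary route is recorded per case with precedence
#' doctor diagnosis > IQCODE + ADL > cognitive tests + ADL.
#'
#' @param cog_flags output of [classify_cognitive_impairment()].
#' @param func_flags output of [classify_functional_impairment()].
#' @param panel the panel the flags were computed from.
#' @param iqcode_cut IQCODE cut-point (default 3.6, boundary inclusive).
#' @param analysis_waves waves eligible for ascertainment (default 1-6).
#' @return data.frame of class `dementia_status`, one row per person:
#'   `is_case`, `prevalent_at_entry`, `onset_year`, `route`,
#'   `ascertainment_wave`, `ascertainment_year`.
#' @export
ascertain_dementia <- function(cog_flags, func_flags, panel,
                               iqcode_cut = 3.6,
                               analysis_waves = 1:6) {
  p <- as_panel_df(panel)
  p <- p[order(p$person_id, p$wave), ]
  key <- paste(p$person_id, p$wave)
  cg <- as.data.frame(cog_flags); fc <- as.data.frame(func_flags)
  ci <- cg$cognitive_impairment[match(key, paste(cg$person_id, cg$wave))]
  ci_nn <- cg$cognitive_impairment_without_numeracy[
    match(key, paste(cg$person_id, cg$wave))]
  fi <- fc$functional_impairment[match(key, paste(fc$person_id, fc$wave))]
  ci[is.na(ci)] <- FALSE; ci_nn[is.na(ci_nn)] <- FALSE; fi[is.na(fi)] <- FALSE

  iq <- !is.na(p$iqcode) & p$iqcode >= iqcode_cut
  dx <- !is.na(p$doctor_dx_dementia) & p$doctor_dx_dementia

  route_tests <- ci & fi
  route_iqcode <- iq & fi
  case_wave <- (route_tests | route_iqcode | dx) & p$wave %in% analysis_waves

  ## vectorised per-person resolution on the wave-sorted panel
  n <- nrow(p)
  new_person <- c(TRUE, p$person_id[-1L] != p$person_id[-n])
  prev_year <- c(NA_real_, p$year[-n]); prev_year[new_person] <- NA_real_
  ## latest previous assessment that carried the numeracy test (waves 1, 4)
  num_year <- ifelse(p$wave %in% c(1L, 4L), p$year, NA_real_)
  filled <- num_year
  carry <- NA_real_
  for (i in seq_len(n)) {  # fill-forward within person
    if (new_person[i]) carry <- NA_real_
    if (is.na(filled[i])) filled[i] <- carry else carry <- filled[i]
  }
  prev_num_year <- c(NA_real_, filled[-n]); prev_num_year[new_person] <- NA_real_

  ## first case wave per person
  seen <- stats::ave(as.integer(case_wave), p$person_id, FUN = cumsum)
  first_case <- case_wave & seen == 1L

  a <- which(first_case)
  route <- ifelse(dx[a], "doctor-diagnosis",
                  ifelse(route_iqcode[a], "IQCODE+ADL", "cognitive-tests+ADL"))
  prevalent <- new_person[a]
  y_prev <- prev_year[a]
  ## caseness hinging solely on numeracy impairment: mid-point between the
  ## two consecutive numeracy-bearing waves
  num_only <- route == "cognitive-tests+ADL" & !ci_nn[a] &
    p$wave[a] %in% c(4L, 6L) & !is.na(prev_num_year[a])
  y_prev[num_only] <- prev_num_year[a][num_only]
  onset <- ifelse(prevalent, p$year[a], midpoint_year(y_prev, p$year[a]))

  ids <- unique(p$person_id)
  res <- data.frame(person_id = ids, is_case = FALSE,
                    prevalent_at_entry = FALSE, onset_year = NA_real_,
                    route = NA_character_, ascertainment_wave = NA_integer_,
                    ascertainment_year = NA_real_)
  m <- match(p$person_id[a], res$person_id)
  res$is_case[m] <- TRUE
  res$prevalent_at_entry[m] <- prevalent
  res$onset_year[m] <- onset
  res$route[m] <- route
  res$ascertainment_wave[m] <- p$wave[a]
  res$ascertainment_year[m] <- p$year[a]
  rownames(res) <- NULL
  class(res) <- c("dementia_status", "data.frame")
  res
}

#' Run the full case definition on a panel
#'
#' Convenience wrapper: standardises scores, classifies cognitive and
#' functional impairment, and ascertains caseness.
#'
#' @inheritParams ascertain_dementia
#' @inheritParams standardize_domain_scores
#' @param threshold domain impairment threshold (default -1.5).
#' @return list with `zscores`, `cog_flags`, `func_flags`, `statuses`.
#' @export
ascertain_panel <- function(panel, threshold = -1.5, iqcode_cut = 3.6,
                            reference_ages = c(50, 80), analysis_waves = 1:6) {
  z <- standardize_domain_scores(panel, reference_ages)
  cg <- classify_cognitive_impairment(z, threshold = threshold)
  fc <- classify_functional_impairment(panel)
  st <- ascertain_dementia(cg, fc, panel, iqcode_cut = iqcode_cut,
                           analysis_waves = analysis_waves)
  list(zscores = z, cog_flags = cg, func_flags = fc, statuses = st)
}

#' Observed dementia incidence rate in a calendar window
#'
#' Incident (non-prevalent) ascertained cases with mid-point onset dates in
#' the window, divided by at-risk person-years observed in the window
#' (ages `min_age`+, dementia-free, from study entry to the earlier of last
#' interview, onset or death).
#'
#' @param panel panel data.frame or `panel_dataset`.
#' @param statuses a `dementia_status` data.frame.
#' @param window calendar window, default c(2009, 2011) (centred on 2010).
#' @param min_age minimum age (default 50).
#' @return data.frame with rate per 1000 person-years by sex and overall.
#' @export
observed_incidence_rate <- function(panel, statuses, window = c(2009, 2011),
                                    min_age = 50) {
  p <- as_panel_df(panel)
  st <- as.data.frame(statuses)
  p <- p[order(p$person_id, p$wave), ]
  first <- !duplicated(p$person_id)
  last <- !duplicated(p$person_id, fromLast = TRUE)
  ids <- p$person_id[first]
  s <- st[match(ids, st$person_id), ]
  t0 <- p$year[first]; t1 <- p$year[last]
  age0 <- p$age[first]; sex <- p$sex[first]
  dy <- p$death_year[first]
  t1 <- ifelse(!is.na(dy), pmin(t1, dy), t1)
  is_case <- !is.na(s$is_case) & s$is_case
  incident <- is_case & !s$prevalent_at_entry
  t1 <- ifelse(is_case & !is.na(s$onset_year), pmin(t1, s$onset_year), t1)
  t0 <- pmax(t0, t0 + (min_age - age0))  # person-time from age min_age
  keep <- !(is_case & s$prevalent_at_entry)
  py <- pmax(0, pmin(t1, window[2L]) - pmax(t0, window[1L]))
  ev <- as.integer(incident & !is.na(s$onset_year) &
                     s$onset_year >= window[1L] & s$onset_year <= window[2L] &
                     age0 + (s$onset_year - p$year[first]) >= min_age)
  d <- data.frame(sex = sex, py = py, events = ev)[keep, ]
  agg <- stats::aggregate(cbind(py, events) ~ sex, data = d, FUN = sum)
  agg$rate_per_1000py <- 1000 * agg$events / agg$py
  total <- data.frame(sex = "all", py = sum(d$py), events = sum(d$events))
  total$rate_per_1000py <- 1000 * total$events / total$py
  rbind(agg, total)
}

## Accept either a panel_dataset or a bare data.frame.
as_panel_df <- function(panel) {
  if (inherits(panel, "panel_dataset")) panel$panel else as.data.frame(panel)
}
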