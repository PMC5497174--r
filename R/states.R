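#' Health-state structure of the projection model
#'
#' The model tracks eight living health states defined by three binary
#' conditions -- cardiovascular disease (CVD), cognitive impairment no
#' dementia (CIND), dementia -- and functional impairment (difficulty with
#' one or more activities of daily living), plus two absorbing death states
#' (CVD death, non-CVD death). Dementia implies functional impairment by the
#' case definition, so states 6 and 7 are the only dementia states, and
#' states 5-8 are the functionally impaired states.
#'
#' Labelling:
#' \enumerate{
#'   \item healthy (no CVD, no CIND, no functional impairment)
#'   \item CVD only
#'   \item CIND only
#'   \item CIND and CVD
#'   \item functional impairment (no dementia), no CVD
#'   \item dementia, no CVD
#'   \item dementia and CVD
#'   \item functional impairment (no dementia) and CVD
#' }
#' Death states carry indices 9 (CVD death) and 10 (non-CVD death).
#'
#' @return a data.frame with one row per living state and logical attribute
#'   columns `has_cvd`, `has_cind`, `has_dementia`, `has_functional_impairment`.
#' @export
health_states <- function() {
  data.frame(
    state = 1:8,
    label = c("healthy", "cvd", "cind", "cind_cvd",
              "fi", "dementia", "dementia_cvd", "fi_cvd"),
    has_cvd = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
    has_cind = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    has_dementia = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    has_functional_impairment = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  )
}

#' @rdname health_states
#' @export
death_states <- function() {
  data.frame(state = 9:10, label = c("death_cvd", "death_noncvd"),
             cause = c("cvd", "noncvd"))
}

STATE_DEMENTIA <- c(6L, 7L)
STATE_CIND <- c(3L, 4L)
STATE_FI <- 5:8
STATE_CVD <- c(2L, 4L, 7L, 8L)
STATE_DEATH_CVD <- 9L
STATE_DEATH_NONCVD <- 10L

#' Allowed transitions between health states
#'
#' Progressive-disease conventions: there is no recovery from dementia and
#' CVD status is never lost. CIND and functional impairment may remit
#' (transient impairment is real in panel data); both switches are
#' configurable. Direct progression from the functionally impaired
#' non-dementia states to dementia (5 to 6, 8 to 7) is allowed. All living
#' states can reach both death states.
#'
#' @param allow_cind_recovery logical; allow transitions out of CIND back to
#'   less-impaired states (default TRUE).
#' @param allow_fi_recovery logical; allow recovery from non-dementia
#'   functional impairment (default TRUE).
#' @return an 8 x 10 logical matrix; rows = from-state 1..8, columns =
#'   to-state 1..10 (9, 10 are deaths).
#' @export
allowed_transitions <- function(allow_cind_recovery = TRUE,
                                allow_fi_recovery = TRUE) {
  st <- health_states()
  M <- matrix(FALSE, 8L, 10L,
              dimnames = list(from = 1:8, to = c(1:8, "death_cvd", "death_noncvd")))
  for (i in 1:8) {
    for (j in 1:8) {
      ok <- TRUE
      # CVD is never lost
      if (st$has_cvd[i] && !st$has_cvd[j]) ok <- FALSE
      # no recovery from dementia
      if (st$has_dementia[i] && !st$has_dementia[j]) ok <- FALSE
      if (!allow_cind_recovery && st$has_cind[i] && !st$has_cind[j]) ok <- FALSE
      if (!allow_fi_recovery && st$has_functional_impairment[i] &&
          !st$has_dementia[i] && !st$has_functional_impairment[j]) ok <- FALSE
      M[i, j] <- ok
    }
  }
  M[, 9:10] <- TRUE
  M
}

#' Named constants used throughout the pipeline
#'
#' Central registry of the tunable cut-points and model anchors, each with
#' its conventional default: the -1.5 SD domain-impairment threshold, the
#' 3.6 informant-questionnaire (IQCODE) cut-point, the 0.973 per-year
#' incidence odds ratio, 1000 Monte Carlo draws, the 2006 model base year,
#' the 2040 projection horizon, the 2015 standard population year for age
#' standardisation, and the 2014 CVD-incidence freeze year used in
#' sensitivity analysis.
#'
#' @return named list of defaults.
#' @export
default_constants <- function() {
  list(
    z_impairment_threshold = -1.5,
    transient_improvement_sd = 1,
    iqcode_cut = 3.6,
    trend_or_per_year = 0.973,
    n_draws = 1000L,
    base_year = 2006L,
    horizon_year = 2040L,
    standard_population_year = 2015L,
    cvd_freeze_year = 2014L,
    min_age = 35L,
    max_age = 100L
  )
}
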