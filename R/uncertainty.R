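## Monte Carlo probabilistic sensitivity analysis and scenario
## orchestration. Parameter uncertainty is propagated by sampling every
## calibrated coefficient vector (transition logistics, state mortality
## odds, incidence-trend log odds ratio) from its estimated multivariate
## normal, rebuilding the derived probabilities per draw so all derived
## quantities stay internally consistent within a draw, and re-running the
## full projection.

#' Sample one coefficient-level parameter draw
#'
#' Multivariate normal draws on each calibrated coefficient vector, using
#' its estimated covariance (repaired to the nearest positive
#' semi-definite matrix if needed); the incidence-trend log odds ratio is
#' drawn from its CI-implied normal. Zero covariance reproduces the point
#' estimates exactly.
#'
#' @param calibration a `model_calibration` (see [calibrate_model()]).
#' @param index draw index (stored for bookkeeping).
#' @return object of class `parameter_draw`: `tp_coefs` (per destination),
#'   `odds_coefs` (per cause), `log_or_trend`.
#' @export
sample_parameters <- function(calibration, index = 1L) {
  tpf <- calibration$tp1$fits
  tp_coefs <- lapply(tpf, function(f) {
    if (is.null(f)) return(NULL)
    stats::setNames(drop(draw_mvn(1L, f$coefficients, f$vcov)),
                    names(f$coefficients))
  })
  odds_coefs <- lapply(calibration$state_odds, function(oc) {
    stats::setNames(drop(draw_mvn(1L, oc$coefficients, oc$vcov)),
                    names(oc$coefficients))
  })
  tr <- calibration$trend
  log_or <- if (inherits(tr, "trend_estimate")) {
    stats::rnorm(1L, tr$log_or_per_year, tr$se_log_or)
  } else {
    log(scenario_or(scenario_spec("estimated"), tr))
  }
  structure(list(index = index, tp_coefs = tp_coefs, odds_coefs = odds_coefs,
                 log_or_trend = log_or),
            class = "parameter_draw")
}

## Rebuild the one-year transition table and state mortality odds implied
## by a parameter draw.
apply_parameter_draw <- function(calibration, draw) {
  tp1 <- calibration$tp1
  ages <- tp1$ages
  grid <- tp1$grid
  P2 <- array(0, dim = dim(tp1$P2), dimnames = dimnames(tp1$P2))
  for (j in 1:10) {
    f <- tp1$fits[[j]]
    if (is.null(f)) next
    pr <- as.vector(stats::plogis(f$X_grid %*% draw$tp_coefs[[j]]))
    pr[f$zero_mask] <- 0
    pr <- pr * tp1$taper
    P2[, , , j][cbind(match(grid$age, ages),
                      match(grid$sex, c("male", "female")),
                      grid$from)] <- pr
  }
  for (i in 1:8) {
    P2[, , i, i] <- 0
    off <- apply(P2[, , i, , drop = FALSE], c(1, 2), sum)
    sc <- pmin(1, 1 / pmax(off, 1e-300))
    for (j in setdiff(1:10, i)) P2[, , i, j] <- P2[, , i, j] * sc
    P2[, , i, i] <- pmax(0, 1 - pmin(off, 1))
  }
  tp1$P2 <- P2
  tp1 <- tp_table_one_year(tp1)

  state_odds <- calibration$state_odds
  for (cause in names(state_odds)) {
    cf <- draw$odds_coefs[[cause]]
    or <- c(1, exp(cf[paste0("from", 2:8)]))
    names(or) <- 1:8
    bad <- !is.finite(or)
    if (any(bad)) or[bad] <- state_odds[[cause]]$or[bad]
    state_odds[[cause]]$or <- or
  }
  trend <- trend_estimate(draw$log_or_trend, 0)
  list(tp1 = tp1, state_odds = state_odds, trend = trend)
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Runs `n_draws` full projections, one per coefficient-level parameter
#' draw, and summarises each output series by its empirical 2.5th, 50th
#' and 97.5th percentiles (the conventional 95\% uncertainty interval from
#' 1000 iterations). Failed draws are logged and excluded; more than 5\%
#' failures is an error.
#'
#' @param calibration a `model_calibration` whose `trend` is set.
#' @param pop_inputs a `population_inputs`.
#' @param scenario a `scenario_spec`.
#' @param n_draws number of Monte Carlo iterations (default 1000).
#' @param seed integer seed controlling the whole draw stream.
#' @return object of class `uncertainty_result`: per series (dementia
#'   count, crude and standardised 50+ prevalence), a years x 3 matrix of
#'   percentiles; `n_draws`, `n_failed`, `point` (the point-estimate
#'   projection summary).
#' @export
run_psa <- function(calibration, pop_inputs, scenario = scenario_spec(),
                    n_draws = 1000L, seed = 1L) {
  set.seed(seed)
  start_prev <- calibration$start_prev
  init0 <- initialize_population(pop_inputs, start_prev)
  years <- scenario$base_year:scenario$horizon_year
  series_names <- c("dementia_count", "prev_50plus", "prev_50plus_std")
  draws <- array(NA_real_, dim = c(n_draws, length(years), length(series_names)),
                 dimnames = list(NULL, years, series_names))
  n_failed <- 0L
  for (d in seq_len(n_draws)) {
    res <- tryCatch({
      pd <- sample_parameters(calibration, d)
      ap <- apply_parameter_draw(calibration, pd)
      tset <- suppressWarnings(
        build_transition_set(ap$tp1, ap$trend, calibration$mort_surface,
                             ap$state_odds, scenario, start_prev))
      out <- project_population(init0, tset, entrants = pop_inputs$entrants,
                                horizon_year = scenario$horizon_year,
                                standard_year = scenario$standard_population_year)
      out$summary
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      warnf("draw %d failed: %s", d, conditionMessage(res))
      next
    }
    draws[d, , "dementia_count"] <- res$dementia_count
    draws[d, , "prev_50plus"] <- res$prev_50plus
    draws[d, , "prev_50plus_std"] <- res$prev_50plus_std
  }
  if (n_failed > 0.05 * n_draws) {
    stopf("%d of %d draws failed (> 5%%)", n_failed, n_draws)
  }
  qs <- lapply(series_names, function(sn) {
    t(apply(draws[, , sn, drop = FALSE], 2L, stats::quantile,
            probs = c(0.025, 0.5, 0.975), na.rm = TRUE))
  })
  names(qs) <- series_names
  point <- {
    tset <- suppressWarnings(
      build_transition_set(calibration$tp1, calibration$trend,
                           calibration$mort_surface, calibration$state_odds,
                           scenario, start_prev))
    project_population(init0, tset, entrants = pop_inputs$entrants,
                       horizon_year = scenario$horizon_year,
                       standard_year = scenario$standard_population_year)$summary
  }
  structure(list(percentiles = qs, years = years, n_draws = n_draws,
                 n_failed = n_failed, point = point, seed = seed),
            class = "uncertainty_result")
}

#' @export
print.uncertainty_result <- function(x, ...) {
  last <- length(x$years)
  p <- x$percentiles$dementia_count
  cat(sprintf("PSA (%d draws, %d failed): dementia count %d: %.0f (95%% UI %.0f-%.0f)\n",
              x$n_draws, x$n_failed, x$years[last],
              p[last, 2L], p[last, 1L], p[last, 3L]))
  invisible(x)
}

SCENARIO_KEYS <- c("estimated", "fixed2", "fixed1.1", "none", "cvd-freeze")

scenario_from_key <- function(key, horizon_year = 2040L,
                              standard_year = 2015L,
                              cvd_freeze_year = 2014L) {
  if (!key %in% SCENARIO_KEYS) {
    stopf("unknown scenario '%s'; valid keys: %s", key,
          paste(SCENARIO_KEYS, collapse = ", "))
  }
  if (key == "cvd-freeze") {
    scenario_spec("estimated", cvd_freeze_year = cvd_freeze_year,
                  horizon_year = horizon_year,
                  standard_population_year = standard_year)
  } else {
    scenario_spec(key, horizon_year = horizon_year,
                  standard_population_year = standard_year)
  }
}

#' Load a pipeline configuration from YAML or JSON
#'
#' A single structured document with sections mirroring the pipeline
#' modules; every conventional constant (the -1.5 SD impairment threshold,
#' 3.6 IQCODE cut-point, 0.973 incidence odds ratio, 1000 draws, 2006 base
#' year, 2040 horizon, 2015 standard year, 2014 CVD freeze year) is a
#' named key defaulting to [default_constants()].
#'
#' @param config a file path (.yaml/.yml/.json) or a list.
#' @return the merged configuration list.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  defaults <- list(
    seed = 1L,
    n_core = 11400L,
    scenarios = SCENARIO_KEYS,
    trend_method = "joint",
    z_impairment_threshold = default_constants()$z_impairment_threshold,
    iqcode_cut = default_constants()$iqcode_cut,
    true_incidence_trend_or = default_constants()$trend_or_per_year,
    n_draws = default_constants()$n_draws,
    base_year = default_constants()$base_year,
    horizon_year = default_constants()$horizon_year,
    standard_population_year = default_constants()$standard_population_year,
    cvd_freeze_year = default_constants()$cvd_freeze_year,
    psa = FALSE,
    out_dir = NULL
  )
  utils::modifyList(defaults, config)
}

#' Run the scenario battery end to end
#'
#' Generates (or accepts) a panel, ascertains dementia, estimates the
#' calendar trend, calibrates the transition model, and projects every
#' requested scenario; optionally adds a probabilistic sensitivity
#' analysis for the first scenario. With an `out_dir`, per-scenario tidy
#' CSV outputs and a JSON run header (inputs, package version) are
#' written.
#'
#' @param config list or config file path (see [load_config()]).
#' @param panel optional pre-built `panel_dataset` (generated from the
#'   config seed when NULL).
#' @return list: `trend`, `calibration`, `projections` (one
#'   `projection_output` per scenario key), `comparison` (per-year
#'   dementia counts side by side), optional `psa`.
#' @export
run_scenarios <- function(config = list(), panel = NULL) {
  cfg <- load_config(config)
  for (key in cfg$scenarios) {
    if (!key %in% SCENARIO_KEYS) {
      stopf("unknown scenario '%s'; valid keys: %s", key,
            paste(SCENARIO_KEYS, collapse = ", "))
    }
  }
  if (is.null(panel)) {
    panel <- generate_cohort(cohort_config(
      n_core = cfg$n_core, seed = cfg$seed,
      true_incidence_trend_or = cfg$true_incidence_trend_or))
  }
  asc <- ascertain_panel(panel, threshold = cfg$z_impairment_threshold,
                         iqcode_cut = cfg$iqcode_cut)
  trend <- if (identical(cfg$trend_method, "joint")) {
    jm <- fit_joint_model(panel, asc$statuses, asc$zscores)
    extract_calendar_trend(predict_dementia_probability(jm, panel, asc$statuses))
  } else {
    fit_naive_trend(panel, asc$statuses)$trend
  }
  calib <- calibrate_model(panel, asc, trend = trend,
                           base_year = cfg$base_year,
                           horizon_year = cfg$horizon_year)
  pop <- generate_population_structure(base_year = cfg$base_year,
                                       horizon_year = cfg$horizon_year)
  init <- initialize_population(pop, calib$start_prev)
  projections <- list()
  for (key in cfg$scenarios) {
    sc <- scenario_from_key(key, cfg$horizon_year,
                            cfg$standard_population_year, cfg$cvd_freeze_year)
    tset <- suppressWarnings(
      build_transition_set(calib$tp1, trend, calib$mort_surface,
                           calib$state_odds, sc, calib$start_prev))
    projections[[key]] <- project_population(
      init, tset, entrants = pop$entrants, horizon_year = cfg$horizon_year,
      standard_year = cfg$standard_population_year)
  }
  comparison <- data.frame(year = projections[[1L]]$years)
  for (key in names(projections)) {
    comparison[[key]] <- projections[[key]]$summary$dementia_count
  }
  res <- list(trend = trend, calibration = calib, projections = projections,
              comparison = comparison, config = cfg, population = pop)
  if (isTRUE(cfg$psa) || (is.list(cfg$psa) && isTRUE(cfg$psa$enabled))) {
    nd <- if (is.list(cfg$psa)) cfg$psa$n_draws %||% cfg$n_draws else cfg$n_draws
    sc1 <- scenario_from_key(cfg$scenarios[1L], cfg$horizon_year,
                             cfg$standard_population_year, cfg$cvd_freeze_year)
    res$psa <- run_psa(calib, pop, sc1, n_draws = nd, seed = cfg$seed)
  }
  if (!is.null(cfg$out_dir)) write_scenario_outputs(res, cfg$out_dir)
  res
}

write_scenario_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(res$projections)) {
    utils::write.csv(res$projections[[key]]$summary,
                     file.path(out_dir, paste0("projection_", gsub("[^a-z0-9.]", "_", key), ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(res$comparison, file.path(out_dir, "scenario_comparison.csv"),
                   row.names = FALSE)
  header <- list(
    package_version = as.character(utils::packageVersion("demproj")),
    seed = res$config$seed,
    scenarios = res$config$scenarios,
    trend_or_per_year = if (inherits(res$trend, "trend_estimate"))
      res$trend$odds_ratio_per_year else res$trend,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(header, file.path(out_dir, "run_header.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
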