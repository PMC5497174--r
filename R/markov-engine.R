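## Discrete-time cohort projection engine: the population, held as counts
## by single year of age (35 to 100+), sex and health state, is pushed
## through the calendar-specific one-year transition probabilities, aged
## by one year, and topped up with the entering cohort of 35-year-olds
## (assumed free of CVD and of cognitive and functional impairment).

#' Initialise the population state from a population grid and prevalences
#'
#' @param pop_inputs a `population_inputs` (see
#'   [generate_population_structure()]).
#' @param start_prev a `starting_prevalence`.
#' @return object of class `population_state`: `year`, `counts` (array
#'   age x sex x state), `cum_deaths` (named by cause), `entered` (total
#'   entrants so far, 0).
#' @export
initialize_population <- function(pop_inputs, start_prev) {
  ages <- start_prev$ages
  base <- pop_inputs$base
  counts <- array(0, dim = c(length(ages), 2L, 8L),
                  dimnames = list(age = ages, sex = c("male", "female"),
                                  state = 1:8))
  for (sx in c("male", "female")) {
    b <- base[base$sex == sx, ]
    m <- match(ages, b$age)
    if (any(is.na(m))) stopf("population grid does not cover ages %s",
                             paste(ages[is.na(m)], collapse = ","))
    counts[, sx, ] <- b$count[m] * start_prev$prev[, sx, ]
  }
  structure(list(year = pop_inputs$base_year, counts = counts,
                 cum_deaths = c(cvd = 0, noncvd = 0), entered = 0),
            class = "population_state")
}

#' Apply a state-transition kernel to a vector of counts
#'
#' The core one-cycle operation on a single stratum: counts by from-state
#' times the transition matrix. Exposed separately so the engine kernel
#' can be validated against direct matrix powers on toy models.
#'
#' @param counts numeric vector of length n_from.
#' @param P transition matrix (n_from x n_to), rows summing to at most 1.
#' @return numeric vector of length n_to.
#' @export
apply_transitions <- function(counts, P) {
  as.vector(crossprod(P, counts))
}

## One year for one sex: transitions (vectorised over ages via rowsum),
## then age advance with an absorbing 100+ band.
step_sex <- function(cmat, Pslice, ages_n) {
  ## cmat: ages x 8; Pslice: ages x 8 x 10
  tmp <- matrix(Pslice, nrow = ages_n * 8L, ncol = 10L) * as.vector(cmat)
  out <- rowsum(tmp, group = rep(seq_len(ages_n), times = 8L), reorder = FALSE)
  live <- out[, 1:8, drop = FALSE]
  aged <- rbind(0, live[-ages_n, , drop = FALSE])
  aged[ages_n, ] <- aged[ages_n, ] + live[ages_n, ]  # open 100+ band
  list(aged = aged, deaths = colSums(out[, 9:10, drop = FALSE]))
}

#' Advance the population by one year
#'
#' Applies the year's one-year transition probabilities, advances age by
#' one year (the 100+ band is open), and injects the entering cohort of
#' 35-year-olds into the healthy state. Deaths accumulate by cause and
#' are attributed to the year of the transition.
#'
#' @param state a `population_state`.
#' @param tset a `transition_set` covering `state$year`.
#' @param entrants named or ordered numeric of length 2 (male, female)
#'   entering at the youngest age, or NULL for none.
#' @return the `population_state` at `year + 1`.
#' @export
step_population <- function(state, tset, entrants = NULL) {
  t <- match(state$year, tset$years)
  if (is.na(t)) stopf("transition set does not cover year %d", state$year)
  nA <- length(tset$ages)
  newc <- state$counts
  deaths <- c(cvd = 0, noncvd = 0)
  for (sx in 1:2) {
    r <- step_sex(state$counts[, sx, ], tset$P[, sx, , , t], nA)
    newc[, sx, ] <- r$aged
    deaths <- deaths + r$deaths
  }
  if (any(newc < -1e-9)) stopf("negative counts after update: invalid transition probabilities")
  entered <- 0
  if (!is.null(entrants)) {
    newc[1L, "male", 1L] <- newc[1L, "male", 1L] + entrants[[1L]]
    newc[1L, "female", 1L] <- newc[1L, "female", 1L] + entrants[[2L]]
    entered <- sum(unlist(entrants))
  }
  structure(list(year = state$year + 1L, counts = newc,
                 cum_deaths = state$cum_deaths + deaths,
                 entered = state$entered + entered),
            class = "population_state")
}

#' Project the population over the full horizon
#'
#' Repeatedly applies [step_population()] from the base year to the
#' horizon, recording state counts, dementia counts (states 6 + 7), crude
#' dementia prevalence for ages 50+ and 65+ by sex and overall, deaths by
#' cause, and age-standardised dementia prevalence (weights = the modelled
#' population age structure of the standard year).
#'
#' @param init a `population_state` (see [initialize_population()]).
#' @param tset a `transition_set` covering every year to the horizon.
#' @param entrants data.frame (year, sex, count) of 35-year-old entrants.
#' @param horizon_year last projected year (defaults to the transition
#'   set's last year).
#' @param standard_year reference year for age standardisation (default
#'   2015).
#' @return object of class `projection_output`: `years`, `counts` (age x
#'   sex x state x year), `summary` (tidy per-year metrics), `deaths`,
#'   `conservation` (relative person-conservation error per year).
#' @export
project_population <- function(init, tset, entrants = NULL,
                               horizon_year = max(tset$years),
                               standard_year = 2015L) {
  if (horizon_year > max(tset$years)) {
    stopf("horizon %d beyond transition set (%d)", horizon_year, max(tset$years))
  }
  years <- init$year:horizon_year
  nY <- length(years)
  nA <- length(tset$ages)
  counts <- array(0, dim = c(nA, 2L, 8L, nY),
                  dimnames = c(dimnames(init$counts), list(year = years)))
  deaths <- matrix(0, nY, 2L, dimnames = list(years, c("cvd", "noncvd")))
  conservation <- numeric(nY)
  initial_total <- sum(init$counts)
  st <- init
  counts[, , , 1L] <- st$counts
  for (t in 2:nY) {
    y_next <- years[t]
    ent <- if (!is.null(entrants)) {
      e <- entrants[entrants$year == y_next, ]
      list(male = sum(e$count[e$sex == "male"]),
           female = sum(e$count[e$sex == "female"]))
    }
    st <- step_population(st, tset, ent)
    counts[, , , t] <- st$counts
    deaths[t, ] <- st$cum_deaths
    conservation[t] <- abs(sum(st$counts) + sum(st$cum_deaths) -
                             initial_total - st$entered) /
      (initial_total + st$entered)
  }
  out <- structure(list(years = years, ages = tset$ages, counts = counts,
                        cum_deaths = deaths, conservation = conservation,
                        standard_year = standard_year),
                   class = "projection_output")
  out$summary <- summarise_projection(out)
  out
}

summarise_projection <- function(out) {
  ages <- out$ages
  dem_states <- STATE_DEMENTIA
  rows <- lapply(seq_along(out$years), function(t) {
    cy <- out$counts[, , , t]
    dem_by_sex <- apply(cy[, , dem_states, drop = FALSE], 2, sum)
    tot_by_sex <- apply(cy, 2, sum)
    r <- data.frame(year = out$years[t],
                    total_population = sum(tot_by_sex),
                    dementia_count = sum(dem_by_sex),
                    dementia_count_male = dem_by_sex[["male"]],
                    dementia_count_female = dem_by_sex[["female"]])
    for (amin in c(50L, 65L)) {
      sel <- ages >= amin
      dem <- apply(cy[sel, , dem_states, drop = FALSE], 2, sum)
      tot <- apply(cy[sel, , , drop = FALSE], 2, sum)
      r[[sprintf("prev_%dplus", amin)]] <- sum(dem) / sum(tot)
      r[[sprintf("prev_%dplus_male", amin)]] <- dem[["male"]] / tot[["male"]]
      r[[sprintf("prev_%dplus_female", amin)]] <- dem[["female"]] / tot[["female"]]
    }
    r
  })
  s <- do.call(rbind, rows)
  ## short runs that end before the standard year fall back to their last
  ## modelled year for the standardisation weights
  std_year <- if (out$standard_year %in% out$years) out$standard_year else max(out$years)
  std <- age_standardised_prevalence(out, standard_year = std_year, min_age = 50L)
  s$prev_50plus_std <- std$standardised_prevalence[match(s$year, std$year)]
  rownames(s) <- NULL
  s
}

#' Age-standardised dementia prevalence series
#'
#' Weights the age-sex-specific dementia prevalence of every projected
#' year by the modelled population structure of the standard year, so
#' changes in age composition are removed from the trend.
#'
#' @param out a `projection_output`.
#' @param standard_year reference year (defaults to the output's).
#' @param min_age lower age bound of the denominator (default 50).
#' @return data.frame: year, standardised_prevalence.
#' @export
age_standardised_prevalence <- function(out, standard_year = out$standard_year,
                                        min_age = 50L) {
  ti <- match(standard_year, out$years)
  if (is.na(ti)) stopf("standard year %d not in the projection", standard_year)
  sel <- out$ages >= min_age
  Wstd <- apply(out$counts[sel, , , ti, drop = FALSE], c(1, 2), sum)
  Wstd <- Wstd / sum(Wstd)
  data.frame(
    year = out$years,
    standardised_prevalence = vapply(seq_along(out$years), function(t) {
      cy <- out$counts[sel, , , t, drop = FALSE]
      dem <- apply(cy[, , STATE_DEMENTIA, , drop = FALSE], c(1, 2), sum)
      tot <- apply(cy, c(1, 2), sum)
      prev <- ifelse(tot > 0, dem / tot, 0)
      sum(Wstd * prev)
    }, numeric(1))
  )
}

#' @export
print.projection_output <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Projection %d-%d: dementia count %.0f -> %.0f; crude 50+ prevalence %.2f%% -> %.2f%%\n",
              min(x$years), max(x$years),
              s$dementia_count[1L], s$dementia_count[nrow(s)],
              100 * s$prev_50plus[1L], 100 * s$prev_50plus[nrow(s)]))
  invisible(x)
}

#' Period and cohort life expectancy and disability-free life expectancy
#'
#' Follows a unit cohort from the starting age through the
#' calendar-varying transition probabilities (the last modelled year's
#' probabilities are held beyond the horizon). Life expectancy is the sum
#' of expected person-years lived after the starting year; disability-free
#' life expectancy counts only person-years in the non-impaired states
#' (1-4 by default).
#'
#' @param tset a `transition_set`.
#' @param age starting age (must be on the grid).
#' @param sex `"male"` or `"female"`.
#' @param year calendar year the cohort starts (default first modelled).
#' @param disability_states states counted as disabled (default 5:8).
#' @param start_state initial state distribution: a single state index or
#'   a probability vector of length 8 (default state 1).
#' @param max_years iteration cap (default 120).
#' @return named numeric: `le` and `dfle`, in years.
#' @export
life_expectancy <- function(tset, age, sex, year = min(tset$years),
                            disability_states = STATE_FI,
                            start_state = 1L, max_years = 120L) {
  ai <- match(age, tset$ages)
  if (is.na(ai)) stopf("starting age %s outside the model age grid", age)
  v <- numeric(8L)
  if (length(start_state) == 1L) v[start_state] <- 1 else v <- start_state / sum(start_state)
  free_states <- setdiff(1:8, disability_states)
  nA <- length(tset$ages)
  le <- 0; dfle <- 0
  a <- ai; y <- year
  for (k in seq_len(max_years)) {
    t <- match(min(y, max(tset$years)), tset$years)
    P <- tset$P[a, match(sex, c("male", "female")), , , t]
    v <- apply_transitions(v, P)[1:8]
    le <- le + sum(v)
    dfle <- dfle + sum(v[free_states])
    a <- min(a + 1L, nA)
    y <- y + 1L
    if (sum(v) < 1e-12) break
  }
  c(le = le, dfle = dfle)
}
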