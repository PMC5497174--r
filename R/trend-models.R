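## Calendar-trend estimators for dementia incidence on biennial panel data.
##
## Events are interval-censored at two-year waves, so all three estimators
## are discrete-time per-epoch formulations: a logistic per-epoch hazard
## (naive analogue of a proportional-hazards fit censoring at death and
## dropout), a multinomial no-event/dementia/death model (competing-risks
## analogue in which epochs ending in death do not dilute the dementia
## hazard), and a shared-random-effects joint model of the longitudinal
## average standardised cognitive score and the event process, which
## corrects for outcome-dependent (informative) dropout.

#' Construct a calendar-trend estimate
#'
#' @param log_or_per_year log odds ratio per calendar year.
#' @param se standard error of the log odds ratio.
#' @param sex_specific optional named list of per-sex `trend_estimate`s.
#' @return object of class `trend_estimate` with `odds_ratio_per_year`,
#'   `ci95`, `relative_annual_decline_pct` (100 x (1 - OR)) and
#'   `odds_ratio_per_epoch` (the two-year-epoch OR, the square of the
#'   per-year OR).
#' @export
trend_estimate <- function(log_or_per_year, se, sex_specific = NULL) {
  or <- exp(log_or_per_year)
  structure(list(
    odds_ratio_per_year = or,
    ci95 = exp(log_or_per_year + c(-1, 1) * 1.96 * se),
    log_or_per_year = log_or_per_year,
    se_log_or = se,
    relative_annual_decline_pct = 100 * (1 - or),
    odds_ratio_per_epoch = or^2,
    sex_specific = sex_specific
  ), class = "trend_estimate")
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf("Calendar trend: OR %.4f per year (95%% CI %.4f-%.4f); relative annual decline %.2f%%\n",
              x$odds_ratio_per_year, x$ci95[1L], x$ci95[2L],
              x$relative_annual_decline_pct))
  invisible(x)
}

## Risk-epoch construction: one row per dementia-free person per two-year
## wave pair, with the epoch outcome. Deaths are known for dropouts too
## (register linkage). Prevalent cases contribute nothing.
build_risk_epochs <- function(panel, statuses, analysis_waves = 1:6) {
  p <- as_panel_df(panel)
  p <- p[p$wave %in% analysis_waves, ]
  p <- p[order(p$person_id, p$wave), ]
  st <- as.data.frame(statuses)
  m <- match(p$person_id, st$person_id)
  asc_wave <- st$ascertainment_wave[m]
  prevalent <- !is.na(st$prevalent_at_entry[m]) & st$prevalent_at_entry[m]

  max_w <- max(analysis_waves)
  ## epoch starts at an observed, dementia-free wave
  at_risk <- p$wave < max_w & !prevalent &
    (is.na(asc_wave) | p$wave < asc_wave)
  e <- p[at_risk, c("person_id", "wave", "year", "age", "sex", "education",
                    "obesity", "hypertension", "diabetes", "smoking",
                    "inactive", "death_year", "death_cause")]
  key_next <- paste(e$person_id, e$wave + 1L)
  interviewed <- key_next %in% paste(p$person_id, p$wave)
  dementia_next <- !is.na(asc_wave[at_risk]) & e$wave + 1L == asc_wave[at_risk]
  died <- !is.na(e$death_year) & e$death_year <= e$year + 2
  e$outcome <- ifelse(died, "death",
                      ifelse(dementia_next, "dementia",
                             ifelse(interviewed, "none", "dropout")))
  e$interviewed <- interviewed & !died
  rownames(e) <- NULL
  e
}

## Shared fixed-effect design for the per-epoch hazard models.
hazard_design <- function(e) {
  data.frame(
    y = as.integer(e$outcome == "dementia"),
    age_c = (e$age - 75) / 10,
    female = as.integer(e$sex == "female"),
    yr_c = e$year - 2006,
    outcome = e$outcome
  )
}

check_separation <- function(coefs) {
  if (any(!is.finite(coefs)) || any(abs(coefs) > 15)) {
    stopf("quasi-separation in the hazard fit; a larger sample is needed")
  }
}

hazard_fit <- function(coefficients, vcov, model_kind, n_epochs) {
  structure(list(coefficients = coefficients, vcov = vcov,
                 model_kind = model_kind, n_epochs = n_epochs),
            class = "hazard_fit")
}

#' Naive discrete-time calendar-trend estimate
#'
#' Logistic per-epoch hazard of incident dementia with terms for age, age
#' squared, sex, age-by-sex and calendar year. Participants are censored at
#' dropout (their post-dropout epochs are excluded) and at death (the epoch
#' in which a dementia-free participant dies counts as an at-risk, no-event
#' epoch). This estimator corrects for neither informative dropout nor the
#' competing risk of death; onsets masked by death within an epoch are
#' lost, which attenuates the calendar trend when mortality declines.
#'
#' @param panel panel data.frame or `panel_dataset`.
#' @param statuses [ascertain_dementia()] output.
#' @param analysis_waves waves used (default 1-6).
#' @return list with `fit` (a `hazard_fit`) and `trend` (a
#'   `trend_estimate`).
#' @export
fit_naive_trend <- function(panel, statuses, analysis_waves = 1:6) {
  e <- build_risk_epochs(panel, statuses, analysis_waves)
  e <- e[e$outcome %in% c("none", "dementia", "death"), ]
  d <- hazard_design(e)
  if (sum(d$y) == 0L) stopf("no incident dementia cases in the risk set")
  fit <- stats::glm(y ~ age_c + I(age_c^2) + female + age_c:female + yr_c,
                    family = stats::binomial(), data = d)
  check_separation(stats::coef(fit))
  b <- stats::coef(fit)[["yr_c"]]
  se <- sqrt(stats::vcov(fit)["yr_c", "yr_c"])
  list(fit = hazard_fit(stats::coef(fit), stats::vcov(fit), "naive", nrow(d)),
       trend = trend_estimate(b, se))
}

#' Competing-risks discrete-time calendar-trend estimate
#'
#' Multinomial per-epoch model with outcomes no-event / incident dementia /
#' death and the same covariates as [fit_naive_trend()]. Death is a
#' distinct outcome rather than a no-event at-risk epoch, so epochs ending
#' in death neither dilute the dementia hazard nor discard the information
#' that an onset could have been masked; the dementia-versus-no-event logit
#' estimates the latent onset hazard free of mortality masking, and its
#' calendar coefficient is the reported trend. With no deaths in the data
#' the model reduces to the naive logistic fit.
#'
#' @inheritParams fit_naive_trend
#' @return list with `fit` (a `hazard_fit`, multinomial coefficients) and
#'   `trend`.
#' @export
fit_competing_risks_trend <- function(panel, statuses, analysis_waves = 1:6) {
  e <- build_risk_epochs(panel, statuses, analysis_waves)
  e <- e[e$outcome %in% c("none", "dementia", "death"), ]
  d <- hazard_design(e)
  if (sum(d$y) == 0L) stopf("no incident dementia cases in the risk set")
  d$outcome <- factor(d$outcome, levels = intersect(c("none", "dementia", "death"),
                                                    unique(d$outcome)))
  fit <- nnet::multinom(outcome ~ age_c + I(age_c^2) + female + age_c:female + yr_c,
                        data = d, trace = FALSE, maxit = 200)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, 1L, dimnames = list("dementia", names(cf)))
  check_separation(cf)
  V <- stats::vcov(fit)
  idx <- grep("^dementia:yr_c$|^yr_c$", rownames(V))
  if (!length(idx)) idx <- which(rownames(V) == "dementia:yr_c")
  b <- cf["dementia", "yr_c"]
  se <- sqrt(V[idx[1L], idx[1L]])
  list(fit = hazard_fit(cf, V, "competing-risks", nrow(d)),
       trend = trend_estimate(b, se))
}

## ---------------------------------------------------------------------
## Joint model of longitudinal cognition and incident dementia
## ---------------------------------------------------------------------

## Longitudinal observations: valid pre-onset average standardised scores.
build_longitudinal_data <- function(panel, statuses, zscores,
                                    analysis_waves = 1:6) {
  p <- as_panel_df(panel)
  z <- as.data.frame(zscores)
  key <- paste(p$person_id, p$wave)
  p$avg_z <- z$avg_z[match(key, paste(z$person_id, z$wave))]
  p$valid <- z$valid_assessment[match(key, paste(z$person_id, z$wave))]
  st <- as.data.frame(statuses)
  m <- match(p$person_id, st$person_id)
  asc_wave <- st$ascertainment_wave[m]
  prevalent <- !is.na(st$prevalent_at_entry[m]) & st$prevalent_at_entry[m]
  keep <- p$wave %in% analysis_waves & !prevalent & !is.na(p$avg_z) & p$valid &
    (is.na(asc_wave) | p$wave < asc_wave)
  l <- p[keep, c("person_id", "wave", "year", "age", "sex", "education",
                 "avg_z")]
  first <- !duplicated(p$person_id)
  entry_year <- p$year[first][match(l$person_id, p$person_id[first])]
  entry_age <- p$age[first][match(l$person_id, p$person_id[first])]
  l$time <- l$year - entry_year
  l$age_entry <- entry_age
  l$age_c65 <- (l$age - 65) / 10  # random-slope variable (decades of age)
  ## midlife risk-factor history: first-wave values
  for (v in c("obesity", "hypertension", "diabetes")) {
    l[[v]] <- p[[v]][first][match(l$person_id, p$person_id[first])]
  }
  l
}

## Closed-form empirical-Bayes posterior of the (intercept, age-slope)
## random effects given the fitted longitudinal parameters. The random
## slope is on current age (decades, centred at 65), so a person's latent
## trajectory is b0 + b1 * (age - 65)/10 around the fixed mean.
eb_posteriors <- function(l, beta, Xl, Sigma_b, sigma2, ids) {
  r <- l$avg_z - as.vector(Xl %*% beta)
  zv <- l$age_c65
  pi_ <- match(l$person_id, ids)
  s11 <- rowsum(rep(1, length(r)), pi_)[, 1L]
  s1t <- rowsum(zv, pi_)[, 1L]
  stt <- rowsum(zv^2, pi_)[, 1L]
  zr1 <- rowsum(r, pi_)[, 1L]
  zrt <- rowsum(r * zv, pi_)[, 1L]
  P <- length(ids)
  present <- sort(unique(pi_))
  S <- matrix(0, P, 5L, dimnames = list(NULL, c("s11", "s1t", "stt", "zr1", "zrt")))
  S[present, ] <- cbind(s11, s1t, stt, zr1, zrt)
  Sinv <- solve(Sigma_b)
  ## precision A = Z'Z/sigma2 + Sigma^-1, elementwise over persons
  a11 <- S[, "s11"] / sigma2 + Sinv[1L, 1L]
  a12 <- S[, "s1t"] / sigma2 + Sinv[1L, 2L]
  a22 <- S[, "stt"] / sigma2 + Sinv[2L, 2L]
  det <- a11 * a22 - a12^2
  v11 <- a22 / det; v12 <- -a12 / det; v22 <- a11 / det
  b1 <- S[, "zr1"] / sigma2; b2 <- S[, "zrt"] / sigma2
  mu1 <- v11 * b1 + v12 * b2
  mu2 <- v12 * b1 + v22 * b2
  ## lower Cholesky of the 2x2 posterior covariance
  l11 <- sqrt(v11)
  l21 <- v12 / l11
  l22 <- sqrt(pmax(v22 - l21^2, 1e-12))
  list(mu = cbind(mu1, mu2), L = cbind(l11, l21, l22),
       n_obs = S[, "s11"])
}

long_fixed_design <- function(df) {
  stats::model.matrix(
    ~ I((age_entry - 65) / 10) + I(((age_entry - 65) / 10)^2) + time +
      I(time^2) + factor(sex, levels = c("male", "female")) +
      I(year - 2006) + factor(education, levels = c("none", "intermediate", "higher")) +
      obesity + hypertension + diabetes,
    data = df)
}

#' Joint model of longitudinal cognition and incident dementia
#'
#' Fits a shared-random-effects joint model in two linked stages. The
#' longitudinal submodel is a linear mixed model for the average
#' standardised cognitive score with fixed effects for age at entry (and
#' its square), time since entry (and its square), sex, calendar year,
#' education and midlife obesity/hypertension/diabetes, and correlated
#' random intercepts and time slopes (maximum likelihood, via lme4). The
#' event submodel is a discrete-time per-epoch logistic hazard of incident
#' dementia whose linear predictor includes the current latent score value
#' (association `alpha_value`) and its slope (`alpha_slope`); its
#' parameters maximise the joint marginal likelihood, integrating the
#' random effects out by adaptive Gauss-Hermite quadrature centred on each
#' person's empirical-Bayes posterior, with the longitudinal parameters
#' held at their ML estimates (the exact conditional decomposition of the
#' joint likelihood). Because dropout that depends on the latent intercept
#' and slope is ignorable given the random effects, the event-submodel
#' estimates are free of selective-attrition bias.
#'
#' @inheritParams fit_naive_trend
#' @param zscores output of [standardize_domain_scores()] (computed from
#'   `panel` when NULL).
#' @param quad_points adaptive Gauss-Hermite points per random-effect
#'   dimension (default 9).
#' @param laplace_fallback use a single-point (Laplace-style) approximation
#'   if the quadrature fit fails to converge.
#' @return object of class `joint_model_fit`.
#' @export
fit_joint_model <- function(panel, statuses, zscores = NULL,
                            analysis_waves = 1:6, quad_points = 9L,
                            laplace_fallback = TRUE) {
  if (is.null(zscores)) zscores <- standardize_domain_scores(panel)
  l <- build_longitudinal_data(panel, statuses, zscores, analysis_waves)
  n_per <- table(l$person_id)
  if (mean(n_per >= 3L) < 0.2) {
    warnf("fewer than 20%% of participants have 3+ longitudinal observations; joint model may be weakly identified")
  }

  ## stage 1: longitudinal linear mixed model (ML)
  lf <- lme4::lmer(
    avg_z ~ I((age_entry - 65) / 10) + I(((age_entry - 65) / 10)^2) + time +
      I(time^2) + factor(sex, levels = c("male", "female")) + I(year - 2006) +
      factor(education, levels = c("none", "intermediate", "higher")) +
      obesity + hypertension + diabetes + (1 + age_c65 | person_id),
    data = l, REML = FALSE,
    control = lme4::lmerControl(calc.derivs = FALSE))
  beta <- lme4::fixef(lf)
  vc <- lme4::VarCorr(lf)$person_id
  Sigma_b <- nearest_psd(matrix(as.numeric(vc), 2L, 2L))
  sigma2 <- stats::sigma(lf)^2

  ## stage 2: event submodel by adaptive Gauss-Hermite quadrature
  e <- build_risk_epochs(panel, statuses, analysis_waves)
  ev <- e[e$interviewed | e$outcome == "dementia", ]
  ev <- annotate_epoch_longitudinal(ev, l)
  ids <- sort(unique(ev$person_id))
  lsub <- l[l$person_id %in% ids, ]
  Xl <- long_fixed_design(lsub)
  post <- eb_posteriors(lsub, beta, Xl, Sigma_b, sigma2, ids)

  es <- event_structures(ev, ids, beta, quad_points, post)
  theta0 <- event_start_values(ev, es)
  obj <- function(th) -event_loglik(th, es)$loglik
  grd <- function(th) -event_loglik(th, es, gradient = TRUE)$gradient
  opt <- stats::optim(theta0, obj, grd, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  converged <- opt$convergence == 0L
  if (!converged && laplace_fallback) {
    es1 <- event_structures(ev, ids, beta, 1L, post)
    opt <- stats::optim(opt$par, function(th) -event_loglik(th, es1)$loglik,
                        function(th) -event_loglik(th, es1, gradient = TRUE)$gradient,
                        method = "BFGS", control = list(maxit = 200))
    converged <- opt$convergence == 0L
  }
  H <- stats::optimHess(opt$par, obj, grd)
  V <- tryCatch(solve(H), error = function(e) {
    warnf("singular Hessian in event submodel; covariance repaired")
    MASS::ginv(H)
  })
  theta <- opt$par

  structure(list(
    longitudinal = list(fixed_effects = beta, re_covariance = Sigma_b,
                        residual_sd = sqrt(sigma2),
                        lmer_loglik = as.numeric(stats::logLik(lf))),
    event = list(coefficients = theta, vcov = V,
                 alpha_value = theta[["alpha_value"]],
                 alpha_slope = theta[["alpha_slope"]]),
    loglik = -opt$value,
    loglik_start = event_loglik(theta0, es)$loglik,
    converged = converged,
    quad_points = quad_points,
    posteriors = post, ids = ids,
    beta = beta, Sigma_b = Sigma_b, sigma2 = sigma2,
    analysis_waves = analysis_waves
  ), class = "joint_model_fit")
}

#' @export
print.joint_model_fit <- function(x, ...) {
  cat("Joint longitudinal / discrete-time event model\n")
  cat(sprintf("  alpha_value %.3f, alpha_slope %.3f; event loglik %.1f; converged: %s\n",
              x$event$alpha_value, x$event$alpha_slope, x$loglik, x$converged))
  invisible(x)
}

## Attach time-since-entry and the longitudinal fixed-effect frame to epochs.
annotate_epoch_longitudinal <- function(ev, l) {
  first <- !duplicated(l$person_id)
  m <- match(ev$person_id, l$person_id[first])
  ev$age_entry <- l$age_entry[first][m]
  ev$entry_year <- (l$year - l$time)[first][m]
  ## persons without longitudinal rows: entry from the epoch itself
  miss <- is.na(ev$age_entry)
  if (any(miss)) {
    fe <- !duplicated(ev$person_id)
    ev$age_entry[miss] <- (ev$age[fe][match(ev$person_id, ev$person_id[fe])])[miss]
    ev$entry_year[miss] <- (ev$year[fe][match(ev$person_id, ev$person_id[fe])])[miss]
  }
  ev$time <- ev$year - ev$entry_year
  for (v in c("obesity", "hypertension", "diabetes")) {
    lv <- l[[v]][first][m]
    ev[[paste0(v, "_entry")]] <- ifelse(is.na(lv), ev[[v]], lv)
  }
  ev
}

## Theta-independent structures for the event marginal likelihood: fixed
## design, per-node latent values M and slopes S, person index, weights.
event_structures <- function(ev, ids, beta, quad_points, post) {
  pi_ <- match(ev$person_id, ids)
  X <- cbind(
    intercept = 1,
    age_c = (ev$age - 75) / 10,
    age_c2 = ((ev$age - 75) / 10)^2,
    female = as.integer(ev$sex == "female"),
    age_sex = (ev$age - 75) / 10 * (ev$sex == "female"),
    yr_c = ev$year - 2006,
    obesity = as.numeric(ev$obesity),
    hypertension = as.numeric(ev$hypertension),
    diabetes = as.numeric(ev$diabetes),
    smoking = as.numeric(ev$smoking),
    inactive = as.numeric(ev$inactive)
  )
  y <- as.integer(ev$outcome == "dementia")
  ## fixed part of the latent value / slope at the epoch start
  lf_frame <- data.frame(age_entry = ev$age_entry, time = ev$time,
                         year = ev$year, sex = ev$sex,
                         education = ev$education,
                         obesity = ev$obesity_entry,
                         hypertension = ev$hypertension_entry,
                         diabetes = ev$diabetes_entry)
  Xlf <- long_fixed_design(lf_frame)
  mfix <- as.vector(Xlf %*% beta)
  sfix <- beta[["time"]] + 2 * beta[["I(time^2)"]] * ev$time

  if (quad_points > 1L) {
    gh <- gh_grid_2d(quad_points)
    z <- gh$z; logw <- gh$logw
  } else {
    z <- matrix(0, 1L, 2L); logw <- 0
  }
  Q <- nrow(z)
  s2 <- sqrt(2)
  B0 <- post$mu[, 1L] + s2 * outer(post$L[, "l11"], z[, 1L])
  B1 <- post$mu[, 2L] + s2 * (outer(post$L[, "l21"], z[, 1L]) +
                                outer(post$L[, "l22"], z[, 2L]))
  a_c <- (ev$age - 65) / 10  # random-slope loading at the epoch start
  M <- mfix + B0[pi_, , drop = FALSE] + B1[pi_, , drop = FALSE] * a_c
  S <- sfix + B1[pi_, , drop = FALSE] / 10  # per-year latent slope
  list(X = X, y = y, pi_ = pi_, M = M, S = S, logw = logw, Q = Q,
       P = length(ids), mfix = mfix, sfix = sfix)
}

## Plug-in start values: logistic fit with posterior-mean latent value and
## slope as covariates (the classic two-stage estimator).
event_start_values <- function(ev, es) {
  mhat <- as.vector(es$M %*% exp(es$logw))
  shat <- as.vector(es$S %*% exp(es$logw))
  d <- as.data.frame(es$X[, -1L])
  d$y <- es$y; d$mhat <- mhat; d$shat <- shat
  covs <- setdiff(colnames(es$X), "intercept")
  f <- stats::glm(stats::as.formula(paste("y ~", paste(c(covs, "mhat", "shat"),
                                                       collapse = " + "))),
                  family = stats::binomial(), data = d)
  cf <- stats::coef(f)
  theta <- c(cf[["(Intercept)"]], cf[covs], cf[["mhat"]], cf[["shat"]])
  names(theta) <- c(colnames(es$X), "alpha_value", "alpha_slope")
  theta
}

## Marginal log-likelihood (and gradient) of the event submodel under the
## adaptive quadrature representation.
event_loglik <- function(theta, es, gradient = FALSE) {
  k <- ncol(es$X)
  eta <- as.vector(es$X %*% theta[seq_len(k)]) +
    theta[[k + 1L]] * es$M + theta[[k + 2L]] * es$S
  ll <- es$y * eta - log1p(exp(eta))
  persum <- rowsum(ll, es$pi_)                     # P x Q
  Li <- row_log_sum_exp(persum + rep(es$logw, each = nrow(persum)))
  out <- list(loglik = sum(Li))
  if (gradient) {
    Om <- exp(persum + rep(es$logw, each = nrow(persum)) - Li)  # posterior wts
    W <- Om[es$pi_, , drop = FALSE]
    E <- (es$y - stats::plogis(eta)) * W
    g_fixed <- as.vector(crossprod(es$X, rowSums(E)))
    out$gradient <- c(g_fixed, sum(E * es$M), sum(E * es$S))
    names(out$gradient) <- names(theta)
  }
  out
}

#' Predicted per-epoch dementia probabilities for everyone alive
#'
#' For every dementia-free person alive at each epoch start -- including
#' participants lost to follow-up, whose vital status is known through
#' register linkage -- computes the marginal probability of incident
#' dementia in that epoch from the fitted event submodel, integrating over
#' the person's empirical-Bayes random-effect posterior given their
#' observed cognitive history. Persons with no valid longitudinal
#' observations receive prior-mean random effects and are flagged.
#'
#' @param fit a [fit_joint_model()] result.
#' @param panel the panel the fit was computed from.
#' @param statuses the ascertained statuses.
#' @param integrate average the response probability over the
#'   random-effect posterior instead of plugging in the empirical-Bayes
#'   posterior mean (default FALSE: plug-in EB, which keeps the log odds
#'   linear in the person-level effects and free of posterior-width
#'   artefacts when follow-up length varies).
#' @return data.frame of class `dementia_predictions`: person-epoch rows
#'   with `p_dementia`, `observed` (epoch outcome was observed) and
#'   `n_longitudinal_obs`.
#' @export
predict_dementia_probability <- function(fit, panel, statuses,
                                         integrate = FALSE) {
  if (!isTRUE(fit$converged)) {
    warnf("joint model did not converge; predictions may be unreliable")
  }
  p <- as_panel_df(panel)
  st <- as.data.frame(statuses)
  aw <- fit$analysis_waves
  wave_years <- sort(unique(p$year[p$wave %in% aw]))
  waves <- sort(unique(p$wave[p$wave %in% aw]))

  first <- !duplicated(p$person_id)
  per <- p[first, c("person_id", "wave", "year", "age", "sex", "education",
                    "obesity", "hypertension", "diabetes", "death_year")]
  m <- match(per$person_id, st$person_id)
  asc_wave <- st$ascertainment_wave[m]
  prevalent <- !is.na(st$prevalent_at_entry[m]) & st$prevalent_at_entry[m]

  ## all epochs from entry while alive and not yet ascertained
  rows <- lapply(seq_len(length(waves) - 1L), function(wi) {
    w <- waves[wi]; y <- wave_years[wi]
    ok <- per$wave <= w & !prevalent &
      (is.na(per$death_year) | per$death_year > y) &
      (is.na(asc_wave) | asc_wave > w)
    if (!any(ok)) return(NULL)
    d <- per[ok, ]
    data.frame(person_id = d$person_id, wave = w, year = y,
               age = d$age + (y - d$year), sex = d$sex,
               education = d$education, obesity = d$obesity,
               hypertension = d$hypertension, diabetes = d$diabetes,
               entry_year = d$year, age_entry = d$age)
  })
  ep <- do.call(rbind, rows)
  ep$time <- ep$year - ep$entry_year
  ep$obesity_entry <- ep$obesity
  ep$hypertension_entry <- ep$hypertension
  ep$diabetes_entry <- ep$diabetes
  ## per-epoch risk-factor values, last observation carried forward for
  ## epochs after dropout
  ep <- locf_risk_factors(ep, p, c("obesity", "hypertension", "diabetes",
                                   "smoking", "inactive"))

  ## posterior structures for the union of persons (prior for the unseen)
  ids_all <- sort(unique(ep$person_id))
  post <- expand_posteriors(fit, ids_all)
  qp <- if (integrate) fit$quad_points else 1L
  es <- event_structures(ep, ids_all, fit$beta, qp, post)
  k <- ncol(es$X)
  theta <- fit$event$coefficients
  eta <- as.vector(es$X %*% theta[seq_len(k)]) +
    theta[[k + 1L]] * es$M + theta[[k + 2L]] * es$S
  ep$p_dementia <- as.vector(stats::plogis(eta) %*% exp(es$logw))
  ep$n_longitudinal_obs <- post$n_obs[match(ep$person_id, ids_all)]
  ep$prior_mean_effects <- ep$n_longitudinal_obs == 0
  ## was this epoch's outcome actually observed?
  e_obs <- build_risk_epochs(p, st, aw)
  ep$observed <- paste(ep$person_id, ep$wave) %in%
    paste(e_obs$person_id, e_obs$wave)[e_obs$interviewed |
                                         e_obs$outcome == "dementia"]
  out <- ep[c("person_id", "wave", "year", "age", "sex", "p_dementia",
              "observed", "n_longitudinal_obs", "prior_mean_effects")]
  class(out) <- c("dementia_predictions", "data.frame")
  out
}

## Per-epoch risk-factor values from the panel, with the last observed
## value carried forward to epochs after dropout. `p` must be sorted by
## person and wave.
locf_risk_factors <- function(d, p, risk_factors) {
  for (v in risk_factors) {
    obs <- p[!is.na(p[[v]]), c("person_id", "wave", v)]
    mkey <- match(paste(d$person_id, d$wave), paste(obs$person_id, obs$wave))
    val <- obs[[v]][mkey]
    lastv <- tapply(obs[[v]], obs$person_id, function(x) x[length(x)])
    val[is.na(val)] <- lastv[as.character(d$person_id[is.na(val)])]
    d[[v]] <- as.numeric(val)
  }
  d
}

## Posterior means/chols for an id set possibly larger than the fit's.
expand_posteriors <- function(fit, ids_all) {
  P <- length(ids_all)
  mu <- matrix(0, P, 2L)
  Sb <- fit$Sigma_b
  l11 <- sqrt(Sb[1L, 1L]); l21 <- Sb[2L, 1L] / l11
  l22 <- sqrt(max(Sb[2L, 2L] - l21^2, 1e-12))
  L <- matrix(rep(c(l11, l21, l22), each = P), P, 3L,
              dimnames = list(NULL, c("l11", "l21", "l22")))
  n_obs <- numeric(P)
  m <- match(fit$ids, ids_all)
  ok <- !is.na(m)
  mu[m[ok], ] <- fit$posteriors$mu[ok, ]
  L[m[ok], ] <- fit$posteriors$L[ok, ]
  n_obs[m[ok]] <- fit$posteriors$n_obs[ok]
  list(mu = mu, L = L, n_obs = n_obs)
}

#' Extract the calendar trend from predicted dementia probabilities
#'
#' Linear regression of the log odds of the predicted per-epoch dementia
#' probability on sex, age, age squared, the interactions of sex with age
#' and age squared, and calendar time; the per-year incidence odds ratio is
#' the exponentiated calendar coefficient.
#'
#' @param predictions output of [predict_dementia_probability()] (any
#'   data.frame with `p_dementia`, `age`, `sex`, `year`).
#' @param eps probabilities at 0 or 1 are clipped to `[eps, 1 - eps]` with
#'   a warning.
#' @param sex_specific also fit per-sex regressions.
#' @return a `trend_estimate`.
#' @export
extract_calendar_trend <- function(predictions, eps = 1e-6,
                                   sex_specific = FALSE) {
  d <- as.data.frame(predictions)
  d$lo <- stats::qlogis(clip_probability(d$p_dementia, eps))
  d$age_c <- (d$age - 75) / 10
  d$female <- as.integer(d$sex == "female")
  d$yr_c <- d$year - 2006
  fml <- lo ~ female * (age_c + I(age_c^2)) + yr_c
  f <- stats::lm(fml, data = d)
  b <- stats::coef(f)[["yr_c"]]
  se <- sqrt(stats::vcov(f)["yr_c", "yr_c"])
  ss <- NULL
  if (sex_specific) {
    ss <- lapply(split(d, d$sex), function(dd) {
      ff <- stats::lm(lo ~ age_c + I(age_c^2) + yr_c, data = dd)
      trend_estimate(stats::coef(ff)[["yr_c"]],
                     sqrt(stats::vcov(ff)["yr_c", "yr_c"]))
    })
  }
  trend_estimate(b, se, sex_specific = ss)
}

#' Risk-factor-adjusted calendar trend and attenuation
#'
#' Repeats the [extract_calendar_trend()] regression with time-varying risk
#' factors added and reports the adjusted per-year odds ratio together with
#' the percentage attenuation of the calendar log-odds coefficient,
#' 100 x (1 - beta_adjusted / beta_unadjusted). For epochs after dropout
#' the last observed risk-factor values are carried forward. Collinear
#' covariates are dropped with a warning.
#'
#' @inheritParams extract_calendar_trend
#' @param panel the panel supplying per-wave risk-factor values.
#' @param risk_factors columns used (default the five generator factors).
#' @return list with `trend` (adjusted `trend_estimate`),
#'   `unadjusted_trend` and `attenuation_pct`.
#' @export
adjust_trend_for_risk_factors <- function(predictions, panel,
                                          risk_factors = c("obesity", "hypertension",
                                                           "diabetes", "smoking",
                                                           "inactive"),
                                          eps = 1e-6) {
  d <- as.data.frame(predictions)
  p <- as_panel_df(panel)
  p <- p[order(p$person_id, p$wave), ]
  missing_rf <- setdiff(risk_factors, names(p))
  if (length(missing_rf)) stopf("panel lacks risk-factor columns: %s",
                                paste(missing_rf, collapse = ", "))
  ## carry last observed values forward to unobserved epochs
  d <- locf_risk_factors(d, p, risk_factors)
  d$lo <- stats::qlogis(clip_probability(d$p_dementia, eps))
  d$age_c <- (d$age - 75) / 10
  d$female <- as.integer(d$sex == "female")
  d$yr_c <- d$year - 2006
  f0 <- stats::lm(lo ~ female * (age_c + I(age_c^2)) + yr_c, data = d)
  fml <- stats::as.formula(paste("lo ~ female * (age_c + I(age_c^2)) + yr_c +",
                                 paste(risk_factors, collapse = " + ")))
  f1 <- stats::lm(fml, data = d)
  cf <- stats::coef(f1)
  if (any(is.na(cf))) {
    warnf("collinear covariates dropped: %s",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  b0 <- stats::coef(f0)[["yr_c"]]
  b1 <- cf[["yr_c"]]
  list(
    trend = trend_estimate(b1, sqrt(stats::vcov(f1)["yr_c", "yr_c"])),
    unadjusted_trend = trend_estimate(b0, sqrt(stats::vcov(f0)["yr_c", "yr_c"])),
    attenuation_pct = 100 * (1 - b1 / b0)
  )
}
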