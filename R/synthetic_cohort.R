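# Synthetic donor cohorts with the exact statistical structure of either
# model family.  Donation status is endogenous: at each visit from the
# second onward, a donor donates exactly when the simulated Hb reaches the
# clinical cut-off (optionally thinned by a non-Hb deferral probability),
# and the donation indicator feeds forward into the next visit's DPV
# covariate.  The first visit is a health check and never a donation.

#' Synthetic cohort configuration
#'
#' Panel-structure settings shared by both generators.  Visit counts are
#' drawn uniformly on `visits_min..visits_max`; entry ages uniformly on
#' `age_entry_low..age_entry_high`; age increases by `age_increment` years
#' per visit (the default 0.20 years corresponds to the ~72-day median
#' inter-visit interval of male donors); seasons are i.i.d. warm with
#' probability `p_warm` (0.5 matches the roughly even cold/warm split of
#' registry visits); `p_other_deferral` is the probability that an
#' Hb-eligible donor is deferred for non-Hb reasons.
#'
#' @param n_donors Number of donors.
#' @param gender `"M"` or `"F"`.
#' @param visits_min,visits_max Bounds on visits per donor (min >= 2).
#' @param age_entry_low,age_entry_high Entry-age range in years.
#' @param age_increment Years added per visit.
#' @param p_warm Probability a visit falls in the warm season.
#' @param p_other_deferral Probability an eligible donor does not donate.
#' @param seed Integer seed; the generators are reproducible given the seed.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_donors, gender = c("M", "F"), visits_min = 2L,
                          visits_max = 12L, age_entry_low = 18,
                          age_entry_high = 65, age_increment = 0.20,
                          p_warm = 0.5, p_other_deferral = 0, seed = NULL) {
  gender <- match.arg(gender)
  stopifnot(is_scalar_number(n_donors), n_donors >= 1,
            is_scalar_number(visits_min), visits_min >= 2,
            is_scalar_number(visits_max), visits_max >= visits_min,
            is_scalar_number(age_increment), age_increment > 0,
            is_scalar_number(p_warm), p_warm >= 0, p_warm <= 1,
            is_scalar_number(p_other_deferral),
            p_other_deferral >= 0, p_other_deferral < 1,
            age_entry_low > 0, age_entry_high >= age_entry_low)
  structure(list(n_donors = as.integer(n_donors), gender = gender,
                 visits_min = as.integer(visits_min),
                 visits_max = as.integer(visits_max),
                 age_entry_low = age_entry_low,
                 age_entry_high = age_entry_high,
                 age_increment = age_increment, p_warm = p_warm,
                 p_other_deferral = p_other_deferral, seed = seed),
            class = "cohort_config")
}

# Draw the covariate frame and the feedback loop shared by both generators.
# `hb_fun(t, age_t, season_t, dpv_t)` returns the visit-t Hb vector for all
# donors given that visit's covariates.
simulate_cohort_engine <- function(config, rule, hb_fun) {
  n <- config$n_donors
  tmax <- config$visits_max
  T_i <- if (config$visits_min == config$visits_max)
    rep(config$visits_min, n)
  else
    sample(config$visits_min:config$visits_max, n, replace = TRUE)
  entry_age <- runif(n, config$age_entry_low, config$age_entry_high)
  season <- matrix(rbinom(n * tmax, 1L, config$p_warm), n, tmax)
  u_other <- matrix(runif(n * tmax), n, tmax)
  cutoff <- hb_cutoff(rule, config$gender)

  hb <- age <- matrix(NA_real_, n, tmax)
  dpv <- donated <- matrix(0L, n, tmax)
  for (t in seq_len(tmax)) {
    age[, t] <- entry_age + (t - 1L) * config$age_increment
    if (t >= 2L) dpv[, t] <- donated[, t - 1L]
    hb[, t] <- hb_fun(t, age[, t], season[, t], dpv[, t])
    if (t >= 2L)  # first visit is a health check, never a donation
      donated[, t] <- as.integer(hb[, t] >= cutoff &
                                   u_other[, t] >= config$p_other_deferral)
  }
  keep <- rep(seq_len(n), T_i)
  visit <- sequence(T_i)
  flat <- cbind(keep, visit)
  as_cohort(data.frame(
    donor_id = sprintf("D%05d", keep),
    gender = config$gender,
    visit = visit,
    age = age[flat],
    season = season[flat],
    dpv = dpv[flat],
    donated = donated[flat],
    hb = hb[flat],
    stringsAsFactors = FALSE))
}

#' Simulate a cohort from the transition (autoregressive) process
#'
#' For each donor a zero-mean latent AR(q) series `z_t` with lag
#' coefficients `gamma` and innovation variance `sigma2_eps` is generated
#' (50 burn-in steps before the first visit), and the observed Hb is
#' `hb_t = mu_w + z_t + beta.(age_t, season_t, dpv_t)` with
#' `mu_w = alpha / (1 - sum(gamma))` — the generative reading of the
#' order-`q` transition model.  Donation status feeds back endogenously
#' through the clinical cut-off.
#'
#' @param params A stationary [transition_params] object.
#' @param config A [cohort_config]; its `seed` makes the draw reproducible.
#' @param rule An [eligibility_rule].
#' @return A `donor_cohort`.
#' @export
simulate_transition_cohort <- function(params, config,
                                       rule = eligibility_rule()) {
  stopifnot(inherits(params, "transition_params"),
            inherits(config, "cohort_config"))
  check_stationary(params$gamma)
  with_seed(config$seed, {
    n <- config$n_donors
    q <- params$q
    burn <- 50L + q
    steps <- burn + config$visits_max
    sd_eps <- sqrt(params$sigma2_eps)
    z <- matrix(0, n, steps)
    for (t in seq_len(steps)) {
      lags <- 0
      for (r in seq_len(min(q, t - 1L)))
        lags <- lags + params$gamma[r] * z[, t - r]
      z[, t] <- lags + rnorm(n, 0, sd_eps)
    }
    z <- z[, (burn + 1L):steps, drop = FALSE]
    mu_w <- params$alpha / (1 - sum(params$gamma))
    b <- params$beta
    simulate_cohort_engine(config, rule, function(t, age, season, dpv) {
      mu_w + z[, t] + b[["age"]] * age + b[["season"]] * season +
        b[["dpv"]] * dpv
    })
  })
}

#' Simulate a cohort from the mixed-model process
#'
#' Per donor, a random intercept `b0 ~ N(0, sigma2_b0)` and (under the
#' `"RIRS"` structure) an independent random age slope `b1 ~ N(0,
#' sigma2_b1)` are drawn, and
#' `hb_t = alpha + b0 + (beta_age + b1) age_t + beta_season season_t +
#' beta_dpv dpv_t + eps_t` with i.i.d. `N(0, sigma2_eps)` errors.  Donation
#' status feeds back endogenously through the clinical cut-off.
#'
#' @param params An [lme_params] object.
#' @param config A [cohort_config]; its `seed` makes the draw reproducible.
#' @param rule An [eligibility_rule].
#' @return A `donor_cohort`.
#' @export
simulate_lme_cohort <- function(params, config, rule = eligibility_rule()) {
  stopifnot(inherits(params, "lme_params"),
            inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_donors
    b0 <- rnorm(n, 0, sqrt(params$sigma2_b0))
    b1 <- if (params$structure == "RIRS")
      rnorm(n, 0, sqrt(params$sigma2_b1)) else rep(0, n)
    eps <- matrix(rnorm(n * config$visits_max, 0, sqrt(params$sigma2_eps)),
                  n, config$visits_max)
    b <- params$beta
    simulate_cohort_engine(config, rule, function(t, age, season, dpv) {
      params$alpha + b0 + (b[["age"]] + b1) * age + b[["season"]] * season +
        b[["dpv"]] * dpv + eps[, t]
    })
  })
}
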