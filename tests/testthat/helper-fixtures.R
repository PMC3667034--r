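# Fixture builders shared across test files.

# Hand-build a cohort from per-donor Hb series; covariates get simple
# deterministic values unless supplied, and dpv is derived from donated.
make_cohort <- function(hb_by_donor, gender = "M", age_start = 30,
                        donated_by_donor = NULL, season_by_donor = NULL) {
  rows <- lapply(seq_along(hb_by_donor), function(i) {
    hb <- hb_by_donor[[i]]
    Tn <- length(hb)
    donated <- if (is.null(donated_by_donor)) c(0L, rep(1L, Tn - 1L)) else
      donated_by_donor[[i]]
    season <- if (is.null(season_by_donor)) rep(c(0L, 1L), length.out = Tn) else
      season_by_donor[[i]]
    data.frame(donor_id = sprintf("D%03d", i), gender = gender,
               visit = seq_len(Tn), age = age_start + i + 0.2 * (seq_len(Tn) - 1L),
               season = season, dpv = c(0L, donated[-Tn]), donated = donated,
               hb = hb, stringsAsFactors = FALSE)
  })
  as_cohort(do.call(rbind, rows))
}

# A random clean cohort with arbitrary (non-model) Hb values, for structural
# and likelihood-identity tests.
random_cohort <- function(n_donors, t_min = 2, t_max = 6, gender = "M",
                          hb_mean = 9.5) {
  hb <- lapply(seq_len(n_donors), function(i) {
    Tn <- if (t_min == t_max) t_min else sample(t_min:t_max, 1)
    round(rnorm(Tn, hb_mean, 0.6), 4)
  })
  donated <- lapply(hb, function(h) c(0L, as.integer(runif(length(h) - 1) > 0.3)))
  make_cohort(hb, gender = gender, donated_by_donor = donated)
}

# Generating truths for the parameter-recovery experiments: the published
# training-set estimates for male and female donor cohorts, used as the
# true values of the simulate -> refit round trips.  The residual variances
# are configuration (the source tables do not report them): sigma_eps = 0.5
# for the transition processes; sigma_b0 = 0.35, sigma_b1 = 0.005,
# sigma_eps = 0.45 for the mixed processes.
recovery_truth <- list(
  male_ar1 = list(params = transition_params(9.6309, c(-0.0043, -0.0615, -0.0469),
                                             0.5158, 0.25),
                  gender = "M", visits_min = 2),
  male_ar2 = list(params = transition_params(9.6441, c(-0.0044, -0.0681, -0.0350),
                                             c(0.3685, 0.2888), 0.25),
                  gender = "M", visits_min = 3),
  female_ar1 = list(params = transition_params(8.2394, c(0.0044, -0.0405, -0.1411),
                                               0.4669, 0.25),
                    gender = "F", visits_min = 2),
  male_lme_ri = list(params = lme_params(9.6719, c(-0.0049, -0.0698, -0.0636),
                                         0.35^2, 0, 0.45^2, "RI"),
                     gender = "M", visits_min = 2),
  female_lme_rirs = list(params = lme_params(8.2832, c(0.0037, -0.0411, -0.1387),
                                             0.35^2, 0.005^2, 0.45^2, "RIRS"),
                         gender = "F", visits_min = 2)
)
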