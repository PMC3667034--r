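test_that("stationary_covariance matches closed forms and a simulated path", {
  # AR(1): variance sigma2 / (1 - gamma^2)
  expect_equal(stationary_covariance(0.5, 1)[1, 1], 4 / 3, tolerance = 1e-12)
  # gamma = 0: white noise, sigma2 * identity
  expect_equal(stationary_covariance(c(0, 0), 2.5), 2.5 * diag(2),
               tolerance = 1e-12)
  expect_equal(stationary_covariance(c(0, 0, 0), 1.1), 1.1 * diag(3),
               tolerance = 1e-12)
  # AR(2): against time averages of one long simulated path
  gamma <- c(0.3, 0.2); sigma2 <- 1
  S <- stationary_covariance(gamma, sigma2)
  set.seed(4)
  n <- 2e6; burn <- 500
  x <- numeric(n + burn)
  for (t in 3:(n + burn))
    x[t] <- gamma[1] * x[t - 1] + gamma[2] * x[t - 2] + rnorm(1)
  x <- x[-(1:burn)]
  expect_equal(S[1, 1], mean(x^2), tolerance = 0.02)
  expect_equal(S[1, 2], mean(x[-1] * x[-n]), tolerance = 0.02)
  expect_true(isSymmetric(S))
  expect_true(all(eigen(S, only.values = TRUE)$values > 0))
  expect_error(stationary_covariance(c(0.7, 0.4), 1), "non-stationary")
})

test_that("exact likelihood reduces to independent normals when gamma = 0", {
  set.seed(21)
  coh <- random_cohort(8)
  p <- transition_params(9.4, c(0, 0, 0), c(0, 0), 0.5)
  expect_equal(exact_loglik(p, coh),
               sum(dnorm(coh$hb, 9.4, sqrt(0.5), log = TRUE)),
               tolerance = 1e-10)
})

test_that("exact likelihood equals direct small-sample normal densities", {
  # q = 1, one donor, 3 visits: trivariate normal with
  # cov(s, t) = sigma2 * gamma^|s-t| / (1 - gamma^2)
  gamma <- 0.6; sigma2 <- 0.4
  p <- transition_params(3.8, c(-0.004, -0.06, -0.05), gamma, sigma2)
  coh <- make_cohort(list(c(9.2, 9.6, 9.1)))
  S <- sigma2 * gamma^abs(outer(1:3, 1:3, "-")) / (1 - gamma^2)
  xb <- as.vector(cbind(coh$age, coh$season, coh$dpv) %*% p$beta)
  mu <- xb + 3.8 / (1 - gamma)
  expect_equal(exact_loglik(p, coh), oracle_dmvnorm(coh$hb, mu, S),
               tolerance = 1e-10)

  # q = 2, one donor with a single visit: stationary marginal
  p2 <- transition_params(2.0, c(-0.004, -0.06, -0.05), c(0.3, 0.2), 0.4)
  one <- data.frame(donor_id = "D1", gender = "M", visit = 1L, age = 40,
                    season = 1L, dpv = 0L, donated = 0L, hb = 9.0)
  mu1 <- sum(c(40, 1, 0) * p2$beta) + 2.0 / (1 - 0.5)
  s11 <- stationary_covariance(c(0.3, 0.2), 0.4)[1, 1]
  expect_equal(exact_loglik(p2, as_cohort(one)),
               dnorm(9.0, mu1, sqrt(s11), log = TRUE), tolerance = 1e-10)
})

test_that("exact likelihood agrees with the dense multivariate-normal oracle", {
  set.seed(22)
  for (q in 1:3) {
    gamma <- switch(q, 0.55, c(0.35, 0.25), c(0.3, 0.2, 0.15))
    p <- transition_params(3.5, c(-0.004, -0.05, -0.06), gamma, 0.3)
    for (rep in 1:3) {
      coh <- random_cohort(6, t_min = 2, t_max = 8)
      expect_equal(exact_loglik(p, coh), oracle_transition_loglik(p, coh),
                   tolerance = 1e-8)
    }
  }
})

test_that("likelihood is invariant to donor order and additive over splits", {
  set.seed(23)
  coh <- random_cohort(9)
  p <- transition_params(3.5, c(-0.004, -0.05, -0.06), c(0.4, 0.2), 0.3)
  ids <- unique(coh$donor_id)
  shuffled <- as_cohort(coh[order(match(coh$donor_id, rev(ids)), coh$visit), ])
  expect_equal(exact_loglik(p, shuffled), exact_loglik(p, coh),
               tolerance = 1e-10)
  part1 <- as_cohort(coh[coh$donor_id %in% ids[1:4], ])
  part2 <- as_cohort(coh[!coh$donor_id %in% ids[1:4], ])
  expect_equal(exact_loglik(p, part1) + exact_loglik(p, part2),
               exact_loglik(p, coh), tolerance = 1e-10)
})

test_that("fit_transition matches a brute-force dense-likelihood optimizer", {
  p <- transition_params(4.7, c(-0.004, -0.06, -0.05), 0.5, 0.25)
  coh <- simulate_transition_cohort(
    p, cohort_config(5, "M", visits_min = 4, visits_max = 4, seed = 61))
  fit <- fit_transition(coh, 1, options = list(reltol = 1e-12, ndeps = 1e-6))
  start <- c(4.0, -0.003, -0.05, -0.04, 0.3, log(0.3))
  brute <- optim(start, function(th) {
    if (abs(th[5]) >= 0.999) return(1e10)
    pp <- transition_params(th[1], th[2:4], th[5], exp(th[6]))
    -oracle_transition_loglik(pp, coh)
  }, method = "BFGS",
  control = list(maxit = 2000, reltol = 1e-12, ndeps = rep(1e-6, 6)))
  expect_equal(fit$params$alpha, brute$par[1], tolerance = 1e-3)
  expect_equal(unname(fit$params$beta), brute$par[2:4], tolerance = 1e-4)
  expect_equal(unname(fit$params$gamma), brute$par[5], tolerance = 1e-4)
  expect_equal(fit$params$sigma2_eps, exp(brute$par[6]), tolerance = 1e-4)
  expect_equal(fit$loglik, -brute$value, tolerance = 1e-6)
})

test_that("null autoregression is recovered as approximately zero", {
  p <- transition_params(9.5, c(-0.004, -0.06, -0.05), 0, 0.25)
  coh <- simulate_transition_cohort(p, cohort_config(800, "M", seed = 62))
  fit <- fit_transition(coh, 1)
  expect_lt(abs(fit$params$gamma), 3 * fit$se[["gamma1"]])
  # and the regression coefficients approach the OLS benchmark
  ols <- fit_ols(coh)
  expect_equal(unname(fit$params$beta), unname(ols$params$beta),
               tolerance = 0.02)
})

test_that("fit_transition rejects unusable designs and reports convergence", {
  p <- transition_params(4.7, c(-0.004, -0.06, -0.05), 0.5, 0.25)
  coh <- simulate_transition_cohort(p, cohort_config(40, "M", seed = 63))
  const <- as.data.frame(coh)
  const$season <- 0L
  expect_error(fit_transition(as_cohort(const), 1), "singular")
  fit <- fit_transition(coh, 1)
  expect_type(fit$converged, "logical")
  expect_true(all(fit$se[is.finite(fit$se)] >= 0))
  expect_identical(fit$n_params, 6L)
})

test_that("dynamic AR predictions use history only, never the current Hb", {
  p <- transition_params(4.7, c(-0.004, -0.06, -0.05), c(0.5, 0.2), 0.25)
  coh <- simulate_transition_cohort(
    p, cohort_config(20, "M", visits_min = 5, visits_max = 7, seed = 64))
  pred <- predict_dynamic_ar(p, coh)
  expect_identical(pred$observed, coh$hb)

  # t = 1: covariates only
  f <- coh$visit == 1
  mu_w <- p$alpha / (1 - sum(p$gamma))
  xb <- as.vector(cbind(coh$age, coh$season, coh$dpv) %*% p$beta)
  expect_equal(pred$predicted[f], xb[f] + mu_w, tolerance = 1e-10)

  # causality: perturbing y at visit t leaves predictions for s <= t unchanged
  pert <- as.data.frame(coh)
  tgt <- which(pert$donor_id == pert$donor_id[1] & pert$visit == 3)
  pert$hb[tgt] <- pert$hb[tgt] + 5
  pred2 <- predict_dynamic_ar(p, as_cohort(pert))
  same <- pred2$donor_id == pert$donor_id[tgt] & pred2$visit <= 3
  expect_equal(pred2$predicted[same], pred$predicted[same], tolerance = 1e-12)
  after <- pred2$donor_id == pert$donor_id[tgt] & pred2$visit == 4
  expect_false(isTRUE(all.equal(pred2$predicted[after], pred$predicted[after])))

  # donor order does not affect per-donor predictions
  ids <- unique(coh$donor_id)
  shuffled <- as_cohort(coh[order(match(coh$donor_id, rev(ids)), coh$visit), ])
  pred3 <- predict_dynamic_ar(p, shuffled)
  key <- paste(pred$donor_id, pred$visit)
  key3 <- paste(pred3$donor_id, pred3$visit)
  expect_equal(pred3$predicted[match(key, key3)], pred$predicted,
               tolerance = 1e-12)
})

test_that("one-step AR(1) prediction equals the conditional-normal mean", {
  gamma <- 0.6; sigma2 <- 0.3
  p <- transition_params(3.8, c(-0.004, -0.06, -0.05), gamma, sigma2)
  coh <- make_cohort(list(c(9.2, 9.6), c(8.9, 9.0)))
  pred <- predict_dynamic_ar(p, coh)
  xb <- as.vector(cbind(coh$age, coh$season, coh$dpv) %*% p$beta)
  mu_w <- 3.8 / (1 - gamma)
  i2 <- which(coh$visit == 2)
  manual <- xb[i2] + mu_w + gamma * (coh$hb[i2 - 1] - xb[i2 - 1] - mu_w)
  expect_equal(pred$predicted[i2], manual, tolerance = 1e-12)
})

test_that("within-stationary-block predictions match the conditional MVN oracle", {
  # q = 3, visits 2 and 3 precede a full lag window: conditional mean of the
  # stationary joint normal given the shorter history
  gamma <- c(0.3, 0.2, 0.15); sigma2 <- 0.3
  p <- transition_params(2.0, c(-0.004, -0.06, -0.05), gamma, sigma2)
  coh <- make_cohort(list(c(9.2, 9.6, 9.1, 9.4)))
  pred <- predict_dynamic_ar(p, coh)
  xb <- as.vector(cbind(coh$age, coh$season, coh$dpv) %*% p$beta)
  mu_w <- 2.0 / (1 - sum(gamma))
  z <- coh$hb - xb - mu_w
  acov <- oracle_ar_acov(gamma, sigma2, 3)
  S <- outer(1:4, 1:4, function(i, j) acov[abs(i - j) + 1])
  for (t in 2:4) {
    cond <- S[t, 1:(t - 1)] %*% solve(S[1:(t - 1), 1:(t - 1)], z[1:(t - 1)])
    expect_equal(pred$predicted[t], xb[t] + mu_w + as.numeric(cond),
                 tolerance = 1e-10)
  }
})

test_that("simulate-refit recovery stays within three standard errors", {
  # reduced-size replicate study; the full-scale recovery runs in the
  # acceptance suite
  tru <- transition_params(4.7, c(-0.004, -0.06, -0.05), 0.45, 0.25)
  n_rep <- 100
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    coh <- simulate_transition_cohort(
      tru, cohort_config(150, "M", visits_min = 2, visits_max = 8,
                         seed = 7000 + r))
    fit <- fit_transition(coh, 1)
    est <- c(fit$params$alpha, fit$params$beta, fit$params$gamma)
    truth <- c(tru$alpha, tru$beta, tru$gamma)
    se <- fit$se[1:5]
    ok[r] <- fit$converged && all(is.finite(se)) &&
      all(abs(est - truth) <= 3 * se)
  }
  expect_gte(mean(ok), 0.95)
})
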