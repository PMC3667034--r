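# Linear mixed-effects models for Hb trajectories:
#
#   RI:    y_it = alpha + b0_i + beta.x_it + eps_it
#   RIRS:  y_it = alpha + b0_i + (beta_age + b1_i) Age_it
#                 + beta_season Season_it + beta_dpv DPV_it + eps_it
#
# with b_i ~ N(0, D), D diagonal, eps_it ~ iid N(0, sigma2_eps), b_i and
# eps_i independent.  Variance components are estimated by REML with the
# fixed effects profiled out by generalized least squares; per-donor
# V_i = Z_i D Z_i' + sigma2 I is handled through the Woodbury identity on
# donor-level cross-products, so evaluation is vectorised over donors.
# Donor-specific effects are predicted by empirical Bayes (BLUP) from the
# donor's accumulated history, which yields the dynamic one-step-ahead
# predictions.

#' Mixed-model parameters
#'
#' @param alpha Intercept (mmol/l).
#' @param beta Length-3 fixed-effect vector `(age, season, dpv)`.
#' @param sigma2_b0 Random-intercept variance, >= 0.
#' @param sigma2_b1 Random age-slope variance, >= 0; forced to 0 for the
#'   `"RI"` structure.
#' @param sigma2_eps Residual variance; must be positive for likelihood
#'   evaluation, while 0 is accepted so that a noise-free cohort can be
#'   simulated.
#' @param structure `"RI"` (random intercept) or `"RIRS"` (random intercept
#'   plus random age slope); the random-effects covariance is diagonal.
#' @return An `lme_params` object.
#' @export
lme_params <- function(alpha, beta, sigma2_b0, sigma2_b1 = 0, sigma2_eps,
                       structure = c("RI", "RIRS")) {
  structure <- match.arg(structure)
  stopifnot(is_scalar_number(alpha), is.numeric(beta), length(beta) == 3L,
            is_scalar_number(sigma2_b0), sigma2_b0 >= 0,
            is_scalar_number(sigma2_b1), sigma2_b1 >= 0,
            is_scalar_number(sigma2_eps), sigma2_eps >= 0)
  if (structure == "RI") sigma2_b1 <- 0
  out <- list(alpha = unname(alpha),
              beta = setNames(as.numeric(beta), c("age", "season", "dpv")),
              sigma2_b0 = unname(sigma2_b0), sigma2_b1 = unname(sigma2_b1),
              sigma2_eps = unname(sigma2_eps), structure = structure)
  class(out) <- "lme_params"
  out
}

# Donor-level sufficient statistics for the Woodbury evaluation.
# Z has columns (1, age); the RI structure simply keeps g1 = 0.
lme_stats <- function(cohort) {
  d <- as_cohort(cohort)
  X <- covariate_matrix(d, intercept = TRUE)
  y <- d$hb
  id <- factor(d$donor_id, levels = unique(d$donor_id))
  one <- rep(1, nrow(d))
  list(d = d, X = X, y = y, id = id,
       n_i = as.vector(rowsum(one, id)),
       Sa = as.vector(rowsum(d$age, id)),
       Saa = as.vector(rowsum(d$age^2, id)),
       U1 = rowsum(X, id),                # Z row 1 (intercept) times X
       U2 = rowsum(X * d$age, id),        # Z row 2 (age) times X
       v1 = as.vector(rowsum(y, id)),
       v2 = as.vector(rowsum(y * d$age, id)),
       XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y^2),
       n = nrow(d), p = ncol(X), g = nlevels(id))
}

# Gaussian (restricted) log-likelihood for variance components
# (s2b0, s2b1, s2e) given the donor-level statistics, with the fixed
# effects profiled out by GLS.  Returns the log-likelihood plus the GLS
# solution, so the fitter and the public criterion share one code path.
lme_objective <- function(st, s2b0, s2b1, s2e, reml = TRUE) {
  g0 <- s2b0 / s2e
  g1 <- s2b1 / s2e
  # K_i = G (I + C_i G)^{-1}, the 2x2 Woodbury core per donor (vectorised)
  detB <- (1 + st$n_i * g0) * (1 + st$Saa * g1) - st$Sa^2 * g0 * g1
  if (any(detB <= 0)) return(list(loglik = -Inf))
  k11 <- g0 * (1 + st$Saa * g1) / detB
  k12 <- -g0 * g1 * st$Sa / detB
  k22 <- g1 * (1 + st$n_i * g0) / detB
  KU1 <- st$U1 * k11 + st$U2 * k12       # row i: K_i %*% (U1_i, U2_i)
  KU2 <- st$U1 * k12 + st$U2 * k22
  A <- (st$XtX - crossprod(st$U1, KU1) - crossprod(st$U2, KU2)) / s2e
  b <- (st$Xty - crossprod(st$U1, st$v1 * k11 + st$v2 * k12)
              - crossprod(st$U2, st$v1 * k12 + st$v2 * k22)) / s2e
  yVy <- (st$yty - sum(st$v1^2 * k11 + 2 * st$v1 * st$v2 * k12 +
                         st$v2^2 * k22)) / s2e
  cA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(cA)) return(list(loglik = -Inf))
  beta_gls <- backsolve(cA, backsolve(cA, b, transpose = TRUE))
  quad <- yVy - sum(b * beta_gls)
  sum_logdet <- st$n * log(s2e) + sum(log(detB))
  ll <- if (reml) {
    -0.5 * (sum_logdet + 2 * sum(log(diag(cA))) + quad +
              (st$n - st$p) * log(2 * pi))
  } else {
    -0.5 * (sum_logdet + quad + st$n * log(2 * pi))
  }
  list(loglik = ll, beta = as.vector(beta_gls), chol_A = cA, quad = quad)
}

#' Restricted log-likelihood of a mixed model
#'
#' Evaluates the Gaussian REML criterion for the given variance components
#' on a donor panel, with the fixed effects profiled out by generalized
#' least squares: per donor `V_i = Z_i D Z_i' + sigma2_eps I`, and the
#' criterion is `-1/2 [ sum_i log|V_i| + log|X'V^-1 X| + y'Py +
#' (n - p) log 2 pi ]`.  The fixed effects inside `params` are ignored
#' (they are profiled out); only the variance components and the structure
#' matter.
#'
#' @param params An [lme_params] object.
#' @param cohort A `donor_cohort`.
#' @return The restricted log-likelihood (scalar).
#' @export
reml_criterion <- function(params, cohort) {
  stopifnot(inherits(params, "lme_params"))
  st <- lme_stats(cohort)
  lme_objective(st, params$sigma2_b0, params$sigma2_b1,
                params$sigma2_eps)$loglik
}

#' Ordinary least squares benchmark
#'
#' Fits the multiple linear regression of Hb on age, season and donation at
#' previous visit, ignoring the within-donor correlation by design; serves
#' as the benchmark the longitudinal models are compared against.  Returned
#' as an `hb_fit` whose `params` are [lme_params] with zero random-effect
#' variances, so [predict_dynamic_lme()] applies directly (the empirical
#' Bayes term is identically zero).
#'
#' @param cohort A clean, single-gender `donor_cohort`.
#' @return An `hb_fit` with `model = "ols"` and `n_params = 5` (four
#'   coefficients plus the residual variance); `loglik` is the ML Gaussian
#'   log-likelihood.
#' @export
fit_ols <- function(cohort) {
  cohort <- check_fit_cohort(cohort)
  X <- covariate_matrix(cohort, intercept = TRUE)
  if (qr(X)$rank < ncol(X))
    stop("singular design: a covariate is constant in this cohort", call. = FALSE)
  fit <- lm(hb ~ age + season + dpv, data = cohort)
  cf <- coef(fit)
  n <- nrow(cohort)
  sigma2_ml <- sum(residuals(fit)^2) / n
  ll <- as.numeric(logLik(fit))
  se <- summary(fit)$coefficients[, "Std. Error"]
  params <- lme_params(cf[[1L]], cf[2:4], sigma2_b0 = 0, sigma2_b1 = 0,
                       sigma2_eps = sigma2_ml, structure = "RI")
  structure(list(model = "ols", params = params,
                 se = setNames(as.numeric(se),
                               c("alpha", "age", "season", "dpv")),
                 loglik = ll, loglik_ml = ll, n_obs = n, n_params = 5L,
                 converged = TRUE, n_iter = 1L,
                 gender = unique(cohort$gender)),
            class = "hb_fit")
}

#' Fit a linear mixed model by REML
#'
#' Maximises [reml_criterion()] over the variance components on the log
#' scale (quasi-Newton), with fixed effects obtained by generalized least
#' squares at the optimum and their standard errors from the GLS
#' covariance.  The maximised ML log-likelihood (variance components refit
#' by ML) is also recorded so that information criteria are comparable
#' across the OLS, transition and mixed models.  A variance component whose
#' estimate falls below `1e-10` is reported as exactly 0 with a boundary
#' flag.
#'
#' @param cohort A clean, single-gender `donor_cohort`.
#' @param structure `"RI"` or `"RIRS"` (random age slope, diagonal D).
#' @param options Optimizer settings: `maxit` (default 500), `reltol`
#'   (default 1e-10).
#' @return An `hb_fit` with `params` ([lme_params]), fixed-effect and
#'   variance-component standard errors, `loglik` (REML), `loglik_ml`,
#'   `boundary` flag, `n_params` (6 for RI, 7 for RIRS).
#' @export
fit_lme <- function(cohort, structure = c("RI", "RIRS"), options = list()) {
  structure <- match.arg(structure)
  cohort <- check_fit_cohort(cohort)
  maxit <- options$maxit %||% 500L
  reltol <- options$reltol %||% 1e-10
  st <- lme_stats(cohort)
  if (qr(st$X)$rank < st$p)
    stop("singular design: a covariate is constant in this cohort", call. = FALSE)
  rs <- structure == "RIRS"

  # moment starting values from the OLS residual decomposition
  ols <- lm.fit(st$X, st$y)
  res <- ols$residuals
  donor_mean <- rowsum(res, st$id) / st$n_i
  s2b0_0 <- max(var(as.vector(donor_mean)), 1e-3)
  s2e_0 <- max(var(res - donor_mean[as.integer(st$id)]), 1e-3)
  theta0 <- if (rs) log(c(s2b0_0, 1e-4, s2e_0)) else log(c(s2b0_0, s2e_0))

  make_negll <- function(reml) {
    function(theta) {
      if (!all(is.finite(theta)) || any(theta > 50)) return(1e10)
      v <- exp(theta)
      s2b1 <- if (rs) v[2L] else 0
      s2e <- v[length(v)]
      ll <- lme_objective(st, v[1L], s2b1, s2e, reml = reml)$loglik
      if (!is.finite(ll)) return(1e10)
      -ll
    }
  }
  opt <- optim(theta0, make_negll(TRUE), method = "BFGS",
               control = list(maxit = maxit, reltol = reltol))
  v <- exp(opt$par)
  s2b0 <- v[1L]
  s2b1 <- if (rs) v[2L] else 0
  s2e <- v[length(v)]
  boundary <- c(sigma2_b0 = s2b0 < 1e-10,
                sigma2_b1 = if (rs) s2b1 < 1e-10 else NA)
  if (isTRUE(boundary[["sigma2_b0"]])) s2b0 <- 0
  if (isTRUE(boundary[["sigma2_b1"]])) s2b1 <- 0

  sol <- lme_objective(st, s2b0, s2b1, s2e, reml = TRUE)
  beta <- sol$beta
  Ainv <- chol2inv(sol$chol_A)
  se_fixed <- sqrt(diag(Ainv))

  # variance-component SEs: inverse Hessian of the REML criterion in theta,
  # delta method back to the variance scale
  se_var <- rep(NA_real_, length(v))
  H <- tryCatch(optimHess(opt$par, make_negll(TRUE)), error = function(e) NULL)
  if (!is.null(H)) {
    Vth <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vth) && all(diag(Vth) > 0)) se_var <- exp(opt$par) * sqrt(diag(Vth))
  }

  opt_ml <- optim(opt$par, make_negll(FALSE), method = "BFGS",
                  control = list(maxit = maxit, reltol = reltol))
  params <- lme_params(beta[1L], beta[2:4], sigma2_b0 = s2b0,
                       sigma2_b1 = s2b1, sigma2_eps = s2e,
                       structure = structure)
  var_names <- if (rs) c("sigma2_b0", "sigma2_b1", "sigma2_eps") else
    c("sigma2_b0", "sigma2_eps")
  se <- c(setNames(se_fixed, c("alpha", "age", "season", "dpv")),
          setNames(se_var, var_names))
  structure(list(model = tolower(structure), params = params, se = se,
                 loglik = sol$loglik, loglik_ml = -opt_ml$value,
                 n_obs = st$n, n_params = if (rs) 7L else 6L,
                 converged = opt$convergence == 0L,
                 n_iter = opt$counts[["function"]],
                 boundary = boundary,
                 gender = unique(cohort$gender)),
            class = "hb_fit")
}

#' Empirical-Bayes estimate of a donor's random effects
#'
#' Posterior mean (BLUP) of the donor-specific intercept and slope given
#' the donor's previous visits: `bhat = D Z' V^{-1} (y - X beta)` computed
#' on the supplied prefix only.  With an empty prefix the prior mean (zero)
#' is returned.
#'
#' @param params An [lme_params] object (fitted values).
#' @param donor_prefix Data frame of one donor's first visits (possibly
#'   zero rows), with the panel columns.
#' @return A list: `donor_id`, `b0_hat`, `b1_hat` (0 under `"RI"`),
#'   `n_used`.
#' @export
empirical_bayes <- function(params, donor_prefix) {
  stopifnot(inherits(params, "lme_params"))
  d <- as.data.frame(donor_prefix)
  if (nrow(d) == 0L)
    return(list(donor_id = NA_character_, b0_hat = 0, b1_hat = 0, n_used = 0L))
  if (length(unique(d$donor_id)) != 1L)
    stop("donor_prefix must contain a single donor", call. = FALSE)
  X <- covariate_matrix(d, intercept = TRUE)
  r <- d$hb - as.vector(X %*% c(params$alpha, params$beta))
  g0 <- params$sigma2_b0 / params$sigma2_eps
  g1 <- params$sigma2_b1 / params$sigma2_eps
  n <- nrow(d); Sa <- sum(d$age); Saa <- sum(d$age^2)
  detB <- (1 + n * g0) * (1 + Saa * g1) - Sa^2 * g0 * g1
  zr1 <- sum(r); zr2 <- sum(r * d$age)
  b0 <- (g0 * (1 + Saa * g1) * zr1 - g0 * g1 * Sa * zr2) / detB
  b1 <- (-g0 * g1 * Sa * zr1 + g1 * (1 + n * g0) * zr2) / detB
  list(donor_id = d$donor_id[1L], b0_hat = b0, b1_hat = b1, n_used = n)
}

#' Dynamic one-step-ahead prediction under the mixed model
#'
#' For every donor and visit `t`, predicts `y_it` from the fixed effects
#' plus the empirical-Bayes random-effect estimate based on the donor's
#' visits `1..t-1` (the prior information is updated at every visit).  At
#' the first visit no history exists, so the prediction is the
#' population-level `alpha + beta.x`.  With all random-effect variances
#' zero this reduces to the OLS prediction.
#'
#' @param params An [lme_params] object (typically from a training-set fit).
#' @param cohort The cohort to predict.
#' @return A `prediction_set` data frame.
#' @export
predict_dynamic_lme <- function(params, cohort) {
  stopifnot(inherits(params, "lme_params"))
  d <- as_cohort(cohort)
  if (nrow(d) == 0L) stop("empty cohort", call. = FALSE)
  X <- covariate_matrix(d, intercept = TRUE)
  fixed <- as.vector(X %*% c(params$alpha, params$beta))
  r <- d$hb - fixed
  id <- factor(d$donor_id, levels = unique(d$donor_id))
  # prefix (strictly previous visits) cumulative sums within donor
  cum_prev <- function(x) as.vector(ave(x, id, FUN = cumsum)) - x
  n_p <- cum_prev(rep(1, nrow(d)))
  Sa_p <- cum_prev(d$age)
  Saa_p <- cum_prev(d$age^2)
  zr1_p <- cum_prev(r)
  zr2_p <- cum_prev(r * d$age)
  g0 <- params$sigma2_b0 / params$sigma2_eps
  g1 <- params$sigma2_b1 / params$sigma2_eps
  detB <- (1 + n_p * g0) * (1 + Saa_p * g1) - Sa_p^2 * g0 * g1
  b0 <- (g0 * (1 + Saa_p * g1) * zr1_p - g0 * g1 * Sa_p * zr2_p) / detB
  b1 <- (-g0 * g1 * Sa_p * zr1_p + g1 * (1 + n_p * g0) * zr2_p) / detB
  label <- if (params$sigma2_b0 == 0 && params$sigma2_b1 == 0) "ols" else
    tolower(params$structure)
  prediction_set(donor_id = d$donor_id, visit = d$visit, gender = d$gender,
                 observed = d$hb, predicted = fixed + b0 + b1 * d$age,
                 model = label)
}

#' Intra-class correlation of the random-intercept model
#'
#' Under the random-intercept structure the correlation between any two Hb
#' measurements of the same donor is constant:
#' `rho = sigma2_b0 / (sigma2_b0 + sigma2_eps)`.  Under the
#' random-intercept-plus-slope structure the within-donor correlation is no
#' longer constant over time, so the ICC is not defined and an error is
#' raised.
#'
#' @param params An [lme_params] with `structure = "RI"`.
#' @return The ICC, in `[0, 1)`.
#' @export
icc <- function(params) {
  stopifnot(inherits(params, "lme_params"))
  if (params$structure != "RI")
    stop("ICC is only constant (and only defined here) for the random-intercept structure",
         call. = FALSE)
  params$sigma2_b0 / (params$sigma2_b0 + params$sigma2_eps)
}

#' Likelihood-ratio test for the random age slope
#'
#' Compares the random-intercept fit against the random-intercept-plus-slope
#' fit.  Because the null value of the slope variance lies on the boundary
#' of the parameter space, the test statistic `L = 2 (l_RIRS - l_RI)`
#' (clipped at 0) is referred to an equal mixture of chi-squared
#' distributions with 1 and 2 degrees of freedom.
#'
#' @param fit_ri,fit_rirs `hb_fit` objects from [fit_lme()] on the same
#'   cohort with the same fixed effects.
#' @return A list: `statistic`, `p_value`.
#' @export
lrt_random_slope <- function(fit_ri, fit_rirs) {
  stopifnot(inherits(fit_ri, "hb_fit"), inherits(fit_rirs, "hb_fit"))
  if (fit_ri$model != "ri" || fit_rirs$model != "rirs")
    stop("expected a random-intercept fit and a random-intercept-plus-slope fit",
         call. = FALSE)
  if (fit_ri$n_obs != fit_rirs$n_obs)
    stop("fits are not on the same cohort", call. = FALSE)
  L <- max(0, 2 * (fit_rirs$loglik - fit_ri$loglik))
  p <- 0.5 * pchisq(L, df = 1, lower.tail = FALSE) +
    0.5 * pchisq(L, df = 2, lower.tail = FALSE)
  list(statistic = L, p_value = p)
}
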