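# Transition (autoregressive panel) model of order q for Hb trajectories:
#
#   y_it = alpha + beta.x_it + sum_{r=1..q} gamma_r (y_{i,t-r} - beta.x_{i,t-r}) + eps_it
#
# with x = (age, warm season, donation at previous visit) and
# eps_it ~ iid N(0, sigma2_eps).  Writing w_it = y_it - beta.x_it, the
# adjusted series w is an AR(q) with intercept alpha and stationary mean
# mu_w = alpha / (1 - sum(gamma)).  Estimation maximises the exact Gaussian
# likelihood: each donor's first min(T_i, q) adjusted values enter through
# the stationary AR distribution (state-space stationary initialization),
# the remainder through the one-step conditional densities.  Donors with
# fewer visits than the order therefore still contribute.

#' Transition-model parameters
#'
#' @param alpha Intercept (mmol/l) of the adjusted autoregression; the
#'   stationary mean of the covariate-adjusted Hb series is
#'   `alpha / (1 - sum(gamma))`.
#' @param beta Length-3 coefficient vector `(age, season, dpv)` in mmol/l
#'   (per year for age).
#' @param gamma Lag coefficients `gamma_1..gamma_q`; the implied AR
#'   polynomial must be stationary.
#' @param sigma2_eps Innovation variance, (mmol/l)^2, positive.
#' @return A `transition_params` object; the order `q` is `length(gamma)`.
#' @export
transition_params <- function(alpha, beta, gamma, sigma2_eps) {
  stopifnot(is_scalar_number(alpha), is.numeric(beta), length(beta) == 3L,
            is.numeric(gamma), length(gamma) >= 1L,
            is_scalar_number(sigma2_eps), sigma2_eps > 0)
  check_stationary(gamma)
  structure(list(alpha = unname(alpha),
                 beta = setNames(as.numeric(beta), c("age", "season", "dpv")),
                 gamma = setNames(as.numeric(gamma),
                                  paste0("gamma", seq_along(gamma))),
                 sigma2_eps = unname(sigma2_eps),
                 q = length(gamma)),
            class = "transition_params")
}

# Largest companion-matrix eigenvalue modulus; < 1 iff the AR(q) with lag
# coefficients gamma is stationary.
ar_spectral_radius <- function(gamma) {
  q <- length(gamma)
  if (q == 1L) return(abs(gamma))
  Tc <- matrix(0, q, q)
  Tc[1L, ] <- gamma
  Tc[cbind(2:q, 1:(q - 1L))] <- 1
  max(Mod(eigen(Tc, only.values = TRUE)$values))
}

check_stationary <- function(gamma, limit = 1) {
  rho <- ar_spectral_radius(gamma)
  if (!is.finite(rho) || rho >= limit)
    stop(sprintf(
      "non-stationary lag coefficients: AR root modulus %.4f (1/%.4f) inside the unit circle",
      1 / rho, rho), call. = FALSE)
  invisible(rho)
}

#' Stationary covariance of q consecutive values of a zero-mean AR(q)
#'
#' Solves the Lyapunov (discrete-time Yule-Walker) equation for the
#' companion-form state covariance, giving the `q x q` covariance matrix of
#' `q` consecutive latent values.  This is the exact covariance used to
#' initialize the likelihood for each donor's first visits.
#'
#' @param gamma Lag coefficients of a stationary AR(q).
#' @param sigma2 Innovation variance.
#' @return A symmetric positive-definite `q x q` Toeplitz matrix whose
#'   `(i, j)` entry is the autocovariance at lag `|i - j|`.
#' @export
stationary_covariance <- function(gamma, sigma2) {
  stopifnot(is.numeric(gamma), length(gamma) >= 1L,
            is_scalar_number(sigma2), sigma2 > 0)
  check_stationary(gamma)
  q <- length(gamma)
  if (q == 1L) {
    P <- matrix(sigma2 / (1 - gamma^2), 1L, 1L)
    return(P)
  }
  Tc <- matrix(0, q, q)
  Tc[1L, ] <- gamma
  Tc[cbind(2:q, 1:(q - 1L))] <- 1
  RQR <- matrix(0, q, q)
  RQR[1L, 1L] <- sigma2
  vecP <- solve(diag(q * q) - kronecker(Tc, Tc), as.vector(RQR))
  P <- matrix(vecP, q, q)
  (P + t(P)) / 2
}

# Autocovariances Gamma_0..Gamma_{max_lag} of the zero-mean AR(q); lags
# beyond q - 1 extend the stationary block by the Yule-Walker recursion
# Gamma_k = sum_r gamma_r Gamma_{k-r}.
ar_autocovariances <- function(gamma, sigma2, max_lag) {
  q <- length(gamma)
  P <- stationary_covariance(gamma, sigma2)
  acov <- numeric(max_lag + 1L)
  acov[seq_len(min(q, max_lag + 1L))] <- P[1L, seq_len(min(q, max_lag + 1L))]
  if (max_lag + 1L > q) {
    for (k in q:max_lag)  # k = lag index (0-based), uses previous q lags
      acov[k + 1L] <- sum(gamma * acov[k + 1L - seq_len(q)])
  }
  acov
}

# Shared preparation: order the panel, subtract the covariate effect and the
# stationary mean, locate each donor's first row, and build the within-donor
# lag matrix of the centred adjusted series z.
transition_workspace <- function(params, cohort) {
  d <- as_cohort(cohort)
  if (nrow(d) == 0L) stop("empty cohort", call. = FALSE)
  q <- params$q
  mu_w <- params$alpha / (1 - sum(params$gamma))
  xb <- as.vector(covariate_matrix(d) %*% params$beta)
  z <- d$hb - xb - mu_w
  n <- nrow(d)
  lagz <- matrix(NA_real_, n, q)
  for (r in seq_len(q)) {
    ok <- d$visit > r  # consecutive 1-based visits: lag r is r rows up
    lagz[ok, r] <- z[which(ok) - r]
  }
  first <- which(!duplicated(d$donor_id))
  T_i <- c(diff(first), n - first[length(first)] + 1L)
  list(d = d, q = q, mu_w = mu_w, xb = xb, z = z, lagz = lagz,
       first = first, T_i = T_i)
}

#' Exact log-likelihood of the transition model
#'
#' Sum over donors of the exact Gaussian log-likelihood of the full visit
#' series under the order-`q` transition model: the prediction-error
#' decomposition of the companion-form state space with stationary initial
#' state.  The first `min(T_i, q)` adjusted observations of donor `i` enter
#' through their stationary joint normal density (so donors with fewer
#' visits than the order contribute through the stationary marginal), later
#' observations through the conditional AR one-step densities.
#'
#' @param params A [transition_params] object.
#' @param cohort A clean, single-gender `donor_cohort`.
#' @return The log-likelihood (a scalar).
#' @export
exact_loglik <- function(params, cohort) {
  stopifnot(inherits(params, "transition_params"))
  ws <- transition_workspace(params, cohort)
  q <- ws$q
  sigma2 <- params$sigma2_eps
  S <- stationary_covariance(params$gamma, sigma2)
  ll <- 0
  m_i <- pmin(ws$T_i, q)
  for (m in sort(unique(m_i))) {
    idx <- ws$first[m_i == m]             # donors whose initial block is m long
    Zm <- matrix(ws$z[rep(idx, each = m) + seq_len(m) - 1L], nrow = m)
    cu <- chol(S[seq_len(m), seq_len(m), drop = FALSE])
    quad <- colSums(backsolve(cu, Zm, transpose = TRUE)^2)
    ll <- ll - 0.5 * (m * log(2 * pi) + 2 * sum(log(diag(cu)))) * length(idx) -
      0.5 * sum(quad)
  }
  cond <- ws$d$visit > q
  if (any(cond)) {
    v <- ws$z[cond] - as.vector(ws$lagz[cond, , drop = FALSE] %*% params$gamma)
    ll <- ll + sum(dnorm(v, 0, sqrt(sigma2), log = TRUE))
  }
  ll
}

#' Fit the transition model by exact maximum likelihood
#'
#' Maximises [exact_loglik()] over `(alpha, beta, gamma, log sigma2_eps)` by
#' quasi-Newton (BFGS).  Starting values: `(alpha, beta)` from ordinary least
#' squares, `gamma` from a least-squares regression of the OLS residuals on
#' their within-donor lags.  Candidate `gamma` whose companion spectral
#' radius reaches 0.999 are rejected (the line search backtracks into the
#' stationary region).  Standard errors come from the inverse numerical
#' Hessian at the optimum (delta method for `sigma2_eps`).
#'
#' @param cohort A clean, single-gender `donor_cohort`.
#' @param q Order of the transition model (>= 1).
#' @param options List of optimizer settings: `maxit` (default 500),
#'   `reltol` (default 1e-8), and optionally `ndeps` (finite-difference
#'   gradient step).
#' @return An `hb_fit` object: `params` ([transition_params]), `se` (named,
#'   same order as the free parameters), `loglik` (maximised, this is also
#'   the ML value used for information criteria), `n_obs`, `n_params`
#'   (`q + 5`), `converged`, `n_iter`, `model = "ar<q>"`.
#' @export
fit_transition <- function(cohort, q, options = list()) {
  cohort <- check_fit_cohort(cohort)
  stopifnot(is_scalar_number(q), q >= 1)
  q <- as.integer(q)
  maxit <- options$maxit %||% 500L
  reltol <- options$reltol %||% 1e-8
  X <- covariate_matrix(cohort, intercept = TRUE)
  if (qr(X)$rank < ncol(X))
    stop("singular design: a covariate is constant in this cohort", call. = FALSE)
  ols <- lm.fit(X, cohort$hb)
  beta0 <- ols$coefficients[-1L]
  res <- ols$residuals
  n <- nrow(cohort)
  lagr <- matrix(NA_real_, n, q)
  for (r in seq_len(q)) {
    ok <- cohort$visit > r
    lagr[ok, r] <- res[which(ok) - r]
  }
  cc <- complete.cases(lagr)
  gamma0 <- rep(0, q)
  sigma2_0 <- var(res)
  if (sum(cc) > 5L * q) {
    lf <- lm.fit(lagr[cc, , drop = FALSE], res[cc])
    if (all(is.finite(lf$coefficients))) {
      gamma0 <- lf$coefficients
      sigma2_0 <- max(var(lf$residuals), 1e-6)
    }
  }
  while (ar_spectral_radius(gamma0) >= 0.95) gamma0 <- gamma0 * 0.9
  alpha0 <- ols$coefficients[1L] * (1 - sum(gamma0))

  par_names <- c("alpha", "age", "season", "dpv",
                 paste0("gamma", seq_len(q)), "log_sigma2")
  par0 <- setNames(c(alpha0, beta0, gamma0, log(sigma2_0)), par_names)
  unpack <- function(par) {
    list(alpha = par[1L], beta = par[2:4], gamma = par[5:(4 + q)],
         sigma2 = exp(par[5L + q]))
  }
  negll <- function(par) {
    p <- unpack(par)
    if (!all(is.finite(par)) || ar_spectral_radius(p$gamma) >= 0.999)
      return(1e10)
    prm <- structure(list(alpha = p$alpha, beta = p$beta, gamma = p$gamma,
                          sigma2_eps = p$sigma2, q = q),
                     class = "transition_params")
    ll <- exact_loglik(prm, cohort)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  ctrl <- list(maxit = maxit, reltol = reltol)
  if (!is.null(options$ndeps)) ctrl$ndeps <- rep(options$ndeps, length(par0))
  opt <- optim(par0, negll, method = "BFGS", control = ctrl)
  p <- unpack(opt$par)
  params <- transition_params(p$alpha, p$beta, p$gamma, p$sigma2)
  se <- rep(NA_real_, length(par0))
  H <- tryCatch(optimHess(opt$par, negll), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) se <- sqrt(diag(V))
  }
  se <- setNames(se, par_names)
  # delta method: se(sigma2) = sigma2 * se(log sigma2)
  se_out <- c(se[seq_len(4L + q)], sigma2_eps = unname(p$sigma2 * se[5L + q]))
  names(se_out)[seq_len(4L + q)] <- c("alpha", "age", "season", "dpv",
                                      paste0("gamma", seq_len(q)))
  structure(list(model = paste0("ar", q), params = params, se = se_out,
                 loglik = -opt$value, loglik_ml = -opt$value,
                 n_obs = n, n_params = q + 5L,
                 converged = opt$convergence == 0L,
                 n_iter = opt$counts[["function"]],
                 gender = unique(cohort$gender)),
            class = "hb_fit")
}

#' Dynamic one-step-ahead prediction under the transition model
#'
#' For every donor and visit `t`, predicts `y_it` from the donor's visits
#' `1..t-1` and the visit-`t` covariates (known before the Hb measurement):
#' `yhat_it = beta.x_it + mu_w + E[z_it | z_i1..z_{i,t-1}]` where `z` is the
#' centred adjusted series.  At the first visit the history term is zero, so
#' the prediction uses covariates only; for `t <= q` the conditional mean
#' comes from the stationary joint normal, for `t > q` from the AR
#' recursion.  The observed `y_it` is never used in its own prediction.
#'
#' @param params A [transition_params] object (typically from a training-set
#'   fit).
#' @param cohort The cohort to predict (e.g. the validation part).
#' @return A `prediction_set`: data frame with `donor_id`, `visit`,
#'   `gender`, `observed`, `predicted`, and a `model` attribute.
#' @export
predict_dynamic_ar <- function(params, cohort) {
  stopifnot(inherits(params, "transition_params"))
  ws <- transition_workspace(params, cohort)
  q <- ws$q
  S <- stationary_covariance(params$gamma, params$sigma2_eps)
  pred_z <- numeric(nrow(ws$d))        # visit 1 rows stay 0
  if (q >= 2L) {
    for (t in 2:q) {
      idx <- ws$first[ws$T_i >= t]     # donors observed at visit t
      if (length(idx) == 0L) next
      cf <- solve(S[seq_len(t - 1L), seq_len(t - 1L), drop = FALSE],
                  S[t, seq_len(t - 1L)])
      Zprev <- matrix(ws$z[rep(idx, each = t - 1L) + seq_len(t - 1L) - 1L],
                      nrow = t - 1L)
      pred_z[idx + t - 1L] <- as.vector(crossprod(Zprev, cf))
    }
  }
  cond <- ws$d$visit > q
  if (any(cond))
    pred_z[cond] <- as.vector(ws$lagz[cond, , drop = FALSE] %*% params$gamma)
  prediction_set(donor_id = ws$d$donor_id, visit = ws$d$visit,
                 gender = ws$d$gender, observed = ws$d$hb,
                 predicted = ws$xb + ws$mu_w + pred_z,
                 model = paste0("ar", q))
}
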