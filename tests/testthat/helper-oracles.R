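# Independent oracles: deliberately brute-force implementations that share no
# code path with the package internals they check.

# Autocovariances Gamma_0..Gamma_K of a zero-mean AR(q) by solving the
# Yule-Walker equations as one dense linear system in the unknowns
# (Gamma_0..Gamma_q), then extending by the recursion.
oracle_ar_acov <- function(gamma, sigma2, K) {
  q <- length(gamma)
  A <- matrix(0, q + 1L, q + 1L)
  rhs <- c(sigma2, rep(0, q))
  for (k in 0:q) {                      # Gamma_k - sum_r gamma_r Gamma_|k-r| = sigma2 * (k == 0)
    A[k + 1L, k + 1L] <- A[k + 1L, k + 1L] + 1
    for (r in seq_len(q))
      A[k + 1L, abs(k - r) + 1L] <- A[k + 1L, abs(k - r) + 1L] - gamma[r]
  }
  acov <- solve(A, rhs)
  if (K > q) {
    acov <- c(acov, numeric(K - q))
    for (k in (q + 1L):K)
      acov[k + 1L] <- sum(gamma * acov[k + 1L - seq_len(q)])
  }
  acov[seq_len(K + 1L)]
}

# Multivariate-normal log density, dense.
oracle_dmvnorm <- function(x, mean, S) {
  k <- length(x)
  cu <- chol(S)
  -0.5 * (k * log(2 * pi) + 2 * sum(log(diag(cu))) +
            sum(backsolve(cu, x - mean, transpose = TRUE)^2))
}

# Dense multivariate-normal log-likelihood of a cohort under the transition
# model: per donor, the T x T Toeplitz autocovariance of the adjusted series.
oracle_transition_loglik <- function(params, cohort) {
  d <- as.data.frame(cohort)
  d <- d[order(d$donor_id, d$visit), ]
  mu_w <- params$alpha / (1 - sum(params$gamma))
  ll <- 0
  for (id in unique(d$donor_id)) {
    di <- d[d$donor_id == id, , drop = FALSE]
    Tn <- nrow(di)
    acov <- oracle_ar_acov(params$gamma, params$sigma2_eps, Tn - 1L)
    S <- outer(seq_len(Tn), seq_len(Tn), function(i, j) acov[abs(i - j) + 1L])
    xb <- as.vector(cbind(di$age, di$season, di$dpv) %*% params$beta)
    ll <- ll + oracle_dmvnorm(di$hb, xb + mu_w, S)
  }
  ll
}

# Dense (restricted) log-likelihood of the mixed model: full block V built
# donor by donor with plain solve()/determinant().
oracle_lme_loglik <- function(params, cohort, reml = TRUE) {
  d <- as.data.frame(cohort)
  d <- d[order(d$donor_id, d$visit), ]
  X <- cbind(1, d$age, d$season, d$dpv)
  y <- d$hb
  n <- nrow(d); p <- ncol(X)
  D <- diag(c(params$sigma2_b0, params$sigma2_b1))
  sum_logdet <- 0
  XtVX <- matrix(0, p, p); XtVy <- numeric(p); yVy <- 0
  for (id in unique(d$donor_id)) {
    rows <- which(d$donor_id == id)
    Zi <- cbind(1, d$age[rows])
    Vi <- Zi %*% D %*% t(Zi) + params$sigma2_eps * diag(length(rows))
    Vinv <- solve(Vi)
    sum_logdet <- sum_logdet +
      as.numeric(determinant(Vi, logarithm = TRUE)$modulus)
    Xi <- X[rows, , drop = FALSE]; yi <- y[rows]
    XtVX <- XtVX + t(Xi) %*% Vinv %*% Xi
    XtVy <- XtVy + t(Xi) %*% Vinv %*% yi
    yVy <- yVy + sum(yi * (Vinv %*% yi))
  }
  beta <- solve(XtVX, XtVy)
  quad <- yVy - sum(XtVy * beta)
  ld_XtVX <- as.numeric(determinant(XtVX, logarithm = TRUE)$modulus)
  if (reml) {
    -0.5 * (sum_logdet + ld_XtVX + quad + (n - p) * log(2 * pi))
  } else {
    -0.5 * (sum_logdet + quad + n * log(2 * pi))
  }
}

# AUC by exhaustive concordant-pair counting (ties count 1/2).
oracle_auc_pairs <- function(score, truth) {
  pos <- score[truth]; neg <- score[!truth]
  total <- 0
  for (sp in pos)
    for (sn in neg)
      total <- total + (sp > sn) + 0.5 * (sp == sn)
  total / (length(pos) * length(neg))
}
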