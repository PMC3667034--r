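# Predictive-accuracy assessment: visit-wise mean squared prediction error,
# information criteria, eligibility classification at the clinical cut-off,
# ROC/AUC (deferral = positive class), and paired bootstrap AUC comparison.

#' Prediction set
#'
#' Pairs each visit's dynamic prediction with the observed Hb value.  One
#' entry per (donor, visit); all values finite.
#'
#' @param donor_id,visit,gender,observed,predicted Parallel vectors.
#' @param model Model label (e.g. `"ar5"`, `"ri"`, `"ols"`).
#' @return A `prediction_set` data frame with a `model` attribute.
#' @export
prediction_set <- function(donor_id, visit, gender, observed, predicted,
                           model = "model") {
  out <- data.frame(donor_id = as.character(donor_id),
                    visit = as.integer(visit),
                    gender = as.character(gender),
                    observed = as.numeric(observed),
                    predicted = as.numeric(predicted),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out[c("donor_id", "visit")]))
    stop("duplicate (donor, visit) entries in prediction set", call. = FALSE)
  if (!all(is.finite(out$observed)) || !all(is.finite(out$predicted)))
    stop("non-finite values in prediction set", call. = FALSE)
  attr(out, "model") <- model
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Mean squared prediction error by visit number
#'
#' `MSPE_t = sum_i (yhat_it - y_it)^2 / N_t` over the entries observed at
#' visit `t`, where `N_t` is the number of donors with a visit `t`.
#'
#' @param pred A `prediction_set`.
#' @return Data frame with columns `visit`, `mspe`, `n`, ordered by visit.
#' @export
mspe_by_visit <- function(pred) {
  stopifnot(nrow(pred) > 0L)
  sq <- (pred$predicted - pred$observed)^2
  agg <- aggregate(sq, by = list(visit = pred$visit),
                   FUN = function(e) c(mspe = mean(e), n = length(e)))
  out <- data.frame(visit = agg$visit, mspe = agg$x[, "mspe"],
                    n = as.integer(agg$x[, "n"]))
  out[order(out$visit), , drop = FALSE]
}

#' Overall mean squared prediction error
#'
#' @param pred A `prediction_set`.
#' @return The mean of the squared prediction errors over all entries.
#' @export
overall_mspe <- function(pred) {
  stopifnot(nrow(pred) > 0L)
  mean((pred$predicted - pred$observed)^2)
}

#' Information criteria of a fit
#'
#' `AIC = -2 l + 2 k` and `BIC = -2 l + k log(n)`, computed from the ML
#' log-likelihood (for REML fits the variance components are refit by ML)
#' so that the criteria are comparable across the regression, transition
#' and mixed models.
#'
#' @param fit An `hb_fit`.
#' @return Named numeric vector `c(aic, bic)`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "hb_fit"))
  ll <- fit$loglik_ml %||% fit$loglik
  if (is.null(ll) || !is.finite(ll)) stop("fit lacks a log-likelihood", call. = FALSE)
  k <- fit$n_params
  c(aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(fit$n_obs))
}

# Deferral indicator: Hb below the gender-specific clinical cut-off.
deferral_labels <- function(pred, rule) {
  stopifnot(inherits(rule, "eligibility_rule"))
  cut <- hb_cutoff(rule, pred$gender)
  list(truth = pred$observed < cut, pred_defer = pred$predicted < cut)
}

#' Eligibility classification at the clinical cut-off
#'
#' The positive class is deferral (observed Hb below the clinical cut-off
#' for the entry's gender); an entry is predicted positive when the
#' predicted Hb falls below the same cut-off.  The full 2x2 table is
#' returned together with both directional readings: sensitivity/specificity
#' for detecting deferral, and their mirror images for detecting
#' eligibility (the "correctly predicted eligible" rate equals the
#' deferral specificity).  If a class is absent the corresponding rate is
#' `NA`, not 0.
#'
#' @param pred A `prediction_set`.
#' @param rule An [eligibility_rule].
#' @return A list: `counts` (tp, fp, tn, fn on the deferral reading),
#'   `sensitivity`, `specificity`, `sensitivity_eligible`,
#'   `specificity_eligible`.
#' @export
classification_at_cutoff <- function(pred, rule = eligibility_rule()) {
  lab <- deferral_labels(pred, rule)
  tp <- sum(lab$truth & lab$pred_defer)
  fn <- sum(lab$truth & !lab$pred_defer)
  tn <- sum(!lab$truth & !lab$pred_defer)
  fp <- sum(!lab$truth & lab$pred_defer)
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  list(counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
       sensitivity = sens, specificity = spec,
       sensitivity_eligible = spec, specificity_eligible = sens)
}

# Mann-Whitney AUC of score (higher = more positive-like) for binary truth;
# ties count 1/2.
mann_whitney_auc <- function(score, truth) {
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC for deferral prediction
#'
#' The state variable is deferral (observed Hb below the clinical cut-off);
#' the test variable is the predicted Hb, with lower predictions indicating
#' deferral.  Sweeping the cut-off applied to the predicted value over the
#' midpoints between distinct predictions traces the ROC curve; the AUC is
#' the Mann-Whitney statistic (ties weighted 1/2) and its standard error
#' comes from a stratified bootstrap over entries (resampling deferrals and
#' non-deferrals separately).
#'
#' @param pred A `prediction_set`; both classes must be present.
#' @param rule An [eligibility_rule].
#' @param B Bootstrap replicates for the AUC standard error (default 2000);
#'   `B = 0` skips the bootstrap.
#' @param seed Seed for the bootstrap.
#' @return A list: `roc` (data frame `threshold`, `fpr`, `tpr`), `auc`,
#'   `se`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(pred, rule = eligibility_rule(), B = 2000L, seed = NULL) {
  lab <- deferral_labels(pred, rule)
  truth <- lab$truth
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L)
    stop("both deferral and non-deferral entries are required for a ROC curve",
         call. = FALSE)
  score <- -pred$predicted            # higher score = more deferral-like
  auc <- mann_whitney_auc(score, truth)
  yhat <- sort(unique(pred$predicted))
  thr <- c(-Inf, if (length(yhat) > 1L) (yhat[-1L] + yhat[-length(yhat)]) / 2,
           Inf)
  tpr <- vapply(thr, function(ct) mean(pred$predicted[truth] < ct), 0)
  fpr <- vapply(thr, function(ct) mean(pred$predicted[!truth] < ct), 0)
  se <- NA_real_
  if (B > 0L) {
    se <- with_seed(seed, {
      ip <- which(truth); ineg <- which(!truth)
      reps <- vapply(seq_len(B), function(b) {
        idx <- c(sample(ip, n1, replace = TRUE),
                 sample(ineg, n0, replace = TRUE))
        mann_whitney_auc(score[idx], truth[idx])
      }, 0)
      sd(reps)
    })
  }
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc, se = se, n_pos = n1, n_neg = n0)
}

#' Paired bootstrap comparison of two AUCs
#'
#' Tests the difference between the AUCs of two models evaluated on the
#' same entries, accounting for the correlation induced by the pairing:
#' entry indices are resampled jointly (the same indices for both models,
#' stratified by deferral status), the AUC difference is recomputed per
#' replicate, and a two-sided normal-approximation p-value is formed from
#' the observed difference divided by the bootstrap standard deviation.
#'
#' @param pred_a,pred_b `prediction_set`s covering the same (donor, visit)
#'   entries with identical observed values.
#' @param rule An [eligibility_rule].
#' @param B Bootstrap replicates (default 2000).
#' @param seed Seed for the resampling.
#' @return A list: `auc_a`, `auc_b`, `diff`, `se`, `p_value`, `B`.
#' @export
compare_auc_bootstrap <- function(pred_a, pred_b, rule = eligibility_rule(),
                                  B = 2000L, seed = NULL) {
  key_a <- paste(pred_a$donor_id, pred_a$visit)
  key_b <- paste(pred_b$donor_id, pred_b$visit)
  ord <- match(key_a, key_b)
  if (anyNA(ord) || length(key_a) != length(key_b))
    stop("prediction sets are not paired: entry sets differ", call. = FALSE)
  pred_b <- pred_b[ord, , drop = FALSE]
  if (!isTRUE(all.equal(pred_a$observed, pred_b$observed)))
    stop("prediction sets are not paired: observed values differ", call. = FALSE)
  truth <- deferral_labels(pred_a, rule)$truth
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L)
    stop("both classes are required to compare AUCs", call. = FALSE)
  sa <- -pred_a$predicted; sb <- -pred_b$predicted
  auc_a <- mann_whitney_auc(sa, truth)
  auc_b <- mann_whitney_auc(sb, truth)
  D <- auc_a - auc_b
  dstar <- with_seed(seed, {
    ip <- which(truth); ineg <- which(!truth)
    vapply(seq_len(B), function(b) {
      idx <- c(sample(ip, n1, replace = TRUE),
               sample(ineg, n0, replace = TRUE))
      mann_whitney_auc(sa[idx], truth[idx]) -
        mann_whitney_auc(sb[idx], truth[idx])
    }, 0)
  })
  sdD <- sd(dstar)
  p <- if (sdD == 0) {
    if (abs(D) < .Machine$double.eps^0.5) 1 else 0
  } else {
    2 * pnorm(-abs(D) / sdD)
  }
  list(auc_a = auc_a, auc_b = auc_b, diff = D, se = sdD, p_value = p, B = B)
}

#' Full evaluation report for a model's predictions
#'
#' Bundles the visit-wise and overall MSPE, the information criteria of the
#' training fit, the classification at the clinical cut-off, and the
#' ROC/AUC analysis.
#'
#' @param pred A `prediction_set` (validation entries).
#' @param fit The `hb_fit` the predictions came from (training fit), or
#'   `NULL` to skip the information criteria.
#' @param rule An [eligibility_rule].
#' @param B,seed Bootstrap settings passed to [roc_auc()].
#' @return A list of class `evaluation_report`.
#' @export
evaluate_predictions <- function(pred, fit = NULL, rule = eligibility_rule(),
                                 B = 2000L, seed = NULL) {
  out <- list(model = attr(pred, "model") %||% "model",
              mspe_by_visit = mspe_by_visit(pred),
              overall_mspe = overall_mspe(pred),
              classification = classification_at_cutoff(pred, rule),
              roc = roc_auc(pred, rule, B = B, seed = seed))
  if (!is.null(fit)) {
    ic <- information_criteria(fit)
    out$aic <- ic[["aic"]]
    out$bic <- ic[["bic"]]
  }
  class(out) <- "evaluation_report"
  out
}
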