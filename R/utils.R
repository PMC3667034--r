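# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so seeded package functions do not disturb
# the global random stream.  `seed = NULL` evaluates `expr` as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Design matrix of the time-varying covariates shared by all models
# (age in years, warm-season indicator, donation-at-previous-visit indicator).
covariate_matrix <- function(cohort, intercept = FALSE) {
  X <- cbind(age = cohort$age, season = cohort$season, dpv = cohort$dpv)
  if (intercept) X <- cbind(intercept = 1, X)
  storage.mode(X) <- "double"
  X
}

# Fitting operations require a structurally clean, single-gender cohort.
check_fit_cohort <- function(cohort) {
  cohort <- as_cohort(cohort)
  if (length(unique(cohort$gender)) > 1L)
    stop("cohort mixes genders; fit models per gender", call. = FALSE)
  v <- validate_panel(cohort)
  if (nrow(v) > 0L)
    stop(sprintf("cohort has %d structural violation(s); see validate_panel()",
                 nrow(v)), call. = FALSE)
  cohort
}
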