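# Donor panel data: container, CSV I/O, validation, donor-level splitting.

PANEL_COLUMNS <- c("donor_id", "gender", "visit", "age", "season", "dpv",
                   "donated", "hb")

#' Donor visit panel
#'
#' A donor cohort is a long-format data frame with one row per blood-bank
#' visit and columns `donor_id`, `gender` (`"M"`/`"F"`), `visit` (sequential
#' visit number, 1-based), `age` (years), `season` (0 = cold
#' fall/winter, 1 = warm spring/summer), `dpv` (donation at previous visit;
#' 0 at the first visit, which is a health check), `donated` (donation made
#' at this visit) and `hb` (hemoglobin, mmol/l).  `as_cohort()` coerces a
#' data frame to this layout, sorts it by donor and visit, and checks the
#' column set; structural rules are checked separately by
#' [validate_panel()].
#'
#' @param x A data frame with the panel columns.
#' @param gender Optional `"M"` or `"F"`: keep only that gender.
#' @return An object of class `donor_cohort` (a sorted data frame).
#' @seealso [read_panel()], [validate_panel()], [split_donors()]
#' @export
as_cohort <- function(x, gender = NULL) {
  if (inherits(x, "donor_cohort") && is.null(gender)) return(x)
  x <- as.data.frame(x)
  missing_cols <- setdiff(PANEL_COLUMNS, names(x))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  x <- x[PANEL_COLUMNS]
  x$donor_id <- as.character(x$donor_id)
  x$gender <- as.character(x$gender)
  if (!all(x$gender %in% c("M", "F")))
    stop("gender must be coded \"M\"/\"F\"", call. = FALSE)
  for (col in c("visit", "season", "dpv", "donated"))
    x[[col]] <- as.integer(x[[col]])
  for (col in c("age", "hb")) x[[col]] <- as.numeric(x[[col]])
  if (!is.null(gender)) {
    gender <- match.arg(gender, c("M", "F"))
    x <- x[x$gender == gender, , drop = FALSE]
  }
  x <- x[order(x$donor_id, x$visit), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("donor_cohort", "data.frame")
  x
}

#' Clinical eligibility cut-offs
#'
#' Donation requires a hemoglobin level of at least 8.4 mmol/l (135 g/l) for
#' men and 7.8 mmol/l (125 g/l) for women; a measurement below the cut-off
#' leads to deferral from donation at that visit.
#'
#' @param cutoff_male,cutoff_female Lower Hb bounds for eligibility, mmol/l.
#' @return An `eligibility_rule` object.
#' @export
eligibility_rule <- function(cutoff_male = 8.4, cutoff_female = 7.8) {
  stopifnot(is_scalar_number(cutoff_male), is_scalar_number(cutoff_female))
  if (!(cutoff_male > cutoff_female && cutoff_female > 0))
    stop("require cutoff_male > cutoff_female > 0", call. = FALSE)
  structure(list(cutoff_male = cutoff_male, cutoff_female = cutoff_female),
            class = "eligibility_rule")
}

#' @rdname eligibility_rule
#' @param rule An `eligibility_rule`.
#' @param gender `"M"` or `"F"` (vectorised).
#' @export
hb_cutoff <- function(rule, gender) {
  stopifnot(inherits(rule, "eligibility_rule"))
  ifelse(gender == "M", rule$cutoff_male, rule$cutoff_female)
}

#' Read a donor panel from CSV
#'
#' Reads a long-format visit panel (comma separated, header required, `.`
#' decimal separator) into a [donor cohort][as_cohort].  Structural rule
#' violations found by [validate_panel()] are reported as a warning but the
#' offending rows are kept, so messy data can be triaged; fitting functions
#' require a clean cohort.
#'
#' @param path Path to a CSV file with the panel columns.
#' @param gender_filter Optional `"M"`/`"F"` to keep a single gender.
#' @param drop_missing_hb If `TRUE`, donors with a missing Hb value at any
#'   visit are excluded entirely (the analysis-set rule for registry data).
#' @return A `donor_cohort`.
#' @export
read_panel <- function(path, gender_filter = NULL, drop_missing_hb = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(PANEL_COLUMNS, names(raw))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in c("visit", "age", "season", "dpv", "donated", "hb")) {
    val <- raw[[col]]
    num <- suppressWarnings(as.numeric(val))
    bad <- which(!is.na(val) & val != "" & is.na(num))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric value in column '%s' at data row %d: \"%s\"",
                   col, bad[1L], val[bad[1L]]), call. = FALSE)
    num[!is.na(val) & val == ""] <- NA_real_
    raw[[col]] <- num
  }
  if (drop_missing_hb) {
    bad_donors <- unique(raw$donor_id[is.na(raw$hb)])
    if (length(bad_donors) > 0L) {
      message(sprintf("excluding %d donor(s) with missing Hb values",
                      length(bad_donors)))
      raw <- raw[!(raw$donor_id %in% bad_donors), , drop = FALSE]
    }
  }
  cohort <- as_cohort(raw, gender = gender_filter)
  viol <- validate_panel(cohort)
  if (nrow(viol) > 0L)
    warning(sprintf("panel has %d structural violation(s); see validate_panel()",
                    nrow(viol)), call. = FALSE)
  cohort
}

#' Write a donor panel to CSV
#'
#' Writes the canonical column order, one row per visit, `.` decimal
#' separator, UTF-8, no quoting.  Numeric fields use the shortest
#' representation that round-trips exactly, so `read_panel(write_panel(x))`
#' reproduces every field and a second write is byte-identical.
#'
#' @param cohort A non-empty `donor_cohort`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  if (nrow(cohort) == 0L) stop("refusing to write an empty cohort", call. = FALSE)
  out <- as.data.frame(cohort)
  out$age <- as.character(out$age)  # R >= 4.3: shortest round-trip digits
  out$hb <- as.character(out$hb)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check the structural rules of a donor panel
#'
#' Verifies, per donor: visit numbers are consecutive integers starting at 1;
#' at least two visits; `dpv` is 0 at the first visit (the first visit is a
#' health check, not a donation) and equals `donated` at the previous visit
#' thereafter; age is non-decreasing; Hb is positive and present.
#' Violations are returned as data, not raised.
#'
#' @param cohort A `donor_cohort`.
#' @return A data frame with columns `donor_id`, `visit`, `rule`; zero rows
#'   if and only if the panel is clean.
#' @export
validate_panel <- function(cohort) {
  d <- as_cohort(cohort)
  n <- nrow(d)
  empty <- data.frame(donor_id = character(), visit = integer(),
                      rule = character(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  first <- !duplicated(d$donor_id)
  prev <- c(NA_integer_, seq_len(n - 1L))
  viol <- list(empty)
  flag <- function(idx, rule) {
    if (length(idx) > 0L)
      data.frame(donor_id = d$donor_id[idx], visit = d$visit[idx],
                 rule = rule, stringsAsFactors = FALSE)
  }
  bad_seq <- (first & d$visit != 1L) |
    (!first & d$visit != d$visit[prev] + 1L)
  viol$seq <- flag(which(bad_seq), "non-consecutive visit")
  viol$dpv1 <- flag(which(first & d$dpv != 0L), "dpv at first visit must be 0")
  viol$dpv <- flag(which(!first & d$dpv != d$donated[prev]),
                   "dpv must equal donated at previous visit")
  viol$age <- flag(which(!first & d$age < d$age[prev]),
                   "age must be non-decreasing")
  viol$hb <- flag(which(!is.finite(d$hb) | d$hb <= 0), "hb must be positive")
  n_by_donor <- table(d$donor_id)
  lone <- names(n_by_donor)[n_by_donor < 2L]
  if (length(lone) > 0L)
    viol$lone <- data.frame(donor_id = lone, visit = 1L,
                            rule = "donor has fewer than 2 visits",
                            stringsAsFactors = FALSE)
  out <- do.call(rbind, Filter(Negate(is.null), viol))
  rownames(out) <- NULL
  out
}

#' Split a cohort at the donor level
#'
#' Randomly divides the donors (not the visits) into a training and a
#' validation part: each donor's full series lands in exactly one part, so
#' the validation predictions never reuse training information from the same
#' donor.
#'
#' @param cohort A `donor_cohort`.
#' @param fraction Proportion of donors assigned to the first (training)
#'   part, strictly between 0 and 1.
#' @param seed Integer seed making the partition reproducible.
#' @return A list with components `train` and `validation`, both
#'   `donor_cohort`s.
#' @export
split_donors <- function(cohort, fraction, seed = NULL) {
  cohort <- as_cohort(cohort)
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  ids <- unique(cohort$donor_id)
  n_train <- round(fraction * length(ids))
  train_ids <- with_seed(seed, sample(ids, n_train))
  in_train <- cohort$donor_id %in% train_ids
  list(train = as_cohort(cohort[in_train, , drop = FALSE]),
       validation = as_cohort(cohort[!in_train, , drop = FALSE]))
}
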