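# Scoring of the study instruments and categorical groupings: BED-Q severity,
# MDI depression bands, eligibility screening, completion-rate categories,
# and the descriptive tables.

#' BED-Q severity band labels, in ascending order
#' @return Character vector of the six ordered bands.
#' @export
bedq_bands <- function() {
  c("none", "subclinical", "mild", "moderate", "severe", "extremely_severe")
}

#' Completion-rate category labels, in ascending order
#' @return Character vector `Low < High < Full`.
#' @export
completion_levels <- function() c("Low", "High", "Full")

check_item_range <- function(x, lo, hi, what) {
  bad <- which(is.na(x) | x < lo | x > hi | x != floor(x))
  if (length(bad))
    stop(sprintf("%s item %d out of range [%d, %d]: %s",
                 what, bad[1], lo, hi, x[bad[1]]))
  invisible(TRUE)
}

#' Score the Binge-Eating Disorder Questionnaire (BED-Q)
#'
#' The sum score is built from the seven symptom-frequency items only (each
#' coded 0-5, 0 = none up to 5 = more than 13 episodes/week). Item 8
#' (compensatory behaviour) and item 9 (binary distress) are screening
#' controls and never enter the sum.
#'
#' @param items_1_7 Integer vector of exactly seven items, each in 0..5.
#' @param item_8 Optional compensatory-behaviour item in 0..5 (ignored by the
#'   score).
#' @param item_9_distress Optional binary distress item (ignored by the
#'   score).
#' @return Integer sum score in 0..35.
#' @export
score_bedq <- function(items_1_7, item_8 = NA, item_9_distress = NA) {
  if (length(items_1_7) != 7L)
    stop("BED-Q requires exactly seven symptom items; got ", length(items_1_7))
  check_item_range(items_1_7, 0L, 5L, "BED-Q")
  if (!is.na(item_8)) check_item_range(item_8, 0L, 5L, "BED-Q compensatory")
  as.integer(sum(items_1_7))
}

#' Classify a BED-Q sum score into a severity band
#'
#' Bands: 0 none; 1-9 subclinical; 10-14 mild; 15-21 moderate; 22-28 severe;
#' 29-35 extremely severe. Vectorised.
#'
#' @param score Integer score(s) in 0..35.
#' @return Ordered factor over [bedq_bands()].
#' @export
classify_bedq_severity <- function(score) {
  if (any(is.na(score) | score < 0 | score > 35))
    stop("BED-Q score outside 0..35")
  cut(score, breaks = c(-1, 0, 9, 14, 21, 28, 35), labels = bedq_bands(),
      ordered_result = TRUE)
}

#' Score the Major Depression Inventory (MDI)
#'
#' Ten items on a 0-5 Likert scale sum to 0..50. Severity bands follow the
#' recommended cutoffs: below 21 none, 21-25 mild, 26-30 moderate, 31 and
#' above severe.
#'
#' @param items Integer vector of exactly ten items in 0..5.
#' @return List with `total` (integer) and `band` (ordered factor over
#'   none < mild < moderate < severe).
#' @export
score_mdi <- function(items) {
  if (length(items) != 10L)
    stop("MDI requires exactly ten items; got ", length(items))
  check_item_range(items, 0L, 5L, "MDI")
  total <- as.integer(sum(items))
  list(total = total, band = classify_mdi_severity(total))
}

#' @rdname score_mdi
#' @param total Integer MDI total score(s) in 0..50.
#' @export
classify_mdi_severity <- function(total) {
  if (any(is.na(total) | total < 0 | total > 50))
    stop("MDI total outside 0..50")
  cut(total, breaks = c(-1, 20, 25, 30, 50),
      labels = c("none", "mild", "moderate", "severe"), ordered_result = TRUE)
}

#' Screen a scored applicant against the study exclusion rules
#'
#' Applicants are excluded for severe BED (BED-Q sum of 22 or more, i.e. the
#' severe or extremely severe band) or an MDI total above 40. Every triggered
#' rule is reported.
#'
#' @param bedq_score BED-Q sum score (0..35).
#' @param mdi_score MDI total (0..50).
#' @return List with `eligible` (logical) and `reasons` (character vector of
#'   triggered exclusion rules, empty when eligible).
#' @export
check_eligibility <- function(bedq_score, mdi_score) {
  stopifnot(bedq_score >= 0, bedq_score <= 35, mdi_score >= 0, mdi_score <= 50)
  reasons <- character()
  if (bedq_score >= 22) reasons <- c(reasons, "severe BED (BED-Q >= 22)")
  if (mdi_score > 40) reasons <- c(reasons, "MDI > 40")
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

#' Completion-rate category from sessions and follow-up
#'
#' Fewer than six completed sessions is Low; six to nine is High; all ten
#' sessions plus the follow-up is Full. Ten sessions without follow-up falls
#' back to High by default (`full_requires_followup = FALSE` relaxes this).
#' Vectorised; monotone non-decreasing in `sessions` for fixed `followup`.
#'
#' @param sessions Integer number of completed sessions in 0..10.
#' @param followup Logical, follow-up completed.
#' @param full_requires_followup Logical; if `FALSE`, ten sessions suffice
#'   for Full.
#' @return Ordered factor over [completion_levels()].
#' @export
completion_category <- function(sessions, followup,
                                full_requires_followup = TRUE) {
  if (any(is.na(sessions) | sessions < 0 | sessions > 10))
    stop("`sessions` outside 0..10")
  followup <- as.logical(followup)
  full <- sessions == 10 & (followup | !full_requires_followup)
  cat <- ifelse(sessions < 6, "Low", ifelse(full, "Full", "High"))
  factor(cat, levels = completion_levels(), ordered = TRUE)
}

#' Completion-rate frequencies and percentages by age group
#'
#' Tabulates the completion category of each patient within age group;
#' percentages are of the age-group total, rounded to two decimals. Rows are
#' ordered Full, High, Low within each group.
#'
#' @param records Cohort data frame (see [read_cohort()]); needs
#'   `age_group`, `sessions_completed`, `followup_done`.
#' @return Data frame with columns `age_group`, `completion_rate`,
#'   `frequency`, `pct_age_group`.
#' @export
completion_table <- function(records) {
  if (!NROW(records)) stop("empty cohort")
  cat <- completion_category(records$sessions_completed, records$followup_done)
  out <- list()
  for (ag in unique(as.character(records$age_group))) {
    sub <- cat[records$age_group == ag]
    freq <- table(factor(sub, levels = c("Full", "High", "Low")))
    out[[ag]] <- data.frame(age_group = ag,
                            completion_rate = names(freq),
                            frequency = as.integer(freq),
                            pct_age_group = round(100 * as.integer(freq) / length(sub), 2))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Descriptive summary of a cohort
#'
#' @param records Cohort data frame; uses `sex`, `age`, `bmi`, `mdi_pre`,
#'   `age_group`.
#' @return List with `n`, `n_male`, `pct_male` (one decimal), `age`, `bmi`,
#'   `mdi` (each mean/min/max), `n_young_adults`.
#' @export
descriptives <- function(records) {
  n <- NROW(records)
  n_male <- sum(records$sex == "male", na.rm = TRUE)
  rng <- function(x) list(mean = mean(x, na.rm = TRUE),
                          min = suppressWarnings(min(x, na.rm = TRUE)),
                          max = suppressWarnings(max(x, na.rm = TRUE)))
  list(n = n,
       n_male = n_male,
       pct_male = round(100 * n_male / n, 1),
       age = rng(records$age),
       bmi = rng(records$bmi),
       mdi = rng(records$mdi_pre),
       n_young_adults = sum(records$age_group == "young_adult", na.rm = TRUE))
}

cohort_columns <- function() {
  c("id", "age", "sex", "bmi", "age_group", "motivation_aims",
    "motivation_online", "therapy_aims_text", "why_online_text",
    "sessions_completed", "followup_done", "bedq_pre", "bedq_post",
    "edeq_pre", "edeq_post", "mdi_pre", "mdi_post", "vas_pre", "vas_post")
}

#' Validate a cohort data frame
#'
#' Checks column presence, value ranges and categorical levels. Pre/post
#' outcome fields may be missing (non-completers); demographics, motivation
#' labels and adherence fields may not.
#'
#' @param records Cohort data frame.
#' @return Character vector of problems; empty when the cohort is valid.
#' @export
validate_cohort <- function(records) {
  probs <- character()
  missing_cols <- setdiff(cohort_columns(), names(records))
  if (length(missing_cols))
    return(paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  chk <- function(cond, msg) if (any(cond, na.rm = TRUE)) probs <<- c(probs, msg)
  chk(records$age < 18, "age below 18")
  chk(!records$sex %in% c("male", "female"), "sex not in {male, female}")
  chk(records$bmi <= 0, "non-positive BMI")
  chk(!records$age_group %in% c("adult", "young_adult"),
      "age_group not in {adult, young_adult}")
  for (q in c("motivation_aims", "motivation_online"))
    chk(!as.character(records[[q]]) %in% sdt_levels(),
        paste(q, "outside the SDT levels"))
  chk(records$sessions_completed < 0 | records$sessions_completed > 10,
      "sessions_completed outside 0..10")
  chk(is.na(records$followup_done), "missing followup_done")
  for (v in c("bedq_pre", "bedq_post"))
    chk(records[[v]] < 0 | records[[v]] > 35, paste(v, "outside 0..35"))
  for (v in c("edeq_pre", "edeq_post"))
    chk(records[[v]] < 0, paste(v, "negative"))
  for (v in c("mdi_pre", "mdi_post"))
    chk(records[[v]] < 0 | records[[v]] > 50, paste(v, "outside 0..50"))
  for (v in c("vas_pre", "vas_post"))
    chk(records[[v]] < 0 | records[[v]] > 100, paste(v, "outside 0..100"))
  probs
}

#' Read a cohort CSV
#'
#' The file must carry exactly the canonical header (see the package
#' vignette), UTF-8 encoded, with empty cells for missing values and RFC
#' 4180 quoting for the free-text fields. Motivation labels are returned as
#' ordered factors on the SDT scale and `followup_done` as logical.
#'
#' @param path CSV file path.
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(path) {
  header <- strsplit(readLines(path, n = 1L, encoding = "UTF-8"), ",")[[1]]
  header <- gsub('"', "", header, fixed = TRUE)
  if (!identical(header, cohort_columns()))
    stop("cohort header does not match the canonical column set")
  rec <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  fileEncoding = "UTF-8")
  rec$followup_done <- rec$followup_done %in% c("1", "TRUE", "true", "yes", 1, TRUE)
  for (q in c("motivation_aims", "motivation_online"))
    rec[[q]] <- factor(rec[[q]], levels = sdt_levels(), ordered = TRUE)
  for (tf in c("therapy_aims_text", "why_online_text"))
    rec[[tf]][is.na(rec[[tf]])] <- ""
  probs <- validate_cohort(rec)
  if (length(probs))
    stop("invalid cohort: ", paste(probs, collapse = "; "))
  rec
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: canonical header, UTF-8, empty cells for
#' missing values, quoted text fields.
#'
#' @param records Cohort data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(records, path) {
  out <- records[, cohort_columns()]
  out$followup_done <- as.integer(out$followup_done)
  for (q in c("motivation_aims", "motivation_online"))
    out[[q]] <- as.character(out[[q]])
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}
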