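#' DAS28-CRP coefficient set
#'
#' The standard published DAS28-CRP weights: score =
#' 0.56 sqrt(TJC28) + 0.28 sqrt(SJC28) + 0.36 ln(CRP + 1) + 0.014 GH + 0.96,
#' with CRP in mg/L and the patient global health VAS (GH) in mm on 0-100.
#' Exposed as a constant set so alternative calibrations can be passed to
#' [das28_crp()].
#'
#' @return Named numeric vector with elements `tjc`, `sjc`, `crp`, `gh`,
#'   `intercept`.
#' @export
das28_coefficients <- function() {
  c(tjc = 0.56, sjc = 0.28, crp = 0.36, gh = 0.014, intercept = 0.96)
}

#' Compute the DAS28-CRP composite score
#'
#' @param tjc28 Tender joint count, integer in 0-28 (vectorized).
#' @param sjc28 Swollen joint count, integer in 0-28.
#' @param crp C-reactive protein in mg/L, >= 0.
#' @param gh Patient global health VAS in mm, 0-100.
#' @param coefficients Coefficient set, see [das28_coefficients()].
#' @return Numeric vector of DAS28-CRP scores.
#' @export
#' @examples
#' das28_crp(4, 2, 10, 50) # about 4.04
das28_crp <- function(tjc28, sjc28, crp, gh,
                      coefficients = das28_coefficients()) {
  if (any(tjc28 < 0 | tjc28 > 28)) stop("tjc28 must be in 0-28", call. = FALSE)
  if (any(sjc28 < 0 | sjc28 > 28)) stop("sjc28 must be in 0-28", call. = FALSE)
  if (any(crp < 0)) stop("crp must be >= 0 mg/L", call. = FALSE)
  if (any(gh < 0 | gh > 100)) stop("gh must be in 0-100 mm", call. = FALSE)
  coefficients[["tjc"]] * sqrt(tjc28) +
    coefficients[["sjc"]] * sqrt(sjc28) +
    coefficients[["crp"]] * log(crp + 1) +
    coefficients[["gh"]] * gh +
    coefficients[["intercept"]]
}

#' Activity-stage thresholds for the DAS28-CRP
#'
#' Cut-offs as used for disease-activity grading: score < 2.6 remission;
#' 2.6 <= score < 3.2 low; 3.2 <= score <= 5.1 moderate; score > 5.1 high.
#'
#' @return Named numeric vector `c(remission_below = 2.6, low_below = 3.2,
#'   moderate_upto = 5.1)`.
#' @export
stage_thresholds <- function() {
  c(remission_below = 2.6, low_below = 3.2, moderate_upto = 5.1)
}

#' Assign an activity stage from a DAS28-CRP score
#'
#' @param score Nonnegative DAS28-CRP score (vectorized).
#' @param thresholds Threshold set, see [stage_thresholds()]. The boundary
#'   at the upper moderate cut-off belongs to moderate (strict `>` for high).
#' @return Ordered factor with levels remission < low < moderate < high.
#' @export
#' @examples
#' das28_stage(c(1.9, 2.4, 3.1)) # remission, remission, low
das28_stage <- function(score, thresholds = stage_thresholds()) {
  if (any(score < 0)) stop("score must be >= 0", call. = FALSE)
  lev <- c("remission", "low", "moderate", "high")
  out <- ifelse(score < thresholds[["remission_below"]], "remission",
         ifelse(score < thresholds[["low_below"]], "low",
         ifelse(score <= thresholds[["moderate_upto"]], "moderate", "high")))
  factor(out, levels = lev, ordered = TRUE)
}

#' Extract the four DAS28-CRP components from a cohort
#'
#' Counts the true tender and swollen flags of each record and passes CRP and
#' GH through.
#'
#' @param cohort Cohort data frame, see [generate_cohort()].
#' @return Data frame with columns `patient_id`, `tjc28`, `sjc28`, `crp`,
#'   `gh`.
#' @export
components_of <- function(cohort) {
  .check_cohort_columns(cohort)
  data.frame(
    patient_id = cohort$patient_id,
    tjc28 = as.integer(rowSums(cohort[, tender_columns(), drop = FALSE])),
    sjc28 = as.integer(rowSums(cohort[, swollen_columns(), drop = FALSE])),
    crp = cohort$crp_mg_l,
    gh = cohort$gh_mm,
    stringsAsFactors = FALSE
  )
}

#' Expand cohort records into the 58-item representation
#'
#' Flattens each record into the d = 58 single items of the DAS28-CRP: the 28
#' tender-joint flags, the 28 swollen-joint flags, CRP and GH, in that order.
#'
#' @param cohort Cohort data frame.
#' @return Numeric matrix (n x 58) with column names
#'   `tender_<joint>`, `swollen_<joint>`, `crp`, `gh` and row names set to
#'   the patient ids.
#' @export
expand_items <- function(cohort) {
  .check_cohort_columns(cohort)
  m <- as.matrix(cohort[, c(tender_columns(), swollen_columns()), drop = FALSE])
  m <- cbind(m, crp = cohort$crp_mg_l, gh = cohort$gh_mm)
  storage.mode(m) <- "double"
  rownames(m) <- cohort$patient_id
  stopifnot(ncol(m) == 58L)
  m
}

#' Score and stage a cohort
#'
#' Convenience wrapper computing the DAS28-CRP score and activity stage of
#' every record.
#'
#' @inheritParams components_of
#' @inheritParams das28_crp
#' @inheritParams das28_stage
#' @return Data frame `patient_id, tjc28, sjc28, crp, gh, das28_crp, stage`.
#' @export
score_cohort <- function(cohort, coefficients = das28_coefficients(),
                         thresholds = stage_thresholds()) {
  comp <- components_of(cohort)
  comp$das28_crp <- das28_crp(comp$tjc28, comp$sjc28, comp$crp, comp$gh,
                              coefficients)
  comp$stage <- das28_stage(comp$das28_crp, thresholds)
  comp
}

.check_cohort_columns <- function(cohort) {
  need <- c("patient_id", tender_columns(), swollen_columns(),
            "crp_mg_l", "gh_mm")
  missing <- setdiff(need, names(cohort))
  if (length(missing) > 0) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
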