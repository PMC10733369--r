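#' Configuration for the synthetic PsA cohort generator
#'
#' Defines the study conditions the generator emulates: a cohort of n = 80
#' psoriatic-arthritis patients with a 59/16/5 remission/low/moderate stage
#' mixture, a planted "signal joint" (tenderness of the right MCP-2, the
#' metacarpophalangeal joint of the right index finger) whose odds are
#' multiplied in non-remission patients, per-activity CRP (lognormal) and
#' global-health (scaled Beta) marginals, and three injected outlier patients
#' (two swollen-dominant, one tender-dominant).
#'
#' The generator samples a latent activity class from `stage_mix`, then draws
#' the score components from the per-class distributions. Activity stages are
#' never stored: they are always re-derived from the generated components via
#' [score_cohort()], so the recorded stage is internally consistent with the
#' DAS28-CRP formula by construction. The default component distributions are
#' calibrated so that the re-derived stage proportions reproduce `stage_mix`.
#'
#' Per-class parameter vectors are named `c(remission=, low=, moderate=)`.
#'
#' @param n_patients Number of patients to generate (before outlier
#'   injection).
#' @param stage_mix Probabilities of the remission/low/moderate latent
#'   activity classes; must sum to 1.
#' @param signal_joint Joint identifier of the planted signal joint (one of
#'   [joint_names()]).
#' @param signal_symptom `"tender"` or `"swollen"`: which flag map carries
#'   the planted signal.
#' @param signal_odds_ratio Odds multiplier applied to the signal joint's
#'   flag in non-remission latent classes; > 0.
#' @param base_tender_prob,base_swollen_prob Per-joint Bernoulli rates by
#'   latent activity class.
#' @param crp_meanlog,crp_sdlog Lognormal parameters of CRP (mg/L) by class.
#' @param gh_shape1,gh_shape2 Beta shape parameters of GH by class; draws are
#'   scaled to 0-100 mm.
#' @param n_outliers_swollen,n_outliers_tender Counts of injected outlier
#'   patients dominated by swollen resp. tender joints.
#' @param seed Integer seed; every draw of the generator is a deterministic
#'   function of it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 80,
                          stage_mix = c(remission = 59, low = 16, moderate = 5) / 80,
                          signal_joint = "mcp2_right",
                          signal_symptom = "tender",
                          signal_odds_ratio = 8,
                          base_tender_prob = c(remission = 0.015, low = 0.07, moderate = 0.20),
                          base_swollen_prob = c(remission = 0.008, low = 0.011, moderate = 0.09),
                          crp_meanlog = c(remission = log(2), low = 1.59, moderate = log(8)),
                          crp_sdlog = c(remission = 0.6, low = 0.12, moderate = 0.4),
                          gh_shape1 = c(remission = 1.5, low = 22, moderate = 6),
                          gh_shape2 = c(remission = 8, low = 56, moderate = 5),
                          n_outliers_swollen = 2,
                          n_outliers_tender = 1,
                          seed = 42L) {
  config <- list(
    n_patients = n_patients, stage_mix = stage_mix,
    signal_joint = signal_joint, signal_symptom = signal_symptom,
    signal_odds_ratio = signal_odds_ratio,
    base_tender_prob = base_tender_prob, base_swollen_prob = base_swollen_prob,
    crp_meanlog = crp_meanlog, crp_sdlog = crp_sdlog,
    gh_shape1 = gh_shape1, gh_shape2 = gh_shape2,
    n_outliers_swollen = n_outliers_swollen,
    n_outliers_tender = n_outliers_tender,
    seed = as.integer(seed)
  )
  class(config) <- "cohort_config"
  validate_cohort_config(config)
  config
}

#' @rdname cohort_config
#' @param config Object to validate.
#' @export
validate_cohort_config <- function(config) {
  classes <- c("remission", "low", "moderate")
  fail <- function(field, why) {
    stop("invalid cohort configuration: field '", field, "' ", why,
         call. = FALSE)
  }
  if (!is.numeric(config$n_patients) || length(config$n_patients) != 1 ||
      config$n_patients < 1) fail("n_patients", "must be a positive count")
  if (length(config$stage_mix) != 3 ||
      abs(sum(config$stage_mix) - 1) > 1e-12 || any(config$stage_mix < 0))
    fail("stage_mix", "must be 3 nonnegative probabilities summing to 1")
  if (!config$signal_joint %in% joint_names())
    fail("signal_joint", "is not a known joint identifier")
  if (!config$signal_symptom %in% c("tender", "swollen"))
    fail("signal_symptom", "must be 'tender' or 'swollen'")
  if (!is.numeric(config$signal_odds_ratio) || config$signal_odds_ratio <= 0)
    fail("signal_odds_ratio", "must be > 0")
  for (field in c("base_tender_prob", "base_swollen_prob")) {
    p <- config[[field]]
    if (length(p) != 3 || any(p < 0) || any(p > 1))
      fail(field, "must be 3 probabilities in [0,1]")
  }
  for (field in c("base_tender_prob", "base_swollen_prob", "crp_meanlog",
                  "crp_sdlog", "gh_shape1", "gh_shape2")) {
    v <- config[[field]]
    if (length(v) != 3 || !setequal(names(v), classes))
      fail(field, "needs one value per latent class (remission, low, moderate)")
  }
  if (any(config$crp_sdlog <= 0)) fail("crp_sdlog", "must be > 0")
  if (any(config$gh_shape1 <= 0)) fail("gh_shape1", "must be > 0")
  if (any(config$gh_shape2 <= 0)) fail("gh_shape2", "must be > 0")
  for (field in c("n_outliers_swollen", "n_outliers_tender")) {
    if (config[[field]] < 0) fail(field, "must be a nonnegative count")
  }
  invisible(config)
}

# multiply the odds of a Bernoulli rate by `or`
.odds_multiply <- function(p, or) {
  odds <- or * p / (1 - p)
  odds / (1 + odds)
}

#' Generate a synthetic PsA cohort
#'
#' Draws `n_patients` records under the configured study conditions: a latent
#' activity class per patient, independent Bernoulli joint flags given the
#' class (the planted signal joint's odds multiplied by
#' `signal_odds_ratio` in non-remission classes), lognormal CRP and
#' Beta-scaled GH. The latent class is returned in a `latent_activity`
#' column as generator-internal ground truth for planted-effect recovery
#' checks; the analysis stage of a patient is always re-derived from the
#' components with [score_cohort()].
#'
#' @param config A [cohort_config()].
#' @return Data frame with one row per patient: `patient_id`, 28
#'   `tender_<joint>` flags, 28 `swollen_<joint>` flags, `crp_mg_l`, `gh_mm`,
#'   `drug_class`, `therapy_start_days`, `is_synthetic`, `injected_outlier`,
#'   `latent_activity`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 20, seed = 1))
#' table(score_cohort(cohort)$stage)
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  n <- config$n_patients
  joints <- joint_names()
  classes <- c("remission", "low", "moderate")

  set.seed(config$seed)
  latent <- sample(classes, n, replace = TRUE, prob = config$stage_mix)

  tender <- matrix(0L, n, 28, dimnames = list(NULL, tender_columns()))
  swollen <- matrix(0L, n, 28, dimnames = list(NULL, swollen_columns()))
  for (j in seq_along(joints)) {
    pt <- config$base_tender_prob[latent]
    ps <- config$base_swollen_prob[latent]
    if (joints[j] == config$signal_joint) {
      boosted <- latent != "remission"
      if (config$signal_symptom == "tender") {
        pt[boosted] <- .odds_multiply(pt[boosted], config$signal_odds_ratio)
      } else {
        ps[boosted] <- .odds_multiply(ps[boosted], config$signal_odds_ratio)
      }
    }
    tender[, j] <- rbinom(n, 1L, pt)
    swollen[, j] <- rbinom(n, 1L, ps)
  }

  crp <- rlnorm(n, config$crp_meanlog[latent], config$crp_sdlog[latent])
  gh <- pmin(100, 100 * rbeta(n, config$gh_shape1[latent],
                              config$gh_shape2[latent]))

  out <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    tender, swollen,
    crp_mg_l = crp, gh_mm = gh,
    drug_class = NA_character_,
    therapy_start_days = NA_integer_,
    is_synthetic = FALSE,
    injected_outlier = FALSE,
    latent_activity = latent,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Inject outlier patients into a cohort
#'
#' Appends `n_outliers_swollen` swollen-dominant records (at least 6 swollen
#' joints, at most 1 tender joint) and `n_outliers_tender` tender-dominant
#' records (at least 6 tender joints, at most 1 swollen joint), mirroring the
#' rare symptom patterns that surface as outliers on the U-matrix. Injected
#' records are real study cases, not augmentation output, so
#' `is_synthetic = FALSE`; they are tagged via `injected_outlier = TRUE`.
#'
#' @param cohort Cohort data frame from [generate_cohort()].
#' @param config The [cohort_config()] used to generate it.
#' @return The cohort with the outlier rows appended.
#' @export
inject_outliers <- function(cohort, config = cohort_config()) {
  validate_cohort_config(config)
  if (nrow(cohort) == 0) stop("cohort must be nonempty", call. = FALSE)
  n_sw <- config$n_outliers_swollen
  n_td <- config$n_outliers_tender
  if (n_sw + n_td == 0) return(cohort)

  set.seed(config$seed + 1000003L)
  make_outlier <- function(id, kind) {
    tender <- setNames(integer(28), tender_columns())
    swollen <- setNames(integer(28), swollen_columns())
    n_dom <- sample(6:10, 1)
    n_off <- sample(0:1, 1)
    if (kind == "swollen") {
      swollen[sample(28, n_dom)] <- 1L
      if (n_off > 0) tender[sample(28, n_off)] <- 1L
      # the swollen-dominant outliers sit in otherwise quiet disease:
      # low CRP and GH, as for the remission class
      crp <- rlnorm(1, config$crp_meanlog[["remission"]],
                    config$crp_sdlog[["remission"]])
      gh <- pmin(100, 100 * rbeta(1, config$gh_shape1[["remission"]],
                                  config$gh_shape2[["remission"]]))
    } else {
      tender[sample(28, n_dom)] <- 1L
      if (n_off > 0) swollen[sample(28, n_off)] <- 1L
      crp <- rlnorm(1, config$crp_meanlog[["low"]],
                    config$crp_sdlog[["low"]])
      gh <- pmin(100, 100 * rbeta(1, config$gh_shape1[["low"]],
                                  config$gh_shape2[["low"]]))
    }
    cbind(
      data.frame(patient_id = id, stringsAsFactors = FALSE),
      as.data.frame(t(tender)), as.data.frame(t(swollen)),
      data.frame(crp_mg_l = crp, gh_mm = gh,
                 drug_class = NA_character_,
                 therapy_start_days = NA_integer_,
                 is_synthetic = FALSE, injected_outlier = TRUE,
                 latent_activity = if (kind == "swollen") "remission" else "low",
                 stringsAsFactors = FALSE)
    )
  }

  rows <- list()
  k <- nrow(cohort)
  for (i in seq_len(n_sw)) {
    rows[[length(rows) + 1L]] <- make_outlier(sprintf("O%04d", k + length(rows) + 1L), "swollen")
  }
  for (i in seq_len(n_td)) {
    rows[[length(rows) + 1L]] <- make_outlier(sprintf("O%04d", k + length(rows) + 1L), "tender")
  }
  out <- rbind(cohort, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Read and write cohort CSV files
#'
#' The on-disk schema is one row per patient with columns `patient_id`,
#' `tender_<joint>` and `swollen_<joint>` (28 each, joint vocabulary as in
#' [joint_names()]), `crp_mg_l`, `gh_mm`, `drug_class`,
#' `therapy_start_days`. Generator-internal columns (latent class, outlier
#' tags) are not part of the interchange format.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `read_cohort` returns the cohort data frame; `write_cohort`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  .check_cohort_columns(cohort)
  cols <- c("patient_id", tender_columns(), swollen_columns(),
            "crp_mg_l", "gh_mm", "drug_class", "therapy_start_days")
  cols <- intersect(cols, names(cohort))
  utils::write.csv(cohort[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_cohort_columns(cohort)
  cohort
}
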