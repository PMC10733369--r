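test_that("generation is deterministic given the seed and honors the count", {
  cfg <- cohort_config(n_patients = 80, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 80)
  expect_false(identical(a, generate_cohort(cohort_config(n_patients = 80, seed = 8))))
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(cohort_config(stage_mix = c(0.5, 0.4, 0.2)), "stage_mix")
  expect_error(cohort_config(signal_odds_ratio = -1), "signal_odds_ratio")
  expect_error(cohort_config(signal_joint = "mcp9_right"), "signal_joint")
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(
    cohort_config(base_tender_prob = c(remission = 0.5, low = 1.2, moderate = 0.1)),
    "base_tender_prob")
})

test_that("signal-joint odds ratio is recovered empirically at large n", {
  # equal base rates across latent classes isolate the planted boost, so the
  # active-vs-remission odds ratio estimates the configured value directly
  cfg <- cohort_config(
    n_patients = 10000, signal_odds_ratio = 8,
    base_tender_prob = c(remission = 0.05, low = 0.05, moderate = 0.05),
    seed = 31)
  cohort <- generate_cohort(cfg)
  active <- cohort$latent_activity != "remission"
  flag <- cohort$tender_mcp2_right
  odds <- function(x) mean(x) / (1 - mean(x))
  or_hat <- odds(flag[active]) / odds(flag[!active])
  expect_gt(or_hat, 6)
  expect_lt(or_hat, 10)
})

test_that("marginal joint prevalence converges to the configured rate", {
  cfg <- cohort_config(n_patients = 10000, seed = 13)
  cohort <- generate_cohort(cfg)
  rem <- cohort$latent_activity == "remission"
  p0 <- cfg$base_tender_prob[["remission"]]
  se <- sqrt(p0 * (1 - p0) / sum(rem))
  # a non-signal joint in the remission class follows the base Bernoulli rate
  expect_lt(abs(mean(cohort$tender_knee_left[rem]) - p0), 3 * se)
  p1 <- cfg$base_swollen_prob[["remission"]]
  se1 <- sqrt(p1 * (1 - p1) / sum(rem))
  expect_lt(abs(mean(cohort$swollen_wrist_right[rem]) - p1), 3 * se1)
})

test_that("derived stages reproduce the configured stage mixture", {
  cfg <- cohort_config(n_patients = 1000, seed = 17)
  stages <- score_cohort(generate_cohort(cfg))$stage
  prop <- prop.table(table(stages))
  expect_lt(abs(prop[["remission"]] - cfg$stage_mix[["remission"]]), 0.05)
  expect_lt(abs(prop[["low"]] - cfg$stage_mix[["low"]]), 0.05)
  expect_lt(abs(prop[["moderate"]] - cfg$stage_mix[["moderate"]]), 0.05)
})

test_that("outlier injection appends the configured dominant patterns", {
  cfg <- cohort_config(n_patients = 40, seed = 3)
  cohort <- generate_cohort(cfg)

  none <- cohort_config(n_patients = 40, n_outliers_swollen = 0,
                        n_outliers_tender = 0, seed = 3)
  expect_identical(inject_outliers(cohort, none), cohort)

  full <- inject_outliers(cohort, cfg)
  expect_equal(nrow(full), nrow(cohort) + 3)
  added <- full[full$injected_outlier, ]
  expect_equal(nrow(added), 3)
  sw <- rowSums(added[, swollen_columns()])
  td <- rowSums(added[, tender_columns()])
  expect_true(all((sw >= 6 & td <= 1) | (td >= 6 & sw <= 1)))
  expect_equal(sum(sw >= 6 & td <= 1), cfg$n_outliers_swollen)
  expect_equal(sum(td >= 6 & sw <= 1), cfg$n_outliers_tender)
  expect_false(any(added$is_synthetic))
})

test_that("cohort CSV round-trips through the documented schema", {
  cohort <- generate_cohort(cohort_config(n_patients = 12, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  cols <- c("patient_id", tender_columns(), swollen_columns(), "crp_mg_l", "gh_mm")
  expect_equal(back[, cols], cohort[, cols], tolerance = 1e-12)
  expect_true(validate_cohort(path)$valid)
})
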