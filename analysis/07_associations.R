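#!/usr/bin/env Rscript
# Step 7 — association statistics.
#
# Quartile-rescales each DAS28-CRP component and tests its association with
# the activity stages (Pearson chi-square). With a cohort CSV carrying a
# drug_class column and therapy_start_days, the same machinery tests drug
# class vs stage and therapy onset vs stage (Kruskal-Wallis); the synthetic
# cohort carries no medication, so those tests are skipped here.

suppressPackageStartupMessages(library(das28map))

cohort <- read_cohort("results/cohort.csv")
scores <- score_cohort(cohort)
stages <- droplevels(scores$stage)

tests <- list()
for (v in c("tjc28", "sjc28", "crp", "gh")) {
  q <- quartile_rescale(scores[[v]])
  tab <- table(quartile = q, stage = stages)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  ct <- chi2_test(tab)
  cat(sprintf("stage vs %-6s quartiles: chi-square = %6.2f, df = %d, p = %.3g\n",
              v, ct$statistic, ct$df, ct$p.value))
  tests[[paste0("stage_vs_", v)]] <- list(statistic = ct$statistic,
                                          df = ct$df, p = ct$p.value)
}

if (any(!is.na(cohort$drug_class))) {
  tab <- table(drug = cohort$drug_class, stage = stages)
  ct <- chi2_test(tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE])
  cat(sprintf("stage vs drug class: chi-square = %.2f, df = %d, p = %.3g\n",
              ct$statistic, ct$df, ct$p.value))
  tests$stage_vs_drug_class <- list(statistic = ct$statistic, df = ct$df,
                                    p = ct$p.value)
} else {
  cat("no drug_class data in this cohort; drug association skipped\n")
}
if (any(!is.na(cohort$therapy_start_days))) {
  groups <- split(cohort$therapy_start_days, stages)
  kw <- kruskal_wallis(groups[lengths(groups) > 0])
  tests$therapy_start_by_stage <- kw
}

jsonlite::write_json(tests, "results/associations.json",
                     auto_unbox = TRUE, digits = NA)
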