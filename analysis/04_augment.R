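#!/usr/bin/env Rscript
# Step 4 — generative equalization of cluster sizes.
#
# Density-guided generation of valid synthetic cases (Gaussian perturbation
# of seed patients, accepted with the P-matrix existence probability and a
# basin-membership check) brings every cluster and outlier group up to the
# size of the largest cluster, so that small subgroups become amenable to
# supervised analysis. Writes results/augmented.csv.
#
# The map and structure matrices are re-derived deterministically from the
# cohort (same seed as step 3).

suppressPackageStartupMessages(library(das28map))
seed <- 42L

cohort <- read_cohort("results/cohort.csv")
scores <- score_cohort(cohort)
comp4 <- as.matrix(scores[, c("tjc28", "sjc28", "crp", "gh")])
sc <- scale_0_100(comp4)
model <- train_esom(sc$scaled, esom_config(seed = seed + 1))
bmus <- assign_bmus(model, sc$scaled)
p <- p_matrix(model, sc$scaled, pareto_radius(sc$scaled))
assignment <- extract_clusters(u_star_matrix(u_matrix(model), p), bmus, model)

eq <- equalize_clusters(model, p, assignment, sc$scaled,
                        augmentation_plan(seed = seed + 2))
cat("cases generated per cluster:\n")
print(eq$additions)
cat("equalized size:", max(table(eq$cluster)), "per cluster;",
    sum(eq$is_synthetic), "generated cases in total\n")

aug <- as.data.frame(eq$data)
names(aug) <- c("tjc28", "sjc28", "crp", "gh")
aug$cluster <- eq$cluster
aug$is_synthetic <- eq$is_synthetic
aug$seed_patient_id <- NA_character_
if (!is.null(eq$provenance)) {
  aug$seed_patient_id[aug$is_synthetic] <-
    cohort$patient_id[eq$provenance$seed_row]
}
write.csv(aug, "results/augmented.csv", row.names = FALSE)
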