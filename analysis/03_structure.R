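#!/usr/bin/env Rscript
# Step 3 — unsupervised structure detection.
#
# PCA of the z-standardized four components, then projection of the
# 0-100-scaled components onto a 50 x 80 toroidal emergent self-organizing
# map; U-, P- and U*-matrices; cluster/outlier extraction from the U*
# landscape; chi-square test of cluster membership against the activity
# stages. Writes the matrices, cluster assignment and a JSON summary.

suppressPackageStartupMessages(library(das28map))
seed <- 42L

cohort <- read_cohort("results/cohort.csv")
scores <- score_cohort(cohort)
comp4 <- as.matrix(scores[, c("tjc28", "sjc28", "crp", "gh")])

pca <- pca_project(comp4)
cat("PCA eigenvalues:", round(pca$eigenvalues, 4), "\n")
cat(sprintf("first two PCs capture %.1f%% of total variance\n",
            sum(pca$variance_explained[1:2])))
cat("component contributions to PC1 (%):\n")
print(round(pca$contributions[, 1], 1))

sc <- scale_0_100(comp4)
model <- train_esom(sc$scaled, esom_config(seed = seed + 1),
                    input_scaling = sc$ranges)
bmus <- assign_bmus(model, sc$scaled)
r <- pareto_radius(sc$scaled)
u <- u_matrix(model)
p <- p_matrix(model, sc$scaled, r)
ustar <- u_star_matrix(u, p)
for (nm in c("u", "p", "ustar")) {
  write.table(matrix(get(nm), 50, 80, byrow = TRUE),
              file.path("results", paste0(nm, "_matrix.csv")),
              sep = ",", row.names = FALSE, col.names = FALSE)
}

assignment <- extract_clusters(ustar, bmus, model)
cat("\ncluster sizes (outlier groups separated):\n")
print(assignment$sizes)
write.csv(data.frame(patient_id = cohort$patient_id,
                     cluster = assignment$cluster,
                     is_outlier = assignment$is_outlier),
          "results/clusters.csv", row.names = FALSE)

assoc <- cluster_stage_association(assignment, scores$stage)
cat(sprintf("\ncluster vs stage: chi-square = %.2f, df = %d, p = %.3g\n",
            assoc$statistic, assoc$df, assoc$p.value))
jsonlite::write_json(
  list(pareto_radius = r, sizes = as.list(assignment$sizes),
       chi_square = assoc$statistic, df = assoc$df, p = assoc$p.value,
       seed = seed),
  "results/structure.json", auto_unbox = TRUE, digits = NA)
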