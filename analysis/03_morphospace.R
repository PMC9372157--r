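#!/usr/bin/env Rscript
# Generalized Procrustes superimposition and covariance PCA of the landmark
# sample; exports PC scores and the PC1-3 non-circularity distances, and
# places the theoretical shapes into the empirical morphospace.

library(orbitmorph)
cv <- read.csv("results/covariates.csv")
lms <- read_tps("results/landmarks.tps")
model <- morphospace_pca(gpa(lms))
print(model)
write_scores_csv(model, "results/scores.csv", covariates = cv)
saveRDS(model, "results/morphospace.rds")

lms_theory <- read_tps("results/landmarks_theoretical.tps")
proj <- t(vapply(lms_theory, function(cf)
  project_config(model, cf)[1:3], numeric(3)))
write.csv(data.frame(shape_id = vapply(lms_theory, `[[`, "",
                                       "specimen_id"),
                     PC1 = proj[, 1], PC2 = proj[, 2], PC3 = proj[, 3]),
          "results/theoretical_scores.csv", row.names = FALSE)
message(sprintf("PC1 %.1f%%, PC2 %.1f%% of shape variance; |r|(PC1, waist) = %.3f",
                100 * model$variance_fraction[1],
                100 * model$variance_fraction[2],
                abs(cor(model$scores[, 1], cv$waist))))
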