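#!/usr/bin/env Rscript
# Thin-plate-spline performance surfaces over the (PC1, PC2) morphospace:
# skull length, dietary regime, and the dorsoventral-compression SCF of the
# theoretical shapes placed into the same space.

library(orbitmorph)
model <- readRDS("results/morphospace.rds")
cv <- read.csv("results/covariates.csv")
sc2 <- model$scores[, 1:2]

s_skull <- interpolate_surface(sc2, cv$skull_length_mm)
write_surface_csv(s_skull, "results/heatmap_skull_length.csv")
s_diet <- interpolate_surface(sc2, diet_encoding(cv$diet))
write_surface_csv(s_diet, "results/heatmap_diet.csv")

th <- read.csv("results/theoretical_scores.csv")
pt <- read.csv("results/performance.csv")
dv <- pt[pt$scenario == "dv_compression" & is.na(pt$error), ]
m <- match(dv$shape_id, th$shape_id)
s_scf <- interpolate_surface(cbind(th$PC1[m], th$PC2[m]), dv$scf)
write_surface_csv(s_scf, "results/heatmap_scf_dv.csv")
message("wrote skull-length, diet and SCF heatmap grids")
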