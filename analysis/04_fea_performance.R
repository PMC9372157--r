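#!/usr/bin/env Rscript
# Plane-stress FE analysis of plates pierced by each theoretical orbit
# shape under the four loading scenarios; writes the stress concentration
# factor table (the biomechanical performance measure).

library(orbitmorph)
dir.create("results", showWarnings = FALSE)
pt <- performance_table(theoretical_set(), target_edge = 10 / 100)
write.csv(pt, "results/performance.csv", row.names = FALSE)
ok <- is.na(pt$error)
message("solved ", sum(ok), "/", nrow(pt), " shape x scenario models")
scf <- function(id, sc) pt$scf[pt$shape_id == id & pt$scenario == sc]
for (sc in unique(pt$scenario))
  message(sprintf("%-16s circle %.2f vs keyhole_w85 %.2f -> keyhole %s",
                  sc, scf("circle", sc), scf("keyhole_w85", sc),
                  ifelse(scf("keyhole_w85", sc) < scf("circle", sc),
                         "lower", "HIGHER")))
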