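#!/usr/bin/env Rscript
# Deformation-space quantification: solves circle / keyhole / wedge plates
# under dorsoventral compression at matched force per load-bearing area,
# landmarks the undeformed and deformed models, and reports the PC1-3
# Euclidean deformation distance per model.

library(orbitmorph)
ts <- theoretical_set()
mat <- fe_material()
ids <- c("circle", "ellipse_tall", "keyhole_w85", "wedge")
ref_geom <- build_plate(ts$circle)
pairs <- lapply(ids, function(id) {
  geom <- build_plate(ts[[id]])
  m <- mesh_plate(geom, target_edge = 10 / 100)
  Fs <- scale_loads(ref_geom, geom, 1)
  sol <- solve_plate(m, mat, make_load_case(m, "dv_compression", Fs),
                     geom$thickness)
  sample_fea_landmarks(sol, m, model_id = id)
})
dd <- deformation_distances(pairs)
write.csv(dd$distances, "results/deformation_distances.csv",
          row.names = FALSE)
print(dd$distances[order(dd$distances$d_euclid), ])
message("largest deformation: ",
        dd$distances$model_id[which.max(dd$distances$d_euclid)])
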