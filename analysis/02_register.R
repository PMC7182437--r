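#!/usr/bin/env Rscript
# Step 2 — preprocessing and dense correspondence.
#
# Reads the simulated cohort, mirrors left knees into the right-side
# convention, smooths and decimates every bone to ~1,000 vertices,
# remeshes the automatically selected low-deformity reference pair to a
# uniform edge length, rigidly aligns each pair to the reference (one
# rotation+translation for the combined femur+tibia cloud, preserving
# joint space), and extracts reference-indexed correspondences per bone
# by coherent point drift followed by closest-point projection. Writes
# results/correspondences.{csv,json} and the reference meshes.

suppressPackageStartupMessages(library(kneessm))

cohort <- read_cohort("results/cohort")
cohort <- lapply(cohort, preprocess_sample, smooth_iterations = 2,
                 target_vertices = 1000)

ref_idx <- select_reference(cohort)
reference <- cohort[[ref_idx]]
cat(sprintf("reference sample: %s (least deformed of %d)\n",
            reference$id, length(cohort)))

edge_f <- kneessm:::derive_edge_length(reference$femur, 1000)
edge_t <- kneessm:::derive_edge_length(reference$tibia, 1000)
reference$femur <- remesh_to_edge_length(reference$femur, edge_f)
reference$tibia <- remesh_to_edge_length(reference$tibia, edge_t)
cat(sprintf("reference remeshed: femur %d v (edge %.2f mm), tibia %d v (edge %.2f mm)\n",
            nrow(reference$femur$vertices), edge_f,
            nrow(reference$tibia$vertices), edge_t))
write_mesh(reference$femur, "results/reference_femur.ply")
write_mesh(reference$tibia, "results/reference_tibia.ply")

t0 <- Sys.time()
corr <- build_correspondences(cohort, reference, cpd_config())
cat(sprintf("correspondences: %d samples x %d points in %.1f min\n",
            nrow(corr$shapes), corr$p_femur + corr$p_tibia,
            as.numeric(Sys.time() - t0, units = "mins")))
if (length(corr$failed))
  cat("failed samples:", paste(corr$failed, collapse = ", "), "\n")
write_correspondences(corr, "results/correspondences")
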