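#!/usr/bin/env Rscript
# Stage 6: principal coordinate analysis of the hotspot-set K2P distances,
# and population-level K2P divergence with 1000 column-bootstrap replicates
# on the spacer (C) and hotspot (G) sets, combined into the two-triangle
# heat-map table. Writes pcoa.tsv, popdiv_* tables under results/.

library(barcodelim)

md <- read_sample_metadata("results/data/metadata.tsv")
plan <- default_region_plan()
regions <- setNames(lapply(seq_len(nrow(plan)), function(i)
  read_fasta_alignment(file.path("results/data", paste0(plan$region[i], ".fasta")),
                       region = plan$region[i],
                       compartment = plan$compartment[i])),
  plan$region)
sets <- build_datasets(regions, default_dataset_definitions(plan))

DG <- k2p_pairwise(sets$G)
pc <- pcoa_k2p(DG, k = 2)
print(pc)
write_pcoa_tsv(pc, md, "results/pcoa.tsv")

pd <- list()
for (code in c("C", "G")) {
  pd[[code]] <- population_divergence(sets[[code]], md, B = 1000L, seed = 42L)
  write_distance_tsv(pd[[code]]$mean, sprintf("results/popdiv_%s_mean.tsv", code))
  write_distance_tsv(pd[[code]]$se, sprintf("results/popdiv_%s_se.tsv", code))
  between <- pd[[code]]$mean[upper.tri(pd[[code]]$mean)]
  cat(sprintf("set %s between-population K2P: %.5f - %.5f\n",
              code, min(between, na.rm = TRUE), max(between, na.rm = TRUE)))
}
write_distance_tsv(combine_triangles(lower = pd$G$mean, upper = pd$C$mean),
                   "results/popdiv_heatmap.tsv")
cat("two-triangle population heat-map table written (lower = hotspots,",
    "upper = spacers)\n")
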