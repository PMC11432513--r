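#!/usr/bin/env Rscript
# Stage 5: collapse haplotypes on the plastid (A) and mitochondrial (B)
# coding data sets and build median-joining networks. Writes GML graphs,
# edge lists and haplotype composition tables under results/.

library(barcodelim)

plan <- default_region_plan()
md <- read_sample_metadata("results/data/metadata.tsv")
regions <- setNames(lapply(seq_len(nrow(plan)), function(i)
  read_fasta_alignment(file.path("results/data", paste0(plan$region[i], ".fasta")),
                       region = plan$region[i],
                       compartment = plan$compartment[i])),
  plan$region)
sets <- build_datasets(regions, default_dataset_definitions(plan))

for (code in c("A", "B")) {
  hap <- collapse_haplotypes(sets[[code]])
  label <- if (code == "A") "chlorotypes" else "mitotypes"
  cat(sprintf("set %s: %d %s among %d samples\n",
              code, length(hap$haplotypes), label, nrow(md)))
  comp <- haplotype_composition(hap, md)
  write.table(comp, sprintf("results/haplotypes_%s.tsv", code),
              sep = "\t", quote = FALSE, row.names = FALSE)
  shared <- comp[comp$multiplicity > 1, ]
  if (nrow(shared))
    cat("  shared haplotypes:",
        paste(sprintf("%s (%d: %s)", shared$haplotype, shared$multiplicity,
                      shared$taxa), collapse = "; "), "\n")
  g <- median_joining_network(hap)
  write_network(g, sprintf("results/network_%s.gml", code),
                sprintf("results/network_%s_edges.tsv", code))
  n_med <- sum(igraph::V(g)$type == "median")
  cat(sprintf("  network: %d nodes (%d median vectors), %d edges\n",
              igraph::vcount(g), n_med, igraph::ecount(g)))
}
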