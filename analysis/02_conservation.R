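#!/usr/bin/env Rscript
# Stage-specific enhancer calling in both species, cross-species coordinate
# translation, and conserved-enhancer statistics (overlap and <1 kb
# definitions), with Jaccard indices and Fisher tests against TP3.

library(ehourglass)

world <- readRDS("scratch/run/world.rds")
distal_A <- classify_distal(world$peaks[world$peaks$species == "A", ],
                            world$tss[world$tss$species == "A", ])
distal_B <- classify_distal(world$peaks[world$peaks$species == "B", ],
                            world$tss[world$tss$species == "B", ])
cat(sprintf("Distal elements: %d (species A), %d (species B)\n",
            length(unique(distal_A$id)), length(unique(distal_B$id))))

cons <- conservation_summary(distal_A, distal_B, world$block_map)
print(as.data.frame(cons$summary[, c("stage", "n_specific_A", "n_conserved_overlap",
                                     "n_conserved_1kb", "jaccard_overlap",
                                     "fisher_p_overlap_vs_TP3")]))
best <- cons$summary$stage[which.max(cons$summary$prop_A_overlap)]
cat(sprintf("\nHighest conserved proportion at %s (the phylotypic stage in this configuration)\n", best))

pleio <- temporal_pleiotropy(distal_A)
write_tsv_report(cons$summary, "results/conservation.tsv")
write_tsv_report(pleio$usage, "results/pleiotropy_usage.tsv")
write_tsv_report(pleio$adjacent, "results/pleiotropy_adjacent.tsv")
saveRDS(cons, "scratch/run/conservation.rds")
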