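#!/usr/bin/env Rscript
# Assemble the hourglass report: per stage, conservation (both definitions),
# Jaccard, and positive-selection proportions split by conservation status.

library(ehourglass)

cons <- readRDS("scratch/run/conservation.rds")
selres <- readRDS("scratch/run/selection.rds")

merged <- dplyr::inner_join(selres$selection, selres$groups,
                            by = c("enhancer_id", "stage"))
rows <- lapply(paste0("TP", 1:5), function(st) {
  cs <- cons$summary[cons$summary$stage == st, ]
  ss <- merged[merged$stage == st, ]
  tibble::tibble(
    stage = st,
    n_specific = cs$n_specific_A,
    conserved_prop_overlap = cs$prop_A_overlap,
    conserved_prop_1kb = cs$prop_A_1kb,
    jaccard = cs$jaccard_overlap,
    positive_prop = mean(ss$positive_call),
    positive_prop_conserved = mean(ss$positive_call[ss$conserved]),
    positive_prop_nonconserved = mean(ss$positive_call[!ss$conserved]))
})
report <- dplyr::bind_rows(rows)
print(as.data.frame(report))

cat(sprintf("\nConserved proportion peaks at %s; positive selection dips at %s.\n",
            report$stage[which.max(report$conserved_prop_overlap)],
            report$stage[which.min(report$positive_prop)]))
cat("Nonconserved > conserved positive proportion (pooled):",
    mean(merged$positive_call[!merged$conserved]) >
      mean(merged$positive_call[merged$conserved]), "\n")
write_tsv_report(report, "results/hourglass_report.tsv")
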