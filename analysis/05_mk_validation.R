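#!/usr/bin/env Rscript
# Substitution/polymorphism excess validation: positive-selection enhancers
# should show an excess of fixed differences relative to segregating sites.

library(ehourglass)

world <- readRDS("scratch/run/world.rds")
selres <- readRDS("scratch/run/selection.rds")

rec <- div_poly_records(selres$selection, world$snp_table)
tb <- mk_tabulate(rec)
ex <- mk_excess_test(tb$table)
cat("Pooled substitution/polymorphism table:\n")
print(tb$table)
cat(sprintf("subs/poly ratio: positive %.2f vs nonpositive %.2f; OR=%.2f, Fisher p=%.3g\n",
            tb$ratios["positive"], tb$ratios["nonpositive"],
            ex$odds_ratio, ex$p_value))

by_stage <- mk_by_stage(selres$selection, world$snp_table)
print(as.data.frame(by_stage))
write_tsv_report(by_stage, "results/mk.tsv")
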