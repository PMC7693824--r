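#!/usr/bin/env Rscript
# Stage 5: nearest-measured-neighbour activity projection for the five novel
# peptides, their ranking, and the combined per-peptide report.

suppressPackageStartupMessages(library(ocellatinr))
dir.create("results", showWarnings = FALSE)

cat_df <- load_catalogue()
act <- load_activity()
novel <- cat_df[match(novel_peptides(), cat_df$name), ]

ranking <- rank_novel(novel, cat_df, act)
cat("projected activity ranking of the novel peptides:\n")
print(ranking, row.names = FALSE)
write.table(ranking, "results/activity_projection.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

run_report(novel, cat_df, act,
           out_tsv = "results/novel_report.tsv",
           out_json = "results/novel_report.json")
cat("wrote results/activity_projection.tsv and results/novel_report.tsv\n")
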