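#!/usr/bin/env Rscript
# Stage 3: the five novel peptides against the family: pairwise
# identity/similarity, positional conservation, motif occurrence, and
# fragment classification of the catalogued fragment records.

suppressPackageStartupMessages(library(ocellatinr))
dir.create("results", showWarnings = FALSE)

cat_df <- load_catalogue()
fam <- cat_df[cat_df$group == "family_member", ]
novel <- cat_df[match(novel_peptides(), cat_df$name), ]

cmp <- compare_peptides(novel, cat_df)
cmp <- cmp[cmp$query != cmp$reference, ]
write.table(cmp, "results/pairwise_identity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
best <- do.call(rbind, lapply(split(cmp, cmp$query), function(d)
  d[order(-d$similarity_pct, -d$identity_pct), ][1, ]))
cat("closest catalogue relative of each novel peptide:\n")
print(best, row.names = FALSE)

cp5 <- conservation_profile(novel$sequence)
cp28 <- conservation_profile(fam$sequence, mode = "left_flush")
cat(sprintf("invariant positions, novel five: {%s}\n",
            paste(cp5$invariant_positions, collapse = ", ")))
cat(sprintf("invariant positions, all 28 (left-flush 1-21): {%s}\n",
            paste(cp28$invariant_positions, collapse = ", ")))
write.table(conservation_matrix(cp28), "results/conservation_matrix.tsv",
            sep = "\t", quote = FALSE, col.names = NA)

motifs <- data.frame(
  name = fam$name,
  strict = vapply(fam$sequence, function(s) motif_scan(s, TRUE)$match,
                  logical(1)),
  relaxed = vapply(fam$sequence, function(s) motif_scan(s, FALSE)$match,
                   logical(1)))
cat(sprintf("GXXDXXK motif: strict %d/28, relaxed %d/28\n",
            sum(motifs$strict), sum(motifs$relaxed)))
write.table(motifs, "results/motif_scan.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

frags <- load_fragments(catalogue = cat_df)
frags$classified <- vapply(frags$sequence, function(s) {
  hit <- fragment_classify(s, cat_df)
  if (is.null(hit)) "none"
  else sprintf("%s (%d-%d)", hit$parent, hit$start, hit$end)
}, character(1))
cat(sprintf("fragment records classified to a parent: %d/%d\n",
            sum(frags$classified != "none"), nrow(frags)))
write.table(frags, "results/fragment_classification.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
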