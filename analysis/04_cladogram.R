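#!/usr/bin/env Rscript
# Stage 4: identity-distance cladogram of the 28-member family (UPGMA, with
# an NJ tree for comparison), exported as Newick.

suppressPackageStartupMessages(library(ocellatinr))
dir.create("results", showWarnings = FALSE)

fam <- local({ d <- load_catalogue(); d[d$group == "family_member", ] })
dm <- distance_matrix(fam)
write.table(round(dm, 4), "results/identity_distance_matrix.tsv",
            sep = "\t", quote = FALSE, col.names = NA)

upgma_tr <- build_tree(dm, method = "upgma")
nj_tr <- build_tree(dm, method = "nj")
write_newick(upgma_tr, "results/ocellatin_upgma.nwk")
write_newick(nj_tr, "results/ocellatin_nj.nwk")

for (set in list(c("ocellatin-10", "ocellatin-6"),
                 c("ocellatin-9", "ocellatin-7", "ocellatin-8", "ocellatin-5"),
                 c("ocellatin-11", "ocellatin-2", "ocellatin-3"))) {
  cat(sprintf("{%s} monophyletic on UPGMA tree: %s\n",
              paste(set, collapse = ", "),
              is_monophyletic(upgma_tr, set)))
}
cat("wrote results/ocellatin_upgma.nwk and results/ocellatin_nj.nwk\n")
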