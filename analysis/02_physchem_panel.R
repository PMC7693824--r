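#!/usr/bin/env Rscript
# Stage 2: physicochemical panel for the full catalogue (28 family members
# plus the P3-Lla-2085 analog): average mass with amidation, formal charge,
# pI, GRAVY, hydrophobic fraction, hydrophobic moment.

suppressPackageStartupMessages(library(ocellatinr))
dir.create("results", showWarnings = FALSE)

cat_df <- load_catalogue()
panel <- do.call(rbind, lapply(seq_len(nrow(cat_df)), function(i) {
  cbind(cat_df[i, c("name", "sequence", "amidated")],
        physchem_profile(cat_df$sequence[i], cat_df$amidated[i]))
}))

cat(sprintf("GRAVY range over the family: %.3f to %.2f\n",
            min(panel$gravy[cat_df$group == "family_member"]),
            max(panel$gravy[cat_df$group == "family_member"])))
cat(sprintf("hydrophobic moment range: %.2f to %.2f\n",
            min(panel$mu_h), max(panel$mu_h)))
cat(sprintf("formal charges span %d to %+d; pI %.2f to %.2f\n",
            min(panel$net_charge_formal), max(panel$net_charge_formal),
            min(panel$pI), max(panel$pI)))

# mass check against the printed theoretical masses where available
have <- !is.na(cat_df$printed_mw)
dev <- abs(panel$mw[have] - cat_df$printed_mw[have])
cat(sprintf("printed-mass agreement: %d/%d within 0.05 Da (max dev %.2f)\n",
            sum(dev <= 0.05), sum(have), max(dev)))

panel$mw <- round(panel$mw, 2)
panel[c("net_charge_continuous", "pI", "gravy", "mu_h")] <-
  round(panel[c("net_charge_continuous", "pI", "gravy", "mu_h")], 3)
write.table(panel, "results/physchem_panel.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# helical wheel geometry for the five novel peptides (numeric, logo-ready)
wheels <- do.call(rbind, lapply(novel_peptides(), function(n) {
  cbind(name = n, helical_wheel(cat_df$sequence[cat_df$name == n]))
}))
write.table(wheels, "results/helical_wheels.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/physchem_panel.tsv and results/helical_wheels.tsv\n")
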