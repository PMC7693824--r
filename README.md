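# ocellatinr

Ocellatins are a family of short, weakly cationic, mostly C-terminally
amidated antimicrobial peptides found exclusively in the skin of
*Leptodactylus* frogs. They are secreted as tripartite prepro-peptides — a
conserved 21-residue signal peptide ending in Cys, an acidic propiece of
19–22 residues ending in the Lys-Arg prohormone processing site, and the
mature peptide, whose terminal Gly (when present) directs C-terminal
amidation. `ocellatinr` implements the complete in-silico characterization
of such peptides for sequence-analysis work on this family: precursor
parsing, a physicochemical panel, family comparison, similarity cladograms,
and similarity-based activity projection. It ships the 28-member family
catalogue, the fragment records, and the MIC activity table as packaged
data.

## What it computes

* **Precursor parsing** — `translate_cds()` (first ATG to first stop,
  automatic frame selection) and `parse_precursor()`, which segments the
  protein by three rules: signal = residues 1..k where k is the first Cys in
  positions 15–25; acidic propiece ends at the *last* K-R dipeptide leaving
  at least 15 mature residues; a terminal Gly on the raw mature peptide is
  removed and recorded as the amidation signal.
* **Physicochemical panel** — isotope-averaged mass (amidation = −0.9847 Da),
  formal pH-7 net charge (+1 N-terminus and K/R, −1 D/E and free C-terminus,
  His neutral), Henderson–Hasselbalch continuous charge and pI (bisection),
  GRAVY (mean Kyte–Doolittle hydropathy), hydrophobic residue percentage
  (set {A,C,F,I,L,M,V,W}, truncated), the Eisenberg-style per-residue
  hydrophobic moment µH = |Σᵢ hᵢ·(cos iδ, sin iδ)| / n with δ = 100°, and
  helical-wheel geometry.
* **Family comparison** — Needleman–Wunsch global alignment (BLOSUM62, gap
  open 10 / extend 0.5, terminal gaps penalized); identity = identical
  columns over total alignment length, similarity additionally counts
  strictly positive BLOSUM62 substitutions; positional conservation
  profiles, the G-X-X-D-X-X-K motif scan, and fragment classification.
* **Cladograms** — identity distance d = 1 − identity fraction, UPGMA
  (default) or neighbor-joining, Newick export, monophyly queries.
* **Activity projection** — a query inherits the MIC of the most similar
  catalogue peptide with an exact measured MIC; novel peptides are ranked by
  projected *E. coli* MIC with charge/µH tie-breaks.
* **Synthetic precursors** — `generate_precursor()` / `emit_fixtures()`
  emulate the precursor architecture with ground truth, so the whole
  pipeline is testable without external sequence data.

## Worked example

```r
library(ocellatinr)
cat_df <- load_catalogue()
oc11 <- cat_df$sequence[cat_df$name == "ocellatin-11"]  # GVLDIFKDAAKQILAHAAEKI

round(average_mass(oc11, amidated = TRUE), 2)
#> [1] 2250.67          # amidated average mass, Da
net_charge_formal(oc11, amidated = TRUE)
#> [1] 1                # weakly cationic
global_align(oc11, cat_df$sequence[cat_df$name == "ocellatin-2"])
#> GVLDIFKDAAKQILAHAAEKI
#> GVLDIFKDAAKQILAHAAEQI
#> identity 95.2% (20/21), similarity 100%
```

The single K20Q difference from ocellatin-2 is a conservative substitution,
hence 95.2% identity but 100% similarity. Projecting activity for the most
promising novel peptide:

```r
project_activity(cat_df$sequence[cat_df$name == "ocellatin-10"],
                 cat_df, load_activity(), query_name = "ocellatin-10")
#> ocellatin-10 -> nearest measured neighbour P3-Lla-2085
#>                 (similarity 95.2%, identity 90.5%)
#>   ... E_coli MIC 15 uM (exact)
```

ocellatin-10 differs from the measured hybrid analog P3-Lla-2085 by one
conservative substitution plus a terminal Val, so it inherits the 15 µM
MIC and ranks first among the five novel peptides (then ocellatin-7, -8,
-9 — bounded by ocellatin-5 at 28 µM — and ocellatin-11).

## Analysis workflow

The numbered drivers under `analysis/` run the full study over the packaged
data and write tables under `results/`:

| script | output |
| --- | --- |
| `01_parse_precursors.R` | synthetic precursor parsing + recovery report |
| `02_physchem_panel.R` | per-peptide panel, helical wheels |
| `03_family_comparison.R` | pairwise identity/similarity, conservation matrix, motif scan, fragment classification |
| `04_cladogram.R` | identity distances, UPGMA/NJ Newick trees |
| `05_activity_projection.R` | projections, ranking, combined report |

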