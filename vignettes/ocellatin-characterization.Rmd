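---
title: "Characterizing ocellatin antimicrobial peptides: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing ocellatin antimicrobial peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocellatinr)
```

Ocellatins are gene-encoded antimicrobial peptides of *Leptodactylus*
frogs: 21, 25 or 32 residues, weakly cationic (formal charges 0 to +3),
amphipathic, and — except for the three longest members — C-terminally
amidated. They are expressed as tripartite prepro-peptides. This vignette
is the package's account of the models it implements, the parameters that
matter, and the choices made where the design was genuinely open.

## The precursor model

`parse_precursor()` segments a translated precursor by three deterministic
rules rather than a trained signal-peptide predictor, because the family's
precursor architecture is strongly stereotyped:

1. **Signal peptide** — residues 1..k, where k is the *first* Cys found in
   the window 15–25. The family signal is 21 residues and ends in its only
   Cys; taking the first Cys encodes the fact that signal peptides are
   N-terminal. Proteins without a window Cys are rejected.
2. **Acidic propiece** — continues to the *last* K-R dipeptide that leaves
   at least 15 residues of mature peptide. The processing site sits at the
   carboxyl terminus of the acidic domain, so when decoy dibasic motifs
   occur upstream the last eligible site is the biologically correct one.
   Only the literal Lys-Arg is accepted: K-K and R-R dibasic sites occur in
   other prohormone systems but are not the signal in this family. The
   resulting propiece must be 15–30 residues long (observed range 19–22,
   with slack for unseen variants).
3. **Amidation** — a terminal Gly on the raw mature segment is removed and
   recorded as `amidated = TRUE`; amidation transfers the Gly nitrogen to
   the preceding residue's carbonyl, replacing the C-terminal OH with NH2.

Coordinates are 1-based inclusive throughout, matching residue-numbering
conventions (Gly^1, Asp^4). Translation (`translate_cds()`) runs from the
first ATG of a frame to the first stop; automatic frame selection requires
a leading Met and a K-R dipeptide in the translation, breaking ties by ORF
length. Codons containing N translate to X, which residue validation
rejects downstream — a deliberate fail-loud choice for ambiguous reads.

## The physicochemical panel

* **Mass.** Isotope-averaged residue masses plus one water; amidation
  subtracts 0.9847 Da (OH → NH2). Average rather than monoisotopic masses
  are used because they reproduce the catalogue's printed theoretical
  masses to within 0.05 Da (verified for all nine peptides with a printed
  mass, `analysis/02_physchem_panel.R`). Notably, the printed mass of
  ocellatin-6 (2273.77) is reproduced only by the catalogued 22-mer *with*
  amidation (2273.76); the package stores that form.
* **Formal charge.** +1 for the free N-terminus and each K/R, −1 for each
  D/E and the free-acid C-terminus, His counted neutral at pH 7. His
  neutrality is required to reproduce every printed family charge; the
  continuous model below gives His its usual pKa instead. Amidation
  removes the C-terminal negative charge, hence +1 relative to the free
  acid.
* **Continuous charge and pI.** A Henderson–Hasselbalch sum over ionizable
  groups with EMBOSS-style pKa values (`PKA_SET`: C-term 3.6, D 3.9,
  E 4.1, H 6.0, N-term 8.6, C 8.5, Y 10.1, K 10.8, R 12.5). The charge is
  strictly decreasing in pH, so the pI is found by bisection on [0, 14] to
  |charge| < 1e-4 (the tolerance is on charge, not pH; with ~200 iteration
  cap the solver cannot fail on a sign-changing function). Published pI
  values for these peptides come from unspecified tools with their own pKa
  sets, so the package treats the printed range (9.66–10.7) as a bracket
  check, not an exact target.
* **GRAVY and hydrophobic fraction.** GRAVY is the mean Kyte–Doolittle
  hydropathy. The hydrophobic fraction counts residues in
  {A,C,F,I,L,M,V,W} and truncates (not rounds) toward zero: this is the
  only convention that reproduces both printed values 42% (9/21 = 42.86)
  and 52% (11/21 = 52.38) simultaneously.
* **Hydrophobic moment.** µH = |Σᵢ hᵢ·(cos iδ, sin iδ)| / n at δ = 100° per
  residue, with Kyte–Doolittle hydropathies — the scale the family
  literature states — normalized per residue. µH is invariant under
  sequence reversal (the sum conjugates and rotates, preserving magnitude)
  and cancels exactly only over full wheel periods (18 residues at 100°).
  The printed family range (0.6–1.49) depends on the upstream tool's exact
  normalization, so the package brackets its values in [0.5, 1.6] rather
  than pinning them; the computed range is 0.59–1.49.
* **MIC conversion.** µM = 1000·(µg/mL)/Mw. The published table is only
  integer-consistent for about two-thirds of its cells; the others are
  rounded to 1–2 significant figures (e.g. 800 µg/mL → "300" µM where the
  conversion gives 303) or derived by doubling. Tests pin exactly the
  self-consistent cells.

## Family comparison

Pairwise comparison uses Needleman–Wunsch global alignment with BLOSUM62,
gap open 10 / extend 0.5, terminal gaps penalized as ordinary gaps
(Biostrings' aligner). Identity divides identical columns by the **total
alignment length** — gap columns stay in the denominator. This convention
is forced by the printed 90.5% for the 21-mer/20-mer pair
ocellatin-10/P3-Lla-2085 (19/21, counting the terminal gap column), and it
makes identity symmetric. Similarity additionally counts substitution
columns with a strictly positive BLOSUM62 score, which reproduces the
printed treatment of K↔Q and I↔L as conservative. Two published cells for
pairs involving ocellatin-5 (71.4/76.2 and 57.1/76.2) are not reproducible
under any simple convention we could identify — the original tool's exact
settings are unrecoverable — and are deliberately not pinned by tests.

Conservation profiles use the family's printed left-flush, gap-free layout:
columns run 1 to the shortest sequence (21 for the full family). No
internal-gap multiple alignment is inferred; that is out of scope by
design, since the family alignment is gap-free as published. The
G-X-X-D-X-X-K motif scan checks positions 1–7 with X ∈ {V,L,I,F,A,M}; the
relaxed variant [GA]-X-X-D-X-X-[KT] admits the observed Ala1 (ocellatin-5,
-6) and Thr7 (ocellatin-4, -V3) alternatives.

## Cladograms

Distances are 1 − identity fraction, uncorrected: the published cladogram
displays raw similarity clustering, not a substitution-model phylogeny, and
the tree-building algorithm behind it is unstated. UPGMA (average-linkage
agglomeration; ultrametric by construction) is the default used for the
cluster-membership checks; NJ is provided for comparison and verified to
recover additive matrices exactly. Cluster membership — {ocellatin-10, -6},
{ocellatin-9, -7, -8, -5}, {ocellatin-11, -2, -3} — is tested; the exact
topology is not, since no algorithm was specified for the original figure.

## Activity projection

The published activity argument is qualitative (ocellatin-10 should behave
like P3-Lla-2085, which differs by one conservative substitution; the less
hydrophobic ocellatin-7/-8/-9 should not exceed ocellatin-5). The package
operationalizes it as deterministic nearest-measured-neighbour transfer:
the neighbour is the catalogue peptide with maximal alignment similarity
among those with an *exact* MIC (lower-bound and "inactive" measurements
are not usable anchors), ties broken by identity then name. Ranking of
novel peptides is by ascending projected *E. coli* MIC with ties broken by
higher formal charge, then higher µH, then name. The charge and µH
tie-breaks are this package's choice — the published relative order of
ocellatin-7/-8/-9/-11 is asserted without a stated metric — and with them
the computed ranking (10, 7, 8, 9, 11) matches the published expectation.
No regression or trained classifier is involved, deliberately: one
measured neighbour is the strongest defensible statement the data allow.

## The synthetic generator

No nucleotide sequences for this family are redistributable in this
package, so `generate_precursor()` emulates the precursor architecture:

* signal: Met + hydrophobic-biased residues + Cys at position 21 (the only
  Cys, making the signal boundary unambiguous);
* acidic propiece: 19–22 residues, interior residues Asp/Glu with
  probability 0.55 (per-record fraction enforced ≥ 0.4), ending K-R, with
  no other K-R unless `adversarial = TRUE` plants a decoy to exercise the
  last-eligible-site rule;
* mature: 21–32 residues sampled from the family's positional frequency
  profile (positions past column 21 draw from the pooled family residue
  frequencies), rejected if it contains Cys or K-R; terminal Gly appended
  with probability 0.9 (the family's amidation rate — all but 3 of 28);
* cDNA: uniform synonymous-codon back-translation, an ATG-free 5' UTR, a
  random stop codon, 3' UTR and poly-A tail. Codon usage and GC content of
  *Leptodactylus* are deliberately not modeled.

The generator is a pure function of its seed and restores the global RNG
state. What passing round-trip tests show is that the parser exactly
inverts this architecture (500/500 at default parameters, decoys included);
what they cannot show is robustness to real cloning artifacts — chimeric
reads, sequencing errors, non-canonical processing sites — which the
rule-based parser would reject loudly rather than mis-segment. Sampling
mature peptides from the positional profile yields formal charges in the
band −3..+6 (empirically; the family itself spans −1..+3), wider than real
ocellatins because column frequencies are sampled independently.

## Numerical conventions and problem sizes

Reported precision follows the published tables: masses to 2 decimals,
percents to 1, GRAVY and µH to 3. Percentages are computed on exact counts
and rounded once at the end. Test and analysis problem sizes — a 28-member
catalogue (378 alignments per distance matrix), cohorts of 100–500
synthetic precursors — are the full study sizes; nothing is subsampled.

## Known limitations

* Secondary-structure content, aggregation propensity, hemolysis and
  ML-based activity prediction are out of scope; the panel is sequence-only.
* The identity/similarity conventions reproduce the robust published pairs
  but not every printed cell (see above); the same holds for coarsely
  rounded MIC conversions.
* The activity projection transfers a single neighbour's MIC; it makes no
  claim about mechanism and cannot extrapolate beyond the measured family.
* Fragment records whose sequences were never printed (P2-Ll-1298, the
  17-mer provisionally called ocellatin-5*) are omitted from the packaged
  fragment table.
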