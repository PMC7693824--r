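Package: ocellatinr
Title: Characterization of Ocellatin Antimicrobial Peptide Precursors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: In-silico characterization workflow for ocellatin antimicrobial
    peptides from Leptodactylus frog skin. Translates cloned cDNA precursors
    and parses the tripartite prepro-peptide (signal peptide, acidic propiece,
    mature peptide) with the Gly-directed C-terminal amidation rule; computes
    the physicochemical panel (average mass, formal and pH-dependent net
    charge, isoelectric point, GRAVY, hydrophobic residue fraction, Eisenberg
    hydrophobic moment, helical-wheel geometry, MIC unit conversion); compares
    peptides against the packaged 28-member ocellatin family catalogue by
    global alignment identity/similarity, positional conservation and motif
    scanning; builds similarity cladograms (UPGMA/NJ) with Newick export; and
    projects antimicrobial activity of novel peptides by nearest measured
    neighbour transfer. Includes a synthetic precursor generator with ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
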