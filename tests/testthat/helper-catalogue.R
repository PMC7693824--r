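# Frozen transcription of the 28-member family alignment (printed left-flush,
# no internal gaps), used as the reference checksum for the packaged file.
FAMILY_TRANSCRIPTION <- c(
  "ocellatin-F"   = "GVVDILKGAAKDIAGHLASKVMNKL",
  "ocellatin-K1"  = "GVVDILKGAAKDLAGHLASKVMNKI",
  "ocellatin-L1"  = "GVVDILKGAAKDLAGHLATKVMNKL",
  "ocellatin-L2"  = "GVVDILKGAAKDLAGHLATKVMDKL",
  "ocellatin-S"   = "GVLDILKGAAKDLAGHVATKVINKI",
  "ocellatin-P"   = "GLLDTLKGAAKNVVGSLASKVMEKL",
  "ocellatin-7"   = "GVVDILKDTGKKLLSHLMEKI",
  "ocellatin-8"   = "GVVDILKDTGKKLLSHLMEKV",
  "ocellatin-9"   = "GVLDIFKDTGKKLLSHLMEKV",
  "ocellatin-5"   = "AVLDILKDVGKGLLSHFMEKV",
  "ocellatin-10"  = "GLLDFLKAAGKGLVSNLIEKV",
  "ocellatin-6"   = "AVLDFIKAAGKGLVTNIMEKVG",
  "ocellatin-PT6" = "GVFDIIKGAGKQLIAHAMEKIAEKVGLNKDGN",
  "ocellatin-PT8" = "GVFDIIKGAGKQLIARAMGKIAEKVGLNKDGN",
  "ocellatin-PT7" = "GVFDIIKGAGKQLIAHAMGKIAEKVGLNKDGN",
  "ocellatin-PT4" = "GVFDIIKGAGKQLIAHAMGKIAEKV",
  "ocellatin-PT1" = "GVFDIIKDAGKQLVAHAMGKIAEKV",
  "ocellatin-PT5" = "GVFDIIKDAGRQLVAHAMGKIAEKV",
  "ocellatin-PT2" = "GVFDIIKDAGKQLVAHATGKIAEKV",
  "ocellatin-PT3" = "GVIDIIKGAGKDLIAHAIGKLAEKV",
  "ocellatin-V1"  = "GVVDILKGAGKDLLAHALSKLSEKV",
  "ocellatin-V3"  = "GVLDILTGAGKDLLAHALSKLSEKV",
  "ocellatin-V2"  = "GVLDILKGAGKDLLAHALSKISEKV",
  "ocellatin-1"   = "GVVDILKGAGKDLLAHLVGKISEKV",
  "ocellatin-11"  = "GVLDIFKDAAKQILAHAAEKI",
  "ocellatin-2"   = "GVLDIFKDAAKQILAHAAEQI",
  "ocellatin-4"   = "GLLDFVTGVGKDIFAQLIKQI",
  "ocellatin-3"   = "GVLDILKNAAKNILAHAAEQI"
)

# Letter sequences as printed in the novel-peptide table (the two rows whose
# display diverges from the family alignment, ocellatin-10 and -6, are not
# included; the packaged form follows the family alignment).
NOVEL_TABLE_SEQS <- c(
  "ocellatin-2"  = "GVLDIFKDAAKQILAHAAEQI",
  "ocellatin-11" = "GVLDIFKDAAKQILAHAAEKI",
  "ocellatin-5"  = "AVLDILKDVGKGLLSHFMEKV",
  "ocellatin-7"  = "GVVDILKDTGKKLLSHLMEKI",
  "ocellatin-8"  = "GVVDILKDTGKKLLSHLMEKV",
  "ocellatin-9"  = "GVLDIFKDTGKKLLSHLMEKV",
  "P3-Lla-2085"  = "GLLDFLKAAGKGLVSNLLEK"
)

.cache <- new.env()

cached_catalogue <- function() {
  if (is.null(.cache$cat)) .cache$cat <- load_catalogue()
  .cache$cat
}

cached_family <- function() {
  cat <- cached_catalogue()
  cat[cat$group == "family_member", ]
}

cached_activity <- function() {
  if (is.null(.cache$act)) .cache$act <- load_activity()
  .cache$act
}

# The family tree takes ~380 pairwise alignments; build once per run.
cached_family_tree <- function() {
  if (is.null(.cache$tree)) {
    .cache$dm <- distance_matrix(cached_family())
    .cache$tree <- build_tree(.cache$dm, method = "upgma")
  }
  .cache$tree
}

cached_family_dm <- function() {
  cached_family_tree()
  .cache$dm
}
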