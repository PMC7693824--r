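## Synthetic precursor cDNAs with the family's tripartite statistical
## structure, plus ground truth, so the whole pipeline is testable without
## any external sequence. The generator enforces uniqueness constraints
## (single Cys in the signal window, single eligible K-R site unless decoys
## are requested) that make the rule-based parse provably unambiguous.

SIGNAL_WEIGHTS <- local({
  w <- stats::setNames(rep(1, length(VALID_RESIDUES)), VALID_RESIDUES)
  w[c("A", "L", "V", "I", "F", "M", "W")] <- 4  # hydrophobic core bias
  w[c("G", "S", "T", "P")] <- 2
  w["C"] <- 0  # the signal's only Cys is its last residue
  w
})

ACIDIC_FILLER <- c("G", "A", "S", "Q", "N", "L", "V", "T", "P", "F")

family_profile <- local({
  env <- new.env()
  function() {
    if (is.null(env$p)) {
      cat <- load_catalogue()
      fam <- cat$sequence[cat$group == "family_member"]
      env$p <- conservation_profile(fam, mode = "left_flush")
      pooled <- table(unlist(strsplit(fam, "")))
      env$pooled <- stats::setNames(as.numeric(pooled) / sum(pooled),
                                    names(pooled))
    }
    list(profile = env$p, pooled = env$pooled)
  }
})

sample_weighted <- function(n, weights) {
  sample(names(weights), n, replace = TRUE, prob = weights)
}

#' Generate one synthetic prepro-peptide precursor with ground truth
#'
#' Emulates the family's precursor architecture: a hydrophobic-biased signal
#' peptide of `signal_len` residues ending in its only Cys; an acidic
#' propiece (>= 40% Asp/Glu) ending in the K-R processing site; a mature
#' peptide sampled from the packaged family's positional frequency profile
#' (positions past the profile draw from the pooled family residue
#' frequencies), free of Cys and of internal K-R; and an optional terminal
#' Gly appended with probability `amidation_prob` (the amidation signal).
#' The cDNA is a uniform synonymous-codon back-translation with an ATG-free
#' 5' UTR, a stop codon, 3' UTR and poly-A tail.
#'
#' With `adversarial = TRUE` a decoy K-R dipeptide is planted in the acidic
#' propiece interior, exercising the parser's last-eligible-K-R rule.
#'
#' @param seed Integer seed; the record is a deterministic function of it.
#' @param signal_len Signal peptide length (Cys position), in 15-25.
#' @param acidic_range Inclusive range of acidic propiece lengths (includes
#'   the terminal K-R).
#' @param mature_range Inclusive range of mature peptide lengths.
#' @param amidation_prob Probability of the terminal Gly amidation signal.
#' @param adversarial Plant a decoy K-R in the propiece interior?
#' @return List of class `synthetic_truth`: `id`, `cdna`, `protein`,
#'   `signal`, `acidic`, `mature`, `amidated`, `seed`.
#' @export
generate_precursor <- function(seed, signal_len = 21L,
                               acidic_range = c(19L, 22L),
                               mature_range = c(21L, 32L),
                               amidation_prob = 0.9,
                               adversarial = FALSE) {
  stopifnot(signal_len >= 15L, signal_len <= 25L,
            acidic_range[1L] >= 17L, acidic_range[2L] <= 30L,
            mature_range[1L] >= 15L, mature_range[2L] <= 40L)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  fp <- family_profile()

  for (attempt in 1:200) {
    signal <- paste(c("M", sample_weighted(signal_len - 2L, SIGNAL_WEIGHTS),
                      "C"), collapse = "")

    acidic_len <- sample(seq(acidic_range[1L], acidic_range[2L]), 1L)
    interior_len <- acidic_len - 2L
    interior <- ifelse(stats::runif(interior_len) < 0.55,
                       sample(c("D", "E"), interior_len, replace = TRUE),
                       sample(ACIDIC_FILLER, interior_len, replace = TRUE))
    if (adversarial && interior_len >= 4L) {
      at <- sample(seq_len(interior_len - 1L), 1L)
      interior[at] <- "K"; interior[at + 1L] <- "R"
    }
    acidic <- paste(c(interior, "K", "R"), collapse = "")
    de_frac <- (sum(interior %in% c("D", "E"))) / acidic_len
    if (de_frac < 0.4) next

    mature_len <- sample(seq(mature_range[1L], mature_range[2L]), 1L)
    cols <- fp$profile$columns
    mature <- vapply(seq_len(mature_len), function(p) {
      f <- if (p <= length(cols)) cols[[p]] else fp$pooled
      sample(names(f), 1L, prob = f)
    }, character(1L))
    mature <- paste(mature, collapse = "")
    if (grepl("KR", mature, fixed = TRUE) || grepl("C", mature, fixed = TRUE))
      next

    amidated <- stats::runif(1L) < amidation_prob
    mature_raw <- if (amidated) paste0(mature, "G") else mature
    protein <- paste0(signal, acidic, mature_raw)

    cdna <- back_translate(protein)
    ok <- tryCatch({
      identical(translate_cds(cdna, frame = "auto"), protein) && {
        p <- parse_precursor(protein)
        identical(p$signal, signal) && identical(p$acidic, acidic) &&
          identical(p$mature, mature) && identical(p$amidated, amidated)
      }
    }, error = function(e) FALSE)
    if (!ok) next

    return(structure(list(id = sprintf("synthetic_precursor_%d", seed),
                          cdna = cdna, protein = protein, signal = signal,
                          acidic = acidic, mature = mature,
                          amidated = amidated, seed = as.integer(seed)),
                     class = "synthetic_truth"))
  }
  stop("could not satisfy generator constraints after bounded rejection ",
       "sampling", call. = FALSE)
}

CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), as.character(gc))
})

back_translate <- function(protein) {
  res <- strsplit(protein, "")[[1L]]
  codons <- vapply(res, function(a) {
    opts <- CODON_TABLE[[a]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1L))
  stop_codon <- sample(CODON_TABLE[["*"]], 1L)
  utr5 <- paste(sample(c("A", "C", "T"), sample(5:30, 1L), replace = TRUE),
                collapse = "")  # ATG-free by construction (no G)
  utr3 <- paste(sample(c("A", "C", "G", "T"), sample(5:30, 1L),
                       replace = TRUE), collapse = "")
  paste0(utr5, paste(codons, collapse = ""), stop_codon, utr3,
         strrep("A", 12L))
}

#' Generate a cohort of synthetic precursors
#'
#' Deterministic given `seed`: record `i` uses sub-seed `seed + i`.
#'
#' @param n Number of records.
#' @param seed Base integer seed.
#' @param ... Passed to [generate_precursor()].
#' @return List of `synthetic_truth` records.
#' @export
generate_cohort <- function(n, seed, ...) {
  lapply(seq_len(n), function(i) generate_precursor(seed + i, ...))
}

#' Write synthetic fixtures: cDNA FASTA plus ground-truth JSON
#'
#' @param n Number of records (>= 1).
#' @param seed Base seed.
#' @param out_dir Output directory (created if needed).
#' @param ... Passed to [generate_precursor()].
#' @return Invisibly, a list with the two file paths.
#' @export
emit_fixtures <- function(n, seed, out_dir, ...) {
  stopifnot(n >= 1L)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  records <- generate_cohort(n, seed, ...)
  fasta <- file.path(out_dir, "fixtures.fasta")
  truth <- file.path(out_dir, "truth.json")
  set <- Biostrings::DNAStringSet(
    stats::setNames(vapply(records, `[[`, character(1L), "cdna"),
                    vapply(records, `[[`, character(1L), "id")))
  Biostrings::writeXStringSet(set, filepath = fasta)
  jsonlite::write_json(lapply(records, unclass), truth, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(fasta = fasta, truth = truth))
}
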