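## Translation of cloned cDNA and rule-based parsing of the tripartite
## prepro-peptide: signal peptide (ends at the characteristic Cys), acidic
## propiece (ends at the Lys-Arg prohormone processing site), mature peptide
## (terminal Gly marks C-terminal amidation).

#' Translate a coding cDNA sequence
#'
#' Translates from the first ATG of the chosen reading frame to the first
#' stop codon, using the standard genetic code. With `frame = "auto"` the
#' frame is chosen whose open reading frame starts with Met and contains a
#' "KR" dipeptide (the prohormone processing signal); ties are broken by the
#' longest open reading frame.
#'
#' Codons containing `N` translate to `X`, which downstream residue
#' validation rejects.
#'
#' @param nucleotides DNA string over `A`, `C`, `G`, `T`, `N`.
#' @param frame `"auto"` or an offset 0, 1, 2.
#' @return Protein string (no stop character).
#' @examples
#' translate_cds("ATGGGCTAA", frame = 0)  # "MG"
#' @export
translate_cds <- function(nucleotides, frame = "auto") {
  if (!is.character(nucleotides) || length(nucleotides) != 1L ||
      nchar(nucleotides) < 3L) {
    stop("nucleotides must be a single DNA string of length >= 3", call. = FALSE)
  }
  nucleotides <- toupper(nucleotides)
  if (grepl("[^ACGTN]", nucleotides)) {
    stop("nucleotides must be over {A,C,G,T,N}", call. = FALSE)
  }
  frames <- if (identical(frame, "auto")) 0:2 else as.integer(frame)
  if (!all(frames %in% 0:2)) stop("frame must be 0, 1, 2 or \"auto\"", call. = FALSE)

  orf_in_frame <- function(f) {
    s <- substr(nucleotides, f + 1L, nchar(nucleotides))
    n_codons <- nchar(s) %/% 3L
    if (n_codons == 0L) return(NULL)
    codons <- substring(s, 3L * (seq_len(n_codons) - 1L) + 1L,
                        3L * seq_len(n_codons))
    aa <- vapply(codons, function(cd) {
      if (grepl("N", cd, fixed = TRUE)) "X"
      else as.character(Biostrings::GENETIC_CODE[[cd]])
    }, character(1L), USE.NAMES = FALSE)
    start <- match("M", aa)
    if (is.na(start)) return(NULL)
    rest <- aa[start:length(aa)]
    stop_at <- match("*", rest)
    if (is.na(stop_at)) return(NULL)
    paste(rest[seq_len(stop_at - 1L)], collapse = "")
  }

  orfs <- lapply(frames, orf_in_frame)
  ok <- !vapply(orfs, is.null, logical(1L))
  if (!any(ok)) stop("no open reading frame (ATG...stop) in any frame",
                     call. = FALSE)
  frames <- frames[ok]; orfs <- orfs[ok]
  if (length(orfs) == 1L || !identical(frame, "auto")) return(orfs[[1L]])
  has_kr <- vapply(orfs, function(p) grepl("KR", p, fixed = TRUE), logical(1L))
  pick <- if (any(has_kr)) which(has_kr) else seq_along(orfs)
  best <- pick[which.max(vapply(orfs[pick], nchar, integer(1L)))]
  orfs[[best]]
}

#' Parse a prepro-peptide into signal, acidic propiece and mature peptide
#'
#' Applies the family's precursor architecture: the signal peptide runs from
#' the initiator Met to the first Cys found at position 15-25 (the conserved
#' signal is 21 residues, ending in its only Cys); the acidic propiece ends
#' at the last "KR" dipeptide that still leaves at least 15 residues of
#' mature peptide; a terminal Gly on the raw mature segment is removed and
#' recorded as the C-terminal amidation signal.
#'
#' @param protein Residue string starting with `M`, length >= 45.
#' @return List of class `precursor_structure` with fields `protein`,
#'   `signal`, `acidic`, `mature_raw`, `mature`, `amidated`, `signal_end`,
#'   `kr_site` (1-based index of the K of the processing K-R).
#' @export
parse_precursor <- function(protein) {
  res <- check_residues(protein, what = "protein")
  n <- length(res)
  if (res[1L] != "M") stop("precursor must start with Met", call. = FALSE)
  if (n < 45L) stop("precursor too short to hold signal + propiece + mature",
                    call. = FALSE)

  window <- 15:25
  cys <- window[res[window] == "C"]
  if (length(cys) == 0L) {
    stop("no Cys in positions 15-25: signal peptide end not found", call. = FALSE)
  }
  signal_end <- cys[1L]

  # last K-R dipeptide after the signal leaving >= 15 mature residues
  ks <- which(res == "K")
  ks <- ks[ks > signal_end & ks + 1L <= n & res[pmin(ks + 1L, n)] == "R"]
  ks <- ks[n - (ks + 1L) >= 15L]
  if (length(ks) == 0L) {
    stop("no eligible K-R processing site found", call. = FALSE)
  }
  kr_site <- max(ks)

  acidic_len <- kr_site + 1L - signal_end
  if (acidic_len < 15L || acidic_len > 30L) {
    stop("acidic propiece length ", acidic_len,
         " outside plausible range [15, 30]", call. = FALSE)
  }

  signal <- paste(res[1:signal_end], collapse = "")
  acidic <- paste(res[(signal_end + 1L):(kr_site + 1L)], collapse = "")
  mature_raw <- paste(res[(kr_site + 2L):n], collapse = "")
  amidated <- endsWith(mature_raw, "G")
  mature <- if (amidated) substr(mature_raw, 1L, nchar(mature_raw) - 1L)
            else mature_raw

  structure(list(protein = protein, signal = signal, acidic = acidic,
                 mature_raw = mature_raw, mature = mature,
                 amidated = amidated, signal_end = signal_end,
                 kr_site = kr_site),
            class = "precursor_structure")
}

#' @export
print.precursor_structure <- function(x, ...) {
  cat("Prepro-peptide parse (", nchar(x$protein), " aa)\n", sep = "")
  cat("  signal  [1-", x$signal_end, "]: ", x$signal, "\n", sep = "")
  cat("  acidic  [", x$signal_end + 1L, "-", x$kr_site + 1L, "]: ",
      x$acidic, "\n", sep = "")
  cat("  mature: ", x$mature,
      if (x$amidated) "-NH2 (Gly-directed amidation)" else " (free acid)",
      "\n", sep = "")
  invisible(x)
}

#' Parse a FASTA file of cDNA precursors
#'
#' Convenience wrapper: translates each cDNA record and parses the resulting
#' prepro-peptide.
#'
#' @param fasta Path to a cDNA FASTA file.
#' @param frame Passed to [translate_cds()].
#' @return data.frame with one row per record: `name`, `signal`, `acidic`,
#'   `mature`, `amidated`.
#' @export
parse_precursor_fasta <- function(fasta, frame = "auto") {
  set <- Biostrings::readDNAStringSet(fasta)
  rows <- lapply(seq_along(set), function(i) {
    p <- parse_precursor(translate_cds(as.character(set[[i]]), frame = frame))
    data.frame(name = names(set)[i], signal = p$signal, acidic = p$acidic,
               mature = p$mature, amidated = p$amidated,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
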