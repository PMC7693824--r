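## Pairwise identity/similarity against the family, positional conservation,
## motif scanning, and fragment classification.

blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      env$m <- env$BLOSUM62
    }
    env$m
  }
})

#' Global pairwise alignment with identity and similarity percentages
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, gap
#' extension 0.5, terminal gaps penalized like any other). Identity counts
#' identical columns over the TOTAL alignment length (gap columns in the
#' denominator); similarity additionally counts substitution columns with a
#' strictly positive BLOSUM62 score (conservative substitutions such as
#' I/L or K/Q).
#'
#' @param a,b Residue strings.
#' @return List of class `alignment_result`: `aligned_a`, `aligned_b`,
#'   `length`, `n_identical`, `n_similar`, `identity_pct`, `similarity_pct`
#'   (percents rounded to one decimal).
#' @examples
#' al <- global_align("GVLDIFKDAAKQILAHAAEKI", "GVLDIFKDAAKQILAHAAEQI")
#' c(al$identity_pct, al$similarity_pct)  # 95.2 100.0
#' @export
global_align <- function(a, b) {
  check_residues(a, "a"); check_residues(b, "b")
  mat <- blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
    type = "global")
  al_a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  al_b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  len <- length(al_a)
  no_gap <- al_a != "-" & al_b != "-"
  identical_col <- no_gap & al_a == al_b
  pos_score <- logical(len)
  pos_score[no_gap] <- mat[cbind(al_a[no_gap], al_b[no_gap])] > 0
  similar_col <- identical_col | pos_score
  structure(list(
    aligned_a = paste(al_a, collapse = ""),
    aligned_b = paste(al_b, collapse = ""),
    length = len,
    n_identical = sum(identical_col),
    n_similar = sum(similar_col),
    identity_pct = round(100 * sum(identical_col) / len, 1),
    similarity_pct = round(100 * sum(similar_col) / len, 1)
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat("identity ", x$identity_pct, "% (", x$n_identical, "/", x$length,
      "), similarity ", x$similarity_pct, "%\n", sep = "")
  invisible(x)
}

#' Pairwise identity/similarity table
#'
#' Aligns every query against every reference and tabulates the percentages.
#'
#' @param queries,references Catalogue-style data.frames (`name`,
#'   `sequence`).
#' @return data.frame with one row per (query, reference) pair.
#' @export
compare_peptides <- function(queries, references) {
  rows <- list()
  for (i in seq_len(nrow(queries))) {
    for (j in seq_len(nrow(references))) {
      al <- global_align(queries$sequence[i], references$sequence[j])
      rows[[length(rows) + 1L]] <- data.frame(
        query = queries$name[i], reference = references$name[j],
        identity_pct = al$identity_pct, similarity_pct = al$similarity_pct,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Positional conservation profile
#'
#' Per-column residue frequencies over a set of sequences. In `left_flush`
#' mode (the family's gap-free printed layout) columns run 1 to the shortest
#' sequence length; in `msa` mode sequences must be equal length and `-`
#' gap characters are ignored in the frequencies.
#'
#' @param sequences Character vector (>= 2 sequences).
#' @param mode `"left_flush"` or `"msa"`.
#' @return List of class `conservation_profile`: `n_sequences`, `columns`
#'   (list of named frequency vectors), `invariant_positions` (columns with
#'   one residue at frequency 1), `consensus` (most frequent residue per
#'   column, ties to the alphabetically first).
#' @export
conservation_profile <- function(sequences, mode = c("left_flush", "msa")) {
  mode <- match.arg(mode)
  if (length(sequences) < 2L) stop("need at least 2 sequences", call. = FALSE)
  split_seqs <- strsplit(sequences, "")
  if (mode == "left_flush") {
    width <- min(lengths(split_seqs))
  } else {
    lens <- unique(lengths(split_seqs))
    if (length(lens) != 1L) stop("msa mode requires equal-length sequences",
                                 call. = FALSE)
    width <- lens
  }
  columns <- vector("list", width)
  for (p in seq_len(width)) {
    col <- vapply(split_seqs, `[[`, character(1L), p)
    col <- col[col != "-"]
    tab <- table(col)
    columns[[p]] <- stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  }
  invariant <- which(vapply(columns, function(f)
    length(f) == 1L && abs(f[[1L]] - 1) < .Machine$double.eps^0.5, logical(1L)))
  consensus <- paste(vapply(columns, function(f)
    names(f)[order(-f, names(f))][1L], character(1L)), collapse = "")
  structure(list(n_sequences = length(sequences), columns = columns,
                 invariant_positions = invariant, consensus = consensus),
            class = "conservation_profile")
}

#' Frequency matrix of a conservation profile
#'
#' Residues-by-positions matrix of observed frequencies, ready for logo
#' plotting or TSV export.
#'
#' @param profile A [conservation_profile()] result.
#' @return Numeric matrix (20 residues x positions).
#' @export
conservation_matrix <- function(profile) {
  m <- matrix(0, nrow = length(VALID_RESIDUES),
              ncol = length(profile$columns),
              dimnames = list(VALID_RESIDUES, seq_along(profile$columns)))
  for (p in seq_along(profile$columns)) {
    f <- profile$columns[[p]]
    m[names(f), p] <- f
  }
  m
}

#' Scan for the family's N-terminal motif
#'
#' The short ocellatins open with the motif G-X-X-D-X-X-K where X is a
#' hydrophobic residue (Val, Leu, Ile, Phe, plus Ala/Met). The relaxed
#' variant admits the observed Ala1 and Thr7 alternatives:
#' `[GA]-X-X-D-X-X-[KT]`.
#'
#' @param sequence Residue string, length >= 7.
#' @param strict Require the literal `G...K` anchors?
#' @return List: `match` (logical), `span` (`c(1, 7)` when matched, else
#'   `NULL`).
#' @export
motif_scan <- function(sequence, strict = TRUE) {
  res <- check_residues(sequence)
  if (length(res) < 7L) stop("sequence must have length >= 7", call. = FALSE)
  phi <- c("V", "L", "I", "F", "A", "M")
  first_ok <- if (strict) res[1L] == "G" else res[1L] %in% c("G", "A")
  last_ok <- if (strict) res[7L] == "K" else res[7L] %in% c("K", "T")
  hit <- first_ok && last_ok && res[4L] == "D" &&
    all(res[c(2L, 3L, 5L, 6L)] %in% phi)
  list(match = hit, span = if (hit) c(1L, 7L) else NULL)
}

#' Classify a peptide as a fragment of a catalogue member
#'
#' Returns the first catalogue peptide containing the query as a contiguous
#' substring, with the 1-based inclusive span; full-length matches report
#' `(1, n)`. `NULL` when no parent exists.
#'
#' @param query Residue string.
#' @param catalogue Catalogue data.frame (`name`, `sequence`).
#' @return List (`parent`, `start`, `end`) or `NULL`.
#' @export
fragment_classify <- function(query, catalogue) {
  check_residues(query, "query")
  if (nrow(catalogue) == 0L) stop("catalogue is empty", call. = FALSE)
  for (i in seq_len(nrow(catalogue))) {
    at <- regexpr(query, catalogue$sequence[i], fixed = TRUE)
    if (at > 0L) {
      return(list(parent = catalogue$name[i], start = as.integer(at),
                  end = as.integer(at) + nchar(query) - 1L))
    }
  }
  NULL
}
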