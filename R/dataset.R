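## Packaged catalogue of the ocellatin family, the fragment records derived
## from it, and the transcribed MIC activity table.

#' Path to a packaged data file
#'
#' @param file File name under `extdata`.
#' @return Absolute path to the installed file.
#' @export
ocellatin_file <- function(file) {
  path <- system.file("extdata", file, package = "ocellatinr")
  if (identical(path, "")) stop("packaged file not found: ", file, call. = FALSE)
  path
}

# Normalize unicode en-dash / minus sign sneaking in from transcription.
normalize_ascii <- function(x) {
  x <- gsub("–", "-", x)
  gsub("−", "-", x)
}

#' Load the ocellatin peptide catalogue
#'
#' Reads the packaged family catalogue (28 family members plus the synthetic
#' hybrid analog P3-Lla-2085) or a user file in the same TSV layout. Every
#' sequence is validated against the 20 standard residues; names must be
#' unique. All family members are C-terminally amidated except the three
#' 32-residue peptides ocellatin-PT6/-PT7/-PT8, which carry a free acidic
#' C-terminus.
#'
#' @param path TSV file with header columns `name`, `species`, `sequence`,
#'   `amidated`, `group`, `printed_mw`, `printed_charge`, `source`. Defaults
#'   to the packaged catalogue.
#' @return A data.frame of peptide records, one row per peptide, with
#'   `amidated` logical and `printed_mw` / `printed_charge` numeric (NA when
#'   the source prints none).
#' @examples
#' cat <- load_catalogue()
#' sum(cat$group == "family_member")  # 28
#' @export
load_catalogue <- function(path = ocellatin_file("ocellatins.tsv")) {
  if (!file.exists(path)) stop("catalogue file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                          fill = TRUE, colClasses = "character")
  needed <- c("name", "species", "sequence", "amidated", "group")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("catalogue is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(data.frame(name = character(), species = character(),
                      sequence = character(), amidated = logical(),
                      group = character(), printed_mw = numeric(),
                      printed_charge = numeric(), source = character(),
                      stringsAsFactors = FALSE))
  }
  df$sequence <- toupper(normalize_ascii(df$sequence))
  for (i in seq_len(nrow(df))) {
    res <- tryCatch(check_residues(df$sequence[i], what = df$name[i]),
                    error = function(e) stop("row ", i, " (", df$name[i], "): ",
                                             conditionMessage(e), call. = FALSE))
    invisible(res)
  }
  if (anyDuplicated(df$name)) {
    stop("duplicate peptide names in catalogue: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
         call. = FALSE)
  }
  df$amidated <- as.logical(df$amidated)
  df$printed_mw <- if ("printed_mw" %in% names(df))
    as.numeric(normalize_ascii(df$printed_mw)) else NA_real_
  df$printed_charge <- if ("printed_charge" %in% names(df))
    as.numeric(normalize_ascii(df$printed_charge)) else NA_real_
  if (!"source" %in% names(df)) df$source <- NA_character_
  rownames(df) <- NULL
  df[, c("name", "species", "sequence", "amidated", "group",
         "printed_mw", "printed_charge", "source")]
}

#' Names of the five novel ocellatins
#'
#' The five 21-residue peptides newly deduced from cloned cDNA precursors of
#' *Leptodactylus latrans*.
#' @return Character vector of catalogue names.
#' @export
novel_peptides <- function() {
  c("ocellatin-7", "ocellatin-8", "ocellatin-9", "ocellatin-10", "ocellatin-11")
}

#' Load fragment records
#'
#' Fragment peptides reported by de novo sequencing are stored as
#' `(parent, start, end)` spans; their sequences are derived from the
#' catalogue at load time so that the fragment letters can never drift from
#' the parent transcription.
#'
#' @param path Fragment TSV (`name`, `parent`, `start`, `end`, `species`,
#'   `note`); defaults to the packaged file.
#' @param catalogue Catalogue data.frame providing the parent sequences.
#' @return data.frame with derived `sequence` and `group = "fragment"`.
#' @export
load_fragments <- function(path = ocellatin_file("fragments.tsv"),
                           catalogue = load_catalogue()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                          fill = TRUE)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  idx <- match(df$parent, catalogue$name)
  if (anyNA(idx)) {
    stop("fragment parent(s) not in catalogue: ",
         paste(unique(df$parent[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  parent_seq <- catalogue$sequence[idx]
  if (any(df$end > nchar(parent_seq))) {
    stop("fragment span exceeds parent length", call. = FALSE)
  }
  df$sequence <- substr(parent_seq, df$start, df$end)
  df$group <- "fragment"
  df$amidated <- FALSE
  df
}

parse_mic_token <- function(token) {
  token <- normalize_ascii(trimws(token))
  if (is.na(token) || token == "") {
    return(list(value = NA_real_, qualifier = "not_tested"))
  }
  if (token == "*")  return(list(value = NA_real_, qualifier = "not_informed"))
  if (token == "NT") return(list(value = NA_real_, qualifier = "not_tested"))
  if (token == "NI") return(list(value = NA_real_, qualifier = "not_informed"))
  if (token == "I")  return(list(value = NA_real_, qualifier = "inactive"))
  if (grepl("^>", token)) {
    v <- suppressWarnings(as.numeric(sub("^>", "", token)))
    if (is.na(v)) stop("unknown MIC qualifier token: ", token, call. = FALSE)
    return(list(value = v, qualifier = "greater_than"))
  }
  v <- suppressWarnings(as.numeric(token))
  if (is.na(v)) stop("unknown MIC qualifier token: ", token, call. = FALSE)
  list(value = v, qualifier = "exact")
}

#' Load the MIC activity table
#'
#' Parses the transcribed MIC (minimal inhibitory concentration) table into
#' one record per peptide and organism. Cell tokens follow the printed
#' legend: a bare number is an exact MIC, `>x` a lower bound, `I` inactive,
#' `NT` not tested, `NI` not informed, and `*` a zone-inhibition assay with
#' no numeric MIC (treated as not informed). When the paired unit cells carry
#' different qualifiers (e.g. an exact microgram value but a `>` micromolar
#' value) the record takes the weaker, `greater_than`, qualifier.
#'
#' @param path Activity TSV; defaults to the packaged transcription.
#' @return data.frame with columns `peptide_name`, `organism` (`E_coli` or
#'   `S_aureus`), `mic_ug_ml`, `mic_um`, `qualifier`.
#' @examples
#' act <- load_activity()
#' subset(act, peptide_name == "ocellatin-5" & organism == "E_coli")
#' @export
load_activity <- function(path = ocellatin_file("activity_mic.tsv")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                          fill = TRUE, colClasses = "character")
  needed <- c("name", "ecoli_ug_ml", "ecoli_um", "saureus_ug_ml", "saureus_um")
  if (!all(needed %in% names(df))) {
    stop("activity table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  one <- function(name, ug, um, organism) {
    a <- parse_mic_token(ug)
    b <- parse_mic_token(um)
    qual <- if (a$qualifier == "greater_than" || b$qualifier == "greater_than") {
      "greater_than"
    } else if (a$qualifier == "exact" || b$qualifier == "exact") {
      "exact"
    } else if (a$qualifier == b$qualifier) a$qualifier else a$qualifier
    data.frame(peptide_name = name, organism = organism,
               mic_ug_ml = a$value, mic_um = b$value, qualifier = qual,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(
    lapply(seq_len(nrow(df)), function(i)
      one(df$name[i], df$ecoli_ug_ml[i], df$ecoli_um[i], "E_coli")),
    lapply(seq_len(nrow(df)), function(i)
      one(df$name[i], df$saureus_ug_ml[i], df$saureus_um[i], "S_aureus"))
  ))
  usable <- out$qualifier %in% c("exact", "greater_than")
  if (any(usable & is.na(out$mic_ug_ml) & is.na(out$mic_um))) {
    stop("record with exact/greater_than qualifier but no value", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Export peptide records as FASTA
#'
#' @param records Catalogue-style data.frame (`name`, `sequence`).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_peptides_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(stats::setNames(records$sequence, records$name))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
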