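## End-to-end report: one row per peptide combining the physicochemical
## panel with the nearest family neighbour and the activity projection.

fmt_num <- function(x, digits) formatC(x, format = "f", digits = digits)

#' Combined per-peptide report
#'
#' Runs the whole characterization for a set of mature peptides: the
#' physicochemical panel, the nearest family neighbour by similarity, and
#' the nearest-measured-neighbour activity projection. This is the single
#' entry point wiring the pipeline stages; the numbered scripts under
#' `analysis/` are thin drivers over it and the stage functions.
#'
#' @param peptides Catalogue-style data.frame (`name`, `sequence`,
#'   `amidated`); defaults to the packaged catalogue's family members.
#' @param catalogue Reference catalogue for comparison/projection.
#' @param activity Activity table for projection.
#' @param out_tsv,out_json Optional output paths; written when non-NULL
#'   (masses to 2 decimals, percents to 1, GRAVY and moment to 3).
#' @return data.frame, one row per peptide.
#' @export
run_report <- function(peptides = NULL, catalogue = load_catalogue(),
                       activity = load_activity(),
                       out_tsv = NULL, out_json = NULL) {
  if (is.null(peptides)) {
    peptides <- catalogue[catalogue$group == "family_member", ]
  }
  if (nrow(peptides) == 0L) {
    warning("empty peptide set: empty report")
    out <- data.frame()
  } else {
    rows <- lapply(seq_len(nrow(peptides)), function(i) {
      seqc <- peptides$sequence[i]
      ami <- isTRUE(peptides$amidated[i])
      prof <- physchem_profile(seqc, ami)
      others <- catalogue[catalogue$sequence != seqc, , drop = FALSE]
      cmp <- compare_peptides(peptides[i, , drop = FALSE], others)
      cmp <- cmp[order(-cmp$similarity_pct, -cmp$identity_pct, cmp$reference), ]
      pr <- project_activity(seqc, catalogue, activity,
                             query_name = peptides$name[i])
      cbind(data.frame(name = peptides$name[i], sequence = seqc,
                       amidated = ami, stringsAsFactors = FALSE),
            prof,
            data.frame(nearest_family = cmp$reference[1L],
                       nearest_similarity_pct = cmp$similarity_pct[1L],
                       projection_neighbor = pr$neighbor,
                       projected_mic_um = projected_ecoli_um(pr),
                       stringsAsFactors = FALSE))
    })
    out <- do.call(rbind, rows)
  }
  if (!is.null(out_tsv)) {
    disp <- out
    if (nrow(disp) > 0L) {
      disp$mw <- fmt_num(disp$mw, 2)
      disp$pI <- fmt_num(disp$pI, 2)
      disp$net_charge_continuous <- fmt_num(disp$net_charge_continuous, 2)
      disp$gravy <- fmt_num(disp$gravy, 3)
      disp$mu_h <- fmt_num(disp$mu_h, 3)
      disp$nearest_similarity_pct <- fmt_num(disp$nearest_similarity_pct, 1)
    }
    utils::write.table(disp, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(out_json)) {
    jsonlite::write_json(out, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  out
}
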