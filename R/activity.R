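## Nearest measured neighbour transfer of antimicrobial activity: a novel
## peptide inherits the MIC of the most similar catalogue peptide that has an
## exact measured MIC, and novel peptides are ranked by the projected E. coli
## MIC.

measured_names <- function(activity) {
  unique(activity$peptide_name[activity$qualifier == "exact"])
}

#' Project antimicrobial activity from the nearest measured neighbour
#'
#' The neighbour is the catalogue peptide with the highest global-alignment
#' similarity to the query among peptides with at least one exact MIC
#' (`greater_than` and `inactive` records are not usable anchors). Ties are
#' broken by higher identity, then lexicographic name. The neighbour's MIC
#' records are carried over verbatim with their qualifiers.
#'
#' @param query_sequence Residue string of the query peptide.
#' @param catalogue Catalogue data.frame (`name`, `sequence`).
#' @param activity Activity table from [load_activity()].
#' @param query_name Optional label for the output.
#' @return List of class `activity_projection`: `query`, `neighbor`,
#'   `similarity_pct`, `identity_pct`, and `projected` (data.frame of the
#'   neighbour's MIC records).
#' @examples
#' cat <- load_catalogue(); act <- load_activity()
#' oc10 <- cat$sequence[cat$name == "ocellatin-10"]
#' project_activity(oc10, cat, act, query_name = "ocellatin-10")
#' @export
project_activity <- function(query_sequence, catalogue = load_catalogue(),
                             activity = load_activity(), query_name = NULL) {
  anchors <- catalogue[catalogue$name %in% measured_names(activity), ]
  if (nrow(anchors) == 0L) {
    stop("no catalogue peptide with an exact measured MIC", call. = FALSE)
  }
  sim <- numeric(nrow(anchors)); idn <- numeric(nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    al <- global_align(query_sequence, anchors$sequence[i])
    sim[i] <- al$similarity_pct
    idn[i] <- al$identity_pct
  }
  ord <- order(-sim, -idn, anchors$name)
  best <- ord[1L]
  projected <- activity[activity$peptide_name == anchors$name[best], ,
                        drop = FALSE]
  rownames(projected) <- NULL
  structure(list(query = if (is.null(query_name)) query_sequence else query_name,
                 neighbor = anchors$name[best],
                 similarity_pct = sim[best], identity_pct = idn[best],
                 projected = projected),
            class = "activity_projection")
}

#' @export
print.activity_projection <- function(x, ...) {
  cat(x$query, "-> nearest measured neighbour", x$neighbor,
      sprintf("(similarity %.1f%%, identity %.1f%%)\n",
              x$similarity_pct, x$identity_pct))
  print(x$projected)
  invisible(x)
}

projected_ecoli_um <- function(projection) {
  rec <- projection$projected
  rec <- rec[rec$organism == "E_coli" & rec$qualifier == "exact", , drop = FALSE]
  if (nrow(rec) == 0L) return(NA_real_)
  rec$mic_um[1L]
}

#' Rank novel peptides by projected activity
#'
#' Orders queries by ascending projected E. coli MIC (uM); ties are broken
#' by higher formal net charge, then higher hydrophobic moment, then name.
#'
#' @param queries Catalogue-style data.frame (`name`, `sequence`,
#'   `amidated`).
#' @param catalogue,activity Passed to [project_activity()].
#' @return data.frame ordered by rank: `name`, `neighbor`, `similarity_pct`,
#'   `projected_mic_um`, `net_charge`, `mu_h`, `rank`.
#' @export
rank_novel <- function(queries, catalogue = load_catalogue(),
                       activity = load_activity()) {
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    pr <- project_activity(queries$sequence[i], catalogue, activity,
                           query_name = queries$name[i])
    data.frame(name = queries$name[i], neighbor = pr$neighbor,
               similarity_pct = pr$similarity_pct,
               projected_mic_um = projected_ecoli_um(pr),
               net_charge = net_charge_formal(queries$sequence[i],
                                              isTRUE(queries$amidated[i])),
               mu_h = hydrophobic_moment(queries$sequence[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$projected_mic_um, -out$net_charge, -out$mu_h, out$name)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
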