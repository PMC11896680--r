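# Plain-text summary report: minimum data set, intraoperative findings with
# English glosses, the canonical classification string, the AJCC category
# table (primary disease only) and the ATA risk-of-recurrence tier.
# ASCII-only so the block can be pasted into an electronic health record.

gloss_involvement <- function(inv) {
  vapply(seq_len(nrow(inv)), function(i) {
    cat <- inv$category[i]
    sub <- inv$subsite[i]
    deg <- inv$degree[i]
    label <- SUBSITE_TABLE$label[SUBSITE_TABLE$key == paste(cat, sub,
                                                            sep = "-")]
    rings <- inv$rings[i]
    ring_txt <- if (!is.na(rings)) {
      sprintf(" (%d tracheal ring%s)", rings, if (rings > 1) "s" else "")
    } else ""
    switch(cat,
      M = paste0("resection of the ", label),
      N = if (deg == 1L) paste0("sacrifice of the ", label)
          else paste0("epineural dissection of the ", label,
                      " (nerve preserved)"),
      PE = if (deg == 1L) paste0("full-thickness resection of the ", label)
           else paste0("resection of the ", label, " muscularis",
                       " (lumen intact)"),
      LT = if (deg == 1L) paste0("full-thickness resection of the ", label,
                                 ring_txt)
           else paste0("subperichondrial dissection of the ", label,
                       ring_txt),
      B = if (deg == 1L) paste0("resection of the ", label)
          else paste0("subperiosteal dissection of the ", label),
      Vas = if (deg == 1L) paste0("resection/encasement of the ", label)
            else paste0("subadventitial dissection of the ", label)
    )
  }, character(1))
}

#' Render a synoptic text report
#'
#' Produces the deterministic plain-text summary that accompanies the final
#' pathology report: the minimum data set, the intraoperative findings with
#' their English glosses, the canonical anatomic classification string, and
#' (for primary disease) the AJCC category table plus the ATA
#' risk-of-recurrence tier. The classification string in the report
#' re-parses to the record's involvement set.
#'
#' @param record A [checklist_record()].
#' @param staged The matching staged result; derived from `record` when
#'   omitted.
#' @return Character vector of report lines (class `thyro_report`; `print`
#'   cats them).
#' @examples
#' rec <- checklist_record(case_id = "25", surgeon = "B",
#'   involvements = rbind(involvement("N", "RLN", degree = 1),
#'                        involvement("M", "SCM")),
#'   pathology_t = "T2", pathology_n = "N1b")
#' render_report(rec)
#' @export
render_report <- function(record, staged = derive_stage(record)) {
  stopifnot(inherits(record, "checklist_record"),
            inherits(staged, "staged_result"))
  mds <- record$mds
  inv <- staged$involvements
  lines <- c(
    "=== Intraoperative gross invasion report ===",
    sprintf("Case: %s    Surgeon: %s", record$case_id, record$surgeon),
    sprintf("Histology: %s", record$histology),
    "",
    "-- Minimum data set --",
    sprintf("Disease status:        %s", mds$disease_status),
    sprintf("Molecular testing:     %s", mds$molecular_testing),
    sprintf("Vocal cord function:   left %s / right %s",
            mds$vocal_cord_function$left, mds$vocal_cord_function$right),
    sprintf("Distant metastases:    %s", mds$distant_mets),
    sprintf("Residual disease:      %s", mds$residual),
    "",
    "-- Intraoperative findings --"
  )
  if (nrow(inv)) {
    tok <- involvement_token(inv)
    lines <- c(lines, sprintf("  %-12s %s", tok, gloss_involvement(inv)))
  } else {
    lines <- c(lines, "  No gross invasion of surrounding structures recorded.")
  }
  lines <- c(lines, "",
             "-- Anatomic classification --",
             paste0("  ", format_classification(staged)))
  if (!is.null(staged$tnm)) {
    floor_note <- if (nrow(staged$rule_trace)) {
      fired <- staged$rule_trace[!is.na(staged$rule_trace$floor), ,
                                 drop = FALSE]
      if (nrow(fired)) {
        sprintf("  (floor %s from %s)",
                t_max(fired$floor),
                paste(unique(fired$involvement), collapse = ", "))
      } else ""
    } else ""
    lines <- c(lines, "",
               "-- AJCC (8th edition) categories --",
               paste0("  T: ", disp_t(staged$tnm$t), floor_note),
               paste0("  N: ", disp_n(staged$tnm$n)),
               paste0("  M: ", disp_m(staged$tnm$m)))
  } else {
    lines <- c(lines, "",
               "  AJCC staging is not applicable to recurrent/persistent disease.")
  }
  lines <- c(lines, "",
             "-- ATA risk of recurrence --",
             paste0("  ", staged$ror,
                    if (length(staged$ror_rules)) {
                      paste0(" (", paste(staged$ror_rules, collapse = ", "),
                             ")")
                    } else ""))
  if (length(staged$warnings)) {
    lines <- c(lines, "", "-- Warnings --",
               paste0("  ", staged$warnings))
  }
  structure(lines, class = "thyro_report")
}

#' @export
print.thyro_report <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}
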