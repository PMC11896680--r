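# Packaged study cohort: 35 consecutive surgical cases of grossly invasive
# thyroid cancer (29 primary resections requiring AJCC staging, 6 recurrent)
# operated by two surgeons, with and without a transmitted anatomic
# checklist. Shipped as a plain CSV under extdata.

#' Load the packaged 35-case study cohort
#'
#' Returns the published audit cohort: 29 primary and 6 recurrent
#' consecutive cases of grossly invasive thyroid cancer from two surgeons.
#' For each case the fixture carries the final pathology report's stage
#' (`reported_tnm`, verbatim), the recommended stage and anatomic
#' classification, the checklist-submission flag, the surgeon label, and
#' one accuracy override (case 5, whose operative report stated the RLN
#' resection in so many words, so its final report counts as accurate).
#'
#' The audit-facing reported content is derived as follows: checklist
#' cases' final reports carried the checklist's full classification
#' (their items-not-reported annotation is empty), so `reported` equals the
#' recommended classification; no-checklist primary cases report only the
#' verbatim pathology T/N/M; the recurrent cases' reports conveyed nothing
#' anatomic.
#'
#' @return List of 35 [cohort_case()] objects.
#' @examples
#' cohort <- invasion_cohort()
#' length(cohort)
#' @export
invasion_cohort <- function() {
  path <- system.file("extdata", "invasion_cohort.csv",
                      package = "thyrostage", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  cases <- lapply(seq_len(nrow(df)), function(i) {
    rec_cls <- parse_classification(df$recommended[i])
    status <- df$disease_status[i]
    checklist <- df$checklist_submitted[i] == "TRUE"
    record <- checklist_record(
      case_id = df$case_id[i],
      surgeon = df$surgeon[i],
      histology = df$diagnosis[i],
      disease_status = status,
      involvements = rec_cls$involvements,
      residual = rec_cls$residual,
      distant_mets = df$distant_mets[i],
      pathology_t = if (nzchar(df$size_t[i])) df$size_t[i]
                    else NA_character_,
      pathology_n = if (!is.null(rec_cls$tnm)) rec_cls$tnm$n
                    else NA_character_,
      pathology_m = if (!is.null(rec_cls$tnm)) rec_cls$tnm$m
                    else NA_character_,
      checklist_submitted = checklist
    )
    reported <- if (checklist) {
      df$recommended[i]
    } else if (nzchar(df$reported_tnm[i])) {
      df$reported_tnm[i]
    } else {
      NA
    }
    cohort_case(record, reported = reported,
                checklist_submitted = checklist,
                accuracy_override = df$accuracy_override[i] == "TRUE",
                surgeon = df$surgeon[i],
                annotations = df$items_not_reported[i])
  })
  check_cohort_fixture(cases)
  cases
}

# integrity check: the fixture must hold exactly the published cohort shape
check_cohort_fixture <- function(cases) {
  status <- vapply(cases, function(cs) cs$record$mds$disease_status, "")
  checklist <- vapply(cases, function(cs) cs$checklist_submitted, TRUE)
  ok <- length(cases) == 35L &&
    sum(status == "primary") == 29L &&
    sum(status != "primary") == 6L &&
    sum(checklist) == 15L &&
    sum(vapply(cases, function(cs) cs$accuracy_override, TRUE)) == 1L
  if (!ok) stop("packaged cohort fixture is corrupted", call. = FALSE)
  invisible(cases)
}
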