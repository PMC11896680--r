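# Cohort audit: per-case accuracy verdicts, structure-omission tallies, and
# a two-tailed Fisher exact test implemented from first principles.

#' Construct a cohort case
#'
#' Pairs a surgical [checklist_record()] (the inputs from which the
#' recommended stage is derived) with the classification content of the
#' final pathology report, for auditing.
#'
#' @param record A [checklist_record()].
#' @param reported Reported classification: string, [classification()]
#'   object, or `NA` when the report conveyed nothing anatomic.
#' @param checklist_submitted Whether the surgeon transmitted the checklist.
#' @param accuracy_override Set `TRUE` when a correctly worded operative
#'   report conveyed the finding even though the classification string does
#'   not (the audit then counts the case as accurate).
#' @param surgeon Surgeon label; defaults to the record's.
#' @param annotations Free-text annotation (e.g. the items-not-reported
#'   gloss); carried along, never parsed.
#' @return An object of class `cohort_case`.
#' @export
cohort_case <- function(record, reported = NA,
                        checklist_submitted = record$checklist_submitted,
                        accuracy_override = FALSE,
                        surgeon = record$surgeon,
                        annotations = NA_character_) {
  stopifnot(inherits(record, "checklist_record"))
  structure(
    list(record = record,
         reported = as_classification(reported),
         checklist_submitted = isTRUE(checklist_submitted),
         accuracy_override = isTRUE(accuracy_override),
         surgeon = as.character(surgeon),
         annotations = as.character(annotations)),
    class = "cohort_case"
  )
}

#' Audit a cohort for understaging
#'
#' Derives the recommended stage for every case, compares it with the
#' reported classification ([compare_stages()]) and classifies each primary
#' case as accurate or discrepant; a case with `accuracy_override` counts
#' as accurate regardless. Recurrent/persistent cases carry no AJCC
#' accuracy verdict and are summarized separately by their missing anatomic
#' items. The summary stratifies primary verdicts by checklist submission
#' and surgeon and attaches the checklist-by-accuracy 2x2 table with its
#' two-tailed Fisher exact p-value.
#'
#' @param cases List of [cohort_case()] objects.
#' @param rules T-floor rule table for [derive_stage()].
#' @return An object of class `cohort_audit`: list with `per_case` (data
#'   frame of verdicts and discrepancy codes), `primary` (counts
#'   `by_checklist` and `by_surgeon`, the `contingency` matrix with rows
#'   checklist yes/no and columns accurate/discrepant, and `fisher_p`) and
#'   `recurrent` (missing-item report per case).
#' @examples
#' audit <- audit_cohort(invasion_cohort())
#' audit$primary$by_checklist
#' audit$primary$fisher_p
#' @export
audit_cohort <- function(cases, rules = default_t_floor_rules()) {
  stopifnot(length(cases) > 0L)
  rows <- lapply(cases, function(cs) {
    stopifnot(inherits(cs, "cohort_case"))
    staged <- derive_stage(cs$record, rules)
    status <- cs$record$mds$disease_status
    if (status == "primary") {
      cmp <- compare_stages(cs$reported, staged)
      verdict <- if (cs$accuracy_override) "accurate" else cmp$verdict
      codes <- cmp$codes
    } else {
      verdict <- NA_character_
      # recurrent: only missing-item reporting
      rec_tok <- involvement_token(staged$involvements)
      rep_key <- involvement_key(cs$reported$involvements)
      codes <- paste0("missing_involvement:",
                      rec_tok[!involvement_key(staged$involvements) %in%
                                rep_key],
                      recycle0 = TRUE)
    }
    data.frame(case_id = cs$record$case_id, surgeon = cs$surgeon,
               status = status, checklist = cs$checklist_submitted,
               override = cs$accuracy_override, verdict = verdict,
               recommended = format_classification(staged),
               codes = paste(codes, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  per_case <- do.call(rbind, rows)

  prim <- per_case[per_case$status == "primary", , drop = FALSE]
  by_checklist <- do.call(rbind, lapply(c(TRUE, FALSE), function(ck) {
    sub <- prim[prim$checklist == ck, , drop = FALSE]
    data.frame(checklist = ck, n = nrow(sub),
               accurate = sum(sub$verdict == "accurate"),
               discrepant = sum(sub$verdict == "discrepant"))
  }))
  surgeons <- sort(unique(prim$surgeon))
  by_surgeon <- do.call(rbind, lapply(surgeons, function(sg) {
    do.call(rbind, lapply(c(TRUE, FALSE), function(ck) {
      sub <- prim[prim$surgeon == sg & prim$checklist == ck, , drop = FALSE]
      data.frame(surgeon = sg, checklist = ck, n = nrow(sub),
                 accurate = sum(sub$verdict == "accurate"),
                 discrepant = sum(sub$verdict == "discrepant"))
    }))
  }))
  contingency <- matrix(
    c(by_checklist$accurate[by_checklist$checklist],
      by_checklist$discrepant[by_checklist$checklist],
      by_checklist$accurate[!by_checklist$checklist],
      by_checklist$discrepant[!by_checklist$checklist]),
    nrow = 2, byrow = TRUE,
    dimnames = list(checklist = c("yes", "no"),
                    verdict = c("accurate", "discrepant")))
  fisher_p <- if (sum(contingency) > 0) {
    fisher_exact_two_tailed(contingency)
  } else NA_real_

  recur <- per_case[per_case$status != "primary", , drop = FALSE]
  structure(
    list(per_case = per_case,
         primary = list(n = nrow(prim), by_checklist = by_checklist,
                        by_surgeon = by_surgeon, contingency = contingency,
                        fisher_p = fisher_p),
         recurrent = list(n = nrow(recur),
                          missing = recur[, c("case_id", "surgeon",
                                              "recommended", "codes")])),
    class = "cohort_audit"
  )
}

#' @export
print.cohort_audit <- function(x, ...) {
  cat("<cohort_audit>", x$primary$n, "primary,", x$recurrent$n,
      "recurrent cases\n")
  print(x$primary$by_checklist, row.names = FALSE)
  cat("Fisher exact (two-tailed) p =", format(x$primary$fisher_p), "\n")
  invisible(x)
}

# structure classes for omission tallies
STRUCTURE_CLASSES <- c("SM", "SCM", "CT", "RLN_sacrifice", "RLN_epineurium",
                       "SLN_Vag", "PE", "LT", "B", "Vas", "nerve_sacrifice")

structure_class <- function(inv) {
  ifelse(inv$category == "M", inv$subsite,
  ifelse(inv$category == "N" & inv$subsite == "RLN",
         ifelse(!is.na(inv$degree) & inv$degree == 1L,
                "RLN_sacrifice", "RLN_epineurium"),
  ifelse(inv$category == "N", "SLN_Vag", inv$category)))
}

#' Tally anatomic structures omitted from final reports
#'
#' For each structure class, counts the cases whose recommended
#' classification contains the structure but whose reported classification
#' does not, plus the corresponding token-level count (a case can omit
#' both `PE-E` and `PE-Ph`; case-level and token-level conventions then
#' differ). The aggregate class `nerve_sacrifice` counts cases omitting any
#' nerve resection at degree 1 (RLN, SLN or vagus).
#'
#' @param cases List of [cohort_case()] objects.
#' @param scope `"discrepant_no_checklist"` (default) restricts the tally
#'   to no-checklist cases with a missing item or a discrepant primary
#'   verdict — the understaged-report population; `"all"` tallies every
#'   supplied case.
#' @param rules T-floor rule table.
#' @return Data frame with columns `class`, `cases`, `tokens`.
#' @examples
#' cohort <- invasion_cohort()
#' primary <- Filter(function(cs)
#'   cs$record$mds$disease_status == "primary", cohort)
#' tally_missing_structures(primary)
#' @export
tally_missing_structures <- function(cases,
                                     scope = c("discrepant_no_checklist",
                                               "all"),
                                     rules = default_t_floor_rules()) {
  scope <- match.arg(scope)
  case_n <- stats::setNames(integer(length(STRUCTURE_CLASSES)),
                            STRUCTURE_CLASSES)
  tok_n <- case_n
  for (cs in cases) {
    staged <- derive_stage(cs$record, rules)
    rec_inv <- staged$involvements
    rep_key <- involvement_key(cs$reported$involvements)
    omitted <- rec_inv[!involvement_key(rec_inv) %in% rep_key, ,
                       drop = FALSE]
    if (scope == "discrepant_no_checklist") {
      if (cs$checklist_submitted) next
      if (cs$record$mds$disease_status == "primary") {
        verdict <- if (cs$accuracy_override) "accurate" else {
          compare_stages(cs$reported, staged)$verdict
        }
        if (verdict != "discrepant") next
      } else if (nrow(omitted) == 0L) next
    }
    if (nrow(omitted) == 0L) next
    cls <- structure_class(omitted)
    for (cl in unique(cls)) case_n[[cl]] <- case_n[[cl]] + 1L
    for (cl in cls) tok_n[[cl]] <- tok_n[[cl]] + 1L
    sac <- omitted$category == "N" & !is.na(omitted$degree) &
      omitted$degree == 1L
    if (any(sac)) {
      case_n[["nerve_sacrifice"]] <- case_n[["nerve_sacrifice"]] + 1L
      tok_n[["nerve_sacrifice"]] <- tok_n[["nerve_sacrifice"]] + sum(sac)
    }
  }
  data.frame(class = STRUCTURE_CLASSES, cases = as.integer(case_n),
             tokens = as.integer(tok_n), stringsAsFactors = FALSE)
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Exact conditional test with fixed margins, implemented by enumeration:
#' with the margins of the observed table held fixed, the p-value is the
#' sum of hypergeometric probabilities of all tables whose probability does
#' not exceed that of the observed table (with a relative tolerance of
#' 1e-7 for ties). Probabilities are computed via log-binomial
#' coefficients for overflow safety. A degenerate margin (an all-zero row
#' or column) returns p = 1 by convention.
#'
#' @param a Either a 2x2 matrix of non-negative counts, or the count in
#'   cell (1,1) with `b`, `c`, `d` supplying the remaining cells in
#'   row-major order.
#' @param b,c,d Remaining cell counts when `a` is scalar.
#' @return The two-tailed p-value in `[0, 1]`.
#' @examples
#' fisher_exact_two_tailed(matrix(c(15, 0, 1, 13), 2, byrow = TRUE))
#' @export
fisher_exact_two_tailed <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (n == 0) stop("empty table", call. = FALSE)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  x <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  log_obs <- logp[x == a]
  p <- sum(exp(logp[logp <= log_obs + log1p(1e-7)]))
  min(p, 1)
}

# cohort CSV dialect ----------------------------------------------------------

#' Read or write a cohort CSV
#'
#' The interchange dialect has one row per case: `case_id`, `surgeon`,
#' `checklist_submitted`, `reported_classification` (empty when nothing
#' anatomic was reported), `recommended_inputs` (the full checklist record
#' as a JSON blob, see [record_to_json()]), `accuracy_override` and
#' `annotations`. The synthetic generator writes the same dialect the
#' audit reads.
#'
#' @param path File path (or connection for `write_cohort_csv`).
#' @param cases List of [cohort_case()] objects.
#' @return `read_cohort_csv()` returns a list of `cohort_case` objects;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  lapply(seq_len(nrow(df)), function(i) {
    record <- record_from_json(df$recommended_inputs[i])
    reported <- df$reported_classification[i]
    cohort_case(
      record = record,
      reported = if (is.na(reported) || !nzchar(reported)) NA else reported,
      checklist_submitted = tolower(df$checklist_submitted[i]) %in%
        c("true", "yes", "1"),
      accuracy_override = tolower(df$accuracy_override[i]) %in%
        c("true", "yes", "1"),
      surgeon = df$surgeon[i],
      annotations = if ("annotations" %in% names(df)) df$annotations[i]
                    else NA_character_
    )
  })
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cases, path) {
  df <- do.call(rbind, lapply(cases, function(cs) {
    rep_str <- if (nrow(cs$reported$involvements) == 0L &&
                   is.null(cs$reported$tnm) && !cs$reported$rec &&
                   cs$reported$residual == "R0") {
      ""
    } else {
      format_classification(cs$reported)
    }
    data.frame(case_id = cs$record$case_id, surgeon = cs$surgeon,
               checklist_submitted = cs$checklist_submitted,
               reported_classification = rep_str,
               recommended_inputs = record_to_json(cs$record),
               accuracy_override = cs$accuracy_override,
               annotations = ifelse(is.na(cs$annotations), "",
                                    cs$annotations),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
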