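# Staging rule engine: per-structure AJCC T-category floors, reconciliation
# with the size/extent pathology T, recurrent-disease handling, and the ATA
# risk-of-recurrence tier.

#' Default T-floor rule table
#'
#' Each rule matches involvements by category, optionally subsite and
#' degree (`NA` = any), and contributes an AJCC T-category floor and/or a
#' coded warning:
#'
#' * gross invasion of any muscle subsite (strap, sternocleidomastoid,
#'   cricothyroid) floors the stage at T3b;
#' * any laryngotracheal, pharyngoesophageal or bone subsite, and the
#'   recurrent laryngeal nerve at either degree (epineural dissection or
#'   sacrifice), floors at T4a;
#' * carotid or innominate artery involvement at degree 1 (transection or
#'   encasement) floors at T4b, while degree 0 (subadventitial dissection)
#'   carries no automatic floor but warns `arterial_involvement_review`;
#' * venous involvement never modifies T;
#' * superior laryngeal and vagus nerve involvement carries no floor and
#'   warns `nerve_outside_rule_table` (human review).
#'
#' @return A data frame with columns `id`, `category`, `subsite`, `degree`,
#'   `floor`, `warning`; `NA` in `subsite`/`degree` is a wildcard.
#' @seealso [t_floor()], [read_rule_table()] for institution-specific
#'   overrides.
#' @export
default_t_floor_rules <- function() {
  data.frame(
    id       = c("R1", "R2a", "R2b", "R2c", "R2d",
                 "R3a", "R3b", "R4a", "R4b", "R5a", "R5b", "R6a", "R6b"),
    category = c("M", "LT", "PE", "N", "B",
                 "Vas", "Vas", "Vas", "Vas", "Vas", "Vas", "N", "N"),
    subsite  = c(NA, NA, NA, "RLN", NA,
                 "A_CC", "A_INN", "A_CC", "A_INN", "V_IJ", "V_INN",
                 "SLN", "Vag"),
    degree   = c(NA, NA, NA, NA, NA, 1L, 1L, 0L, 0L, NA, NA, NA, NA),
    floor    = c("T3b", "T4a", "T4a", "T4a", "T4a",
                 "T4b", "T4b", NA, NA, NA, NA, NA, NA),
    warning  = c(NA, NA, NA, NA, NA, NA, NA,
                 "arterial_involvement_review", "arterial_involvement_review",
                 NA, NA, "nerve_outside_rule_table",
                 "nerve_outside_rule_table"),
    stringsAsFactors = FALSE
  )
}

validate_rule_table <- function(rules) {
  need <- c("id", "category", "subsite", "degree", "floor", "warning")
  if (!is.data.frame(rules) || !all(need %in% names(rules))) {
    stop("rule table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rules$id)) stop("duplicate rule ids", call. = FALSE)
  bad <- !is.na(rules$floor) & !rules$floor %in% T_ORDERED
  if (any(bad)) stop("invalid floor: ", rules$floor[bad][1], call. = FALSE)
  invisible(rules)
}

#' Read or write a T-floor rule table
#'
#' Rule tables are plain tab-separated files so institutions can adjust the
#' floors (e.g. treat subadventitial arterial dissection as T4b) without
#' touching code. `write_rule_table(default_t_floor_rules(), path)` exports
#' the default table bit-exactly.
#'
#' @param path File path.
#' @param rules A rule table as returned by [default_t_floor_rules()].
#' @return `read_rule_table()` returns the rule table data frame;
#'   `write_rule_table()` returns `path` invisibly.
#' @export
read_rule_table <- function(path) {
  rules <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  rules$degree <- as.integer(rules$degree)
  validate_rule_table(rules)
  rules
}

#' @rdname read_rule_table
#' @export
write_rule_table <- function(rules, path) {
  validate_rule_table(rules)
  utils::write.table(rules, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Derive the AJCC T-category floor implied by an involvement set
#'
#' Applies the rule table to every involvement and returns the maximum
#' floor over fired rules (under the [t_order()] total order), together
#' with the full rule trace and any coded warnings. The result is
#' permutation-invariant in the involvement set and monotone: adding an
#' involvement never lowers the floor.
#'
#' @param involvements Involvement data frame (see [involvement()]).
#' @param rules Rule table; defaults to [default_t_floor_rules()].
#' @return A list with elements `floor` (T category or `NA` when no rule
#'   assigns one), `trace` (data frame of `rule` id and the `involvement`
#'   token that fired it) and `warnings` (character).
#' @examples
#' t_floor(involvement("M", "SM"))$floor           # "T3b"
#' t_floor(involvement("N", "RLN", degree = 0))$floor  # "T4a"
#' t_floor(involvement("Vas", "A_CC", degree = 1))$floor  # "T4b"
#' @export
t_floor <- function(involvements, rules = default_t_floor_rules()) {
  rule_v <- character(); tok_v <- character(); floor_v <- character()
  warnings <- character()
  if (nrow(involvements)) {
    inv <- sort_involvements(involvements)
    tok <- involvement_token(inv)
    inv_cat <- inv$category; inv_sub <- inv$subsite; inv_deg <- inv$degree
    r_cat <- rules$category; r_sub <- rules$subsite; r_deg <- rules$degree
    r_id <- rules$id; r_floor <- rules$floor; r_warn <- rules$warning
    for (r in seq_along(r_id)) {
      hit <- inv_cat == r_cat[r] &
        (is.na(r_sub[r]) | inv_sub == r_sub[r]) &
        (is.na(r_deg[r]) | (!is.na(inv_deg) & inv_deg == r_deg[r]))
      if (any(hit)) {
        k <- sum(hit)
        rule_v <- c(rule_v, rep.int(r_id[r], k))
        tok_v <- c(tok_v, tok[hit])
        floor_v <- c(floor_v, rep.int(r_floor[r], k))
        if (!is.na(r_warn[r])) warnings <- c(warnings, r_warn[r])
      }
    }
  }
  list(floor = t_max(floor_v),
       trace = data.frame(rule = rule_v, involvement = tok_v,
                          floor = floor_v, stringsAsFactors = FALSE),
       warnings = unique(warnings))
}

#' Derive the recommended stage for a checklist record
#'
#' For primary disease the recommended T category is the maximum (under
#' [t_order()]) of the size/extent pathology T and the anatomic T-floor
#' from [t_floor()]; with neither available the T is `TX` with a warning.
#' N passes through from the record; M is forced to `M1` when the minimum
#' data set reports distant metastases, otherwise passes through. The
#' residual code is carried, the involvement set is ordered canonically,
#' and the ATA risk-of-recurrence tier is attached ([classify_ror()]).
#'
#' Recurrent or persistent disease takes no AJCC T/N/M: the result renders
#' as `Rec` plus the anatomic suffix, the risk tier is `not_applicable`,
#' and a supplied pathology T draws a warning.
#'
#' @param record A [checklist_record()].
#' @param rules T-floor rule table, defaulting to
#'   [default_t_floor_rules()].
#' @return An object of class `staged_result`: list with `tnm` (list or
#'   `NULL`), `residual`, `involvements`, `ror`, `warnings`, `rule_trace`
#'   and `disease_status`. `format()` renders the canonical classification
#'   string.
#' @examples
#' rec <- checklist_record(involvements = involvement("M", "SM"),
#'                         pathology_t = "T2", pathology_n = "N1a")
#' format(derive_stage(rec))  # "pT3b N1a Mx M-SM"
#' @export
derive_stage <- function(record, rules = default_t_floor_rules()) {
  stopifnot(inherits(record, "checklist_record"))
  viol <- validate_record(record)
  if (length(viol)) {
    stop("invalid record: ", paste(viol, collapse = ", "), call. = FALSE)
  }
  status <- record$mds$disease_status
  inv <- sort_involvements(record$involvements)
  fl <- t_floor(inv, rules)
  warnings <- fl$warnings

  if (status != "primary") {
    if (!is.na(record$pathology_t)) {
      warnings <- c(warnings, "tnm_not_applicable_recurrent")
    }
    ror <- list(tier = "not_applicable", rules = character(),
                warnings = character())
    tnm <- NULL
  } else {
    path_t <- record$pathology_t
    if (!is.na(path_t) && path_t == "TX") path_t <- NA_character_
    t_rec <- t_max(c(path_t, fl$floor))
    if (is.na(t_rec)) {
      t_rec <- "TX"
      warnings <- c(warnings, "t_unresolved")
    }
    n_rec <- if (is.na(record$pathology_n)) "NX" else record$pathology_n
    m_rec <- if (identical(record$mds$distant_mets, "present")) {
      "M1"
    } else if (is.na(record$pathology_m)) "MX" else record$pathology_m
    tnm <- list(t = t_rec, n = n_rec, m = m_rec)
    ror <- classify_ror(record)
    warnings <- c(warnings, ror$warnings)
  }

  structure(
    list(tnm = tnm, residual = record$mds$residual, involvements = inv,
         ror = ror$tier, ror_rules = ror$rules,
         warnings = unique(warnings), rule_trace = fl$trace,
         disease_status = status),
    class = "staged_result"
  )
}

#' @export
format.staged_result <- function(x, ...) format_classification(x)

#' @export
print.staged_result <- function(x, ...) {
  cat("<staged_result>", format_classification(x), "\n")
  cat("  ATA risk of recurrence:", x$ror, "\n")
  if (length(x$warnings)) {
    cat("  warnings:", paste(x$warnings, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ATA risk-of-recurrence tier from checklist data
#'
#' The checklist feeds the high-risk rules directly: gross
#' extrathyroidal/extranodal invasion (any involvement), incomplete
#' resection (R1/R2) or distant metastases each classify the case as high
#' risk of recurrence. When no high-risk rule fires, the finer
#' low/intermediate distinction needs inputs the checklist does not carry
#' (histologic vascular invasion, nodal burden, mutation interpretation),
#' so the tier is reported as `low` with warning `ror_incomplete_inputs`.
#' Recurrent disease is `not_applicable`.
#'
#' @param record A [checklist_record()].
#' @return List with `tier` (`"low"`, `"high"` or `"not_applicable"`),
#'   `rules` (fired rule ids) and `warnings`.
#' @export
classify_ror <- function(record) {
  stopifnot(inherits(record, "checklist_record"))
  if (record$mds$disease_status != "primary") {
    return(list(tier = "not_applicable", rules = character(),
                warnings = character()))
  }
  fired <- character()
  if (nrow(record$involvements) > 0L) fired <- c(fired, "ror_high_gross_invasion")
  if (record$mds$residual %in% c("R1", "R2")) {
    fired <- c(fired, "ror_high_incomplete_resection")
  }
  if (identical(record$mds$distant_mets, "present")) {
    fired <- c(fired, "ror_high_distant_mets")
  }
  if (length(fired)) {
    list(tier = "high", rules = fired, warnings = character())
  } else {
    list(tier = "low", rules = character(),
         warnings = "ror_incomplete_inputs")
  }
}

#' Compare a reported stage against the recommended stage
#'
#' A final pathology report is discrepant when it understages the T
#' category (reported T strictly below recommended T under [t_order()]),
#' omits a recommended R1/R2 residual-disease code, or lacks any
#' recommended anatomic involvement (subsite-level match; a degree mismatch
#' on a matched subsite is also discrepant).
#'
#' @param reported The reported classification: a string, a
#'   [classification()] object, or `NA` when nothing anatomic was reported.
#' @param recommended The recommended stage: a `staged_result` from
#'   [derive_stage()] or a classification.
#' @return List with `verdict` (`"accurate"` or `"discrepant"`) and
#'   `codes`, a character vector enumerating each miss
#'   (`"t_understaged"`, `"residual_omitted"`,
#'   `"missing_involvement:<token>"`, `"degree_mismatch:<token>"`,
#'   `"tnm_missing"`).
#' @examples
#' compare_stages("pT1b N1a Mx", "pT4a N1a Mx N-RLN^1")
#' @export
compare_stages <- function(reported, recommended) {
  rp <- as_classification(reported)
  rc <- as_classification(recommended)
  codes <- character()

  if (!is.null(rc$tnm)) {
    if (is.null(rp$tnm)) {
      codes <- c(codes, "tnm_missing")
    } else if (t_order(rp$tnm$t, rc$tnm$t) == "less") {
      codes <- c(codes, "t_understaged")
    }
  }
  if (rc$residual %in% c("R1", "R2") &&
      !identical(rp$residual, rc$residual)) {
    codes <- c(codes, "residual_omitted")
  }
  if (nrow(rc$involvements)) {
    rc_inv <- rc$involvements
    rc_key <- involvement_key(rc_inv)
    rp_key <- involvement_key(rp$involvements)
    tok <- involvement_token(rc_inv)
    hit <- match(rc_key, rp_key)
    miss <- is.na(hit)
    codes <- c(codes, paste0("missing_involvement:", tok[miss],
                             recycle0 = TRUE))
    if (any(!miss)) {
      deg_rep <- rp$involvements$degree[hit[!miss]]
      deg_rec <- rc_inv$degree[!miss]
      bad <- !((is.na(deg_rep) & is.na(deg_rec)) |
                 (!is.na(deg_rep) & !is.na(deg_rec) & deg_rep == deg_rec))
      codes <- c(codes, paste0("degree_mismatch:", tok[!miss][bad],
                               recycle0 = TRUE))
    }
  }
  list(verdict = if (length(codes)) "discrepant" else "accurate",
       codes = codes)
}
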