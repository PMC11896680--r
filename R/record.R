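# Checklist records: one surgical case as the surgeon documents it
# intraoperatively, plus the pathology T/N/M determined from size/extent.

MDS_STATES <- list(
  vocal_cord = c("mobile", "paretic", "paralyzed", "unknown"),
  distant_mets = c("present", "absent", "unknown"),
  disease_status = c("primary", "recurrent", "persistent")
)

#' Construct a surgical checklist record
#'
#' A checklist record captures what the surgeon saw and did: the minimum
#' data set (molecular testing, vocal cord function, distant metastasis,
#' residual disease, disease status), the set of anatomic involvements, and
#' the pathology T/N/M categories determined from tumor size/extent alone
#' (all optional; the staging engine reconciles them with the anatomic
#' T-category floors).
#'
#' @param case_id Opaque case identifier (no patient identifiers).
#' @param surgeon Opaque surgeon label.
#' @param histology Free-text histologic diagnosis.
#' @param disease_status `"primary"`, `"recurrent"` or `"persistent"`.
#'   Recurrent and persistent disease suppress AJCC staging.
#' @param involvements Involvement data frame (see [involvement()]).
#' @param residual Residual-disease code `"R0"`, `"R1"` or `"R2"`
#'   (default `"R0"` when unstated).
#' @param molecular_testing Free text or `"unknown"`.
#' @param vocal_cord_left,vocal_cord_right Per-side vocal cord function:
#'   `"mobile"`, `"paretic"`, `"paralyzed"` or `"unknown"`.
#' @param distant_mets `"present"`, `"absent"` or `"unknown"`.
#' @param pathology_t,pathology_n,pathology_m Pathology T/N/M category
#'   codes, or `NA` if not (yet) determined.
#' @param checklist_submitted Whether the surgeon transmitted the checklist
#'   to the pathologist.
#' @return An object of class `checklist_record`.
#' @examples
#' rec <- checklist_record(
#'   case_id = "25", surgeon = "B",
#'   involvements = rbind(involvement("N", "RLN", degree = 1),
#'                        involvement("M", "SCM")),
#'   pathology_t = "T2", pathology_n = "N1b"
#' )
#' validate_record(rec)
#' @export
checklist_record <- function(case_id = "", surgeon = NA_character_,
                             histology = NA_character_,
                             disease_status = "primary",
                             involvements = empty_involvements(),
                             residual = "R0",
                             molecular_testing = "unknown",
                             vocal_cord_left = "unknown",
                             vocal_cord_right = "unknown",
                             distant_mets = "unknown",
                             pathology_t = NA_character_,
                             pathology_n = NA_character_,
                             pathology_m = NA_character_,
                             checklist_submitted = FALSE) {
  structure(
    list(
      case_id = as.character(case_id),
      surgeon = as.character(surgeon),
      histology = as.character(histology),
      mds = list(
        molecular_testing = as.character(molecular_testing),
        vocal_cord_function = list(left = as.character(vocal_cord_left),
                                   right = as.character(vocal_cord_right)),
        distant_mets = as.character(distant_mets),
        residual = as.character(residual),
        disease_status = as.character(disease_status)
      ),
      involvements = sort_involvements(involvements),
      pathology_t = if (is.na(pathology_t)) NA_character_ else norm_t(pathology_t),
      pathology_n = if (is.na(pathology_n)) NA_character_ else norm_n(pathology_n),
      pathology_m = if (is.na(pathology_m)) NA_character_ else norm_m(pathology_m),
      checklist_submitted = isTRUE(checklist_submitted)
    ),
    class = "checklist_record"
  )
}

#' Validate a checklist record
#'
#' Checks every structural invariant of the record and returns the
#' violations as data rather than raising conditions: unknown or duplicate
#' subsites, a degree superscript on a muscle subsite (muscle involvement is
#' binary), a missing degree on a degree-taking subsite, a ring count on
#' anything but the trachea, out-of-vocabulary minimum-data-set states and
#' T/N/M codes.
#'
#' @param record A [checklist_record()].
#' @return Character vector of violation codes; empty when the record is
#'   well formed. Codes carry the offending field after a colon, e.g.
#'   `"muscle_degree_forbidden:M-SM"`.
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "checklist_record"))
  out <- involvement_violations(record$involvements)
  mds <- record$mds
  if (!mds$disease_status %in% MDS_STATES$disease_status) {
    out <- c(out, "invalid_disease_status")
  }
  if (!mds$distant_mets %in% MDS_STATES$distant_mets) {
    out <- c(out, "invalid_distant_mets")
  }
  if (!mds$residual %in% RESIDUAL_CODES) out <- c(out, "invalid_residual")
  for (side in c("left", "right")) {
    if (!mds$vocal_cord_function[[side]] %in% MDS_STATES$vocal_cord) {
      out <- c(out, paste0("invalid_vocal_cord_", side))
    }
  }
  if (!is.na(mds$molecular_testing) && !nzchar(mds$molecular_testing)) {
    out <- c(out, "invalid_molecular_testing")
  }
  if (!is.na(record$pathology_t) && !record$pathology_t %in% T_CODES) {
    out <- c(out, "invalid_pathology_t")
  }
  if (!is.na(record$pathology_n) && !record$pathology_n %in% N_CODES) {
    out <- c(out, "invalid_pathology_n")
  }
  if (!is.na(record$pathology_m) && !record$pathology_m %in% M_CODES) {
    out <- c(out, "invalid_pathology_m")
  }
  out
}

#' @export
print.checklist_record <- function(x, ...) {
  cat("<checklist_record>", x$case_id,
      paste0("(", x$mds$disease_status, ")"), "\n")
  cat("  surgeon:", x$surgeon, " histology:", x$histology, "\n")
  cat("  T/N/M (pathology):",
      paste(x$pathology_t, x$pathology_n, x$pathology_m), "\n")
  cat("  residual:", x$mds$residual,
      " distant mets:", x$mds$distant_mets, "\n")
  if (nrow(x$involvements)) {
    cat("  involvements:",
        paste(involvement_token(x$involvements), collapse = " "), "\n")
  } else {
    cat("  involvements: none\n")
  }
  invisible(x)
}

# JSON (de)serialization -----------------------------------------------------

record_to_list <- function(record) {
  inv <- record$involvements
  list(
    case_id = record$case_id,
    surgeon = record$surgeon,
    histology = record$histology,
    mds = record$mds,
    involvements = lapply(seq_len(nrow(inv)), function(i) {
      list(category = inv$category[i], subsite = inv$subsite[i],
           degree = if (is.na(inv$degree[i])) NULL else inv$degree[i],
           rings = if (is.na(inv$rings[i])) NULL else inv$rings[i])
    }),
    pathology_t = record$pathology_t,
    pathology_n = record$pathology_n,
    pathology_m = record$pathology_m,
    checklist_submitted = record$checklist_submitted
  )
}

#' Serialize a checklist record to JSON
#'
#' @param record A [checklist_record()].
#' @param pretty Pretty-print the JSON.
#' @return A JSON string conforming to [record_schema()].
#' @export
record_to_json <- function(record, pretty = FALSE) {
  as.character(jsonlite::toJSON(record_to_list(record), auto_unbox = TRUE,
                                null = "null", na = "null", pretty = pretty))
}

#' Deserialize a checklist record from JSON
#'
#' @param json A JSON string (or path handled by the caller) as produced by
#'   [record_to_json()].
#' @return A [checklist_record()].
#' @export
record_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  inv <- empty_involvements()
  for (it in x$involvements) {
    inv <- rbind(inv, involvement(it$category, it$subsite,
                                  degree = it$degree %||% NA,
                                  rings = it$rings %||% NA))
  }
  vc <- x$mds$vocal_cord_function %||% list()
  checklist_record(
    case_id = x$case_id %||% "",
    surgeon = x$surgeon %||% NA_character_,
    histology = x$histology %||% NA_character_,
    disease_status = x$mds$disease_status %||% "primary",
    involvements = inv,
    residual = x$mds$residual %||% "R0",
    molecular_testing = x$mds$molecular_testing %||% "unknown",
    vocal_cord_left = vc$left %||% "unknown",
    vocal_cord_right = vc$right %||% "unknown",
    distant_mets = x$mds$distant_mets %||% "unknown",
    pathology_t = x$pathology_t %||% NA_character_,
    pathology_n = x$pathology_n %||% NA_character_,
    pathology_m = x$pathology_m %||% NA_character_,
    checklist_submitted = isTRUE(x$checklist_submitted)
  )
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' JSON schema for checklist records
#'
#' @return A nested list describing the record JSON interchange format
#'   (JSON Schema draft-07 dialect); serialize with
#'   `jsonlite::toJSON(record_schema(), auto_unbox = TRUE, pretty = TRUE)`.
#' @export
record_schema <- function() {
  enum_str <- function(values) list(type = "string", enum = values)
  list(
    `$schema` = "http://json-schema.org/draft-07/schema#",
    title = "checklist_record",
    type = "object",
    required = c("case_id", "mds", "involvements", "checklist_submitted"),
    properties = list(
      case_id = list(type = "string"),
      surgeon = list(type = c("string", "null")),
      histology = list(type = c("string", "null")),
      mds = list(
        type = "object",
        required = c("molecular_testing", "vocal_cord_function",
                     "distant_mets", "residual", "disease_status"),
        properties = list(
          molecular_testing = list(type = "string"),
          vocal_cord_function = list(
            type = "object",
            required = c("left", "right"),
            properties = list(left = enum_str(MDS_STATES$vocal_cord),
                              right = enum_str(MDS_STATES$vocal_cord))
          ),
          distant_mets = enum_str(MDS_STATES$distant_mets),
          residual = enum_str(RESIDUAL_CODES),
          disease_status = enum_str(MDS_STATES$disease_status)
        )
      ),
      involvements = list(
        type = "array",
        items = list(
          type = "object",
          required = c("category", "subsite"),
          properties = list(
            category = enum_str(CATEGORY_ORDER),
            subsite = enum_str(unique(SUBSITE_TABLE$code)),
            degree = list(type = c("integer", "null"), enum = c(0L, 1L)),
            rings = list(type = c("integer", "null"), minimum = 1L)
          )
        )
      ),
      pathology_t = list(type = c("string", "null"), enum = T_CODES),
      pathology_n = list(type = c("string", "null"), enum = N_CODES),
      pathology_m = list(type = c("string", "null"), enum = M_CODES),
      checklist_submitted = list(type = "boolean")
    )
  )
}
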