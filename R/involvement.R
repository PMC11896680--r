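# Involvement sets: one row per anatomic structure involved by tumor.
# Degree is the extent-of-surgery superscript (0 = dissected in a preserving
# plane / muscularis only, 1 = resected / transmural); it is absent exactly
# for muscle subsites. rings is the tracheal ring count (LT-T only).

empty_involvements <- function() {
  data.frame(category = character(), subsite = character(),
             degree = integer(), rings = integer(),
             stringsAsFactors = FALSE)
}

#' Construct an involvement set
#'
#' @param category Site category code (`"LT"`, `"B"`, `"N"`, `"PE"`,
#'   `"Vas"`, `"M"`); matched case-insensitively.
#' @param subsite Subsite code within the category (e.g. `"RLN"`,
#'   `"A_CC"`); matched case-insensitively.
#' @param degree Degree-of-invasion superscript, 0 or 1. Must be `NA` for
#'   muscle subsites (muscle involvement is binary) and present for all
#'   others.
#' @param rings Number of tracheal rings involved; only meaningful for the
#'   trachea (`LT-T`), `NA` otherwise.
#' @return A one-row involvement data frame with columns `category`,
#'   `subsite`, `degree`, `rings`. Combine involvements with [rbind()].
#' @examples
#' rbind(involvement("N", "RLN", degree = 1),
#'       involvement("M", "SCM"))
#' @export
involvement <- function(category, subsite, degree = NA, rings = NA) {
  cat <- canonical_category(category)
  if (is.na(cat)) stop("unknown site category: ", category, call. = FALSE)
  sub <- canonical_subsite(cat, subsite)
  if (is.na(sub)) {
    stop("unknown subsite for category ", cat, ": ", subsite, call. = FALSE)
  }
  data.frame(category = cat, subsite = sub,
             degree = as.integer(degree), rings = as.integer(rings),
             stringsAsFactors = FALSE)
}

involvement_key <- function(inv) paste(inv$category, inv$subsite, sep = "-")

sort_involvements <- function(inv) {
  if (nrow(inv) == 0L) return(inv)
  idx <- match(involvement_key(inv), SUBSITE_TABLE$key)
  ord <- order(match(inv$category, CATEGORY_ORDER), SUBSITE_TABLE$sub_order[idx])
  out <- inv[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# canonical shorthand token for one involvement row, e.g. "LT-T_2^0"
involvement_token <- function(inv) {
  if (nrow(inv) == 0L) return(character())
  sub <- inv$subsite
  sub <- ifelse(inv$category == "LT" & sub == "T" & !is.na(inv$rings),
                paste0("T_", inv$rings), sub)
  deg <- ifelse(is.na(inv$degree), "", paste0("^", inv$degree))
  paste0(inv$category, "-", sub, deg)
}

# violation codes for an involvement data frame (shared by validate_record
# and the notation parser's post-checks)
involvement_violations <- function(inv) {
  out <- character()
  if (nrow(inv) == 0L) return(out)
  key <- involvement_key(inv)
  idx <- match(key, SUBSITE_TABLE$key)
  if (anyNA(idx)) {
    out <- c(out, paste0("unknown_subsite:", key[is.na(idx)]))
    inv <- inv[!is.na(idx), , drop = FALSE]
    key <- key[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  if (anyDuplicated(key)) {
    out <- c(out, paste0("duplicate_subsite:", unique(key[duplicated(key)])))
  }
  takes_deg <- SUBSITE_TABLE$takes_degree[idx]
  bad_muscle <- !takes_deg & !is.na(inv$degree)
  if (any(bad_muscle)) {
    out <- c(out, paste0("muscle_degree_forbidden:", key[bad_muscle]))
  }
  missing_deg <- takes_deg & is.na(inv$degree)
  if (any(missing_deg)) {
    out <- c(out, paste0("degree_missing:", key[missing_deg]))
  }
  bad_deg <- !is.na(inv$degree) & !inv$degree %in% c(0L, 1L)
  if (any(bad_deg)) out <- c(out, paste0("bad_degree:", key[bad_deg]))
  ring_ok <- SUBSITE_TABLE$takes_ring_count[idx]
  misplaced <- !is.na(inv$rings) & !ring_ok
  if (any(misplaced)) {
    out <- c(out, paste0("ring_count_misplaced:", key[misplaced]))
  }
  bad_rings <- !is.na(inv$rings) & ring_ok & inv$rings < 1L
  if (any(bad_rings)) out <- c(out, paste0("bad_ring_count:", key[bad_rings]))
  out
}
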