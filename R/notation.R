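# Shorthand classification strings (ASCII dialect): optional "Rec" prefix for
# recurrent/persistent disease, optional residual code R1/R2, optional
# pT/N/M triple, then anatomic involvement tokens such as "LT-T_2^0" or
# "Vas-V_IJ^1". '^' carries the degree superscript, '_' the subscript
# (tracheal ring count, or the vessel name which is part of the subsite).
# Within one category token, subsites may be chained by concatenation
# ("PE-E^0Ph^0") or compressed with '/' ("M-SM/CT", "VAS-V_IJ/INN^1"); '/'
# distributes the category, the vessel-type letter and a shared trailing
# degree over all listed subsites.

stop_parse <- function(code, pos, detail = "") {
  msg <- sprintf("parse error [%s] at character %d%s", code, pos,
                 if (nzchar(detail)) paste0(": ", detail) else "")
  cond <- structure(
    class = c("thyrostage_parse_error", "error", "condition"),
    list(message = msg, call = NULL, code = code, pos = pos)
  )
  stop(cond)
}

#' Construct a parsed classification
#'
#' The structured form of a shorthand classification string: the
#' recurrent-disease prefix, the residual-disease code, the T/N/M triple
#' (absent for recurrent disease) and the involvement set.
#'
#' @param rec Logical; `TRUE` for recurrent/persistent disease. A recurrent
#'   classification never carries a T/N/M triple.
#' @param residual Residual-disease code, default `"R0"` (not emitted).
#' @param tnm `NULL`, or a list/character vector with elements `t`, `n`,
#'   `m`.
#' @param involvements Involvement data frame (see [involvement()]).
#' @return An object of class `thyro_classification`.
#' @examples
#' cls <- classification(tnm = c(t = "T4a", n = "N1b", m = "MX"),
#'                       involvements = involvement("N", "RLN", degree = 1))
#' format(cls)
#' @export
classification <- function(rec = FALSE, residual = "R0", tnm = NULL,
                           involvements = empty_involvements()) {
  if (!is.null(tnm)) {
    tnm <- as.list(tnm)
    tnm <- list(t = norm_t(tnm$t %||% "TX"),
                n = norm_n(tnm$n %||% "NX"),
                m = norm_m(tnm$m %||% "MX"))
    if (anyNA(unlist(tnm))) stop("invalid T/N/M category", call. = FALSE)
    if (isTRUE(rec)) stop("recurrent disease takes no T/N/M", call. = FALSE)
  }
  if (!residual %in% RESIDUAL_CODES) {
    stop("invalid residual code: ", residual, call. = FALSE)
  }
  viol <- involvement_violations(involvements)
  if (length(viol)) {
    stop("invalid involvements: ", paste(viol, collapse = ", "),
         call. = FALSE)
  }
  structure(list(rec = isTRUE(rec), residual = residual, tnm = tnm,
                 involvements = sort_involvements(involvements)),
            class = "thyro_classification")
}

#' Parse a shorthand classification string
#'
#' Accepts the ASCII dialect of the checklist shorthand: `^` for the degree
#' superscript, `_` for subscripts, `/` for subsite compression within a
#' category, whitespace between tokens. Category and subsite codes match
#' case-insensitively (`Vas-`/`VAS-` both occur in practice); `^`/`_`
#' suffixes are accepted in either order; a glued `N0Mx` splits into its N
#' and M categories; a missing M token defaults to `Mx`.
#'
#' @param text A single non-empty classification string, e.g.
#'   `"pT4a N1b Mx PE-E^0 Vas-V_IJ^1 LT-T_2^0 N-RLN^1"`.
#' @return A [classification()] object.
#' @section Errors: Malformed input raises a condition of class
#'   `thyrostage_parse_error` whose `code` field names the defect
#'   (`unknown_subsite`, `muscle_degree_forbidden`, `duplicate_subsite`,
#'   `malformed_tnm`, `rec_with_tnm`, ...) and whose `pos` field gives the
#'   character offset.
#' @examples
#' parse_classification("Rec N-RLN^1 PE-E^1")
#' parse_classification("R2 pT2 N1b Mx VAS-V_IJ/INN^1")
#' @export
parse_classification <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop_parse("empty_input", 1L, "classification string is empty")
  }
  m <- gregexpr("\\S+", text)[[1]]
  toks <- regmatches(text, gregexpr("\\S+", text))[[1]]
  pos <- as.integer(m)
  i <- 1L
  rec <- FALSE
  residual <- "R0"
  tnm <- NULL

  # Rec prefix, possibly glued to the first token with a hyphen ("Rec-LT-...")
  if (grepl("^[Rr][Ee][Cc](-|$)", toks[i])) {
    rec <- TRUE
    rest <- sub("^[Rr][Ee][Cc]-?", "", toks[i])
    if (nzchar(rest)) {
      pos[i] <- pos[i] + (nchar(toks[i]) - nchar(rest))
      toks[i] <- rest
    } else {
      i <- i + 1L
    }
  }

  if (i <= length(toks) && grepl("^[Rr][12]$", toks[i])) {
    residual <- toupper(toks[i])
    i <- i + 1L
  }

  # T/N/M triple, led by the pT token; N is required after pT, M optional
  if (i <= length(toks) && grepl("^[Pp][Tt]", toks[i])) {
    if (rec) {
      stop_parse("rec_with_tnm", pos[i],
                 "AJCC staging is not applicable to recurrent disease")
    }
    tcode <- norm_t(substring(toks[i], 2L))
    if (is.na(tcode)) stop_parse("malformed_tnm", pos[i], toks[i])
    i <- i + 1L
    ncode <- NA_character_
    mcode <- NA_character_
    if (i <= length(toks) && grepl("^[Nn]", toks[i]) &&
        !grepl("-", toks[i], fixed = TRUE)) {
      ntok <- toks[i]
      ncode <- norm_n(ntok)
      if (is.na(ncode) && nchar(ntok) > 2L &&
          grepl("^[Mm][Xx01]$", substring(ntok, nchar(ntok) - 1L))) {
        # glued form like "N0Mx"
        ncode <- norm_n(substr(ntok, 1L, nchar(ntok) - 2L))
        mcode <- norm_m(substring(ntok, nchar(ntok) - 1L))
      }
      if (is.na(ncode)) stop_parse("malformed_tnm", pos[i], ntok)
      i <- i + 1L
    } else {
      stop_parse("malformed_tnm", if (i <= length(pos)) pos[i] else nchar(text),
                 "expected an N category after the pT token")
    }
    if (is.na(mcode) && i <= length(toks) && grepl("^[Mm][Xx01]$", toks[i])) {
      mcode <- norm_m(toks[i])
      i <- i + 1L
    }
    if (is.na(mcode)) mcode <- "MX"
    tnm <- list(t = tcode, n = ncode, m = mcode)
  }

  # involvement tokens; a token without a category prefix continues the
  # previous category ("pT4a N0 Mx B-St^1 Clav^1")
  acc <- list()
  last_cat <- NULL
  cat_re <- "^(LT|PE|VAS|B|N|M)-(.+)$"
  while (i <= length(toks)) {
    tok <- toks[i]
    mm <- regmatches(tok, regexec(cat_re, tok, ignore.case = TRUE))[[1]]
    if (length(mm) == 3L) {
      cat <- canonical_category(mm[2])
      body <- mm[3]
      body_pos <- pos[i] + nchar(mm[2]) + 1L
      last_cat <- cat
    } else if (!is.null(last_cat)) {
      cat <- last_cat
      body <- tok
      body_pos <- pos[i]
    } else {
      stop_parse("unknown_token", pos[i], tok)
    }
    acc[[length(acc) + 1L]] <- parse_group_chain(cat, body, body_pos)
    i <- i + 1L
  }
  inv <- if (length(acc)) {
    data.frame(
      category = unlist(lapply(acc, `[[`, "category")),
      subsite = unlist(lapply(acc, `[[`, "subsite")),
      degree = unlist(lapply(acc, `[[`, "degree")),
      rings = unlist(lapply(acc, `[[`, "rings")),
      stringsAsFactors = FALSE)
  } else {
    empty_involvements()
  }

  key <- involvement_key(inv)
  if (anyDuplicated(key)) {
    stop_parse("duplicate_subsite", nchar(text),
               unique(key[duplicated(key)])[1])
  }
  classification(rec = rec, residual = residual, tnm = tnm,
                 involvements = inv)
}

# parse the body of one category token (after "CAT-"); returns parallel
# vectors of involvement fields
parse_group_chain <- function(cat, body, p0) {
  subs <- character(); degs <- integer(); ring_v <- integer()
  k <- 1L
  n <- nchar(body)
  while (k <= n) {
    chain <- list()
    repeat {
      prev <- if (length(chain)) chain[[length(chain)]]$subsite else NULL
      g <- parse_one_group(cat, body, k, p0, prev = prev)
      chain[[length(chain) + 1L]] <- g
      k <- g$end + 1L
      if (k <= n && substr(body, k, k) == "/") k <- k + 1L else break
    }
    # a shared trailing degree distributes over the '/'-compressed chain
    last_deg <- chain[[length(chain)]]$degree
    for (g in chain) {
      deg <- if (is.na(g$degree)) last_deg else g$degree
      if (cat == "M" && !is.na(deg)) {
        stop_parse("muscle_degree_forbidden", p0 + g$start - 1L,
                   "muscle invasion is binary and takes no superscript")
      }
      if (cat != "M" && is.na(deg)) {
        stop_parse("degree_missing", p0 + g$start - 1L,
                   paste0(cat, "-", g$subsite,
                          " requires a degree superscript"))
      }
      subs <- c(subs, g$subsite)
      degs <- c(degs, deg)
      ring_v <- c(ring_v, g$rings)
    }
  }
  list(category = rep.int(cat, length(subs)), subsite = subs,
       degree = as.integer(degs), rings = as.integer(ring_v))
}

# parse one subsite group starting at position k of body; prev is the
# already-parsed subsite when inside a '/'-chain (lets "V_IJ/INN" inherit
# the vessel-type letter)
parse_one_group <- function(cat, body, k, p0, prev = NULL) {
  str <- substring(body, k)
  err_pos <- p0 + k - 1L
  if (cat == "Vas") {
    mm <- regmatches(str, regexec("^([AVav])_?(CC|INN|IJ)", str,
                                  ignore.case = TRUE))[[1]]
    if (length(mm) == 3L) {
      sub <- paste0(toupper(mm[2]), "_", toupper(mm[3]))
      used <- nchar(mm[1])
    } else if (!is.null(prev)) {
      mm <- regmatches(str, regexec("^(CC|INN|IJ)", str,
                                    ignore.case = TRUE))[[1]]
      if (length(mm) != 2L) stop_parse("unknown_subsite", err_pos, str)
      sub <- paste0(substr(prev, 1L, 1L), "_", toupper(mm[2]))
      used <- nchar(mm[1])
    } else {
      stop_parse("unknown_subsite", err_pos, str)
    }
    sub <- canonical_subsite("Vas", sub)
    if (is.na(sub)) stop_parse("unknown_subsite", err_pos, str)
  } else {
    codes <- subsites_for(cat)$code
    codes <- codes[order(-nchar(codes))]
    sub <- NA_character_
    for (code in codes) {
      if (toupper(substr(str, 1L, nchar(code))) == toupper(code)) {
        sub <- code
        used <- nchar(code)
        break
      }
    }
    if (is.na(sub)) stop_parse("unknown_subsite", err_pos, str)
  }

  degree <- NA_integer_
  rings <- NA_integer_
  j <- used + 1L
  while (j <= nchar(str)) {
    ch <- substr(str, j, j)
    if (ch == "^") {
      if (!is.na(degree)) stop_parse("bad_degree", err_pos + j - 1L, str)
      d <- substr(str, j + 1L, j + 1L)
      if (!d %in% c("0", "1")) {
        stop_parse("bad_degree", err_pos + j - 1L,
                   "degree superscript must be 0 or 1")
      }
      degree <- as.integer(d)
      j <- j + 2L
    } else if (ch == "_") {
      mm <- regmatches(substring(str, j),
                       regexec("^_([0-9]+)", substring(str, j)))[[1]]
      if (length(mm) != 2L) {
        stop_parse("subscript_misplaced", err_pos + j - 1L, str)
      }
      if (!(cat == "LT" && sub == "T")) {
        stop_parse("subscript_misplaced", err_pos + j - 1L,
                   "only the trachea takes a ring-count subscript")
      }
      rings <- as.integer(mm[2])
      if (rings < 1L) stop_parse("bad_ring_count", err_pos + j - 1L, str)
      j <- j + nchar(mm[1])
    } else {
      break
    }
  }
  list(subsite = sub, degree = degree, rings = rings,
       start = k, end = k + j - 2L)
}

#' Format a classification in canonical form
#'
#' Canonical order: `Rec` prefix, residual code (R1/R2 only), the T/N/M
#' triple, then involvement tokens by category (`LT`, `B`, `N`, `PE`,
#' `Vas`, `M`) and fixed subsite order within each category. Every subsite
#' is emitted as its own full token (no `/` compression), subscript before
#' superscript, one space between tokens. `format()` and `as.character()`
#' methods delegate here.
#'
#' @param x A [classification()] object (or staged result; see
#'   [derive_stage()]).
#' @return A single classification string; parsing it back yields an object
#'   equal to `x`.
#' @examples
#' format_classification(parse_classification("M-SM/CT PE-E^0Ph^0"))
#' @export
format_classification <- function(x) {
  if (inherits(x, "staged_result")) x <- as_classification(x)
  stopifnot(inherits(x, "thyro_classification"))
  parts <- character()
  if (x$rec) parts <- "Rec"
  if (x$residual %in% c("R1", "R2")) parts <- c(parts, x$residual)
  if (!is.null(x$tnm)) {
    parts <- c(parts, paste0("p", disp_t(x$tnm$t)), disp_n(x$tnm$n),
               disp_m(x$tnm$m))
  }
  parts <- c(parts, involvement_token(sort_involvements(x$involvements)))
  paste(parts, collapse = " ")
}

#' @export
format.thyro_classification <- function(x, ...) format_classification(x)

#' @export
as.character.thyro_classification <- function(x, ...) format_classification(x)

#' @export
print.thyro_classification <- function(x, ...) {
  cat(format_classification(x), "\n")
  invisible(x)
}

# coerce strings / staged results / classifications to classification;
# NA means "nothing reported" (empty classification)
as_classification <- function(x) {
  if (inherits(x, "thyro_classification")) return(x)
  if (inherits(x, "staged_result")) {
    return(classification(rec = !identical(x$disease_status, "primary"),
                          residual = x$residual, tnm = x$tnm,
                          involvements = x$involvements))
  }
  if (length(x) == 1L && is.na(x)) return(classification())
  if (is.character(x)) return(parse_classification(x))
  stop("cannot interpret as a classification: ", class(x)[1], call. = FALSE)
}
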