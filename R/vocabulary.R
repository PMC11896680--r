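# Controlled vocabulary for the anatomic checklist: six site categories, their
# subsites, and the AJCC 8th edition thyroid T/N/M category codes.

# Category codes in canonical emission order.
CATEGORY_ORDER <- c("LT", "B", "N", "PE", "Vas", "M")

CATEGORY_LABELS <- c(
  LT  = "Laryngotracheal complex",
  B   = "Bone",
  N   = "Nerves",
  PE  = "Pharyngoesophagus",
  Vas = "Arteries and veins",
  M   = "Muscle"
)

# One row per subsite; sub_order gives the canonical emission order within a
# category. Muscle invasion is binary (no degree superscript); only the
# trachea takes a ring-count subscript.
SUBSITE_TABLE <- data.frame(
  category = c("LT", "LT", "LT",
               "B", "B",
               "N", "N", "N",
               "PE", "PE",
               "Vas", "Vas", "Vas", "Vas",
               "M", "M", "M"),
  code = c("Th", "Cr", "T",
           "Clav", "St",
           "RLN", "SLN", "Vag",
           "Ph", "E",
           "A_CC", "A_INN", "V_IJ", "V_INN",
           "SM", "SCM", "CT"),
  label = c("thyroid ala", "cricoid cartilage", "trachea",
            "clavicular head", "sternum",
            "recurrent laryngeal nerve", "superior laryngeal nerve",
            "vagus nerve",
            "pharynx", "esophagus",
            "common carotid artery", "innominate artery",
            "internal jugular vein", "innominate vein",
            "strap muscles", "sternocleidomastoid muscle",
            "cricothyroid muscle"),
  sub_order = c(1L, 2L, 3L,
                1L, 2L,
                1L, 2L, 3L,
                1L, 2L,
                1L, 2L, 3L, 4L,
                1L, 2L, 3L),
  stringsAsFactors = FALSE
)
SUBSITE_TABLE$takes_degree <- SUBSITE_TABLE$category != "M"
SUBSITE_TABLE$takes_ring_count <-
  SUBSITE_TABLE$category == "LT" & SUBSITE_TABLE$code == "T"
SUBSITE_TABLE$key <- paste(SUBSITE_TABLE$category, SUBSITE_TABLE$code,
                           sep = "-")

# Ordered T categories; TX sits outside the order (incomparable).
T_ORDERED <- c("T0", "T1a", "T1b", "T2", "T3a", "T3b", "T4a", "T4b")
T_CODES <- c("TX", T_ORDERED)
N_CODES <- c("NX", "N0", "N0a", "N0b", "N1", "N1a", "N1b")
M_CODES <- c("MX", "M0", "M1")
RESIDUAL_CODES <- c("R0", "R1", "R2")

#' Site categories of the anatomic checklist
#'
#' The checklist groups gross extrathyroidal/extranodal invasion into six
#' anatomic site categories: the laryngotracheal complex (`LT`), bone (`B`),
#' nerves (`N`), the pharyngoesophagus (`PE`), arteries and veins (`Vas`)
#' and muscle (`M`).
#'
#' @return A data frame with columns `code` and `label`, one row per
#'   category, in canonical emission order.
#' @examples
#' site_categories()
#' @export
site_categories <- function() {
  data.frame(code = CATEGORY_ORDER,
             label = unname(CATEGORY_LABELS[CATEGORY_ORDER]),
             stringsAsFactors = FALSE)
}

#' Subsite vocabulary
#'
#' All anatomic subsites recognised by the shorthand notation, with their
#' category, human-readable label, whether they take a degree-of-invasion
#' superscript (all categories except muscle) and whether they take a
#' tracheal ring-count subscript (trachea only).
#'
#' @return A data frame with one row per subsite, columns `category`,
#'   `code`, `label`, `takes_degree`, `takes_ring_count` and the combined
#'   token `key` (e.g. `"N-RLN"`).
#' @examples
#' subsite_vocabulary()
#' @export
subsite_vocabulary <- function() {
  SUBSITE_TABLE[, c("category", "code", "label", "takes_degree",
                    "takes_ring_count", "key")]
}

# internal lookups ----------------------------------------------------------

subsites_for <- function(category) {
  SUBSITE_TABLE[SUBSITE_TABLE$category == category, , drop = FALSE]
}

canonical_category <- function(x) {
  hit <- match(toupper(x), toupper(CATEGORY_ORDER))
  if (is.na(hit)) NA_character_ else CATEGORY_ORDER[hit]
}

canonical_subsite <- function(category, x) {
  subs <- subsites_for(category)
  hit <- match(toupper(x), toupper(subs$code))
  if (is.na(hit)) NA_character_ else subs$code[hit]
}

t_rank <- function(t) match(t, T_ORDERED)

#' Compare two AJCC T categories
#'
#' The eight substantive T categories admit a strict total order
#' `T0 < T1a < T1b < T2 < T3a < T3b < T4a < T4b`, which underlies the
#' definition of understaging. `TX` is incomparable with every category
#' (including itself).
#'
#' @param a,b T category codes (e.g. `"T3b"`).
#' @return One of `"less"`, `"equal"`, `"greater"`, `"incomparable"`.
#' @examples
#' t_order("T1b", "T4a")  # "less": a pT1b report understages pT4a disease
#' t_order("TX", "T2")    # "incomparable"
#' @export
t_order <- function(a, b) {
  a0 <- a; b0 <- b
  a <- norm_t(a); b <- norm_t(b)
  if (is.na(a)) stop("unknown T category: ", a0, call. = FALSE)
  if (is.na(b)) stop("unknown T category: ", b0, call. = FALSE)
  if (a == "TX" || b == "TX") return("incomparable")
  d <- t_rank(a) - t_rank(b)
  if (d < 0) "less" else if (d > 0) "greater" else "equal"
}

# max of T categories under t_order, ignoring NA/TX; NA if none comparable
t_max <- function(ts) {
  ts <- ts[!is.na(ts) & ts %in% T_ORDERED]
  if (length(ts) == 0L) return(NA_character_)
  T_ORDERED[max(t_rank(ts))]
}

norm_t <- function(x) {
  hit <- match(toupper(x), toupper(T_CODES))
  if (is.na(hit)) NA_character_ else T_CODES[hit]
}

norm_n <- function(x) {
  hit <- match(toupper(x), toupper(N_CODES))
  if (is.na(hit)) NA_character_ else N_CODES[hit]
}

norm_m <- function(x) {
  hit <- match(toupper(x), toupper(M_CODES))
  if (is.na(hit)) NA_character_ else M_CODES[hit]
}

# display forms: internal codes are uppercase (MX); reports print Mx/Nx/Tx
disp_t <- function(t) if (identical(t, "TX")) "Tx" else t
disp_n <- function(n) if (identical(n, "NX")) "Nx" else n
disp_m <- function(m) if (identical(m, "MX")) "Mx" else m
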