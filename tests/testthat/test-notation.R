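# Lexer/parser and canonical formatter for the shorthand classification.

expect_parse_error <- function(text, code) {
  err <- tryCatch(parse_classification(text), error = function(e) e)
  expect_s3_class(err, "thyrostage_parse_error")
  expect_identical(err$code, code)
  expect_true(is.numeric(err$pos) && err$pos >= 1)
}

inv_key_set <- function(x) sort(paste(x$involvements$category,
                                      x$involvements$subsite, sep = "-"))

test_that("published classification strings parse to the right structure", {
  # full primary classification with vein, trachea rings and RLN
  p <- parse_classification("pT4a N1b Mx PE-E^0 Vas-V_IJ^1 LT-T_2^0 N-RLN^1")
  expect_identical(p$tnm, list(t = "T4a", n = "N1b", m = "MX"))
  expect_false(p$rec)
  expect_identical(inv_key_set(p), c("LT-T", "N-RLN", "PE-E", "Vas-V_IJ"))
  expect_identical(p$involvements$rings[p$involvements$subsite == "T"], 2L)
  expect_identical(p$involvements$degree[p$involvements$subsite == "V_IJ"], 1L)

  # recurrent disease: Rec prefix, no TNM, binary muscle token
  r <- parse_classification("Rec N-RLN^0 M-SCM")
  expect_true(r$rec)
  expect_null(r$tnm)
  expect_identical(inv_key_set(r), c("M-SCM", "N-RLN"))
  expect_true(is.na(r$involvements$degree[r$involvements$subsite == "SCM"]))

  # residual code + '/'-compressed vessels sharing the trailing degree
  v <- parse_classification("R2 pT2 N1b Mx VAS-V_IJ/INN^1")
  expect_identical(v$residual, "R2")
  expect_identical(v$tnm$t, "T2")
  expect_identical(inv_key_set(v), c("Vas-V_IJ", "Vas-V_INN"))
  expect_identical(v$involvements$degree, c(1L, 1L))

  # chained bare group carries the category forward
  b <- parse_classification("pT4a N0 Mx B-St^1 Clav^1")
  expect_identical(inv_key_set(b), c("B-Clav", "B-St"))
  expect_identical(b$involvements$degree, c(1L, 1L))
})

test_that("dialect quirks are tolerated and normalized", {
  # glued N/M categories and '/'-compressed muscles
  g <- parse_classification("pT4a N0Mx M-SM/CT PE-E^0")
  expect_identical(g$tnm, list(t = "T4a", n = "N0", m = "MX"))
  expect_identical(inv_key_set(g), c("M-CT", "M-SM", "PE-E"))

  # concatenated subsite groups inside one token
  cc <- parse_classification("pT4a N1a M1 N-RLN^1 LT-T_2^0Cr^0 PE-E^0Ph^0")
  expect_identical(inv_key_set(cc),
                   c("LT-Cr", "LT-T", "N-RLN", "PE-E", "PE-Ph"))

  # missing M token defaults to MX; uppercase PT accepted
  expect_identical(parse_classification("pT3b N1a M-SM")$tnm$m, "MX")
  expect_identical(parse_classification("PT3b N1a Mx")$tnm$t, "T3b")

  # hyphenated Rec prefix and superscript-before-subscript ordering
  w <- parse_classification("Rec-LT-T^0_2")
  expect_true(w$rec)
  expect_identical(w$involvements$rings, 2L)
  expect_identical(w$involvements$degree, 0L)

  # vessel subsite without underscore, mixed case category
  a <- parse_classification("Rec N-Vag^1 VAS-Acc^1")
  expect_identical(inv_key_set(a), c("N-Vag", "Vas-A_CC"))
})

test_that("malformed classifications raise coded positional errors", {
  expect_parse_error("M-SM^1", "muscle_degree_forbidden")
  expect_parse_error("pT4a N0 Mx PE-E^0 PE-E^1", "duplicate_subsite")
  expect_parse_error("Rec pT2 N0 Mx", "rec_with_tnm")
  expect_parse_error("LT-Q^0", "unknown_subsite")
  expect_parse_error("PE-E_2^0", "subscript_misplaced")
  expect_parse_error("pT9 N0 Mx", "malformed_tnm")
  expect_parse_error("pT2 N7 Mx", "malformed_tnm")
  expect_parse_error("PE-E", "degree_missing")
  expect_parse_error("PE-E^3", "bad_degree")
  expect_parse_error("", "empty_input")
  expect_parse_error("RLN^1", "unknown_token")
})

test_that("canonical formatting is deterministic and expansion-stable", {
  # already-canonical strings are fixed points
  for (s in c("pT4a N1b Mx N-RLN^1 M-SCM",
              "Rec LT-T_2^0",
              "R1 pT4a N1b Mx LT-T_1^0 N-RLN^1 PE-Ph^0 M-SM",
              "pT2 N0 M0")) {
    expect_identical(format_classification(parse_classification(s)), s)
  }

  # '/'-compression expands to full tokens in canonical category order
  expect_identical(
    format_classification(parse_classification("pT3b N1b Mx M-SM/CT")),
    "pT3b N1b Mx M-SM M-CT")

  # compressed and expanded spellings are the same involvement set
  expect_identical(
    inv_key_set(parse_classification("M-SM/CT")),
    inv_key_set(parse_classification("M-SM M-CT")))
  expect_identical(
    format_classification(parse_classification("pT2 N0 Mx Vas-V_IJ^1 Vas-V_INN^1")),
    format_classification(parse_classification("pT2 N0 Mx VAS-V_IJ/INN^1")))
})

test_that("parse/format round trip holds on random classifications", {
  set.seed(421)
  for (i in 1:500) {
    p <- random_parsed()
    s <- format_classification(p)
    q <- parse_classification(s)
    expect_identical(format_classification(q), s)
    expect_identical(q$involvements, p$involvements)
    expect_identical(q$tnm, p$tnm)
    expect_identical(q$rec, p$rec)
  }
})
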