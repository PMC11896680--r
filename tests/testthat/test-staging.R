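# T-floor rule engine, stage derivation, risk-of-recurrence tier and
# reported-vs-recommended comparison.

test_that("t_floor applies the published per-structure floors", {
  floor_of <- function(inv) t_floor(inv)$floor
  # gross strap muscle invasion classifies T3b
  expect_identical(floor_of(involvement("M", "SM")), "T3b")
  expect_identical(floor_of(rbind(involvement("M", "SM"),
                                  involvement("M", "CT"))), "T3b")
  # RLN at either degree, pharyngoesophagus, laryngotracheal and bone: T4a
  expect_identical(floor_of(involvement("N", "RLN", degree = 0)), "T4a")
  expect_identical(floor_of(involvement("N", "RLN", degree = 1)), "T4a")
  expect_identical(floor_of(involvement("PE", "E", degree = 0)), "T4a")
  expect_identical(floor_of(involvement("LT", "T", degree = 0, rings = 1)),
                   "T4a")
  expect_identical(floor_of(involvement("B", "St", degree = 1)), "T4a")
  # arterial transection/encasement: T4b
  expect_identical(floor_of(involvement("Vas", "A_CC", degree = 1)), "T4b")
  # veins never modify T
  expect_true(is.na(floor_of(rbind(involvement("Vas", "V_IJ", degree = 1),
                                   involvement("Vas", "V_INN", degree = 1)))))
  # empty set fires no rule
  empty <- t_floor(thyrostage:::empty_involvements())
  expect_true(is.na(empty$floor))
  expect_identical(nrow(empty$trace), 0L)
})

test_that("t_floor warnings flag structures outside the rule table", {
  art <- t_floor(involvement("Vas", "A_CC", degree = 0))
  expect_true(is.na(art$floor))
  expect_true("arterial_involvement_review" %in% art$warnings)

  sln <- t_floor(involvement("N", "SLN", degree = 1))
  expect_true(is.na(sln$floor))
  expect_true("nerve_outside_rule_table" %in% sln$warnings)

  # vein involvement is traced but warning-free
  vein <- t_floor(involvement("Vas", "V_IJ", degree = 1))
  expect_identical(vein$warnings, character())
  expect_true(nrow(vein$trace) == 1L)
})

test_that("every fired rule references an involvement in the input", {
  set.seed(77)
  for (i in 1:50) {
    inv <- random_involvements()
    fl <- t_floor(inv)
    toks <- thyrostage:::involvement_token(
      thyrostage:::sort_involvements(inv))
    expect_true(all(fl$trace$involvement %in% toks))
  }
})

test_that("t_floor is permutation-invariant and monotone", {
  set.seed(99)
  for (i in 1:60) {
    inv <- random_involvements(p = 0.35)
    if (nrow(inv) < 2) next
    perm <- inv[sample(nrow(inv)), , drop = FALSE]
    expect_identical(t_floor(perm)$floor, t_floor(inv)$floor)
    # adding an involvement never lowers the floor
    drop1 <- inv[-sample(nrow(inv), 1), , drop = FALSE]
    f_small <- t_floor(drop1)$floor
    f_big <- t_floor(inv)$floor
    if (!is.na(f_small)) {
      expect_false(is.na(f_big))
      expect_true(t_order(f_big, f_small) %in% c("equal", "greater"))
    }
  }
})

test_that("derive_stage reconciles the size-based T with the floor", {
  # floor raises the size-based T (strap muscle: T2 -> T3b)
  rec <- checklist_record(involvements = involvement("M", "SM"),
                          pathology_t = "T2", pathology_n = "N1a")
  expect_identical(format(derive_stage(rec)), "pT3b N1a Mx M-SM")

  # pathology T above the floor wins
  rec2 <- checklist_record(involvements = involvement("M", "SM"),
                           pathology_t = "T4a", pathology_n = "N0")
  expect_identical(derive_stage(rec2)$tnm$t, "T4a")

  # no pathology T: the floor alone sets T
  rec3 <- checklist_record(involvements = involvement("N", "RLN", degree = 0),
                           pathology_n = "N0", pathology_m = "MX")
  expect_identical(format(derive_stage(rec3)), "pT4a N0 Mx N-RLN^0")

  # neither available: TX with warning
  rec4 <- checklist_record(involvements = involvement("Vas", "V_IJ",
                                                      degree = 1))
  s4 <- derive_stage(rec4)
  expect_identical(s4$tnm$t, "TX")
  expect_true("t_unresolved" %in% s4$warnings)

  # distant metastases force M1 over MX
  rec5 <- checklist_record(involvements = involvement("N", "RLN", degree = 1),
                           pathology_n = "N1a", pathology_m = "MX",
                           distant_mets = "present")
  expect_identical(derive_stage(rec5)$tnm$m, "M1")
})

test_that("derive_stage emits the canonical anatomic suffix order", {
  rec <- checklist_record(
    involvements = rbind(involvement("N", "RLN", degree = 1),
                         involvement("LT", "T", degree = 0, rings = 2),
                         involvement("LT", "Cr", degree = 0),
                         involvement("PE", "E", degree = 0),
                         involvement("PE", "Ph", degree = 0)),
    pathology_n = "N1a", distant_mets = "present")
  expect_identical(format(derive_stage(rec)),
                   "pT4a N1a M1 LT-Cr^0 LT-T_2^0 N-RLN^1 PE-Ph^0 PE-E^0")
})

test_that("recurrent and persistent disease suppress AJCC staging", {
  for (status in c("recurrent", "persistent")) {
    rec <- checklist_record(disease_status = status,
                            involvements = involvement("N", "RLN",
                                                       degree = 1))
    s <- derive_stage(rec)
    expect_null(s$tnm)
    expect_identical(format(s), "Rec N-RLN^1")
    expect_identical(s$ror, "not_applicable")
  }
  # a supplied pathology T on recurrent disease draws a warning
  rec2 <- checklist_record(disease_status = "recurrent",
                           involvements = involvement("N", "RLN", degree = 1),
                           pathology_t = "T2")
  expect_true("tnm_not_applicable_recurrent" %in% derive_stage(rec2)$warnings)
})

test_that("risk-of-recurrence tier follows the high-risk rules", {
  # gross invasion -> high
  high <- checklist_record(involvements = rbind(
    involvement("N", "RLN", degree = 1), involvement("M", "SCM")))
  expect_identical(classify_ror(high)$tier, "high")

  # incomplete resection -> high even without involvements
  r2 <- checklist_record(residual = "R2")
  expect_identical(classify_ror(r2)$tier, "high")
  expect_true("ror_high_incomplete_resection" %in% classify_ror(r2)$rules)

  # nothing high-risk: low with an incompleteness warning
  low <- classify_ror(checklist_record(distant_mets = "absent"))
  expect_identical(low$tier, "low")
  expect_true("ror_incomplete_inputs" %in% low$warnings)

  # recurrent disease is not applicable
  rec <- checklist_record(disease_status = "recurrent")
  expect_identical(classify_ror(rec)$tier, "not_applicable")
})

test_that("compare_stages enumerates understaging discrepancies", {
  # understaged T and a missing nerve token
  cmp <- compare_stages("pT1b N1a Mx", "pT4a N1a Mx N-RLN^1")
  expect_identical(cmp$verdict, "discrepant")
  expect_true("t_understaged" %in% cmp$codes)
  expect_true("missing_involvement:N-RLN^1" %in% cmp$codes)

  # omitted residual code and vessel tokens despite a higher reported T
  cmp2 <- compare_stages("pT4a N1b Mx",
                         "R2 pT2 N1b Mx Vas-V_IJ^1 Vas-V_INN^1")
  expect_identical(cmp2$verdict, "discrepant")
  expect_true("residual_omitted" %in% cmp2$codes)
  expect_true(any(grepl("^missing_involvement:Vas", cmp2$codes)))
  expect_false("t_understaged" %in% cmp2$codes)

  # identical classifications are accurate
  s <- "R1 pT4a N1b Mx LT-T_1^0 N-RLN^1 PE-Ph^0 M-SM"
  expect_identical(compare_stages(s, s)$verdict, "accurate")

  # degree mismatch on a matched subsite is discrepant
  cmp3 <- compare_stages("pT4a N0 Mx N-RLN^0", "pT4a N0 Mx N-RLN^1")
  expect_identical(cmp3$codes, "degree_mismatch:N-RLN^1")

  # nothing reported at all
  cmp4 <- compare_stages(NA, "pT4a N0 Mx N-RLN^1")
  expect_true("tnm_missing" %in% cmp4$codes)
})

test_that("rule tables survive a file round trip and alter staging", {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path), add = TRUE)
  write_rule_table(default_t_floor_rules(), path)
  back <- read_rule_table(path)
  expect_identical(back, default_t_floor_rules())

  # an institutional override: subadventitial arterial dissection -> T4b
  rules <- default_t_floor_rules()
  rules$floor[rules$id == "R4a"] <- "T4b"
  rec <- checklist_record(involvements = involvement("Vas", "A_CC",
                                                     degree = 0),
                          pathology_t = "T2", pathology_n = "N0")
  expect_identical(derive_stage(rec)$tnm$t, "T2")
  expect_identical(derive_stage(rec, rules)$tnm$t, "T4b")
})
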