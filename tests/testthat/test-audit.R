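# Audit pipeline and the from-first-principles two-tailed Fisher exact test.

test_that("fisher test handles canonical and degenerate tables", {
  # the study's checklist-by-accuracy table is strongly significant
  p <- fisher_exact_two_tailed(matrix(c(15, 0, 1, 13), 2, byrow = TRUE))
  expect_lt(p, 0.01)
  expect_equal(p, oracle_fisher(15, 0, 1, 13), tolerance = 1e-12)

  # the modal table: every mass qualifies
  expect_equal(fisher_exact_two_tailed(5, 5, 5, 5), 1.0)
  # degenerate margin convention
  expect_equal(fisher_exact_two_tailed(0, 10, 0, 10), 1.0)
  expect_equal(fisher_exact_two_tailed(0, 0, 3, 4), 1.0)

  expect_error(fisher_exact_two_tailed(0, 0, 0, 0), "empty")
  expect_error(fisher_exact_two_tailed(-1, 2, 3, 4), "non-negative")
})

test_that("fisher test matches the enumeration oracle and stats::fisher.test", {
  set.seed(2024)
  for (i in 1:200) {
    cells <- as.integer(rpois(4, lambda = sample(c(2, 8, 25), 1)))
    if (sum(cells) == 0) cells[1] <- 1L
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    p <- fisher_exact_two_tailed(a, b, c, d)
    expect_equal(p, oracle_fisher(a, b, c, d), tolerance = 1e-10)
    m <- matrix(cells, 2, byrow = TRUE)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-7)
    }
  }
})

test_that("fisher p is invariant under row and column swaps", {
  set.seed(11)
  for (i in 1:50) {
    cells <- as.integer(rpois(4, 6)) + c(1L, 0L, 0L, 0L)
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    p <- fisher_exact_two_tailed(a, b, c, d)
    expect_equal(fisher_exact_two_tailed(c, d, a, b), p, tolerance = 1e-12)
    expect_equal(fisher_exact_two_tailed(b, a, d, c), p, tolerance = 1e-12)
  }
})

test_that("audit verdicts honor overrides and count by stratum", {
  cohort <- invasion_cohort()
  audit <- audit_cohort(cohort)

  # case 5: override makes the lone accurate no-checklist report
  row5 <- audit$per_case[audit$per_case$case_id == "5", ]
  expect_identical(row5$verdict, "accurate")
  expect_true(row5$override)

  # recurrent cases carry no AJCC verdict, only missing items
  recur <- audit$per_case[audit$per_case$status != "primary", ]
  expect_identical(nrow(recur), 6L)
  expect_true(all(is.na(recur$verdict)))
  expect_true(all(grepl("missing_involvement", recur$codes)))

  # contingency table equals the stratified counts
  expect_identical(as.vector(audit$primary$contingency),
                   c(15L, 1L, 0L, 13L))
})

test_that("audit counts are permutation-invariant in case order", {
  cohort <- invasion_cohort()
  set.seed(5)
  shuffled <- cohort[sample(length(cohort))]
  a1 <- audit_cohort(cohort)$primary$by_checklist
  a2 <- audit_cohort(shuffled)$primary$by_checklist
  expect_identical(a1, a2)
})

test_that("an all-accurate cohort yields zero discrepancies", {
  cohort <- generate_cohort(synth_params(40, seed = 3, p_omit = 0))
  audit <- audit_cohort(cohort)
  expect_identical(sum(audit$primary$by_checklist$discrepant), 0L)
})

test_that("structure tallies count recommended-minus-reported omissions", {
  cohort <- invasion_cohort()
  tl <- tally_missing_structures(primary_cases(cohort))
  expect_identical(tally_of(tl, "SM"), 7L)
  expect_identical(tally_of(tl, "RLN_sacrifice"), 4L)
  expect_identical(tally_of(tl, "CT"), 4L)
  expect_identical(tally_of(tl, "LT"), 1L)
  # pharyngoesophagus under both conventions (case-level vs token-level)
  expect_identical(tl$cases[tl$class == "PE"], 7L)
  expect_identical(tl$tokens[tl$class == "PE"], 9L)
  # widening the scope pulls in the override case's unreported RLN sacrifice
  ta <- tally_missing_structures(primary_cases(cohort), scope = "all")
  expect_identical(tally_of(ta, "RLN_sacrifice"), 5L)

  # recurrent cases: four unreported nerve sacrifices (3 RLN + 1 vagus)
  tr <- tally_missing_structures(recurrent_cases(cohort), scope = "all")
  expect_identical(tally_of(tr, "nerve_sacrifice"), 4L)
  expect_identical(tally_of(tr, "RLN_sacrifice"), 3L)
  expect_identical(tally_of(tr, "SLN_Vag"), 1L)
  expect_identical(tally_of(tr, "RLN_epineurium"), 1L)
})

test_that("cohort CSV round trip preserves audit results", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  cohort <- invasion_cohort()
  write_cohort_csv(cohort, path)
  back <- read_cohort_csv(path)
  expect_identical(length(back), 35L)
  a1 <- audit_cohort(cohort)
  a2 <- audit_cohort(back)
  expect_identical(a1$primary$by_checklist, a2$primary$by_checklist)
  expect_identical(a1$primary$by_surgeon, a2$primary$by_surgeon)
  expect_equal(a1$primary$fisher_p, a2$primary$fisher_p)
})
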