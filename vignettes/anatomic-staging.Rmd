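---
title: "Anatomic checklist staging: notation, rules and the understaging audit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomic checklist staging: notation, rules and the understaging audit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyrostage)
```

## The reporting problem

For most thyroid cancers the final pathology report can be written from the
specimen alone. Grossly invasive disease is different: cancer can be
dissected off the trachea, the recurrent laryngeal nerve (RLN) or the
esophageal muscularis without leaving histologic evidence in the specimen,
and gross residual disease left in the tumor bed is by definition invisible
to the pathologist. AJCC 8th edition staging explicitly incorporates the
surgeon's description of gross extrathyroidal extension (ETE), yet the only
standard channel for that information is the free-text operative note,
which non-surgeons reliably under-extract. The result is systematic
understaging: a report that assigns a lower T category, or omits anatomic
involvement or a residual-disease code, relative to what the intraoperative
findings justify.

`thyrostage` implements the machinery around a synoptic anatomic checklist
for these cases: a shorthand notation for structural involvement, a rule
engine that turns intraoperative findings into AJCC T-category floors and an
ATA risk-of-recurrence (ROR) tier, an audit pipeline that detects
understaged reports at cohort scale, the packaged 35-case study cohort, and
a seeded synthetic-cohort generator.

## The shorthand notation

Six site categories cover the structures gross ETE or extranodal extension
(ENE) usually involves, each with a fixed subsite vocabulary:

```{r}
subsite_vocabulary()
```

An involvement is written `CAT-SUB^degree`, with two modifiers:

* the **degree superscript** `^0`/`^1` records the extent of surgery:
  `0` means the structure was involved but cleared in a preserving plane
  (epineural, subperichondrial, subperiosteal, subadventitial — or, for the
  pharyngoesophagus, muscularis-only resection with the lumen intact);
  `1` means resection or a transmural defect. Muscle involvement is a
  binary determination and never takes a superscript.
* the **tracheal ring subscript** `T_k` counts involved rings; no other
  subsite takes a numeric subscript (vessel names such as `V_IJ` are part
  of the subsite code).

The package uses an ASCII dialect (`^` and `_` instead of typographic
super/subscripts) so classification strings survive plain-text interchange.
The parser accepts the spelling variation seen in practice — `Vas`/`VAS`,
`Cr`/`CR`, `Acc` for `A_CC`, suffixes in either order (`T^0_2` = `T_2^0`),
glued T/N/M tokens (`N0Mx`), a missing M token (normalized to `Mx`),
`/`-compression (`M-SM/CT`, `VAS-V_IJ/INN^1`, where a shared trailing
degree distributes over the chain) and bare continuation tokens
(`B-St^1 Clav^1`). The formatter always emits one canonical form: `Rec`
prefix, residual code, T/N/M, then one full token per subsite in fixed
category order `LT B N PE Vas M`:

```{r}
format_classification(parse_classification("pT4a N0Mx M-SM/CT PE-E^0 Ph^0"))
```

Two parsing choices were genuinely open and are resolved as follows.
A missing degree on a degree-taking subsite is a **parse error**, not an
implicit `^0`: in the source material every non-muscle token carries a
superscript, and silently defaulting would fabricate the clinically loaded
distinction between preservation and sacrifice. Second, `Rec` combined
with a `pT` token is an error rather than a tolerated redundancy, because
AJCC staging is undefined for recurrent surgical disease and a consumer
must not be handed both.

## The staging rule engine

Each involvement can imply a minimum (floor) T category; the recommended T
is the maximum of the size/extent-based pathology T and the floors, under
the strict order `T0 < T1a < T1b < T2 < T3a < T3b < T4a < T4b` (`TX`
incomparable). The default table:

```{r}
default_t_floor_rules()
```

Where the rule set was underdetermined, the package resolves it from the
cohort's own recommendations rather than guessing:

* **Cricothyroid muscle** is grouped with strap/SCM at floor T3b, not with
  the larynx at T4a: the cohort's `M-SM/CT` case is recommended pT3b.
* **Veins never modify T**: the case with resected internal jugular and
  innominate veins is recommended pT2 (size-based), which contradicts any
  mediastinal-vessel T4b reading.
* **Arterial degree 0** (subadventitial dissection) warns
  (`arterial_involvement_review`) but sets no floor: AJCC T4b requires
  encasement, and no packaged case arbitrates. Institutions that disagree
  can override via `read_rule_table()`/`write_rule_table()`.
* **RLN at degree 0** (epineural dissection, nerve preserved) floors at
  T4a, following the cohort's explicit `N-RLN^0` recommendation; this is
  the most debatable rule — AJCC wording emphasizes gross invasion, not
  plane of clearance — and is deliberately kept in the editable table.
* **SLN/vagus** carry no floor but warn (`nerve_outside_rule_table`): no
  primary case and no AJCC text assigns one (the only vagus case in the
  cohort is recurrent, hence unstaged, and cannot arbitrate).

For recurrent or persistent disease the engine emits no T/N/M at all: the
classification renders as `Rec` plus the anatomic suffix and the ROR tier
is `not_applicable`. "Persistent" shares the behavior class of
"recurrent" — both describe surgery after a prior operation, to which the
initial-staging framework does not apply.

The ROR tier is computed only to the resolution the checklist feeds: gross
invasion (any involvement — the audit's inclusion criterion), incomplete
resection (R1/R2) or distant metastases each imply **high** risk. When no
high-risk rule fires, the low/intermediate distinction requires inputs the
checklist does not carry (histologic vascular invasion, nodal burden,
mutation interpretation); the engine reports `low` with warning
`ror_incomplete_inputs` instead of guessing.

## The audit

A reported classification is **discrepant** when it understages T (reported
T strictly below recommended T), omits a recommended R1/R2 code, or lacks a
recommended involvement (subsite-level match; degree mismatches count).
One packaged case is accurate by **override**: its operative report stated
the RLN sacrifice in plain words and the final report incorporated it, so
the audit must be able to represent that human judgment explicitly
(`accuracy_override`) rather than infer it from strings.

In the packaged cohort the 15 checklist-accompanied final reports carried
the checklist's full classification (their items-not-reported annotation is
empty), so their audit-facing reported content is the recommended
classification itself; the 14 no-checklist reports contribute only their
verbatim pathology T/N/M. Recurrent cases carry no AJCC verdict and are
summarized by missing items only.

The checklist-by-accuracy 2×2 table is tested with a **two-tailed Fisher
exact test written from first principles**: with margins fixed, the p-value
sums the hypergeometric probabilities of all tables whose probability does
not exceed the observed table's (relative tie tolerance 1e-7, the
convention used by standard implementations), with probabilities computed
via log-binomial coefficients for overflow safety. Degenerate margins
return p = 1 by convention. The test suite checks exact agreement with an
independent `dhyper`-based enumeration oracle on every 2×2 table with
grand total ≤ 40, and with `stats::fisher.test` on random tables —
the library implementation is a cross-check, never the engine.

Structure-omission tallies are computed as recommended-minus-reported set
difference at subsite-class level. The pharyngoesophageal class is reported
under **both** counting conventions — cases with any omitted PE token, and
omitted PE tokens — because the two differ (7 vs 9 in the packaged
no-checklist discrepant cases) and the published headline count for that
structure (8) does not reconcile with either; neither convention is forced.
The items-not-reported annotations are carried as free text and never
parsed: in one packaged case the annotation names a structure absent from
the recommended classification, so they are non-authoritative.

## The synthetic generator

`generate_cohort()` emulates the study's omission mechanism: each case
draws involvements by per-subsite prevalence, derives its true recommended
stage through the same engine, and then constructs the reported
classification — equal to the recommendation when a checklist accompanies
the case, otherwise with each involvement independently dropped with
probability `p_omit` and the reported T re-derived from the surviving set.
Omission acts on whole involvements, not degrees, because the documented
misses are whole structures.

Defaults are the stated world of the packaged cohort: prevalence equals the
empirical subsite frequencies among its 29 primary cases (e.g. `N-RLN`
0.45, `M-SM` 0.38, `PE-E` 0.38; structures unseen there get small nominal
rates so the vocabulary stays exercised); `p_checklist = 15/29`; cases are
conditioned on at least one involvement (the study enrolled only gross
ETE/ENE); and `p_omit = 0.9`, reflecting no-checklist reports that conveyed
essentially no structural detail. Degree-1 proportions per category and the
size-based T distribution are set once from the same cases. The generator
does **not** model residual-code omission, annotation text, N-category
errors or pathologist reading of operative notes — a green synthetic test
therefore establishes the engine's internal consistency under the omission
model, not fidelity to any wider clinical reality.

Reproducibility: one seed draws per-case subseeds up front, and each case
is generated on its own substream, so case content is independent of
generation order. The no-checklist discrepancy rate has the closed form
implemented in `expected_no_checklist_discrepancy()` (a case is discrepant
exactly when at least one involvement is dropped), and the test suite
checks empirical convergence at n = 10,000 within three standard errors.

## Numerical and interface choices

* Fisher tie tolerance 1e-7 (relative); log-space probabilities; p clipped
  to 1.
* T/N/M codes are uppercase internally (`MX`); reports print the
  conventional mixed case (`Mx`).
* `N0a`/`N0b` are accepted as distinct N categories but the audit never
  distinguishes them from `N0` (no accuracy judgment depends on N).
* Histology is free text: it alters no implemented rule, and prognostic
  stage groups (which would need it, plus age) are out of scope.
* Case identifiers are opaque; no patient identifiers are modeled, and the
  text report is ASCII-only for EHR paste-ability.
* The JSON record schema is published by `record_schema()` and the CLI
  `schema` subcommand; cohort CSVs embed the full record as a JSON blob so
  a cohort file is self-contained.

## Limitations

The floor table encodes current AJCC practice plus the cohort-arbitrated
choices above; it is a reporting aid, not an outcome model — no survival or
recurrence prediction is attempted. The packaged cohort is small (35
cases, two surgeons) and its headline counts are reproduced exactly rather
than estimated. ROR is resolved only to the high/not-high boundary.
Prognostic stage groups I–IV, nodal-burden sub-rules and
histology-specific staging tables are out of scope.
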