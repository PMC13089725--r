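---
title: "Methods: operationalizing PLTC-based severe maternal morbidity surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: operationalizing PLTC-based severe maternal morbidity surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Severe maternal morbidity (SMM) under the WHO's potentially
life-threatening conditions (PLTC) framework is defined by 26 criteria in
four groups: haemorrhagic disorders, hypertensive disorders, other
systemic disorders, and severe-management indicators. Administrative
hospital claims record neither laboratory values nor clinical findings, so
the criteria must be *operationalized* as code sets: ICD-10 diagnoses
(recorded in 14 fields in the public SIH/SUS dialect, 4 fields in the
private ANS dialect), SIGTAP or TUSS procedure acts, the public schema's
monthly ICU-days counter, and dates. Four criteria — accreta/increta/
percreta placenta, HELLP syndrome, thrombocytopenia < 100,000, and return
to the operating room — have no identifying code in either terminology;
the codebook declares them with `operationalized: false` and the
classifier refuses to evaluate them rather than silently returning false.

The surveillance analysis then has three surfaces: criterion frequencies
(against all obstetric hospitalizations and against SMM cases), the odds
ratio of in-hospital death per criterion (convergent validity: a severity
marker should predict death), and deaths by number of criteria met.

## The codebook is data

All code sets live in `inst/extdata/pltc_codebook.yaml` and are loaded by
`load_codebook()`, so alternative operationalizations can be swapped in
without touching code. Matching semantics:

* 4-character ICD entries match exactly; 3-character entries are category
  prefixes (`O45` covers `O450`–`O459`); ranges such as `Z34-Z39` compare
  the code's prefix of the endpoints' width lexicographically. The
  redundant listings that occur in published code tables (`O45` alongside
  `O450, O459`) are therefore harmless: a property test asserts that
  adding a 4-character code already covered by its 3-character category
  never changes any match.
* SIGTAP is fixed-width 10-digit; codes printed with 9 digits (a dropped
  leading zero) are left-zero-padded. TUSS is 8-digit. Any other width is
  flagged invalid and never matched.
* Malformed ICD strings normalize to `NA` and never match any set.

Two transcription decisions are worth recording. The sepsis row of the
published criterion table prints a bare `413` inside the enumeration
`A412, 413, A414`; the codebook carries it as `A413`. The hysterectomy row
lists the delivery code `O822` (caesarean hysterectomy); it is transcribed
as printed.

## Obstetric identification and the perinatal allow-list

Public episodes are obstetric iff any diagnosis field carries a
chapter-"O" code or any act is on the SIGTAP obstetric list. Private
records add the type-of-hospitalization field (3 = obstetric) and the
problem that newborn admissions are often billed under the insured
woman's event. The rule set is: (a) type 3, unless the record carries a
perinatal ("P") diagnosis outside a tolerated allow-list — such records
are neonatal stays; (b) any "O", Z34–Z39 or enumerated-"P" diagnosis when
the type is not pediatric; (c) any TUSS obstetric act.

The printed allow-list mixes two- and three-character stems
("P0, P1, P2, … P20, P35, …"). Read as plain prefixes it is internally
inconsistent: `P2` would subsume the separately listed `P20`, and a
newborn record coded `P22.0` (respiratory distress of the newborn) would
count as obstetric, which is exactly what the exception exists to
prevent. We resolve the grammar by reading the single-digit stems as the
`P00`–`P05` category block — consistent with the diagnosis-side
enumeration, which spells out `P000–P059` — so the allow-list is the
three-character categories {P00–P05, P20, P35, P37, P50, P56, P93, P95,
P96}. This is the one deliberately interpretive choice in the rule set and
it is isolated in the codebook (`p_group_type3_allow`) for anyone who
reads the grammar differently.

Rule (a) is intentionally satisfiable by records with *no* diagnoses at
all: ICD registration is not mandatory in the private schema (about 30 %
of admissions carry none), and blocking on missingness would silently
drop a third of the sector. The allow-list exception is also the single
non-monotone clause in the pipeline — adding a diagnosis can only ever
flip a record *out* of the obstetric set through it — and is tested as
such.

An age filter (10–49) belongs upstream at ingestion; neither dialect's
age field enters these predicates.

## Episode assembly

A public-sector hospital stay can generate several admission forms (AIH),
e.g. when a surgical procedure is indicated during an initially clinical
admission. The published linkage algorithm for this is external to the
analysis we reproduce, so `assemble_episodes()` implements a documented
replacement: forms chain when they share person and facility keys and the
next admission starts at most `max_gap_days` (default 1) after the
episode's running discharge date; chaining is transitive, and the
partition equals the connected components of the pairwise rule (a
property verified against an exhaustive-closure oracle). The gap default
encodes same-day/next-day continuation forms; it is a configuration knob,
and `require_same_hospital` can be relaxed. Private events are never
chained — the schema carries neither the facility number nor the woman's
birth date, the fields such linkage needs.

Episode fields aggregate as: minimum admission and maximum discharge
date, summed ICU days, union of diagnoses (with field provenance) and of
procedures, and the chronologically final member's discharge outcome. A
death on a non-final member is a validation error. Classification uses
the episode-level union because the case definition attaches to the
episode of care, not to the individual billing form.

## Classification rules beyond plain code matching

* **Prolonged hospital stay**: discharge − admission strictly greater
  than 7 days, in episodes admitted for childbirth. "Childbirth" is a
  configured delivery-procedure subset; the published tables do not
  enumerate which obstetric codes are deliveries, so the default takes
  the normal-delivery SIGTAP block (03.10.01.001-2 … 005-5) and the
  cesarean block (04.11.01.001-8 … 004-2), with a TUSS counterpart, all
  editable in the codebook. Public episodes carrying the in-hospital
  newborn-care act (08.02.01.002-4) are excluded — there the long stay
  belongs to the newborn.
* **ICU admission**: public, the `UTI_MES_TOT` counter > 0 or an ICU
  daily-rate act; private, the ICU TUSS codes.
* **Surgical intervention / conditional curettage**: the public
  curettage act does not distinguish post-abortion from puerperal
  curettage, so it counts only when the episode also contains a delivery
  procedure or a puerperal-complication diagnosis (default stems
  O85–O92). Other listed acts count unconditionally.
* All diagnosis fields are consulted uniformly, including the public
  schema's `icd_death` field, which the schema documentation lists among
  the diagnosis fields.

Group totals and the overall SMM count use union semantics: an episode
contributes once to each group it touches. The published frequency table
confirms this reading — its printed group totals fall below the column
sums.

## Mortality analysis

`known_outcome_filter()` keeps episodes ending in live discharge or
in-hospital death; stays, transfers and unreported discharges leave
survival unknown and are excluded from all mortality denominators.
Frequency tables deliberately use the *unfiltered* obstetric denominator
while the odds-ratio and deaths-by-count tables use the known-outcome
denominator — the two denominators are explicit function parameters
because published surveillance tables switch between them.

The odds ratio is the plain cross-product `(a*d)/(b*c)` with the
complement of the criterion (including episodes meeting other criteria)
as reference, no continuity correction. Edge cases are explicit: `a = 0`
yields 0 (the published tables print a dash); `b = 0` or `c = 0` is
undefined and yields `NA`. Printed-value comparisons round half away from
zero at two decimals, which matches every published row we spot-checked;
R's own banker's rounding does not. A Woolf log-OR interval is available
(`woolf_ci()`) but off by default: the published analysis prints point
estimates only.

The private-sector published tables carry two internal inconsistencies
(the odds-ratio table's header N and its overall-SMM death count disagree
with the deaths-by-count table's totals). Reconstruction checks for that
sector are therefore restricted to rows consistent with the
deaths-by-count totals; the shipped reference data documents, and does
not resolve, the conflict.

## The synthetic-cohort generator

`simulate_cohort()` writes both schema file pairs plus a truth table. It
emulates: the schema mix (default 16.7 % private, the national ratio of
obstetric hospitalizations); independent Bernoulli criterion planting at
per-criterion prevalences matching the national public-sector magnitudes;
~30 % missing-ICD private records; multi-form public episodes (default
8 %, 2–3 forms, same-day or next-day continuations); unknown-outcome
fractions of 1 % (public) and 5.2 % (private); and in-hospital death from
`logit(p) = -8 + 1.1 * n_observable`, calibrated to the order of
magnitude of the national mortality gradient (baseline death risk a few
per 10,000, rising roughly threefold per criterion). The death-model
coefficients are explicitly synthetic constants, not estimates. Every
planted hit is realized by a trigger code drawn uniformly from the
criterion's set; on missing-ICD records an ICD hit substitutes a
procedure trigger when the criterion has one and is otherwise recorded as
planted-but-unobservable in the truth table. Each criterion remains
independently plantable; a correlation structure is deliberately out of
scope since no joint distribution is published.

Randomness is drawn once, up front, in a fixed order, with all fraction
parameters applied as thresholds on pre-drawn uniforms. Consequences:
the same seed gives byte-identical files, and raising
`missing_icd_fraction` produces nested masks, so classified private
prevalence is deterministically non-increasing in the missingness — the
mechanical form of the under-ascertainment argument.

What the generator does *not* emulate, and hence what passing tests do
not show about real data: code-entry error and nonspecific procedure
coding, criterion correlation, repeat admissions of one woman (each
episode gets its own person key, so episode assembly recovers exactly the
planted multi-form groups), facility-level variation, and any covariate
structure (age, region, year). Recovery tests demonstrate that the
pipeline is faithful to its own rules, not that the rules are sensitive
or specific against clinical reality.

## Numerical and scale choices

Problem sizes in tests and the acceptance script are chosen for
statistical adequacy: prevalence recovery uses 50,000 episodes (3
binomial standard errors at a planted 3 % prevalence); death-gradient
recovery uses 250,000 public episodes because with a baseline death risk
of ~3 per 10,000 a smaller cohort observes too few deaths among cases for
the fitted slope's sign to be stable; the end-to-end run uses 100,000
episodes. All complete in seconds on one CPU. Oracles are brute-force:
exhaustive pairwise closure for episode chaining and per-episode cell
enumeration for the 2×2 tables, on hand-sized cohorts.

## Limitations

The episode-chaining rule is a documented stand-in for the published
linkage algorithm, not a reimplementation of it; the delivery-procedure
subset and the perinatal allow-list resolution are configuration defaults
that a user with access to the terminologies' full descriptions may wish
to refine; and no geographic, temporal or cost stratification is
implemented. Maternal near-miss (organ-dysfunction) criteria are out of
scope: the claims schemas lack the laboratory and clinical fields they
require.
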