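# smmsurv — severe maternal morbidity surveillance in hospital claims

Maternal deaths are too rare for most municipalities to learn anything from
them year to year, so surveillance programmes track **severe maternal
morbidity (SMM)** instead: the WHO's *potentially life-threatening
conditions* (PLTC), a layer of 26 criteria spanning haemorrhagic disorders,
hypertensive disorders, other systemic disorders and severe-management
indicators. `smmsurv` operationalizes those criteria over the two Brazilian
hospital-claims dialects — the public **SIH/SUS** pair (a "reduced"
admissions table of AIH forms plus a "professional services" table of
procedure acts, linked by AIH number, with SIGTAP procedure codes) and the
private **ANS** pair (a "consolidated" admissions table with four ICD
fields plus a "detailed" procedures table, linked by event key, with TUSS
procedure codes) — and reproduces the standard validity analysis that
justifies the case definition: criteria associated with death are criteria
that measure severity.

The package is for epidemiologists and health-surveillance analysts who
want a reusable, auditable pipeline rather than a one-off script: the
entire code registry is data (an editable YAML codebook), every pipeline
stage is a tested function, and a synthetic-cohort generator makes the
whole thing verifiable without access to the national databases.

## What it computes

For each episode of care *i* with criterion profile
$C_i \subseteq \{1,\dots,22\}$ (22 of the 26 criteria are operationalizable
from ICD-10 diagnoses, SIGTAP/TUSS procedures, the ICU-days counter and
length of stay; 4 are declared but unidentifiable in either schema):

* **Episode assembly** — public-schema admission forms chain into one
  episode when they share person and facility keys and each continuation
  starts within `max_gap_days` (default 1) of the running discharge date;
  private events are always singletons (the schema lacks the linkage
  fields).
* **Obstetric identification** — per-schema rules over diagnosis chapter
  "O", Z34–Z39, an enumerated perinatal ("P") allow-list, the
  type-of-hospitalization field, and per-terminology obstetric procedure
  lists.
* **Frequency surfaces** — per-criterion case counts, shares of obstetric
  hospitalizations and of SMM cases; group totals use union semantics (an
  episode counts once per group however many of the group's criteria it
  meets).
* **Convergent validity** — for each criterion the odds ratio of
  in-hospital death from the 2×2 table against its complement within the
  known-outcome cohort (live discharge or death only):

  $$\mathrm{OR} = \frac{a\,d}{b\,c},$$

  with no continuity correction; a zero-death criterion arm prints 0, a
  zero `b` or `c` cell is undefined. Deaths are also tabulated by the
  number of criteria met.
* **Synthetic cohorts** — schema-faithful file pairs with planted
  per-criterion prevalence, ~30 % missing-ICD private records, multi-form
  public episodes, and a logistic death model
  $\operatorname{logit} p = \beta_0 + \beta_1 n_{\text{criteria}}$,
  plus a truth table for recovery analysis.

## Worked example

```r
library(smmsurv)
cb  <- load_codebook()                       # shipped PLTC registry
res <- simulate_cohort(sim_config(n_episodes = 20000, seed = 2024), "ex")
pub <- read_public_pair("ex/reduced.csv", "ex/services.csv")
pub
#> <smm_cohort> PUBLIC: 18326 records, 17431 diagnoses, 13263 procedure acts
#>   load report: 18326 rows in, 0 flagged, 0 orphan procedure rows

sp <- smm_surveillance(pub, cb)   # assemble -> identify -> classify
c(sp$n_episodes, sp$n_obstetric, sum(sp$profiles$is_smm))
#> [1] 16660 12446  1200
```

18,326 admission forms collapse to 16,660 episodes of care (multi-form
stays chained by person/facility/date), 12,446 of them obstetric, of which
1,200 (9.6 %) meet at least one morbidity criterion. The three analysis
surfaces:

```r
freq <- frequency_table(sp$profiles, sp$n_obstetric)
head(dplyr::arrange(subset(freq, level == "criterion"), -n_cases), 3)
#>   name                n_cases pct_of_hospitalizations pct_of_smm_cases
#> 1 severe_hypertension     406                    3.26             33.8
#> 2 prolonged_stay          186                    1.49             15.5
#> 3 severe_preeclampsia     133                    1.07             11.1

criterion_or_table(sp$profiles)[27, ]       # overall SMM row
#>   name  level     a     b     c     d  odds_ratio
#> 1 SMM   overall   3  1184     6 11141       4.70

deaths_by_count(sp$profiles)
#>   n_criteria deaths alive total pct_death
#> 1          0      6 11141 11147    0.0538
#> 2          1      2  1125  1127    0.177
#> 3          2      1    56    57    1.75
#> 4          3      0     3     3    0
```

Severe hypertension dominates case counts (as it does nationally), the
odds of dying are ~4.7-fold higher in case episodes, and the death
percentage climbs with the criterion count — the monotone gradient the
case definition is validated against. `recover_parameters(sp$profiles,
res$truth)` scores this classification against the generator's planted
truth (sensitivity 1 wherever a trigger code was recordable).

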