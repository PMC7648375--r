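# frids

Medication-related fall risk is routinely ignored by the short fall-risk
screens used on admission to geriatric wards and nursing homes, even though
fall-risk-increasing drugs (FRIDs) are among the most modifiable risk
factors in older adults. `frids` implements a transparent, statutory-data
approach for bringing medication into that screen:

* **A/B/C categorization of medicines.** Every medicine's Summary of Product
  Characteristics (SmPC) lists its adverse drug effects (ADEs) in statutory
  frequency classes. For the eight balance-disturbing mechanisms (sedation,
  orthostatic hypotension, syncope, dizziness, drowsiness, blood-pressure
  change, impaired balance, and a direct "falls" listing), the rule is:

  | highest ADE frequency           | class | fall risk |
  |---------------------------------|-------|-----------|
  | very common (≥ 1/10) or common (≥ 1/100) | A | high |
  | uncommon (≥ 1/1000)             | B     | moderate  |
  | rare, very rare, or none listed | C     | none      |

  ADEs of unknown frequency never decide the class but are surfaced as a
  flag.
* **A packaged knowledge base** of the 102 active substances categorized as
  high risk in a cohort of 188 fall-experienced patients (128 hospital, 60
  nursing home), with per-substance user counts; the 11 most-used
  ingredients carry their full SmPC ADE profiles, the rest a minimal
  inferred annotation flagged as such.
* **Scoring.** The routine 4-item admission score (recent fall, confusion,
  impaired balance, dizziness/drowsiness; one point each, 0 = no risk … 4 =
  full risk) and its proposed 5-item extension that adds one point for
  exposure to ≥ 1 category-A medicine (threshold configurable).
* **Cohort analytics.** Exposure profiles per patient, category shares at
  the medicament and substance denominators, ATC level-1/2/3 roll-ups,
  top-FRID rankings, and score distributions — with explicit denominators
  and round-half-up percentage conventions throughout.
* **A seedable synthetic-cohort simulator** calibrated to the study's
  published marginals, so every pipeline stage is testable without patient
  data.

## Worked example

```r
library(frids)
kb <- frid_knowledge_base()          # 102 category-A substances

categorize_drug(kb_ades(kb, "quetiapine"))
#> risk level A; deciding ADEs: dizziness, drowsiness

items <- admission_items(recent_fall = TRUE, confusion = FALSE,
                         impaired_balance = TRUE, dizziness_drowsiness = FALSE)
base_score(items)
#> # A tibble: 1 × 4
#>   points max_points label       medication_item
#>    <int>      <int> <chr>       <lgl>
#> 1      2          4 medium_risk NA

extended_score(items, c("metoprolol", "bromazepam"), kb)
#> # A tibble: 1 × 4
#>   points max_points label     medication_item
#>    <int>      <int> <chr>     <lgl>
#> 1      3          5 high_risk TRUE
```

The same patient screens as *medium risk* on the routine 4-item scale but
*high risk* once their two high-risk medicines (a beta blocker and a
benzodiazepine) are counted: exactly the under-estimation the extended
score is designed to surface.

Cohort-level, on the reconstruction shipped with the package:

```r
kb  <- reference_knowledge_base()    # published A + synthetic B/C pools
coh <- reference_cohort(kb)
summarize_cohort(coh, kb)
#> == Fall-risk categories ==
#>   medicaments (n=1748): A 710 (41%)  B 331 (19%)  C 707 (40%)
#>   substances  (n=216): A 102 (47%)  B 29 (13%)  C 85 (39%)
#>   category A per patient: mean 3.8, min 3, max 4, median 4
#> == Top category-A ingredients ==
#>   metoprolol                   C07AB02   49 (26.1%)
#>   perindopril                  C09AA04   38 (20.2%)
#>   ...
```

A thin command-line wrapper is installed at `inst/cli/frids`
(`frids categorize`, `frids score`, `frids screen`, `frids summarize`,
`frids simulate`).

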