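---
title: "Categorizing fall-risk-increasing drugs and scoring medication-aware fall risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Categorizing fall-risk-increasing drugs and scoring medication-aware fall risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frids)
```

## The problem

Falls are a leading preventable cause of injury in older adults in
hospitals and nursing homes. Admission screens in routine use are
deliberately short — four yes/no items scored by a nurse — and typically
omit medication, although many commonly prescribed medicines disturb
balance through sedation, orthostatic hypotension, syncope, dizziness,
drowsiness, blood-pressure changes or impaired gait. `frids` packages a
reproducible way to (i) classify medicines by their documented propensity
for such effects, (ii) quantify a ward's or cohort's exposure to the
high-risk class, and (iii) add that exposure as a fifth item to the
admission screen.

## The categorization model

Every EU-authorized medicine carries a Summary of Product Characteristics
(SmPC) that lists adverse drug effects (ADEs) in statutory frequency
classes, defined as the proportion of treated patients affected:

```{r}
frequency_classes()
```

The categorization rule is deliberately simple and auditable: restrict
attention to the eight balance-relevant ADE mechanisms, take the **highest
frequency class** among them, and map

* very common or common → **A** (high fall risk) — at least one affected
  patient per hundred users;
* uncommon → **B** (moderate);
* rare, very rare, or nothing listed → **C** (none).

Two boundary situations get explicit treatment rather than a silent
default:

* **Unknown frequency.** There is no frequency row for "not known", so an
  unknown-frequency ADE can neither cause nor block a rating; it is
  recorded in `flags` as `unknown_frequency_present`. The motivating case
  is a benzodiazepine whose SmPC lists "falls" at unknown frequency — the
  drug is A regardless, via common drowsiness.
* **No listed fall-risk ADE.** Category C, with flag
  `no_fall_risk_ade_listed`, so that "documented as rare" and "nothing
  documented" stay distinguishable in audits.

When several ADEs tie at the deciding frequency tier, all of them are
reported as `deciding_ades`; there is no first-wins choice. If the same
mechanism appears with different frequencies (as happens across SmPC
sections), the highest listed frequency wins — consistent with the max
rule and conservative for a screening instrument.

SmPCs name mechanisms inconsistently, so raw terms pass through a synonym
map (`ade_vocabulary()`): somnolence → drowsiness, vertigo → dizziness,
ataxia → impaired balance, and so on. Bradycardia is folded into
blood-pressure change rather than given a ninth canonical mechanism: the
mechanism list has seven entries plus the direct "falls" listing, yet
published profiles list bradycardia for beta blockers and digoxin, and a
synonym mapping is the least-surprising reconciliation. The map is
user-extensible (`ade_vocabulary(extra_synonyms=)`, or YAML via
`read_vocabulary_config()`), and unresolvable terms are an error — a term
that silently fails to match could flip a drug's category.

Ingredient names are case-folded and combination components joined by
`/`; salt suffixes are stripped only through an explicit alias table.
Fixed-dose combinations are one record under their combination ATC code,
because exposure analyses count medicaments, not components.

## The packaged knowledge base

`frid_knowledge_base()` ships the 102 substances categorized A in a
188-patient cohort of fall-experienced older adults, with per-substance
user counts as metadata. Only the 11 most-used ingredients have published
ADE profiles (`annotation_source = "smpc"`); the other 91 carry one
common-frequency placeholder annotation, flagged
`annotation_source = "inferred"`, which reproduces their category-A
membership while keeping provenance honest. Two ATC misprints in the
published table (ramipril sharing perindopril's code; two levodopa
combinations sharing one code) are kept as printed — the lookup layer
therefore allows an ATC key to match several records and, when profiling,
resolves it to the highest-risk match so exposure is never under-counted.

No moderate- or no-risk substances are published, so
`synthetic_risk_pool()` provides 29 B and 85 C stand-ins under Z-prefixed
codes (a letter no real anatomical main group uses), clearly labelled
synthetic. `reference_knowledge_base()` concatenates both, giving the 216
substances (102/29/85) that the substance-level shares are computed over.

## Scoring

The 4-item admission score counts positive items (recent fall; confusion;
impaired balance; dizziness/drowsiness) and maps 0→no, 1→low, 2→medium,
3→high, 4→full risk. A missing item is a validation error, never an
implicit zero: silent under-scoring is precisely the failure mode a
screening tool must not have.

The extended score adds one point when the patient uses at least
`threshold` category-A medicines (default 1). The threshold is a
parameter, not a constant, because concomitant high-risk use is the norm
in this population (mean 3.8 category-A medicaments per patient) and
stricter cutoffs are the obvious subject for follow-up calibration. On the
5-point scale, 4 keeps its 4-item label and 5 maps to full risk — the
least inventive extension of the published label table, and documented
here as provisional.

## Cohort analytics and numerical conventions

Three denominators recur and are kept explicit everywhere: medicament
occurrences (a medicine counts each time it appears in a patient list —
1748 in the reference cohort), distinct substances (216), and distinct
users of an ingredient (a patient counts once however often they use it).
Duplicate list entries deliberately count twice at the medicament
denominator.

Rounding follows the conventions of published cohort tables: integer
percentages and one-decimal user percentages, both **round half away from
zero** (`round_half_up()`), which base R's `round()` (half-to-even) would
violate (e.g. 69/188 → 37, 49/188 → 26.1). Two published figures are
inconsistent with any consistent rounding of their own counts: 88/188
printed as 46% (round-half-up gives 47) and 85/216 printed as 40% (gives
39). The package reports the recomputed values and leaves both
discrepancies documented rather than patched; CSV outputs carry the
unrounded shares next to the display columns so downstream users are not
bound by either convention.

ATC roll-ups aggregate at level 1 (first letter), 2 (first three
characters) or 3 (first four); percentages are relative to the rolled-up
input (e.g. the 710 category-A medicaments), never the cohort. Top-FRID
rankings sort by distinct users, ties alphabetical.

## The reference cohort reconstruction

Patient-level study data are not deposited. `reference_cohort()` instead
builds, deterministically, a 188-patient cohort *exactly consistent* with
the published aggregates: each category-A ingredient is dealt to as many
distinct patients as its published user count, the published 331 B and
707 C occurrences are spread near-uniformly over the synthetic pools, and
occurrences are dealt round-robin so every patient holds 9–10 medicaments
(within the published 2–17 range). Admission items realize the published
score distribution (5, 17, 66, 69, 31 patients at scores 0–4), cycling
through the item combinations of each weight. Ages, stays and MMSE values
cycle through fixed in-range sequences — they satisfy validation, and are
not calibrated to the published means.

Aggregates that depend only on the published tables (category shares,
roll-up shares, user percentages, mean per-patient A burden, score
percentages) are invariant to these reconstruction choices. Aggregates
that depend on the joint patient-by-drug allocation — the per-patient
minimum, maximum and median category-A count — are properties of the
reconstruction, not estimates of the study's (which reported min 0, max 8,
median 3), and are neither asserted nor reported as such.

## The synthetic-cohort generator

`generate_cohort(simulation_config(...))` draws fully synthetic cohorts
for testing and power exploration. Defaults are the study marginals:
128/188 hospital; sex splits 67/128 and 18/60 male; age truncated
discretized normal with mean 79 on 60–97; medicaments per patient
truncated negative binomial with mean 9.3 on 2–17 (concurrent-medication
counts are over-dispersed; the dispersion is moment-matched to the range,
SD ≈ range/4, and the untruncated mean is solved by `uniroot()` so the
*truncated* mean hits the target); hospital MMSE mean 21.7 on 5–30;
hospital stay mean 15.8 days on 1–56; nursing-home stays `permanent`. The
published age SD (18.5) is inconsistent with the 60–97 range and is not
used; the default SD of 8 (and MMSE SD 6) are realistic values for a
geriatric inpatient cohort, chosen once.

Medications are sampled per patient without replacement, with category
weights proportional to the published medicament shares (710/331/707) and
within-A weights proportional to published user counts; B/C weights are
uniform over the synthetic pools — honest about what is and is not
published.

Only the marginal score distribution is published, so admission items are
generated independently per item, with probabilities chosen by
`calibrate_item_prevalences()` to minimize the total-variation distance
between the implied Poisson-binomial score distribution and the target
(L-BFGS-B on the unit cube; corner targets handled exactly). Independence
cannot fit every target — the achieved distance (≈ 0.04 for the default
target) is returned rather than hidden. Likewise the generator treats
score items and medication burden as independent, because their joint
distribution is unpublished; synthetic cohorts therefore cannot exhibit
confounding between frailty and polypharmacy, and passing tests on them
says nothing about such structure in real data.

Determinism: all sampling runs under `withr::with_seed()`, so a config
with a fixed seed reproduces byte-for-byte through `write_cohort()`, and
the caller's RNG state is untouched.

## Problem sizes and test design

The test suite checks the categorization engine exhaustively against an
independent row-by-row frequency-table oracle over all profiles of up to
four annotations (6^1 + … + 6^4 = 1554 cases), property-tests
monotonicity and permutation invariance on seeded random profiles, and
validates simulator parameter recovery at n = 2000 within three standard
errors — sizes at which the whole suite runs in about two minutes on one
core. Cohort-level checks run on the 188-patient reference
reconstruction.

## Limitations

* The categorization is frequency-class-only: no dose, duration or
  interaction modifiers, and no per-indication nuance.
* The packaged knowledge base covers only the medicines used in one
  188-patient cohort; it is a starting point, not a formulary-wide
  reference, and 91 of its 102 entries carry inferred placeholder
  annotations.
* The B/C pools are synthetic; substance-level B/C analyses on real
  cohorts require a user-supplied knowledge base.
* SmPC curation itself (parsing documents, cross-validating against
  similar products) is out of scope; the package starts from an already
  curated table.
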