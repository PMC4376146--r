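---
title: "Deterministic mother-child linkage: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic mother-child linkage: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairlink)
```

## The problem

Clinical data warehouses hold one record per patient and no explicit family
structure, so research that needs mother-child dyads (medication exposure in
pregnancy, familial disease clustering, recruitment of family cohorts) has
historically required manual chart review. `fairlink` implements a
deterministic two-step linkage over three identifiers that most warehouses
carry — insurance number, phone number and address — together with the
machinery needed to evaluate how well such a linkage performs: a
test-characteristics module, and a synthetic population generator whose
ground truth stands in for a chart audit.

## The algorithm

**Step 1 — candidate generation.** All three raw identifiers are
canonicalized (`normalize_insurance()`, `normalize_phone()`,
`normalize_address()`) and an inverted index maps each key to the patients
carrying it. Under a `match_strategy()` a candidate for child $c$ is any
other patient sharing at least one listed identifier key (`single`,
`any_of`) or every listed key (`all_of`). Matching is exact string equality
on canonical keys — deliberately not probabilistic. The method's errors are
then fully attributable to the data (shared family identifiers absent,
unrelated people sharing identifiers) rather than to a tunable score.

**Step 2 — mother classification.** Candidates are filtered to patients
recorded female whose age gap over the child lies in a configurable window,
15 to 50 completed years inclusive by default. If several remain, a
tie-break cascade prefers stronger evidence — candidates matching on both
insurance and phone, then insurance, then phone — and the oldest surviving
female is selected, which avoids picking an adult sibling who shares every
household identifier. A residual birth-date tie falls to the smallest
patient id so output is reproducible.

Ages are integer completed years at a fixed reference date, never
fractional. The gap window is inclusive at both ends; both bounds are
configurable because boundary handling is a convention, not a fact about
families.

### Tie-break semantics

A cascade stage keeps exactly the candidates whose *recorded shared
identifiers* contain the stage's whole set, and a stage that would eliminate
every candidate is skipped. Because a candidate's shared identifiers only
ever record identifiers the strategy listed, address never participates in
tie-breaking under the default cascade, and under a single-identifier
strategy the cascade degenerates gracefully to the oldest-female rule. This
realises "evaluate the cascade on the evidence the strategy considered"
without the classifier needing to know the strategy.

## Identifier normalization

* **Insurance.** Provider numbering schemes differ, so normalization is an
  ordered rule list (first matching pattern wins, with a mandatory
  catch-all). A family-plan rule strips the member suffix — text after the
  final delimiter, or a fixed-length tail — so mother and child share the
  account key. An `individual_unique` rule models safety-net plans
  (e.g. Medicaid) that number individuals: the whole string is the key, so
  family members never share it. This is the central socioeconomic failure
  mode of insurance matching: households on such plans are invisible to it.
* **Phone.** Strip non-digits, drop a single leading country-code `1` from
  an 11-digit string, require exactly 10 digits (US numbers; the default
  study population is a single US area code). Partial numbers become
  missing rather than partially matching.
* **Address.** Upper-case, strip punctuation, collapse whitespace, expand
  street-type abbreviations token-wise. Unit designators are kept verbatim
  when present and never imputed: two unit-less records for the same
  multi-unit building compare equal, which is precisely how such addresses
  produce false family matches. We deliberately do not attempt unit
  inference, USPS standardization or geocoding — the missing token is a
  property of the data the evaluation should expose, not repair.

Missing raw values always yield missing keys, and missing keys never match
anything.

## Evaluation conventions

`confusion()` scores one child at a time against the reference standard.
The default `per_child` convention assigns each child exactly one cell:

* child with an in-system mother: TP if linked to exactly her, else FN —
  including when the algorithm linked the *wrong* person;
* child without: FP if any link was emitted, else TN.

This is the convention under which a published strategy table's marginals
add up (TP+FN fixed at the number of with-mother children, TN+FP at the
rest, NPV denominator = TN + (with-mother − TP)). The `strict` mode
additionally counts a wrong-person link as an FP on top of the FN, the
common epidemiological reading; its cells then sum to more than the cohort
size. Both are exposed because the two conventions answer different
questions ("how often is the child handled correctly" vs "how often is an
emitted link wrong").

Undefined metrics (zero denominator) are reported `NA`, never 0. Printed
percentages round half away from zero — base R's banker's rounding would
turn 93.94% into 93% instead of 94%. Table-style output uses one decimal
for sensitivity, PPV and NPV and whole percent for specificity, matching
the typical clinical-informatics table.

The ROC output of `compare_strategies()` is a scatter of one operating
point per strategy. The strategies are not threshold-ordered, so no curve
is interpolated and no AUC is computed.

## The synthetic population

`simulate_population()` generates one household per index child and, with
probability `p_mother_in_system` (default 0.80), a record for the mother.
The generator reproduces the mechanisms that break deterministic family
linkage, each behind its own knob:

| Knob | Mechanism | Default |
|---|---|---|
| `p_safety_net_insurance` | individually numbered plans: no family insurance key | 0.25 |
| `p_family_insurance_number` | family account shared by mother and child (else individual commercial numbers) | 0.85 |
| `p_phone_churn` | mother's record carries an outdated number | 0.15 |
| `p_multi_unit` | household is in a multi-unit building | 0.30 |
| `p_unit_missing` | a record in such a building lacks the unit token | 0.40 |
| `p_stepmother` | female co-resident sharing phone and address | 0.05 |
| `n_decoy_households` | unrelated adult women per multi-unit building | 2 |

These defaults are order-of-magnitude choices: no measured rates exist for
the phenomena, so each was fixed once at a value plausible for a US
pediatric catchment with a sizeable safety-net population, and is not tuned
thereafter.
`study_like_config()` pins the *measured* marginals instead: 500 children,
80.2% mother prevalence, the study's five child age bands
(2.4/36/27.6/24.8/9.2%), and identifier availability of 96.6% (insurance),
100% (phone) and 99.4% (address).

The mother-child age gap is uniform over 16–45 completed years — strictly
inside the classifier's 15–50 window — so that, with all noise knobs at
zero, every miss would indicate a defect rather than a boundary effect.
Boundary stress-testing is done separately with hand-built fixtures.

Raw identifier strings are drawn from small fixed template sets (phone
punctuation variants, `ACCOUNT-NN` insurance shapes, abbreviated and
punctuated address spellings) so the normalizers are exercised realistically
rather than fed pre-canonical keys. All identifier pools are globally
unique by construction; households share keys only through the generative
mechanisms above, which makes closed-form expectations (perfect recovery at
zero noise; monotone degradation in each knob) exact rather than
approximate.

All randomness flows from one seed with a fixed draw order (child
demographics, household flags, availability, identifier pools, formatting
styles), so a configuration is a complete description of its population;
the generator restores the caller's RNG state.

### What the simulator does not model

No names, geography, clinical content, longitudinal records, fathers, or
full pedigrees; households are independent (no shared grandmothers across
households, no sibling index children); identifier errors are structural
(absent, churned, truncated) rather than typographical. Tests passing on
this population therefore demonstrate that the algorithm behaves as
specified under the documented mechanisms — not that the specific published
operating points would be reproduced on real warehouse data, which is
impossible without the original patient records. Accordingly the evaluation
asserts exact metric arithmetic on the published counts, and qualitative
mechanism properties (orderings, monotone degradation) on simulations.

## Numerical and degenerate-input choices

* Completed-years age uses calendar arithmetic (month/day comparison), not
  day counts divided by 365.25.
* Insurance stripping never produces an empty key; a value that is all
  suffix keeps its whole string.
* An empty candidate set, an empty cohort and an all-`none` reference are
  all valid inputs with well-defined outputs.
* Unknown sex codes map to `unknown`, never `female`, since only recorded
  females can be classified as mothers.
* Readers reject rows rather than silently dropping them: input rows always
  equal records plus reported rejects.

## Problem sizes used in the shipped tests

Oracle-equivalence checks run 20 seeded populations of 50–500 children
against an index-free all-pairs implementation; perfect-recovery checks use
ten 500-child populations; monotone-degradation checks use 2000 children
per configuration with two-standard-error tolerances per step, sizes at
which the binomial noise on a sensitivity step is below one percentage
point. Calibration checks compare ten 500-child study-like draws against
the target marginals at three binomial standard errors.

## Known limitations

* Exact-equality matching cannot tolerate typos; fuzzy or probabilistic
  (Fellegi–Sunter) linkage is out of scope by design.
* The classifier emits at most one mother per child and nothing else — no
  fathers, siblings or general pedigrees.
* `per_child` NPV inherits the reference standard's blind spots: a
  reference built by imperfect manual review understates the true number of
  in-system mothers, which biases NPV downward.
* The stepmother mechanism makes some wrong-person links *correct by
  household* but wrong biologically; no structured data distinguishes the
  two, and the package does not attempt to.
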