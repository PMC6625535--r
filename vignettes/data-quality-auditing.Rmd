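---
title: "Auditing juvenile-justice case extracts: conformance, completeness, plausibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing juvenile-justice case extracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jjdq)
```

## The problem

County juvenile courts record case processing in vendor case-management
systems (CMSs). Extracts from these systems are increasingly linked to
health records and other administrative data to study the health of
justice-involved youth — which assumes the justice data are trustworthy.
Unlike survey data, administrative extracts have no gold standard to
validate against: quality must be judged by triangulating within the
data themselves.

`jjdq` operationalises that triangulation for one common extract shape:
one row per arrest ("case"), with identifiers, demographics, and seven
decision points — diverted, detained, petitioned, adjudicated
delinquent, placed on probation, confined, waived to adult court — each
recorded as `yes`, `no` or missing. Three quality dimensions are
measured:

* **Conformance** — do the raw tokens fall in the permitted
  `yes`/`no`/missing vocabulary?
* **Completeness** — what percentage of cases is missing at each
  decision point?
* **Plausibility** — are the responses jointly believable within a case?

## The plausibility rules and first-error accounting

Five within-case patterns are treated as logical inconsistencies
(`rule_ids()`):

| rule | pattern | anchor |
|---|---|---|
| `inconsistent_petition` | diverted = yes and petitioned = yes | 3 |
| `implausible_case` | diverted = no and petitioned = no | 3 |
| `excess_information` | diverted = yes and any later point = yes | earliest offending yes (4–7) |
| `inconsistent_adjudication` | adjudicated = no and probation/confined = yes | earliest offending yes (5–6) |
| `inconsistent_waiver` | waived = yes and adjudicated/probation/confined = yes | 7 |

Three evaluation conventions matter and are fixed package-wide:

1. **Missing matches nothing.** A missing response satisfies neither a
   yes- nor a no-literal, so e.g. diverted = missing and petitioned = no
   fires no rule. The one documented exception is opt-in:
   `adjudication_missing_counts = TRUE` extends
   `inconsistent_adjudication` to a blank adjudication field, since in
   practice that error usually arises from an unfilled field. The
   default follows the printed rule (adjudicated = no) so that the
   completeness and plausibility dimensions stay independent.
2. **Detention participates in no rule.** A youth can be detained before
   or after any other point, so `detained` is order-exempt: it neither
   fires nor rescues any pattern (a courtesy detention does not make a
   no-diversion/no-petition case plausible).
3. **One error per case.** Decision-point fields are logically
   interdependent, so once one violation is found the rest of the case
   needs review anyway; counting every fired rule would double-count a
   single underlying error. Each case is therefore attributed only its
   *first* inconsistency in case chronology: the fired rule with the
   smallest anchor. The anchor is the canonical position of the decision
   point at which the pattern becomes detectable — both petition rules
   complete at `petitioned` (position 3), so a case that is both
   inconsistently petitioned and inconsistently waived is recorded as an
   inconsistent petition. Because the source convention defines "first
   in chronology" but not per-rule anchor positions, the anchors above
   are a package convention chosen to reproduce that worked example.
   Ties (only possible between `excess_information` and
   `inconsistent_adjudication`, co-anchored at the same offending
   disposition) are broken by the fixed priority order of `rule_ids()`,
   which keeps output deterministic.

The per-rule first-error categories partition the flagged cases, so
per-rule counts sum exactly to the "at least one inconsistency" count
before rounding. Percentages are rounded half away from zero to one
decimal for display; the partition identity is enforced on counts. (In
published tables of this kind the printed at-least-one row occasionally
differs from its column sum by 0.1 — a rounding artefact; the package
keeps the pre-rounding identity exact and the acceptance checks use
columns where rounding happens to be consistent.)

```{r}
case <- make_case(diverted = "yes", petitioned = "yes",
                  adjudicated = "yes", waived = "yes")
detect_all(case)[, c("rule", "anchor")]
first_inconsistency(case)$rule
```

## Parsing and conformance

The CSV contract fixes column names and order (see `read_extract()`).
The empty string is the canonical missing encoding; `yes`/`no`
(case-insensitive, trimmed) are the only conforming non-missing tokens.
Any other token is recorded verbatim as a conformance violation *and*
parsed to missing, so completeness and plausibility still run on the
affected case while the conformance report retains the raw evidence.
One consequence, stated rather than hidden: nonconforming cells count
as missing in the completeness profile. `write_extract()` re-inserts
recorded violation tokens, so read–write is an identity on records and
violations alike.

## Cleaning

Each rule has a menu of resolution scenarios (`resolution_strategies()`)
mirroring how flagged cases resolve when checked against court paper
files: an overturned diversion or a violated informal-adjustment
agreement for inconsistent petitions; a courtesy detention (excluded
from the county's case total) or a clerical error needing
full-chronology review for implausible cases; erroneously linked
subsequent arrests (cleared to missing) or a wrongly filled diversion
field for excess information; data-entry fixes for inconsistent
waivers; and back-filling the adjudication for inconsistent
adjudications.

Paper files are not available to software, so the scenario choice is a
declarative *policy*: a default strategy per rule plus per-case
overrides (`resolution_policy()`, YAML-serialisable). On synthetic data
`truth_policy()` replays the generator's injected scenarios, which makes
"post-cleaning" reproducible and lets tests assert exact contracts:

* the resolved rule never refires on the edited case;
* kept + excluded records = input records (conservation);
* cleaning is idempotent under a fixed policy (clerical cases persist,
  unedited and flagged, by design);
* the action log covers exactly the flagged, non-clerical cases
  (exclusions are logged; clerical no-ops are not).

An edit can surface a *different* pattern — `fix_diversion` on a
non-petitioned case yields the no-diversion/no-petition implausible
pattern — so a cleaned extract is re-audited rather than assumed
flag-free; post-cleaning percentages are genuinely nonzero in realistic
runs. Excluded courtesy detentions are dropped from the post-cleaning
denominator; the returned exclusion list keeps them available for
global conservation reporting.

## The synthetic generator

Real county extracts are confidential, so validation runs on a
generator (`generate_extract()`) whose defaults emulate the documented
shape of such data: four CMSs with very unequal caseloads (roughly
9%/5%/79%/6% of cases), three counties per CMS, about two-thirds male
cases, a race/ethnicity mix dominated by White and Black youths, ages
10–18 with mean near 15.3, a charge-severity mix led by serious
misdemeanors and status offenses, and `1 + Poisson(0.3)` arrests per
youth (multiple arrests per youth are documented; the count
distribution is not, so a shifted Poisson with mean 1.3 was chosen once
as a realistic default). All of these are configuration, not constants.

Cases start from four rule-free trajectory templates (diversion
terminal; petition → adjudication → probation/confinement; petition →
waiver; petition → allegations not true), fixed a priori — so the
"clean by construction" property test is independent of the detector it
checks. Corruption then proceeds in a fixed order chosen to keep the
ground-truth labels exact:

1. **Missingness** first: independent Bernoulli per (case, point) cell
   at the configured rate.
2. **Rule injection** on disjoint case subsets: per-rule case counts are
   drawn multinomially at the configured rates (so audited rates are
   binomial around them), then assigned to eligible cases — the right
   trajectory, with the needed cells non-missing. Each injection flips
   exactly one non-missing cell (inverting a cleaning strategy), so
   realised missingness marginals are untouched, every corruption is
   detectable (100% recall), and the injected rule is the case's first
   error. The excess-information scenario injected by the generator is
   `unlink` — the dominant real-world cause (erroneously linked
   subsequent arrests) and the only one whose corruption both leaves
   the planted rule first in chronology on a rule-free template and
   restores the original under its matching resolution. The
   `fix_diversion` strategy remains available to cleaning policies.
3. **Conformance noise** last, on uncorrupted cases only, drawing bad
   tokens from a small fixed vocabulary (`unknown`, `TRUE`, `y`) —
   membership, not content, is what matters.

Injection and resolution are inverse on the fields they touch;
field-exact for every scenario except `unlink`, which clears the
planted yes to missing (the unlinked information belongs to another
arrest) rather than back to `no`.

What the generator does *not* emulate — and hence what passing tests do
not establish about real extracts: systematic, CMS-specific missingness
(e.g. a vendor missing an entire field), correlation between charge
severity and trajectory, within-case timestamps (chronology is
structural, by canonical position), cross-case linkage errors beyond
the one-case excess pattern, and any real demographic joint
distribution (only marginals are controlled).

## Reporting

`build_report()` assembles a demographics table (counts and percentages
by gender, race/ethnicity, age with mean/SD, and charge severity, per
CMS), and completeness/plausibility tables with side-by-side pre- and
post-cleaning columns; a CMS with no post-cleaning audit renders blank
post cells, and a demographic dimension a CMS never supplied renders no
rows. Small-cell suppression protects against identification: any
nonzero demographic count below the threshold (default 10) displays as
`"<10"` with its percentage withheld; zeros are displayed, since only
small nonzero cells identify. Suppression applies to demographic cells
only — rule percentages are aggregate enough to print exactly.
Percent denominators are all cases in the CMS (missing responses appear
as an explicit `missing` category row), a documented choice in
preference to guessing per-dimension non-missing denominators.

## Numerical and degenerate-input conventions

* Percentages round half away from zero to one decimal (base `round()`
  rounds half to even, which does not match published tables of this
  kind).
* Completeness, audit, demographics: an empty extract is an explicit
  error, never 0/0.
* Ages outside 10–18 parse to missing; an age column that fails integer
  parsing likewise.
* `(case_id, extraction_phase)` must be unique; duplicate or missing
  header columns are schema errors naming the columns.

## Problem sizes used in validation

The exhaustive detector check covers all 3^7 = 2,187 tri-state
assignments against an independently written transcription of the rule
definitions. Rate-recovery checks run at about 10,000 cases with 5%
injection per rule and 10% missingness per point, asserting agreement
within three binomial standard errors; cleaning contracts at about
2,600 cases; the suppression invariant over 1,000 random small
extracts. Accounting checks replay county-sized extracts (1,474 and
12,662 cases) with fixed pattern counts. These sizes were chosen to
make binomial bounds tight while keeping the default validation run
fast on a laptop.

## Limitations

Within-case rules only: no cross-case sequencing (e.g. re-arrest order
within a youth) is audited. The CSV schema is a package convention —
vendor delivery formats vary and are adapted upstream. Resolution
correctness is relative to the supplied policy; the package cannot
infer the right scenario from narrative fields, which are out of scope.
Suppression is threshold-only, with no complementary suppression, so a
determined attacker combining tables could in principle recover a
suppressed cell from unsuppressed margins.
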