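# jjdq — data quality auditing for juvenile justice case extracts

Juvenile courts record case processing in vendor case-management
systems (CMSs). Before those extracts can be linked to health records
or used for oversight (detention reform, disproportionate-minority
contact reporting), their quality has to be measured — and there is no
gold standard to measure against, only the internal consistency of the
data themselves.

`jjdq` audits case-level CSV extracts — one row per arrest, with seven
decision points (diverted, detained, petitioned, adjudicated
delinquent, placed on probation, confined, waived) each recorded
yes/no/missing — along three dimensions:

* **conformance** — raw tokens outside the `yes`/`no`/missing
  vocabulary, captured verbatim at parse time;
* **completeness** — percent missing per decision point;
* **plausibility** — five within-case logical inconsistencies
  (e.g. *inconsistent petition*: diverted = yes ∧ petitioned = yes;
  *implausible case*: diverted = no ∧ petitioned = no). A missing value
  satisfies no rule literal, and detention is order-exempt.

Because decision-point fields are interdependent, each case is charged
with only its **first** inconsistency in case chronology (the fired
rule whose pattern completes at the earliest decision point), making
the per-rule categories a partition of flagged cases: per-rule counts
sum exactly to the "at least one inconsistency" count.

The package also applies rule-specific **cleaning strategies**
(overturn the diversion, exclude the courtesy detention, unlink the
erroneously attached arrest, back-fill the adjudication, …) under a
declarative policy, re-audits the result, and renders pre/post
comparison reports with small-cell suppression (`"<10"`) on
demographic tables. A **synthetic generator** with exact ground-truth
labels for injected missingness, rule patterns and bad tokens stands in
for the confidential county data and lets tests score detector recall
and first-error attribution exactly.

## Worked example

```r
library(jjdq)

cfg <- generator_config(
  n_youth = 800, seed = 2026,
  injection_rates = c(inconsistent_petition = 0.03, implausible_case = 0.08,
                      excess_information = 0.02,
                      inconsistent_adjudication = 0.05),
  missingness_rates = c(confined = 0.15, waived = 0.10)
)
g   <- generate_extract(cfg)
pre <- audit(g$extract)
pre
#> <jj_audit> 1007 cases [synthetic (seed 2026)]
#>   conformance violations: 0
#>   completeness (% missing):
#>     diverted       0.0
#>     detained       0.0
#>     petitioned     0.0
#>     adjudicated    0.0
#>     probation      0.0
#>     confined      16.1
#>     waived        11.6
#>   plausibility (first error per case):
#>     inconsistent_petition          33 (3.3%)
#>     implausible_case               90 (8.9%)
#>     excess_information             28 (2.8%)
#>     inconsistent_adjudication      47 (4.7%)
#>     inconsistent_waiver             0 (0.0%)
#>     at least one inconsistency    198 (19.7%)
```

The audited rates sit near the injected ones (3/8/2/5%), and the
completeness profile recovers the 15%/10% blanking of the confined and
waived fields. Cleaning with the generator's true scenarios resolves
what is resolvable — courtesy detentions are excluded from the county
denominators, clerical cases stay flagged pending review:

```r
cleaned <- clean_extract(g$extract, pre, truth_policy(g$truth))
post    <- audit(cleaned$post)
c(kept = n_cases(cleaned$post), excluded = nrow(cleaned$excluded))
#>     kept excluded
#>      955       52
post$at_least_one
#> $count
#> [1] 38
#> $pct
#> [1] 4

dplyr::filter(comparison_tables(pre, post)$plausibility, cms_id == "CMS3")
#> # A tibble: 6 × 4
#>   rule                      cms_id   pre  post
#>   <chr>                     <chr>  <dbl> <dbl>
#> 1 inconsistent_petition     CMS3     3.6   0
#> 2 implausible_case          CMS3     8.5   3.2
#> 3 excess_information        CMS3     2.5   0
#> 4 inconsistent_adjudication CMS3     4.9   0
#> 5 inconsistent_waiver       CMS3     0     0
#> 6 at_least_one              CMS3    19.6   3.2
```

The residual 3.2% are the clerical implausible cases, which no field
edit can honestly resolve. `build_report()` + `render_report()` write
the demographics/completeness/plausibility tables as CSV and JSON.

The same pipeline is available from a shell:

```sh
jjdq=$(Rscript -e 'cat(system.file("cli", "jjdq", package = "jjdq"))')
Rscript $jjdq simulate --out-dir run --seed 7
Rscript $jjdq audit    --input run/extract_pre.csv --out run/audit.json
Rscript $jjdq clean    --input run/extract_pre.csv --out-dir run
Rscript $jjdq report   --input run/extract_pre.csv \
                       --post run/extract_post.csv --out-dir run
```

## Vignette

`vignettes/data-quality-auditing.Rmd` documents the rule semantics
(anchors, tie-breaks, missing-value handling), the cleaning scenarios,
what the generator does and does not emulate, and the package's
numerical conventions.
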