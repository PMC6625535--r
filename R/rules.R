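#' Plausibility rules
#'
#' Five within-case logical inconsistencies violate data plausibility.
#' Writing D, P, A for the diverted/petitioned/adjudicated fields:
#'
#' * `inconsistent_petition` — yes to diverted and yes to petitioned
#'   (a diverted case should never reach formal court processing).
#' * `implausible_case` — no to diverted and no to petitioned (every
#'   real case is one or the other; the classic cause is a courtesy
#'   detention held for another county).
#' * `excess_information` — yes to diverted and yes to any subsequent
#'   decision point (adjudicated, probation, confined or waived):
#'   diversion should be the last decision point on its arrest.
#' * `inconsistent_waiver` — yes to waived and yes to any of
#'   adjudicated, probation or confined: a waived case has no further
#'   juvenile-court activity.
#' * `inconsistent_adjudication` — no to adjudicated delinquent and yes
#'   to probation or confined: no formal disposition without an
#'   adjudication.
#'
#' A missing value matches neither yes nor no, so it never satisfies a
#' rule literal; the order-exempt detained field participates in no rule.
#'
#' Each fired rule carries an *anchor*: the canonical position of the
#' decision point at which the pattern first becomes detectable in case
#' chronology. Both petition rules complete at `petitioned` (position 3);
#' `excess_information` and `inconsistent_adjudication` anchor at the
#' earliest offending subsequent yes; `inconsistent_waiver` anchors at
#' `waived` (position 7).
#'
#' @return `rule_ids()` returns the five rule identifiers in tie-break
#'   priority order (the order used to break equal anchors).
#' @examples
#' rule_ids()
#' @export
rule_ids <- function() RULE_IDS

RULE_IDS <- c(
  "inconsistent_petition",
  "implausible_case",
  "excess_information",
  "inconsistent_adjudication",
  "inconsistent_waiver"
)

# Tie-break priority at equal anchors, smaller wins. Petition vs
# implausible are mutually exclusive by construction; the ordering
# matters only for excess vs adjudication co-anchored cases.
RULE_PRIORITY <- stats::setNames(seq_along(RULE_IDS), RULE_IDS)

is_yes <- function(x) !is.na(x) & x == "yes"
is_no <- function(x) !is.na(x) & x == "no"

# Vectorised rule evaluation over a records tibble. Returns a tibble of
# every fired (row, rule) pair with its anchor and priority rank.
detect_flags_records <- function(rec, adjudication_missing_counts = FALSE) {
  dv <- rec$diverted; pt <- rec$petitioned; ad <- rec$adjudicated
  pb <- rec$probation; cf <- rec$confined; wv <- rec$waived
  n <- nrow(rec)

  # anchor of the earliest yes among candidate columns (positions pos)
  earliest_yes <- function(cols, pos) {
    anchor <- rep(NA_integer_, n)
    for (i in rev(seq_along(cols))) {
      anchor[is_yes(cols[[i]])] <- pos[i]
    }
    anchor
  }

  adj_no <- if (adjudication_missing_counts) is_no(ad) | is.na(ad) else is_no(ad)

  fired <- list(
    inconsistent_petition = list(
      hit = is_yes(dv) & is_yes(pt),
      anchor = rep(point_position("petitioned"), n)
    ),
    implausible_case = list(
      hit = is_no(dv) & is_no(pt),
      anchor = rep(point_position("petitioned"), n)
    ),
    excess_information = list(
      hit = is_yes(dv) & (is_yes(ad) | is_yes(pb) | is_yes(cf) | is_yes(wv)),
      anchor = earliest_yes(list(ad, pb, cf, wv), 4:7)
    ),
    inconsistent_adjudication = list(
      hit = adj_no & (is_yes(pb) | is_yes(cf)),
      anchor = earliest_yes(list(pb, cf), 5:6)
    ),
    inconsistent_waiver = list(
      hit = is_yes(wv) & (is_yes(ad) | is_yes(pb) | is_yes(cf)),
      anchor = rep(point_position("waived"), n)
    )
  )

  out <- lapply(names(fired), function(r) {
    hit <- fired[[r]]$hit
    tibble::tibble(
      row = which(hit),
      rule = r,
      anchor = fired[[r]]$anchor[hit],
      priority = RULE_PRIORITY[[r]]
    )
  })
  dplyr::bind_rows(out)
}

rule_involved_points <- function(rule, case) {
  offending <- function(cols) {
    cols[vapply(cols, function(p) is_yes(case[[p]]), logical(1))]
  }
  switch(rule,
    inconsistent_petition = c("diverted", "petitioned"),
    implausible_case = c("diverted", "petitioned"),
    excess_information = c(
      "diverted", offending(c("adjudicated", "probation", "confined", "waived"))
    ),
    inconsistent_waiver = c(
      "waived", offending(c("adjudicated", "probation", "confined"))
    ),
    inconsistent_adjudication = c(
      "adjudicated", offending(c("probation", "confined"))
    ),
    abort_jjdq(paste0("unknown rule: ", rule), "jjdq_rule_error")
  )
}

as_case_row <- function(case) {
  if (inherits(case, "jj_extract")) case <- case$records
  case <- tibble::as_tibble(case)
  if (nrow(case) != 1) {
    abort_jjdq("expected a single case record", "jjdq_domain_error")
  }
  case
}

#' Detect every fired plausibility rule on one case
#'
#' Evaluates all five rule predicates on a single case record and returns
#' every rule whose pattern holds, regardless of chronology. Use
#' [first_inconsistency()] for the one-error-per-case accounting.
#'
#' @param case a one-row records tibble (or one-case `jj_extract`).
#' @param adjudication_missing_counts if `TRUE`, `inconsistent_adjudication`
#'   also fires when the adjudication field is missing rather than "no"
#'   (the blank-field reading of that error); default `FALSE` follows the
#'   printed rule definition.
#' @return tibble with columns `rule`, `anchor` and list-column
#'   `involved_points`; zero rows when no rule fires.
#' @examples
#' case <- make_case(diverted = "yes", petitioned = "yes")
#' detect_all(case)$rule
#' @export
detect_all <- function(case, adjudication_missing_counts = FALSE) {
  case <- as_case_row(case)
  flags <- detect_flags_records(case, adjudication_missing_counts)
  flags <- flags[order(flags$anchor, flags$priority), ]
  tibble::tibble(
    rule = flags$rule,
    anchor = flags$anchor,
    involved_points = lapply(flags$rule, rule_involved_points, case = case)
  )
}

#' First inconsistency in case chronology
#'
#' Although a case may exhibit several inconsistencies, only one error is
#' recorded per case: the fired rule whose pattern occurs earliest in the
#' case chronology (smallest anchor position). A case firing both an
#' inconsistent petition (anchor 3) and an inconsistent waiver (anchor 7)
#' is therefore recorded as an inconsistent petition. Equal anchors are
#' broken by the fixed priority of [rule_ids()].
#'
#' @inheritParams detect_all
#' @return one-row tibble (`rule`, `anchor`, `involved_points`), or `NULL`
#'   when no rule fires.
#' @export
first_inconsistency <- function(case, adjudication_missing_counts = FALSE) {
  all <- detect_all(case, adjudication_missing_counts)
  if (nrow(all) == 0) {
    return(NULL)
  }
  all[1, ]
}

#' Conformance report for an extract
#'
#' Data conformance asks whether recorded decision-point responses fall
#' within the permitted yes/no/missing vocabulary. Violations are captured
#' verbatim at parse time ([read_extract()]); this returns them itemised
#' and grouped by field.
#'
#' @param extract a `jj_extract`.
#' @return list with `count` (total nonconforming raw tokens), `by_field`
#'   (tibble `field`, `n`) and `violations` (the itemised tibble).
#' @export
check_conformance <- function(extract) {
  stopifnot(inherits(extract, "jj_extract"))
  v <- extract$violations
  by_field <- dplyr::count(v, .data$field, name = "n")
  list(count = nrow(v), by_field = by_field, violations = v)
}

#' Completeness profile of an extract
#'
#' Data completeness is reported as the percentage of cases in which
#' "missing" was recorded at each decision point, to one decimal.
#' Nonconforming tokens parse to missing and therefore count as missing
#' here; they are reported separately by [check_conformance()].
#'
#' @param extract a `jj_extract` with at least one case.
#' @return named numeric vector, one percentage per decision point.
#' @export
completeness_profile <- function(extract) {
  stopifnot(inherits(extract, "jj_extract"))
  rec <- extract$records
  if (nrow(rec) == 0) {
    abort_jjdq("completeness is undefined on an empty extract",
               "jjdq_empty_error")
  }
  vapply(
    rec[DECISION_POINTS],
    function(col) pct1(sum(is.na(col)), nrow(rec)),
    numeric(1)
  )
}

#' Audit an extract
#'
#' Runs the full data-quality audit on one extract: conformance count,
#' per-point completeness, and per-case first-inconsistency assignment
#' with per-rule tallies. The per-rule categories partition the flagged
#' cases (each flagged case is counted under exactly one rule — its first
#' error), so per-rule counts sum exactly to the "at least one
#' inconsistency" count. Percentages are rounded half-up to one decimal;
#' counts are kept so identities can be checked pre-rounding.
#'
#' @param extract a nonempty `jj_extract`.
#' @param adjudication_missing_counts see [detect_all()].
#' @return a `jj_audit` object: list with `n_cases`, `provenance`,
#'   `completeness`, `completeness_by_cms`, `first_error` (tibble
#'   `case_id`, `cms_id`, `rule`, `anchor`), `per_rule` (tibble `rule`,
#'   `count`, `pct`), `per_rule_by_cms`, `at_least_one` (`count`, `pct`),
#'   `at_least_one_by_cms`, `conformance` and `cms_n` (cases per CMS).
#' @examples
#' ex <- generate_extract(generator_config(n_youth = 50, seed = 42,
#'   injection_rates = c(implausible_case = 0.1)))$extract
#' a <- audit(ex)
#' a$at_least_one
#' @export
audit <- function(extract, adjudication_missing_counts = FALSE) {
  stopifnot(inherits(extract, "jj_extract"))
  rec <- extract$records
  if (nrow(rec) == 0) {
    abort_jjdq("audit is undefined on an empty extract", "jjdq_empty_error")
  }
  n <- nrow(rec)
  flags <- detect_flags_records(rec, adjudication_missing_counts)
  first <- flags |>
    dplyr::arrange(.data$row, .data$anchor, .data$priority) |>
    dplyr::distinct(.data$row, .keep_all = TRUE)
  first_error <- tibble::tibble(
    case_id = rec$case_id[first$row],
    cms_id = rec$cms_id[first$row],
    rule = first$rule,
    anchor = first$anchor
  )

  per_rule <- tibble::tibble(rule = RULE_IDS) |>
    dplyr::left_join(
      dplyr::count(first_error, .data$rule, name = "count"),
      by = "rule"
    ) |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      pct = pct1(.data$count, n)
    )

  cms_n <- dplyr::count(rec, .data$cms_id, name = "n_cases")
  per_rule_by_cms <- tidyr::expand_grid(
    cms_id = cms_n$cms_id, rule = RULE_IDS
  ) |>
    dplyr::left_join(
      dplyr::count(first_error, .data$cms_id, .data$rule, name = "count"),
      by = c("cms_id", "rule")
    ) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::left_join(cms_n, by = "cms_id") |>
    dplyr::mutate(pct = pct1(.data$count, .data$n_cases)) |>
    dplyr::select(-"n_cases")

  at_least_one_by_cms <- per_rule_by_cms |>
    dplyr::group_by(.data$cms_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::left_join(cms_n, by = "cms_id") |>
    dplyr::mutate(pct = pct1(.data$count, .data$n_cases)) |>
    dplyr::select(-"n_cases")

  completeness_by_cms <- rec |>
    dplyr::group_by(.data$cms_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(DECISION_POINTS), ~ sum(is.na(.x))),
      n_cases = dplyr::n(), .groups = "drop"
    ) |>
    tidyr::pivot_longer(
      dplyr::all_of(DECISION_POINTS),
      names_to = "point", values_to = "n_missing"
    ) |>
    dplyr::mutate(pct = pct1(.data$n_missing, .data$n_cases)) |>
    dplyr::select("cms_id", "point", "n_missing", "pct")

  structure(
    list(
      n_cases = n,
      provenance = extract$provenance,
      completeness = completeness_profile(extract),
      completeness_by_cms = completeness_by_cms,
      first_error = first_error,
      per_rule = per_rule,
      per_rule_by_cms = per_rule_by_cms,
      at_least_one = list(
        count = nrow(first_error), pct = pct1(nrow(first_error), n)
      ),
      at_least_one_by_cms = at_least_one_by_cms,
      conformance = check_conformance(extract)[c("count", "by_field")],
      cms_n = cms_n,
      adjudication_missing_counts = adjudication_missing_counts
    ),
    class = "jj_audit"
  )
}

#' @export
print.jj_audit <- function(x, ...) {
  cat("<jj_audit> ", x$n_cases, " cases",
      if (nzchar(x$provenance %||% "")) paste0(" [", x$provenance, "]"),
      "\n", sep = "")
  cat("  conformance violations: ", x$conformance$count, "\n", sep = "")
  cat("  completeness (% missing):\n")
  for (p in DECISION_POINTS) {
    cat(sprintf("    %-12s %5.1f\n", p, x$completeness[[p]]))
  }
  cat("  plausibility (first error per case):\n")
  for (i in seq_len(nrow(x$per_rule))) {
    cat(sprintf("    %-26s %6d (%.1f%%)\n", x$per_rule$rule[i],
                x$per_rule$count[i], x$per_rule$pct[i]))
  }
  cat(sprintf("    %-26s %6d (%.1f%%)\n", "at least one inconsistency",
              x$at_least_one$count, x$at_least_one$pct))
  invisible(x)
}

#' Serialise an audit as JSON
#'
#' @param audit a `jj_audit`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly, when `path` is given).
#' @export
audit_json <- function(audit, path = NULL) {
  stopifnot(inherits(audit, "jj_audit"))
  per_rule <- lapply(seq_len(nrow(audit$per_rule)), function(i) {
    list(count = audit$per_rule$count[i], pct = audit$per_rule$pct[i])
  })
  names(per_rule) <- audit$per_rule$rule
  obj <- list(
    n_cases = audit$n_cases,
    completeness = as.list(audit$completeness),
    per_rule = per_rule,
    at_least_one = audit$at_least_one,
    conformance = audit$conformance$count
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}
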