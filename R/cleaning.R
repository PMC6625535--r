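#' Resolution strategies per rule
#'
#' Each plausibility rule admits the correction scenarios observed when
#' flagged cases are checked against paper court files:
#'
#' * `inconsistent_petition`: `overturned` — the early diversion was
#'   overturned by the prosecutor, who then filed a petition (set
#'   diverted = no, petitioned = yes); `violated_agreement` — the youth
#'   violated a condition of an informal adjustment (set diverted = yes,
#'   petitioned = no).
#' * `implausible_case`: `courtesy_detention` — the case was processed in
#'   another jurisdiction, so it is excluded from the county's case total;
#'   `clerical` — a county-wide clerical error needing full-chronology
#'   review: values are left in place and the case stays flagged.
#' * `excess_information`: `unlink` — the subsequent yes values belong to
#'   other arrests erroneously linked to the diversion and are cleared to
#'   missing; `fix_diversion` — the diversion field itself was wrong (set
#'   diverted = no).
#' * `inconsistent_waiver`: `fix` — data-entry correction setting the
#'   offending subsequent yes values to no.
#' * `inconsistent_adjudication`: `backfill` — the adjudication field was
#'   left blank or mis-keyed while later decisions reflect the true
#'   outcome (set adjudicated = yes).
#'
#' @return named list: rule id -> character vector of strategy names.
#' @export
resolution_strategies <- function() RULE_STRATEGIES

RULE_STRATEGIES <- list(
  inconsistent_petition = c("overturned", "violated_agreement"),
  implausible_case = c("courtesy_detention", "clerical"),
  excess_information = c("unlink", "fix_diversion"),
  inconsistent_waiver = c("fix"),
  inconsistent_adjudication = c("backfill")
)

DEFAULT_STRATEGIES <- c(
  inconsistent_petition = "overturned",
  implausible_case = "courtesy_detention",
  excess_information = "unlink",
  inconsistent_waiver = "fix",
  inconsistent_adjudication = "backfill"
)

#' Build a resolution policy
#'
#' The correct scenario for a flagged case lives outside the extract (in
#' court paper files); a policy is the declarative stand-in: a default
#' strategy per rule, optionally overridden per case. For synthetic data,
#' [truth_policy()] derives the overrides from the generator's injected
#' ground truth.
#'
#' @param defaults named character vector, rule id -> strategy; missing
#'   rules fall back to the package defaults shown in
#'   [resolution_strategies()].
#' @param overrides named character vector, case_id -> strategy.
#' @return a `jj_policy` object.
#' @export
resolution_policy <- function(defaults = character(), overrides = character()) {
  defaults <- utils::modifyList(as.list(DEFAULT_STRATEGIES), as.list(defaults))
  defaults <- unlist(defaults)[RULE_IDS]
  for (r in RULE_IDS) {
    if (!is.na(defaults[[r]]) && !defaults[[r]] %in% RULE_STRATEGIES[[r]]) {
      abort_jjdq(
        paste0("strategy '", defaults[[r]], "' is not in the menu for rule '",
               r, "' (", paste(RULE_STRATEGIES[[r]], collapse = ", "), ")"),
        "jjdq_policy_error"
      )
    }
  }
  structure(
    list(defaults = defaults, overrides = unlist(as.list(overrides))),
    class = "jj_policy"
  )
}

#' Derive a per-case policy from synthetic ground truth
#'
#' @param truth the `truth` element returned by [generate_extract()].
#' @return a `jj_policy` whose overrides replay each injected scenario.
#' @export
truth_policy <- function(truth) {
  corrupted <- truth$cases[!is.na(truth$cases$injected_rule), ]
  resolution_policy(
    overrides = stats::setNames(corrupted$injected_scenario, corrupted$case_id)
  )
}

#' Read / write a policy as YAML
#'
#' @param path YAML file with optional `defaults` and `overrides` maps.
#' @return `read_policy()` a `jj_policy`; `write_policy()` the path,
#'   invisibly.
#' @export
read_policy <- function(path) {
  y <- yaml::read_yaml(path)
  resolution_policy(
    defaults = unlist(y$defaults %||% list()),
    overrides = unlist(y$overrides %||% list())
  )
}

#' @rdname read_policy
#' @param policy a `jj_policy`.
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "jj_policy"))
  yaml::write_yaml(
    list(defaults = as.list(policy$defaults),
         overrides = as.list(policy$overrides)),
    path
  )
  invisible(path)
}

policy_strategy <- function(policy, case_id, rule) {
  strategy <- policy$overrides[[case_id]] %||% policy$defaults[[rule]]
  if (is.null(strategy) || is.na(strategy)) {
    abort_jjdq(paste0("policy supplies no strategy for rule '", rule, "'"),
               "jjdq_policy_error")
  }
  if (!strategy %in% RULE_STRATEGIES[[rule]]) {
    abort_jjdq(
      paste0("strategy '", strategy, "' is not in the menu for rule '", rule,
             "' (case ", case_id, ")"),
      "jjdq_policy_error"
    )
  }
  strategy
}

#' Resolve one flagged case
#'
#' Applies the policy's strategy for the case's first inconsistency and
#' returns the edited record (or an exclusion) together with the logged
#' cleaning action. After resolution the resolved rule no longer fires on
#' the returned record; note that an edit can create a *different*
#' pattern (e.g. `fix_diversion` on a non-petitioned case yields the
#' no-diversion/no-petition implausible-case pattern), which is why
#' cleaned extracts are re-audited rather than assumed flag-free.
#'
#' @param case one-row records tibble.
#' @param flag the case's first inconsistency, as returned by
#'   [first_inconsistency()].
#' @param policy a `jj_policy`.
#' @return list with `record` (one-row tibble, or `NULL` when the case is
#'   excluded), `excluded` (logical), `unresolved` (logical; `TRUE` for
#'   the clerical strategy, which leaves the case flagged) and `action`
#'   (tibble `case_id`, `rule`, `strategy`, `field`, `old`, `new`,
#'   `excluded`; zero rows for clerical).
#' @export
resolve_case <- function(case, flag, policy) {
  case <- as_case_row(case)
  if (is.null(flag) || nrow(flag) == 0) {
    abort_jjdq("resolve_case requires a fired inconsistency flag",
               "jjdq_policy_error")
  }
  rule <- flag$rule[[1]]
  strategy <- policy_strategy(policy, case$case_id, rule)

  edits <- character()  # point -> new value; NA value = set missing
  excluded <- FALSE
  unresolved <- FALSE
  offending_yes <- function(points) {
    points[vapply(points, function(p) is_yes(case[[p]]), logical(1))]
  }
  set_to <- function(points, value) {
    stats::setNames(rep(value, length(points)), points)
  }

  if (rule == "inconsistent_petition" && strategy == "overturned") {
    edits <- c(diverted = "no", petitioned = "yes")
  } else if (rule == "inconsistent_petition" && strategy == "violated_agreement") {
    edits <- c(diverted = "yes", petitioned = "no")
  } else if (rule == "implausible_case" && strategy == "courtesy_detention") {
    excluded <- TRUE
  } else if (rule == "implausible_case" && strategy == "clerical") {
    unresolved <- TRUE
  } else if (rule == "excess_information" && strategy == "unlink") {
    edits <- set_to(
      offending_yes(c("adjudicated", "probation", "confined", "waived")),
      NA_character_
    )
  } else if (rule == "excess_information" && strategy == "fix_diversion") {
    edits <- c(diverted = "no")
  } else if (rule == "inconsistent_waiver" && strategy == "fix") {
    edits <- set_to(
      offending_yes(c("adjudicated", "probation", "confined")), "no"
    )
  } else if (rule == "inconsistent_adjudication" && strategy == "backfill") {
    edits <- c(adjudicated = "yes")
  }

  record <- case
  action_rows <- list()
  if (excluded) {
    record <- NULL
    action_rows[[1]] <- tibble::tibble(
      case_id = case$case_id, rule = rule, strategy = strategy,
      field = NA_character_, old = NA_character_, new = NA_character_,
      excluded = TRUE
    )
  } else if (!unresolved && length(edits) > 0) {
    for (p in names(edits)) {
      old <- record[[p]]
      record[[p]] <- unname(edits[[p]])
      action_rows[[length(action_rows) + 1]] <- tibble::tibble(
        case_id = case$case_id, rule = rule, strategy = strategy,
        field = p, old = old, new = unname(edits[[p]]), excluded = FALSE
      )
    }
  }
  action <- if (length(action_rows) > 0) {
    dplyr::bind_rows(action_rows)
  } else {
    empty_actions()
  }
  list(record = record, excluded = excluded, unresolved = unresolved,
       action = action)
}

empty_actions <- function() {
  tibble::tibble(
    case_id = character(), rule = character(), strategy = character(),
    field = character(), old = character(), new = character(),
    excluded = logical()
  )
}

#' Clean an extract
#'
#' Applies the policy to every case flagged in the audit, emulating the
#' corrected second extraction: field-level corrections for resolvable
#' scenarios, county-denominator exclusion for courtesy detentions, and
#' no-ops for clerical cases awaiting full-chronology review. Record
#' conservation holds by construction: kept + excluded = input.
#'
#' @param extract the audited `jj_extract`.
#' @param audit the [audit()] of `extract`.
#' @param policy a `jj_policy`.
#' @return list with `post` (a `jj_extract` re-tagged `POST`), `excluded`
#'   (records tibble of courtesy-detention exclusions) and `actions` (the
#'   action log; covers exactly the flagged, non-clerical cases).
#' @examples
#' g <- generate_extract(generator_config(n_youth = 80, seed = 7,
#'   injection_rates = c(inconsistent_adjudication = 0.1)))
#' pre <- audit(g$extract)
#' cleaned <- clean_extract(g$extract, pre, truth_policy(g$truth))
#' audit(cleaned$post)$at_least_one$count <= pre$at_least_one$count
#' @export
clean_extract <- function(extract, audit, policy) {
  stopifnot(inherits(extract, "jj_extract"), inherits(audit, "jj_audit"),
            inherits(policy, "jj_policy"))
  if (audit$n_cases != nrow(extract$records)) {
    abort_jjdq("audit does not match extract (case counts differ)",
               "jjdq_policy_error")
  }
  rec <- extract$records
  flagged <- audit$first_error
  drop_rows <- integer()
  edited_cells <- list()
  actions <- list()

  for (i in seq_len(nrow(flagged))) {
    row <- match(flagged$case_id[i], rec$case_id)
    res <- resolve_case(rec[row, ], flagged[i, ], policy)
    if (res$excluded) {
      drop_rows <- c(drop_rows, row)
    } else if (!res$unresolved) {
      for (p in res$action$field) {
        rec[[p]][row] <- res$action$new[res$action$field == p]
        edited_cells[[length(edited_cells) + 1]] <-
          tibble::tibble(row = row, field = p)
      }
    }
    actions[[length(actions) + 1]] <- res$action
  }
  actions <- if (length(actions) > 0) dplyr::bind_rows(actions) else empty_actions()

  # carry conformance violations for kept rows, remapping row indices and
  # dropping any whose cell a cleaning edit has since rewritten
  v <- extract$violations
  if (length(edited_cells) > 0 && nrow(v) > 0) {
    ed <- dplyr::bind_rows(edited_cells)
    v <- dplyr::anti_join(v, ed, by = c("row", "field"))
  }
  keep <- setdiff(seq_len(nrow(rec)), drop_rows)
  if (nrow(v) > 0) {
    v <- v[v$row %in% keep, , drop = FALSE]
    v$row <- match(v$row, keep)
  }

  post_rec <- rec[keep, , drop = FALSE]
  post_rec$extraction_phase <- "POST"
  post <- new_extract(
    post_rec,
    provenance = paste0(extract$provenance,
                        if (nzchar(extract$provenance)) " " , "[cleaned]"),
    violations = v
  )
  list(post = post, excluded = extract$records[drop_rows, , drop = FALSE],
       actions = actions)
}

#' Write a cleaning action log as CSV
#'
#' @param actions the `actions` tibble from [clean_extract()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_actions <- function(actions, path) {
  out <- dplyr::mutate(actions, dplyr::across(
    dplyr::where(is.character), ~ ifelse(is.na(.x), "", .x)
  ))
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
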