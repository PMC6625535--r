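#' Configure the synthetic extract generator
#'
#' Builds a validated configuration for [generate_extract()]. Defaults
#' emulate the shape of real county case-management extracts: a handful
#' of youths contribute several arrests each, four CMS vendors of very
#' different sizes, demographic marginals resembling published
#' juvenile-court case descriptions (about two-thirds male, mean age a
#' little over 15), and four clean case trajectories through the seven
#' decision points. Missingness, rule-pattern corruption and
#' nonconforming raw tokens are injected at configurable rates, each with
#' exact ground-truth labels.
#'
#' @param n_youth number of youths; each contributes `1 + Poisson(mean-1)`
#'   arrests.
#' @param arrests_per_youth_mean mean arrests per youth (>= 1).
#' @param cms_mix probability vector over the four CMS labels.
#' @param gender_marginal,race_marginal,age_marginal,severity_marginal
#'   named probability vectors for the demographic dimensions.
#' @param trajectory_mix probability vector over the four clean
#'   trajectories `diversion_terminal`, `petition_path`,
#'   `waiver_terminal`, `not_true_path` (see [sample_trajectory()]).
#' @param detention_prob probability a case includes a detention stay
#'   (detention is order-exempt and independent of the trajectory).
#' @param probation_prob within `petition_path`, probability the
#'   disposition is probation rather than confinement.
#' @param missingness_rates named per-point probabilities of blanking a
#'   response (independent per cell).
#' @param injection_rates named per-rule corruption probabilities;
#'   corrupted subsets are disjoint (one injected rule per case) and must
#'   sum to at most 1.
#' @param conformance_noise_rate per-cell probability of replacing a
#'   decision-point token with a nonconforming one (only on uncorrupted
#'   cases, so injected patterns stay detectable).
#' @param seed integer seed; generation is fully reproducible.
#' @return a validated `jj_generator_config` list.
#' @export
generator_config <- function(
    n_youth = 1000,
    arrests_per_youth_mean = 1.3,
    cms_mix = c(CMS1 = 0.092, CMS2 = 0.054, CMS3 = 0.791, CMS4 = 0.063),
    gender_marginal = c(male = 0.67, female = 0.33),
    race_marginal = c(
      "African American/Black" = 0.300, "Asian" = 0.006,
      "Hawaiian/Pacific Islander" = 0.001, "Hispanic/Latino" = 0.049,
      "Native American or Native Alaskan" = 0.002, "White" = 0.559,
      "Other" = 0.083
    ),
    age_marginal = c(
      "10" = 0.008, "11" = 0.018, "12" = 0.040, "13" = 0.080, "14" = 0.141,
      "15" = 0.195, "16" = 0.252, "17" = 0.253, "18" = 0.013
    ),
    severity_marginal = c(
      "Felony A" = 0.002, "Felony B" = 0.020, "Felony C" = 0.020,
      "Felony D" = 0.128, "Misdemeanor A" = 0.247, "Misdemeanor B" = 0.143,
      "Misdemeanor C" = 0.018, "Status Offense" = 0.207,
      "Violation of Probation" = 0.215
    ),
    trajectory_mix = c(
      diversion_terminal = 0.30, petition_path = 0.40,
      waiver_terminal = 0.10, not_true_path = 0.20
    ),
    detention_prob = 0.30,
    probation_prob = 0.70,
    missingness_rates = stats::setNames(rep(0, 7), DECISION_POINTS),
    injection_rates = stats::setNames(rep(0, 5), RULE_IDS),
    conformance_noise_rate = 0,
    seed = 1L) {
  cfg <- list(
    n_youth = n_youth,
    arrests_per_youth_mean = arrests_per_youth_mean,
    cms_mix = cms_mix,
    gender_marginal = gender_marginal,
    race_marginal = race_marginal,
    age_marginal = age_marginal,
    severity_marginal = severity_marginal,
    trajectory_mix = trajectory_mix,
    detention_prob = detention_prob,
    probation_prob = probation_prob,
    missingness_rates = fill_named(missingness_rates, DECISION_POINTS, 0),
    injection_rates = fill_named(injection_rates, RULE_IDS, 0),
    conformance_noise_rate = conformance_noise_rate,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "jj_generator_config")
}

fill_named <- function(x, levels, default) {
  out <- stats::setNames(rep(default, length(levels)), levels)
  if (length(x) > 0) {
    unknown <- setdiff(names(x), levels)
    if (length(unknown) > 0) {
      abort_jjdq(paste0("unknown name(s): ", paste(unknown, collapse = ", ")),
                 "jjdq_config_error")
    }
    out[names(x)] <- x
  }
  out
}

validate_generator_config <- function(cfg) {
  fail <- function(field, msg) {
    abort_jjdq(paste0("invalid generator config field '", field, "': ", msg),
               "jjdq_config_error")
  }
  if (!is.numeric(cfg$n_youth) || cfg$n_youth < 1) {
    fail("n_youth", "must be a positive count")
  }
  if (cfg$arrests_per_youth_mean < 1) {
    fail("arrests_per_youth_mean", "must be >= 1")
  }
  probs <- c("cms_mix", "gender_marginal", "race_marginal", "age_marginal",
             "severity_marginal", "trajectory_mix")
  for (f in probs) {
    v <- cfg[[f]]
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      fail(f, "must be a probability vector summing to 1")
    }
  }
  rates <- c("detention_prob", "probation_prob", "conformance_noise_rate")
  for (f in rates) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) fail(f, "must lie in [0, 1]")
  }
  if (any(cfg$missingness_rates < 0) || any(cfg$missingness_rates > 1)) {
    fail("missingness_rates", "every rate must lie in [0, 1]")
  }
  if (any(cfg$injection_rates < 0) || any(cfg$injection_rates > 1)) {
    fail("injection_rates", "every rate must lie in [0, 1]")
  }
  if (sum(cfg$injection_rates) > 1) {
    fail("injection_rates",
         "rates must sum to at most 1 (injected subsets are disjoint)")
  }
  invisible(cfg)
}

#' Read a generator configuration from YAML
#'
#' Scalar fields and named vectors use the argument names of
#' [generator_config()]; omitted fields keep their defaults.
#'
#' @param path YAML file.
#' @return a `jj_generator_config`.
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- lapply(y, function(v) if (is.list(v)) unlist(v) else v)
  do.call(generator_config, args)
}

TRAJECTORY_KINDS <- c(
  "diversion_terminal", "petition_path", "waiver_terminal", "not_true_path"
)

#' Sample one clean case trajectory
#'
#' Returns a rule-free assignment of the seven decision points for one of
#' the four trajectory templates, mirroring how real cases move through
#' the system:
#' `diversion_terminal` (diverted, nothing further), `petition_path`
#' (petitioned, adjudicated delinquent, then probation or confinement),
#' `waiver_terminal` (petitioned then waived to adult court with no
#' juvenile disposition), `not_true_path` (petitioned but allegations not
#' found true). Detention is set independently — a youth can be detained
#' before or after any other point.
#'
#' Uses the global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param kind one of the four template names.
#' @param detained logical: did the case include a detention stay?
#' @param probation_prob within `petition_path`, probability of a
#'   probation (vs confinement) disposition.
#' @return named character vector over the seven decision points.
#' @examples
#' sample_trajectory("diversion_terminal")
#' @export
sample_trajectory <- function(kind, detained = FALSE, probation_prob = 0.7) {
  if (!kind %in% TRAJECTORY_KINDS) {
    abort_jjdq(paste0("unknown trajectory kind: ", kind), "jjdq_config_error")
  }
  pts <- stats::setNames(rep("no", 7), DECISION_POINTS)
  if (kind == "diversion_terminal") {
    pts["diverted"] <- "yes"
  } else if (kind == "petition_path") {
    pts[c("petitioned", "adjudicated")] <- "yes"
    disp <- if (stats::runif(1) < probation_prob) "probation" else "confined"
    pts[disp] <- "yes"
  } else if (kind == "waiver_terminal") {
    pts[c("petitioned", "waived")] <- "yes"
  } else { # not_true_path
    pts["petitioned"] <- "yes"
  }
  pts["detained"] <- if (detained) "yes" else "no"
  pts
}

# scenario -> how a clean case is corrupted so that the target rule fires
# and the matching resolution strategy restores it. Each entry names the
# edited point, the value written, and the eligibility predicate.
INJECTION_SCENARIOS <- list(
  overturned = list(
    rule = "inconsistent_petition", point = "diverted", value = "yes",
    pools = c("petition_path", "not_true_path", "waiver_terminal")
  ),
  violated_agreement = list(
    rule = "inconsistent_petition", point = "petitioned", value = "yes",
    pools = "diversion_terminal"
  ),
  courtesy_detention = list(
    rule = "implausible_case", point = "petitioned", value = "no",
    pools = c("not_true_path", "waiver_terminal")
  ),
  clerical = list(
    rule = "implausible_case", point = "petitioned", value = "no",
    pools = c("not_true_path", "waiver_terminal")
  ),
  unlink = list(
    rule = "excess_information", point = NA_character_, value = "yes",
    pools = "diversion_terminal"
  ),
  fix = list(
    rule = "inconsistent_waiver", point = "adjudicated", value = "yes",
    pools = "waiver_terminal"
  ),
  backfill = list(
    rule = "inconsistent_adjudication", point = "adjudicated", value = "no",
    pools = "petition_path"
  )
)

# scenarios sampled per injected rule (uniform over the menu)
RULE_INJECTION_SCENARIOS <- list(
  inconsistent_petition = c("overturned", "violated_agreement"),
  implausible_case = c("courtesy_detention", "clerical"),
  excess_information = c("unlink"),
  inconsistent_waiver = c("fix"),
  inconsistent_adjudication = c("backfill")
)

#' Corrupt one clean case so a rule fires
#'
#' Inverts a cleaning strategy on a rule-free case: the corrupted case
#' fires `rule` under [detect_all()] as its first error, and applying the
#' matching resolution strategy restores a rule-free case (field-exact for
#' every scenario except `unlink`, which clears the planted yes to
#' missing rather than back to no). The case's trajectory must admit the
#' scenario — e.g. `violated_agreement` corrupts a diverted case,
#' `backfill` an adjudicated one.
#'
#' @param case one-row records tibble, currently rule-free.
#' @param rule the rule to plant.
#' @param scenario the resolution scenario to invert; default is the
#'   first entry of the rule's menu.
#' @param offending_point for `unlink`, which subsequent point to set yes;
#'   default picks the first eligible (non-missing "no") one.
#' @return the corrupted one-row tibble.
#' @export
inject_case <- function(case, rule, scenario = NULL, offending_point = NULL) {
  case <- as_case_row(case)
  if (!rule %in% RULE_IDS) {
    abort_jjdq(paste0("unknown rule: ", rule), "jjdq_rule_error")
  }
  scenario <- scenario %||% RULE_INJECTION_SCENARIOS[[rule]][1]
  sc <- INJECTION_SCENARIOS[[scenario]]
  if (is.null(sc) || sc$rule != rule) {
    abort_jjdq(paste0("scenario '", scenario, "' does not invert rule '",
                      rule, "'"), "jjdq_rule_error")
  }
  if (nrow(detect_all(case)) > 0) {
    abort_jjdq("inject_case requires a rule-free case", "jjdq_rule_error")
  }
  point <- sc$point
  if (scenario == "unlink") {
    subsequent <- c("adjudicated", "probation", "confined", "waived")
    eligible <- subsequent[vapply(subsequent, function(p) is_no(case[[p]]),
                                  logical(1))]
    point <- offending_point %||% eligible[1]
    if (is.na(point) || !point %in% eligible) {
      abort_jjdq("no eligible subsequent point to plant excess information",
                 "jjdq_rule_error")
    }
  }
  if (is.na(case[[point]])) {
    abort_jjdq(paste0("cannot corrupt missing field '", point, "'"),
               "jjdq_rule_error")
  }
  case[[point]] <- sc$value
  planted <- first_inconsistency(case)
  if (is.null(planted) || planted$rule != rule) {
    abort_jjdq(
      paste0("case trajectory does not admit scenario '", scenario, "'"),
      "jjdq_rule_error"
    )
  }
  case
}

#' Generate a labelled synthetic extract
#'
#' Draws youths and their arrests, assigns clean trajectories, then (in
#' order) blanks responses at the configured per-point missingness rates,
#' corrupts disjoint case subsets so each configured rule fires (sampling
#' the scenario from the rule's menu), and plants nonconforming raw
#' tokens on uncorrupted cases. Corruption only ever flips non-missing
#' cells and each corrupted case carries exactly one injected rule, so
#' the truth labels score detector recall and first-error attribution
#' exactly, and the realised missingness marginals stay at their
#' configured rates.
#'
#' @param config a [generator_config()].
#' @return list with `extract` (a `jj_extract`, phase `PRE`) and `truth`:
#'   `cases` (per-case trajectory and injected rule/scenario labels),
#'   `missing` (blanked cells), `nonconforming` (planted bad tokens) and
#'   `originals` (pre-corruption decision-point values of corrupted
#'   cases).
#' @examples
#' g <- generate_extract(generator_config(n_youth = 30, seed = 3))
#' audit(g$extract)$at_least_one$count  # clean by construction
#' @export
generate_extract <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  n_youth <- as.integer(config$n_youth)

  arrests <- 1L + stats::rpois(n_youth, config$arrests_per_youth_mean - 1)
  youth <- tibble::tibble(
    youth_id = sprintf("Y%05d", seq_len(n_youth)),
    cms_id = sample(names(config$cms_mix), n_youth, TRUE, config$cms_mix),
    gender = sample(names(config$gender_marginal), n_youth, TRUE,
                    config$gender_marginal),
    race_ethnicity = sample(names(config$race_marginal), n_youth, TRUE,
                            config$race_marginal),
    age = as.integer(sample(names(config$age_marginal), n_youth, TRUE,
                            config$age_marginal))
  )
  # three counties share each CMS (the study's 4 x 3 county design)
  youth$county_id <- paste0(youth$cms_id, "-", sample(1:3, n_youth, TRUE))

  idx <- rep(seq_len(n_youth), arrests)
  n <- length(idx)
  rec <- youth[idx, ]
  rec$case_id <- sprintf("C%06d", seq_len(n))
  rec$extraction_phase <- "PRE"
  rec$charge_severity <- sample(names(config$severity_marginal), n, TRUE,
                                config$severity_marginal)
  kind <- sample(TRAJECTORY_KINDS, n, TRUE, config$trajectory_mix)
  detained <- stats::runif(n) < config$detention_prob
  disposition <- ifelse(stats::runif(n) < config$probation_prob,
                        "probation", "confined")

  rec$diverted <- ifelse(kind == "diversion_terminal", "yes", "no")
  rec$detained <- ifelse(detained, "yes", "no")
  rec$petitioned <- ifelse(kind == "diversion_terminal", "no", "yes")
  rec$adjudicated <- ifelse(kind == "petition_path", "yes", "no")
  rec$probation <- ifelse(kind == "petition_path" & disposition == "probation",
                          "yes", "no")
  rec$confined <- ifelse(kind == "petition_path" & disposition == "confined",
                         "yes", "no")
  rec$waived <- ifelse(kind == "waiver_terminal", "yes", "no")
  rec <- rec[, EXTRACT_COLUMNS]

  # 1. missingness: independent Bernoulli per (case, point) cell
  missing_truth <- list()
  for (p in DECISION_POINTS) {
    r <- config$missingness_rates[[p]]
    if (r > 0) {
      hit <- stats::runif(n) < r
      rec[[p]][hit] <- NA_character_
      if (any(hit)) {
        missing_truth[[p]] <- tibble::tibble(
          case_id = rec$case_id[hit], point = p
        )
      }
    }
  }
  missing_truth <- if (length(missing_truth) > 0) {
    dplyr::bind_rows(missing_truth)
  } else {
    tibble::tibble(case_id = character(), point = character())
  }

  # 2. rule injection on disjoint eligible subsets
  counts <- stats::rmultinom(
    1, n, c(config$injection_rates, none = 1 - sum(config$injection_rates))
  )[, 1]
  injected_rule <- rep(NA_character_, n)
  injected_scenario <- rep(NA_character_, n)
  injected_point <- rep(NA_character_, n)
  originals <- integer()

  scenario_eligible <- function(scname) {
    sc <- INJECTION_SCENARIOS[[scname]]
    ok <- kind %in% sc$pools & is.na(injected_rule)
    if (scname == "unlink") {
      ok & is_yes(rec$diverted) &
        (is_no(rec$adjudicated) | is_no(rec$probation) |
           is_no(rec$confined) | is_no(rec$waived))
    } else if (scname == "backfill") {
      ok & is_yes(rec$adjudicated) &
        (is_yes(rec$probation) | is_yes(rec$confined))
    } else if (scname == "fix") {
      ok & is_no(rec$adjudicated) & is_yes(rec$waived)
    } else if (scname == "overturned") {
      ok & is_no(rec$diverted) & is_yes(rec$petitioned)
    } else if (scname == "violated_agreement") {
      ok & is_no(rec$petitioned) & is_yes(rec$diverted)
    } else { # courtesy_detention / clerical
      ok & is_yes(rec$petitioned) & is_no(rec$diverted)
    }
  }

  # allocation order keeps the scarcer trajectory pools free for the
  # scenarios that need them (waiver_terminal before the petition rules)
  scenario_order <- c("fix", "backfill", "violated_agreement", "unlink",
                      "courtesy_detention", "clerical", "overturned")
  scenario_counts <- stats::setNames(integer(length(INJECTION_SCENARIOS)),
                                     names(INJECTION_SCENARIOS))
  for (r in RULE_IDS) {
    menu <- RULE_INJECTION_SCENARIOS[[r]]
    k <- counts[[r]]
    if (length(menu) == 1) {
      scenario_counts[menu] <- k
    } else {
      split <- stats::rbinom(1, k, 1 / length(menu))
      scenario_counts[menu[1]] <- split
      scenario_counts[menu[2]] <- k - split
    }
  }
  for (scname in scenario_order) {
    k <- scenario_counts[[scname]]
    if (k == 0) next
    pool <- which(scenario_eligible(scname))
    if (length(pool) < k) {
      abort_jjdq(
        paste0("injection rate for scenario '", scname, "' needs ", k,
               " eligible cases but only ", length(pool),
               " are available; lower the rate or shift trajectory_mix"),
        "jjdq_config_error"
      )
    }
    chosen <- if (length(pool) == 1) pool else sample(pool, k)
    sc <- INJECTION_SCENARIOS[[scname]]
    originals <- c(originals, chosen)
    for (i in chosen) {
      point <- sc$point
      if (scname == "unlink") {
        subsequent <- c("adjudicated", "probation", "confined", "waived")
        elig <- subsequent[vapply(subsequent, function(p) is_no(rec[[p]][i]),
                                  logical(1))]
        point <- if (length(elig) == 1) elig else sample(elig, 1)
      }
      injected_point[i] <- point
    }
    injected_rule[chosen] <- sc$rule
    injected_scenario[chosen] <- scname
  }
  originals <- sort(originals)
  originals_tbl <- dplyr::bind_cols(
    tibble::tibble(case_id = rec$case_id[originals]),
    rec[originals, DECISION_POINTS]
  )
  for (i in which(!is.na(injected_rule))) {
    rec[[injected_point[i]]][i] <-
      INJECTION_SCENARIOS[[injected_scenario[i]]]$value
  }

  # 3. conformance noise on uncorrupted cases only
  violations <- list()
  noncf <- list()
  if (config$conformance_noise_rate > 0) {
    tokens <- c("unknown", "TRUE", "y")
    for (p in DECISION_POINTS) {
      hit <- stats::runif(n) < config$conformance_noise_rate &
        is.na(injected_rule)
      if (any(hit)) {
        tok <- sample(tokens, sum(hit), TRUE)
        rec[[p]][hit] <- NA_character_
        violations[[p]] <- tibble::tibble(row = which(hit), field = p,
                                          token = tok)
        noncf[[p]] <- tibble::tibble(case_id = rec$case_id[hit], field = p,
                                     token = tok)
      }
    }
  }
  violations <- if (length(violations) > 0) {
    dplyr::arrange(dplyr::bind_rows(violations), .data$row, .data$field)
  } else {
    empty_violations()
  }
  noncf <- if (length(noncf) > 0) {
    dplyr::bind_rows(noncf)
  } else {
    tibble::tibble(case_id = character(), field = character(),
                   token = character())
  }

  extract <- new_extract(
    rec,
    provenance = paste0("synthetic (seed ", config$seed, ")"),
    violations = violations
  )
  truth <- list(
    cases = tibble::tibble(
      case_id = rec$case_id,
      youth_id = rec$youth_id,
      trajectory = kind,
      injected_rule = injected_rule,
      injected_scenario = injected_scenario,
      injected_point = injected_point
    ),
    missing = missing_truth,
    nonconforming = noncf,
    originals = originals_tbl
  )
  list(extract = extract, truth = truth)
}

#' Write synthetic ground truth as JSON
#'
#' @param truth the `truth` element of [generate_extract()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(cases = truth$cases, missing = truth$missing,
         nonconforming = truth$nonconforming, originals = truth$originals),
    path, dataframe = "rows", na = "null", pretty = TRUE
  )
  invisible(path)
}
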