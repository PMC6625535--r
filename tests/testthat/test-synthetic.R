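test_that("every trajectory template is rule-free, detained or not", {
  set.seed(1)
  for (kind in c("diversion_terminal", "petition_path", "waiver_terminal",
                 "not_true_path")) {
    for (det in c(TRUE, FALSE)) {
      pts <- sample_trajectory(kind, detained = det)
      case <- do.call(make_case, as.list(pts))
      expect_equal(nrow(detect_all(case)), 0,
                   label = paste(kind, "detained =", det))
    }
  }
  pts <- sample_trajectory("waiver_terminal")
  expect_equal(pts[["waived"]], "yes")
  expect_true(all(pts[c("adjudicated", "probation", "confined")] == "no"))
  expect_error(sample_trajectory("walk_free"), class = "jjdq_config_error")
})

test_that("a degenerate trajectory mix diverts every case", {
  g <- generate_extract(generator_config(
    n_youth = 40, seed = 9,
    trajectory_mix = c(diversion_terminal = 1, petition_path = 0,
                       waiver_terminal = 0, not_true_path = 0)
  ))
  expect_true(all(g$extract$records$diverted == "yes"))
})

test_that("inject_case plants a first-firing rule for every scenario", {
  set.seed(2)
  scenarios <- list(
    list(kind = "petition_path", rule = "inconsistent_petition",
         scenario = "overturned"),
    list(kind = "diversion_terminal", rule = "inconsistent_petition",
         scenario = "violated_agreement"),
    list(kind = "not_true_path", rule = "implausible_case",
         scenario = "courtesy_detention"),
    list(kind = "diversion_terminal", rule = "excess_information",
         scenario = "unlink"),
    list(kind = "waiver_terminal", rule = "inconsistent_waiver",
         scenario = "fix"),
    list(kind = "petition_path", rule = "inconsistent_adjudication",
         scenario = "backfill")
  )
  for (sc in scenarios) {
    case <- do.call(make_case, as.list(sample_trajectory(sc$kind)))
    corrupted <- inject_case(case, sc$rule, sc$scenario)
    expect_true(sc$rule %in% detect_all(corrupted)$rule, label = sc$scenario)
    expect_equal(first_inconsistency(corrupted)$rule, sc$rule,
                 label = sc$scenario)
  }
})

test_that("injection and resolution are inverse on the fields they touch", {
  set.seed(3)
  round_trip <- function(kind, rule, scenario) {
    case <- do.call(make_case, as.list(sample_trajectory(kind)))
    corrupted <- inject_case(case, rule, scenario)
    policy <- resolution_policy(
      overrides = stats::setNames(scenario, case$case_id)
    )
    resolve_case(corrupted, first_inconsistency(corrupted), policy)$record
  }
  expect_identical(
    round_trip("petition_path", "inconsistent_petition", "overturned"),
    do.call(make_case, as.list({
      set.seed(3); sample_trajectory("petition_path")
    }))
  )
  # field-exact restoration for the value-rewriting scenarios
  for (sc in list(
    c("diversion_terminal", "inconsistent_petition", "violated_agreement"),
    c("waiver_terminal", "inconsistent_waiver", "fix"),
    c("petition_path", "inconsistent_adjudication", "backfill")
  )) {
    set.seed(7)
    original <- do.call(make_case, as.list(sample_trajectory(sc[1])))
    corrupted <- inject_case(original, sc[2], sc[3])
    policy <- resolution_policy(
      overrides = stats::setNames(sc[3], original$case_id)
    )
    restored <- resolve_case(corrupted, first_inconsistency(corrupted),
                             policy)$record
    expect_identical(restored, original, label = sc[3])
  }
  # unlink restores rule-freedom but leaves the unlinked field missing
  original <- do.call(make_case, as.list(sample_trajectory("diversion_terminal")))
  corrupted <- inject_case(original, "excess_information", "unlink",
                           offending_point = "confined")
  policy <- resolution_policy(
    overrides = stats::setNames("unlink", original$case_id)
  )
  restored <- resolve_case(corrupted, first_inconsistency(corrupted),
                           policy)$record
  expect_true(is.na(restored$confined))
  expect_identical(restored[setdiff(names(restored), "confined")],
                   original[setdiff(names(original), "confined")])
  expect_equal(nrow(detect_all(restored)), 0)
})

test_that("inject_case rejects impossible requests", {
  clean <- make_case(diverted = "yes")
  expect_error(inject_case(clean, "inconsistent_waiver", "fix"),
               class = "jjdq_rule_error")
  expect_error(inject_case(clean, "implausible_case", "unlink"),
               class = "jjdq_rule_error")
  flagged <- make_case(diverted = "yes", petitioned = "yes")
  expect_error(inject_case(flagged, "excess_information"),
               "rule-free", class = "jjdq_rule_error")
})

test_that("generation is deterministic in the seed", {
  cfg <- generator_config(
    n_youth = 150, seed = 77,
    injection_rates = c(implausible_case = 0.1),
    missingness_rates = c(waived = 0.2), conformance_noise_rate = 0.05
  )
  g1 <- generate_extract(cfg)
  g2 <- generate_extract(cfg)
  expect_identical(g1$extract$records, g2$extract$records)
  expect_identical(g1$extract$violations, g2$extract$violations)
  expect_identical(g1$truth, g2$truth)

  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_extract(g1$extract, p1)
  write_extract(g2$extract, p2)
  expect_identical(readr::read_file(p1), readr::read_file(p2))

  g3 <- generate_extract(generator_config(
    n_youth = 150, seed = 78,
    injection_rates = c(implausible_case = 0.1),
    missingness_rates = c(waived = 0.2), conformance_noise_rate = 0.05
  ))
  expect_false(identical(g1$extract$records, g3$extract$records))
})

test_that("zero rates generate a pristine extract", {
  g <- generate_extract(generator_config(n_youth = 200, seed = 12))
  a <- audit(g$extract)
  expect_equal(a$at_least_one$count, 0)
  expect_true(all(a$completeness == 0))
  expect_equal(a$conformance$count, 0)
  expect_true(all(is.na(g$truth$cases$injected_rule)))
})

test_that("truth labels exactly describe every corruption", {
  g <- generate_extract(generator_config(
    n_youth = 800, seed = 41,
    injection_rates = stats::setNames(rep(0.05, 5), rule_ids()),
    missingness_rates = stats::setNames(rep(0.08, 7),
                                        decision_points()$point),
    conformance_noise_rate = 0.01
  ))
  a <- audit(g$extract)
  truth <- g$truth$cases[!is.na(g$truth$cases$injected_rule), ]
  m <- merge(truth, a$first_error, by = "case_id")
  expect_equal(nrow(m), nrow(truth))          # recall: every corruption found
  expect_true(all(m$injected_rule == m$rule)) # first-error attribution
  # missingness labels match blanked cells (nonconforming cells also parse
  # to missing and are labelled separately)
  rec <- g$extract$records
  for (p in decision_points()$point) {
    labelled <- g$truth$missing$case_id[g$truth$missing$point == p]
    noisy <- g$truth$nonconforming$case_id[g$truth$nonconforming$field == p]
    expect_setequal(rec$case_id[is.na(rec[[p]])], union(labelled, noisy))
  }
  expect_equal(nrow(g$truth$nonconforming), nrow(g$extract$violations))
})

test_that("realised rates track their binomial sampling bounds", {
  g <- generate_extract(generator_config(
    n_youth = 1200, seed = 55, conformance_noise_rate = 0.05
  ))
  n_cells <- 7 * n_cases(g$extract)
  se <- sqrt(0.05 * 0.95 / n_cells)
  expect_lt(abs(nrow(g$extract$violations) / n_cells - 0.05), 3 * se)
})

test_that("invalid configurations are rejected field by field", {
  expect_error(generator_config(n_youth = 0), "n_youth",
               class = "jjdq_config_error")
  expect_error(generator_config(trajectory_mix = c(
    diversion_terminal = 0.5, petition_path = 0.4,
    waiver_terminal = 0.2, not_true_path = 0
  )), "trajectory_mix", class = "jjdq_config_error")
  expect_error(
    generator_config(injection_rates = stats::setNames(rep(0.3, 5),
                                                       rule_ids())),
    "injection_rates", class = "jjdq_config_error"
  )
  expect_error(generator_config(detention_prob = 1.2), "detention_prob",
               class = "jjdq_config_error")
  expect_error(generator_config(missingness_rates = c(bogus_point = 0.1)),
               "bogus_point", class = "jjdq_config_error")
})

test_that("generator configs load from YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_youth: 25",
    "seed: 99",
    "injection_rates:",
    "  implausible_case: 0.2",
    "trajectory_mix:",
    "  diversion_terminal: 0.2",
    "  petition_path: 0.3",
    "  waiver_terminal: 0.1",
    "  not_true_path: 0.4"
  ), p)
  cfg <- read_generator_config(p)
  expect_equal(cfg$n_youth, 25)
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$injection_rates[["implausible_case"]], 0.2)
  expect_equal(cfg$injection_rates[["inconsistent_waiver"]], 0)
})
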