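test_that("each rule fires on its defining pattern", {
  expect_equal(detect_all(case_with(diverted = "yes", petitioned = "yes"))$rule,
               "inconsistent_petition")
  # courtesy detention: detention does not rescue a no-diversion/no-petition
  expect_equal(detect_all(case_with(detained = "yes"))$rule,
               "implausible_case")
  expect_equal(detect_all(case_with(diverted = "yes", confined = "yes"))$rule,
               c("excess_information", "inconsistent_adjudication"))
  expect_equal(detect_all(case_with(petitioned = "yes", adjudicated = "yes",
                                    waived = "yes"))$rule,
               "inconsistent_waiver")
  expect_equal(detect_all(case_with(petitioned = "yes",
                                    probation = "yes"))$rule,
               "inconsistent_adjudication")
})

test_that("missing matches neither yes nor no in any rule literal", {
  # diverted missing: neither petition rule can complete
  expect_equal(nrow(detect_all(case_with(diverted = NA))), 0)
  expect_equal(nrow(detect_all(case_with(diverted = NA,
                                         petitioned = "yes"))), 0)
  # a missing subsequent point is not an offending yes
  expect_equal(nrow(detect_all(case_with(diverted = "yes", petitioned = "no",
                                         confined = NA))), 0)
  # adjudication missing does not count as "no"... by default
  blank_adj <- case_with(petitioned = "yes", adjudicated = NA,
                         probation = "yes")
  expect_equal(nrow(detect_all(blank_adj)), 0)
  # ...but the blank-field reading can be switched on
  flags <- detect_all(blank_adj, adjudication_missing_counts = TRUE)
  expect_equal(flags$rule, "inconsistent_adjudication")
})

test_that("multiple rules can fire on one case; detect_all returns all", {
  flags <- detect_all(case_with(diverted = "yes", petitioned = "yes",
                                confined = "yes"))
  expect_setequal(flags$rule, c("inconsistent_petition", "excess_information",
                                "inconsistent_adjudication"))
})

test_that("first error follows case chronology: petition before waiver", {
  case <- case_with(diverted = "yes", petitioned = "yes",
                    adjudicated = "yes", waived = "yes")
  fired <- detect_all(case)
  expect_true(all(c("inconsistent_petition", "inconsistent_waiver") %in%
                    fired$rule))
  expect_equal(first_inconsistency(case)$rule, "inconsistent_petition")
  expect_equal(first_inconsistency(case)$anchor, 3L)
})

test_that("anchors sit at the earliest offending decision point", {
  expect_equal(first_inconsistency(case_with(diverted = "yes",
                                             waived = "yes"))$anchor, 7L)
  expect_equal(first_inconsistency(case_with(diverted = "yes",
                                             probation = "yes"))$anchor, 5L)
  # co-anchored excess and adjudication resolve by fixed priority
  first <- first_inconsistency(case_with(diverted = "yes", confined = "yes"))
  expect_equal(first$rule, "excess_information")
  expect_equal(first$anchor, 6L)
})

test_that("involved points name the fields making the pattern", {
  flag <- first_inconsistency(case_with(diverted = "yes", petitioned = "no",
                                        probation = "yes", waived = "yes"))
  expect_equal(flag$rule, "excess_information")
  expect_setequal(flag$involved_points[[1]],
                  c("diverted", "probation", "waived"))
})

test_that("no-rule cases yield NULL first inconsistency", {
  expect_null(first_inconsistency(make_case(diverted = "yes")))
})

test_that("completeness reports percent missing per point to one decimal", {
  ex <- extract_of(
    case_with(confined = NA), case_with(confined = NA),
    case_with(confined = NA), case_with(confined = NA)
  )
  prof <- completeness_profile(ex)
  expect_equal(prof[["confined"]], 100.0)
  expect_equal(prof[["diverted"]], 0.0)

  none <- extract_of(case_with(), case_with(diverted = "yes"))
  expect_true(all(completeness_profile(none) == 0))

  # 1 of 3 missing -> 33.3 (one decimal, half-up)
  third <- extract_of(case_with(waived = NA), case_with(), case_with())
  expect_equal(completeness_profile(third)[["waived"]], 33.3)

  expect_error(completeness_profile(new_extract(make_case()[0, ])),
               class = "jjdq_empty_error")
})

test_that("percentages round half away from zero to one decimal", {
  expect_equal(jjdq:::round_half_up(12.25, 1), 12.3)
  expect_equal(jjdq:::round_half_up(0.05, 1), 0.1)
  expect_equal(jjdq:::round_half_up(71.15, 1), 71.2)
  # 1 flagged of 16 cases = 6.25% -> 6.3
  ex <- extract_with_counts(16, n_implausible = 1)
  expect_equal(audit(ex)$per_rule$pct[2], 6.3)
})

test_that("conformance tally groups parse-time violations by field", {
  p <- withr::local_tempfile(fileext = ".csv")
  lines <- c(
    paste(jjdq:::EXTRACT_COLUMNS, collapse = ","),
    "C1,Y1,CMS1,CMS1-1,PRE,male,White,15,Felony D,yes,no,no,no,no,no,Y3S",
    "C2,Y2,CMS1,CMS1-1,PRE,male,White,15,Felony D,true,no,no,no,no,no,no",
    "C3,Y3,CMS1,CMS1-1,PRE,male,White,15,Felony D,unknown,no,no,no,no,no,no"
  )
  writeLines(lines, p)
  conf <- check_conformance(read_extract(p))
  expect_equal(conf$count, 3)
  expect_equal(conf$by_field$n[conf$by_field$field == "diverted"], 2L)
  expect_equal(conf$by_field$n[conf$by_field$field == "waived"], 1L)

  clean <- extract_of(case_with(diverted = "yes"))
  expect_equal(check_conformance(clean)$count, 0)
})

test_that("audit partitions flagged cases exactly across rules", {
  ex <- extract_of(
    case_with(diverted = "yes", petitioned = "yes"),     # petition
    case_with(),                                         # implausible
    case_with(diverted = "yes", confined = "yes"),       # excess (+adj)
    case_with(petitioned = "yes", probation = "yes"),    # adjudication
    clean_cases(6)
  )
  a <- audit(ex)
  expect_equal(a$n_cases, 10)
  expect_equal(sum(a$per_rule$count), a$at_least_one$count)
  expect_equal(a$at_least_one$count, 4)
  expect_equal(a$at_least_one$pct, 40.0)
  # 2 flagged of 10 -> 20.0%
  small <- extract_of(case_with(), case_with(petitioned = "yes",
                                             probation = "yes"),
                      clean_cases(8))
  expect_equal(audit(small)$at_least_one$pct, 20.0)
  expect_error(audit(new_extract(make_case()[0, ])),
               class = "jjdq_empty_error")
})

test_that("partition identity holds on random synthetic extracts", {
  for (seed in c(4, 19, 88)) {
    g <- generate_extract(generator_config(
      n_youth = 300, seed = seed,
      injection_rates = stats::setNames(rep(0.04, 5), rule_ids()),
      missingness_rates = c(probation = 0.1)
    ))
    a <- audit(g$extract)
    expect_equal(sum(a$per_rule$count), a$at_least_one$count)
    by_cms <- dplyr::summarise(
      dplyr::group_by(a$per_rule_by_cms, .data$cms_id),
      count = sum(.data$count)
    )
    expect_equal(
      by_cms$count[order(by_cms$cms_id)],
      a$at_least_one_by_cms$count[order(a$at_least_one_by_cms$cms_id)]
    )
  }
})

test_that("adding an inconsistency-free case never raises a percentage", {
  ex <- extract_of(
    case_with(), case_with(diverted = "yes", waived = "yes"), clean_cases(5)
  )
  before <- audit(ex)
  bigger <- new_extract(dplyr::bind_rows(
    ex$records, make_case(case_id = "C999999", diverted = "yes")
  ))
  after <- audit(bigger)
  expect_true(all(after$per_rule$pct <= before$per_rule$pct))
  expect_lte(after$at_least_one$pct, before$at_least_one$pct)
})

test_that("audit JSON carries the documented shape", {
  a <- audit(extract_of(case_with(), clean_cases(3)))
  j <- jsonlite::fromJSON(audit_json(a))
  expect_equal(j$n_cases, 4)
  expect_named(j$completeness, jjdq:::DECISION_POINTS)
  expect_equal(j$per_rule$implausible_case$count, 1)
  expect_equal(j$at_least_one$pct, 25.0)
  expect_equal(j$conformance, 0)
})
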