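# Shared fixture builders (all fixtures are generated in code).

# a case with given point values, everything else defaulted
case_with <- function(..., id = "C000001") {
  make_case(case_id = id, ...)
}

# extract from a list of one-row case tibbles
extract_of <- function(...) {
  rows <- dplyr::bind_rows(...)
  rows$case_id <- sprintf("C%06d", seq_len(nrow(rows)))
  new_extract(rows, provenance = "test fixture")
}

# n copies of a template row (vectorised; bind_rows of single rows is slow)
replicate_case <- function(n, ...) {
  if (n == 0) return(make_case()[0, ])
  out <- make_case(...)[rep(1, n), ]
  out
}

# n clean diversion-terminal filler cases
clean_cases <- function(n, cms_id = "CMS1") {
  out <- replicate_case(n, cms_id = cms_id, diverted = "yes")
  out$case_id <- sprintf("F%06d", seq_len(n))
  out$youth_id <- sprintf("Y%05d", seq_len(n))
  out
}

# extract with exact per-rule pattern counts on top of clean filler;
# used to exercise the partition/rounding accounting at a chosen n
extract_with_counts <- function(n_total, n_implausible = 0, n_excess = 0,
                                n_adjudication = 0, n_petition = 0,
                                cms_id = "CMS1") {
  rows <- dplyr::bind_rows(
    replicate_case(n_petition, diverted = "yes", petitioned = "yes"),
    replicate_case(n_implausible, diverted = "no", petitioned = "no"),
    replicate_case(n_excess, diverted = "yes", confined = "yes"),
    replicate_case(n_adjudication, diverted = "no", petitioned = "yes",
                   adjudicated = "no", probation = "yes"),
    clean_cases(n_total - n_petition - n_implausible - n_excess -
                  n_adjudication)
  )
  rows$case_id <- sprintf("C%06d", seq_len(nrow(rows)))
  rows$youth_id <- sprintf("Y%05d", seq_len(nrow(rows)))
  rows$cms_id <- cms_id
  rows$county_id <- paste0(cms_id, "-1")
  new_extract(rows, provenance = "count fixture")
}

points_of <- function(case) {
  unlist(case[1, ORACLE_POINTS])
}
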