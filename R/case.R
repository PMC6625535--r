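#' Construct a single case record
#'
#' Convenience constructor for a one-row records tibble with every column
#' of the extract contract filled in. Decision points default to `"no"`;
#' pass `NA` for a missing response.
#'
#' @param case_id,youth_id,cms_id,county_id,extraction_phase identifiers.
#' @param gender,race_ethnicity,age,charge_severity demographics.
#' @param diverted,detained,petitioned,adjudicated,probation,confined,waived
#'   decision-point responses: `"yes"`, `"no"` or `NA` (missing).
#' @return a one-row tibble usable with [detect_all()] or, bound with
#'   others, with [new_extract()].
#' @examples
#' make_case(diverted = "yes", petitioned = "yes")
#' @export
make_case <- function(case_id = "C000001", youth_id = "Y00001",
                      cms_id = "CMS1", county_id = "CMS1-01",
                      extraction_phase = "PRE",
                      gender = "male", race_ethnicity = "White",
                      age = 15L, charge_severity = "Misdemeanor A",
                      diverted = "no", detained = "no", petitioned = "no",
                      adjudicated = "no", probation = "no", confined = "no",
                      waived = "no") {
  tibble::tibble(
    case_id = as.character(case_id),
    youth_id = as.character(youth_id),
    cms_id = as.character(cms_id),
    county_id = as.character(county_id),
    extraction_phase = as.character(extraction_phase),
    gender = as.character(gender),
    race_ethnicity = as.character(race_ethnicity),
    age = as.integer(age),
    charge_severity = as.character(charge_severity),
    diverted = as.character(diverted),
    detained = as.character(detained),
    petitioned = as.character(petitioned),
    adjudicated = as.character(adjudicated),
    probation = as.character(probation),
    confined = as.character(confined),
    waived = as.character(waived)
  )
}
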