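#' Decision points of the juvenile court trajectory
#'
#' Seven decision points are recorded per arrest ("case"), each valued
#' `"yes"`, `"no"` or missing (`NA`). Their canonical order reflects the
#' sequence in which a youth typically moves through the system: diversion,
#' detention, petition, adjudication, probation, confinement, waiver to
#' adult court. Detention is order-exempt — a youth may be detained before
#' or after any other point — so it participates in no plausibility rule.
#'
#' @return `decision_points()` returns a tibble with columns `point`,
#'   `position` (1-7) and `order_exempt`.
#' @examples
#' decision_points()
#' @export
decision_points <- function() {
  tibble::tibble(
    point = DECISION_POINTS,
    position = seq_along(DECISION_POINTS),
    order_exempt = DECISION_POINTS == "detained"
  )
}

DECISION_POINTS <- c(
  "diverted", "detained", "petitioned", "adjudicated",
  "probation", "confined", "waived"
)

point_position <- function(point) {
  match(point, DECISION_POINTS)
}

# Fixed column contract for extract CSV files.
EXTRACT_COLUMNS <- c(
  "case_id", "youth_id", "cms_id", "county_id", "extraction_phase",
  "gender", "race_ethnicity", "age", "charge_severity",
  DECISION_POINTS
)

CMS_LEVELS <- paste0("CMS", 1:4)
PHASE_LEVELS <- c("PRE", "POST")
GENDER_LEVELS <- c("male", "female")

RACE_LEVELS <- c(
  "African American/Black", "Asian", "Hawaiian/Pacific Islander",
  "Hispanic/Latino", "Native American or Native Alaskan", "White", "Other"
)

SEVERITY_LEVELS <- c(
  "Felony A", "Felony B", "Felony C", "Felony D",
  "Misdemeanor A", "Misdemeanor B", "Misdemeanor C",
  "Status Offense", "Violation of Probation"
)

# Conforming non-missing tokens for a decision-point field, after trimming
# and lower-casing; the empty string is the canonical missing encoding.
CONFORMING_TOKENS <- c("yes", "no")

AGE_RANGE <- c(10L, 18L)
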