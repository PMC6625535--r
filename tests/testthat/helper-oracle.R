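# Independent brute-force oracle for the five plausibility rules.
#
# A literal, case-at-a-time transcription of the rule definitions and of
# the first-error accounting (earliest anchor in case chronology, fixed
# priority at ties). Deliberately written without reusing any package
# internals so it can arbitrate the vectorised detector.

ORACLE_POINTS <- c("diverted", "detained", "petitioned", "adjudicated",
                   "probation", "confined", "waived")

oracle_yes <- function(v) !is.na(v) && v == "yes"
oracle_no <- function(v) !is.na(v) && v == "no"

# pts: named character vector over the seven points ("yes"/"no"/NA)
oracle_detect <- function(pts) {
  fired <- list()
  add <- function(rule, anchor, priority) {
    fired[[length(fired) + 1]] <<- data.frame(
      rule = rule, anchor = anchor, priority = priority,
      stringsAsFactors = FALSE
    )
  }
  if (oracle_yes(pts[["diverted"]]) && oracle_yes(pts[["petitioned"]])) {
    add("inconsistent_petition", 3L, 1L)
  }
  if (oracle_no(pts[["diverted"]]) && oracle_no(pts[["petitioned"]])) {
    add("implausible_case", 3L, 2L)
  }
  subsequent <- c(adjudicated = 4L, probation = 5L, confined = 6L,
                  waived = 7L)
  if (oracle_yes(pts[["diverted"]])) {
    offending <- names(subsequent)[vapply(names(subsequent),
                                          function(p) oracle_yes(pts[[p]]),
                                          logical(1))]
    if (length(offending) > 0) {
      add("excess_information", min(subsequent[offending]), 3L)
    }
  }
  if (oracle_no(pts[["adjudicated"]])) {
    disp <- c(probation = 5L, confined = 6L)
    offending <- names(disp)[vapply(names(disp),
                                    function(p) oracle_yes(pts[[p]]),
                                    logical(1))]
    if (length(offending) > 0) {
      add("inconsistent_adjudication", min(disp[offending]), 4L)
    }
  }
  if (oracle_yes(pts[["waived"]]) &&
        (oracle_yes(pts[["adjudicated"]]) || oracle_yes(pts[["probation"]]) ||
           oracle_yes(pts[["confined"]]))) {
    add("inconsistent_waiver", 7L, 5L)
  }
  if (length(fired) == 0) {
    return(data.frame(rule = character(), anchor = integer(),
                      priority = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, fired)
  out[order(out$anchor, out$priority), , drop = FALSE]
}

oracle_first <- function(pts) {
  fired <- oracle_detect(pts)
  if (nrow(fired) == 0) NULL else fired[1, , drop = FALSE]
}

# all 3^7 = 2187 decision-point assignments
all_point_assignments <- function() {
  grid <- expand.grid(rep(list(c("yes", "no", NA_character_)), 7),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- ORACLE_POINTS
  grid
}
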