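#' Case extract container
#'
#' A `jj_extract` bundles one CSV extract from a case management system
#' (CMS): one row per arrest ("case"), with identifiers, demographics and
#' the seven decision-point fields, plus the conformance violations found
#' while parsing. A raw decision-point token outside the permitted
#' vocabulary (`yes`/`no`/empty) is preserved verbatim in `violations`
#' and the parsed field is set to missing, so completeness and
#' plausibility checks still run while the conformance report keeps the
#' offending token.
#'
#' @param records tibble with the extract columns (see [read_extract()]).
#' @param provenance free-text label describing where the extract came from.
#' @param violations tibble with columns `row`, `field`, `token`.
#' @return an object of class `jj_extract`.
#' @seealso [read_extract()], [write_extract()], [audit()]
#' @export
new_extract <- function(records, provenance = "",
                        violations = empty_violations()) {
  records <- tibble::as_tibble(records)
  x <- structure(
    list(records = records, provenance = provenance, violations = violations),
    class = "jj_extract"
  )
  validate_extract(x)
  x
}

empty_violations <- function() {
  tibble::tibble(row = integer(), field = character(), token = character())
}

validate_extract <- function(x) {
  rec <- x$records
  missing_cols <- setdiff(EXTRACT_COLUMNS, names(rec))
  if (length(missing_cols) > 0) {
    abort_jjdq(
      paste0("extract is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "jjdq_schema_error"
    )
  }
  for (p in DECISION_POINTS) {
    bad <- !is.na(rec[[p]]) & !rec[[p]] %in% CONFORMING_TOKENS
    if (any(bad)) {
      abort_jjdq(
        paste0("decision point '", p, "' holds non-tri-state value(s): ",
               paste(unique(rec[[p]][bad]), collapse = ", ")),
        "jjdq_domain_error"
      )
    }
  }
  key <- paste(rec$case_id, rec$extraction_phase, sep = "\r")
  if (anyDuplicated(key) > 0) {
    dups <- unique(rec$case_id[duplicated(key)])
    abort_jjdq(
      paste0("duplicate (case_id, extraction_phase): ",
             paste(utils::head(dups, 5), collapse = ", ")),
      "jjdq_uniqueness_error"
    )
  }
  bad_age <- !is.na(rec$age) & (rec$age < AGE_RANGE[1] | rec$age > AGE_RANGE[2])
  if (any(bad_age)) {
    abort_jjdq(
      paste0("age outside [", AGE_RANGE[1], ", ", AGE_RANGE[2], "] for case(s): ",
             paste(utils::head(rec$case_id[bad_age], 5), collapse = ", ")),
      "jjdq_domain_error"
    )
  }
  invisible(x)
}

#' @export
print.jj_extract <- function(x, ...) {
  cat("<jj_extract> ", nrow(x$records), " cases",
      if (nzchar(x$provenance)) paste0(" [", x$provenance, "]"), "\n", sep = "")
  cat("  conformance violations: ", nrow(x$violations), "\n", sep = "")
  phases <- table(x$records$extraction_phase)
  cat("  phases: ", paste(names(phases), phases, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of cases in an extract
#' @param x a `jj_extract`.
#' @return integer case count.
#' @export
n_cases <- function(x) {
  stopifnot(inherits(x, "jj_extract"))
  nrow(x$records)
}

#' Read a case extract from CSV
#'
#' Parses a comma-delimited, UTF-8, header-first extract with the fixed
#' column contract
#' `case_id,youth_id,cms_id,county_id,extraction_phase,gender,race_ethnicity,age,charge_severity,diverted,detained,petitioned,adjudicated,probation,confined,waived`.
#' Unknown extra columns are carried through untouched.
#'
#' Decision-point tokens are trimmed and lower-cased; `"yes"` and `"no"`
#' are the only conforming non-missing tokens and the empty string is the
#' canonical missing encoding. Any other token is recorded verbatim as a
#' conformance violation and the field is set to missing — the violation
#' is preserved for the conformance report, never silently coerced away.
#'
#' @param path path to a CSV file.
#' @param provenance label stored on the extract; defaults to the path.
#' @return a [new_extract()] object.
#' @examples
#' ex <- generate_extract(generator_config(n_youth = 20, seed = 1))$extract
#' p <- tempfile(fileext = ".csv")
#' write_extract(ex, p)
#' identical(read_extract(p)$records, ex$records)
#' @export
read_extract <- function(path, provenance = path) {
  if (!file.exists(path)) {
    abort_jjdq(paste0("extract file not found: ", path), "jjdq_io_error")
  }
  header <- parse_csv_header(path)
  missing_cols <- setdiff(EXTRACT_COLUMNS, header)
  if (length(missing_cols) > 0) {
    abort_jjdq(
      paste0("extract header is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      "jjdq_schema_error"
    )
  }
  dup_cols <- unique(header[duplicated(header)])
  if (length(dup_cols) > 0) {
    abort_jjdq(
      paste0("extract header repeats column(s): ",
             paste(dup_cols, collapse = ", ")),
      "jjdq_schema_error"
    )
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  rec <- raw[, c(EXTRACT_COLUMNS, setdiff(header, EXTRACT_COLUMNS))]

  violations <- list()
  for (p in DECISION_POINTS) {
    tok <- rec[[p]]
    norm <- tolower(trimws(tok))
    parsed <- ifelse(norm %in% CONFORMING_TOKENS, norm, NA_character_)
    bad <- !is.na(tok) & norm != "" & !norm %in% CONFORMING_TOKENS
    if (any(bad)) {
      violations[[p]] <- tibble::tibble(
        row = which(bad), field = p, token = tok[bad]
      )
    }
    rec[[p]] <- parsed
  }
  violations <- if (length(violations) > 0) {
    dplyr::arrange(dplyr::bind_rows(violations), .data$row, .data$field)
  } else {
    empty_violations()
  }

  rec$extraction_phase <- toupper(trimws(rec$extraction_phase))
  bad_phase <- !rec$extraction_phase %in% PHASE_LEVELS
  if (any(bad_phase)) {
    abort_jjdq(
      paste0("extraction_phase must be PRE or POST; found: ",
             paste(unique(rec$extraction_phase[bad_phase]), collapse = ", ")),
      "jjdq_domain_error"
    )
  }
  gender <- tolower(trimws(rec$gender))
  rec$gender <- ifelse(gender %in% GENDER_LEVELS, gender, NA_character_)
  rec$race_ethnicity <- blank_to_na(rec$race_ethnicity)
  rec$charge_severity <- blank_to_na(rec$charge_severity)
  age <- suppressWarnings(as.integer(trimws(rec$age)))
  age[!is.na(age) & (age < AGE_RANGE[1] | age > AGE_RANGE[2])] <- NA_integer_
  rec$age <- age

  new_extract(rec, provenance = provenance, violations = violations)
}

blank_to_na <- function(x) {
  x <- trimws(x)
  ifelse(is.na(x) | x == "", NA_character_, x)
}

parse_csv_header <- function(path) {
  line <- readr::read_lines(path, n_max = 1)
  if (length(line) == 0) {
    abort_jjdq("extract file is empty (no header row)", "jjdq_schema_error")
  }
  hdr <- scan(text = line, what = character(), sep = ",", quote = "\"",
              quiet = TRUE, strip.white = TRUE)
  hdr
}

#' Write a case extract to CSV
#'
#' Inverse of [read_extract()]: missing values are written as empty
#' strings and nonconforming raw tokens recorded in `violations` are
#' re-inserted at their original positions, so that reading the written
#' file reproduces the extract record-for-record, field-for-field,
#' violations included.
#'
#' @param extract a `jj_extract`.
#' @param path output path.
#' @param raw_tokens if `TRUE` (default), re-insert recorded nonconforming
#'   tokens so the file mirrors the as-delivered extract; if `FALSE`,
#'   write the parsed tri-state values only.
#' @return `path`, invisibly.
#' @export
write_extract <- function(extract, path, raw_tokens = TRUE) {
  stopifnot(inherits(extract, "jj_extract"))
  validate_extract(extract)
  out <- extract$records
  out$age <- as.character(out$age)
  if (raw_tokens && nrow(extract$violations) > 0) {
    v <- extract$violations
    for (i in seq_len(nrow(v))) {
      out[[v$field[i]]][v$row[i]] <- v$token[i]
    }
  }
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::everything(), ~ ifelse(is.na(.x), "", as.character(.x))
  ))
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Group a youth's arrests
#'
#' One youth may contribute several cases (arrests) to an extract. Groups
#' records by `youth_id`, preserving file order within groups and the
#' order of first appearance across groups.
#'
#' @param extract a `jj_extract`.
#' @return named list of record tibbles, one per youth.
#' @export
cases_by_youth <- function(extract) {
  stopifnot(inherits(extract, "jj_extract"))
  rec <- extract$records
  if (nrow(rec) == 0) {
    return(stats::setNames(list(), character()))
  }
  ids <- unique(rec$youth_id)
  out <- lapply(ids, function(y) rec[rec$youth_id == y, , drop = FALSE])
  stats::setNames(out, ids)
}
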