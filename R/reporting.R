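#' Demographic description of an extract, by CMS
#'
#' Tabulates counts and one-decimal percentages of gender, race/ethnicity,
#' age and charge severity per CMS, in the style of a case-description
#' table. Cell values under the suppression threshold are not reported,
#' to limit possible identification of individual youths: any displayed
#' count c with 0 < c < threshold is replaced by the sentinel `"<10"`
#' (for the default threshold). Zero counts are displayed — only small
#' nonzero cells identify. Percent denominators are all cases in the CMS.
#' A dimension a CMS supplied no data for (all values missing) yields no
#' rows for that CMS, so its column renders empty.
#'
#' @param extract a nonempty `jj_extract`.
#' @param suppress_threshold minimum displayable nonzero cell count.
#' @return list with `cells` (tibble `cms_id`, `dimension`, `category`,
#'   `n`, `pct`, `display`) and `age_summary` (tibble `cms_id`, `mean_age`,
#'   `sd_age`, one decimal).
#' @export
demographics_table <- function(extract, suppress_threshold = 10) {
  stopifnot(inherits(extract, "jj_extract"))
  rec <- extract$records
  if (nrow(rec) == 0) {
    abort_jjdq("demographics are undefined on an empty extract",
               "jjdq_empty_error")
  }
  dims <- list(
    gender = GENDER_LEVELS,
    race_ethnicity = RACE_LEVELS,
    age = as.character(AGE_RANGE[1]:AGE_RANGE[2]),
    charge_severity = SEVERITY_LEVELS
  )
  cms_n <- dplyr::count(rec, .data$cms_id, name = "n_cases")
  cells <- list()
  for (d in names(dims)) {
    vals <- as.character(rec[[d]])
    for (cms in cms_n$cms_id) {
      in_cms <- rec$cms_id == cms
      total <- sum(in_cms)
      v <- vals[in_cms]
      if (all(is.na(v))) next  # dimension not supplied by this CMS
      cats <- dims[[d]]
      counts <- table(factor(v, levels = cats))
      rows <- tibble::tibble(
        cms_id = cms, dimension = d, category = cats,
        n = as.integer(counts),
        pct = pct1(as.integer(counts), total)
      )
      n_miss <- sum(is.na(v))
      if (n_miss > 0) {
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          cms_id = cms, dimension = d, category = "missing",
          n = n_miss, pct = pct1(n_miss, total)
        ))
      }
      cells[[length(cells) + 1]] <- rows
    }
  }
  cells <- dplyr::bind_rows(cells)
  suppressed <- cells$n > 0 & cells$n < suppress_threshold
  cells$display <- ifelse(suppressed, paste0("<", suppress_threshold),
                          as.character(cells$n))
  cells$pct[suppressed] <- NA_real_

  age_summary <- rec |>
    dplyr::group_by(.data$cms_id) |>
    dplyr::summarise(
      mean_age = round_half_up(mean(.data$age, na.rm = TRUE), 1),
      sd_age = round_half_up(stats::sd(.data$age, na.rm = TRUE), 1),
      .groups = "drop"
    )
  list(cells = cells, age_summary = age_summary)
}

#' Pre/post-cleaning comparison tables
#'
#' Builds the completeness (percent missing per decision point) and
#' plausibility (percent of cases per first-error rule, plus the
#' at-least-one-inconsistency row) tables side by side for the pre- and
#' post-cleaning audits, by CMS. When no post-cleaning audit is available
#' (a CMS that never supplied a second extraction), the post columns
#' render blank.
#'
#' @param pre_audit a `jj_audit` of the pre-cleaning extract.
#' @param post_audit a `jj_audit` of the cleaned extract, or `NULL`.
#' @return list of two tibbles, `completeness` (`point`, `cms_id`, `pre`,
#'   `post`) and `plausibility` (`rule`, `cms_id`, `pre`, `post`; the
#'   final rule row is `at_least_one`).
#' @export
comparison_tables <- function(pre_audit, post_audit = NULL) {
  stopifnot(inherits(pre_audit, "jj_audit"))
  if (!is.null(post_audit)) {
    stopifnot(inherits(post_audit, "jj_audit"))
    pre_cms <- sort(pre_audit$cms_n$cms_id)
    post_cms <- sort(post_audit$cms_n$cms_id)
    if (!identical(pre_cms, post_cms)) {
      abort_jjdq(
        paste0("pre and post audits cover different CMS sets: {",
               paste(pre_cms, collapse = ", "), "} vs {",
               paste(post_cms, collapse = ", "), "}"),
        "jjdq_structure_error"
      )
    }
  }

  completeness <- pre_audit$completeness_by_cms |>
    dplyr::select("cms_id", "point", pre = "pct")
  plaus_pre <- dplyr::bind_rows(
    dplyr::select(pre_audit$per_rule_by_cms, "cms_id", "rule", pre = "pct"),
    dplyr::mutate(
      dplyr::select(pre_audit$at_least_one_by_cms, "cms_id", pre = "pct"),
      rule = "at_least_one"
    )
  )
  if (is.null(post_audit)) {
    completeness$post <- NA_real_
    plaus_pre$post <- NA_real_
    plausibility <- plaus_pre
  } else {
    completeness <- dplyr::left_join(
      completeness,
      dplyr::select(post_audit$completeness_by_cms, "cms_id", "point",
                    post = "pct"),
      by = c("cms_id", "point")
    )
    plaus_post <- dplyr::bind_rows(
      dplyr::select(post_audit$per_rule_by_cms, "cms_id", "rule",
                    post = "pct"),
      dplyr::mutate(
        dplyr::select(post_audit$at_least_one_by_cms, "cms_id", post = "pct"),
        rule = "at_least_one"
      )
    )
    plausibility <- dplyr::left_join(plaus_pre, plaus_post,
                                     by = c("cms_id", "rule"))
  }
  rule_order <- c(RULE_IDS, "at_least_one")
  plausibility <- plausibility |>
    dplyr::arrange(match(.data$rule, rule_order), .data$cms_id) |>
    dplyr::select("rule", "cms_id", "pre", "post")
  completeness <- completeness |>
    dplyr::arrange(match(.data$point, DECISION_POINTS), .data$cms_id) |>
    dplyr::select("point", "cms_id", "pre", "post")
  list(completeness = completeness, plausibility = plausibility)
}

#' Assemble a quality report
#'
#' @param extract the pre-cleaning `jj_extract` (for demographics).
#' @param pre_audit its audit; computed here when omitted.
#' @param post_audit audit of the cleaned extract, or `NULL` when no
#'   post-cleaning data are available.
#' @param suppress_threshold small-cell suppression threshold for the
#'   demographics table (default 10).
#' @return a `jj_report`: list with `demographics`, `age_summary`,
#'   `completeness`, `plausibility`, `suppression_threshold`, `cms_n`.
#' @export
build_report <- function(extract, pre_audit = NULL, post_audit = NULL,
                         suppress_threshold = 10) {
  pre_audit <- pre_audit %||% audit(extract)
  demo <- demographics_table(extract, suppress_threshold)
  cmp <- comparison_tables(pre_audit, post_audit)
  structure(
    list(
      demographics = demo$cells,
      age_summary = demo$age_summary,
      completeness = cmp$completeness,
      plausibility = cmp$plausibility,
      suppression_threshold = suppress_threshold,
      cms_n = pre_audit$cms_n
    ),
    class = "jj_report"
  )
}

#' Render a quality report
#'
#' `csv` writes `report_demographics.csv`, `report_completeness.csv` and
#' `report_plausibility.csv` into `dir` (pre/post columns spread per CMS);
#' `json` writes `report.json`, which [read_report()] round-trips to an
#' equal report; `text` returns a printable string. Output is
#' deterministic for a fixed report.
#'
#' @param report a `jj_report`.
#' @param format one of `"csv"`, `"json"`, `"text"`.
#' @param dir output directory for file formats (created if needed).
#' @return invisibly, the written file paths (csv/json) or the text string.
#' @export
render_report <- function(report, format = c("csv", "json", "text"),
                          dir = ".") {
  stopifnot(inherits(report, "jj_report"))
  if (length(format) != 1 || !format %in% c("csv", "json", "text")) {
    abort_jjdq("format must be one of: csv, json, text", "jjdq_usage_error")
  }
  if (format == "text") {
    return(invisible(report_text(report)))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (format == "json") {
    path <- file.path(dir, "report.json")
    json <- jsonlite::toJSON(
      list(
        suppression_threshold = report$suppression_threshold,
        cms_n = report$cms_n,
        demographics = report$demographics,
        age_summary = report$age_summary,
        completeness = report$completeness,
        plausibility = report$plausibility
      ),
      dataframe = "columns", auto_unbox = TRUE, digits = NA, na = "null",
      pretty = TRUE
    )
    writeLines(json, path)
    return(invisible(path))
  }
  paths <- c(
    demographics = file.path(dir, "report_demographics.csv"),
    completeness = file.path(dir, "report_completeness.csv"),
    plausibility = file.path(dir, "report_plausibility.csv")
  )
  readr::write_csv(report$demographics, paths[["demographics"]], na = "",
                   progress = FALSE)
  readr::write_csv(spread_phases(report$completeness, "point"),
                   paths[["completeness"]], na = "", progress = FALSE)
  readr::write_csv(spread_phases(report$plausibility, "rule"),
                   paths[["plausibility"]], na = "", progress = FALSE)
  invisible(paths)
}

spread_phases <- function(tbl, key) {
  tbl |>
    tidyr::pivot_longer(c("pre", "post"), names_to = "phase",
                        values_to = "pct") |>
    dplyr::mutate(col = paste0(.data$cms_id, "_", .data$phase)) |>
    dplyr::select(dplyr::all_of(key), "col", "pct") |>
    tidyr::pivot_wider(names_from = "col", values_from = "pct")
}

report_text <- function(report) {
  lines <- c(
    "Quality report",
    paste0("  suppression threshold: ", report$suppression_threshold),
    "", "Demographics (n, % by CMS)",
    utils::capture.output(print(as.data.frame(report$demographics),
                                row.names = FALSE)),
    "", "Completeness (% missing, pre/post)",
    utils::capture.output(print(as.data.frame(
      spread_phases(report$completeness, "point")), row.names = FALSE)),
    "", "Plausibility (% of cases, first error per case, pre/post)",
    utils::capture.output(print(as.data.frame(
      spread_phases(report$plausibility, "rule")), row.names = FALSE))
  )
  paste(lines, collapse = "\n")
}

#' @export
print.jj_report <- function(x, ...) {
  cat(report_text(x), "\n")
  invisible(x)
}

#' Read a JSON quality report back
#'
#' Inverse of `render_report(format = "json")`.
#'
#' @param path path to a `report.json`.
#' @return a `jj_report` equal to the rendered one.
#' @export
read_report <- function(path) {
  j <- jsonlite::fromJSON(path)
  as_tbl <- function(x, int_cols = character(), num_cols = character()) {
    t <- tibble::as_tibble(x)
    for (cc in intersect(int_cols, names(t))) t[[cc]] <- as.integer(t[[cc]])
    for (cc in intersect(num_cols, names(t))) t[[cc]] <- as.numeric(t[[cc]])
    t
  }
  structure(
    list(
      demographics = as_tbl(j$demographics, int_cols = "n",
                            num_cols = "pct"),
      age_summary = as_tbl(j$age_summary, num_cols = c("mean_age", "sd_age")),
      completeness = as_tbl(j$completeness, num_cols = c("pre", "post")),
      plausibility = as_tbl(j$plausibility, num_cols = c("pre", "post")),
      suppression_threshold = j$suppression_threshold,
      cms_n = as_tbl(j$cms_n, int_cols = "n_cases")
    ),
    class = "jj_report"
  )
}
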