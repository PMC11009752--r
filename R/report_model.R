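## Report data model: a report set wraps one tibble with one row per report
## version and list-columns for drug mentions and event preferred terms.

#' Construct a report set
#'
#' A report set is the package's container for spontaneous adverse-event
#' reports. It wraps a tibble with one row per report *version* and the
#' columns:
#'
#' * `report_id` — unique per report version,
#' * `case_id` — stable across versions of the same case,
#' * `version` — non-negative integer,
#' * `receipt_date` — `Date`,
#' * `sex`, `age_band` — see [pv_sexes()], [pv_age_bands()],
#' * `drugs` — list-column of tibbles with `verbatim_name` and `role`,
#' * `events` — list-column of character vectors of preferred terms
#'   (uppercased, non-empty).
#'
#' Every report must carry at least one drug mention and at least one event
#' term; reports violating this are rejected here and dropped (with a
#' warning) by [load_reports()].
#'
#' @param reports A tibble with the columns above.
#' @param provenance Free-text label describing where the reports came from.
#' @return An object of class `report_set`.
#' @seealso [load_reports()], [deduplicate()], [filter_window()]
#' @export
report_set <- function(reports, provenance = "") {
  rs <- new_report_set(tibble::as_tibble(reports), provenance)
  validate_report_set(rs)
  rs
}

new_report_set <- function(reports, provenance = "") {
  structure(list(reports = reports, provenance = provenance),
            class = "report_set")
}

validate_report_set <- function(rs) {
  tbl <- rs$reports
  needed <- c("report_id", "case_id", "version", "receipt_date", "sex",
              "age_band", "drugs", "events")
  missing <- setdiff(needed, names(tbl))
  if (length(missing) > 0) {
    pv_abort(paste0("report set is missing column(s): ",
                    paste(missing, collapse = ", ")))
  }
  if (nrow(tbl) == 0) return(invisible(rs))
  if (any(tbl$version < 0, na.rm = TRUE)) {
    pv_abort("report versions must be non-negative")
  }
  if (!all(tbl$sex %in% pv_sexes())) {
    pv_abort("sex values must be one of F, M, NS")
  }
  if (!all(tbl$age_band %in% pv_age_bands())) {
    pv_abort("age_band values must be one of the enumerated bands")
  }
  if (any(lengths(tbl$events) == 0)) {
    pv_abort("every report must carry at least one event term")
  }
  if (any(vapply(tbl$drugs, nrow, integer(1)) == 0)) {
    pv_abort("every report must carry at least one drug mention")
  }
  invisible(rs)
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("<report_set: %d report(s)%s>\n", nrow(x$reports),
              if (nzchar(x$provenance)) paste0(", ", x$provenance) else ""))
  if (nrow(x$reports) > 0) print(utils::head(x$reports, 5))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.report_set <- function(x, ...) x$reports

#' Number of reports in a report set
#' @param rs A [report_set()].
#' @return Integer count of report rows.
#' @export
n_reports <- function(rs) nrow(rs$reports)

#' Read spontaneous reports from disk
#'
#' Two dialects are supported. The *native* format is a UTF-8 CSV with a
#' header and one row per (report, drug, event) triple; required columns are
#' `report_id`, `case_id`, `version`, `receipt_date` (ISO-8601, partial
#' dates allowed), `sex` (F/M/NS), `drug_verbatim`, `drug_role`
#' (PS/SS/C/I/NS) and `event_pt`, with optional `age` (years) and `age_band`
#' (the band wins when both are present). Rows sharing a `report_id` are
#' merged into one report. The *faers_ascii* dialect reads a directory of
#' `"$"`-delimited DEMO/DRUG/REAC quarterly extract files keyed by
#' `primaryid`/`caseid`.
#'
#' Unparseable sex or age values become `NS`; event terms are uppercased and
#' trimmed before matching. Reports without any event term (or without any
#' drug mention) cannot satisfy the report invariant and are dropped with a
#' warning. An empty input file yields an empty report set, not an error. One
#' summary line per load reports rows read, reports formed and records
#' dropped.
#'
#' @param path File path (native) or directory path (faers_ascii).
#' @param format `"native"` or `"faers_ascii"`.
#' @return A [report_set()].
#' @export
load_reports <- function(path, format = c("native", "faers_ascii")) {
  format <- match.arg(format)
  switch(format,
         native = load_native(path),
         faers_ascii = load_faers_ascii(path))
}

load_native <- function(path) {
  if (!file.exists(path)) pv_abort(paste0("no such file: ", path))
  if (file.size(path) == 0) {
    return(new_report_set(empty_report_tbl(), provenance = path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    show_col_types = FALSE)
  mandatory <- c("report_id", "case_id", "version", "receipt_date", "sex",
                 "drug_verbatim", "drug_role", "event_pt")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing) > 0) {
    pv_abort(paste0("native report file is missing mandatory column(s): ",
                    paste(missing, collapse = ", ")),
             class = "pv_format_error")
  }
  if (nrow(raw) == 0) {
    return(new_report_set(empty_report_tbl(), provenance = path))
  }
  if (!"age" %in% names(raw)) raw$age <- NA_character_
  if (!"age_band" %in% names(raw)) raw$age_band <- NA_character_

  band_from_label <- normalize_age_band(raw$age_band)
  band <- dplyr::coalesce(band_from_label, age_to_band(raw$age))

  rows <- tibble::tibble(
    report_id = trimws(raw$report_id),
    case_id = trimws(raw$case_id),
    version = suppressWarnings(as.integer(raw$version)),
    receipt_date = parse_report_date(raw$receipt_date),
    sex = normalize_sex(raw$sex),
    age_band = band,
    drug_verbatim = trimws(raw$drug_verbatim),
    drug_role = dplyr::coalesce(
      unname(.role_from_code[toupper(trimws(raw$drug_role))]), "unknown"),
    event_pt = normalize_pt(raw$event_pt)
  )
  assemble_reports(rows, n_rows_read = nrow(raw), provenance = path)
}

# collapse normalized (report, drug, event) rows into one row per report
assemble_reports <- function(rows, n_rows_read, provenance) {
  by_report <- rows |>
    dplyr::group_by(.data$report_id) |>
    dplyr::summarise(
      case_id = dplyr::first(.data$case_id),
      version = dplyr::first(.data$version),
      receipt_date = dplyr::first(.data$receipt_date),
      sex = dplyr::first(.data$sex),
      age_band = dplyr::first(.data$age_band),
      drugs = {
        v <- .data$drug_verbatim
        r <- .data$drug_role
        keep <- !is.na(v) & nzchar(v)
        list(dplyr::distinct(
          tibble::tibble(verbatim_name = v[keep], role = r[keep])))
      },
      events = {
        e <- .data$event_pt
        list(sort(unique(e[!is.na(e) & nzchar(e)])))
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$report_id)
  by_report$version[is.na(by_report$version)] <- 0L

  keep <- lengths(by_report$events) > 0 &
    vapply(by_report$drugs, nrow, integer(1)) > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    rlang::warn(sprintf(
      "dropped %d report(s) with no event term or no drug mention", n_dropped))
  }
  rlang::inform(sprintf(
    "load: %d row(s) read, %d report(s) formed, %d dropped",
    n_rows_read, sum(keep), n_dropped))
  new_report_set(by_report[keep, , drop = FALSE], provenance = provenance)
}

empty_report_tbl <- function() {
  tibble::tibble(
    report_id = character(), case_id = character(), version = integer(),
    receipt_date = as.Date(character()), sex = character(),
    age_band = character(), drugs = list(), events = list()
  )
}

#' Write a report set in the native CSV format
#'
#' Expands each report back into one row per (report, drug, event) triple so
#' that [load_reports()] round-trips to an equal report set.
#'
#' @param rs A [report_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_native <- function(rs, path) {
  tbl <- rs$reports
  if (nrow(tbl) == 0) {
    readr::write_csv(tibble::tibble(
      report_id = character(), case_id = character(), version = integer(),
      receipt_date = character(), sex = character(), age_band = character(),
      drug_verbatim = character(), drug_role = character(),
      event_pt = character()), path)
    return(invisible(path))
  }
  out <- tbl |>
    tidyr::unnest("drugs") |>
    tidyr::unchop("events") |>
    dplyr::transmute(
      report_id = .data$report_id,
      case_id = .data$case_id,
      version = .data$version,
      receipt_date = format(.data$receipt_date, "%Y-%m-%d"),
      sex = .data$sex,
      age_band = .data$age_band,
      drug_verbatim = .data$verbatim_name,
      drug_role = unname(.role_to_code[.data$role]),
      event_pt = .data$events
    )
  readr::write_csv(out, path)
  invisible(path)
}

#' Deduplicate case versions
#'
#' Spontaneous-report databases receive resubmitted versions of the same
#' case. For each `case_id` exactly one report is retained: the one with the
#' highest `version`, ties broken by latest `receipt_date`, then by
#' lexicographically largest `report_id`. Output is sorted by `case_id`, so
#' the operation is deterministic and idempotent.
#'
#' @param rs A [report_set()].
#' @return A [report_set()] with unique `case_id`s.
#' @export
deduplicate <- function(rs) {
  tbl <- rs$reports |>
    dplyr::arrange(.data$case_id, dplyr::desc(.data$version),
                   dplyr::desc(.data$receipt_date),
                   dplyr::desc(.data$report_id)) |>
    dplyr::distinct(.data$case_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$case_id)
  new_report_set(tbl, provenance = rs$provenance)
}

#' Filter reports by receipt-date window
#'
#' Retains reports whose `receipt_date` lies in `[start, end]`, both ends
#' inclusive. Reports with an unparseable (missing) receipt date are
#' excluded, since window membership cannot be established.
#'
#' @param rs A [report_set()].
#' @param start,end Window bounds (`Date` or ISO-8601 strings);
#'   `start <= end` is required.
#' @return The filtered [report_set()].
#' @export
filter_window <- function(rs, start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end)) pv_abort("window bounds must be valid dates")
  if (start > end) pv_abort("window start must not be after window end")
  keep <- !is.na(rs$reports$receipt_date) &
    rs$reports$receipt_date >= start & rs$reports$receipt_date <= end
  new_report_set(rs$reports[keep, , drop = FALSE], provenance = rs$provenance)
}
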