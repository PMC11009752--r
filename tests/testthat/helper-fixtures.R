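# shared fixtures: the demo vocabulary and builders for tiny native files

demo_vocab <- pv_demo_vocabulary()

# one native-format row; override fields as needed
native_row <- function(report_id, case_id = report_id, version = 1,
                       receipt_date = "2021-01-01", sex = "F", age = NA,
                       age_band = NA, drug = "tiotropium", role = "PS",
                       pt = "HEADACHE") {
  tibble::tibble(
    report_id = report_id, case_id = case_id, version = version,
    receipt_date = receipt_date, sex = sex, age = age, age_band = age_band,
    drug_verbatim = drug, drug_role = role, event_pt = pt
  )
}

# write rows to a temp CSV cleaned up with the calling test
write_native_fixture <- function(rows, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = envir)
  readr::write_csv(rows, path)
  path
}

load_quiet <- function(path, format = "native") {
  suppressWarnings(suppressMessages(load_reports(path, format = format)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# build an in-memory report set from (id, drug(s), events, ...) specs
mk_reports <- function(...) {
  specs <- list(...)
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    tibble::tibble(
      report_id = s$id %||% sprintf("R%03d", i),
      case_id = s$id %||% sprintf("R%03d", i),
      version = 1L,
      receipt_date = as.Date("2021-06-15"),
      sex = s$sex %||% "F",
      age_band = s$band %||% "NS",
      drugs = list(tibble::tibble(
        verbatim_name = s$drug,
        role = s$role %||% rep("primary_suspect", length(s$drug)))),
      events = list(toupper(s$events))
    )
  })
  report_set(dplyr::bind_rows(rows))
}

# canonical form of a report set for equality comparison
canonical_reports <- function(rs) {
  tbl <- tibble::as_tibble(rs)
  tbl$drugs <- lapply(tbl$drugs, function(d) {
    dplyr::arrange(d, .data$verbatim_name, .data$role)
  })
  dplyr::arrange(tbl, .data$report_id)
}
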