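## Reader for the "$"-delimited DEMO/DRUG/REAC quarterly extract dialect.
## The three files live in one directory and are joined on primaryid; caseid
## and caseversion come from DEMO, verbatim drug names and role codes from
## DRUG, preferred terms from REAC.

load_faers_ascii <- function(path) {
  if (!dir.exists(path)) {
    pv_abort(paste0("faers_ascii expects a directory: ", path),
             class = "pv_format_error")
  }
  demo <- read_faers_table(path, "demo",
                           required = c("primaryid", "caseid"))
  drug <- read_faers_table(path, "drug",
                           required = c("primaryid", "drugname"))
  reac <- read_faers_table(path, "reac",
                           required = c("primaryid", "pt"))

  n_rows <- nrow(demo) + nrow(drug) + nrow(reac)

  sex_col <- if ("sex" %in% names(demo)) demo$sex else demo[["gndr_cod"]]
  if (is.null(sex_col)) sex_col <- rep(NA_character_, nrow(demo))
  age_years <- faers_age_years(demo)

  demo_tbl <- tibble::tibble(
    report_id = trimws(demo$primaryid),
    case_id = trimws(demo$caseid),
    version = faers_version(demo),
    receipt_date = parse_report_date(demo[["fda_dt"]] %||%
                                       rep(NA_character_, nrow(demo))),
    sex = normalize_sex(sex_col),
    age_band = age_to_band(age_years)
  )

  drug_tbl <- tibble::tibble(
    report_id = trimws(drug$primaryid),
    verbatim_name = trimws(drug$drugname),
    role = dplyr::coalesce(unname(.role_from_code[
      toupper(trimws(drug[["role_cod"]] %||%
                       rep(NA_character_, nrow(drug))))]), "unknown")
  ) |>
    dplyr::filter(nzchar(.data$verbatim_name)) |>
    dplyr::distinct()

  reac_tbl <- tibble::tibble(
    report_id = trimws(reac$primaryid),
    event_pt = normalize_pt(reac$pt)
  ) |>
    dplyr::filter(nzchar(.data$event_pt)) |>
    dplyr::distinct()

  by_report <- demo_tbl |>
    dplyr::left_join(
      drug_tbl |> dplyr::group_by(.data$report_id) |>
        dplyr::summarise(drugs = {
          v <- .data$verbatim_name
          r <- .data$role
          list(tibble::tibble(verbatim_name = v, role = r))
        }, .groups = "drop"),
      by = "report_id") |>
    dplyr::left_join(
      reac_tbl |> dplyr::group_by(.data$report_id) |>
        dplyr::summarise(events = list(sort(unique(.data$event_pt))),
                         .groups = "drop"),
      by = "report_id") |>
    dplyr::arrange(.data$report_id)

  by_report$drugs <- lapply(by_report$drugs, function(d) {
    if (is.null(d)) tibble::tibble(verbatim_name = character(),
                                   role = character()) else d
  })
  by_report$events <- lapply(by_report$events, function(e) {
    if (is.null(e)) character() else e
  })

  keep <- lengths(by_report$events) > 0 &
    vapply(by_report$drugs, nrow, integer(1)) > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    rlang::warn(sprintf(
      "dropped %d report(s) with no event term or no drug mention", n_dropped))
  }
  rlang::inform(sprintf(
    "load: %d row(s) read, %d report(s) formed, %d dropped",
    n_rows, sum(keep), n_dropped))
  new_report_set(by_report[keep, , drop = FALSE], provenance = path)
}

read_faers_table <- function(dir, stem, required) {
  hits <- list.files(dir, pattern = paste0("^", stem), ignore.case = TRUE,
                     full.names = TRUE)
  if (length(hits) == 0) {
    pv_abort(paste0("faers_ascii directory lacks a ", toupper(stem), " file"),
             class = "pv_format_error")
  }
  tbl <- readr::read_delim(hits[[1]], delim = "$",
                           col_types = readr::cols(
                             .default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  names(tbl) <- tolower(names(tbl))
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    pv_abort(paste0(toupper(stem), " file is missing mandatory column(s): ",
                    paste(missing, collapse = ", ")),
             class = "pv_format_error")
  }
  tbl
}

faers_version <- function(demo) {
  v <- suppressWarnings(as.integer(demo[["caseversion"]] %||%
                                     rep(NA_character_, nrow(demo))))
  v[is.na(v)] <- 0L
  v
}

# convert DEMO age + age unit code to years; unparseable -> NA
faers_age_years <- function(demo) {
  age <- suppressWarnings(as.numeric(demo[["age"]] %||%
                                       rep(NA_character_, nrow(demo))))
  cod <- toupper(trimws(demo[["age_cod"]] %||% rep("YR", nrow(demo))))
  cod[is.na(cod) | !nzchar(cod)] <- "YR"
  mult <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52, DY = 1 / 365,
            HR = 1 / (365 * 24))
  m <- unname(mult[cod])
  m[is.na(m)] <- 1
  age * m
}

`%||%` <- function(x, y) if (is.null(x)) y else x
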