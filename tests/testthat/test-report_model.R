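test_that("native loader merges rows by report and normalizes fields", {
  rows <- dplyr::bind_rows(
    native_row("R1", pt = "Atrial Fibrillation "),
    native_row("R1", pt = "cardiac failure"),
    native_row("R1", pt = "HEADACHE"),
    native_row("R2", sex = "male", age = 70, pt = "nausea")
  )
  rs <- load_quiet(write_native_fixture(rows))
  expect_equal(n_reports(rs), 2)
  tbl <- tibble::as_tibble(rs)
  r1 <- tbl[tbl$report_id == "R1", ]
  expect_equal(r1$events[[1]],
               c("ATRIAL FIBRILLATION", "CARDIAC FAILURE", "HEADACHE"))
  r2 <- tbl[tbl$report_id == "R2", ]
  expect_equal(r2$sex, "M")
  expect_equal(r2$age_band, "65to85")
})

test_that("sex, role and age banding map unknowns to NS/unknown", {
  rows <- dplyr::bind_rows(
    native_row("R1", sex = "weiblich", role = "XX"),
    native_row("R2", age = 17), native_row("R3", age = 18),
    native_row("R4", age = 64), native_row("R5", age = 65),
    native_row("R6", age = 85), native_row("R7", age = 86),
    native_row("R8", age = 40, age_band = "over85") # band wins over age
  )
  tbl <- tibble::as_tibble(load_quiet(write_native_fixture(rows)))
  expect_equal(tbl$sex[tbl$report_id == "R1"], "NS")
  expect_equal(tbl$drugs[tbl$report_id == "R1"][[1]]$role, "unknown")
  bands <- tbl$age_band[match(paste0("R", 2:8), tbl$report_id)]
  expect_equal(bands, c("under18", "18to64", "18to64", "65to85", "65to85",
                        "over85", "over85"))
})

test_that("missing mandatory columns are named; empty input is not an error", {
  rows <- native_row("R1")
  rows$event_pt <- NULL
  rows$case_id <- NULL
  err <- expect_error(load_reports(write_native_fixture(rows)),
                      class = "pv_format_error")
  expect_match(conditionMessage(err), "case_id")
  expect_match(conditionMessage(err), "event_pt")

  empty <- write_native_fixture(native_row("R1")[0, ])
  expect_equal(n_reports(load_quiet(empty)), 0)
})

test_that("reports without any event term are dropped with a warning", {
  rows <- dplyr::bind_rows(
    native_row("R1", pt = "HEADACHE"),
    native_row("R2", pt = "")
  )
  path <- write_native_fixture(rows)
  expect_warning(suppressMessages(load_reports(path)), "dropped 1")
  rs <- load_quiet(path)
  expect_equal(tibble::as_tibble(rs)$report_id, "R1")
})

test_that("partial receipt dates coerce to the first of the period", {
  expect_equal(parse_report_date("202001"), as.Date("2020-01-01"))
  expect_equal(parse_report_date("2023-09"), as.Date("2023-09-01"))
  expect_equal(parse_report_date("2021"), as.Date("2021-01-01"))
  expect_equal(parse_report_date("20230930"), as.Date("2023-09-30"))
  expect_true(is.na(parse_report_date("not a date")))
})

test_that("deduplicate keeps the highest version with date and id tie-breaks", {
  rows <- dplyr::bind_rows(
    native_row("R1", case_id = "C1", version = 1, pt = "HEADACHE"),
    native_row("R2", case_id = "C1", version = 2, pt = "NAUSEA"),
    # equal versions: latest receipt date wins
    native_row("R3", case_id = "C2", version = 2,
               receipt_date = "2021-01-01", pt = "COUGH"),
    native_row("R4", case_id = "C2", version = 2,
               receipt_date = "2021-06-01", pt = "RASH"),
    # fully tied: lexicographically largest report_id wins
    native_row("R5", case_id = "C3", version = 1, pt = "FATIGUE"),
    native_row("R6", case_id = "C3", version = 1, pt = "PRURITUS")
  )
  rs <- deduplicate(load_quiet(write_native_fixture(rows)))
  tbl <- tibble::as_tibble(rs)
  expect_equal(tbl$report_id, c("R2", "R4", "R6"))
  expect_equal(tbl$case_id, c("C1", "C2", "C3"))

  # idempotence
  expect_identical(canonical_reports(deduplicate(rs)), canonical_reports(rs))
})

test_that("deduplicate leaves already-unique cases unchanged up to order", {
  rows <- dplyr::bind_rows(native_row("R2", case_id = "C2"),
                           native_row("R1", case_id = "C1"))
  rs <- load_quiet(write_native_fixture(rows))
  expect_identical(canonical_reports(deduplicate(rs)), canonical_reports(rs))
})

test_that("filter_window is inclusive at both ends and validates bounds", {
  rows <- dplyr::bind_rows(
    native_row("R1", receipt_date = "2023-09-30"),
    native_row("R2", receipt_date = "2023-10-01"),
    native_row("R3", receipt_date = "2020-01-01"),
    native_row("R4", receipt_date = "2019-12-31")
  )
  rs <- load_quiet(write_native_fixture(rows))
  kept <- filter_window(rs, "2020-01-01", "2023-09-30")
  expect_equal(sort(tibble::as_tibble(kept)$report_id), c("R1", "R3"))
  expect_error(filter_window(rs, "2023-01-01", "2020-01-01"),
               "start must not be after")
})

test_that("window filtering never grows the set and a covering window is identity", {
  dates <- sprintf("20%02d-06-15", 15:24)
  rows <- dplyr::bind_rows(lapply(seq_along(dates), function(i) {
    native_row(sprintf("R%02d", i), receipt_date = dates[i])
  }))
  rs <- load_quiet(write_native_fixture(rows))
  inside <- filter_window(rs, "2020-01-01", "2023-09-30") # 2020..2023 -> 4
  expect_equal(n_reports(inside), 4)
  expect_lte(n_reports(inside), n_reports(rs))
  all_of_it <- filter_window(rs, "1900-01-01", "2100-01-01")
  expect_identical(canonical_reports(all_of_it), canonical_reports(rs))
})

test_that("native write/load round-trips to an equal report set", {
  rows <- dplyr::bind_rows(
    native_row("R1", sex = "F", age_band = "65to85",
               drug = "tiotropium bromide", pt = "ATRIAL FIBRILLATION"),
    native_row("R1", sex = "F", age_band = "65to85",
               drug = "umeclidinium", role = "SS", pt = "HEADACHE"),
    native_row("R2", sex = "M", drug = "glycopyrrolate", role = "C",
               pt = "NAUSEA")
  )
  rs <- load_quiet(write_native_fixture(rows))
  out <- withr::local_tempfile(fileext = ".csv")
  write_native(rs, out)
  rs2 <- load_quiet(out)
  expect_identical(canonical_reports(rs2), canonical_reports(rs))
})

test_that("faers_ascii dialect joins DEMO/DRUG/REAC and drops event-less cases", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "primaryid$caseid$caseversion$fda_dt$age$age_cod$sex",
    "1001$100$1$20210315$72$YR$F",
    "2001$200$2$202106$6$MON$M"
  ), file.path(dir, "DEMO23Q1.txt"))
  writeLines(c(
    "primaryid$caseid$role_cod$drugname",
    "1001$100$PS$TIOTROPIUM BROMIDE",
    "1001$100$C$ASPIRIN",
    "2001$200$PS$UMECLIDINIUM"
  ), file.path(dir, "DRUG23Q1.txt"))
  writeLines(c(
    "primaryid$caseid$pt",
    "1001$100$Atrial fibrillation",
    "1001$100$Dyspnoea"
    # no REAC rows for case 2001: it cannot satisfy the report invariant
  ), file.path(dir, "REAC23Q1.txt"))

  expect_warning(suppressMessages(load_reports(dir, format = "faers_ascii")),
                 "dropped 1")
  rs <- load_quiet(dir, format = "faers_ascii")
  expect_equal(n_reports(rs), 1)
  tbl <- tibble::as_tibble(rs)
  expect_equal(tbl$report_id, "1001")
  expect_equal(tbl$case_id, "100")
  expect_equal(tbl$receipt_date, as.Date("2021-03-15"))
  expect_equal(tbl$sex, "F")
  expect_equal(tbl$age_band, "65to85")
  expect_equal(tbl$events[[1]], c("ATRIAL FIBRILLATION", "DYSPNOEA"))
  expect_equal(tbl$drugs[[1]]$role, c("primary_suspect", "concomitant"))
})
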