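#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.125 -> 0.13 at 2 digits), the
#' convention used when displaying reporting odds ratios and percentages.
#' Base [round()] rounds half to even, which gives different printed values
#' for exact .5 ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(1.605, 2) # 1.61, where round() gives 1.6
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Parse possibly partial report dates
#'
#' Spontaneous-report receipt dates are sometimes reported without a day or
#' month component. This parser accepts `YYYY-MM-DD`, `YYYYMMDD`, `YYYY-MM`,
#' `YYYYMM` and `YYYY`; missing components are coerced to the first of the
#' month (or January 1), so that window filtering is total. Anything else
#' parses to `NA`.
#'
#' @param x Character vector (or `Date`, returned unchanged).
#' @return A `Date` vector.
#' @export
parse_report_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  full <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[full] <- as.Date(x[full], format = "%Y-%m-%d")
  compact <- grepl("^\\d{8}$", x)
  out[compact] <- as.Date(x[compact], format = "%Y%m%d")
  ym_dash <- grepl("^\\d{4}-\\d{2}$", x)
  out[ym_dash] <- as.Date(paste0(x[ym_dash], "-01"), format = "%Y-%m-%d")
  ym <- grepl("^\\d{6}$", x)
  out[ym] <- as.Date(paste0(x[ym], "01"), format = "%Y%m%d")
  y <- grepl("^\\d{4}$", x)
  out[y] <- as.Date(paste0(x[y], "-01-01"), format = "%Y-%m-%d")
  out
}

#' Assign ages in years to age bands
#'
#' Band boundaries are 18, 65 and 85, with 85 itself belonging to the
#' `65to85` band; missing ages map to `"NS"`.
#'
#' @param age Numeric vector of ages in years.
#' @return Character vector of age bands (see [pv_age_bands()]).
#' @export
age_to_band <- function(age) {
  age <- suppressWarnings(as.numeric(age))
  dplyr::case_when(
    is.na(age) ~ "NS",
    age < 18 ~ "under18",
    age < 65 ~ "18to64",
    age <= 85 ~ "65to85",
    .default = "over85"
  )
}

# normalize free-text sex to the F/M/NS enum
normalize_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  dplyr::case_when(
    x %in% c("F", "FEMALE") ~ "F",
    x %in% c("M", "MALE") ~ "M",
    .default = "NS"
  )
}

# normalize an age-band label; NA when unrecognized (caller falls back to age)
normalize_age_band <- function(x) {
  x <- tolower(gsub("[ _-]", "", trimws(as.character(x))))
  key <- c(
    under18 = "under18", "<18" = "under18",
    "18to64" = "18to64", "1864" = "18to64",
    "65to85" = "65to85", "6585" = "65to85",
    over85 = "over85", ">85" = "over85", morethan85 = "over85",
    ns = "NS", unknown = "NS"
  )
  unname(key[x])
}

# normalize preferred terms for matching: trim + uppercase
normalize_pt <- function(x) toupper(trimws(as.character(x)))

# abort with a class so the CLI can map validation failures to exit code 2
pv_abort <- function(msg, class = "pv_error") {
  rlang::abort(msg, class = c(class, "pv_error"))
}
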