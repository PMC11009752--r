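## Reporting odds ratio on 2x2 contingency tables built under an
## active-comparator (or rest-of-database) design, with log-scale Wald
## confidence intervals and the lower-bound signal criterion.

#' A 2x2 reporting contingency table
#'
#' Cell `a` counts target-exposure reports with at least one event in the
#' event group of interest, `b` those with none; `c` and `d` are the same
#' split for the comparator cohort. Counting is *case-level*: a report with
#' several qualifying preferred terms still contributes exactly one case, so
#' `a + b` is the target cohort size and `c + d` the comparator cohort size.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return An object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    pv_abort("all four cells must be non-negative integers")
  }
  structure(as.list(cells), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
              dimnames = list(c("target", "comparator"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

#' Define an exposure-vs-comparator design
#'
#' The target cohort is every report exposed to at least one target product;
#' the comparator cohort is either every report exposed to at least one of a
#' reference product set (active-comparator design) or every report *not*
#' exposed to any target product (rest-of-database design). With
#' `exclusive = TRUE` (the default), reports exposed to both target and
#' reference products are dropped from both cohorts and the dropped count is
#' logged — a report cannot serve as its own comparator.
#'
#' @param target Non-empty character vector of target product ids.
#' @param comparator Character vector of reference product ids, or the
#'   string `"rest_of_database"`.
#' @param exclusive Drop reports exposed to both cohorts?
#' @return An object of class `comparator_design`.
#' @export
comparator_design <- function(target, comparator = "rest_of_database",
                              exclusive = TRUE) {
  target <- as.character(target)
  if (length(target) == 0) pv_abort("design needs at least one target product")
  rest <- identical(comparator, "rest_of_database")
  if (!rest && length(comparator) == 0) {
    pv_abort("reference comparator set must be non-empty")
  }
  structure(list(target = target,
                 comparator = if (rest) "rest_of_database"
                 else as.character(comparator),
                 rest_of_database = rest,
                 exclusive = isTRUE(exclusive)),
            class = "comparator_design")
}

# per-report exposure product sets, vectorized over the report table
report_exposures <- function(tbl, vocabulary, roles) {
  n <- nrow(tbl)
  out <- vector("list", n)
  out[] <- list(character())
  if (n == 0) return(out)
  long <- tibble::tibble(.row = seq_len(n), drugs = tbl$drugs) |>
    tidyr::unnest("drugs")
  long$product <- normalize_drug(vocabulary, long$verbatim_name)
  keep <- !is.na(long$product) & long$role %in% roles
  if (any(keep)) {
    got <- split(long$product[keep], long$.row[keep])
    out[as.integer(names(got))] <-
      lapply(got, function(p) if (length(p) > 1) unique(p) else p)
  }
  out
}

# logical: does each report carry >=1 PT of the group? (case-level)
report_has_event <- function(tbl, vocabulary, group_id) {
  n <- nrow(tbl)
  has <- logical(n)
  if (n == 0) return(has)
  long <- tibble::tibble(.row = seq_len(n), events = tbl$events) |>
    tidyr::unchop("events")
  hit_rows <- long$.row[pts_in_group(vocabulary, long$events, group_id)]
  has[unique(hit_rows)] <- TRUE
  has
}

#' Build the 2x2 table for one comparison
#'
#' Assigns each (deduplicated) report to the target cohort, the comparator
#' cohort, or neither, according to `design`, and splits each cohort by
#' whether the report carries at least one preferred term of `group_id`.
#' Counting is case-level: a report with three qualifying cardiac terms adds
#' 1 to cell `a`, not 3. Under an exclusive design, reports exposed to both
#' cohorts are dropped and their number logged; the dropped count is also
#' attached as attribute `n_dual_dropped`.
#'
#' @param rs A deduplicated [report_set()].
#' @param vocabulary A [pv_vocabulary()].
#' @param design A [comparator_design()].
#' @param group_id Event-group id present in the vocabulary.
#' @param roles Drug roles that count as exposure (see
#'   [exposure_products()]).
#' @return A [two_by_two()].
#' @export
build_contingency <- function(rs, vocabulary, design, group_id,
                              roles = c("primary_suspect",
                                        "secondary_suspect", "unknown")) {
  if (!group_id %in% names(vocabulary$event_groups)) {
    pv_abort(paste0("unknown event group: ", group_id),
             class = "pv_validation_error")
  }
  tbl <- rs$reports
  expo <- report_exposures(tbl, vocabulary, roles)
  in_target <- vapply(expo, function(p) any(p %in% design$target), logical(1))
  in_comp <- if (design$rest_of_database) {
    !in_target
  } else {
    vapply(expo, function(p) any(p %in% design$comparator), logical(1))
  }
  both <- in_target & in_comp
  n_dual <- sum(both)
  if (design$exclusive && n_dual > 0) {
    rlang::inform(sprintf(
      "dropped %d report(s) exposed to both target and comparator", n_dual))
    in_target[both] <- FALSE
    in_comp[both] <- FALSE
  }
  ev <- report_has_event(tbl, vocabulary, group_id)
  t <- two_by_two(
    a = sum(in_target & ev), b = sum(in_target & !ev),
    c = sum(in_comp & ev), d = sum(in_comp & !ev)
  )
  attr(t, "n_dual_dropped") <- n_dual
  t
}

#' Reporting odds ratio with 95% Wald interval and signal flag
#'
#' The point estimate is the cross-product odds ratio
#' `ROR = (a/b) / (c/d)`; its log-scale standard error is
#' `sqrt(1/a + 1/b + 1/c + 1/d)` and the 95% confidence interval is
#' `exp(ln(ROR) -/+ 1.959964 * SE)`. A result is flagged as a signal when
#' the lower confidence bound strictly exceeds 1 *and* there are at least 3
#' event cases (`a >= 3`).
#'
#' With `correction = "none"` any zero cell makes the estimate undefined and
#' raises a degenerate-table error naming the cell. With
#' `correction = "haldane_half"` (Haldane–Anscombe), 0.5 is added to all
#' four cells whenever any cell is zero — intended for exploratory output
#' only; `n_cases` always reports the uncorrected `a`.
#'
#' @param t A [two_by_two()].
#' @param correction `"none"` or `"haldane_half"`.
#' @return An object of class `ror_result` with elements `ror`, `ci_lower`,
#'   `ci_upper`, `n_cases`, `is_signal`, `correction_applied` and the input
#'   `table`.
#' @examples
#' # aclidinium (188 cardiac cases of 1254 reports) vs tiotropium
#' # (1238 of 12472): ROR 1.60, 95% CI 1.36-1.89
#' ror(two_by_two(188, 1066, 1238, 11234))
#' @export
ror <- function(t, correction = c("none", "haldane_half")) {
  correction <- match.arg(correction)
  stopifnot(inherits(t, "two_by_two"))
  cells <- c(a = t$a, b = t$b, c = t$c, d = t$d)
  applied <- FALSE
  if (any(cells == 0)) {
    if (correction == "none") {
      zero <- names(cells)[cells == 0][1]
      pv_abort(paste0("degenerate 2x2 table: cell '", zero,
                      "' is zero (use correction = \"haldane_half\" ",
                      "for exploratory estimates)"),
               class = "pv_degenerate_table")
    }
    cells <- cells + 0.5
    applied <- TRUE
  }
  est <- (cells[["a"]] / cells[["b"]]) / (cells[["c"]] / cells[["d"]])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(0.975)
  lo <- exp(log(est) - z * se)
  hi <- exp(log(est) + z * se)
  structure(list(
    ror = est, ci_lower = lo, ci_upper = hi,
    n_cases = t$a,
    is_signal = signal_rule(lo, t$a),
    correction_applied = applied,
    table = t
  ), class = "ror_result")
}

signal_rule <- function(ci_lower, n_cases) {
  isTRUE(ci_lower > 1) && n_cases >= 3
}

#' Signal criterion
#'
#' A disproportionality result is a signal when the lower bound of its 95%
#' confidence interval is strictly greater than 1 and it rests on at least 3
#' event cases.
#'
#' @param r A `ror_result` (from [ror()]).
#' @return Logical.
#' @export
is_signal <- function(r) {
  stopifnot(inherits(r, "ror_result"))
  signal_rule(r$ci_lower, r$n_cases)
}

#' @export
print.ror_result <- function(x, ...) {
  cat(sprintf("ROR %.2f (95%% CI %.2f-%.2f), %d case(s)%s%s\n",
              round_half_up(x$ror, 2), round_half_up(x$ci_lower, 2),
              round_half_up(x$ci_upper, 2), x$n_cases,
              if (x$is_signal) " [signal]" else "",
              if (x$correction_applied) " [0.5 correction]" else ""))
  invisible(x)
}

#' @export
as.data.frame.ror_result <- function(x, ...) {
  data.frame(a = x$table$a, b = x$table$b, c = x$table$c, d = x$table$d,
             ror = x$ror, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
             n_cases = x$n_cases, is_signal = x$is_signal,
             correction_applied = x$correction_applied)
}

#' Stratified reporting odds ratios
#'
#' Splits the report set by sex or by age band, builds the 2x2 table within
#' each stratum that occurs in the data, and estimates the ROR per stratum.
#' Strata where a cohort is empty or (without correction) a cell is zero are
#' reported as degenerate rows carrying the counts, `NA` estimates and a
#' reason code, rather than being silently dropped. No pooling across strata
#' is performed.
#'
#' @inheritParams build_contingency
#' @param strata `"sex"` or `"age_band"`.
#' @param correction Passed to [ror()].
#' @return A tibble with one row per stratum: the stratum label, the four
#'   cells, `ror`, `ci_lower`, `ci_upper`, `n_cases`, `is_signal`,
#'   `correction_applied` and `degenerate_reason` (`NA` for estimable
#'   strata).
#' @export
stratified_rors <- function(rs, vocabulary, design, group_id,
                            strata = c("sex", "age_band"),
                            correction = c("none", "haldane_half"),
                            roles = c("primary_suspect", "secondary_suspect",
                                      "unknown")) {
  strata <- match.arg(strata)
  correction <- match.arg(correction)
  levels_order <- if (strata == "sex") pv_sexes() else pv_age_bands()
  present <- intersect(levels_order, unique(rs$reports[[strata]]))
  rows <- lapply(present, function(lev) {
    sub <- new_report_set(
      rs$reports[rs$reports[[strata]] == lev, , drop = FALSE],
      provenance = rs$provenance)
    t <- suppressMessages(
      build_contingency(sub, vocabulary, design, group_id, roles = roles))
    base <- tibble::tibble(stratum = lev, a = t$a, b = t$b, c = t$c, d = t$d)
    if (t$a + t$b == 0 || t$c + t$d == 0) {
      return(dplyr::mutate(base, ror = NA_real_, ci_lower = NA_real_,
                           ci_upper = NA_real_, n_cases = t$a,
                           is_signal = FALSE, correction_applied = FALSE,
                           degenerate_reason = "empty_cohort"))
    }
    r <- tryCatch(ror(t, correction = correction),
                  pv_degenerate_table = function(e) NULL)
    if (is.null(r)) {
      return(dplyr::mutate(base, ror = NA_real_, ci_lower = NA_real_,
                           ci_upper = NA_real_, n_cases = t$a,
                           is_signal = FALSE, correction_applied = FALSE,
                           degenerate_reason = "zero_cell"))
    }
    dplyr::mutate(base, ror = r$ror, ci_lower = r$ci_lower,
                  ci_upper = r$ci_upper, n_cases = r$n_cases,
                  is_signal = r$is_signal,
                  correction_applied = r$correction_applied,
                  degenerate_reason = NA_character_)
  })
  dplyr::bind_rows(rows)
}
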