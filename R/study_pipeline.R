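## End-to-end study orchestration: load -> deduplicate -> window filter ->
## descriptive cohort tables -> configured disproportionality comparisons,
## with CSV export of every table.

#' Read a study configuration file
#'
#' The YAML configuration names the inputs and the comparisons to run:
#'
#' ```yaml
#' reports_path: reports.csv
#' vocabulary_path: vocab.yaml
#' window: {start: 2020-01-01, end: 2023-09-30}
#' event_group: cardiac_disorders
#' cohort_products: [tiotropium, aclidinium, glycopyrronium, umeclidinium]
#' subgroup_groups: [arrhythmias, cardiac_failure, ischaemic_heart_disease]
#' comparisons:
#'   - name: aclidinium_vs_tiotropium
#'     target: [aclidinium]
#'     comparator: [tiotropium]
#' stratify: [sex, age_band]
#' correction: none
#' exclusive: true
#' output_dir: out
#' ```
#'
#' `comparator` may also be the string `rest_of_database`; a comparison may
#' override the study-level `event_group`. All fields except the two input
#' paths are optional.
#'
#' @param path Path to the YAML file.
#' @return A study-configuration list accepted by [run_study()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) pv_abort(paste0("no such file: ", path))
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (field in c("reports_path", "vocabulary_path", "output_dir")) {
    p <- cfg[[field]]
    if (!is.null(p) && !grepl("^(/|[A-Za-z]:)", p)) {
      cfg[[field]] <- file.path(base, p)
    }
  }
  cfg
}

# fill defaults and check every referenced product/group before computing
prepare_study_config <- function(config, vocabulary) {
  cfg <- config
  cfg$event_group <- cfg$event_group %||% "cardiac_disorders"
  cfg$correction <- cfg$correction %||% "none"
  cfg$exclusive <- cfg$exclusive %||% TRUE
  cfg$stratify <- cfg$stratify %||% character()
  cfg$comparisons <- cfg$comparisons %||% list()
  cfg$roles <- cfg$roles %||%
    c("primary_suspect", "secondary_suspect", "unknown")

  ref_products <- character()
  for (cmp in cfg$comparisons) {
    ref_products <- c(ref_products, as.character(cmp$target))
    if (!identical(cmp$comparator, "rest_of_database")) {
      ref_products <- c(ref_products, as.character(cmp$comparator))
    }
  }
  cfg$cohort_products <- cfg$cohort_products %||% unique(ref_products)
  cfg$subgroup_groups <- cfg$subgroup_groups %||%
    setdiff(event_group_ids(vocabulary), cfg$event_group)

  unknown_products <- setdiff(
    unique(c(ref_products, cfg$cohort_products)),
    names(vocabulary$products))
  if (length(unknown_products) > 0) {
    pv_abort(paste0("config references unknown product(s): ",
                    paste(unknown_products, collapse = ", ")),
             class = "pv_validation_error")
  }
  groups_used <- unique(c(
    cfg$event_group, cfg$subgroup_groups,
    unlist(lapply(cfg$comparisons, function(cmp) cmp$event_group))))
  unknown_groups <- setdiff(groups_used, event_group_ids(vocabulary))
  if (length(unknown_groups) > 0) {
    pv_abort(paste0("config references unknown event group(s): ",
                    paste(unknown_groups, collapse = ", ")),
             class = "pv_validation_error")
  }
  bad_strata <- setdiff(cfg$stratify, c("sex", "age_band"))
  if (length(bad_strata) > 0) {
    pv_abort(paste0("unknown stratification variable(s): ",
                    paste(bad_strata, collapse = ", ")),
             class = "pv_validation_error")
  }
  if (!cfg$correction %in% c("none", "haldane_half")) {
    pv_abort("correction must be 'none' or 'haldane_half'",
             class = "pv_validation_error")
  }
  cfg
}

#' Totals summary for an event group
#'
#' Counts deduplicated reports and event cases (case-level: a report with
#' several qualifying terms is one case) and expresses the case share as a
#' percentage of all reports, rounded half-up to 1 decimal for display.
#'
#' @param rs A deduplicated [report_set()].
#' @param vocabulary A [pv_vocabulary()].
#' @param group_id Event-group id.
#' @return A one-row tibble with `n_reports`, `n_event_cases`, `share_pct`.
#' @export
totals_summary <- function(rs, vocabulary, group_id) {
  if (!group_id %in% event_group_ids(vocabulary)) {
    pv_abort(paste0("unknown event group: ", group_id),
             class = "pv_validation_error")
  }
  n <- nrow(rs$reports)
  if (n == 0) pv_abort("share of an empty report set is undefined")
  n_cases <- sum(report_has_event(rs$reports, vocabulary, group_id))
  tibble::tibble(
    n_reports = n,
    n_event_cases = n_cases,
    share_pct = round_half_up(100 * n_cases / n, 1)
  )
}

#' Percentage breakdown across event subgroups
#'
#' Expresses each subgroup's case count as a percentage of the *sum of the
#' subgroup counts* (not of the broad event-group total: subgroups can
#' overlap on one report and need not exhaust the broad group, so only the
#' subgroup sum gives a well-defined 100%). Percentages are rounded half-up
#' to 1 decimal.
#'
#' @param case_counts Named non-negative numeric vector, one entry per
#'   subgroup; at least one entry must be positive.
#' @return A tibble with columns `subgroup`, `count`, `pct`.
#' @examples
#' subgroup_breakdown(c(arrhythmias = 373, cardiac_failure = 211,
#'                      ischaemic_heart_disease = 417))
#' @export
subgroup_breakdown <- function(case_counts) {
  if (length(case_counts) == 0 || is.null(names(case_counts))) {
    pv_abort("case_counts must be a named vector")
  }
  if (any(case_counts < 0) || all(case_counts == 0)) {
    pv_abort("subgroup breakdown needs at least one positive count")
  }
  tibble::tibble(
    subgroup = names(case_counts),
    count = as.integer(case_counts),
    pct = round_half_up(100 * as.numeric(case_counts) / sum(case_counts), 1)
  )
}

# per-product descriptive cohort table (report counts, event cases, and the
# sex / age-band split of the event cases)
cohort_table <- function(rs, vocabulary, products, group_id, roles) {
  tbl <- rs$reports
  expo <- report_exposures(tbl, vocabulary, roles)
  ev <- report_has_event(tbl, vocabulary, group_id)
  rows <- lapply(products, function(p) {
    in_p <- vapply(expo, function(e) p %in% e, logical(1))
    case <- in_p & ev
    counts <- c(
      n_reports = sum(in_p),
      n_event_cases = sum(case),
      stats::setNames(vapply(pv_sexes(), function(s) {
        sum(case & tbl$sex == s)
      }, integer(1)), paste0("cases_sex_", pv_sexes())),
      stats::setNames(vapply(pv_age_bands(), function(b) {
        sum(case & tbl$age_band == b)
      }, integer(1)), paste0("cases_age_", pv_age_bands()))
    )
    tibble::as_tibble(as.list(counts)) |>
      dplyr::mutate(product = p, .before = 1)
  })
  dplyr::bind_rows(rows)
}

# per-product subgroup counts and percentages (Table-2 shape)
subgroup_table <- function(rs, vocabulary, products, subgroups, group_id,
                           roles) {
  tbl <- rs$reports
  expo <- report_exposures(tbl, vocabulary, roles)
  hit <- lapply(subgroups, function(g) report_has_event(tbl, vocabulary, g))
  names(hit) <- subgroups
  rows <- lapply(products, function(p) {
    in_p <- vapply(expo, function(e) p %in% e, logical(1))
    counts <- vapply(subgroups, function(g) sum(in_p & hit[[g]]), integer(1))
    if (all(counts == 0)) {
      return(tibble::tibble(product = p, subgroup = subgroups,
                            count = 0L, pct = NA_real_))
    }
    subgroup_breakdown(counts) |>
      dplyr::mutate(product = p, .before = 1)
  })
  dplyr::bind_rows(rows)
}

# one comparison -> crude (and optionally stratified) forest rows
forest_rows <- function(rs, vocabulary, cmp, cfg) {
  design <- comparator_design(
    target = cmp$target,
    comparator = if (identical(cmp$comparator, "rest_of_database")) {
      "rest_of_database"
    } else {
      as.character(cmp$comparator)
    },
    exclusive = cfg$exclusive)
  group_id <- cmp$event_group %||% cfg$event_group
  comparator_label <- if (design$rest_of_database) {
    "rest_of_database"
  } else {
    paste(design$comparator, collapse = "+")
  }
  label <- cmp$name %||% paste0(paste(design$target, collapse = "+"),
                                "_vs_", comparator_label)

  crude_t <- suppressMessages(
    build_contingency(rs, vocabulary, design, group_id, roles = cfg$roles))
  crude <- if (crude_t$a + crude_t$b == 0 || crude_t$c + crude_t$d == 0) {
    tibble::tibble(stratum = "crude", a = crude_t$a, b = crude_t$b,
                   c = crude_t$c, d = crude_t$d, ror = NA_real_,
                   ci_lower = NA_real_, ci_upper = NA_real_,
                   n_cases = crude_t$a, is_signal = FALSE,
                   correction_applied = FALSE,
                   degenerate_reason = "empty_cohort")
  } else {
    r <- tryCatch(ror(crude_t, correction = cfg$correction),
                  pv_degenerate_table = function(e) NULL)
    if (is.null(r)) {
      tibble::tibble(stratum = "crude", a = crude_t$a, b = crude_t$b,
                     c = crude_t$c, d = crude_t$d, ror = NA_real_,
                     ci_lower = NA_real_, ci_upper = NA_real_,
                     n_cases = crude_t$a, is_signal = FALSE,
                     correction_applied = FALSE,
                     degenerate_reason = "zero_cell")
    } else {
      tibble::tibble(stratum = "crude", a = crude_t$a, b = crude_t$b,
                     c = crude_t$c, d = crude_t$d, ror = r$ror,
                     ci_lower = r$ci_lower, ci_upper = r$ci_upper,
                     n_cases = r$n_cases, is_signal = r$is_signal,
                     correction_applied = r$correction_applied,
                     degenerate_reason = NA_character_)
    }
  }
  strat <- lapply(cfg$stratify, function(sv) {
    stratified_rors(rs, vocabulary, design, group_id, strata = sv,
                    correction = cfg$correction, roles = cfg$roles) |>
      dplyr::mutate(stratum = paste0(sv, ":", .data$stratum))
  })
  dplyr::bind_rows(c(list(crude), strat)) |>
    dplyr::mutate(
      comparison = label,
      target = paste(design$target, collapse = "+"),
      comparator = comparator_label,
      event_group = group_id,
      .before = 1)
}

#' Run a configured disproportionality study
#'
#' Executes the full pipeline deterministically: load reports, deduplicate
#' case versions, filter to the receipt-date window, then compute (i) the
#' totals summary for the study event group, (ii) the per-product cohort
#' table with sex and age-band splits of the event cases, (iii) the
#' per-product subgroup breakdown, and (iv) one forest row (plus optional
#' sex / age-band strata) per configured comparison. Configuration errors —
#' unknown products, event groups or strata — are raised before any
#' computation. When `output_dir` is set, `totals.csv`, `cohorts.csv`,
#' `subgroups.csv` and `forest.csv` are written there (degenerate
#' comparisons included, carrying a reason code); counts at each filtering
#' stage are logged.
#'
#' In the descriptive tables a report exposed to two cohort products counts
#' in both product rows; the forest comparisons instead apply the design's
#' `exclusive` rule, which keeps descriptive tabulation and inferential
#' contrasts cleanly separated.
#'
#' @param config A configuration list (see [read_study_config()]) or the
#'   path to a YAML configuration file. In-memory objects may be supplied
#'   directly via the `reports` (a [report_set()]) and `vocabulary` (a
#'   [pv_vocabulary()]) fields in place of the path fields.
#' @return An object of class `study_report`: a list with `totals`,
#'   `cohorts`, `subgroups`, `forest` (tibbles) and the resolved `config`.
#' @export
run_study <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_study_config(config)
  }
  vocabulary <- config[["vocabulary"]] %||% {
    if (is.null(config$vocabulary_path)) {
      pv_abort("config needs 'vocabulary_path' or an in-memory 'vocabulary'",
               class = "pv_validation_error")
    }
    read_vocabulary(config$vocabulary_path)
  }
  cfg <- prepare_study_config(config, vocabulary)

  rs <- cfg[["reports"]] %||% {
    if (is.null(cfg$reports_path)) {
      pv_abort("config needs 'reports_path' or an in-memory 'reports'",
               class = "pv_validation_error")
    }
    load_reports(cfg$reports_path, format = cfg$reports_format %||% "native")
  }
  n_loaded <- nrow(rs$reports)
  rs <- deduplicate(rs)
  n_dedup <- nrow(rs$reports)
  if (!is.null(cfg$window)) {
    rs <- filter_window(rs, cfg$window$start, cfg$window$end)
  }
  n_window <- nrow(rs$reports)
  rlang::inform(sprintf(
    "study: %d report(s) loaded, %d after deduplication, %d in window",
    n_loaded, n_dedup, n_window))

  totals <- totals_summary(rs, vocabulary, cfg$event_group)
  cohorts <- cohort_table(rs, vocabulary, cfg$cohort_products,
                          cfg$event_group, cfg$roles)
  subgroups <- subgroup_table(rs, vocabulary, cfg$cohort_products,
                              cfg$subgroup_groups, cfg$event_group,
                              cfg$roles)
  forest <- dplyr::bind_rows(lapply(cfg$comparisons, function(cmp) {
    forest_rows(rs, vocabulary, cmp, cfg)
  }))

  report <- structure(list(totals = totals, cohorts = cohorts,
                           subgroups = subgroups, forest = forest,
                           config = cfg),
                      class = "study_report")
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(totals, file.path(cfg$output_dir, "totals.csv"))
    readr::write_csv(cohorts, file.path(cfg$output_dir, "cohorts.csv"))
    readr::write_csv(subgroups, file.path(cfg$output_dir, "subgroups.csv"))
    forest_out <- if (nrow(forest) == 0) {
      tibble::tibble(comparison = character(), target = character(),
                     comparator = character(), event_group = character(),
                     stratum = character(), a = integer(), b = integer(),
                     c = integer(), d = integer(), ror = numeric(),
                     ci_lower = numeric(), ci_upper = numeric(),
                     n_cases = integer(), is_signal = logical(),
                     correction_applied = logical(),
                     degenerate_reason = character())
    } else {
      forest
    }
    readr::write_csv(forest_out, file.path(cfg$output_dir, "forest.csv"))
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  reports: %d, event cases: %d (%.1f%%)\n",
              x$totals$n_reports, x$totals$n_event_cases,
              x$totals$share_pct))
  cat(sprintf("  cohort products: %d, comparisons: %d\n",
              nrow(x$cohorts),
              length(unique(x$forest$comparison))))
  invisible(x)
}
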