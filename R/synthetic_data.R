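## Synthetic spontaneous-report generator with known ground truth. Ground
## truth is defined on the odds scale: each product's event odds are the
## reference product's baseline odds times a product-specific multiplier, so
## a requested multiplier equals the expected reporting odds ratio of that
## product against the reference.

# minimal tibble constructor for drug-mention list-columns; tibble() itself
# is too slow to call once per synthetic report
mention_tbl <- function(verbatim, role) {
  structure(list(verbatim_name = verbatim, role = role),
            class = c("tbl_df", "tbl", "data.frame"),
            row.names = c(NA_integer_, -length(verbatim)))
}

# non-cardiac preferred terms used for non-case reports; none of these may
# appear in the demo vocabulary's cardiac group
.noncardiac_pts <- c(
  "HEADACHE", "NAUSEA", "COUGH", "DYSPNOEA", "DIZZINESS", "DRY MOUTH",
  "URINARY RETENTION", "CONSTIPATION", "VISION BLURRED", "RASH",
  "OROPHARYNGEAL PAIN", "INSOMNIA", "FATIGUE", "DIARRHOEA", "PRURITUS"
)

#' Parameters for the synthetic report generator
#'
#' Defaults emulate the cohort structure of the 2020–2023 reporting window
#' for the four inhaled long-acting muscarinic antagonists: cohort sizes
#' equal the observed per-drug report counts, the reference product
#' (tiotropium) has baseline cardiac-event odds 1238/11234, and the default
#' odds multipliers are all 1 (a global null — supply other multipliers to
#' inject known effects). Sex and age mixtures approximate the observed
#' overall strata; remaining knobs exercise the messy features of real
#' spontaneous data: multiple cardiac terms per case (`1 + Poisson(mean)`
#' extra terms), synonym usage in verbatim drug names, resubmitted duplicate
#' case versions, and dual exposures.
#'
#' @param cohort_sizes Named integer vector: product id -> number of
#'   reports.
#' @param baseline_product Name of the reference product (must be in
#'   `cohort_sizes`).
#' @param baseline_odds Baseline event odds for the reference product.
#' @param odds_multipliers Named positive vector, one entry per product;
#'   each product's event odds are `baseline_odds * multiplier`.
#' @param sex_mix,age_mix Named probability vectors over [pv_sexes()] /
#'   [pv_age_bands()]; need not include every level.
#' @param mean_extra_pts Mean number of *extra* cardiac terms per event
#'   case (>= 0).
#' @param synonym_prob Probability that a mention uses a random dictionary
#'   synonym instead of the canonical product name.
#' @param duplicate_prob Probability that a case also emits a superseded
#'   earlier version (removed again by [deduplicate()]).
#' @param dual_exposure_prob Probability of a second, secondary-suspect
#'   product mention on a report.
#' @param seed Integer seed; generation is a pure function of the
#'   parameters including the seed.
#' @return An object of class `synthetic_params`.
#' @export
synthetic_params <- function(
    cohort_sizes = c(tiotropium = 12472, aclidinium = 1254,
                     glycopyrronium = 1883, umeclidinium = 2599),
    baseline_product = "tiotropium",
    baseline_odds = 1238 / 11234,
    odds_multipliers = NULL,
    sex_mix = c(F = 0.54, M = 0.34, NS = 0.12),
    age_mix = c(under18 = 0.005, "18to64" = 0.275, "65to85" = 0.32,
                over85 = 0.08, NS = 0.32),
    mean_extra_pts = 0.3,
    synonym_prob = 0.5,
    duplicate_prob = 0.02,
    dual_exposure_prob = 0.01,
    seed = 20200101) {
  if (is.null(names(cohort_sizes)) || any(!nzchar(names(cohort_sizes)))) {
    pv_abort("cohort_sizes must be named by product id")
  }
  if (any(cohort_sizes < 0)) pv_abort("cohort sizes must be >= 0")
  if (!baseline_product %in% names(cohort_sizes)) {
    pv_abort("baseline_product must appear in cohort_sizes")
  }
  if (is.null(odds_multipliers)) {
    odds_multipliers <- stats::setNames(rep(1, length(cohort_sizes)),
                                        names(cohort_sizes))
  }
  missing_mult <- setdiff(names(cohort_sizes), names(odds_multipliers))
  if (length(missing_mult) > 0) {
    pv_abort(paste0("odds_multipliers missing for: ",
                    paste(missing_mult, collapse = ", ")))
  }
  if (any(odds_multipliers <= 0)) pv_abort("odds multipliers must be > 0")
  if (baseline_odds <= 0) pv_abort("baseline_odds must be > 0")
  probs <- c(synonym_prob = synonym_prob, duplicate_prob = duplicate_prob,
             dual_exposure_prob = dual_exposure_prob)
  if (any(probs < 0 | probs > 1)) {
    pv_abort("probability parameters must lie in [0, 1]")
  }
  if (mean_extra_pts < 0) pv_abort("mean_extra_pts must be >= 0")
  if (any(sex_mix < 0) || sum(sex_mix) <= 0 ||
      !all(names(sex_mix) %in% pv_sexes())) {
    pv_abort("sex_mix must be non-negative over F/M/NS")
  }
  if (any(age_mix < 0) || sum(age_mix) <= 0 ||
      !all(names(age_mix) %in% pv_age_bands())) {
    pv_abort("age_mix must be non-negative over the age bands")
  }
  structure(list(
    cohort_sizes = cohort_sizes, baseline_product = baseline_product,
    baseline_odds = baseline_odds, odds_multipliers = odds_multipliers,
    sex_mix = sex_mix / sum(sex_mix), age_mix = age_mix / sum(age_mix),
    mean_extra_pts = mean_extra_pts, synonym_prob = synonym_prob,
    duplicate_prob = duplicate_prob,
    dual_exposure_prob = dual_exposure_prob,
    seed = as.integer(seed)
  ), class = "synthetic_params")
}

#' True reporting odds ratios implied by synthetic parameters
#'
#' Because effects are defined on the odds scale, the expected ROR of any
#' product against the baseline product equals the ratio of their odds
#' multipliers.
#'
#' @param params A [synthetic_params()].
#' @return Named numeric vector of true RORs versus the baseline product.
#' @export
true_rors <- function(params) {
  m <- params$odds_multipliers[names(params$cohort_sizes)]
  m / m[[params$baseline_product]]
}

#' Generate a synthetic report set
#'
#' Draws one report per cohort slot: a verbatim drug name (canonical or a
#' dictionary synonym), demographics from the configured mixtures, an
#' event-case indicator from the product's odds, and — for cases — one or
#' more cardiac preferred terms from the vocabulary's `cardiac_disorders`
#' group (`1 + Poisson(mean_extra_pts)` draws, deduplicated, so a case
#' carries at least one term). Non-cases receive one non-cardiac term. With
#' the configured probabilities a report additionally gains a
#' secondary-suspect mention of another product, or emits a superseded
#' earlier case version that [deduplicate()] removes again. Receipt dates
#' are uniform over 2020-01-01 to 2023-09-30.
#'
#' Output is a deterministic function of `params` (including the seed):
#' writing the same parameters twice yields byte-identical files.
#'
#' @param params A [synthetic_params()].
#' @param path Optional path; when given the report set is written in the
#'   native CSV format and the ground truth (parameters, seed, true RORs)
#'   is echoed to a `<path>.meta.json` sidecar.
#' @param vocabulary Vocabulary supplying synonyms and cardiac terms;
#'   defaults to the bundled demo vocabulary.
#' @return A [report_set()]; when `path` is given, also written to disk.
#' @export
generate_reports <- function(params, path = NULL,
                             vocabulary = pv_demo_vocabulary()) {
  stopifnot(inherits(params, "synthetic_params"))
  sizes <- params$cohort_sizes[params$cohort_sizes > 0]
  if (length(sizes) == 0) {
    pv_abort("all cohort sizes are zero; nothing to generate")
  }
  for (p in names(sizes)) {
    if (!p %in% names(vocabulary$products)) {
      pv_abort(paste0("product '", p, "' is not in the vocabulary"),
               class = "pv_validation_error")
    }
  }
  cardiac <- vocabulary$event_groups[["cardiac_disorders"]]$terms
  if (is.null(cardiac)) {
    pv_abort("vocabulary must define a 'cardiac_disorders' group")
  }
  syn_by_product <- split(names(vocabulary$synonym_map),
                          unname(vocabulary$synonym_map))

  tbl <- withr::with_seed(params$seed, {
    product <- rep(names(sizes), times = sizes)
    n <- length(product)
    odds <- params$baseline_odds * params$odds_multipliers[product]
    p_event <- odds / (1 + odds)
    is_case <- stats::rbinom(n, 1, p_event) == 1

    case_id <- sprintf("SYN%07d", seq_len(n))
    sex <- sample(names(params$sex_mix), n, replace = TRUE,
                  prob = params$sex_mix)
    age_band <- sample(names(params$age_mix), n, replace = TRUE,
                       prob = params$age_mix)
    window_days <- as.integer(as.Date("2023-09-30") - as.Date("2020-01-01"))
    receipt_date <- as.Date("2020-01-01") +
      sample.int(window_days + 1, n, replace = TRUE) - 1

    use_syn <- stats::runif(n) < params$synonym_prob
    verbatim <- product
    if (any(use_syn)) {
      n_syn <- lengths(syn_by_product)[product[use_syn]]
      pick <- ceiling(stats::runif(sum(use_syn)) * n_syn)
      verbatim[use_syn] <- mapply(function(p, i) syn_by_product[[p]][i],
                                  product[use_syn], pick, USE.NAMES = FALSE)
    }

    dual <- stats::runif(n) < params$dual_exposure_prob &
      length(sizes) > 1
    dual_partner <- rep(NA_character_, n)
    if (any(dual)) {
      others_of <- lapply(stats::setNames(nm = names(sizes)),
                          function(p) setdiff(names(sizes), p))
      pick <- ceiling(stats::runif(sum(dual)) * (length(sizes) - 1))
      dual_partner[dual] <- mapply(function(p, i) others_of[[p]][i],
                                   product[dual], pick, USE.NAMES = FALSE)
    }
    drugs <- mapply(function(v, dp) {
      if (is.na(dp)) {
        mention_tbl(v, "primary_suspect")
      } else {
        mention_tbl(c(v, dp), c("primary_suspect", "secondary_suspect"))
      }
    }, verbatim, dual_partner, SIMPLIFY = FALSE, USE.NAMES = FALSE)

    n_terms <- ifelse(is_case, 1 + stats::rpois(n, params$mean_extra_pts), 1)
    pool <- character(sum(n_terms))
    owner <- rep(seq_len(n), times = n_terms)
    case_slots <- rep(is_case, times = n_terms)
    pool[case_slots] <- sample(cardiac, sum(case_slots), replace = TRUE)
    pool[!case_slots] <- sample(.noncardiac_pts, sum(!case_slots),
                                replace = TRUE)
    events <- lapply(split(pool, factor(owner, levels = seq_len(n))),
                     function(e) if (length(e) > 1) sort(unique(e)) else e)

    base <- tibble::tibble(
      report_id = paste0(case_id, "-2"),
      case_id = case_id,
      version = 2L,
      receipt_date = receipt_date,
      sex = sex,
      age_band = age_band,
      drugs = drugs,
      events = unname(events)
    )
    dup <- stats::runif(n) < params$duplicate_prob
    if (any(dup)) {
      early <- base[dup, , drop = FALSE]
      early$report_id <- paste0(early$case_id, "-1")
      early$version <- 1L
      early$receipt_date <- pmax(early$receipt_date - 30,
                                 as.Date("2020-01-01"))
      base <- dplyr::bind_rows(base, early)
    }
    dplyr::arrange(base, .data$report_id)
  })

  rs <- new_report_set(tbl, provenance = sprintf(
    "synthetic (seed %d)", params$seed))
  if (!is.null(path)) {
    write_native(rs, path)
    meta <- list(
      seed = params$seed,
      cohort_sizes = as.list(params$cohort_sizes),
      baseline_product = params$baseline_product,
      baseline_odds = params$baseline_odds,
      odds_multipliers = as.list(params$odds_multipliers),
      true_rors = as.list(true_rors(params)),
      mean_extra_pts = params$mean_extra_pts,
      synonym_prob = params$synonym_prob,
      duplicate_prob = params$duplicate_prob,
      dual_exposure_prob = params$dual_exposure_prob
    )
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  rs
}

## Fixture reproducing the published per-drug marginals ----------------------

# per-drug composition: total reports, event cases split into
# arrhythmia-only / failure-only / ischaemia-only / arrhythmia+ischaemia
# overlap / cardiac-but-no-subgroup remainder, and the sex split of cases
.table1_spec <- list(
  tiotropium = list(n_ae = 12472, arr = 373, hf = 211, ihd = 417,
                    overlap = 0, generic = 237,
                    sex = c(F = 502, M = 599, NS = 137)),
  aclidinium = list(n_ae = 1254, arr = 33, hf = 24, ihd = 112,
                    overlap = 19, generic = 0,
                    sex = c(F = 86, M = 74, NS = 28)),
  glycopyrronium = list(n_ae = 1883, arr = 175, hf = 40, ihd = 149,
                        overlap = 12, generic = 0,
                        sex = c(F = 207, M = 128, NS = 41)),
  umeclidinium = list(n_ae = 2599, arr = 194, hf = 92, ihd = 92,
                      overlap = 0, generic = 81,
                      sex = c(F = 145, M = 254, NS = 60))
)

#' Deterministic fixture with the published per-drug marginals
#'
#' Emits a minimal report set whose per-drug totals match the observed
#' 2020–2023 cohorts exactly: 12,472 tiotropium reports with 1,238
#' cardiac-disorder cases, 1,254/188 for aclidinium, 1,883/376 for
#' glycopyrronium and 2,599/459 for umeclidinium (18,208 reports and 2,261
#' cardiac cases in all). Within each drug the cases are composed so that
#' the arrhythmia / cardiac-failure / ischaemic-heart-disease subgroup
#' counts also match the published breakdown; where the subgroup counts
#' exceed the case count, the surplus cases carry one arrhythmia *and* one
#' ischaemia term (case-level counting keeps them single cases), and where
#' they fall short, the remainder carry a cardiac term outside all three
#' subgroups. Case sex labels follow the published split; age bands are not
#' published at this granularity and are left `NS`.
#'
#' Running the fixture through [deduplicate()] and [run_study()] reproduces
#' the published reporting odds ratios against tiotropium end to end.
#'
#' @param path Optional path; when given the fixture is also written as a
#'   native CSV.
#' @return A [report_set()].
#' @export
table1_fixture <- function(path = NULL) {
  arr_pt <- "ATRIAL FIBRILLATION"
  hf_pt <- "CARDIAC FAILURE"
  ihd_pt <- "MYOCARDIAL INFARCTION"
  generic_pt <- "PERICARDITIS"
  noncase_pt <- "HEADACHE"

  rows <- lapply(names(.table1_spec), function(drug) {
    s <- .table1_spec[[drug]]
    n_cd <- s$arr + s$hf + s$ihd + s$overlap + s$generic
    n_non <- s$n_ae - n_cd
    events <- c(
      rep(list(arr_pt), s$arr),
      rep(list(hf_pt), s$hf),
      rep(list(ihd_pt), s$ihd),
      rep(list(sort(c(arr_pt, ihd_pt))), s$overlap),
      rep(list(generic_pt), s$generic),
      rep(list(noncase_pt), n_non)
    )
    sex <- c(rep(names(s$sex), times = s$sex), rep("NS", n_non))
    id <- paste0(toupper(substr(drug, 1, 3)),
                 sprintf("%06d", seq_len(s$n_ae)))
    tibble::tibble(
      report_id = id,
      case_id = id,
      version = 1L,
      receipt_date = as.Date("2021-06-15"),
      sex = sex,
      age_band = "NS",
      drugs = rep(list(tibble::tibble(verbatim_name = drug,
                                      role = "primary_suspect")), s$n_ae),
      events = events
    )
  })
  rs <- new_report_set(dplyr::bind_rows(rows),
                       provenance = "table1 marginal fixture")
  if (!is.null(path)) write_native(rs, path)
  rs
}
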