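quiet_contingency <- function(...) suppressMessages(build_contingency(...))

test_that("build_contingency assigns cohorts and counts at case level", {
  rs <- mk_reports(
    list(drug = "umeclidinium", events = "ATRIAL FIBRILLATION"),
    list(drug = "umeclidinium", events = "HEADACHE"),
    list(drug = "tiotropium", events = "CARDIAC FAILURE"),
    list(drug = "tiotropium", events = "NAUSEA")
  )
  d <- comparator_design("umeclidinium", "tiotropium")
  t <- quiet_contingency(rs, demo_vocab, d, "cardiac_disorders")
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 1))

  # three qualifying terms on one report still contribute a single case
  rs2 <- mk_reports(
    list(drug = "umeclidinium",
         events = c("ATRIAL FIBRILLATION", "CARDIAC FAILURE",
                    "MYOCARDIAL INFARCTION")),
    list(drug = "umeclidinium", events = "HEADACHE"),
    list(drug = "tiotropium", events = "CARDIAC FAILURE"),
    list(drug = "tiotropium", events = "NAUSEA")
  )
  t2 <- quiet_contingency(rs2, demo_vocab, d, "cardiac_disorders")
  expect_equal(c(t2$a, t2$b, t2$c, t2$d), c(1, 1, 1, 1))
})

test_that("exclusive designs drop dual-exposed reports from both cohorts", {
  rs <- mk_reports(
    list(drug = c("umeclidinium", "tiotropium"),
         role = c("primary_suspect", "secondary_suspect"),
         events = "ATRIAL FIBRILLATION"),
    list(drug = "umeclidinium", events = "HEADACHE"),
    list(drug = "tiotropium", events = "NAUSEA")
  )
  d <- comparator_design("umeclidinium", "tiotropium", exclusive = TRUE)
  expect_message(
    t <- build_contingency(rs, demo_vocab, d, "cardiac_disorders"),
    "exposed to both")
  expect_equal(c(t$a, t$b, t$c, t$d), c(0, 1, 0, 1))
  expect_equal(attr(t, "n_dual_dropped"), 1)

  d2 <- comparator_design("umeclidinium", "tiotropium", exclusive = FALSE)
  t2 <- quiet_contingency(rs, demo_vocab, d2, "cardiac_disorders")
  expect_equal(c(t2$a, t2$b, t2$c, t2$d), c(1, 1, 1, 1))
})

test_that("rest-of-database comparator is everything not target-exposed", {
  rs <- mk_reports(
    list(drug = "umeclidinium", events = "ATRIAL FIBRILLATION"),
    list(drug = "tiotropium", events = "NAUSEA"),
    list(drug = "aclidinium", events = "CARDIAC FAILURE")
  )
  d <- comparator_design("umeclidinium", "rest_of_database")
  t <- quiet_contingency(rs, demo_vocab, d, "cardiac_disorders")
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 0, 1, 1))
  expect_error(quiet_contingency(rs, demo_vocab, d, "no_such_group"),
               class = "pv_validation_error")
})

test_that("ror matches the closed form on balanced and published tables", {
  r <- ror(two_by_two(1, 1, 1, 1))
  expect_equal(r$ror, 1)
  # CI symmetric about 1 on the log scale
  expect_equal(log(r$ci_upper), -log(r$ci_lower))
  expect_false(r$is_signal)

  r_acl <- ror(two_by_two(188, 1066, 1238, 11234))
  expect_equal(round_half_up(r_acl$ror, 2), 1.60)
  expect_equal(round_half_up(r_acl$ci_lower, 2), 1.36)
  expect_equal(round_half_up(r_acl$ci_upper, 2), 1.89)
  expect_true(r_acl$is_signal)
  expect_equal(r_acl$n_cases, 188)
})

test_that("zero cells error by default and Haldane correction matches arithmetic", {
  err <- expect_error(ror(two_by_two(0, 10, 5, 100)),
                      class = "pv_degenerate_table")
  expect_match(conditionMessage(err), "'a'")
  expect_error(ror(two_by_two(5, 10, 5, 0)), "'d'",
               class = "pv_degenerate_table")

  # hand-computed oracle on the corrected table (0.5, 10.5, 5.5, 100.5)
  r <- ror(two_by_two(0, 10, 5, 100), correction = "haldane_half")
  est <- (0.5 / 10.5) / (5.5 / 100.5)
  se <- sqrt(1 / 0.5 + 1 / 10.5 + 1 / 5.5 + 1 / 100.5)
  expect_equal(r$ror, est, tolerance = 1e-12)
  expect_equal(r$ci_lower, exp(log(est) - qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_equal(r$ci_upper, exp(log(est) + qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_true(r$correction_applied)
  expect_equal(r$n_cases, 0) # uncorrected case count
  # no zero cell: correction requested but not applied
  expect_false(ror(two_by_two(1, 1, 1, 1), "haldane_half")$correction_applied)
})

test_that("signal rule needs a lower bound above 1 and at least 3 cases", {
  mk <- function(ci_lower, n_cases) {
    structure(list(ci_lower = ci_lower, n_cases = n_cases),
              class = "ror_result")
  }
  expect_true(is_signal(mk(1.05, 3)))
  expect_false(is_signal(mk(1.05, 2)))
  expect_false(is_signal(mk(1.00, 1000))) # strict inequality
})

test_that("ror is antisymmetric, factorization-invariant and monotone", {
  set.seed(101)
  for (i in 1:25) {
    cells <- sample(1:200, 4, replace = TRUE)
    r <- ror(do.call(two_by_two, as.list(cells)))
    r_swap <- ror(two_by_two(cells[3], cells[4], cells[1], cells[2]))
    expect_equal(r$ror * r_swap$ror, 1, tolerance = 1e-12)
    expect_equal(r$ci_lower, 1 / r_swap$ci_upper, tolerance = 1e-12)
    expect_equal(r$ci_upper, 1 / r_swap$ci_lower, tolerance = 1e-12)
    # transposition: (a/c)/(b/d) is the same cross-product ratio
    r_t <- ror(two_by_two(cells[1], cells[3], cells[2], cells[4]))
    expect_equal(r_t$ror,
                 (cells[1] / cells[3]) / (cells[2] / cells[4]),
                 tolerance = 1e-12)
    expect_equal(r$ror, r_t$ror, tolerance = 1e-12)
  }
  # strictly increasing in a, all else fixed
  ests <- vapply(1:30, function(a) ror(two_by_two(a, 50, 20, 60))$ror,
                 numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("stratified estimates agree with crude on a single stratum", {
  rs <- mk_reports(
    list(drug = "umeclidinium", events = "ATRIAL FIBRILLATION", sex = "F"),
    list(drug = "umeclidinium", events = "HEADACHE", sex = "F"),
    list(drug = "tiotropium", events = "CARDIAC FAILURE", sex = "F"),
    list(drug = "tiotropium", events = "NAUSEA", sex = "F")
  )
  d <- comparator_design("umeclidinium", "tiotropium")
  crude <- ror(quiet_contingency(rs, demo_vocab, d, "cardiac_disorders"))
  strat <- stratified_rors(rs, demo_vocab, d, "cardiac_disorders", "sex")
  expect_equal(nrow(strat), 1)
  expect_equal(strat$stratum, "F")
  expect_equal(strat$ror, crude$ror)
})

test_that("stratified output covers balanced strata and flags degenerate ones", {
  balanced <- function(sex) list(
    list(drug = "umeclidinium", events = "ATRIAL FIBRILLATION", sex = sex),
    list(drug = "umeclidinium", events = "HEADACHE", sex = sex),
    list(drug = "tiotropium", events = "CARDIAC FAILURE", sex = sex),
    list(drug = "tiotropium", events = "NAUSEA", sex = sex)
  )
  rs <- do.call(mk_reports, c(
    balanced("F"), balanced("M"),
    # M stratum gains a zero cell: one extra target case only
    list(list(drug = "umeclidinium", events = "PERICARDITIS", sex = "NS"))
  ))
  d <- comparator_design("umeclidinium", "tiotropium")
  strat <- stratified_rors(rs, demo_vocab, d, "cardiac_disorders", "sex")
  expect_equal(strat$stratum, c("F", "M", "NS"))
  expect_equal(strat$ror[1:2], c(1, 1))
  # the NS stratum has no comparator reports: counts kept, estimate absent
  expect_equal(strat$degenerate_reason[3], "empty_cohort")
  expect_true(is.na(strat$ror[3]))
  expect_equal(strat$a[3], 1)
})
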