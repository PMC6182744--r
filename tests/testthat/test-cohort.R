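test_that("progression rule: 0.7 mm loss is a case, 0.69 is not, missing is ineligible", {
  expect_equal(classify_progression(3.8, 3.1), "case")       # delta exactly 0.7
  expect_equal(classify_progression(3.80, 3.11), "control")  # delta 0.69
  expect_equal(classify_progression(NA, 3.1), "ineligible")
  expect_equal(classify_progression(3.8, NA), "ineligible")
  expect_equal(classify_progression(c(4, 4, NA), c(2.5, 3.9, 1)),
               c("case", "control", "ineligible"))
  # widening joint space is a control, not an error
  expect_equal(classify_progression(3.0, 3.5), "control")
  expect_error(classify_progression(-1, 2), "negative")
})

test_that("exclusions fire in precedence order with one reason per subject", {
  rec <- data.frame(
    subject_id = c("ok", "missing", "kl4", "lateral", "kl4_and_lateral",
                   "tie"),
    minjsw_36m = c(4, NA, 4, 4, 4, 4),
    minjsw_72m = c(3, 3, 3, 3, 3, 3),
    kl_grade_36m = c(2, 2, 4, 2, 4, 2),
    oarsi_jsn_medial_36m = c(1, 1, 1, 0, 0, 2),
    oarsi_jsn_lateral_36m = c(0, 0, 0, 2, 2, 2),
    stringsAsFactors = FALSE)
  out <- apply_exclusions(rec)
  expect_equal(out$eligible$subject_id, c("ok", "tie"))  # tie is not "greater"
  lg <- out$exclusion_log
  expect_equal(lg$reason[lg$subject_id == "missing"], "missing minJSW")
  expect_equal(lg$reason[lg$subject_id == "kl4"], "KL4 ceiling")
  expect_equal(lg$reason[lg$subject_id == "lateral"], "lateral predominant")
  expect_equal(lg$reason[lg$subject_id == "kl4_and_lateral"], "KL4 ceiling")
})

test_that("exact assignment equals brute-force enumeration on random instances", {
  set.seed(10)
  for (s in 1:30) {
    n <- sample(2:5, 1); m <- n + sample(0:3, 1)
    cost <- matrix(runif(n * m, 0, 10), n, m)
    sol <- solve_lap(cost)
    expect_equal(sol$total_cost, oracle_min_assignment(cost),
                 tolerance = 1e-10)
    expect_false(any(duplicated(sol$assignment)))
  }
})

test_that("matching identical covariates achieves zero total distance", {
  cohort <- data.frame(
    subject_id = c(paste0("c", 1:3), paste0("k", 1:5)),
    group = rep(c("case", "control"), c(3, 5)),
    age = c(60, 65, 70, 60, 65, 70, 55, 80),
    sex = c("F", "M", "F", "F", "M", "F", "M", "M"),
    bmi = c(30, 31, 32, 30, 31, 32, 28, 35),
    minjsw_36m = c(4, 3.5, 3, 4, 3.5, 3, 5, 2.5),
    stringsAsFactors = FALSE)
  mc <- propensity_match(cohort)
  expect_equal(nrow(mc$pairs), 3)
  expect_equal(mc$total_distance, 0, tolerance = 1e-8)
  expect_equal(sort(mc$pairs$control_id), c("k1", "k2", "k3"))
  expect_length(mc$reserve_controls, 2)
})

test_that("optimal matching equals enumeration over all pairings on small cohorts", {
  set.seed(33)
  for (s in 1:5) {
    nc <- sample(3:4, 1); nk <- nc + sample(1:2, 1)
    cohort <- data.frame(
      subject_id = c(paste0("c", 1:nc), paste0("k", 1:nk)),
      group = rep(c("case", "control"), c(nc, nk)),
      age = rnorm(nc + nk, 64, 8),
      sex = sample(c("F", "M"), nc + nk, replace = TRUE),
      bmi = rnorm(nc + nk, 31, 4),
      minjsw_36m = pmax(1, rnorm(nc + nk, 3.8, 1.2)),
      stringsAsFactors = FALSE)
    # tiny cohorts can be separable in the propensity model; that is fine here
    mc <- suppressWarnings(propensity_match(cohort))
    d <- abs(outer(mc$logit[paste0("c", 1:nc)], mc$logit[paste0("k", 1:nk)],
                   `-`))
    expect_equal(mc$total_distance, oracle_min_assignment(d),
                 tolerance = 1e-10)
  }
})

test_that("matching is infeasible with fewer controls than cases", {
  cohort <- data.frame(
    subject_id = c("c1", "c2", "k1"), group = c("case", "case", "control"),
    age = c(60, 61, 62), sex = c("F", "M", "F"), bmi = c(30, 31, 32),
    minjsw_36m = c(4, 3, 3.5), stringsAsFactors = FALSE)
  expect_error(propensity_match(cohort), "infeasible")
})

test_that("re-matching removes pairs of excluded cases and replaces excluded controls", {
  set.seed(8)
  n <- 6
  cohort <- data.frame(
    subject_id = c(paste0("c", 1:n), paste0("k", 1:(2 * n))),
    group = rep(c("case", "control"), c(n, 2 * n)),
    age = rnorm(3 * n, 64, 8), sex = sample(c("F", "M"), 3 * n, TRUE),
    bmi = rnorm(3 * n, 31, 4), minjsw_36m = pmax(1, rnorm(3 * n, 3.8, 1.2)),
    stringsAsFactors = FALSE)
  mc <- propensity_match(cohort)
  # excluded case: its control leaves too
  gone_case <- mc$pairs$case_id[1]
  gone_ctrl_of_case <- mc$pairs$control_id[1]
  # excluded control: replaced by the nearest reserve
  gone_ctrl <- mc$pairs$control_id[2]
  its_case <- mc$pairs$case_id[2]
  mc2 <- rematch_excluded(mc, c(gone_case, gone_ctrl))
  expect_equal(nrow(mc2$pairs), n - 1)
  expect_false(gone_case %in% mc2$pairs$case_id)
  expect_false(gone_ctrl_of_case %in% mc2$pairs$control_id)
  expect_false(gone_ctrl %in% mc2$pairs$control_id)
  new_ctrl <- mc2$pairs$control_id[mc2$pairs$case_id == its_case]
  expect_true(new_ctrl %in% mc$reserve_controls)
  expect_true(mc2$pairs$replaced[mc2$pairs$case_id == its_case])
  # the replacement is the nearest unused reserve on the logit scale
  reserve <- setdiff(mc$reserve_controls, c(gone_case, gone_ctrl))
  expect_equal(new_ctrl,
               reserve[which.min(abs(mc$logit[its_case] - mc$logit[reserve]))])
  # controls stay distinct
  expect_false(any(duplicated(mc2$pairs$control_id)))
})

test_that("an exhausted reserve pool drops the case with a warning", {
  cohort <- data.frame(
    subject_id = c("c1", "c2", "k1", "k2"),
    group = c("case", "case", "control", "control"),
    age = c(60, 61, 62, 63), sex = c("F", "M", "F", "M"),
    bmi = c(30, 31, 32, 33), minjsw_36m = c(4, 3, 3.5, 3.7),
    stringsAsFactors = FALSE)
  mc <- propensity_match(cohort)
  gone <- mc$pairs$control_id[1]
  expect_warning(mc2 <- rematch_excluded(mc, gone), "exhausted")
  expect_equal(nrow(mc2$pairs), 1)
})

test_that("standardized mean differences behave and balance improves with matching", {
  expect_equal(standardized_mean_diff(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(standardized_mean_diff(c(2, 4), c(1, 3)),
               1 / sqrt(2))  # mean diff 1, each variance 2, pooled SD sqrt(2)
  set.seed(91)
  n_case <- 40; n_pool <- 120
  cohort <- data.frame(
    subject_id = c(paste0("c", 1:n_case), paste0("k", 1:n_pool)),
    group = rep(c("case", "control"), c(n_case, n_pool)),
    age = c(rnorm(n_case, 66, 8), rnorm(n_pool, 63, 8)),
    sex = c(sample(c("F", "M"), n_case, TRUE, prob = c(0.5, 0.5)),
            sample(c("F", "M"), n_pool, TRUE, prob = c(0.38, 0.62))),
    bmi = c(rnorm(n_case, 32, 4.5), rnorm(n_pool, 30.5, 4.5)),
    minjsw_36m = pmax(1, c(rnorm(n_case, 3.6, 1.1), rnorm(n_pool, 4.0, 1.2))),
    stringsAsFactors = FALSE)
  mc <- propensity_match(cohort)
  bal <- match_balance(mc, cohort)
  expect_equal(sort(bal$covariate), sort(c("age", "sex", "bmi", "minjsw_36m")))
  expect_true(all(abs(bal$smd) < 0.25))
})
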