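mk_model <- function(beta, center = NULL, scale = NULL, intercept = 0) {
  nm <- names(beta)
  structure(list(beta = beta, intercept = intercept,
                 center = if (is.null(center)) setNames(rep(0, length(nm)), nm)
                          else center,
                 scale = if (is.null(scale)) setNames(rep(1, length(nm)), nm)
                         else scale,
                 null_model = all(beta == 0), dataset_tag = "test"),
            class = "score_model")
}

test_that("rank AUC agrees with pROC and handles ties and constants", {
  skip_if_not_installed("pROC")
  set.seed(2)
  for (s in 1:10) {
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    sc <- rnorm(60) + y
    expect_equal(auc_rank(sc, y),
                 as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE))),
                 tolerance = 1e-12)
  }
  expect_equal(auc_rank(rep(1, 10), rep(c(0, 1), 5)), 0.5)  # all tied
  expect_error(auc_rank(1:5, rep(1, 5)), "both classes")
})

test_that("under the null, CV error tracks minority prevalence and CV AUC centres on 0.5", {
  set.seed(5)
  errs <- numeric(50); aucs <- numeric(50)
  for (s in 1:50) {
    X <- matrix(rnorm(100 * 10), 100, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- rep(c(0, 1), c(60, 40))  # minority prevalence 0.4
    f <- fit_lasso_cv(X, y, n_folds = 10, seed = 100 + s)
    errs[s] <- f$cv_error; aucs[s] <- f$cv_auc
  }
  expect_lt(abs(mean(errs) - 0.4), 0.08)
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("a perfect linear separator is selected and drives CV error to zero", {
  set.seed(9)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(sep = y * 2 - 1 + rnorm(n, 0, 0.01),
             matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("f", 1:5))))
  X <- scale(X)
  f <- fit_lasso_cv(X, y, seed = 4)
  expect_gt(abs(f$beta[["sep"]]), 0)
  expect_lt(f$cv_error, 0.05)
  expect_gt(f$cv_auc, 0.99)
})

test_that("fit preconditions: degenerate outcome and thin classes are errors", {
  X <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("f", 1:4)))
  expect_error(fit_lasso_cv(X, rep(1, 40)), "degenerate")
  expect_error(fit_lasso_cv(X, rep(c(0, 1), c(36, 4)), n_folds = 10),
               "per class")
})

test_that("representative iteration minimizes distance to the mean CV error", {
  set.seed(11)
  X <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c(0, 1), 25)
  m <- repeat_and_select(X, y, n_iter = 12, n_folds = 5, base_seed = 3)
  errs <- m$iteration_errors
  expect_length(errs, 12)
  expect_equal(abs(errs[m$representative_iteration] - mean(errs)),
               min(abs(errs - mean(errs))))
  # ties break to the lowest index: with a dominant separator all iterations
  # reach zero error, so iteration 1 is representative
  Xs <- cbind(sep = (y * 2 - 1) * 3, X)
  ms <- repeat_and_select(Xs, y, n_iter = 5, n_folds = 5, base_seed = 3)
  expect_equal(unique(ms$iteration_errors), 0)
  expect_equal(ms$representative_iteration, 1L)
})

test_that("repeated selection is bitwise reproducible for a fixed base seed", {
  set.seed(13)
  X <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rep(c(0, 1), 25)
  m1 <- repeat_and_select(X, y, n_iter = 6, n_folds = 5, base_seed = 42)
  m2 <- repeat_and_select(X, y, n_iter = 6, n_folds = 5, base_seed = 42)
  expect_identical(m1, m2)
  # and does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1)
  invisible(repeat_and_select(X, y, n_iter = 2, n_folds = 5, base_seed = 7))
  expect_identical(runif(1), before)
})

test_that("constant feature columns are dropped with a warning", {
  set.seed(17)
  X <- cbind(const = rep(1, 40),
             matrix(rnorm(40 * 4), 40, 4,
                    dimnames = list(NULL, paste0("f", 1:4))))
  y <- rep(c(0, 1), 20)
  expect_warning(m <- repeat_and_select(X, y, n_iter = 2, n_folds = 5,
                                        base_seed = 1), "constant")
  expect_false("const" %in% names(m$beta))
})

test_that("composite score: standardization, zero model, single feature", {
  set.seed(19)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- mk_model(c(a = 0.7, b = -0.2, c = 0))
  sc <- composite_score(X, m)
  expect_equal(mean(sc), 0, tolerance = 1e-12)
  expect_equal(sd(sc), 1, tolerance = 1e-12)
  # all-zero coefficients: constant score, flagged
  sc0 <- composite_score(X, mk_model(c(a = 0, b = 0, c = 0)))
  expect_true(attr(sc0, "null_model"))
  expect_equal(unique(as.numeric(sc0)), 0)
  # a single nonzero coefficient reproduces that standardized column
  sc1 <- composite_score(X, mk_model(c(a = 2, b = 0, c = 0)))
  expect_equal(as.numeric(sc1), as.numeric(scale(X[, "a"])),
               tolerance = 1e-12)
  expect_error(composite_score(X[, 1:2], m), "missing feature")
})

test_that("odds ratio per SD recovers a known slope and its test holds its level", {
  set.seed(23)
  # recovery: true log-odds slope ln 2 per SD
  hits <- 0; sims <- 200
  for (s in 1:sims) {
    sc <- rnorm(1000)
    y <- rbinom(1000, 1, plogis(log(2) * sc))
    o <- odds_ratio_per_sd(sc, y)
    if (o$or >= 1.7 && o$or <= 2.3) hits <- hits + 1
    if (s <= 5) {
      expect_gt(o$or, o$ci_low)
      expect_lt(o$or, o$ci_high)
    }
  }
  expect_gte(hits / sims, 0.9)
  # calibration of the likelihood-ratio test on a fixed score
  ps <- replicate(1000, {
    sc <- rnorm(120)
    y <- rbinom(120, 1, 0.5)
    odds_ratio_per_sd(sc, y)$p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.025)
})

test_that("odds ratio edge cases: null score and perfect separation", {
  o <- odds_ratio_per_sd(rep(0, 20), rep(c(0, 1), 10))
  expect_equal(o$or, 1)
  expect_equal(o$p, 1)
  expect_true(o$null_score)
  sc <- c(rnorm(10, -3), rnorm(10, 3))
  o2 <- odds_ratio_per_sd(sc, as.numeric(sc > 0))
  expect_true(o2$separation)
  expect_true(is.na(o2$or))
})

test_that("c-statistic summary: degenerate and exact cases", {
  cs <- c_statistic_summary(rep(0.7, 100))
  expect_equal(cs$c_statistic, 0.7)
  expect_equal(cs$ci_low, 0.7)
  expect_equal(cs$ci_high, 0.7)
  cs2 <- c_statistic_summary(c(0.6, 0.8))
  expect_equal(cs2$c_statistic, 0.7)
  expect_true(cs2$ci_low < 0.7 && cs2$ci_high > 0.7)
})

test_that("the score pipeline is invariant to affine feature rescaling", {
  set.seed(29)
  n <- 60
  y <- rep(c(0, 1), n / 2)
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  X[, 1] <- X[, 1] + y
  m1 <- repeat_and_select(X, y, n_iter = 4, n_folds = 5, base_seed = 5)
  X2 <- sweep(sweep(X, 2, c(3, 0.1, 10, 2, 5, 0.01), "*"), 2, 1:6, "+")
  m2 <- repeat_and_select(X2, y, n_iter = 4, n_folds = 5, base_seed = 5)
  expect_equal(composite_score(X, m1), composite_score(X2, m2),
               tolerance = 1e-8)
  expect_equal(m1$iteration_aucs, m2$iteration_aucs, tolerance = 1e-8)
})

test_that("split confirmation holds out half the labels and detects real signal", {
  set.seed(31)
  n <- 120
  y <- rep(c(0, 1), n / 2)
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  X[, 1:2] <- X[, 1:2] + 1.2 * y
  sc <- split_confirmation(X, y, n_iter = 5, n_folds = 5, seed = 77)
  expect_equal(sc$n_train + sc$n_test, n)
  expect_true(abs(sc$n_train - sc$n_test) <= 2)
  expect_lt(sc$p, 0.01)
  expect_true(is.na(sc$or) || sc$or > 2)  # strong effect; separation possible
  # deterministic given the seed
  sc2 <- split_confirmation(X, y, n_iter = 5, n_folds = 5, seed = 77)
  expect_identical(sc[c("or", "p", "n_train")], sc2[c("or", "p", "n_train")])
})

test_that("the association suite reports six models with the Bonferroni gate applied", {
  set.seed(37)
  n_sub <- 44
  ids <- sprintf("S%02d", 1:n_sub)
  y <- setNames(rep(c(0, 1), n_sub / 2), ids)
  reg <- paste0("f", 1:6)
  recs <- list()
  for (i in seq_len(n_sub)) for (rg in c("medial_tibia", "medial_femur"))
    for (tp in c("initial", "followup")) {
      v <- rnorm(6)
      # change signal only, in both regions
      if (tp == "followup") v <- v + 1.5 * y[[i]]
      recs[[length(recs) + 1L]] <- list(
        subject_id = ids[i], region = rg, timepoint = tp,
        features = setNames(v, reg))
    }
  ft <- build_feature_table(recs)
  suite <- run_association_suite(ft, y, retained = reg, n_iter = 4,
                                 n_folds = 5, base_seed = 2)
  res <- suite$results
  expect_equal(nrow(res), 6)
  expect_setequal(res$region, c("tibial", "femoral", "combined"))
  expect_true(all(c("odds_ratio", "ci_low", "ci_high", "p", "significant",
                    "top_features", "c_statistic", "c_ci_low", "c_ci_high")
                  %in% names(res)))
  expect_equal(res$significant, !is.na(res$p) & res$p < 0.008)
  # a p of 0.01 would not pass the multiplicity-adjusted gate
  expect_false(0.01 < 0.008)
  # change models see the constructed signal; initial models do not
  expect_true(all(res$c_statistic[res$timebase == "change"] > 0.8))
  expect_true(all(res$c_statistic[res$timebase == "initial"] < 0.7))
  expect_length(suite$models, 6)
  expect_length(suite$scores, 6)
})
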