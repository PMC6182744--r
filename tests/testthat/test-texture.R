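# hand-built quantized grid (bypasses quantize) for closed-form cases
mk_q <- function(grid, n_levels) {
  structure(list(grid = grid, levels = grid[!is.na(grid)],
                 n_levels = as.integer(n_levels),
                 degenerate = length(unique(grid[!is.na(grid)])) < 2L),
            class = "quantized_roi")
}

test_that("GLCM counts and features match the brute-force oracle on masked images", {
  for (s in 1:12) {
    im <- random_masked_image(8, 9, seed = s)
    q <- quantize(im$px, im$mk, bits = 4)
    for (d in c(0, 45, 90, 135)) for (off in c(1, 3)) {
      g <- compute_glcm(q, d, off)
      oc <- oracle_glcm(q$grid, q$n_levels, d, off)
      if (is.null(g)) {
        expect_equal(sum(oc), 0)
        next
      }
      expect_equal(g$counts, oc)
      expect_equal(unlist(glcm_features(g)[names(oracle_glcm_features(g$probabilities))]),
                   oracle_glcm_features(g$probabilities), tolerance = 1e-12)
    }
  }
})

test_that("GLCM is symmetric, normalized, and counts each pair twice", {
  im <- random_masked_image(10, 10, seed = 77)
  q <- quantize(im$px, im$mk, bits = 6)
  g <- compute_glcm(q, 45, 2)
  expect_equal(g$counts, t(g$counts))
  expect_equal(sum(g$probabilities), 1)
  expect_true(all(g$counts %% 2 == 0) || sum(g$counts) %% 2 == 0)
  # an offset larger than the grid admits no pairs
  tiny <- mk_q(matrix(c(1L, 2L), 2, 2), 2)
  expect_null(compute_glcm(tiny, 0, 5))
})

test_that("constant ROI gives ASM 1, contrast 0, entropy 0 and degenerate correlation", {
  q <- mk_q(matrix(1L, 4, 4), 64)
  f <- glcm_features(compute_glcm(q, 0, 1))
  expect_equal(f$asm, 1)
  expect_equal(f$contrast, 0)
  expect_equal(f$entropy, 0)
  expect_true(f$degenerate)
  expect_equal(f$correlation, 0)
})

test_that("4x4 checkerboard gives GLCM contrast 1, ASM 0.5, entropy ln 2", {
  grid <- matrix(1L + (outer(1:4, 1:4, `+`) %% 2L), 4, 4)
  q <- mk_q(grid, 2)
  f <- glcm_features(compute_glcm(q, 0, 1))
  expect_equal(f$contrast, 1)
  expect_equal(f$asm, 0.5)
  expect_equal(f$entropy, log(2))
})

test_that("RLM matches the run-walking oracle and conserves pixels", {
  for (s in 1:12) {
    im <- random_masked_image(9, 8, seed = 40 + s)
    q <- quantize(im$px, im$mk, bits = 4)
    n_px <- sum(im$mk)
    for (d in c(0, 45, 90, 135)) {
      r <- compute_rlm(q, d)
      oc <- oracle_rlm(q$grid, q$n_levels, d)
      expect_equal(r$counts[, seq_len(ncol(oc)), drop = FALSE], oc)
      if (ncol(r$counts) > ncol(oc))
        expect_true(all(r$counts[, -seq_len(ncol(oc))] == 0))
      # every in-mask pixel sits in exactly one maximal run
      expect_equal(sum(sweep(r$counts, 2, seq_len(ncol(r$counts)), "*")), n_px)
      expect_equal(unlist(rlm_features(r)),
                   oracle_rlm_features(r$counts, n_px), tolerance = 1e-12)
    }
  }
})

test_that("4x4 constant grid horizontal RLM gives SRE 1/16, LRE 16, fraction 0.25", {
  q <- mk_q(matrix(1L, 4, 4), 2)
  f <- rlm_features(compute_rlm(q, 0))
  expect_equal(f$short_run_emphasis, 1 / 16)
  expect_equal(f$long_run_emphasis, 16)
  expect_equal(f$fraction_in_runs, 0.25)
})

test_that("gradient and histogram features match their oracles", {
  for (s in 1:10) {
    im <- random_masked_image(9, 9, seed = 70 + s, hole_prob = 0.1)
    g <- gradient_features(im$px, im$mk, bits = 4)
    q4 <- quantize(im$px, im$mk, 4)
    G <- oracle_gradient(q4$grid)
    mo <- oracle_moments(G)
    expect_equal(g$gr_mean, mo[["mean"]], tolerance = 1e-12)
    expect_equal(g$gr_variance, mo[["variance"]], tolerance = 1e-12)
    expect_equal(g$gr_nonzeros, mean(G > 0), tolerance = 1e-12)
    h <- histogram_features(im$px[im$mk])
    x <- im$px[im$mk]
    x <- (x - min(x)) / (max(x) - min(x))
    expect_equal(unlist(h[c("mean", "variance", "skewness", "kurtosis")]),
                 oracle_moments(x), tolerance = 1e-12)
  }
})

test_that("degenerate inputs report zero higher moments, not NaN", {
  h <- histogram_features(rep(3.2, 10))
  expect_equal(h$skewness, 0)
  expect_equal(h$kurtosis, 0)
  expect_true(h$degenerate)
  g <- gradient_features(matrix(1, 8, 8), matrix(TRUE, 8, 8))
  expect_equal(g$gr_mean, 0)
  expect_equal(g$gr_nonzeros, 0)
})

test_that("configuration averaging drops skipped configurations", {
  expect_equal(aggregate_feature(c(1, NA, 3)), 2)
  expect_true(is.na(aggregate_feature(c(NA_real_, NA_real_))))
})

test_that("the default registry has the 19 features in four classes", {
  reg <- texture_registry()
  expect_length(reg, 19)
  expect_length(texture_registry(full = TRUE), 23)
  expect_true(all(c("mean", "variance", "gr_mean", "gr_variance",
                    "short_run_emphasis", "asm", "contrast", "entropy",
                    "correlation") %in% reg))
  expect_false(any(duplicated(reg)))
})

test_that("slice features are invariant to affine intensity rescaling", {
  im <- random_masked_image(24, 24, seed = 5, hole_prob = 0)
  f1 <- slice_features(im$px, im$mk)
  f2 <- slice_features(im$px * 12.5 + 3, im$mk)
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("feature table assembly, changes, and dataset matrices are consistent", {
  reg <- c("f1", "f2")
  rec <- function(id, rg, tp, v)
    list(subject_id = id, region = rg, timepoint = tp,
         features = setNames(v, reg))
  recs <- list(
    rec("A", "medial_tibia", "initial", c(1, 10)),
    rec("A", "medial_tibia", "followup", c(3, 14)),
    rec("A", "medial_femur", "initial", c(2, 20)),
    rec("A", "medial_femur", "followup", c(2.5, 19)),
    rec("B", "medial_tibia", "initial", c(5, 50)),
    rec("B", "medial_tibia", "followup", c(4, 55)),
    rec("B", "medial_femur", "initial", c(6, 60)),
    rec("B", "medial_femur", "followup", c(7, 58)))
  ft <- build_feature_table(recs)
  expect_s3_class(ft, "feature_table")
  ch <- feature_changes(ft)
  expect_equal(ch$f1[ch$subject_id == "A" & ch$region == "medial_tibia"], 2)
  expect_equal(ch$f2[ch$subject_id == "B" & ch$region == "medial_femur"], -2)
  Xt <- dataset_matrix(ft, "tibial", "initial")
  expect_equal(Xt["A", "f1"], 1)
  Xc <- dataset_matrix(ft, "combined", "change")
  expect_equal(colnames(Xc), c("T_f1", "T_f2", "F_f1", "F_f2"))
  expect_equal(Xc["B", "T_f1"], -1)
  expect_equal(Xc["A", "F_f2"], -1)
  # duplicate keys rejected
  expect_error(build_feature_table(c(recs, recs[1])), "duplicate")
  # a subject missing follow-up is omitted from change rows
  ft2 <- build_feature_table(recs[-2])
  ch2 <- feature_changes(ft2)
  expect_false(any(ch2$subject_id == "A" & ch2$region == "medial_tibia"))
})

test_that("longer generative correlation length lowers entropy (organization knob)", {
  cfg <- texture_config()
  ent <- sapply(c(2, 8), function(cl) {
    tp <- texture_params(correlation_length = cl, image_size = 64)
    vals <- sapply(1:6, function(s) {
      sl <- make_trabecular_slice(tp, seed = 900 + s)
      slice_features(sl$image, sl$masks$medial_tibia, cfg)[["entropy"]]
    })
    mean(vals)
  })
  expect_gt(ent[1], ent[2])
})
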