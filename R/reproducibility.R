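# Inter-observer agreement screening: features with poor reproducibility in
# either region (ICC < 0.8 or RMSCV > 10%) are excluded before modelling.

#' Single-measures absolute-agreement intraclass correlation
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC (ICC(A,1)),
#' computed from explicit two-way ANOVA sums of squares over an n-subjects by
#' k-raters table:
#' `(MS_rows - MS_err) / (MS_rows + (k-1) MS_err + (k/n)(MS_cols - MS_err))`.
#' Absolute agreement penalizes systematic rater offsets, unlike consistency
#' ICCs.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns
#'   (at least 3 subjects, no missing cells).
#' @return list with `icc` and `defined` (FALSE when total variance is zero).
#' @export
icc_single_absolute <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3L) stop("need at least 3 subjects")
  if (anyNA(ratings)) stop("missing cells not allowed")
  grand <- mean(ratings)
  if (sum((ratings - grand)^2) <= 0)
    return(list(icc = NA_real_, defined = FALSE))
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  icc <- (ms_rows - ms_err) /
    (ms_rows + (k - 1) * ms_err + (k / n) * (ms_cols - ms_err))
  list(icc = icc, defined = TRUE)
}

#' Root-mean-square average coefficient of variation (percent)
#'
#' Per subject, `CV_i = SD(ratings_i) / |mean(ratings_i)|` with the sample
#' (n-1) SD — for two ratings a, b this is `|a - b| / sqrt(2)` — and
#' `RMSCV = 100 * sqrt(mean(CV_i^2))`. Subjects whose mean magnitude falls
#' below `eps_frac` times the feature scale (median absolute rating) are
#' excluded: CV is ill-defined near zero, which matters for sign-crossing
#' features such as skewness.
#'
#' @param ratings numeric matrix, subjects x raters.
#' @param eps_frac relative near-zero threshold (default 1e-8).
#' @return list with `rmscv` (percent; `NA` when every subject was excluded),
#'   `n_used`, `n_excluded`.
#' @export
rmscv <- function(ratings, eps_frac = 1e-8) {
  ratings <- as.matrix(ratings)
  mu <- rowMeans(ratings)
  s <- apply(ratings, 1, sd)
  scale <- stats::median(abs(ratings))
  eps <- eps_frac * max(scale, .Machine$double.eps)
  keep <- abs(mu) >= eps
  if (!any(keep))
    return(list(rmscv = NA_real_, n_used = 0L, n_excluded = nrow(ratings)))
  cv <- s[keep] / abs(mu[keep])
  list(rmscv = 100 * sqrt(mean(cv^2)),
       n_used = sum(keep), n_excluded = sum(!keep))
}

#' Per-feature, per-region reproducibility report
#'
#' @param dup_features named list by region; each element a list with
#'   `rater1`, `rater2`: subjects-by-features matrices with identical
#'   dimnames.
#' @param icc_min retain threshold on ICC (exclusion is strictly `< icc_min`).
#' @param rmscv_max retain threshold on RMSCV percent (exclusion strictly
#'   `> rmscv_max`).
#' @return data frame `feature`, `region`, `icc`, `rmscv_percent`, `ok`
#'   (thresholds met in that region); class `reproducibility_report`.
#' @export
reproducibility_report <- function(dup_features, icc_min = 0.8,
                                   rmscv_max = 10) {
  rows <- list()
  for (rg in names(dup_features)) {
    r1 <- dup_features[[rg]]$rater1
    r2 <- dup_features[[rg]]$rater2
    stopifnot(identical(dimnames(r1), dimnames(r2)))
    for (f in colnames(r1)) {
      tab <- cbind(r1[, f], r2[, f])
      ic <- icc_single_absolute(tab)
      cv <- rmscv(tab)
      ok <- isTRUE(ic$defined && !is.na(cv$rmscv) &&
                   ic$icc >= icc_min && cv$rmscv <= rmscv_max)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, region = rg, icc = ic$icc,
        rmscv_percent = cv$rmscv, ok = ok, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("reproducibility_report", "data.frame")
  out
}

#' Screen the feature registry on reproducibility
#'
#' A feature is retained only when it meets both thresholds in both regions
#' (the exclusion rule is "either ROI"). Boundary values are retained:
#' exclusion is strictly ICC < `icc_min` or RMSCV > `rmscv_max`.
#'
#' @param report a `reproducibility_report` covering both regions.
#' @param registry feature names in registry order.
#' @param icc_min,rmscv_max thresholds (defaults 0.8 and 10).
#' @return character vector of retained features, in registry order.
#' @export
screen_registry <- function(report, registry = texture_registry(),
                            icc_min = 0.8, rmscv_max = 10) {
  regions <- unique(report$region)
  if (length(regions) < 2L) stop("report must cover both regions")
  pass <- vapply(registry, function(f) {
    sub <- report[report$feature == f, , drop = FALSE]
    nrow(sub) == length(regions) &&
      all(!is.na(sub$icc) & !is.na(sub$rmscv_percent) &
          sub$icc >= icc_min & sub$rmscv_percent <= rmscv_max)
  }, logical(1))
  retained <- registry[pass]
  if (length(retained) == 0L)
    stop("no features survived the reproducibility screen")
  retained
}
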