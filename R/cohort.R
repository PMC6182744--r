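# Progression-defined case-control construction: the FNIH radiographic
# progression rule (>= 0.7 mm medial minJSW loss over 36 months), eligibility
# exclusions, and 1:1 optimal propensity-score matching with next-best
# re-matching after image-based exclusions.

#' Classify radiographic progression from minJSW trajectory
#'
#' A knee is a case (progressor) when minimum medial joint space width
#' decreases by at least 0.7 mm between the 36- and 72-month visits; the
#' boundary is inclusive. Knees missing either measurement are ineligible.
#'
#' @param minjsw_36m,minjsw_72m minimum medial JSW in mm (vectorized; `NA`
#'   allowed).
#' @param threshold_mm progression threshold (default 0.7).
#' @return character vector in `{"case", "control", "ineligible"}`.
#' @export
classify_progression <- function(minjsw_36m, minjsw_72m, threshold_mm = 0.7) {
  if (any(minjsw_36m < 0, na.rm = TRUE) || any(minjsw_72m < 0, na.rm = TRUE))
    stop("input error: negative joint space width")
  delta <- minjsw_36m - minjsw_72m
  # inclusive boundary with a tolerance far below the 0.01 mm measurement
  # precision, so a loss recorded as exactly 0.7 mm is a case even when the
  # subtraction lands a few ulps short
  out <- ifelse(is.na(delta), "ineligible",
                ifelse(delta >= threshold_mm - 1e-9, "case", "control"))
  out
}

#' Apply eligibility exclusions
#'
#' Drops knees with missing minJSW at either visit, KL grade 4 at 36 months
#' (ceiling effect on minJSW progression), or lateral-predominant disease
#' (greater OARSI JSN grade laterally than medially at 36 months; a tie is
#' not "greater"). Exactly one reason is logged per excluded subject, in that
#' precedence order.
#'
#' @param records data frame with columns `subject_id`, `minjsw_36m`,
#'   `minjsw_72m`, `kl_grade_36m`, `oarsi_jsn_medial_36m`,
#'   `oarsi_jsn_lateral_36m`.
#' @return list: `eligible` (subset of `records`), `exclusion_log` (data frame
#'   `subject_id`, `reason`).
#' @export
apply_exclusions <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  miss <- is.na(records$minjsw_36m) | is.na(records$minjsw_72m)
  reason[miss] <- "missing minJSW"
  kl4 <- !miss & records$kl_grade_36m == 4
  reason[kl4] <- "KL4 ceiling"
  lat <- is.na(reason) &
    records$oarsi_jsn_lateral_36m > records$oarsi_jsn_medial_36m
  reason[lat] <- "lateral predominant"
  keep <- is.na(reason)
  list(
    eligible = records[keep, , drop = FALSE],
    exclusion_log = data.frame(
      subject_id = records$subject_id[!keep],
      reason = reason[!keep], stringsAsFactors = FALSE)
  )
}

#' Exact solution of the rectangular linear assignment problem
#'
#' Minimizes total cost over one-to-one assignments of rows to columns
#' (rows <= columns) by the shortest-augmenting-path (Jonker-Volgenant style)
#' algorithm with dual potentials.
#'
#' @param cost numeric matrix, `nrow(cost) <= ncol(cost)`, finite entries.
#' @return list: `assignment` (column index per row), `total_cost`.
#' @export
solve_lap <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("need at least as many columns as rows")
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  u <- numeric(n); v <- numeric(m)
  p <- integer(m + 1L)  # p[1]: row being inserted; p[j+1]: row matched to col j
  way <- integer(m)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m)
    repeat {
      if (j0 > 0L) used[j0] <- TRUE
      i0 <- if (j0 == 0L) p[1L] else p[j0 + 1L]
      free <- which(!used)
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      u[p[1L]] <- u[p[1L]] + delta  # virtual column 0 is always in the tree
      usedj <- which(used)
      if (length(usedj)) {
        u[p[usedj + 1L]] <- u[p[usedj + 1L]] + delta
        v[usedj] <- v[usedj] - delta
      }
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    while (j0 != 0L) {  # augment along the alternating path
      j1 <- way[j0]
      p[j0 + 1L] <- if (j1 == 0L) p[1L] else p[j1 + 1L]
      j0 <- j1
    }
  }
  assignment <- integer(n)
  cols <- which(p[-1L] > 0L)
  assignment[p[cols + 1L]] <- cols
  list(assignment = assignment,
       total_cost = sum(cost[cbind(seq_len(n), assignment)]))
}

.encode_sex <- function(sex) {
  if (is.numeric(sex)) return(as.numeric(sex))
  as.numeric(tolower(as.character(sex)) %in% c("f", "female", "1"))
}

#' 1:1 optimal propensity-score matching of cases to controls
#'
#' Fits a logistic propensity model of case status on age, sex, BMI and
#' initial medial minJSW, then pairs every case with a distinct control by
#' globally minimizing total distance on the logit-propensity scale (exact
#' linear assignment; no caliper).
#'
#' @param cohort data frame with columns `subject_id`, `group`
#'   (`"case"`/`"control"`), `age`, `sex`, `bmi`, `minjsw_36m`.
#' @return object of class `matched_cohort`: `pairs` (data frame `case_id`,
#'   `control_id`, `distance`, `replaced`), `propensity_coef`, `logit` (named
#'   vector over all subjects), `reserve_controls` (unused control ids),
#'   `distance_metric`.
#' @export
propensity_match <- function(cohort) {
  cases <- cohort[cohort$group == "case", , drop = FALSE]
  ctrls <- cohort[cohort$group == "control", , drop = FALSE]
  if (nrow(ctrls) < nrow(cases))
    stop("infeasible matching: fewer controls than cases")
  dat <- data.frame(
    y = as.numeric(cohort$group == "case"),
    age = cohort$age, sex = .encode_sex(cohort$sex),
    bmi = cohort$bmi, minjsw = cohort$minjsw_36m)
  fit <- glm(y ~ age + sex + bmi + minjsw, family = binomial(), data = dat)
  if (!fit$converged) stop("propensity model did not converge")
  lp <- setNames(predict(fit, type = "link"), cohort$subject_id)
  d <- abs(outer(lp[cases$subject_id], lp[ctrls$subject_id], `-`))
  sol <- solve_lap(d)
  pairs <- data.frame(
    case_id = cases$subject_id,
    control_id = ctrls$subject_id[sol$assignment],
    distance = d[cbind(seq_len(nrow(cases)), sol$assignment)],
    replaced = FALSE, stringsAsFactors = FALSE)
  structure(list(
    pairs = pairs,
    propensity_coef = coef(fit),
    logit = lp,
    reserve_controls = setdiff(ctrls$subject_id, pairs$control_id),
    distance_metric = "absolute difference of logit propensity",
    total_distance = sol$total_cost), class = "matched_cohort")
}

#' Re-match after post-hoc exclusions
#'
#' Subjects excluded after matching (motion artefact, unavailable MRI, cysts,
#' surgery) are handled pairwise: an excluded case takes its matched control
#' out of the analysis with it; an excluded control is replaced by the
#' nearest unused reserve control for its case, or the case is dropped with a
#' warning when the reserve pool is exhausted.
#'
#' @param mc a `matched_cohort`.
#' @param excluded_ids subject ids to remove.
#' @return updated `matched_cohort` with a `rematch_log` data frame
#'   (`subject_id`, `role`, `action`).
#' @export
rematch_excluded <- function(mc, excluded_ids) {
  pairs <- mc$pairs
  reserve <- mc$reserve_controls
  log <- list()
  note <- function(id, role, action)
    data.frame(subject_id = id, role = role, action = action,
               stringsAsFactors = FALSE)
  # excluded cases first: their controls leave too
  drop_case <- pairs$case_id %in% excluded_ids
  for (id in pairs$case_id[drop_case])
    log[[length(log) + 1L]] <- note(id, "case", "pair removed")
  for (id in pairs$control_id[drop_case])
    log[[length(log) + 1L]] <- note(id, "control", "removed with its case")
  pairs <- pairs[!drop_case, , drop = FALSE]
  # excluded controls: next-best unused reserve for the same case
  reserve <- setdiff(reserve, excluded_ids)
  for (r in which(pairs$control_id %in% excluded_ids)) {
    old <- pairs$control_id[r]
    if (length(reserve) == 0L) {
      log[[length(log) + 1L]] <- note(pairs$case_id[r], "case",
                                      "dropped: reserve exhausted")
      pairs$control_id[r] <- NA_character_
      warning("reserve controls exhausted; case ", pairs$case_id[r],
              " dropped")
      next
    }
    dist <- abs(mc$logit[pairs$case_id[r]] - mc$logit[reserve])
    pick <- reserve[which.min(dist)]
    reserve <- setdiff(reserve, pick)
    pairs$control_id[r] <- pick
    pairs$distance[r] <- min(dist)
    pairs$replaced[r] <- TRUE
    log[[length(log) + 1L]] <- note(old, "control",
                                    paste("replaced by", pick))
  }
  pairs <- pairs[!is.na(pairs$control_id), , drop = FALSE]
  mc$pairs <- pairs
  mc$reserve_controls <- reserve
  mc$rematch_log <- if (length(log)) do.call(rbind, log) else
    data.frame(subject_id = character(0), role = character(0),
               action = character(0))
  mc
}

#' Standardized mean difference between matched groups
#'
#' `(mean_case - mean_control) / sqrt((var_case + var_control) / 2)`; the
#' usual covariate-balance diagnostic (|SMD| < 0.1 indicates good balance).
#'
#' @param x_case,x_control numeric vectors.
#' @return scalar SMD (0 when both variances vanish and means agree).
#' @export
standardized_mean_diff <- function(x_case, x_control) {
  s <- sqrt((var(x_case) + var(x_control)) / 2)
  d <- mean(x_case) - mean(x_control)
  if (s == 0) return(if (d == 0) 0 else Inf)
  d / s
}

#' Post-match covariate balance table
#'
#' @param mc a `matched_cohort`.
#' @param cohort the cohort data frame used for matching.
#' @return data frame `covariate`, `smd` for age, sex, BMI, initial minJSW.
#' @export
match_balance <- function(mc, cohort) {
  rows <- cohort[match(c(mc$pairs$case_id, mc$pairs$control_id),
                       cohort$subject_id), , drop = FALSE]
  n <- nrow(mc$pairs)
  grp <- rep(c("case", "control"), each = n)
  covs <- list(age = rows$age, sex = .encode_sex(rows$sex), bmi = rows$bmi,
               minjsw_36m = rows$minjsw_36m)
  data.frame(
    covariate = names(covs),
    smd = vapply(covs, function(x)
      standardized_mean_diff(x[grp == "case"], x[grp == "control"]),
      numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
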