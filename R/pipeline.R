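# End-to-end orchestration over a synthetic (or loaded) study: feature
# extraction, duplicate-analyst reproducibility screening, progression
# classification, matching with re-matching, and the six-model association
# suite.

#' Extract the subject-level feature table from a synthetic study
#'
#' Computes per-region, direction/offset-averaged, slice-averaged texture
#' features for the requested subjects. Follow-up series are skipped for
#' subjects flagged with a follow-up image exclusion; initial-flagged
#' subjects are skipped entirely (they leave the analysis at re-matching).
#'
#' @param study a `synthetic_study`.
#' @param subject_ids subjects to extract (default: all).
#' @param config a [texture_config()].
#' @param honor_exclusions apply the study's image-exclusion flags.
#' @param regions regions to extract (default both).
#' @return a `feature_table`.
#' @export
extract_study_features <- function(study,
                                   subject_ids = study$cohort$subject_id,
                                   config = texture_config(),
                                   honor_exclusions = TRUE,
                                   regions = c("medial_tibia",
                                               "medial_femur")) {
  records <- list()
  co <- study$cohort
  for (id in subject_ids) {
    row <- co[co$subject_id == id, ]
    if (honor_exclusions && row$excl_initial != "none") next
    tps <- "initial"
    if (!honor_exclusions || row$excl_followup == "none")
      tps <- c(tps, "followup")
    for (tpnt in tps) {
      ser <- subject_series(study, id, tpnt)
      sf <- series_features(ser, config, regions = regions)
      for (rg in names(sf)) {
        records[[length(records) + 1L]] <- list(
          subject_id = id, region = rg, timepoint = tpnt,
          features = sf[[rg]])
      }
    }
  }
  build_feature_table(records)
}

#' Duplicate-analyst feature extraction for the reproducibility screen
#'
#' Re-analyses a random subsample of subjects with independently perturbed
#' ROIs (second analyst) at the initial timepoint and returns, per region,
#' the two subjects-by-features rating matrices.
#'
#' @param study a `synthetic_study`.
#' @param n_subjects duplicate-rated subjects (default from the study's
#'   cohort parameters, 23).
#' @param config a [texture_config()].
#' @param seed subject-sampling seed.
#' @param candidate_ids pool to sample from (default: subjects without
#'   initial-image exclusions).
#' @return named list by region with `rater1`, `rater2` matrices, suitable
#'   for [reproducibility_report()].
#' @export
duplicate_rater_features <- function(study,
                                     n_subjects =
                                       study$cohort_params$n_duplicate_rated,
                                     config = texture_config(), seed = 1L,
                                     candidate_ids = NULL) {
  if (is.null(candidate_ids))
    candidate_ids <-
      study$cohort$subject_id[study$cohort$excl_initial == "none"]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- sample(candidate_ids, min(n_subjects, length(candidate_ids)))
  regions <- c("medial_tibia", "medial_femur")
  mats <- lapply(regions, function(rg) {
    r1 <- r2 <- matrix(NA_real_, length(ids), length(config$registry),
                       dimnames = list(ids, config$registry))
    list(rater1 = r1, rater2 = r2)
  })
  names(mats) <- regions
  for (i in seq_along(ids)) {
    s1 <- series_features(subject_series(study, ids[i], "initial", rater = 1L),
                          config)
    s2 <- series_features(subject_series(study, ids[i], "initial", rater = 2L),
                          config)
    for (rg in regions) {
      mats[[rg]]$rater1[i, ] <- s1[[rg]]
      mats[[rg]]$rater2[i, ] <- s2[[rg]]
    }
  }
  mats
}

#' Run the full analysis on a synthetic study
#'
#' Classifies progression from the minJSW trajectory, applies eligibility
#' exclusions, builds the 1:1 optimal propensity-matched cohort, re-matches
#' around image-based exclusions, extracts texture features for the analysis
#' subjects, screens the registry on duplicate-analyst reproducibility, and
#' runs the six-model association suite.
#'
#' @param study a `synthetic_study`.
#' @param config a [texture_config()].
#' @param n_iter LASSO repetitions per model (default 100).
#' @param n_folds CV folds (default 10).
#' @param seed analysis seed (folds, duplicate-rater subsample).
#' @param screen apply the reproducibility screen (set `FALSE` to keep the
#'   full registry, e.g. for timing experiments).
#' @return list: `results` (six-model Table-style data frame), `models`,
#'   `scores`, `matched` (`matched_cohort`), `balance`, `report`
#'   (reproducibility), `retained`, `feature_table`, `exclusion_log`,
#'   `labels`, `provenance`.
#' @export
analyze_study <- function(study, config = texture_config(), n_iter = 100L,
                          n_folds = 10L, seed = 1L, screen = TRUE) {
  co <- study$cohort
  co$progression <- classify_progression(co$minjsw_36m, co$minjsw_72m)
  ex <- apply_exclusions(co)
  elig <- ex$eligible[ex$eligible$progression != "ineligible", , drop = FALSE]
  elig$group <- elig$progression
  mc <- propensity_match(elig)
  # image-based exclusions at the initial timepoint trigger re-matching
  excl_ini <- co$subject_id[co$excl_initial != "none"]
  mc <- rematch_excluded(mc, excl_ini)
  analysis_ids <- c(mc$pairs$case_id, mc$pairs$control_id)
  ft <- extract_study_features(study, analysis_ids, config = config)
  retained <- config$registry
  report <- NULL
  if (screen) {
    dup <- duplicate_rater_features(study, config = config, seed = seed,
                                    candidate_ids = analysis_ids)
    report <- reproducibility_report(dup)
    retained <- screen_registry(report, registry = config$registry)
  }
  labels <- setNames(as.numeric(co$progression[match(analysis_ids,
                                                     co$subject_id)] ==
                                  "case"), analysis_ids)
  suite <- run_association_suite(ft, labels, retained, n_iter = n_iter,
                                 n_folds = n_folds, base_seed = seed)
  list(results = suite$results, models = suite$models, scores = suite$scores,
       matched = mc, balance = match_balance(mc, elig), report = report,
       retained = retained, feature_table = ft,
       exclusion_log = ex$exclusion_log, labels = labels,
       provenance = list(seed = seed, n_iter = n_iter, n_folds = n_folds,
                         study_seed = study$seed,
                         cohort_params = study$cohort_params,
                         texture_params = study$texture_params,
                         r_version = R.version.string))
}

#' Write the Table-style results of an analysis to CSV
#'
#' @param analysis result of [analyze_study()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_results <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(results = file.path(dir, "association_results.csv"),
             balance = file.path(dir, "match_balance.csv"),
             exclusions = file.path(dir, "exclusion_log.csv"))
  write.csv(analysis$results, paths["results"], row.names = FALSE)
  write.csv(analysis$balance, paths["balance"], row.names = FALSE)
  write.csv(analysis$exclusion_log, paths["exclusions"], row.names = FALSE)
  if (!is.null(analysis$report)) {
    paths <- c(paths,
               reproducibility = file.path(dir, "reproducibility_report.csv"))
    write.csv(analysis$report, paths["reproducibility"], row.names = FALSE)
  }
  invisible(paths)
}
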