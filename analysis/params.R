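# Shared configuration for the numbered analysis scripts. Each script is
# run from the repository root as, e.g., `Rscript analysis/01_simulate.R`,
# and writes its tables under results/. The generator and analysis defaults
# reproduce the study conditions; change them here to rerun the whole
# workflow under different assumptions.

suppressPackageStartupMessages(library(ostex))

params <- list(
  study_seed    = 1L,     # synthetic-study seed (cohort, images, exclusions)
  analysis_seed = 2L,     # folds, duplicate-rater subsample, split halves
  n_iter        = 100L,   # LASSO repetitions per model
  n_folds       = 10L,
  results_dir   = "results"
)

dir.create(params$results_dir, recursive = TRUE, showWarnings = FALSE)

# the study object is deterministic in (parameters, seed) and images are
# generated lazily, so every script can rebuild it cheaply
build_study <- function() {
  make_study(cohort_params(), texture_params(), seed = params$study_seed)
}

res_path <- function(name) file.path(params$results_dir, name)
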