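# Duplicate-analyst reproducibility screen: re-extract a subsample of
# subjects with independently placed ROIs, compute per-feature ICC and
# RMSCV in both regions, and screen the feature registry.
# Reads:  results/matched_pairs.csv
# Writes: results/reproducibility_report.csv, results/retained_features.csv

source("analysis/params.R")

study <- build_study()
pairs <- read.csv(res_path("matched_pairs.csv"), stringsAsFactors = FALSE)
ids <- c(pairs$case_id, pairs$control_id)

dup <- duplicate_rater_features(study, seed = params$analysis_seed,
                                candidate_ids = ids)
rep <- reproducibility_report(dup)
retained <- screen_registry(rep, registry = texture_registry())

write.csv(rep, res_path("reproducibility_report.csv"), row.names = FALSE)
write.csv(data.frame(feature = retained),
          res_path("retained_features.csv"), row.names = FALSE)

cat(length(retained), "of", length(texture_registry()),
    "features retained (ICC >= 0.8 and RMSCV <= 10% in both regions)\n")
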