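#!/usr/bin/env Rscript
# Method-validation studies on planted ground truth: reporter-score null
# calibration and power, dereplication fast-path vs brute-force oracle,
# recovery of the planted cross-host sharing fraction, enterotype recovery,
# and Wilcoxon null calibration. These are the same computations
# scripts/acceptance.R reports.

source("analysis/00_config.R")

seed <- 20L
rows <- list()
add <- function(study, quantity, value) {
  rows[[length(rows) + 1]] <<- data.frame(study = study, quantity = quantity,
                                          value = value)
  message(sprintf("%-22s %-28s %g", study, quantity, value))
}

nul <- study_reporter_null(seed = seed)
add("reporter_null", "tail_fraction_ge_1.6", nul$frac_above)
add("reporter_null", "expected_tail", nul$expected_tail)
add("reporter_null", "mean_score", nul$mean_z)

pow <- study_reporter_power(seed = seed + 1000L)
add("reporter_power", "detection_rate", pow$power)

der <- study_dereplication_oracle(seed = seed + 2000L)
add("dereplication", "oracle_agreement", as.numeric(der$identical))
add("dereplication", "clusters_of_300", der$n_clusters)

cat_res <- study_catalog_recovery(seed = seed + 3000L)
add("catalog_overlap", "recovered_share", cat_res$recovered)
add("catalog_overlap", "planted_share", cat_res$planted)

et <- study_enterotype_recovery(seed = seed + 5000L)
add("enterotype", "success_fraction", et$frac_success)
add("enterotype", "mean_ari", mean(et$replicates$ari))

wn <- study_wilcoxon_null(seed = seed + 6000L)
add("wilcoxon_null", "rejection_at_0.05", wn$rejection_rate)

cons <- study_profile_conservation(seed = seed + 7000L)
add("profiling", "max_colsum_deviation", cons$max_deviation)

write_table(do.call(rbind, rows), file.path(RESULTS_DIR, "validation.tsv"),
            sort_rows = FALSE)
message("wrote ", file.path(RESULTS_DIR, "validation.tsv"))
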