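#!/usr/bin/env Rscript
# Gene richness: incidence-based rarefaction over samples (100 draws with
# replacement per sample count) and the bias-corrected Chao1 estimate of
# the total gene pool, with the fraction of it captured by the cohort.

source("analysis/00_config.R")

sd <- study_data()
counts <- sd$countsim$counts

curve <- rarefy(counts, repetitions = 100, seed = sd$cfg$seed)
write_table(as.data.frame(curve), file.path(RESULTS_DIR, "rarefaction.tsv"),
            sort_rows = FALSE)

inc <- incidence_summary(counts)
est <- chao1(inc)
cov <- coverage(inc$S_obs, est)
write_table(data.frame(S_obs = inc$S_obs, f1 = inc$f1, f2 = inc$f2,
                       chao1 = est, coverage = cov),
            file.path(RESULTS_DIR, "richness.tsv"))

message("observed genes: ", inc$S_obs, " (singletons ", inc$f1,
        ", doubletons ", inc$f2, ")")
message(sprintf("Chao1 estimate: %.1f genes -> %.2f%% of the estimated pool captured",
                est, cov))
message(sprintf("observed richness rises %.1f (1 sample) -> %.1f (all %d samples)",
                curve$s_obs_mean[1], curve$s_obs_mean[nrow(curve)],
                nrow(curve)))
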