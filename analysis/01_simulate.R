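#!/usr/bin/env Rscript
# Simulate the study cohort: two host gene catalogs sharing ~40% of their
# genes, and a 20-sample / two-diet-group community over host 1 with planted
# enterotype structure, diet-responsive genera and an enriched 8-KO module.
# Writes the raw inputs every later stage consumes.

source("analysis/00_config.R")

dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)
cfg <- study_config()
catalog <- simulate_catalog(cfg)
countsim <- simulate_counts(cfg, catalog)
paths <- write_simulation(catalog, countsim, DATA_DIR)

message("hosts: ", length(unique(catalog$genes$host)),
        ", genes/host: ", sum(catalog$genes$host == "host1"),
        ", planted cross-host pairs: ", nrow(catalog$truth$shared_pairs))
message("samples: ", nrow(countsim$metadata),
        " (", paste(table(countsim$metadata$group), collapse = " vs "), ")",
        ", enterotype sizes: ",
        paste(table(countsim$metadata$true_enterotype), collapse = "/"))
message("wrote: ", paste(basename(paths), collapse = ", "))
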