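# Shared study configuration, sourced by every numbered driver so all
# stages operate on the same simulated cohort.

suppressMessages(library(gutcatkit))

DATA_DIR <- "results/data"
RESULTS_DIR <- "results"

study_config <- function() {
  sim_config(
    seed = 20,
    genes_per_host = 500,
    pairwise_share = 0.4,
    reads_per_sample = 1e5,
    # denser annotation than the package default so the genus/KO stages
    # have material to work with at this desk scale
    annotation_rates = list(phylum = 0.9, genus = 0.9, species = 0.5,
                            ko = 0.9, phage = 0.15),
    enterotype_spec = list(k = 3,
                           drivers = c("Prevotella", "Lactobacillus",
                                       "Ruminococcus"),
                           boost = 10, concentration = 200),
    effect_features = list(
      list(type = "genus", id = "Parabacteroides", fold_change = 3,
           group = "G2"),
      list(type = "genus", id = "Succinatimonas", fold_change = 3,
           group = "G2"),
      list(type = "genus", id = "Ruminococcus", fold_change = 0.4,
           group = "G2"),
      list(type = "ko", id = sprintf("K%05d", 1:8), fold_change = 3,
           group = "G2")))
}

# rebuild the simulated objects (seeded, so identical across scripts)
study_data <- function(cfg = study_config()) {
  catalog <- simulate_catalog(cfg)
  countsim <- simulate_counts(cfg, catalog)
  genes1 <- catalog$genes[catalog$genes$host == "host1", ]
  list(cfg = cfg, catalog = catalog, countsim = countsim,
       lengths = setNames(genes1$length, genes1$gene_id),
       genus_map = setNames(genes1$genus, genes1$gene_id),
       ko_map = setNames(genes1$ko, genes1$gene_id),
       groups = setNames(countsim$metadata$group,
                         countsim$metadata$sample_id))
}
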