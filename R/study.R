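# Simulation-study drivers: each function sets up one planted-truth
# experiment, runs the corresponding pipeline stage, and measures recovery.
# The numbered scripts under analysis/, the test suite and
# scripts/acceptance.R all call these, so every reported number comes from
# one implementation.

default_drivers <- c("Prevotella", "Lactobacillus", "Ruminococcus")

#' Null calibration of the reporter score
#'
#' Scores randomly assembled pathways under a no-effect configuration:
#' per-KO adjusted p-values are uniform, so member Z-scores are standard
#' normal, and a well-calibrated reporter score should exceed the 1.6
#' detection threshold with the standard-normal tail probability
#' `1 - pnorm(1.6) ~ 0.0548`.
#'
#' @param seed Integer seed.
#' @param n_pathways Number of random pathways (default 200).
#' @param k_range Pathway sizes, drawn uniformly (default 5:25).
#' @param n_kos Size of the scored-KO universe (default 500).
#' @param n_random Background draws per distinct k (default 1000).
#' @param threshold Detection threshold (default 1.6).
#' @return List: `frac_above` (empirical tail fraction), `expected_tail`,
#'   `mean_z`, `sd_z`, `n_pathways`, and the per-pathway `scores`.
#' @export
study_reporter_null <- function(seed, n_pathways = 200L, k_range = 5:25,
                                n_kos = 500L, n_random = 1000L,
                                threshold = 1.6) {
  with_seed(seed, {
    kos <- sprintf("K%05d", seq_len(n_kos))
    z <- stats::setNames(reporter_z(stats::runif(n_kos)), kos)
    paths <- do.call(rbind, lapply(seq_len(n_pathways), function(i)
      data.frame(pathway = sprintf("rand%04d", i),
                 ko = sample(kos, sample(k_range, 1)),
                 stringsAsFactors = FALSE)))
    rr <- reporter_score(z, paths, n_random = n_random, seed = seed + 1L)
    list(frac_above = mean(rr$z_adjusted >= threshold),
         expected_tail = 1 - stats::pnorm(threshold),
         mean_z = mean(rr$z_adjusted), sd_z = stats::sd(rr$z_adjusted),
         n_pathways = nrow(rr), scores = rr)
  })
}

#' Power of the reporter score for a planted pathway
#'
#' Each replicate simulates a two-group community (10 vs 10 samples by
#' default) in which the genes of 8 planted KOs are enriched by a fold
#' change in group G2, runs the full KO chain (profiling, one-tailed
#' Wilcoxon with occurrence filter, BH, inverse-normal, reporter score), and
#' records whether the planted pathway reaches the detection threshold in
#' the correct direction.
#'
#' @param seed Integer seed (replicate r uses `seed + r`).
#' @param n_replicates Number of replicates (default 50).
#' @param fold_change Planted enrichment (default 3).
#' @param n_planted_kos Planted pathway size (default 8).
#' @param genes_per_host Catalog size per replicate (default 400).
#' @param reads_per_sample Read depth (default 5e4).
#' @param n_random,threshold Reporter parameters.
#' @return List: `power`, `z_adjusted` per replicate, `threshold`,
#'   `n_replicates`.
#' @export
study_reporter_power <- function(seed, n_replicates = 50L, fold_change = 3,
                                 n_planted_kos = 8L, genes_per_host = 400L,
                                 reads_per_sample = 5e4, n_random = 1000L,
                                 threshold = 1.6) {
  planted <- sprintf("K%05d", seq_len(n_planted_kos))
  paths <- rbind(data.frame(pathway = "planted", ko = planted,
                            stringsAsFactors = FALSE), toy_pathways())
  z <- vapply(seq_len(n_replicates), function(r) {
    cfg <- sim_config(seed = seed + r, n_hosts = 1,
                      pairwise_share = matrix(1, 1, 1),
                      genes_per_host = genes_per_host,
                      reads_per_sample = reads_per_sample,
                      annotation_rates = list(phylum = 1, genus = 1,
                                              species = 1, ko = 1,
                                              phage = 0.15),
                      effect_features = lapply(planted, function(k)
                        list(type = "ko", id = k, fold_change = fold_change,
                             group = "G2")))
    ct <- simulate_catalog(cfg)
    cs <- simulate_counts(cfg, ct)
    prof <- gene_abundance(cs$counts,
                           stats::setNames(ct$genes$length, ct$genes$gene_id))
    kop <- aggregate_profile(prof, stats::setNames(ct$genes$ko,
                                                   ct$genes$gene_id))
    kop <- kop[setdiff(rownames(kop), "__unassigned__"), , drop = FALSE]
    grp <- stats::setNames(cs$metadata$group, cs$metadata$sample_id)
    rr <- reporter_analysis(kop, grp, paths, n_random = n_random,
                            seed = seed + r)
    rr$z_adjusted[rr$pathway == "planted" & rr$direction == "G2"]
  }, numeric(1))
  list(power = mean(z >= threshold), z_adjusted = z, threshold = threshold,
       n_replicates = n_replicates)
}

#' Dereplication fast path against the brute-force greedy oracle
#'
#' Builds a redundant pool (progenitors plus variants spanning identity
#' targets below and above the 95% threshold), clusters it with the k-mer
#' prefilter enabled and with a full alignment for every candidate pair, and
#' checks that the two cluster sets are identical and that all cluster-set
#' invariants hold (membership thresholds; variants sit with their
#' progenitors where the target identity exceeds the threshold).
#'
#' @param seed Integer seed.
#' @param n_progenitors Progenitor count (default 100; with two variants
#'   each the pool holds 300 sequences).
#' @param target_identity Per-variant identity targets (default one below
#'   and one above the clustering threshold).
#' @param gene_length_range Sequence lengths (default 300-600 bp).
#' @return List: `identical` (fast path == oracle), `n_sequences`,
#'   `n_clusters`, `invariants_ok`, `truth_ok`.
#' @export
study_dereplication_oracle <- function(seed, n_progenitors = 100L,
                                       target_identity = c(0.90, 0.97),
                                       gene_length_range = c(300L, 600L)) {
  cfg <- sim_config(seed = seed, gene_length_range = gene_length_range,
                    redundancy_spec = list(
                      n_progenitors = n_progenitors,
                      variants_per_progenitor = length(target_identity),
                      target_identity = target_identity,
                      length_fraction = 1))
  rs <- simulate_redundant_sequences(cfg)
  fast <- dereplicate(rs$sequences)
  brute <- dereplicate(rs$sequences, prefilter = FALSE)
  mem <- fast$members[fast$members$member_id != fast$members$representative_id, ]
  invariants_ok <- all(mem$identity > 0.95) && all(mem$overlap > 0.90) &&
    !anyDuplicated(fast$members$member_id) &&
    setequal(fast$members$member_id, names(rs$sequences))
  rep_of <- stats::setNames(fast$members$representative_id,
                            fast$members$member_id)
  above <- rs$truth[rs$truth$target_identity > 0.95, ]
  below <- rs$truth[rs$truth$target_identity <= 0.90 &
                      rs$truth$seq_id != rs$truth$progenitor, ]
  truth_ok <- all(rep_of[above$seq_id] == above$progenitor) &&
    all(rep_of[below$seq_id] == below$seq_id)
  list(identical = identical(fast$members, brute$members),
       n_sequences = length(rs$sequences),
       n_clusters = length(fast$representatives),
       invariants_ok = invariants_ok, truth_ok = truth_ok)
}

#' Recovery of a planted cross-host sharing fraction
#'
#' Simulates two host catalogs with a planted pairwise sharing fraction and
#' measures the fraction recovered by [compare_catalogs()] under the
#' 95%/90% identity rule.
#'
#' @param seed Integer seed.
#' @param genes_per_host Catalog size (default 500).
#' @param share Planted sharing fraction (default 0.4).
#' @return List: `planted`, `recovered` (mean of the two directed
#'   fractions), `per_direction`, `n_genes`.
#' @export
study_catalog_recovery <- function(seed, genes_per_host = 500L, share = 0.4) {
  cfg <- sim_config(seed = seed, genes_per_host = genes_per_host,
                    pairwise_share = share)
  ct <- simulate_catalog(cfg)
  cats <- split(stats::setNames(ct$genes$sequence, ct$genes$gene_id),
                ct$genes$host)
  ov <- compare_catalogs(cats)
  list(planted = share, recovered = mean(ov$pairs$shared_fraction),
       per_direction = ov$pairs$shared_fraction,
       n_genes = genes_per_host)
}

#' Enterotype recovery across simulation replicates
#'
#' Each replicate simulates a community with three planted Dirichlet
#' clusters at the default separation, runs the genus-profile chain
#' (profiling, Jensen-Shannon distance, Calinski-Harabasz k selection, PAM,
#' driver identification), and records the chosen k, the adjusted Rand
#' index against the planted labels, and whether the planted driver genera
#' were recovered.
#'
#' @param seed Integer seed (replicate r uses `seed + r`).
#' @param n_replicates Number of replicates (default 20).
#' @param k_true Planted cluster count (default 3).
#' @param boost,concentration Separation parameters (defaults 10, 200).
#' @param genes_per_host,reads_per_sample Community size (defaults 300, 5e4).
#' @return List: `replicates` (data.frame: `k_chosen`, `ari`, `drivers_ok`),
#'   `frac_k_correct`, `frac_ari_high`, `frac_success` (both conditions).
#' @export
study_enterotype_recovery <- function(seed, n_replicates = 20L, k_true = 3L,
                                      boost = 10, concentration = 200,
                                      genes_per_host = 300L,
                                      reads_per_sample = 5e4) {
  drivers <- default_drivers[seq_len(k_true)]
  rows <- lapply(seq_len(n_replicates), function(r) {
    cfg <- sim_config(seed = seed + r, n_hosts = 1,
                      pairwise_share = matrix(1, 1, 1),
                      genes_per_host = genes_per_host,
                      reads_per_sample = reads_per_sample,
                      annotation_rates = list(phylum = 1, genus = 1,
                                              species = 1, ko = 1,
                                              phage = 0.15),
                      enterotype_spec = list(k = k_true, drivers = drivers,
                                             boost = boost,
                                             concentration = concentration))
    ct <- simulate_catalog(cfg)
    cs <- simulate_counts(cfg, ct)
    prof <- gene_abundance(cs$counts,
                           stats::setNames(ct$genes$length, ct$genes$gene_id))
    gp <- aggregate_profile(prof, stats::setNames(ct$genes$genus,
                                                  ct$genes$gene_id))
    et <- enterotype(gp)
    truth <- cs$truth$enterotype[names(et$labels)]
    data.frame(k_chosen = et$k,
               ari = adjusted_rand_index(et$labels, truth),
               drivers_ok = setequal(unname(et$drivers), drivers))
  })
  rep_df <- do.call(rbind, rows)
  list(replicates = rep_df,
       frac_k_correct = mean(rep_df$k_chosen == k_true),
       frac_ari_high = mean(rep_df$ari >= 0.9),
       frac_success = mean(rep_df$k_chosen == k_true & rep_df$ari >= 0.9),
       frac_drivers_ok = mean(rep_df$drivers_ok))
}

#' Null calibration of the per-feature Wilcoxon test
#'
#' @param seed Integer seed.
#' @param n_features Features tested (default 1000).
#' @param n_per_group Samples per group (default 10).
#' @param alpha Nominal level (default 0.05).
#' @return List: `rejection_rate`, `alpha`, `n_features`, `se` (binomial).
#' @export
study_wilcoxon_null <- function(seed, n_features = 1000L, n_per_group = 10L,
                                alpha = 0.05) {
  with_seed(seed, {
    g <- stats::setNames(rep(c("G1", "G2"), each = n_per_group),
                         sprintf("S%03d", seq_len(2 * n_per_group)))
    prof <- matrix(stats::rlnorm(n_features * 2 * n_per_group),
                   n_features, 2 * n_per_group,
                   dimnames = list(sprintf("f%04d", seq_len(n_features)),
                                   names(g)))
    res <- wilcoxon_features(prof, g)
    list(rejection_rate = mean(res$p < alpha), alpha = alpha,
         n_features = n_features,
         se = sqrt(alpha * (1 - alpha) / n_features))
  })
}

#' Column-mass conservation through profiling and aggregation
#'
#' Simulates random communities and measures the largest deviation of any
#' profile column sum from 1 across the gene, genus and KO levels.
#'
#' @param seed Integer seed.
#' @param n_communities Communities simulated (default 100).
#' @param n_genes,n_samples Community size per replicate.
#' @return List: `max_deviation`, `n_communities`.
#' @export
study_profile_conservation <- function(seed, n_communities = 100L,
                                       n_genes = 60L, n_samples = 6L) {
  with_seed(seed, {
    tax <- toy_taxonomy()
    worst <- 0
    for (i in seq_len(n_communities)) {
      counts <- matrix(stats::rpois(n_genes * n_samples, 3),
                       n_genes, n_samples,
                       dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                       sprintf("S%02d", seq_len(n_samples))))
      lens <- stats::setNames(sample(300:1500, n_genes, replace = TRUE),
                              rownames(counts))
      genus <- stats::setNames(
        sample(c(tax$genus, ""), n_genes, replace = TRUE), rownames(counts))
      ko <- stats::setNames(
        sample(c(toy_ko_universe()[1:50], "", ""), n_genes, replace = TRUE),
        rownames(counts))
      prof <- gene_abundance(counts, lens)
      dev <- max(abs(colSums(prof) - 1),
                 abs(colSums(aggregate_profile(prof, genus)) - 1),
                 abs(colSums(aggregate_profile(prof, ko)) - 1))
      worst <- max(worst, dev)
    }
    list(max_deviation = worst, n_communities = n_communities)
  })
}
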