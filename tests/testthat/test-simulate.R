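small_cfg <- function(...) {
  sim_config(seed = 42, genes_per_host = 120, reads_per_sample = 2e4,
             gene_length_range = c(300L, 900L), ...)
}

test_that("identical config and seed reproduce the simulation bit-for-bit", {
  cfg <- small_cfg()
  a <- simulate_catalog(cfg); b <- simulate_catalog(cfg)
  expect_identical(a, b)
  ca <- simulate_counts(cfg, a); cb <- simulate_counts(cfg, b)
  expect_identical(ca, cb)
  # and the caller's RNG stream is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_catalog(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("pairwise sharing plants verbatim copies at the configured rate", {
  cfg0 <- small_cfg(pairwise_share = matrix(c(1, 0, 0, 1), 2))
  ct0 <- simulate_catalog(cfg0)
  h1 <- ct0$genes$sequence[ct0$genes$host == "host1"]
  h2 <- ct0$genes$sequence[ct0$genes$host == "host2"]
  expect_length(intersect(h1, h2), 0)
  expect_equal(nrow(ct0$truth$shared_pairs), 0)

  cfg <- sim_config(seed = 7, genes_per_host = 500, pairwise_share = 0.4)
  ct <- simulate_catalog(cfg)
  h1 <- ct$genes$sequence[ct$genes$host == "host1"]
  h2 <- ct$genes$sequence[ct$genes$host == "host2"]
  frac <- mean(h1 %in% h2)
  # binomial 99% bounds around 0.4 at n = 500
  se <- sqrt(0.4 * 0.6 / 500)
  expect_gt(frac, 0.4 - 2.58 * se)
  expect_lt(frac, 0.4 + 2.58 * se)
})

test_that("share-matrix validation rejects inconsistent inputs", {
  expect_error(sim_config(pairwise_share = matrix(c(1, 0.2, 0.5, 1), 2)),
               "symmetric")
  expect_error(sim_config(pairwise_share = matrix(c(1, 2, 2, 1), 2)),
               "\\[0, 1\\]")
  expect_error(sim_config(n_hosts = 2,
                          pairwise_share = matrix(c(0.5, 0, 0, 1), 2)),
               "diagonal")
})

test_that("redundant variants hit their identity targets under the aligner", {
  cfg <- small_cfg(redundancy_spec = list(
    n_progenitors = 15, variants_per_progenitor = 2,
    target_identity = c(0.97, 1.0), length_fraction = c(1, 1)))
  rs <- simulate_redundant_sequences(cfg)
  expect_equal(nrow(rs$truth), 45)
  for (p in sprintf("p%04d", 1:5)) {
    # target 1.0, full length: variant equals progenitor
    expect_identical(rs$sequences[[paste0(p, "_v02")]], rs$sequences[[p]])
    al <- align_identity(rs$sequences[[p]], rs$sequences[[paste0(p, "_v01")]])
    expect_gte(al[["identity"]], 0.955)
    expect_lte(al[["identity"]], 0.985)
  }
  # truncation controls overlap
  cfg2 <- small_cfg(redundancy_spec = list(
    n_progenitors = 3, variants_per_progenitor = 1,
    target_identity = 1.0, length_fraction = 0.5))
  rs2 <- simulate_redundant_sequences(cfg2)
  al <- align_identity(rs2$sequences[["p0001"]], rs2$sequences[["p0001_v01"]])
  expect_equal(al[["identity"]], 1.0)
  expect_equal(al[["overlap"]], 1.0)  # denominator is the shorter (truncated)
  expect_equal(nchar(rs2$sequences[["p0001_v01"]]),
               round(0.5 * nchar(rs2$sequences[["p0001"]])))

  expect_error(simulate_redundant_sequences(small_cfg()), "redundancy_spec")
  expect_error(small_cfg(redundancy_spec = list(
    n_progenitors = 2, variants_per_progenitor = 1,
    target_identity = 0.4, length_fraction = 1)), "0.5")
})

test_that("zero variants per progenitor yields exactly the progenitor set", {
  cfg <- small_cfg(redundancy_spec = list(
    n_progenitors = 10, variants_per_progenitor = 0,
    target_identity = 0.97, length_fraction = 1))
  rs <- simulate_redundant_sequences(cfg)
  expect_length(rs$sequences, 10)
  expect_identical(rs$truth$seq_id, rs$truth$progenitor)
})

test_that("counts are multinomial with the configured total and degenerate cases hold", {
  cfg <- small_cfg()
  ct <- simulate_catalog(cfg)
  cs <- simulate_counts(cfg, ct)
  expect_true(all(colSums(cs$counts) == cfg$reads_per_sample))
  expect_equal(dim(cs$counts), c(120L, 20L))

  one <- ct$genes[ct$genes$host == "host1", ][1, ]
  one$true_genus <- "Prevotella"; one$true_ko <- "K00001"
  cs1 <- simulate_counts(cfg, one)
  expect_true(all(cs1$counts == cfg$reads_per_sample))

  bad <- small_cfg(); bad$reads_per_sample <- 0L
  expect_error(simulate_counts(bad, ct), "reads_per_sample")
})

test_that("a boosted driver genus dominates its cluster", {
  cfg <- sim_config(seed = 5, n_hosts = 1, pairwise_share = matrix(1, 1, 1),
                    genes_per_host = 300, reads_per_sample = 5e4,
                    annotation_rates = list(phylum = 1, genus = 1, species = 1,
                                            ko = 1, phage = 0.15),
                    enterotype_spec = list(
                      k = 3,
                      drivers = c("Prevotella", "Lactobacillus", "Ruminococcus"),
                      boost = 50, concentration = 200))
  ct <- simulate_catalog(cfg)
  cs <- simulate_counts(cfg, ct)
  genus <- ct$genes$genus
  for (cl in 1:3) {
    in_cl <- cs$metadata$true_enterotype == cl
    genus_mass <- rowsum(cs$truth$true_abundance[, in_cl, drop = FALSE], genus)
    top <- rownames(genus_mass)[which.max(rowMeans(genus_mass))]
    expect_identical(top, cfg$enterotype_spec$drivers[cl])
  }
})
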