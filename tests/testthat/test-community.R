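# small helper: simulate a genus profile with planted enterotype structure
enterotype_profile <- function(seed, k = 3, boost = 10, concentration = 200,
                               genes = 300, reads = 5e4) {
  drivers <- c("Prevotella", "Lactobacillus", "Ruminococcus")[seq_len(k)]
  cfg <- sim_config(seed = seed, n_hosts = 1, pairwise_share = matrix(1, 1, 1),
                    genes_per_host = genes, reads_per_sample = reads,
                    annotation_rates = list(phylum = 1, genus = 1, species = 1,
                                            ko = 1, phage = 0.15),
                    enterotype_spec = list(k = k, drivers = drivers,
                                           boost = boost,
                                           concentration = concentration))
  ct <- simulate_catalog(cfg)
  cs <- simulate_counts(cfg, ct)
  prof <- gene_abundance(cs$counts,
                         setNames(ct$genes$length, ct$genes$gene_id))
  list(genus = aggregate_profile(prof, setNames(ct$genes$genus,
                                                ct$genes$gene_id)),
       truth = cs$truth$enterotype, drivers = drivers)
}

test_that("Jensen-Shannon distance has its closed-form limits and symmetry", {
  p <- matrix(c(1, 0, 0, 1, 0.5, 0.5), 2, 3,
              dimnames = list(c("A", "B"), c("S1", "S2", "S3")))
  d <- jsd_distance(p, pseudocount = 1e-14)
  expect_equal(d["S1", "S1"], 0)
  # disjoint supports approach sqrt(ln 2)
  expect_equal(d["S1", "S2"], sqrt(log(2)), tolerance = 1e-5)
  expect_equal(d, t(d))
  expect_true(all(d >= 0) && all(d <= sqrt(log(2)) + 1e-12))
  expect_error(jsd_distance(-p), "nonnegative")
  expect_error(jsd_distance(p[, 1, drop = FALSE]), "two samples")
})

test_that("sqrt-JSD satisfies the triangle inequality on random triples", {
  set.seed(404)
  for (rep in 1:2000) {
    p <- matrix(rgamma(15, 0.5), 5, 3,
                dimnames = list(paste0("f", 1:5), c("P", "Q", "R")))
    p <- sweep(p, 2, colSums(p), "/")
    d <- jsd_distance(p)
    expect_lte(d["P", "R"], d["P", "Q"] + d["Q", "R"] + 1e-12)
  }
})

test_that("PAM clustering honors k, duplicates and the objective", {
  set.seed(9)
  prof <- matrix(rgamma(10 * 8, 1), 10, 8,
                 dimnames = list(paste0("f", 1:10), paste0("S", 1:8)))
  prof[, 5] <- prof[, 4]   # duplicate sample points
  prof <- sweep(prof, 2, colSums(prof), "/")
  d <- jsd_distance(prof)

  one <- pam_cluster(d, 1)
  expect_true(all(one$labels == 1))
  # the single medoid minimizes the summed distance (ties allowed)
  expect_equal(sum(d[, one$medoids]), min(colSums(d)))

  two <- pam_cluster(d, 3)
  expect_equal(unname(two$labels["S4"]), unname(two$labels["S5"]))
  expect_true(all(two$medoids %in% names(two$labels)))
  # medoids belong to the clusters they represent
  for (i in seq_along(two$medoids))
    expect_equal(unname(two$labels[two$medoids[i]]), i)
  expect_error(pam_cluster(d, 9), "exceeds")
})

test_that("select_k recovers the planted number of clusters", {
  ep3 <- enterotype_profile(seed = 301)
  d3 <- jsd_distance(ep3$genus)
  sel3 <- select_k(d3)
  expect_equal(sel3$k, 3)
  expect_equal(nrow(sel3$index), length(2:8))  # index reported for every k
  expect_gte(ari(sel3$labels, ep3$truth[names(sel3$labels)]), 0.99)

  ep2 <- enterotype_profile(seed = 302, k = 2)
  sel2 <- select_k(jsd_distance(ep2$genus))
  expect_equal(sel2$k, 2)

  expect_error(select_k(matrix(0, 4, 4)), "degenerate")
})

test_that("driver genera are recovered and ties break deterministically", {
  ep <- enterotype_profile(seed = 303, boost = 50)
  et <- enterotype(ep$genus)
  expect_setequal(unname(et$drivers), ep$drivers)
  # each cluster's driver matches the truth-label majority cluster's driver
  for (cl in seq_len(et$k)) {
    truth_cl <- as.integer(names(which.max(
      table(ep$truth[names(et$labels)[et$labels == cl]]))))
    expect_identical(unname(et$drivers[as.character(cl)]),
                     ep$drivers[truth_cl])
  }

  # single cluster: degenerate contrast = top overall mean
  d1 <- structure(list(labels = setNames(rep(1L, ncol(ep$genus)),
                                         colnames(ep$genus)),
                       medoids = colnames(ep$genus)[1], k = 1L),
                  class = "cluster_assignment")
  top <- rownames(ep$genus)[which.max(rowMeans(
    ep$genus[setdiff(rownames(ep$genus), "__unassigned__"), ]))]
  expect_identical(unname(driver_genera(d1, ep$genus)["1"]), top)

  # two identical clusters: documented tie-break (lexicographic genus order)
  flat <- matrix(0.25, 4, 4, dimnames = list(c("D", "C", "B", "A"),
                                             paste0("S", 1:4)))
  a2 <- structure(list(labels = setNames(c(1L, 1L, 2L, 2L), paste0("S", 1:4)),
                       medoids = c("S1", "S3"), k = 2L),
                  class = "cluster_assignment")
  expect_equal(unname(driver_genera(a2, flat)), c("A", "A"))
})

test_that("ordination embeds planted clusters separably and deterministically", {
  ep <- enterotype_profile(seed = 304)
  d <- jsd_distance(ep$genus)
  ord <- ordinate(d)
  expect_equal(ncol(ord$coordinates), 2)
  expect_lte(sum(ord$explained), 1)
  # duplicated samples map to identical coordinates
  prof2 <- cbind(ep$genus, DUP = ep$genus[, 1])
  colnames(prof2)[ncol(prof2)] <- "DUP"
  d2 <- jsd_distance(prof2)
  ord2 <- ordinate(d2)
  expect_equal(unname(ord2$coordinates["DUP", ]),
               unname(ord2$coordinates[colnames(ep$genus)[1], ]),
               tolerance = 1e-8)
  # mean silhouette of the truth labels in 2-D exceeds 0.5
  sil <- cluster::silhouette(ep$truth[rownames(ord$coordinates)],
                             dist(ord$coordinates))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  # sign convention: largest-magnitude coordinate positive on each axis
  for (j in 1:2)
    expect_gt(ord$coordinates[which.max(abs(ord$coordinates[, j])), j], 0)
})

test_that("hierarchical clustering is available behind a flag", {
  ep <- enterotype_profile(seed = 305, boost = 50)
  et <- enterotype(ep$genus, method = "hclust")
  expect_equal(et$k, 3)
  expect_gte(ari(et$labels, ep$truth[names(et$labels)]), 0.99)
})
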