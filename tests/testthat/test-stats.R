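two_group <- function(n = 10) setNames(rep(c("G1", "G2"), each = n),
                                       sprintf("S%03d", seq_len(2 * n)))

test_that("wilcoxon p-values hit the exact-enumeration benchmarks", {
  g <- two_group(10)
  # the two groups hold the same values: two-tailed p = 1
  prof <- matrix(c(1:10, 1:10), 1, 20, dimnames = list("f", names(g)))
  res <- wilcoxon_features(prof, g)
  expect_equal(res$p, 1)
  expect_equal(res$direction, "none")

  # complete separation: p = 2 / C(20, 10)
  sep <- matrix(c(1:10, 101:110), 1, 20, dimnames = list("f", names(g)))
  res <- wilcoxon_features(sep, g)
  expect_equal(res$p, 2 / choose(20, 10))
  expect_equal(res$direction, "G2")

  # one-sided alternatives refer to the first group
  res_g <- wilcoxon_features(sep, g, alternative = "greater")
  res_l <- wilcoxon_features(sep, g, alternative = "less")
  expect_equal(res_l$p, 1 / choose(20, 10))
  expect_gt(res_g$p, 0.999)

  expect_error(wilcoxon_features(sep, setNames(rep("G1", 20), names(g))),
               "two groups")
  expect_error(wilcoxon_features(sep[, 1:11, drop = FALSE],
                                 setNames(c(rep("G1", 10), "G2"),
                                          names(g)[1:11])),
               "at least two")
})

test_that("the occurrence filter excludes sparse features from testing", {
  g <- two_group(5)
  prof <- rbind(sparse = c(1, 0, 0, 0, 0, 2, 0, 0, 0, 0),
                dense = rexp(10) + 1)
  colnames(prof) <- names(g)
  res <- wilcoxon_features(prof, g, min_nonzero = 6)
  expect_true(res$excluded[res$feature == "sparse"])
  expect_true(is.na(res$p[res$feature == "sparse"]))
  expect_false(res$excluded[res$feature == "dense"])
})

test_that("null rejection rate is calibrated at alpha = 0.05", {
  set.seed(71)
  g <- two_group(10)
  prof <- matrix(rlnorm(1000 * 20), 1000, 20,
                 dimnames = list(paste0("f", 1:1000), names(g)))
  res <- wilcoxon_features(prof, g)
  rate <- mean(res$p < 0.05)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("exact and approximate wilcoxon paths agree on tie-free 8 vs 8", {
  set.seed(72)
  g <- two_group(8)
  prof <- matrix(rnorm(200 * 16), 200, 16,
                 dimnames = list(paste0("f", 1:200), names(g)))
  pe <- wilcoxon_features(prof, g, exact = TRUE)$p
  pa <- wilcoxon_features(prof, g, exact = FALSE)$p
  # the approximation is accurate in the body of the distribution and
  # conservative (never anti-conservative) in the tail it cannot track
  body <- pe >= 0.05
  expect_true(all(abs(pe - pa)[body] / pe[body] < 0.10))
  expect_true(all(pa[!body] >= pe[!body]))
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(73)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-12))
    # same order under p and q
    expect_equal(order(q[order(p)]), seq_along(p))
  }
})

test_that("reporter_z is the inverse-normal transform with clamping", {
  expect_equal(reporter_z(0.5), 0)
  expect_equal(reporter_z(0.05), qnorm(0.95), tolerance = 1e-10)
  expect_equal(reporter_z(0.05), 1.6449, tolerance = 1e-4)
  expect_equal(reporter_z(1), qnorm(1e-10))     # clamped, finite
  expect_equal(reporter_z(0), qnorm(1 - 1e-10))
  expect_true(all(is.finite(reporter_z(c(0, 1e-20, 1)))))
  expect_error(reporter_z(1.5), "\\[0, 1\\]")
})

test_that("reporter aggregation follows the 1/sqrt(k) rule", {
  z <- setNames(rnorm(50), toy_ko_universe()[1:50])
  z[["K00001"]] <- 1.7
  paths <- data.frame(pathway = "p1", ko = "K00001")
  rr <- reporter_score(z, paths, n_random = 100, seed = 1)
  expect_equal(rr$z_pathway, 1.7)   # k = 1: aggregate equals the member Z
  expect_equal(rr$k, 1L)
  expect_equal(rr$z_adjusted, (1.7 - rr$mu_k) / rr$sigma_k)

  z0 <- 0.9
  z[c("K00002", "K00003", "K00004", "K00005")] <- z0
  p4 <- data.frame(pathway = "p4", ko = c("K00002", "K00003", "K00004", "K00005"))
  rr4 <- reporter_score(z, p4, n_random = 100, seed = 1)
  expect_equal(rr4$z_pathway, 2 * z0)   # (1/sqrt(4)) * 4 * z0

  # identical-k pathways share one background
  both <- reporter_score(z, data.frame(
    pathway = rep(c("a", "b"), each = 4),
    ko = toy_ko_universe()[1:8]), n_random = 200, seed = 5)
  expect_equal(both$mu_k[1], both$mu_k[2])
  expect_equal(both$sigma_k[1], both$sigma_k[2])
  # same seed, same background
  again <- reporter_score(z, p4, n_random = 100, seed = 1)
  expect_identical(rr4, again)

  expect_error(reporter_score(z[1:3], data.frame(pathway = "p", ko = names(z)[1:3] )[0, ]),
               "no pathway")
  expect_error(reporter_score(setNames(rep(1, 30), toy_ko_universe()[1:30]),
                              data.frame(pathway = "p",
                                         ko = toy_ko_universe()[1:5]),
                              n_random = 50),
               "sigma_k = 0")
})

test_that("significant_pathways includes the threshold boundary", {
  rr <- data.frame(pathway = c("a", "b", "c"), k = 5L,
                   z_pathway = 1, mu_k = 0, sigma_k = 1,
                   z_adjusted = c(1.6, 1.59, 2.2))
  sig <- significant_pathways(rr, 1.6)
  expect_setequal(sig$pathway, c("a", "c"))
})

test_that("marker selection applies the documented threshold rule", {
  empty <- data.frame(feature = character(), p = numeric(), q = numeric(),
                      direction = character())
  expect_equal(nrow(select_markers(empty, 0.01)), 0)

  set.seed(74)
  g <- two_group(10)
  prof <- matrix(rlnorm(500 * 20), 500, 20,
                 dimnames = list(paste0("f", 1:500), names(g)))
  res <- differential_abundance(prof, g)
  mk <- select_markers(res, 0.05)
  # null configuration: marker count within binomial bounds of 0.05 * 500
  expect_lt(abs(nrow(mk) - 25), 3 * sqrt(500 * 0.05 * 0.95) + 1)
  expect_false(attr(mk, "use_adjusted"))
  expect_equal(attr(mk, "p_threshold"), 0.05)

  mq <- select_markers(res, 0.05, use_adjusted = TRUE)
  expect_lte(nrow(mq), nrow(mk))
})

test_that("planted fold-change markers are recovered with high power", {
  set.seed(75)
  hits <- 0; total <- 0
  for (rep in 1:10) {
    g <- two_group(10)
    prof <- matrix(rlnorm(60 * 20, sdlog = 0.5), 60, 20,
                   dimnames = list(paste0("f", 1:60), names(g)))
    planted <- paste0("f", 1:10)
    prof[planted, g == "G2"] <- prof[planted, g == "G2"] * 4
    res <- differential_abundance(prof, g)
    mk <- select_markers(res, 0.01)
    hits <- hits + sum(planted %in% mk$feature)
    total <- total + length(planted)
    expect_true(all(mk$direction[mk$feature %in% planted] == "G2"))
  }
  expect_gte(hits / total, 0.8)
})
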