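test_that("align_identity handles self-alignment, substrings and substitutions", {
  set.seed(101)
  a <- random_seq(300)
  expect_equal(align_identity(a, a), c(identity = 1, overlap = 1))

  b <- substr(a, 1, 200)   # exact prefix: denominator is the shorter
  expect_equal(align_identity(a, b), c(identity = 1, overlap = 1))
  expect_equal(align_identity(b, a), align_identity(a, b))  # symmetric

  m <- mutate_seq(a, 30)
  al <- align_identity(a, m)
  expect_lt(abs(al[["identity"]] - 0.90), 0.01)
  orc <- oracle_align(a, m)
  expect_lt(abs(al[["identity"]] - orc[["identity"]]), 0.01)

  expect_error(align_identity("ACGN", "ACGT"), "non-ACGT")
  expect_error(align_identity("", "ACGT"), "non-empty")
})

test_that("align_identity agrees with the dynamic-programming oracle", {
  set.seed(202)
  for (i in 1:12) {
    L <- sample(80:140, 1)
    a <- random_seq(L)
    b <- mutate_seq(a, sample(0:round(0.15 * L), 1))
    if (i %% 3 == 0) b <- substr(b, 1, round(0.7 * nchar(b)))  # truncation
    impl <- align_identity(a, b)
    orc <- oracle_align(a, b)
    expect_lt(abs(impl[["identity"]] - orc[["identity"]]), 0.015)
    expect_lt(abs(impl[["overlap"]] - orc[["overlap"]]), 0.02)
  }
})

test_that("dereplicate clusters by the identity/overlap rule", {
  set.seed(11)
  a <- random_seq(300)
  # two identical sequences collapse
  cs <- dereplicate(c(g1 = a, g2 = a))
  expect_length(cs$representatives, 1)
  expect_equal(sort(cs$members$member_id), c("g1", "g2"))

  # 80% identity stays apart (oracle confirms the pair is below threshold)
  b <- mutate_seq(a, 60)
  expect_lt(oracle_align(a, b)[["identity"]], 0.95)
  cs <- dereplicate(c(g1 = a, g2 = b))
  expect_length(cs$representatives, 2)

  # shared 100-bp block but overlap 0.5 < 0.9 despite local identity 1
  long <- random_seq(300)
  short <- paste0(random_seq(50), substr(long, 101, 200), random_seq(50))
  # local alignment may extend a few chance-matching columns past the block
  orc <- oracle_align(long, short)
  expect_gte(orc[["identity"]], 0.95)
  expect_lt(orc[["overlap"]], 0.6)
  cs <- dereplicate(c(gl = long, gs = short))
  expect_length(cs$representatives, 2)

  expect_error(dereplicate(c(g1 = a), identity_threshold = 1.2), "thresholds")
  expect_error(dereplicate(character(0)), "no sequences")
})

test_that("cluster-set invariants hold on a mixed redundant pool", {
  cfg <- sim_config(seed = 31, gene_length_range = c(300L, 600L),
                    redundancy_spec = list(
                      n_progenitors = 40, variants_per_progenitor = 2,
                      target_identity = c(0.97, 0.99),
                      length_fraction = c(1, 0.95)))
  rs <- simulate_redundant_sequences(cfg)
  cs <- dereplicate(rs$sequences)
  # every input in exactly one cluster
  expect_setequal(cs$members$member_id, names(rs$sequences))
  expect_false(anyDuplicated(cs$members$member_id) > 0)
  # member thresholds hold
  mem <- cs$members[cs$members$member_id != cs$members$representative_id, ]
  expect_true(all(mem$identity > 0.95))
  expect_true(all(mem$overlap > 0.90))
  # representatives pairwise fail the criterion
  reps <- rs$sequences[cs$representatives]
  for (i in seq_along(reps)[-1]) {
    hits <- vapply(seq_len(i - 1), function(j) {
      al <- align_identity(reps[[j]], reps[[i]])
      al[["identity"]] > 0.95 && al[["overlap"]] > 0.90
    }, logical(1))
    expect_false(any(hits))
  }
  # truth recovery: variants sit with their progenitors
  rep_of <- setNames(cs$members$representative_id, cs$members$member_id)
  expect_true(all(rep_of[rs$truth$seq_id] == rs$truth$progenitor))
})

test_that("dereplication matches the hand-written greedy DP oracle on a small pool", {
  cfg <- sim_config(seed = 47, gene_length_range = c(80L, 120L),
                    redundancy_spec = list(
                      n_progenitors = 12, variants_per_progenitor = 1,
                      target_identity = c(0.92, 0.97), length_fraction = 1))
  rs <- simulate_redundant_sequences(cfg)
  got <- dereplicate(rs$sequences)$members
  want <- oracle_dereplicate(rs$sequences)
  expect_equal(got[, c("member_id", "representative_id")], want)
})

test_that("raising the identity threshold never decreases the cluster count", {
  cfg <- sim_config(seed = 77, gene_length_range = c(300L, 500L),
                    redundancy_spec = list(
                      n_progenitors = 25, variants_per_progenitor = 2,
                      target_identity = c(0.94, 0.975), length_fraction = 1))
  rs <- simulate_redundant_sequences(cfg)
  ks <- vapply(c(0.90, 0.95, 0.97, 0.99),
               function(thr) length(dereplicate(rs$sequences,
                                                identity_threshold = thr)$representatives),
               numeric(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("compare_catalogs recovers planted sharing and degenerate cases", {
  set.seed(55)
  A <- setNames(vapply(1:30, function(i) random_seq(400), ""), paste0("a", 1:30))
  ov <- compare_catalogs(list(A = A, A2 = A))
  expect_true(all(ov$pairs$shared_fraction == 1))

  B <- setNames(vapply(1:30, function(i) random_seq(500), ""), paste0("b", 1:30))
  ov <- compare_catalogs(list(A = A, B = B))
  expect_true(all(ov$pairs$shared_fraction == 0))
  expect_true(all(ov$patterns$pattern == ""))

  expect_error(compare_catalogs(list(A = A)), "two catalogs")
  expect_error(compare_catalogs(list(A = A, B = character(0))), "empty")
})

test_that("the min_partners flag implements the literal two-or-more rule", {
  set.seed(66)
  a <- random_seq(400)
  A <- c(q1 = a)
  B <- c(t1 = a, t2 = mutate_seq(a, 4), t3 = random_seq(400))
  one <- compare_catalogs(list(A = A, B = B), min_partners = 1L)
  two <- compare_catalogs(list(A = A, B = B), min_partners = 2L)
  three <- compare_catalogs(list(A = A, B = B), min_partners = 3L)
  expect_equal(one$pairs$shared[one$pairs$query == "A"], 1L)
  expect_equal(two$pairs$shared[two$pairs$query == "A"], 1L)   # t1 and t2 match
  expect_equal(three$pairs$shared[three$pairs$query == "A"], 0L)
})

test_that("subsample_catalog draws are seeded, uniform and size-checked", {
  ids <- paste0("g", 1:500)
  full <- subsample_catalog(ids, n = 500, repeats = 3, seed = 1)
  for (d in full) expect_setequal(d, ids)
  expect_identical(subsample_catalog(ids, 100, 5, seed = 9),
                   subsample_catalog(ids, 100, 5, seed = 9))
  expect_error(subsample_catalog(ids, 501, 1, 1), "exceeds")

  # mean pairwise Jaccard of half-size draws near the uniform expectation:
  # E|A∩B| = n^2/N, so J ≈ (n/N) / (2 - n/N) = 1/3
  draws <- subsample_catalog(ids, 250, 10, seed = 4)
  jac <- c()
  for (i in 1:9) for (j in (i + 1):10) {
    inter <- length(intersect(draws[[i]], draws[[j]]))
    jac <- c(jac, inter / (500 - inter))
  }
  # |A∩B| ~ mean 125, sd ~ sqrt(500 * .25 * .75) ≈ 9.7 -> J sd ≈ 0.023/pair
  expect_lt(abs(mean(jac) - 1 / 3), 4 * 0.023 / sqrt(45) + 0.01)
})
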