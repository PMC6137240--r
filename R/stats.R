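#' Per-feature Wilcoxon rank-sum tests between two groups
#'
#' Runs a rank-sum test on every feature row. Mid-ranks handle ties; the
#' exact null distribution is used when both groups have at most 12 samples
#' and the feature is tie-free, otherwise the normal approximation with tie
#' correction and continuity correction. Features nonzero in fewer than
#' `min_nonzero` samples (across the whole cohort) are marked excluded and
#' not tested — the occurrence filter applied to KO-level reporter input.
#'
#' @param profile Abundance matrix (features x samples).
#' @param groups Named character vector sample -> group; exactly two groups,
#'   each with >= 2 samples.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`;
#'   one-sided alternatives refer to the lexicographically first group.
#' @param min_nonzero Occurrence filter: minimum number of samples with
#'   nonzero abundance (0 disables; 6 encodes "occurred in more than five
#'   samples").
#' @param exact `NULL` (default) chooses the exact null for tie-free groups
#'   of at most 12; `TRUE`/`FALSE` force one path.
#' @return data.frame: `feature`, `p` (NA when excluded), `direction` (group
#'   with the higher median, `"none"` on ties), group means, `excluded`.
#' @export
wilcoxon_features <- function(profile, groups,
                              alternative = c("two.sided", "greater", "less"),
                              min_nonzero = 0L, exact = NULL) {
  alternative <- match.arg(alternative)
  groups <- groups[colnames(profile)]
  if (anyNA(groups)) stop("groups must cover every profile sample")
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly two groups are required")
  if (any(table(groups) < 2L)) stop("each group needs at least two samples")
  ia <- which(groups == lev[1]); ib <- which(groups == lev[2])

  res <- lapply(rownames(profile), function(f) {
    v <- profile[f, ]
    x <- v[ia]; y <- v[ib]
    excluded <- sum(v > 0) < min_nonzero
    p <- NA_real_
    if (!excluded) {
      use_exact <- if (is.null(exact))
        length(x) <= 12L && length(y) <= 12L && !anyDuplicated(v)
      else exact
      p <- suppressWarnings(stats::wilcox.test(
        x, y, alternative = alternative, exact = use_exact,
        correct = TRUE))$p.value
    }
    dm <- stats::median(x) - stats::median(y)
    data.frame(feature = f, p = p,
               direction = if (dm > 0) lev[1] else if (dm < 0) lev[2] else "none",
               mean_a = mean(x), mean_b = mean(y), excluded = excluded,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", lev[1])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", lev[2])
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1. Input is validated to lie in \[0, 1\].
#'
#' @param p Numeric vector of raw p-values (NAs propagate).
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential abundance between two groups
#'
#' [wilcoxon_features()] followed by [bh_adjust()] over the tested (non
#' excluded) features.
#'
#' @inheritParams wilcoxon_features
#' @return The [wilcoxon_features()] data.frame with a `q` column added.
#' @export
differential_abundance <- function(profile, groups,
                                   alternative = c("two.sided", "greater", "less"),
                                   min_nonzero = 0L) {
  res <- wilcoxon_features(profile, groups, alternative, min_nonzero)
  res$q <- bh_adjust(res$p)
  res
}

#' Inverse-normal transform of an adjusted p-value
#'
#' `Z = qnorm(1 - q)` after clamping `q` into `[clamp, 1 - clamp]` so the
#' transform stays finite.
#'
#' @param q Adjusted p-values in \[0, 1\].
#' @param clamp Clamping constant (default 1e-10).
#' @return Z-scores.
#' @export
reporter_z <- function(q, clamp = 1e-10) {
  if (any(!is.na(q) & (q < 0 | q > 1))) stop("q-values must lie in [0, 1]")
  stats::qnorm(1 - pmin(pmax(q, clamp), 1 - clamp))
}

#' Reporter score of pathways from per-KO Z-scores
#'
#' Aggregates member-KO Z-scores per pathway as
#' `Z_pathway = (1 / sqrt(k)) * sum(Z_KO)`, then standardizes against a
#' random-set background: `n_random` without-replacement draws of `k` KOs
#' from the universe of scored KOs, aggregated identically, give `mu_k` and
#' `sigma_k`, and `Z_adjusted = (Z_pathway - mu_k) / sigma_k` is the reporter
#' score. Pathways with the same `k` share one seeded background set, so
#' their scores are directly comparable.
#'
#' @param z_by_ko Named numeric vector KO -> Z. Its names are the KO
#'   universe the background is drawn from.
#' @param pathways data.frame with columns `pathway` and `ko`, or a named
#'   list of KO character vectors.
#' @param n_random Background draws per distinct `k` (default 1000).
#' @param seed Integer seed for the background draws.
#' @return data.frame of class `reporter_result`: `pathway`, `k`,
#'   `z_pathway`, `mu_k`, `sigma_k`, `z_adjusted`.
#' @export
reporter_score <- function(z_by_ko, pathways, n_random = 1000L, seed = 1L) {
  if (is.data.frame(pathways))
    pathways <- split(pathways$ko, pathways$pathway)
  universe <- names(z_by_ko)
  if (is.null(universe) || !length(universe)) stop("z_by_ko must be named")
  members <- lapply(pathways, function(k) intersect(unique(k), universe))
  ks <- lengths(members)
  if (any(ks == 0L)) {
    message("dropping ", sum(ks == 0L), " pathway(s) with no scored KOs")
    members <- members[ks > 0L]; ks <- ks[ks > 0L]
  }
  if (!length(members)) stop("no pathway has scored member KOs")
  if (max(ks) > length(universe))
    stop("KO universe (", length(universe), ") smaller than the largest pathway")

  z_path <- vapply(members, function(m) sum(z_by_ko[m]) / sqrt(length(m)),
                   numeric(1))
  bg <- with_seed(seed, {
    lapply(stats::setNames(nm = sort(unique(ks))), function(k) {
      draws <- vapply(seq_len(n_random),
                      function(i) sum(sample(z_by_ko, k)) / sqrt(k),
                      numeric(1))
      c(mu = mean(draws), sigma = stats::sd(draws))
    })
  })
  mu <- vapply(as.character(ks), function(k) bg[[k]]["mu"], numeric(1))
  sigma <- vapply(as.character(ks), function(k) bg[[k]]["sigma"], numeric(1))
  if (any(sigma == 0))
    stop("degenerate background (sigma_k = 0) for k = ",
         paste(unique(ks[sigma == 0]), collapse = ", "),
         "; are all KO Z-scores identical?")
  out <- data.frame(pathway = names(members), k = as.integer(ks),
                    z_pathway = unname(z_path), mu_k = unname(mu),
                    sigma_k = unname(sigma),
                    z_adjusted = unname((z_path - mu) / sigma),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("reporter_result", class(out))
  out
}

#' Pathways passing the reporter-score threshold
#'
#' @param results A `reporter_result` data.frame (possibly with a
#'   `direction` column from [reporter_analysis()]).
#' @param threshold Detection threshold on `z_adjusted` (default 1.6, the
#'   90%-confidence normal quantile rounded down); the comparison is
#'   inclusive (>=).
#' @return The filtered rows.
#' @export
significant_pathways <- function(results, threshold = 1.6) {
  results[results$z_adjusted >= threshold, , drop = FALSE]
}

#' Directional reporter-score analysis of a KO profile
#'
#' Runs the full enrichment chain in both directions: one-tailed Wilcoxon
#' per KO (occurrence filter: nonzero in more than five samples), BH
#' adjustment, inverse-normal transform, and [reporter_score()], once for
#' KOs higher in each group. Both background sets use the same seed so
#' directions are comparable.
#'
#' @param ko_profile KO relative-abundance matrix (KOs x samples).
#' @param groups Named character vector sample -> group (two groups).
#' @param pathways Pathway definitions as in [reporter_score()].
#' @param n_random,seed Background parameters.
#' @param min_nonzero Occurrence filter (default 6).
#' @param clamp Passed to [reporter_z()].
#' @return A `reporter_result` data.frame with a `direction` column naming
#'   the group a positive score is enriched in.
#' @export
reporter_analysis <- function(ko_profile, groups, pathways,
                              n_random = 1000L, seed = 1L,
                              min_nonzero = 6L, clamp = 1e-10) {
  lev <- sort(unique(groups[colnames(ko_profile)]))
  if (length(lev) != 2L) stop("exactly two groups are required")
  res <- list()
  for (alt in c("greater", "less")) {
    wt <- wilcoxon_features(ko_profile, groups, alternative = alt,
                            min_nonzero = min_nonzero)
    tested <- wt[!wt$excluded, ]
    q <- bh_adjust(tested$p)
    z <- stats::setNames(reporter_z(q, clamp), tested$feature)
    rr <- reporter_score(z, pathways, n_random = n_random, seed = seed)
    rr$direction <- if (alt == "greater") lev[1] else lev[2]
    res[[alt]] <- rr
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("reporter_result", class(out))
  out
}

#' Select differentially abundant marker features
#'
#' Filters a [differential_abundance()] result at a p-value threshold and
#' labels each marker with its enriched group. Whether the raw or the
#' BH-adjusted p-value is thresholded is an explicit argument, recorded on
#' the output.
#'
#' @param results data.frame from [differential_abundance()].
#' @param p_threshold Strict upper bound on the (raw or adjusted) p-value.
#' @param use_adjusted Threshold `q` instead of raw `p` (default FALSE).
#' @return The marker rows, with attributes `p_threshold` and
#'   `use_adjusted` recording the selection rule.
#' @export
select_markers <- function(results, p_threshold, use_adjusted = FALSE) {
  val <- if (use_adjusted) results$q else results$p
  keep <- !is.na(val) & val < p_threshold
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "p_threshold") <- p_threshold
  attr(out, "use_adjusted") <- use_adjusted
  out
}
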