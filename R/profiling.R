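#' Length-normalized relative gene abundance
#'
#' Per sample, each gene's count is divided by its length in bp and the
#' length-normalized values are rescaled to sum to one: with count `x_i` and
#' length `L_i`, `b_i = x_i / L_i` and `a_i = b_i / sum_j b_j`. This inverts
#' length-proportional read sampling, so `a_i` estimates the gene's relative
#' copy abundance rather than its share of reads.
#'
#' @param counts Integer matrix (genes x samples) with dimnames, or a
#'   data.frame whose first column is `gene_id`.
#' @param lengths Named numeric vector of gene lengths (bp), covering every
#'   gene in `counts`.
#' @return Numeric matrix (genes x samples) of relative abundances; every
#'   column sums to 1.
#' @export
gene_abundance <- function(counts, lengths) {
  if (is.data.frame(counts)) {
    rn <- counts[[1L]]
    counts <- as.matrix(counts[, -1L, drop = FALSE])
    rownames(counts) <- rn
  }
  genes <- rownames(counts)
  if (is.null(genes)) stop("counts must carry gene ids as rownames")
  miss <- setdiff(genes, names(lengths))
  if (length(miss)) stop("missing length for gene(s): ",
                         paste(utils::head(miss, 3), collapse = ", "))
  L <- lengths[genes]
  if (any(L <= 0)) stop("gene lengths must be positive")
  zero <- colSums(counts) == 0
  if (any(zero)) stop("sample(s) with zero mapped reads: ",
                      paste(colnames(counts)[zero], collapse = ", "))
  b <- counts / L
  sweep(b, 2L, colSums(b), "/")
}

#' Aggregate a gene profile to genus or KO level
#'
#' Sums member-gene relative abundances per label. Genes with no label
#' (missing, `NA` or empty string in the mapping) are pooled under the
#' reserved `__unassigned__` label so columns still sum to one — the profile
#' stays compositional.
#'
#' @param profile Relative-abundance matrix from [gene_abundance()].
#' @param mapping Named character vector gene -> label (genus, KO, ...);
#'   may be partial.
#' @return Relative-abundance matrix (labels x samples), labels sorted with
#'   `__unassigned__` last.
#' @export
aggregate_profile <- function(profile, mapping) {
  lab <- mapping[rownames(profile)]
  lab[is.na(lab) | !nzchar(lab)] <- "__unassigned__"
  agg <- rowsum(profile, group = as.character(lab))
  ord <- order(rownames(agg) == "__unassigned__", rownames(agg))
  agg[ord, , drop = FALSE]
}

#' Core features of a host: present in every sample
#'
#' A feature (genus, gene, KO) is core when its abundance is strictly
#' positive in 100% of the host's samples; no minimum-abundance threshold is
#' applied.
#'
#' @param profile Relative-abundance matrix (features x samples).
#' @param host Optional host name recorded in the result.
#' @return A list of class `core_set`: `host`, `features` (data.frame:
#'   `feature`, `mean_abundance`, sorted by decreasing mean).
#' @export
core_features <- function(profile, host = NA_character_) {
  if (ncol(profile) < 1L) stop("profile must contain at least one sample")
  keep <- rownames(profile)[apply(profile > 0, 1L, all)]
  keep <- setdiff(keep, "__unassigned__")
  mu <- rowMeans(profile[keep, , drop = FALSE])
  ord <- order(-mu, keep)
  structure(list(host = host,
                 features = data.frame(feature = keep[ord],
                                       mean_abundance = unname(mu[ord]),
                                       stringsAsFactors = FALSE)),
            class = "core_set")
}

#' Features shared among each host's top-n core features
#'
#' Takes each host's `n` most abundant core features (by mean abundance, ties
#' broken lexicographically) and intersects across hosts.
#'
#' @param cores List (>= 2) of `core_set` objects.
#' @param n Top-n cutoff per host (default 20). A host with fewer core
#'   features contributes its full core set, with a warning.
#' @return Character vector of shared feature ids, sorted.
#' @export
shared_top_n <- function(cores, n = 20L) {
  if (length(cores) < 2L) stop("need core sets from at least two hosts")
  tops <- lapply(cores, function(cs) {
    f <- cs$features
    if (nrow(f) < n)
      warning("host '", cs$host, "' has only ", nrow(f),
              " core features (< n = ", n, "); using all of them")
    utils::head(f$feature, n)
  })
  sort(Reduce(intersect, tops))
}
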