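#' Jensen-Shannon distance matrix of sample profiles
#'
#' The root Jensen-Shannon divergence with natural-log entropy:
#' `d(P,Q) = sqrt( H((P+Q)/2) - (H(P)+H(Q))/2 )`, a metric bounded by
#' `sqrt(ln 2)`. The reserved `__unassigned__` row is dropped and columns
#' renormalized first; a pseudocount is added (and columns renormalized
#' again) so zero components do not produce infinite logs.
#'
#' @param profiles Relative-abundance matrix (features x samples), >= 2
#'   samples.
#' @param pseudocount Mass added to every component before renormalizing.
#' @return A symmetric `dist`-compatible matrix with zero diagonal and sample
#'   ids as dimnames.
#' @export
jsd_distance <- function(profiles, pseudocount = 1e-9) {
  if (ncol(profiles) < 2L) stop("need at least two samples")
  if (any(profiles < 0)) stop("abundances must be nonnegative")
  p <- profiles[setdiff(rownames(profiles), "__unassigned__"), , drop = FALSE]
  p <- sweep(p, 2L, colSums(p), "/")
  p <- p + pseudocount
  p <- sweep(p, 2L, colSums(p), "/")
  H <- function(x) -sum(x * log(x))
  n <- ncol(p)
  h <- apply(p, 2L, H)
  d <- matrix(0, n, n, dimnames = list(colnames(p), colnames(p)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    m <- (p[, i] + p[, j]) / 2
    v <- H(m) - (h[i] + h[j]) / 2
    d[i, j] <- d[j, i] <- sqrt(max(v, 0))
  }
  d
}

#' Partitioning-around-medoids clustering of a distance matrix
#'
#' k-medoids via the BUILD + SWAP algorithm (swaps applied until none
#' improves the total distance-to-medoid objective); deterministic for a
#' given distance matrix.
#'
#' @param dist Symmetric distance matrix with sample dimnames.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Accepted for interface uniformity; PAM is deterministic.
#' @return A list of class `cluster_assignment`: `labels` (named integer
#'   vector in 1..k), `medoids` (sample ids), `k`, and `objective`.
#' @export
pam_cluster <- function(dist, k, seed = 1L) {
  n <- nrow(dist)
  if (k > n) stop("k exceeds the number of samples")
  if (k < 1L) stop("k must be at least 1")
  fit <- cluster::pam(stats::as.dist(dist), k = k, diss = TRUE)
  structure(list(labels = fit$clustering, medoids = fit$medoids, k = k,
                 objective = unname(fit$objective["swap"])),
            class = "cluster_assignment")
}

# Calinski-Harabasz pseudo-F from a distance matrix only, using the identity
# sum_i d^2(x_i, centroid_C) = (1/|C|) * sum_{i<j in C} d^2(x_i, x_j).
ch_index <- function(dist, labels) {
  d2 <- dist^2
  n <- nrow(dist)
  tot <- sum(d2[upper.tri(d2)]) / n
  within <- sum(vapply(unique(labels), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) return(0)
    dd <- d2[idx, idx, drop = FALSE]
    sum(dd[upper.tri(dd)]) / length(idx)
  }, numeric(1)))
  k <- length(unique(labels))
  between <- tot - within
  (between / (k - 1)) / (within / (n - k))
}

#' Choose the number of enterotype-like clusters
#'
#' Runs [pam_cluster()] (or average-linkage hierarchical clustering) for each
#' candidate `k` and picks the `k` maximizing the Calinski-Harabasz index
#' computed from the distance matrix; index values for every candidate are
#' reported alongside the winning assignment.
#'
#' @param dist Symmetric distance matrix.
#' @param k_range Candidate cluster numbers (default 2:8), within
#'   `[2, n - 1]`.
#' @param seed Passed to the clusterer.
#' @param method `"pam"` (default) or `"hclust"` (average linkage).
#' @return A `cluster_assignment` with an extra element `index` (data.frame:
#'   `k`, `ch`).
#' @export
select_k <- function(dist, k_range = 2:8, seed = 1L,
                     method = c("pam", "hclust")) {
  method <- match.arg(method)
  n <- nrow(dist)
  if (all(dist == 0)) stop("degenerate distance matrix (all zero)")
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (!length(k_range)) stop("no valid k in k_range for ", n, " samples")
  fits <- lapply(k_range, function(k) cluster_samples(dist, k, seed, method))
  ch <- vapply(seq_along(k_range), function(i) ch_index(dist, fits[[i]]$labels),
               numeric(1))
  best <- which.max(ch)
  out <- fits[[best]]
  out$index <- data.frame(k = k_range, ch = ch)
  out
}

cluster_samples <- function(dist, k, seed = 1L, method = c("pam", "hclust")) {
  method <- match.arg(method)
  if (method == "pam") return(pam_cluster(dist, k, seed))
  hc <- stats::hclust(stats::as.dist(dist), method = "average")
  labels <- stats::cutree(hc, k = k)
  medoids <- vapply(seq_len(k), function(cl) {
    idx <- which(labels == cl)
    names(labels)[idx][which.min(colSums(dist[idx, idx, drop = FALSE]))]
  }, character(1))
  structure(list(labels = labels, medoids = medoids, k = k,
                 objective = NA_real_), class = "cluster_assignment")
}

#' Driver genus of each cluster
#'
#' For every cluster, the genus with the highest ratio of mean abundance
#' within the cluster to mean abundance outside it; ties go to the higher
#' within-cluster mean, then lexicographically first genus. With a single
#' cluster the contrast degenerates to the genus with the top overall mean.
#'
#' @param assign A `cluster_assignment`.
#' @param profiles Genus relative-abundance matrix (genera x samples)
#'   covering the assigned samples.
#' @return Named character vector, cluster id -> driver genus.
#' @export
driver_genera <- function(assign, profiles) {
  profiles <- profiles[setdiff(rownames(profiles), "__unassigned__"), ,
                       drop = FALSE]
  labels <- assign$labels[colnames(profiles)]
  if (anyNA(labels)) stop("assignment does not cover all profile samples")
  out <- character(0)
  for (cl in sort(unique(labels))) {
    inside <- profiles[, labels == cl, drop = FALSE]
    if (all(inside == 0)) stop("cluster ", cl, " has an all-zero profile")
    mu_in <- rowMeans(inside)
    outside <- profiles[, labels != cl, drop = FALSE]
    if (ncol(outside) == 0L) {
      ord <- order(-mu_in, rownames(profiles))
    } else {
      mu_out <- rowMeans(outside)
      ratio <- mu_in / pmax(mu_out, .Machine$double.xmin)
      ord <- order(-ratio, -mu_in, rownames(profiles))
    }
    out[as.character(cl)] <- rownames(profiles)[ord[1L]]
  }
  out
}

#' Two-dimensional ordination of samples
#'
#' Principal-coordinate analysis (classical MDS) of a distance matrix, or PCA
#' of centered profiles when given an abundance matrix. Axis signs follow a
#' deterministic convention: on each axis the coordinate of largest magnitude
#' is made positive.
#'
#' @param x Distance matrix (samples x samples, symmetric, zero diagonal) or
#'   abundance matrix (features x samples).
#' @param k Number of axes (default 2).
#' @return A list of class `ordination`: `coordinates` (samples x k matrix)
#'   and `explained` (fraction of variance per axis; sums to <= 1).
#' @export
ordinate <- function(x, k = 2L) {
  is_dist <- nrow(x) == ncol(x) && all(abs(x - t(x)) < 1e-12) &&
    all(abs(diag(x)) < 1e-12)
  if (is_dist) {
    n <- nrow(x)
    if (n < 3L) stop("need at least three samples")
    mds <- stats::cmdscale(stats::as.dist(x), k = min(k, n - 1L), eig = TRUE)
    coords <- mds$points
    pos <- pmax(mds$eig, 0)
    expl <- pos[seq_len(ncol(coords))] / sum(pos)
    if (ncol(coords) < k)
      warning("rank-deficient input: only ", ncol(coords), " axes returned")
  } else {
    if (ncol(x) < 3L) stop("need at least three samples")
    pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
    kk <- min(k, ncol(pc$x))
    coords <- pc$x[, seq_len(kk), drop = FALSE]
    expl <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(kk)]
  }
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords, explained = expl),
            class = "ordination")
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples;
#' 1 for identical partitions (up to label permutation), ~0 for independent
#' ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(sum(tab))
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Enterotype-like clustering of a genus profile
#'
#' Convenience wrapper chaining [jsd_distance()], cluster-number selection
#' (or a fixed `k`), and [driver_genera()].
#'
#' @param genus_profile Genus relative-abundance matrix (genera x samples).
#' @param k Fixed number of clusters, or `NULL` to select by
#'   Calinski-Harabasz over `k_range`.
#' @param k_range Candidates when `k` is `NULL`.
#' @param method `"pam"` or `"hclust"`.
#' @param seed Seed passed through.
#' @return A `cluster_assignment` with extra elements `drivers` and
#'   `distance`.
#' @export
enterotype <- function(genus_profile, k = NULL, k_range = 2:8,
                       method = c("pam", "hclust"), seed = 1L) {
  method <- match.arg(method)
  d <- jsd_distance(genus_profile)
  assign <- if (is.null(k)) select_k(d, k_range, seed, method)
            else cluster_samples(d, k, seed, method)
  assign$drivers <- driver_genera(assign, genus_profile)
  assign$distance <- d
  assign
}
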