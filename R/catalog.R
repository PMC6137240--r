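ALIGN_MATCH <- 1
ALIGN_MISMATCH <- -1
# gap of length L costs 5 + 2*(L-1): opening (first gapped position) 5,
# each extension 2. Biostrings parameterization: gapOpening + L*gapExtension.
ALIGN_GAP_OPENING <- 3
ALIGN_GAP_EXTENSION <- 2

check_dna <- function(x, what = "sequence") {
  if (any(!nzchar(x))) stop(what, " must be non-empty")
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) stop(what, " contains non-ACGT characters: ",
                     paste(utils::head(names(x)[bad], 3), collapse = ", "))
  invisible(x)
}

# Vectorized local alignment of one query against many references.
# Returns a data.frame with identity (matches / aligned columns) and
# overlap (aligned length of the shorter sequence / shorter length).
align_many <- function(query, refs) {
  subject <- Biostrings::DNAString(query)
  pats <- Biostrings::DNAStringSet(refs)
  al <- Biostrings::pairwiseAlignment(
    pats, subject, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = ALIGN_MATCH, mismatch = ALIGN_MISMATCH),
    gapOpening = ALIGN_GAP_OPENING, gapExtension = ALIGN_GAP_EXTENSION)
  cols <- Biostrings::nchar(al)
  shorter <- pmin(nchar(refs), nchar(query))
  shorter_aln <- ifelse(nchar(refs) <= nchar(query),
                        Biostrings::width(Biostrings::pattern(al)),
                        Biostrings::width(Biostrings::subject(al)))
  data.frame(identity = Biostrings::nmatch(al) / cols,
             overlap = shorter_aln / shorter)
}

#' Pairwise identity and overlap of two gene sequences
#'
#' Computes the best local alignment (match +1, mismatch -1, gap open -5,
#' gap extend -2) and reports `identity` = matches / aligned columns and
#' `overlap` = aligned length of the shorter sequence / shorter length, the
#' quantities thresholded by the 95%/90% dereplication rule. Symmetric in its
#' arguments.
#'
#' @param a,b DNA sequences (character scalars over ACGT).
#' @return Named numeric vector with elements `identity` and `overlap`, both
#'   in \[0, 1\].
#' @export
align_identity <- function(a, b) {
  check_dna(c(a = a, b = b))
  r <- align_many(b, a)
  c(identity = r$identity, overlap = r$overlap)
}

# Prefilter: candidate pairs must share >= 2 distinct 12-mers. Provably
# conservative at the 95%/90% rule for shorter lengths >= 120 bp: the matched
# region spans >= 108 bp with <= 5 mismatches, whose match segments contain
# >= 6 * (108/6 - 11) > 2 exact 12-mer windows (pigeonhole, even spacing is
# the worst case).
MIN_SHARED_KMERS <- 2L

# unique k-mers of a sequence, used by the conservative prefilter
seq_kmers <- function(s, k = 12L) {
  L <- nchar(s)
  if (L < k) return(s)
  unique(substring(s, seq_len(L - k + 1L), seq(k, L)))
}

#' Greedy non-redundant dereplication of gene sequences
#'
#' CD-HIT-style greedy clustering: sequences are sorted by length descending
#' (ties by id, lexicographic) and each sequence joins the first existing
#' representative it matches at identity > `identity_threshold` AND overlap >
#' `overlap_threshold`, else founds a new cluster. The non-redundant catalog
#' is the set of representatives.
#'
#' A shared-12-mer prefilter skips pairs that cannot reach the identity
#' threshold (a >=95%-identity overlap of >=90% of a >=120 bp sequence must
#' contain a 12 bp exact run, by pigeonhole); `prefilter = FALSE` forces a
#' full alignment for every candidate pair and gives identical results.
#'
#' @param seqs Named character vector of DNA sequences (names are gene ids).
#' @param identity_threshold,overlap_threshold Strict lower bounds in (0, 1].
#' @param prefilter Use the conservative k-mer prefilter (default TRUE).
#' @return A list of class `cluster_set`: `members` (data.frame: `member_id`,
#'   `representative_id`, `identity`, `overlap`) and `representatives`
#'   (character vector in creation order).
#' @export
dereplicate <- function(seqs, identity_threshold = 0.95,
                        overlap_threshold = 0.90, prefilter = TRUE) {
  if (!length(seqs)) stop("no sequences to dereplicate")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  if (identity_threshold <= 0 || identity_threshold > 1 ||
      overlap_threshold <= 0 || overlap_threshold > 1)
    stop("thresholds must lie in (0, 1]")
  check_dna(seqs)

  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  ids <- names(seqs)

  rep_ids <- character(); rep_seqs <- character()
  rep_index <- new.env(hash = TRUE, parent = emptyenv())  # kmer -> rep indices
  member_rep <- character(length(seqs))
  member_ident <- numeric(length(seqs)); member_ov <- numeric(length(seqs))

  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    assigned <- FALSE
    if (length(rep_ids)) {
      cand <- seq_along(rep_ids)
      if (prefilter) {
        hits <- unlist(mget(seq_kmers(s), envir = rep_index,
                            ifnotfound = list(NULL)), use.names = FALSE)
        tab <- tabulate(as.integer(hits), nbins = length(rep_ids))
        cand <- which(tab >= MIN_SHARED_KMERS)
      }
      if (length(cand)) {
        hits <- align_many(s, rep_seqs[cand])
        ok <- hits$identity > identity_threshold & hits$overlap > overlap_threshold
        if (any(ok)) {
          j <- cand[which(ok)[1L]]   # first representative in creation order
          member_rep[i] <- rep_ids[j]
          member_ident[i] <- hits$identity[which(ok)[1L]]
          member_ov[i] <- hits$overlap[which(ok)[1L]]
          assigned <- TRUE
        }
      }
    }
    if (!assigned) {
      rep_ids <- c(rep_ids, ids[i])
      rep_seqs <- c(rep_seqs, s)
      ri <- length(rep_ids)
      for (km in seq_kmers(s))
        assign(km, c(rep_index[[km]], ri), envir = rep_index)
      member_rep[i] <- ids[i]
      member_ident[i] <- 1; member_ov[i] <- 1
    }
  }
  structure(list(
    members = data.frame(member_id = ids, representative_id = member_rep,
                         identity = member_ident, overlap = member_ov,
                         stringsAsFactors = FALSE),
    representatives = rep_ids), class = "cluster_set")
}

#' Cross-catalog gene-identity comparison
#'
#' For each ordered pair of catalogs, counts query genes with at least
#' `min_partners` "identical" genes in the target (identity > 95%, overlap >
#' 90% by default), and computes the Venn-style sharing pattern of every gene
#' (which other catalogs contain an identical partner).
#'
#' @param catalogs Named list (>= 2) of named character vectors of sequences.
#' @param identity_threshold,overlap_threshold As in [dereplicate()].
#' @param min_partners Partners required to call a gene shared; 1 by default
#'   (presence/absence of sharing), 2 for the literal "two and more" variant.
#' @param prefilter Use the conservative k-mer prefilter.
#' @return A list of class `catalog_overlap`: `pairs` (data.frame: `query`,
#'   `target`, `n_query`, `shared`, `shared_fraction`) and `patterns`
#'   (data.frame: `catalog`, `pattern` -- comma-joined catalogs with a
#'   partner, `""` = unique -- and `count`).
#' @export
compare_catalogs <- function(catalogs, identity_threshold = 0.95,
                             overlap_threshold = 0.90, min_partners = 1L,
                             prefilter = TRUE) {
  if (length(catalogs) < 2L) stop("need at least two catalogs")
  if (is.null(names(catalogs)) || any(!nzchar(names(catalogs))))
    stop("catalogs must be named")
  for (nm in names(catalogs)) {
    if (!length(catalogs[[nm]])) stop("catalog '", nm, "' is empty")
    check_dna(catalogs[[nm]], paste0("catalog '", nm, "'"))
  }
  nms <- names(catalogs)
  # inverted 12-mer index per catalog: kmer -> gene indices containing it
  kindex <- lapply(catalogs, function(ct) {
    km <- lapply(ct, seq_kmers)
    split(rep(seq_along(km), lengths(km)), unlist(km))
  })

  n_partners <- function(q, t) {
    # partner counts in catalog t for every gene of catalog q
    vapply(seq_along(catalogs[[q]]), function(i) {
      s <- catalogs[[q]][[i]]
      cand <- if (prefilter) {
        hits <- unlist(kindex[[t]][seq_kmers(s)], use.names = FALSE)
        tab <- tabulate(as.integer(hits), nbins = length(catalogs[[t]]))
        which(tab >= MIN_SHARED_KMERS)
      } else seq_along(catalogs[[t]])
      if (!length(cand)) return(0L)
      hits <- align_many(s, unname(catalogs[[t]][cand]))
      sum(hits$identity > identity_threshold &
            hits$overlap > overlap_threshold)
    }, integer(1))
  }

  pairs <- list(); pattern_rows <- list()
  partner_mat <- list()   # per query catalog: gene x other-catalog logical
  for (q in nms) {
    others <- setdiff(nms, q)
    m <- matrix(FALSE, length(catalogs[[q]]), length(others),
                dimnames = list(names(catalogs[[q]]), others))
    for (t in others) {
      np <- n_partners(q, t)
      m[, t] <- np >= min_partners
      pairs[[paste(q, t)]] <- data.frame(
        query = q, target = t, n_query = length(np),
        shared = sum(np >= min_partners),
        shared_fraction = mean(np >= min_partners),
        stringsAsFactors = FALSE)
    }
    pat <- apply(m, 1L, function(r) paste(others[r], collapse = ","))
    tab <- table(pat)
    pattern_rows[[q]] <- data.frame(catalog = q, pattern = names(tab),
                                    count = as.integer(tab),
                                    stringsAsFactors = FALSE)
    partner_mat[[q]] <- m
  }
  structure(list(pairs = do.call(rbind, c(pairs, make.row.names = FALSE)),
                 patterns = do.call(rbind, c(pattern_rows,
                                             make.row.names = FALSE)),
                 partners = partner_mat),
            class = "catalog_overlap")
}

#' Random subsamples of a catalog
#'
#' Draws `repeats` uniform without-replacement subsets of `n` gene ids,
#' seeded and reproducible — the desk-scale analogue of repeatedly picking a
#' fixed number of genes from a large catalog.
#'
#' @param catalog Named character vector of sequences (or a character vector
#'   of gene ids).
#' @param n Subsample size; must not exceed the catalog size.
#' @param repeats Number of draws.
#' @param seed Integer seed.
#' @return List of `repeats` character vectors of gene ids.
#' @export
subsample_catalog <- function(catalog, n, repeats = 10L, seed = 1L) {
  ids <- if (is.null(names(catalog))) catalog else names(catalog)
  if (n > length(ids)) stop("n exceeds catalog size")
  with_seed(seed, lapply(seq_len(repeats), function(i) sample(ids, n)))
}
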