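random_dna <- function(n, len_range) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

#' Simulate annotated multi-host gene catalogs
#'
#' Generates `n_hosts` gene catalogs of random nucleotide ORF-like sequences.
#' For each host pair, each gene of the earlier host is copied verbatim into
#' the later host with the configured sharing probability, replacing one of
#' its genes — so cross-host "identical gene" pairs exist at a known rate.
#' Every gene carries a true lineage (drawn from the fixed toy taxonomy) and a
#' true KO; observed annotations are thinned independently per rank at the
#' configured rates, with unannotated fields left as empty strings.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_catalog` with elements `genes` (data.frame:
#'   `host`, `gene_id`, `sequence`, `length`, observed `superkingdom`,
#'   `phylum`, `genus`, `species`, `ko`, `phage_flag`) and `truth` (gene-host
#'   membership, true annotations, cross-host identity pairs).
#' @export
simulate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed + 11L, {
    tax <- toy_taxonomy()
    kos <- toy_ko_universe()
    G <- config$genes_per_host
    hosts <- paste0("host", seq_len(config$n_hosts))

    per_host <- lapply(seq_len(config$n_hosts), function(h) {
      seqs <- random_dna(G, config$gene_length_range)
      gi <- sample.int(nrow(tax), G, replace = TRUE, prob = tax$weight)
      data.frame(
        host = hosts[h],
        gene_id = sprintf("%s_g%05d", hosts[h], seq_len(G)),
        sequence = seqs,
        length = nchar(seqs),
        true_phylum = tax$phylum[gi],
        true_genus = tax$genus[gi],
        true_species = tax$species[gi],
        true_ko = sample(kos, G, replace = TRUE),
        true_phage = as.integer(stats::runif(G) < config$annotation_rates$phage),
        stringsAsFactors = FALSE
      )
    })

    # plant verbatim cross-host copies at the configured pairwise fractions
    shared_pairs <- list()
    if (config$n_hosts >= 2L) {
      for (i in seq_len(config$n_hosts - 1L)) {
        for (j in seq(i + 1L, config$n_hosts)) {
          s <- config$pairwise_share[i, j]
          if (s <= 0) next
          donors <- which(stats::runif(G) < s)
          if (!length(donors)) next
          targets <- sample.int(G, length(donors))
          cp <- c("sequence", "length", "true_phylum", "true_genus",
                  "true_species", "true_ko", "true_phage")
          per_host[[j]][targets, cp] <- per_host[[i]][donors, cp]
          shared_pairs[[length(shared_pairs) + 1L]] <- data.frame(
            host_a = hosts[i], gene_a = per_host[[i]]$gene_id[donors],
            host_b = hosts[j], gene_b = per_host[[j]]$gene_id[targets],
            stringsAsFactors = FALSE
          )
        }
      }
    }
    genes <- do.call(rbind, per_host)
    rownames(genes) <- NULL

    # observed annotations: independent per-rank dropout
    n <- nrow(genes)
    r <- config$annotation_rates
    keep_phy <- stats::runif(n) < r$phylum
    keep_gen <- stats::runif(n) < r$genus
    keep_spe <- stats::runif(n) < r$species
    keep_ko <- stats::runif(n) < r$ko
    genes$superkingdom <- ifelse(keep_phy, "Bacteria", "")
    genes$phylum <- ifelse(keep_phy, genes$true_phylum, "")
    genes$genus <- ifelse(keep_gen, genes$true_genus, "")
    genes$species <- ifelse(keep_spe, genes$true_species, "")
    genes$ko <- ifelse(keep_ko, genes$true_ko, "")
    genes$phage_flag <- genes$true_phage

    truth <- list(
      gene_host = stats::setNames(genes$host, genes$gene_id),
      true_annotation = genes[, c("gene_id", "true_phylum", "true_genus",
                                  "true_species", "true_ko", "true_phage")],
      shared_pairs = if (length(shared_pairs)) do.call(rbind, shared_pairs)
                     else data.frame(host_a = character(), gene_a = character(),
                                     host_b = character(), gene_b = character())
    )
    genes <- genes[, c("host", "gene_id", "sequence", "length", "superkingdom",
                       "phylum", "genus", "species", "ko", "phage_flag")]
    structure(list(genes = genes, truth = truth), class = "sim_catalog")
  })
}

#' Simulate redundant sequence sets with known cluster membership
#'
#' Emits progenitor sequences plus mutated/truncated variants for exercising
#' the dereplication rule. The mutation model is substitutions at uniformly
#' random positions (each to a different base) plus optional 3' truncation;
#' indels are excluded so realized identity to the progenitor equals the
#' target up to local-alignment end trimming.
#'
#' @param config A [sim_config()] with a `redundancy_spec`; fields
#'   `n_progenitors` (default 100), `variants_per_progenitor`,
#'   `target_identity` and `length_fraction` (both recycled across variants).
#' @return A list with `sequences` (named character vector, progenitors first)
#'   and `truth` (data.frame: `seq_id`, `progenitor`, `target_identity`,
#'   `length_fraction`; progenitors point to themselves).
#' @export
simulate_redundant_sequences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$redundancy_spec
  if (is.null(spec)) stop("config$redundancy_spec is required")
  validate_sim_config(config)
  n_prog <- if (is.null(spec$n_progenitors)) 100L else as.integer(spec$n_progenitors)
  n_var <- as.integer(spec$variants_per_progenitor)

  with_seed(config$seed + 23L, {
    prog <- random_dna(n_prog, config$gene_length_range)
    names(prog) <- sprintf("p%04d", seq_len(n_prog))
    seqs <- prog
    truth <- data.frame(seq_id = names(prog), progenitor = names(prog),
                        target_identity = 1, length_fraction = 1,
                        stringsAsFactors = FALSE)
    if (n_var > 0L) {
      ti <- rep_len(spec$target_identity, n_var)
      lf <- rep_len(spec$length_fraction, n_var)
      for (p in seq_len(n_prog)) {
        for (v in seq_len(n_var)) {
          base <- strsplit(prog[[p]], "")[[1]]
          newL <- max(1L, round(lf[v] * length(base)))
          base <- base[seq_len(newL)]
          n_sub <- round((1 - ti[v]) * newL)
          if (n_sub > 0L) {
            pos <- sample.int(newL, n_sub)
            for (q in pos)
              base[q] <- sample(setdiff(c("A", "C", "G", "T"), base[q]), 1L)
          }
          id <- sprintf("%s_v%02d", names(prog)[p], v)
          seqs[[id]] <- paste(base, collapse = "")
          truth <- rbind(truth, data.frame(
            seq_id = id, progenitor = names(prog)[p],
            target_identity = ti[v], length_fraction = lf[v],
            stringsAsFactors = FALSE))
        }
      }
    }
    list(sequences = seqs, truth = truth)
  })
}

#' Simulate per-sample gene read counts with planted effects
#'
#' Per-gene base abundance is log-normal(0, `abundance_sigma`); planted effect
#' features are multiplied by their fold change in the samples of their
#' enriched group; if an `enterotype_spec` is present, each sample is assigned
#' a cluster and its genus-level abundance mass is redrawn from a Dirichlet
#' distribution whose driver genus is boosted. Expected read counts are
#' proportional to abundance times gene length (so length normalization in
#' profiling is a real inversion), and counts are drawn multinomially with
#' `reads_per_sample` total per sample.
#'
#' @param config A [sim_config()].
#' @param catalog A `sim_catalog` (host 1's genes are used) or a data.frame of
#'   genes with at least `gene_id`, `length`, and true annotation columns
#'   (`true_genus`, `true_ko`) or observed ones as fallback.
#' @return A list of class `sim_counts`: `counts` (integer matrix, genes x
#'   samples; columns sum to `reads_per_sample`), `metadata` (data.frame:
#'   `sample_id`, `group`, `true_enterotype`), and `truth` (base abundances,
#'   per-sample true relative abundances, planted effects, cluster labels).
#' @export
simulate_counts <- function(config, catalog) {
  stopifnot(inherits(config, "sim_config"))
  if (config$reads_per_sample <= 0L) stop("reads_per_sample must be positive")
  genes <- if (inherits(catalog, "sim_catalog")) {
    g <- catalog$genes[catalog$genes$host == catalog$genes$host[1], ]
    tr <- catalog$truth$true_annotation
    g$true_genus <- tr$true_genus[match(g$gene_id, tr$gene_id)]
    g$true_ko <- tr$true_ko[match(g$gene_id, tr$gene_id)]
    g
  } else as.data.frame(catalog)
  if (nrow(genes) == 0L) stop("catalog must contain at least one gene")
  if (is.null(genes$true_genus)) genes$true_genus <- genes$genus
  if (is.null(genes$true_ko)) genes$true_ko <- genes$ko

  with_seed(config$seed + 37L, {
    G <- nrow(genes)
    n <- config$n_groups * config$n_samples_per_group
    samples <- sprintf("S%03d", seq_len(n))
    group <- rep(paste0("G", seq_len(config$n_groups)),
                 each = config$n_samples_per_group)

    base_ab <- stats::rlnorm(G, meanlog = 0, sdlog = config$abundance_sigma)

    es <- config$enterotype_spec
    labels <- if (is.null(es)) rep(1L, n) else sample(rep(seq_len(es$k), length.out = n))

    tax <- toy_taxonomy()
    w <- stats::setNames(tax$weight, tax$genus)

    counts <- matrix(0L, G, n, dimnames = list(genes$gene_id, samples))
    true_ab <- matrix(0, G, n, dimnames = list(genes$gene_id, samples))
    for (s in seq_len(n)) {
      ab <- base_ab
      if (!is.null(es)) {
        wk <- w
        wk[es$drivers[labels[s]]] <- wk[es$drivers[labels[s]]] * es$boost
        wk <- wk / sum(wk)
        gm <- stats::rgamma(length(wk), shape = es$concentration * wk)
        gm <- stats::setNames(gm / sum(gm), names(wk))
        tot <- tapply(ab, genes$true_genus, sum)
        scale <- gm[genes$true_genus] / tot[genes$true_genus]
        scale[!is.finite(scale)] <- 0
        ab <- ab * as.numeric(scale)
      }
      # diet effects multiply on top of the (possibly reshaped) composition,
      # so genus-level fold changes survive the enterotype structure
      for (ef in config$effect_features) {
        if (!identical(group[s], ef$group)) next
        members <- switch(ef$type,
          gene = genes$gene_id %in% ef$id,
          genus = genes$true_genus %in% ef$id,
          ko = genes$true_ko %in% ef$id)
        ab[members] <- ab[members] * ef$fold_change
      }
      ab <- ab / sum(ab)
      true_ab[, s] <- ab
      p <- ab * genes$length
      counts[, s] <- stats::rmultinom(1L, config$reads_per_sample, p)[, 1L]
    }

    metadata <- data.frame(sample_id = samples, group = group,
                           true_enterotype = labels, stringsAsFactors = FALSE)
    truth <- list(base_abundance = stats::setNames(base_ab, genes$gene_id),
                  true_abundance = true_ab,
                  effects = config$effect_features,
                  enterotype = stats::setNames(labels, samples))
    structure(list(counts = counts, metadata = metadata, truth = truth),
              class = "sim_counts")
  })
}

#' Write a simulated study to disk
#'
#' Emits the standard file set: one `catalog_<host>.fasta` per host (60-column
#' wrap), `annotations.tsv`, `counts.tsv`, `metadata.tsv` and `truth.json`.
#'
#' @param catalog A `sim_catalog`.
#' @param countsim A `sim_counts`, or `NULL` to write the catalog only.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(catalog, countsim = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- catalog$genes
  paths <- character()
  for (h in unique(genes$host)) {
    gh <- genes[genes$host == h, ]
    p <- file.path(dir, paste0("catalog_", h, ".fasta"))
    write_fasta(stats::setNames(gh$sequence, gh$gene_id), p)
    paths <- c(paths, p)
  }
  ann <- genes[, c("gene_id", "superkingdom", "phylum", "genus", "species",
                   "ko", "phage_flag")]
  p <- file.path(dir, "annotations.tsv")
  write_table(ann, p)
  paths <- c(paths, p)
  if (!is.null(countsim)) {
    ct <- data.frame(gene_id = rownames(countsim$counts),
                     countsim$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    p <- file.path(dir, "counts.tsv"); write_table(ct, p); paths <- c(paths, p)
    p <- file.path(dir, "metadata.tsv")
    write_table(countsim$metadata, p); paths <- c(paths, p)
    p <- file.path(dir, "truth.json")
    jsonlite::write_json(list(enterotype = as.list(countsim$truth$enterotype),
                              effects = countsim$truth$effects),
                         p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
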