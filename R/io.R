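#' Read a FASTA file of gene sequences
#'
#' Ids must be unique and records non-empty; lower-case bases are upper-cased
#' with a warning; CRLF line endings are accepted.
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case DNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- gsub("\r", "", as.character(set), fixed = TRUE)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs))) stop("empty sequence record(s) in ", path)
  if (any(grepl("[a-z]", seqs))) {
    warning("lower-case bases in ", path, "; upper-casing")
    seqs <- toupper(seqs)
  }
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA (60-column wrap)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  if (any(!nzchar(seqs))) stop("refusing to write empty sequence records")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a typed TSV table
#'
#' @param path TSV path with a header line.
#' @param schema Optional named character vector column -> type
#'   (`"character"`, `"integer"`, `"numeric"`); listed columns must exist and
#'   parse, other columns are type-converted heuristically. Empty strings in
#'   character columns are preserved (not turned into NA).
#' @return data.frame.
#' @export
read_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE, na.strings = NULL,
                           stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    miss <- setdiff(names(schema), names(raw))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    for (col in names(schema)) {
      if (schema[[col]] == "character") next
      conv <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(conv) & nzchar(raw[[col]]))
      if (length(bad))
        stop("non-numeric value in column '", col, "' at row ", bad[1],
             ": '", raw[[col]][bad[1]], "'")
      raw[[col]] <- if (schema[[col]] == "integer") as.integer(conv) else conv
    }
    others <- setdiff(names(raw), names(schema))
  } else others <- names(raw)
  for (col in others)
    raw[[col]] <- utils::type.convert(raw[[col]], as.is = TRUE,
                                      na.strings = character(0))
  raw
}

#' Write a TSV table at full precision
#'
#' Numeric columns are written with 17 significant digits so round-trips are
#' value-exact; row order is made deterministic by sorting on the first
#' column unless `sort_rows = FALSE`.
#'
#' @param df data.frame.
#' @param path Output path.
#' @param sort_rows Sort rows by the first column (default TRUE).
#' @return Invisibly, `path`.
#' @export
write_table <- function(df, path, sort_rows = TRUE) {
  if (sort_rows && nrow(df) > 1L) df <- df[order(df[[1L]]), , drop = FALSE]
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles the simulator configuration with the analysis thresholds: 95%
#' identity / 90% overlap for dereplication and catalog comparison, marker
#' p-value cutoffs (0.01 for genes, 0.05 for genera and phage genes, raw
#' p-values), the 1.6 reporter-score detection threshold, and the
#' more-than-five-samples occurrence filter for KO tests.
#'
#' @param sim A [sim_config()].
#' @param out_dir Output directory for artifacts.
#' @param stages Stages to run, a subset of the default order.
#' @param identity_threshold,overlap_threshold Dereplication thresholds.
#' @param gene_marker_p,feature_marker_p Raw-p cutoffs for gene-level and
#'   genus/phage-level markers.
#' @param reporter_threshold Reporter-score detection threshold.
#' @param min_nonzero KO occurrence filter.
#' @param k_range Candidate enterotype numbers.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(sim = sim_config(), out_dir = "gutcatkit_run",
                            stages = c("simulate", "dereplicate", "profile",
                                       "rarefy", "enterotype", "diff",
                                       "reporter", "compare"),
                            identity_threshold = 0.95,
                            overlap_threshold = 0.90,
                            gene_marker_p = 0.01, feature_marker_p = 0.05,
                            reporter_threshold = 1.6, min_nonzero = 6L,
                            k_range = 2:8) {
  structure(list(sim = sim, out_dir = out_dir, stages = stages,
                 identity_threshold = identity_threshold,
                 overlap_threshold = overlap_threshold,
                 gene_marker_p = gene_marker_p,
                 feature_marker_p = feature_marker_p,
                 reporter_threshold = reporter_threshold,
                 min_nonzero = as.integer(min_nonzero),
                 k_range = k_range), class = "run_config")
}

read_counts_matrix <- function(path) {
  tab <- read_table(path)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- tab[[1L]]
  m
}

#' Run the full workflow
#'
#' Executes the stages in order (simulate, dereplicate, profile, rarefy,
#' enterotype, diff, reporter, compare — any subset selectable via the
#' config), writing every artifact plus a `provenance.json` (config, seed,
#' package version) into `out_dir`. Identical config + seed yields identical
#' artifact checksums. When `simulate` is not among the stages, the input
#' files it would have produced must already exist in `out_dir`; they are
#' checked before any stage runs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of written artifact paths by stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  stages <- config$stages

  if (!"simulate" %in% stages) {
    needed <- c("counts.tsv", "annotations.tsv", "metadata.tsv",
                "catalog_host1.fasta")
    missing <- needed[!file.exists(out(needed))]
    if (length(missing))
      stop("missing input file(s): ", paste(out(missing), collapse = ", "))
  }

  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    r
  }

  artifacts <- list()
  if ("simulate" %in% stages) {
    artifacts$simulate <- run_stage("simulate", {
      cat <- simulate_catalog(config$sim)
      cs <- simulate_counts(config$sim, cat)
      write_simulation(cat, cs, config$out_dir)
    })
  }

  ann <- read_table(out("annotations.tsv"),
                    schema = c(gene_id = "character", genus = "character",
                               ko = "character", phage_flag = "integer"))
  host_fastas <- list.files(config$out_dir, pattern = "^catalog_.*\\.fasta$",
                            full.names = TRUE)
  catalogs <- lapply(host_fastas, read_fasta)
  names(catalogs) <- sub("^catalog_(.*)\\.fasta$", "\\1", basename(host_fastas))

  if ("dereplicate" %in% stages) {
    artifacts$dereplicate <- run_stage("dereplicate", {
      all_seqs <- unlist(unname(lapply(catalogs, identity)))
      cs <- dereplicate(all_seqs, config$identity_threshold,
                        config$overlap_threshold)
      write_table(cs$members, out("clusters.tsv"))
    })
  }

  counts <- read_counts_matrix(out("counts.tsv"))
  lengths <- nchar(catalogs[[1]])[rownames(counts)]
  meta <- read_table(out("metadata.tsv"),
                     schema = c(sample_id = "character", group = "character"))
  groups <- stats::setNames(meta$group, meta$sample_id)

  profile <- NULL
  if (any(c("profile", "rarefy", "enterotype", "diff", "reporter") %in% stages)) {
    profile <- gene_abundance(counts, lengths)
    genus_map <- stats::setNames(ann$genus, ann$gene_id)
    ko_map <- stats::setNames(ann$ko, ann$gene_id)
    genus_prof <- aggregate_profile(profile, genus_map)
    ko_prof <- aggregate_profile(profile, ko_map)
  }
  if ("profile" %in% stages) {
    artifacts$profile <- run_stage("profile", {
      wr <- function(m, f) write_table(
        data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE), out(f))
      c(wr(profile, "profile_gene.tsv"), wr(genus_prof, "profile_genus.tsv"),
        wr(ko_prof, "profile_ko.tsv"))
    })
  }

  if ("rarefy" %in% stages) {
    artifacts$rarefy <- run_stage("rarefy", {
      curve <- rarefy(counts, repetitions = 100L, seed = config$sim$seed)
      inc <- incidence_summary(counts)
      est <- chao1(inc)
      write_table(data.frame(S_obs = inc$S_obs, f1 = inc$f1, f2 = inc$f2,
                             chao1 = est,
                             coverage = coverage(inc$S_obs, est)),
                  out("richness.tsv"))
      write_table(as.data.frame(curve), out("rarefaction.tsv"),
                  sort_rows = FALSE)
    })
  }

  if ("enterotype" %in% stages) {
    artifacts$enterotype <- run_stage("enterotype", {
      et <- enterotype(genus_prof, k_range = config$k_range,
                       seed = config$sim$seed)
      write_table(data.frame(sample = rownames(et$distance), et$distance,
                             check.names = FALSE), out("distance.tsv"))
      write_table(data.frame(sample = names(et$labels),
                             cluster = unname(et$labels),
                             medoid_flag = as.integer(
                               names(et$labels) %in% et$medoids),
                             driver = unname(et$drivers[as.character(et$labels)])),
                  out("enterotypes.tsv"))
      ord <- ordinate(et$distance)
      write_table(data.frame(sample = rownames(ord$coordinates),
                             ord$coordinates,
                             check.names = FALSE), out("ordination.tsv"))
      out(c("distance.tsv", "enterotypes.tsv", "ordination.tsv"))
    })
  }

  if ("diff" %in% stages) {
    artifacts$diff <- run_stage("diff", {
      dg <- differential_abundance(profile, groups)
      write_table(select_markers(dg, config$gene_marker_p),
                  out("markers_gene.tsv"))
      dgen <- differential_abundance(
        genus_prof[setdiff(rownames(genus_prof), "__unassigned__"), ,
                   drop = FALSE], groups)
      write_table(select_markers(dgen, config$feature_marker_p),
                  out("markers_genus.tsv"))
      phage_genes <- ann$gene_id[ann$phage_flag == 1L]
      phage_genes <- intersect(phage_genes, rownames(profile))
      if (length(phage_genes) >= 1L) {
        dph <- differential_abundance(profile[phage_genes, , drop = FALSE],
                                      groups)
        write_table(select_markers(dph, config$feature_marker_p),
                    out("markers_phage.tsv"))
      }
      out(c("markers_gene.tsv", "markers_genus.tsv", "markers_phage.tsv"))
    })
  }

  if ("reporter" %in% stages) {
    artifacts$reporter <- run_stage("reporter", {
      ko_only <- ko_prof[setdiff(rownames(ko_prof), "__unassigned__"), ,
                         drop = FALSE]
      rr <- reporter_analysis(ko_only, groups, toy_pathways(),
                              seed = config$sim$seed,
                              min_nonzero = config$min_nonzero)
      write_table(rr, out("reporter.tsv"))
      write_table(significant_pathways(rr, config$reporter_threshold),
                  out("reporter_significant.tsv"))
      out(c("reporter.tsv", "reporter_significant.tsv"))
    })
  }

  if ("compare" %in% stages && length(catalogs) >= 2L) {
    artifacts$compare <- run_stage("compare", {
      ov <- compare_catalogs(catalogs, config$identity_threshold,
                             config$overlap_threshold)
      write_table(ov$pairs, out("overlap_pairs.tsv"))
      write_table(ov$patterns, out("overlap.tsv"))
      out(c("overlap_pairs.tsv", "overlap.tsv"))
    })
  }

  prov <- list(package = "gutcatkit",
               version = as.character(utils::packageVersion("gutcatkit")),
               seed = config$sim$seed,
               stages = stages,
               thresholds = list(identity = config$identity_threshold,
                                 overlap = config$overlap_threshold,
                                 gene_marker_p = config$gene_marker_p,
                                 feature_marker_p = config$feature_marker_p,
                                 reporter = config$reporter_threshold,
                                 min_nonzero = config$min_nonzero))
  jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(artifacts)
}
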