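#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic-community
#' simulator. Defaults emulate the study design the package targets: 20
#' samples in two diet groups of 10, two host catalogs sharing ~40% of their
#' genes, log-normal gene abundances with length-weighted multinomial read
#' sampling, and partial annotation (a large fraction of genes carry no genus
#' or KO label, as in real catalogs).
#'
#' @param seed Integer seed; fixes every simulator output bit-for-bit.
#' @param n_hosts Number of host catalogs to simulate.
#' @param genes_per_host Genes per host catalog.
#' @param pairwise_share Symmetric host-by-host matrix of sharing fractions in
#'   \[0,1\] with unit diagonal; entry (i,j) is the probability that a gene of
#'   host i has a verbatim copy in host j. A scalar is expanded to a constant
#'   off-diagonal matrix.
#' @param n_groups Number of sample groups (2 for a diet contrast).
#' @param n_samples_per_group Samples per group.
#' @param gene_length_range Integer pair, min/max gene length in bp.
#' @param abundance_sigma Log-normal scale of per-gene base abundance.
#' @param reads_per_sample Total reads drawn per sample (multinomial size).
#' @param effect_features List of planted effects, each a list with `type`
#'   (`"gene"`, `"genus"` or `"ko"`), `id`, `fold_change` (> 0) and `group`
#'   (the group whose samples get the multiplier).
#' @param annotation_rates Named list of labeling fractions: `phylum`,
#'   `genus`, `species`, `ko`, `phage`. Dropout is independent per rank.
#' @param enterotype_spec `NULL` for unstructured communities, or a list with
#'   `k` (number of clusters), `drivers` (genus per cluster), `boost`
#'   (driver concentration multiplier) and `concentration` (total Dirichlet
#'   concentration controlling within-cluster spread).
#' @param redundancy_spec `NULL`, or a list with `n_progenitors`,
#'   `variants_per_progenitor`, `target_identity` (vector, recycled per
#'   variant; each in (0.5, 1\]) and `length_fraction` (vector, recycled;
#'   fraction of the progenitor retained after 3' truncation).
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_hosts = 2L,
                       genes_per_host = 500L,
                       pairwise_share = 0.4,
                       n_groups = 2L,
                       n_samples_per_group = 10L,
                       gene_length_range = c(300L, 1500L),
                       abundance_sigma = 1.5,
                       reads_per_sample = 1e5,
                       effect_features = list(),
                       annotation_rates = list(phylum = 0.65, genus = 0.14,
                                               species = 0.09, ko = 0.53,
                                               phage = 0.15),
                       enterotype_spec = NULL,
                       redundancy_spec = NULL) {
  if (length(pairwise_share) == 1L) {
    m <- matrix(pairwise_share, n_hosts, n_hosts)
    diag(m) <- 1
    pairwise_share <- m
  }
  cfg <- list(
    seed = as.integer(seed), n_hosts = as.integer(n_hosts),
    genes_per_host = as.integer(genes_per_host),
    pairwise_share = pairwise_share,
    n_groups = as.integer(n_groups),
    n_samples_per_group = as.integer(n_samples_per_group),
    gene_length_range = as.integer(gene_length_range),
    abundance_sigma = abundance_sigma,
    reads_per_sample = as.integer(reads_per_sample),
    effect_features = effect_features,
    annotation_rates = annotation_rates,
    enterotype_spec = enterotype_spec,
    redundancy_spec = redundancy_spec
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  s <- cfg$pairwise_share
  if (!is.matrix(s) || nrow(s) != cfg$n_hosts || ncol(s) != cfg$n_hosts)
    stop("pairwise_share must be an n_hosts x n_hosts matrix")
  if (any(s < 0) || any(s > 1))
    stop("pairwise_share entries must lie in [0, 1]")
  if (!isTRUE(all.equal(s, t(s))))
    stop("pairwise_share must be symmetric")
  if (!isTRUE(all.equal(unname(diag(s)), rep(1, cfg$n_hosts))))
    stop("pairwise_share must have unit diagonal")
  if (cfg$genes_per_host < 1L) stop("genes_per_host must be positive")
  if (cfg$abundance_sigma <= 0) stop("abundance_sigma must be positive")
  if (length(cfg$gene_length_range) != 2L ||
      cfg$gene_length_range[1] < 1L ||
      cfg$gene_length_range[2] < cfg$gene_length_range[1])
    stop("gene_length_range must be an increasing positive integer pair")
  rates <- unlist(cfg$annotation_rates)
  if (any(rates < 0) || any(rates > 1))
    stop("annotation_rates must lie in [0, 1]")
  for (ef in cfg$effect_features) {
    if (is.null(ef$fold_change) || ef$fold_change <= 0)
      stop("effect_features fold_change must be > 0")
    if (!ef$type %in% c("gene", "genus", "ko"))
      stop("effect_features type must be 'gene', 'genus' or 'ko'")
  }
  if (!is.null(cfg$redundancy_spec)) {
    ti <- cfg$redundancy_spec$target_identity
    if (any(ti <= 0.5) || any(ti > 1))
      stop("redundancy target_identity must lie in (0.5, 1]")
  }
  if (!is.null(cfg$enterotype_spec)) {
    es <- cfg$enterotype_spec
    if (length(es$drivers) != es$k)
      stop("enterotype_spec must name one driver genus per cluster")
    if (!all(es$drivers %in% toy_taxonomy()$genus))
      stop("enterotype drivers must be genera of the toy taxonomy")
  }
  invisible(cfg)
}

# Run `expr` under a fixed RNG state, restoring the caller's state after.
# Every simulator entry point uses an offset so the stages have independent
# streams while remaining fully determined by config$seed.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
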