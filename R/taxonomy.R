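#' Fixed toy taxonomy shipped with the package
#'
#' A small, versioned table of 15 gut-associated bacterial genera with their
#' lineages. The simulator draws gene taxonomy from this table so that examples
#' and tests are stable across sessions; it stands in for a full reference
#' taxonomy, which is out of scope here.
#'
#' @return A data.frame with columns `superkingdom`, `phylum`, `genus`,
#'   `species` and `weight` (the relative prior mass a genus receives when
#'   gene lineages are drawn).
#' @export
toy_taxonomy <- function() {
  tab <- data.frame(
    superkingdom = "Bacteria",
    phylum = c(
      "Bacteroidetes", "Bacteroidetes", "Bacteroidetes", "Bacteroidetes",
      "Firmicutes", "Firmicutes", "Firmicutes", "Firmicutes", "Firmicutes",
      "Firmicutes", "Firmicutes", "Firmicutes", "Firmicutes",
      "Verrucomicrobia", "Proteobacteria"
    ),
    genus = c(
      "Prevotella", "Bacteroides", "Parabacteroides", "Alistipes",
      "Ruminococcus", "Lactobacillus", "Streptococcus", "Clostridium",
      "Eubacterium", "Roseburia", "Faecalibacterium", "Blautia", "Dorea",
      "Akkermansia", "Succinatimonas"
    ),
    stringsAsFactors = FALSE
  )
  tab$species <- paste(tab$genus, "sp1")
  # mildly uneven prior so communities are not artificially uniform
  tab$weight <- rep(c(2, 1.5, 1, 0.75), length.out = nrow(tab))
  tab$weight <- tab$weight / sum(tab$weight)
  tab
}

#' Fixed toy KO universe
#'
#' @return Character vector of 200 KEGG-orthology-style identifiers
#'   (`K00001` ... `K00200`).
#' @export
toy_ko_universe <- function() {
  sprintf("K%05d", seq_len(200))
}

#' Fixed toy pathway definitions
#'
#' Twenty pathways of 5-25 member KOs drawn deterministically (by fixed
#' arithmetic, no RNG) from [toy_ko_universe()], with overlapping membership
#' as in real pathway maps.
#'
#' @return A data.frame with columns `pathway` and `ko`, one row per
#'   pathway-member pair.
#' @export
toy_pathways <- function() {
  kos <- toy_ko_universe()
  n_ko <- length(kos)
  out <- vector("list", 20L)
  for (i in seq_len(20L)) {
    size <- 5L + ((i * 7L) %% 21L)          # sizes cycle over 5..25
    idx <- ((i * 13L + (seq_len(size) - 1L) * 11L) %% n_ko) + 1L
    out[[i]] <- data.frame(
      pathway = sprintf("path%05d", i),
      ko = kos[sort(unique(idx))],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
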