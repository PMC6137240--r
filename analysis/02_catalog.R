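#!/usr/bin/env Rscript
# Build the non-redundant gene catalog (95% identity / 90% overlap greedy
# clustering over both hosts' genes pooled) and compare the two host
# catalogs gene-by-gene, the way published gut catalogs are compared.

source("analysis/00_config.R")

sd <- study_data()
seqs <- setNames(sd$catalog$genes$sequence, sd$catalog$genes$gene_id)
cats <- split(seqs, sd$catalog$genes$host)

cs <- dereplicate(seqs)
write_table(cs$members, file.path(RESULTS_DIR, "clusters.tsv"))
message("pooled genes: ", length(seqs),
        " -> non-redundant catalog: ", length(cs$representatives),
        " (", nrow(sd$catalog$truth$shared_pairs),
        " cross-host copies planted)")

ov <- compare_catalogs(cats)
write_table(ov$pairs, file.path(RESULTS_DIR, "overlap_pairs.tsv"))
write_table(ov$patterns, file.path(RESULTS_DIR, "overlap.tsv"))
for (i in seq_len(nrow(ov$pairs)))
  message(sprintf("%s vs %s: %d/%d genes shared (%.1f%%)",
                  ov$pairs$query[i], ov$pairs$target[i], ov$pairs$shared[i],
                  ov$pairs$n_query[i], 100 * ov$pairs$shared_fraction[i]))

# repeated random subsampling, the desk-scale analogue of drawing a fixed
# number of genes from each catalog before comparison
sub <- subsample_catalog(cats$host1, n = 250, repeats = 10,
                         seed = sd$cfg$seed)
message("10 subsamples of 250 genes drawn from host1 (first draw overlaps ",
        length(intersect(sub[[1]], sub[[2]])), " genes with the second)")
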