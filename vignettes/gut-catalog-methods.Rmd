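---
title: "Methods: gene-catalog construction, profiling and enrichment in gutcatkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-catalog construction, profiling and enrichment in gutcatkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gutcatkit implements the analysis chain used to characterize a mammalian gut
metagenome from a non-redundant (NR) gene catalog: catalog dereplication,
relative-abundance profiling, richness estimation, enterotype-like
clustering, differential abundance between two diet groups, reporter-score
pathway enrichment, and cross-host catalog comparison. Because the raw
sequencing data behind such catalogs is far beyond desk scale, the package
ships a synthetic-community simulator with planted ground truth; every
stage is validated against that truth. This vignette documents the models,
the parameters that matter, and the design choices made where the
methodology left room.

## The gene catalog

Predicted genes (ORF nucleotide sequences) are dereplicated by greedy
clustering: sequences are sorted by length descending (ties broken by id so
runs are reproducible), and each sequence joins the first existing cluster
representative it matches at **identity > 0.95 and overlap > 0.90**;
otherwise it founds a new cluster. The NR catalog is the set of
representatives.

The matcher behind the rule is a local alignment with match +1, mismatch
−1, and affine gaps costing 5 for the first gapped position and 2 for each
additional one. Identity is matches over aligned columns; overlap is the
aligned length of the *shorter* sequence divided by its length — the
convention of the clustering tools this rule originates from, so a short
gene fully contained in a longer one has overlap 1. Only the given strand
is compared: ORFs are orientation-fixed, so reverse-complement matching
would be wrong.

Pairs that cannot reach the identity threshold are skipped by a 12-mer
prefilter: a candidate pair must share at least two distinct 12-mers. This
is provably conservative for the configured length range — a >95%-identity
match over ≥90% of a ≥120 bp sequence spans ≥108 bp with at most 5
mismatches, and by pigeonhole its match segments contain far more than two
exact 12-base windows. The prefilter is an optimization only: the
brute-force path (`prefilter = FALSE`, a full alignment for every candidate
pair) is retained and the test suite asserts the two produce identical
clusters on a 300-sequence pool of progenitors and variants.

Cross-host comparison applies the same rule per ordered catalog pair: a
query gene is "shared" when it has at least one identical partner in the
target. The source methodology's phrase "two and more genes" is read as
presence/absence of sharing (at least one partner), which is what a
sharing-pattern Venn describes; the literal ≥2-partners variant is exposed
as `min_partners = 2`. Whether the original comparison ran in nucleotide or
protein space is unstated; nucleotide space is used here.

## Relative abundance and aggregation

For gene counts $x_i$ and lengths $L_i$ in one sample, $b_i = x_i / L_i$
and $a_i = b_i / \sum_j b_j$. This inverts length-proportional read
sampling: $a_i$ estimates copy abundance, not read share. Counts are
assumed uniquely assigned; multi-mapping resolution is upstream of this
package. Genus and KO profiles sum member-gene abundances; genes without a
label are pooled under `__unassigned__` so every profile column still sums
to one and stays compositional. The enterotype stage is the only consumer
that drops `__unassigned__` (and renormalizes), because cluster structure
should reflect the annotated composition.

Core features are those with strictly positive abundance in every sample of
a host — presence is presence, with no minimum-abundance floor, since any
threshold would be an arbitrary second parameter.

## Richness

Richness uses sample-incidence: $S_{obs}$ features observed, $f_1$ seen in
exactly one sample, $f_2$ in exactly two. The bias-corrected Chao1
estimator

$$\hat S = S_{obs} + \frac{f_1 (f_1 - 1)}{2 (f_2 + 1)}$$

is the default because it is defined at $f_2 = 0$; the classical
$S_{obs} + f_1^2 / (2 f_2)$ sits behind `bias_corrected = FALSE`. Coverage
is $100 \cdot S_{obs} / \hat S$.

The rarefaction curve draws $m$ samples *with replacement* (100 repetitions
per $m$) and reports the mean and s.d. of the Chao1 estimate, plus the mean
observed richness of the drawn samples. Two caveats are worth stating
plainly. First, a sample drawn twice counts twice in the incidence.
Second, the Chao1 estimate targets the *total* richness at every $m$, so
its curve is roughly flat — and at $m = 1$ every observed feature is a
singleton, making the estimate strongly upward-biased there. The familiar
saturating curve is the observed-richness column (`s_obs_mean`), which is
the quantity that is non-decreasing in $m$; the suite checks monotonicity
on it and checks the Chao1 column against an independent resampling oracle.

## Enterotype-like clustering

Genus profiles are compared by the root Jensen-Shannon divergence with
natural-log entropy,
$d(P,Q) = \sqrt{H\!\left(\tfrac{P+Q}{2}\right) - \tfrac{H(P)+H(Q)}{2}}$,
which is a metric bounded by $\sqrt{\ln 2} \approx 0.8326$. A pseudocount
of $10^{-9}$ (renormalized) keeps zero components finite without visibly
moving distances.

Samples are clustered by partitioning around medoids (PAM, BUILD + SWAP) on
this distance. The source methodology names PAM in one place and
hierarchical clustering in another; PAM on root-JSD is primary here because
it is the standard of the enterotype literature, and average-linkage
hierarchical clustering is available via `method = "hclust"`. No rule for
choosing the number of clusters is stated either; the Calinski-Harabasz
pseudo-F, computed directly from the distance matrix via
$\sum_{i \in C} d^2(x_i, \bar x_C) = \frac{1}{|C|}\sum_{i<j \in C} d^2(x_i, x_j)$,
is maximized over k = 2..8 — again the convention of that literature.
Each cluster's *driver genus* maximizes the ratio of within-cluster to
outside-cluster mean abundance (ties: higher within-cluster mean, then
alphabetical). Ordination is classical PCoA of the distance matrix with a
deterministic sign convention (the largest-magnitude coordinate on each
axis is made positive).

## Differential abundance and reporter scores

Two-group comparisons use the Wilcoxon rank-sum test with mid-ranks: the
exact null when both groups have ≤12 tie-free samples, otherwise the normal
approximation with tie and continuity corrections. The approximation is
accurate in the body of the p distribution and conservative in the far
tail, which the suite asserts explicitly. Multiple testing uses
Benjamini-Hochberg. Marker selection thresholds the *raw* p-value by
default (0.01 for gene markers, 0.05 for genus- and phage-level markers) —
whether the original marker counts used raw or adjusted p is unstated, so
the choice is an explicit, recorded argument.

Pathway enrichment follows the reporter-score procedure. Per KO occurring
in more than five samples, a one-tailed Wilcoxon p is BH-adjusted and
transformed, $Z_{KO} = \Phi^{-1}(1 - q)$, with $q$ clamped to
$[10^{-10}, 1 - 10^{-10}]$ so the transform stays finite. Per pathway with
$k$ scored members,

$$Z_{pathway} = \frac{1}{\sqrt{k}} \sum Z_{KO}, \qquad
  Z_{adjusted} = \frac{Z_{pathway} - \mu_k}{\sigma_k},$$

where $\mu_k, \sigma_k$ summarize 1000 random draws of $k$ KOs (without
replacement) from the universe of scored KOs, aggregated identically.
Pathways with the same $k$ share one seeded background so their scores are
comparable. $Z_{adjusted} \ge 1.6$ (the 90%-confidence normal quantile,
inclusive) flags a pathway as enriched. Because the direction of the
one-tailed test is not stated in the source methodology while results are
reported per diet, both directions are computed and each pathway carries a
`direction` column.

One calibration subtlety: under a data-level null, BH-adjusted q-values
clump near 1, so the per-KO Z distribution is far from normal and the tail
of $Z_{adjusted}$ beyond 1.6 is mildly inflated relative to the normal
tail even after standardization. The calibration study
(`study_reporter_null()`) therefore plants the null where the procedure's
own contract places it — uniform *adjusted* p-values, giving exactly
standard-normal member scores — and recovers the nominal tail
$1 - \Phi(1.6) \approx 0.055$. A 500-KO universe is used there so that 200
random pathways do not share too few scores.

## The simulator and what it does (not) emulate

The simulator generates: multiple host catalogs of uniform-random ORF-like
sequences with verbatim cross-host copies planted per gene with the
configured pairwise probability; redundant variant sets (substitutions at
uniform positions plus optional 3′ truncation — no indels, so identity
targets are exact and overlap is controlled independently); and per-sample
counts. Counts arise from per-gene log-normal(0, σ) base abundances,
optionally reshaped at the genus level by a Dirichlet mixture (one
component per enterotype cluster, the cluster's driver genus boosted), then
multiplied by diet fold-changes in the enriched group, length-weighted, and
drawn multinomially at fixed depth. Effects multiply *after* the Dirichlet
reshaping so genus-level fold changes survive the enterotype structure.
Annotations (a fixed 15-genus taxonomy, 200 KOs, 20 pathways of 5–25 KOs)
are thinned independently per rank.

Key defaults and why:

* **20 samples, two groups of 10** — the study design this package
  emulates.
* **Pairwise sharing 0.4** — the order of the published macaque-human
  catalog overlap, and the planted value the comparison stage is asked to
  recover (tolerance ±0.05).
* **σ = 1.5, reads = 10⁵, genes 300–1500 bp** — a heavy-tailed abundance
  distribution at a depth where length normalization recovers true
  abundances (Spearman ρ ≥ 0.9 at 200 genes).
* **Annotation rates: phylum 0.65, genus 0.14, species 0.09, KO 0.53,
  phage 0.15** — mirroring the annotation fractions reported for real
  catalogs. These are deliberately sparse; analyses that need dense genus
  or KO structure (the enterotype and reporter studies, the analysis/
  drivers) raise them explicitly in their configs.
* **Enterotypes: k = 3, drivers Prevotella / Lactobacillus / Ruminococcus,
  boost 10, concentration 200** — drivers land at roughly 30–50% relative
  abundance in their cluster, the range reported for real enterotypes, with
  within-cluster noise small enough that the structure is real but not
  degenerate. No empirical effect sizes are published for the diet
  contrast, so the default fold-changes planted by the analysis scripts
  (3, and 0.4 for a depletion) are package choices, labeled as such.

What the simulator does *not* emulate: sequencing error and FASTQ-level
reads, assembly chimerism, host contamination, multi-mapping ambiguity,
phylogenetic correlation between genes of one genome, and indel variation
between redundant gene copies. Passing tests therefore demonstrate that
the implementations are correct and well calibrated on communities with
these idealizations — not that the pipeline is robust to assembly or
alignment artifacts, which are out of scope upstream stages.

## Numerical choices and degenerate inputs

* Dereplication ties (equal length) break lexicographically by id; greedy
  assignment always takes the *first* matching representative in creation
  order, so results are order-deterministic.
* JSD uses natural logs; `sqrt` of a numerically tiny negative divergence
  is clamped to 0.
* All-zero samples are an error in `gene_abundance` (they are upstream
  failures, not data); empty catalogs, k > n, σ_k = 0 backgrounds, and
  estimated richness below observed all fail fast with named messages.
* Every stochastic entry point takes a seed and restores the caller's RNG
  state; identical config + seed reproduces every artifact byte-for-byte.
* Problem sizes in the shipped studies (500-gene catalogs, 300-sequence
  dereplication pools, 20-sample cohorts, 50 power replicates, 1000
  background draws) were chosen so each study completes in minutes on one
  CPU while leaving the Monte-Carlo bands meaningfully narrow.

## Known limitations

* The aligner delegates to Biostrings' Smith-Waterman; tie-broken optimal
  alignments with equal score but different identity are theoretically
  possible, though not for the substitution-only variant model used in
  validation.
* Chao1 at one sample is a formula evaluation, not a useful estimate (see
  above); consumers should read coverage off the full-cohort estimate.
* The reporter background draws KOs independently of pathway topology;
  overlapping pathways are scored independently, as in the original
  procedure.
* With fewer than ~120 bp sequences the k-mer prefilter's conservativeness
  argument weakens; the package targets gene-length (≥300 bp) inputs.
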