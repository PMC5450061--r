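---
title: "Identifying neoplastic cells in whole-tumor scRNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying neoplastic cells in whole-tumor scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellverdict)
```

## The problem

A dissociated tumor biopsy profiled by single-cell RNA-seq is a mixture of
neoplastic cells and infiltrating stromal and immune cells. Expression
clustering alone separates these populations imperfectly: clusters mix
stochastically, and neoplastic cells can express immune-associated genes.
When a matched tumor/blood exome-seq experiment is available, however, the
tumor's genomic fingerprint — its large-scale copy-number variants (CNVs),
the skewed variant-allele frequencies (VAFs) of germline SNVs inside those
CNVs, and its validated somatic SNVs — can be looked up cell by cell in the
transcriptome. cellverdict integrates four per-cell evidence sources into a
`neoplastic` / `non_neoplastic` / `ambiguous` verdict:

1. presence/absence of exome-defined large-scale CNVs, tested per cell
   against a non-malignant control;
2. allele patterns of heterozygous germline SNVs in regions of copy-number
   loss (monoallelic expression supports the loss, biallelic contradicts it);
3. expressed somatic SNVs validated in exome-seq;
4. hierarchical clustering in tumor-/immune-marker space.

The worked model system throughout is a primary glioblastoma with a clonal
gain of chromosome 7 and loss of chromosome 10 and a
macrophage/microglia (TAM) infiltrate, but every gene list and threshold is
configurable.

## Expression-based CNV evidence

Counts are normalized to counts per million (CPM; every nonzero cell column
scaled to sum to $10^6$; all-zero columns are kept and flagged). Genes are
ordered along each chromosome by annotated start coordinate, ties broken
lexicographically and strand ignored — adjacency is purely positional.

**Window profile.** For each cell, mean CPM is computed in sliding windows
of $w = 100$ adjacent genes (step 1; windows never cross a chromosome
boundary, so a chromosome with $n \ge w$ genes yields exactly $n - w + 1$
windows) and compared against the mean over control cells of the same
window statistic:

$$\mathrm{log2FC}_{i,c} \;=\; \log_2
  \frac{\overline{\mathrm{CPM}}_{i,c} + p}
       {\frac{1}{|N|}\sum_{n \in N}\overline{\mathrm{CPM}}_{i,n} + p}$$

with pseudocount $p = 1$ CPM (avoids $-\infty$ on silent windows; at
typical window means of hundreds of CPM its bias is negligible). A clonal
single-copy loss is expected near $-1$, a single-copy gain near
$\log_2 1.5 \approx +0.585$. The control mean is taken over per-cell window
means, not pooled reads, so units stay cell-comparable. Overlapping windows
(step 1) maximize positional resolution; the window mean itself is what
suppresses single-gene stochastic up/down-regulation.

**Exome segments.** Tumor/blood depth-ratio bins are scanned for maximal
runs of consecutive bins all above $1 + \delta$ (gain) or below $1 - \delta$
(loss), with $\delta = 0.2$ and a minimum span of 10 Mb. Only such
large-scale events are testable per cell — the whole approach rests on
averaging away single-gene noise over many genes. A run covering at least
90% of its chromosome's binned span is flagged whole-chromosome and takes
every annotated gene on the chromosome as its gene set; otherwise a gene
belongs to the segment when its start coordinate falls inside it.

**Per-cell test.** Each cell's segment statistic — the sum-total CPM over
segment genes — is placed within the empirical distribution of the same
statistic over control cells (mid-rank quantile $q$ for ties; at least 20
control cells required). The CNV is called present when the cell falls
outside the one-sided $\alpha = 0.05$ band of the control distribution:
$q > 1 - \alpha$ for a gain, $q < \alpha$ for a loss. The test is
distribution-free by design — no parametric form is assumed for the
control statistic. One-sided is the default because exome-seq fixes the
direction of each event, which buys power; `sided = "two"` splits
$\alpha$ between the tails for users who prefer a direction-agnostic band.
A degenerate control distribution (all values equal) yields `absent` with
an explicit flag rather than a silent call.

## Germline and somatic SNV evidence

**Informative sites.** Heterozygous germline sites are anchored at blood
VAF 0.5 (tolerance `het_tol = 0.1`); a site is informative when its tumor
VAF shifted by at least `shift_min = 0.15` and it lies inside an exome
segment. Sites in gain segments are kept (allelic imbalance) but flagged by
segment direction; only loss segments support the strict monoallelic
argument. Biology fixes the 0.5 blood anchor and the "both alleles"
outlier criterion, but not numeric cutoffs; the defaults are deliberately
conservative and exposed in `pipeline_params()`.

**Allele patterns.** Per cell and site: `no_coverage` below
`min_reads = 3` total reads; `biallelic` when both alleles have at least
`min_minor = 2` reads (two-read minimum absorbs singleton sequencing
errors — no explicit error model is fitted); otherwise `ref_only` /
`alt_only` (ties to reference). Per cell: `biallelic_observed` if any site
is biallelic, `monoallelic_consistent` if at least one covered site and
none biallelic, else `uninformative`.

**Somatic tallies.** A somatic site is detected in a cell when its alt
allele has at least `min_alt = 1` read; what "expressed" means for a
somatic SNV is not standardized, so the threshold is exposed, defaulting
to the most sensitive choice — these sites are already exome-validated, so
a single alt read is meaningful.

## Marker-space clustering and the decision table

Cells are clustered over $\log_2(\mathrm{CPM}+1)$ vectors of the combined
tumor + immune marker panel (complete linkage, Euclidean distance, cut at
$k = 2$). Determinism comes from `stats::hclust`, whose merge order is
fixed for a given distance matrix. The immune-majority cluster is the one
with the higher mean immune-marker expression — automatic and
deterministic. Default marker lists (`default_marker_genes()`) are the
canonical GBM stem/tumor panel (CD44, PROM1, NES, KLF4, MYC, NANOG, STAT3,
SOX2, MET) and a TAM/microglia panel; both are plain config.

The verdict is a total, pure function of the four votes:

* **neoplastic** — (CNV `supports_tumor` *or* somatic tally $\ge 1$) and
  the germline pattern does not contradict (no biallelic site inside a
  loss segment called present in that same cell);
* **non_neoplastic** — every segment cleanly absent, somatic tally 0,
  germline `biallelic_observed` or `uninformative`, and the cell sits in
  the immune-majority cluster;
* **ambiguous** — everything else; contradictory strong evidence (somatic
  SNV + biallelic-in-present-loss) is additionally flagged as a conflict.

Two design choices deserve emphasis. Clustering is corroborative only: it
can confirm `non_neoplastic` but never alone makes a cell neoplastic,
because expression clustering mixes stochastically. And mutational
evidence takes precedence over transcriptional evidence on conflict — a
ranking the source material implies but never states; cells where strong
mutational signals disagree are surfaced as flagged `ambiguous`, never
resolved silently.

## Cycling cells

Expression is transformed to $E = \log_2(\mathrm{CPM}/10 + 1)$ — the
convention of the glioma single-cell literature this score descends from;
the 1.2 threshold is only meaningful on this scale, which is why both the
formula and the threshold are config-exposed. A cell's score for a gene
set is the mean $E$ over the set minus the mean $E$ over all measured
genes; the centering makes the score invariant to adding a constant to
every gene's $E$. A cell is cycling when the average of its G1/S and G2/M
scores strictly exceeds 1.2, and is assigned the dominant phase when one
score exceeds the other by more than 0.3 (default), `intermediate`
otherwise. The shipped G1/S (replication) and G2/M (mitosis) sets of 12
genes each are editable defaults; the score definition is the module's
central documented ambiguity, since no universal standard exists.

## Ligand–receptor crosstalk

For each pair in a user-supplied database, the ligand must be expressed by
at least 20% of sender cells (inclusive) with mean expression strictly
above 2 CPM over *all* sender cells (zeros included); the receptor rule
mirrors these thresholds by default, with a documented
`receiver_any_expression` relaxation, since "expressed in tumor cells" is
all the source logic requires of receptors. "Expressing" means CPM
strictly above `expressed_floor = 0`. Whether the mean should run over
expressing cells only is genuinely open; all-cells is the default because
it is the harsher and more reproducible convention, and the floor is
switchable. Output is sorted by ligand then receptor; tightening any
threshold yields a subset.

## The synthetic-data generator

`simulate_bundle()` emulates the structure the classifier assumes, with
full truth labels:

* **Genome**: 2,400 genes, 200 per chromosome over chr1–chr12, laid
  uniformly (100 kb spacing) so window logic sees realistic adjacency.
* **Counts**: negative binomial with log-normal gene base means
  (meanlog $\log 3$, sdlog 1.2), log-normal cell library factors
  (sdlog 0.25), dispersion 0.3, thinned by logistic mean-dependent dropout
  with midpoint 0.3 counts and slope 2. These dropout parameters
  concentrate dropout in lowly expressed genes (about 6% of entries
  overall, a full-length-protocol regime) and were chosen analytically so
  the dropout-induced bias on window log2FC stays small: the model's
  expected window log2FC is $-1.02$ for fold 0.5 and $+0.59$ for
  fold 1.5. The NB + logistic-dropout form is the simplest standard
  scRNA-seq noise model; amplification noise and 3′ bias are summarized
  under dropout, not modeled mechanistically.
* **Populations**: 180 neoplastic + 20 immune biopsy cells (10% immune)
  and 120 control cells. Neoplastic cells carry every configured CNV
  clonally (default chr7 gain fold 1.5, chr10 loss fold 0.5 — the
  symmetric pair keeps library composition, hence CPM, stable); immune and
  control cells carry none. Tumor markers are boosted 6× in neoplastic
  cells, TAM markers 8× in immune cells.
* **Variants**: 12 germline het sites (8 on the highest-expressed chr10
  genes, where single-cell coverage is realistic; 4 neutral on chr8),
  blood VAF ≈ 0.5, tumor VAF ≈ 0.15/0.85 in the loss. Allele reads arise
  only where the site's gene is expressed in the cell (site detection
  tracks expression level), with per-allele dropout 0.2 and zero
  sequencing error; neoplastic cells in the loss emit a single clonally
  retained haplotype. 30 somatic sites on well-expressed genes emit alt
  reads only in neoplastic cells at rate 0.053 per expressed site, set so
  about two-thirds of biopsy cells carry at least one expressed somatic
  SNV, matching the worked example this scenario emulates.
* **Cell state and crosstalk**: 20% of neoplastic cells cycle (phase set
  boosted 8×, the companion set 4×, on cycle genes pinned at the median
  base mean so non-cycling scores center near zero); 5 true
  ligand–receptor pairs (immune-boosted ligands, tumor-boosted receptors)
  are planted among 50 decoys that fail on one side by construction.

What passing tests on this generator do **not** show: robustness to batch
effects, doublets, ambient RNA, UMI saturation, subclonal CNVs, or
cell-type-specific dropout — none of which are modeled. The generator
validates the logic and calibration of the pipeline, not its performance
on any particular real dataset.

## Numerical choices and degenerate inputs

* Mid-rank quantiles handle ties in the empirical test; with $n$ controls
  the null present-rate is $\lceil \alpha n\rceil/(n+1) \approx \alpha$.
* All-zero cells survive CPM normalization unchanged and flagged; all-zero
  cells score 0 in every phase score.
* Duplicate gene rows collapse by summation (deterministic, conservative
  for window means); duplicate annotation records keep the first after
  positional sorting.
* VCF positions are 1-based; BED input is converted to 1-based closed on
  read. Chromosomes order naturally (chr1…chr22, chrX, chrY) unless
  overridden.
* Clustering tie-breaks are delegated to `stats::hclust`; oracle
  comparisons in the test suite use tie-free data.
* Test and acceptance problem sizes — 200 biopsy cells, 120–1,200
  controls, 2,400 genes, 1,000 null cells for calibration — are the
  package's chosen balance between statistical resolution (e.g. the exact
  binomial 95% band around a 5% rate at $n = 1000$ is [3.7%, 6.4%]) and
  the few seconds each run takes.

## Known limitations

The CNV test requires exome guidance (no de novo CNV discovery) and a
non-malignant control measured on a comparable platform. Tumors without
large-scale CNVs leave evidence source 1 uninformative, and verdicts then
lean on sparse SNV evidence, inflating `ambiguous`. The germline argument
is strict only in loss regions. No statistical significance is attached to
crosstalk candidates — the thresholds are a screen, not a test, and no
null model is defined. Batch correction, variant calling and alignment are
out of scope: variants arrive as VCFs from the DNA side.
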