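---
title: "Identifying PPBC-like cells in mammary single-cell RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying PPBC-like cells in mammary single-cell RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Post-partum breast cancer (PPBC) has been characterized by a high cell-cycle
score, loss of p53, and the activity of a 14-transcription-factor regulon.
`ppbclike` implements the computational side of asking whether an analogous
cell state exists in the mouse mammary gland around lactation: given
single-cell UMI counts from two genotypes (a C57 nuclear background carrying
either its own or an NZB mitochondrial genome) sampled non-lactating (NL) and
at day 21 of lactation (LacD21), three mice per group, it

1. annotates the epithelial compartment into luminal alveolar (AV), luminal
   hormone-sensing (HS) and myoepithelial (ME) cells from marker panels,
2. scores every barcode for a 6-gene proliferation list and the 14-gene
   regulon,
3. calls **PPBC-like** the barcodes that co-exceed an adaptive cutoff on both
   scores,
4. counts p53-expressing (Trp53-detecting) luminal HS cells per sample, and
5. compares genotypes with replicate-level Welch t-tests.

A separate branch partitions bulk RNA-seq differential-expression gene sets
across lactation days and genotypes into exclusive and common Venn regions.

## The score and the half-max cutoff

The per-cell score for a gene list $G$ is the log2-transformed combined
feature sum

$$s_i = \log_2\!\Big(1 + \sum_{g \in G} x_{ig}\Big),$$

where $x_{ig}$ is the depth-normalized count. The classification cutoff for a
list is **half of the maximum** score, the maximum taken over all barcodes of
all samples pooled — one cutoff per list for the whole experiment. A cell is
PPBC-like when it passes the cutoff for *both* the proliferation list and the
regulon. Because the cutoff is set at half of an observed maximum, it adapts
to the dataset; because positivity additionally requires a strictly positive
score, an all-zero score vector produces no calls rather than all calls.

Two details of the score are genuinely underdetermined and are therefore
explicit, recorded parameters rather than silent assumptions:

* **Pseudocount.** Raw feature sums can be zero, so the log is taken of
  `pseudocount + sum` with default 1 (an all-zero cell scores exactly 0).
* **Normalization.** The default rescales each cell to the median per-cell
  total, so sequencing depth cannot masquerade as signature activity. The
  median total is measured in units of the smallest positive matrix entry —
  on raw UMI counts that unit is 1, so this is precisely "scale every cell to
  the median total", and measuring the target this way makes the normalized
  matrix, every score, every threshold and hence every call *exactly*
  invariant under a global rescaling of the counts. Both choices can be
  toggled (`normalization = "none"`, `pseudocount`).

The gene lists ship in `inst/extdata/signatures.json` and load with
`ppbc_signatures()`. They are stored verbatim; in particular the published
proliferation list contains `Bud1`, which may be a typographical variant of
`Bub1` — scoring reports signature genes absent from a matrix rather than
auto-correcting symbols. `Esr1` legitimately appears in both the HS marker
panel and the regulon.

## Cell-type annotation

Each marker panel is scored the same way, panel scores are z-standardized
across cells (panels differ in length and baseline, so raw argmax would favor
long panels), and the label is the argmax panel when its z-score is positive,
otherwise `unassigned`; exact ties break in the fixed order AV < HS < ME. This
per-cell rule is deterministic and exactly testable; a clustering front-end
(the original analysis labeled Loupe clusters) is deliberately out of scope,
and ambiguous cells may be assigned differently than a cluster-level rule
would.

## The simulator

`simulate_cells()` draws UMI counts gene-wise from a negative binomial with
variance $\mu + \mu^2/\text{size}$. Per-gene baseline means are log-normal;
per-cell depth factors are log-normal and multiply $\mu$ (not post-hoc
thinning), so fold changes act on the mean and the NB family — and the exact
testability of depth normalization — are preserved. Each cell gets a type
(marker genes of that type elevated `marker_fold`-fold), each condition
plants PPBC-like cells with probability `ppbc_fraction[condition]`
(proliferation and regulon genes elevated `ppbc_fold`-fold), and luminal HS
cells in configured conditions have Trp53 forced to structural zero with
probability `trp53_silencing[condition]`. Structural zeros (rather than a
reduced mean) make p53 positivity — a detection call, raw count > 0 — exactly
known in truth labels. Planted PPBC-like cells are HS with probability 0.61
by default, mirroring the reported HS share of that population; the rest
split between AV and ME by their fractions.

The defaults encode the full study design: 2 genotypes x {NL, LacD21} x 3
mice, 2000 cells per sample, 1000 genes; alveolar expansion during lactation
(AV fraction 0.40 NL vs 0.60 LacD21); an elevated PPBC fraction (0.03 vs
0.005 elsewhere) and Trp53 silencing (0.8) only in NZB-LacD21.

### How the emission defaults were chosen

The free emission parameters have no empirical anchor (the underlying
matrices are not public) and are chosen to give the planted-label recovery
tests power, not to imitate real library sizes. The reasoning, in the
package's own terms:

* The half-max cutoff lives in log2 space, so it equals the *geometric mean*
  of 1 and the maximum linear feature sum: baseline cells must stay below
  roughly the square root of the top planted cell's sum, while planted cells
  must stay above it. A large activation fold with a small baseline sum
  maximizes that margin on both sides, hence `ppbc_fold = 16` on a per-gene
  baseline of median 0.1 (6-gene baseline sums near 0.7, planted sums near
  11).
* Off-type marker expression is what confuses the z-argmax annotation: with
  per-gene baseline 0.1, a 5-gene panel is detected in a minority of
  off-type cells while `marker_fold = 16` puts own-type scores far outside
  the off-type noise.
* NB size 10 (mild overdispersion) and depth log-sd 0.2 keep tails thin
  enough that the pooled maximum — and with it the cutoff — is stable.

What the simulator deliberately does **not** model: doublets, ambient RNA,
batch effects beyond per-cell depth, gene-gene correlation, and realistic
library sizes. Passing recovery tests therefore demonstrates that the
pipeline's logic is correct under its own assumptions, not that the
thresholds would behave identically on real nuclei data.

## Bulk Venn logic

`de_filter()` applies the strict cutoffs adjusted p < 0.05 (boundary genes
excluded) with sign of the log2 fold change; a fold change of exactly zero is
in neither direction. `venn_partition()` computes the $2^k - 1$ disjoint
regions of 2-3 named sets by exact per-gene membership, and
`cross_genotype_unique()` splits two genotypes' gene sets into shared and
unique pieces. DE tables are accepted as *inputs*: the original bulk DE was
produced by an external vendor pipeline and is not reimplemented; tables read
without a `padj` column get an honest Benjamini-Hochberg adjustment computed
from `pvalue` and are flagged. `simulate_bulk_de()` builds per-day tables
with deterministic block membership (a seeded permutation sliced into a
common core and day-exclusive blocks, per direction), so expected region
counts are exact.

## Statistics

* **Welch t** (unequal variance, Welch–Satterthwaite df) is used for
  replicate-level contrasts despite the original wording "Student's t-test",
  because n = 3 groups with unequal variances are the norm here; zero-variance
  groups get a machine-epsilon-scaled variance floor so fully separated
  degenerate groups return a finite, extreme statistic. The pooled test is a
  one-line change if wanted; the choice is recorded in the report manifest.
* **BH** is used wherever "adjusted P" is required; the original adjustment
  method is unstated, so this is a documented assumption.
* **Per-gene DE** between cell groups uses a two-sided Wilcoxon rank-sum test
  (normal approximation, tie-corrected, no continuity correction) on
  log2(1 + normalized) expression, since the original browser's internal test
  is not described; genes with identical values in both groups get p = 1.
  The top-gene rule is raw p < 0.0002, ordered by p, then |log2fc|, then
  symbol (deterministic ties), truncated to 40.
* **Heatmap ordering** is average-linkage agglomeration on 1 - Pearson
  correlation; zero-variance rows take correlation 0 (distance 1).
* **Tumor volume** is the modified ellipsoidal formula
  $V = \tfrac{1}{2} L W^2$.

## Problem sizes used in the test suite

The unit suite exercises reduced simulations (300 genes, 400-500 cells per
sample) so the default run stays fast; the recovery and direction checks that
define the pipeline's headline behavior run at the full design scale (1000
genes, 2000 cells x 12 samples) over 5 and 20 seeds respectively, and the
null calibration of the replicate t-test uses 2000 Monte-Carlo replicates.
These sizes are the package's own choices and are stated here so results can
be reproduced exactly.

## Known limitations

* The half-max cutoff depends on a single observed maximum, so it is
  sensitive to outlier barcodes; per-experiment pooling (the default, per the
  published wording "among total barcodes") stabilizes it across samples but
  a doublet-rich dataset would call conservatively.
* Per-cell marker argmax can disagree with cluster-level labeling near
  cluster boundaries.
* The convenience bulk DE for synthetic data (Welch t on log2 CPM) is not the
  original vendor method and is only intended to feed the Venn logic in
  examples and tests.
```{r setup, eval = FALSE}
library(ppbclike)

report <- run_pipeline(simulation_config(seed = 1),
                       bulk_tables = simulate_bulk_de(seed = 1))
glance(report)
tidy(report)          # replicate-level Welch t-tests
autoplot(report$classification)
plot_type_proportions(report$proportions)
```
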