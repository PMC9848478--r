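---
title: "Methods: spike-in normalized chromatin-state analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-in normalized chromatin-state analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistate)
```

# The problem

Cell types that undergo genome-wide epigenetic resetting — primordial
germ cells are the canonical case — can lose or gain a histone
modification globally. Depth normalization is blind to such changes:
if every region loses half its H3K27me3, read *shares* are unchanged
and a depth-normalized comparison reports no difference. The remedy is
an exogenous chromatin spike-in (fly cells added at a fixed fraction of
the target cell number, 1/20 here): when target chromatin shrinks, the
spike-in claims a larger share of the library, and the ratio of spike
reads across samples calibrates absolute abundance.

This package implements that quantitative comparison as a reusable,
tested pipeline: spike-in factors, reproducible peak retention,
rule-based combinatorial chromatin states over an eight-mark panel
(5mC, H3K9me3, H3K27me3, H2aK119ub, H3K4me3, H3K4me1, H3K27ac, ATAC),
cross-cell-type state transitions, threshold-based expression
categories and differential calls for per-copy transposable-element
(TE) analysis, TE-to-promoter proximity links, a self-organizing map
for multi-assay integration, and the effect-size statistics used for
reporting. A synthetic-data generator with known ground truth closes
the loop: every stage is validated by recovering what was planted.

# Normalization model

For region $r$ (length $L_r$) and IP sample $s$:

$$NC_{r,s} = f_s \cdot
  \frac{c^{IP}_{r,s} + \varepsilon}{\hat c^{input}_{r,s} + \varepsilon}
  \Big/ (L_r/1000),$$

where $\hat c^{input}$ is the paired input count scaled to the IP
sample's mapped-read depth, $\varepsilon = 0.5$ keeps zero counts
finite, and $f_s = G/\text{spike}_s$ with $G$ the geometric mean of
spike read totals across all IP samples of the same antibody. The
published description names the ingredients (input, length, spike
factor) but not the functional form; the ratio form above is
symmetric, scale-free and finite on zeros, and we document that
published per-region values are not bit-reproducible from it. Only
ratios of factors within an antibody group are identifiable; the
geometric-mean reference fixes the scale so the factors multiply to 1.

Two caveats are deliberate:

* Inputs carry no spike-in in the protocol, so they are depth-scaled,
  not spike-scaled.
* A factor computed from *raw* spike read totals is only comparable
  across samples sequenced to matched depth. The synthetic world
  therefore sequences all IP libraries of an antibody group to matched
  nominal depth; with wildly unequal depths a per-depth spike rate
  would be needed, and the reference used in the published analysis is
  not stated.

# Peaks and occupancy

Peak calling itself is out of scope (peak files from an external
caller are read directly); a minimal Poisson-window caller exists so
synthetic tests can run end-to-end. The ENCODE-style retention rule is
implemented exactly: a pooled-replicate peak is kept if it overlaps
(by at least 1 bp — the convention; the source is silent) peaks in
both biological replicates or in both pooled pseudoreplicates, then
filtered at FDR $< 10^{-3}$ (histone) or $< 10^{-4}$ (ATAC).
Pseudoreplicates are seeded random halves, $\lfloor n/2\rfloor$ and
$\lceil n/2\rceil$.

A region is *occupied* by a mark when it overlaps a retained peak
**and** its replicate-mean $NC$ exceeds the mean $NC$ of negative
regions. The published analysis does not define its negative set; the
default here is the same-kind regions overlapping no retained peak,
and the set is user-overridable. 5mC occupancy comes from region-mean
methylation (CpGs with coverage strictly above 5x; unweighted mean;
regions with no qualifying CpG are undefined and called unoccupied)
with a configurable threshold, default 0.5 — published counts are
threshold-dependent and not reproduced.

# States, transitions, enrichment

The repressive set is $\{$5mC, H3K9me3, H3K27me3, H2aK119ub$\}$, the
active set $\{$H3K4me3, H3K27ac$\}$. A region is *bivalent* when both
sets are represented, *repressive*/*active* when only one is, and
*neutral* otherwise. H3K4me1 and ATAC are carried as flags outside the
classifying sets, so an H3K4me1-only region is "neutral (H3K4me1)",
matching the usage in the source analysis; the categories partition
any region set by construction. Transition tables cross-tabulate exact
repressive signatures between two cell types; "de novo" occupancy
means an empty signature becoming non-empty. Family enrichment is
observed/expected under background proportions, with Cohen's $w$ as
the table-level effect size.

# Expression and methylation

Per-copy TE expression is on the $\log_2(\mathrm{RPKM}+1)$ scale,
where the "million" counts only protein-coding-mapped reads. Category
thresholds are the published ones (TE: 0.4/1.4; gene: 1.5/5.0,
boundaries inclusive on the left exactly as printed). The
differential rule — at least 4-fold change with the higher value above
0.4 — is read on this scale as $|\Delta| \ge 2$: whether the published
4-fold was taken on RPKM or RPKM+1 ratios is unstated; our reading is
exact for values $\gg 1$ and conservative near zero, and is flagged as
an interpretation. External model-based significance (e.g. from a
count model) can be AND-combined when supplied.

# TE-gene links

TEs anchor at their midpoint (the published tool's internal anchor is
unstated) and link to the nearest TSS strictly within 100 kb, signed
negative upstream in gene orientation, ties broken to the smallest
gene id. Correlations of TE and gene expression changes are Pearson,
overall and in signed distance bins (default 10 kb). A TE
up-regulated in the target cell type is called putatively regulatory
when it lies upstream and carries an active mark or ATAC signal.

# Self-organizing map

The SOM is implemented from scratch: 10 x 10 grid, 5000 online cycles,
learning rate linearly declining 0.09 to 0.01, matching the published
configuration. "Circular grids" is read as toroidal (wrap-around)
topology — the testable interpretation — and is configurable off. The
neighborhood is a bubble with initial radius at the 2/3 quantile of
grid distances, shrinking linearly to zero (so training ends as online
k-means); a Gaussian neighborhood is available. The distance metric is
Euclidean; the published map's metric and neighborhood are unstated,
so node-level reproduction of the published maps is explicitly not a
goal. Codebooks initialize uniformly within each feature's data range:
initialization inside the data cloud can be transiently *degraded* by
the wide-radius ordering phase, whereas range-uniform initialization
makes the quantization-error trajectory decrease, which is the
contract the tests check. Signal features are $\log_2(x+1)$-transformed
then z-scaled; methylation (already a bounded fraction) is z-scaled
only. Constant features are dropped with a warning, regions with
undefined methylation with a message.

# Effect sizes

Wilcoxon $r = |Z|/\sqrt{N}$ with tie- and continuity-corrected normal
$Z$ and $N$ the total observation count in both modes (for paired
data some references use the pair count instead; the two differ by a
constant $\sqrt 2$). Exhaustive enumeration of rank assignments is
used as the test oracle at $n \le 10$, where the approximation tracks
the exact normal score to within 0.08. Cohen's
$w = \sqrt{\chi^2/N}$. Reporting levels: $n$ below 0.2, `*` to 0.3,
`**` to 0.5, `***` at or above 0.5.

# The synthetic world

The generator's defaults state one fixed world; they are not tuned:

* Genome: 2 chromosomes of 1.5 Mb; 120 promoters ([-2000, +500)
  TSS windows on a jittered grid, strand random) and 240 TEs
  (0.3-3 kb), placed without overlap and with a 500 bp margin —
  TE copies and promoter annotations are disjoint in practice, and
  the margin keeps one region's fragment pileup out of its neighbor's
  occupancy call.
* States: drawn per region from a joint (cell A, cell B) distribution
  over mark subsets encoding the germline biology — global 5mC loss
  with derepression, H3K9me3 retention (3x biased toward young
  families SVA/L1HS/ERVK), Polycomb compensation at formerly
  methylated regions, stable active and bivalent compartments.
* Counts: negative binomial (dispersion 10), 100 IP reads/kb on
  occupied regions vs 4 on unoccupied, inputs flat at 20 per region;
  IP means scale with region length so the ratio-over-length
  normalization is a length-free abundance measure. Fragments (150 bp,
  one per counted read, plus uniform intergenic background at the
  unoccupied rate) feed the peak caller. Under a global abundance
  multiplier the per-region *shares* are unchanged — exactly the
  blindness spike-ins address — and only the spike total moves, as
  depth x 1/20 / multiplier.
* Expression: category-coupled bases (repressive near 0, active past
  the "expressed" threshold) give the bimodal distribution the
  thresholds assume; 20% of TEs carry planted upward deltas in
  2.5-4, nulls are jitter truncated to [-1, 1]; linked genes inherit a
  rho = 0.5 correlated delta from their nearest linked TE. Values are
  clamped at 0 (the scale's natural floor), which mildly distorts
  table-level deltas; the exact-rho construction is exposed separately
  as `simulate_link_deltas()` and used for correlation-recovery tests.
* Methylation: about 10 CpGs per region, Poisson coverage (mean 15),
  beta-binomial per-CpG levels around 0.85 (5mC-occupied) or 0.10.
* One RNG stream per output type, derived from the master seed, so
  adding an output never perturbs the others.

What a green test does *not* establish: the generator has no
mappability structure, no multi-mapping TE reads, no local chromatin
biases, no replicate batch effects, and its input libraries are flat
per region. Recovery at 100% of regions here is a statement about the
pipeline's correctness at the stated signal-to-noise, not about
real-data performance; the published per-dataset counts and
percentages depend on the deposited human data and are intentionally
not acceptance surfaces.

# Pipeline

`run_all()` executes simulate, normalize, peaks, occupancy, states,
transitions, express, link, som and stats in order, writing TSV
outputs atomically under one directory with a JSON manifest (content
hashes, parameter hash, seed, package version). Unchanged stages are
skipped unless forced. Configuration is a plain R object or JSON (the
declared environment carries no YAML parser; JSON preserves the same
schema checking, and unknown keys are rejected by name). The default
synthetic run completes in well under a minute on one CPU.

# Known limitations

* The minimal peak caller is a global-background Poisson scan for
  synthetic tests only; local-lambda backgrounds, fragment-model
  estimation and IDR are out of scope.
* Wilcoxon paired-mode $N$ and the 4-fold reading are documented
  interpretations (above).
* Depth-comparability of raw spike totals is assumed (matched
  sequencing depth), as discussed under normalization.
* The SOM is the classical online algorithm; batch/hexagonal/supervised
  variants are not provided.
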