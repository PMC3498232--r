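---
title: "Methods: time-course heat-stress analysis and promoter cis-element statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-course heat-stress analysis and promoter cis-element statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panicleHeat)
```

# The experimental design and the expression model

The package targets the classic single-channel microarray time course:
an untreated control (CK) and five durations of continuous heat
(20 min, 60 min, 2 h, 4 h, 8 h), two biological replicates each, twelve
arrays in all. All analysis happens on the log2 scale. The processing
order is the GeneSpring-era convention: quantile normalization across
arrays, baseline-to-median centering of each probe, replicate QC,
detection-flag filtering, then fold changes.

Three choices in this stage deserve spelling out, because the underlying
workflow descriptions in the literature usually leave them implicit:

* **Fold changes are differences of replicate-mean log2 values**, i.e.
  `log2FC(p, t) = mean(log2 x[p, t]) − mean(log2 x[p, CK])`. This is the
  log of the ratio of geometric means, not the ratio of arithmetic
  means; on log2-transformed array data it is the standard convention.
* **"More than 3-fold" is strict**: a probe qualifies at a time point
  when `|log2FC| > log2(3)`. A probe at exactly 3-fold does not.
* **Direction is free to vary across time points.** The heat-responsive
  (HR) definition — differential in at least 2 of the 5 time points —
  counts a probe that is 3-fold up early and 3-fold down late. This is
  deliberate: early-down/late-up temporal clusters exist, and their
  members must be able to reach the HR set. The all-time-point (Venn)
  intersection likewise requires a differential call at every time
  point, not a consistent direction.

Detection flags (P/A/M, Present/Absent/Marginal) gate the analysis: a
probe is kept when at least 6 of its 12 measurements are `P`. Missing
flags are treated as `A` (conservative). For non-standard sample counts
the threshold rescales to `ceiling(n/2)` with a warning. Gene-level sets
use the any-probe rule — a gene is in a set as soon as one of its probes
is — which reproduces the usual dual "genes (probes)" accounting without
inventing a probe-summarization model.

# Clustering and pattern labels

HR profiles are partitioned with Euclidean k-means, k = 12 by default.
The input space is the 12 normalized, median-centered sample columns
(so cluster shapes reflect the full replicate structure); the 5-point
log2FC rows can be passed instead. Because the classic desktop tools do
not document their initialization, determinism had to be designed in:
`kmeans_cluster()` uses k-means++ seeding under a caller-supplied seed,
Lloyd iterations, 10 restarts with the best within-cluster sum of
squares kept, and an emptied cluster is re-seeded from the point
farthest from its centroid. Plain random initialization was not
acceptable here: with 12 well-separated planted archetypes it visibly
merges/splits clusters in a sizable fraction of runs, while k-means++
recovers the planted partition essentially always.

Pattern labels formalize what is usually done by eye. A centroid is
reduced to its 5-point log2FC profile (per-time-point means minus the CK
mean, so labels are invariant to constant shifts of all samples), and
windows are early = {20 min, 60 min, 2 h}, late = {4 h, 8 h}. With the
threshold `up_thresh` (default 1.0 on log2, i.e. 2-fold): continuous-up
when all five points clear it; early-/late-up when only that window's
mean clears it; mirror rules for down; early-down-late-up when the early
mean is at or below the negative threshold and the late mean at or above
the positive one; otherwise `mixed`. The explicit precedence (continuous
first, then the sign-reversing class, then single-window classes)
resolves the overlaps among these conditions.

Category over-representation per cluster uses the same upper-tail
hypergeometric machinery as the promoter statistics (below), reporting
raw p-values with the conventional 0.05 flag. No multiple-testing
correction is applied by default — matching how such cluster
annotations are traditionally reported — but a Benjamini–Hochberg column
is one argument away (`bh_correct = TRUE`).

# Promoter cis-element statistics

Promoters are the −3000..−1 region upstream of the ATG; coordinates in
all outputs are 1-based and promoter-local (truncated promoters are
legal, so local coordinates are the only unambiguous ones). Scanning is
deterministic degenerate-consensus matching of IUPAC strings on both
strands: every offset is tested, overlapping matches are all reported, a
reverse-strand match is reported at the forward coordinate of its
leftmost base, and `N` in a sequence matches nothing. A position-weight
matrix mode is out of scope: PlantCARE-style element libraries are
consensus strings, and consensus matching makes every downstream count
exactly reproducible.

All statistics are **gene-level**: a motif "occurs" in a gene if it has
at least one match anywhere in the promoter, and a motif pair
"co-occurs" in a gene if any occurrence of one lies within the window
(250 bp by default) of any occurrence of the other — measured
**start-to-start**, strand ignored, counted at most once per gene no
matter the multiplicity. Start-to-start is a choice (edge-to-edge and
center-to-center are equally defensible); it is symmetric, simple, and
monotone in the window, and the window is a visible argument everywhere.
Self-pairs are excluded: co-occurrence edges connect distinct elements.

With `m` of the `M` cluster genes and `n` of the `N` database genes
containing a motif, the enrichment ratio is `(m/M)/(n/N)` and the
p-value is the upper tail
`P(X ≥ m)` for `X ~ Hypergeom(N, n, M)`, accumulated via `lchoose()` so
large gene counts cannot overflow, and clamped to (0, 1]. The
co-occurrence test is the identical tail on the pair counts
(`t` of `T` cluster genes, `k` of `K` database genes). A motif absent
from the database (`n = 0`) has undefined enrichment and is skipped.
Significance classes follow the Cytoscape rendering convention — node
shape diamond (p < 0.001), triangle (0.001 ≤ p < 0.05), circle
otherwise; edge solid (p < 0.01), dashed (0.01 ≤ p < 0.05), absent at
p ≥ 0.05. A p-value landing exactly on a class boundary falls into the
*less* significant class: the conventional legend intervals are open, so
the boundaries had to be assigned, and rounding down the claimed
significance is the conservative direction. Raw p-values are reported
(BH optional, off by default), matching the tradition of these network
figures.

Node attributes map as: size = `m` (genes in the cluster containing the
motif), color = enrichment ratio, shape = significance class; only
p < 0.05 edges are written. `write_network_sif()` emits the SIF plus
node/edge attribute tables that Cytoscape imports directly.

# qPCR relative quantification

`delta_delta_ct()` implements 2^(−ΔΔCT) with the reference gene
(actin1 by convention) and CK as calibrator. Technical replicates are
averaged **on the CT scale** (the usual practice; averaging RQ instead
changes little but is not what the method's derivation assumes), ΔCT and
ΔΔCT are formed within each biological replicate, and RQ is averaged
over biological replicates with its SD reported — so error bars reflect
biological, not technical, spread. RQ of the calibrator is exactly 1 by
construction, and RQ is invariant to any per-condition CT shift that
affects target and reference alike (e.g. input amount).

# What the synthetic generators emulate — and what they do not

The generators exist so that every stage has a ground truth.

* `generate_expression_dataset()` draws per-probe log2 baselines
  (`N(8, 2)` by default), adds the planted archetype log2FC at treatment
  time points, and adds i.i.d. Gaussian cell noise. Intensities are
  generated directly on the log2 scale; the linear scale never exists.
  Flags are i.i.d. `A` with the configured rate, else `P`. The twelve
  default archetypes mirror the canonical temporal patterns (one early
  down, one early-down/late-up, one late down, one continuous down, four
  early up, three late up, one continuous up).
* `generate_promoter_set()` draws i.i.d. background sequence at a
  configurable GC content (default 0.43, typical of rice promoters) and
  plants concrete instantiations of IUPAC motifs at uniform
  non-overlapping positions; pair plants put the second motif exactly
  `distance` bp (start-to-start) after the first. Cluster index 0 in the
  planting tables targets the background genes, so background
  co-occurrence rates can be set too. Ground truth lists planted sites
  only — chance matches in the random background are real matches for
  the scanner but are not ground truth, which is exactly the situation
  with real promoters.
* `generate_qpcr_plate()` builds CT values so that the noiseless
  2^(−ΔΔCT) equals the requested fold change, with 2 biological × 3
  technical replicates and Gaussian CT noise.

What they deliberately do **not** model: probe sequence effects, dye and
batch effects, spatial array artifacts, intensity-dependent variance,
dinucleotide or repeat structure in promoters, motif positional bias
toward the transcription start, and amplification-efficiency differences
in qPCR. Passing the simulation-based tests therefore shows the
*algorithms* are correct and calibrated under clean assumptions; it does
not certify performance on real arrays, where normalization and flag
quality do real work.

# Numerical choices and problem sizes

* Hypergeometric tails are exact log-gamma sums, cross-checked in the
  test suite against both `phyper` and exhaustive subset enumeration
  (all parameterizations with N ≤ 12 agree to < 1e−12).
* Quantile normalization delegates to `limma::normalizeQuantiles(ties =
  TRUE)`: ties within a column receive the mean of their tied
  rank-means.
* k-means is seeded; identical seeds give identical partitions. The
  final assignment is verified to be a fixed point of reassignment.
* Degenerate inputs: single-column quantile normalization is a warned
  no-op; zero-variance samples yield undefined correlations reported as
  QC failures; all-identical rows with k > 1 warn; empty clusters in the
  enrichment functions error.

The validation simulations are sized to be decisive yet quick: 1,000
probes for zero-noise recovery; 720 profiles (12 archetypes × 60) at
noise SD 0.05 for clustering recovery; a 240-gene promoter database
(200 background + one 40-gene cluster, 3 kb promoters) for planted
enrichment (80% vs 10%) and pair co-occurrence (60% vs 2% at 100 bp);
and 100 null simulations of a 200-gene database with 1 kb promoters for
type-I calibration, where the empirical rejection rate at α = 0.05 sits
slightly below nominal — the expected mild conservatism of a discrete
test statistic.

# Known limitations

* Consensus scanning has no match-quality score; a PWM/FIMO-style mode
  would be needed to rank degenerate matches.
* The co-occurrence window convention (start-to-start) differs from
  edge-to-edge by up to one motif length; conclusions near the window
  boundary should be checked at both conventions.
* The hypergeometric co-occurrence test conditions on the database pair
  count and ignores promoter length heterogeneity; strongly truncated
  promoters deflate both `k` and `t` but not necessarily at the same
  rate.
* No multiple-testing correction is applied by default anywhere; with
  large motif libraries, enable the BH options.
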