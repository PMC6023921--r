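---
title: "Methods: dissecting IAHC formation from single-cell UMI counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting IAHC formation from single-cell UMI counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological setting and what the package computes

Definitive haematopoietic stem cells (HSCs) arise in the mid-gestation mouse
aorta: haemogenic endothelial (HE) cells convert to blood through an
endothelial-to-haematopoietic transition (EHT) and accumulate as intra-aortic
haematopoietic clusters (IAHCs) containing HSC precursors (pre-HSC type I,
CD45^-^, and type II, CD45^+^) and committed progenitors.  CEL-Seq single-cell
UMI profiling of the sorted populations — non-HE, HE, EHT, IAHC cells,
pre-HSCs, yolk-sac HSPCs — plus whole mechanically picked clusters (wIAHCs)
turns several questions into well-defined computations, and `iahctools`
implements that computational core as a reusable, tested pipeline:

1. **In silico purification** of IAHC cells by marker transcript thresholds
   (`purify()`), removing mesenchymal, erythro-myeloid-progenitor-like (EMP)
   and sub-aortic-patch contamination that no antibody panel fully avoids.
2. **Exact downsampling normalization** of every cell to a common number of
   unique transcripts (`downsample_cells()`).
3. **Clustering and pseudotime ordering** of cells along the EHT axis
   (`cluster_cells()`, `order_cells()`).
4. **Sliding-window differential expression** along pseudotime with an own
   negative-binomial Wald test (`de_test()`, `windowed_de()`).
5. **Transcription-factor temporal programs and correlation networks**
   (`smooth_profiles()`, `cluster_tf_profiles()`, `build_network()`).
6. **Swap-search deconvolution** resolving each wIAHC bulk into its `n`
   constituent single cells (`deconvolve()` and its aggregations).

A synthetic-data generator (`simulate_cells()`, `simulate_wiahcs()`) emulates
the study design with full ground truth, so every stage is validated by
parameter recovery rather than by eye.

## The synthetic-data generator

The generator is the package's statement of the study conditions, not a
tuning knob.  Counts for gene $g$ in cell $c$ are negative binomial,
$x_{gc} \sim \mathrm{NB}(\mu_{gc}, \phi)$ with variance
$\mu + \phi\mu^2$ and a shared dispersion $\phi = 0.3$ (a typical UMI-level
value).  Per-cell mean vectors are relative weights normalized so the
expected total equals `mean_depth = 12000` unique transcripts, the CEL-Seq
calibration of the emulated experiment.

* **Background genes** carry static log-normal weights
  (`sdlog = 1.2`) — no temporal structure.
* **Opposing gradients**: the endothelial panel (*Vwf, Cdh5, Pecam1, Gja4,
  Gja5*) follows a decreasing logistic curve of true time $t \in [0,1]$, the
  haematopoietic panel (*Kit, Runx1, Mpo, Mt1, Rac2, Ptprc*) an increasing
  one.  *Gpr56* rises at the EHT and stays high in cluster-resident
  populations while staying at noise level in contaminants.
* **Contaminants** (mesenchymal, EMP-like, sub-aortic) sit off the
  differentiation axis (no true time) and express their own marker panels
  (*Epha7, Crabp1, Cxcl12, Pdgfrb, ...*; *Csf1r, Fcgr3*; *Gata3, Cdkn1c*).
* **TF archetypes**: three panels of 12 TFs follow Gaussian bumps peaking at
  $t = 0.15, 0.5, 0.85$ (pseudotime 4.5 / 15 / 25.5 after scaling), the
  early / intermediate / late temporal programs.
* **Population inventories**: `scenario_e11()` totals 554 cells
  (27 non-HE / 45 HE / 43 EHT / 58+55 sorted pre-HSCs / 44 YS HSPCs); the
  282 purified IAHC cells carry no published sub-population split, so the
  package allocates 91/91/100 of them to preHSC-I/preHSC-II/progenitor.
  `scenario_e10()` totals 464 cells (39/96/116 non-HE/HE/EHT, 73 IAHC split
  40/33, 140 YS HSPCs).  Per-cell true times are normal around each
  population's centre (sd 0.05, clipped to $[0,1]$).
* **wIAHC pseudo-bulks** are *exact* element-wise sums of 3–30 member cells
  drawn from the cluster-resident populations, so deconvolution correctness
  is separable from measurement noise; Poisson resampling is an opt-in
  stress mode, and ventral/dorsal labels are assigned with identical member
  composition on both sides (the published finding at the level where it is
  testable).  Real wIAHC cell numbers per cluster are not tabulated in the
  literature; the default 3–30 range is a configurable judgement call.

What passing tests on these data do **not** show: robustness to ambient RNA,
batch effects, doublets, cell-cycle structure, or read-level artefacts — none
of which the generator emulates.

## Preprocessing

**Downsampling.**  Each cell's retained profile is a uniform sample without
replacement of exactly `depth = 5000` UMIs from its pool (jointly
multivariate hypergeometric across genes); cells below the target depth are
discarded and listed.  This equalizes sampling noise across cells at the cost
of discarding information — the trade the emulated protocol makes.

**Purification.**  The thresholds are read literally as strict integer
inequalities: keep a cell iff it has *more than one* *Gpr56* transcript
(≥ 2) and *no more than two* transcripts of every non-IAHC marker (reject on
≥ 3).  The full exclusion list was never published as a table; the default
unions the named mesenchymal/EMP/sub-aortic markers and is replaceable.
Purification runs on **raw** counts by default: the published order of
operations is unstated, and raw counts preserve the most evidence about
marker presence; this is configurable.  In `run_pipeline()` the rule applies
only to the sorted c-kit^+^ pool (IAHC-type populations plus contaminants,
`purify_pool`) — the separately sorted non-HE/HE/EHT/YS populations enter by
sort identity, mirroring the emulated workflow.

**Gene filter.**  Genes expressed with ≥ 5 transcripts in ≥ 1 cell enter the
pseudotime embedding.

## Trajectory inference

Analyses of this system conventionally use RaceID2 for clustering and
Monocle for pseudotime.  Those tools are prior contributions, not this
pipeline's, and their internal settings are rarely reproducible from a
methods section alone, so the package ships documented stand-ins chosen as the *simplest fully specified methods*
whose outputs the downstream stages need:

* `cluster_cells()`: PAM k-medoids on $1 - r$ (Pearson) distance of
  $\log_2(1+x)$ profiles; `k` by average silhouette over 2–10 unless fixed.
* `order_cells()`: two principal components of $\log_2(1+x)$ over the
  filtered genes, a minimum spanning tree over cells in that plane,
  pseudotime as distance along the tree's diameter path (off-path cells
  projected to their nearest path node), min–max scaled to $[0, 30]$.

The $[0,30]$ scale is a convention chosen so that the canonical
"10 pseudotime units" window spans a third of the axis; it matches the
published visual scale but is not itself a measured quantity.  Orientation is
anchored: the end with higher mean endothelial-marker expression is time 0
(implemented as the sign of the correlation between path position and mean
anchor expression, which reverses exactly when the anchor panel is swapped
for the haematopoietic one).  Ties in pseudotime break by cell identifier.
Fidelity is judged solely by recovery of the generator's true time
(Spearman $|\rho| \ge 0.8$ on both default scenarios; the tests observe
≈ 0.95).

## Differential expression

`de_test()` is an own negative-binomial Wald test in the DESeq role: per
gene, method-of-moments dispersion pooled across the two groups (floored at
$10^{-8}$), statistic $(\log\bar{x}_A - \log\bar{x}_B)/\mathrm{SE}$ with
$\mathrm{SE} = \sqrt{(1/\mu_A + \phi)/n_A + (1/\mu_B + \phi)/n_B}$, normal
two-sided p-values and Benjamini–Hochberg correction.  A group-following
pseudocount of $0.5/n$ keeps the swap symmetry exact.  The published
significance threshold is unstated; the default is FDR 0.05 with no
fold-change cutoff, both configurable.  Cell-cycle "correction" is realized
as pre-test exclusion of a user-supplied gene list (`exclude_genes`) — the
original procedure is unstated.  Cells are treated as replicates
(pseudo-replication), as in the emulated analysis; the tests therefore
validate calibration under the generator's independence assumptions, not
under biological replication.

`windowed_de()` slides a width-10 window (step 1) along pseudotime and
compares the first five units against the second five; windows are half-open
except at the end of the axis (so the maximum-pseudotime cell is counted),
and half-windows with fewer than 3 cells yield `NA` rather than an error.

`overlap_test()` is the exact upper-tail hypergeometric test used for
comparing significant-gene lists between studies.

## TF programs and networks

Because most TFs are lowly expressed, profiles are smoothed along pseudotime
before anything else: a truncated rolling mean over the `window_cells`
nearest cells in rank order.  The published smoothing method is unspecified;
the default window, `max(5, 10% of cells)` made odd, is strong enough to
rescue dropout yet preserves three distinguishable peaks, and it is a logged
parameter.  TFs are kept when their smoothed maximum reaches one transcript.
Profiles scaled to unit maximum are clustered by complete-linkage
hierarchical clustering on $1 - r$ (shape, not amplitude, defines the
programs), cut at $k = 3$, and labelled I/II/III by ascending mean peak
pseudotime.  Constant profiles have undefined correlation; they are placed by
peak time alone and flagged.  The network keeps edges with $|r| \ge 0.4$
(threshold unpublished, configurable, recorded in the output).
`cross_stage_cluster_overlap()` computes, per cluster, the shared /
stage-only proportions over the union of TFs carrying the label at either
stage.

## wIAHC deconvolution

Each bulk's constituent cell count `n` is known from imaging and is an
input — no estimation of `n` is attempted.  Per restart the search
initializes with `n` distinct reference cells uniformly at random and
proposes 10,000 uniform member/non-member swaps, accepting a swap iff the
Pearson correlation between the transformed member-sum and the transformed
bulk strictly increases; 100 restarts from fresh starts guard against local
optima.  The published description labels this "MCMC" while describing
selection of the highest-correlation set; the default is therefore greedy
hill-climbing, with an optional Metropolis mode (`acceptance =
"metropolis"`, acceptance probability $e^{\Delta r / T}$) preserving the
stochastic-chain reading.  The correlation space is likewise unstated;
default $\log_2(1 + \text{counts-per-10k})$, raw-space by flag.

Numerically: when the reference has integer entries and uniform column
totals (the post-downsampling case) the scale factor $10^4/S$ is invariant
under swaps, and the transform of every candidate member-sum is evaluated
through an exact lookup table over integer gene sums — this is what makes
$2\times10^7$ objective evaluations tractable in seconds, with a direct
evaluation fallback for general references.  Aggregations use final member
sets only: `contribution_probability()` (fraction of restarts containing a
cell; sums to `n` by a counting identity), `cluster_contribution()`
(per-restart member fractions, mean across restarts), and
`pseudotime_density()` — a probability-weighted Gaussian KDE with Silverman
bandwidth and **boundary reflection** at both ends of the axis so the
density integrates to 1 over $[0, 30]$ within $10^{-3}$.
`wiahc_similarity()` reproduces the bulk–bulk similarity structure: Pearson
correlation of transformed bulk profiles, Euclidean distance between rows of
that correlation matrix, average-linkage leaf order for heatmaps.

## Reproducibility and problem sizes

All randomness flows from one root seed; `derive_seed(seed, stage)` gives
each stage an independent, reproducible sub-seed, and identical
configuration plus seed reproduces every artifact byte for byte.  The test
suite exercises the default scenarios at their native sizes (554 and 464
cells, 2,000 genes), the windowed-DE null across 20 independent simulations,
and the deconvolution contracts on a 200-reference-cell, 20-bulk panel at
the full default search size; these sizes were chosen as the smallest ones
at which the published design is represented faithfully.

## Known limitations

* The trajectory stand-ins (PAM, PCA+MST) are deliberately simpler than
  RaceID2/Monocle; on real data with branching topologies the diameter-path
  assumption of a single 1-D trajectory may fail.
* The NB Wald test with moment dispersion is slightly anti-conservative for
  very small groups; the windowed counts should be read as a profile along
  pseudotime, not as calibrated per-gene inference.
* Greedy swap acceptance can stall in local optima for very large `n`;
  restarts mitigate but do not bound this.
* The generator draws genes independently given the archetypes; co-expression
  beyond the planted structure (and hence correlation-network topology on
  real data) is not emulated.
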