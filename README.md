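# iahctools

Computational dissection of haematopoietic stem cell emergence in the mouse
aorta from single-cell UMI counts.

During mid-gestation, haemogenic endothelial (HE) cells lining the aorta
convert to blood through an endothelial-to-haematopoietic transition (EHT)
and pile up as intra-aortic haematopoietic clusters (IAHCs) containing
HSC precursors (pre-HSC type I/II) and committed progenitors.  `iahctools`
implements, as a tested reusable pipeline, the analyses this system calls
for when profiled by CEL-Seq single-cell RNA-seq:

* **In silico purification** of IAHC cells by marker transcript thresholds —
  keep cells with more than one *Gpr56* transcript, reject cells with more
  than two transcripts of any non-IAHC (mesenchymal / EMP / sub-aortic)
  marker (`purify()`).
* **Exact downsampling** of every cell to a fixed number of unique
  transcripts, multivariate-hypergeometric per cell (`downsample_cells()`).
* **Clustering and pseudotime**: k-medoids on correlation distance
  (`cluster_cells()`) and a PCA + minimum-spanning-tree ordering scaled to
  [0, 30] with an endothelial anchor at time 0 (`order_cells()`).
* **Sliding-window differential expression** along pseudotime: an own
  negative-binomial Wald test with BH correction, applied in width-10
  windows split 5/5 (`de_test()`, `windowed_de()`), plus exact
  hypergeometric gene-list overlap (`overlap_test()`).
* **TF temporal programs**: smoothing along pseudotime, selection of TFs
  expressed after smoothing, hierarchical clustering into early /
  intermediate / late programs (I/II/III), and Pearson correlation networks
  (`smooth_profiles()`, `cluster_tf_profiles()`, `build_network()`).
* **wIAHC deconvolution**: resolve a whole-cluster bulk profile of known
  cell number *n* into the best-matching set of *n* reference single cells
  by random-swap search — per restart, 10,000 member/non-member swaps
  accepted on strict Pearson-correlation improvement, 100 restarts — then
  per-cell contribution probabilities, per-cluster contribution fractions,
  and contribution densities along pseudotime (`deconvolve()` and friends).
* A **synthetic-data generator** emulating the study design — negative
  binomial UMI counts at ~12,000 transcripts/cell, opposing
  endothelial/haematopoietic marker gradients, contaminant populations,
  three Gaussian-bump TF archetypes, and pseudo-bulk wIAHCs of known
  membership — so every stage is validated against ground truth
  (`simulate_cells()`, `simulate_wiahcs()`, `scenario_e11()`,
  `scenario_e10()`).

The model at the deconvolution core: for bulk profile $b$ and reference
cells $x_1,\dots,x_C$, find $S \subset \{1..C\}$, $|S| = n$, maximizing
$r\!\left(\,T\!\big(\textstyle\sum_{i\in S} x_i\big),\, T(b)\right)$ where
$r$ is Pearson correlation and $T = \log_2(1 + \text{counts-per-10k})$, by
greedy random swaps with restarts.  The DE statistic per gene is
$z = (\log\bar{x}_A - \log\bar{x}_B) \big/
\sqrt{(1/\mu_A + \phi)/n_A + (1/\mu_B + \phi)/n_B}$ with method-of-moments
dispersion $\phi$ and BH-adjusted normal p-values.

## Worked example

```r
library(iahctools)

sim <- simulate_cells(scenario_e11(contaminants =
         c(mesenchymal = 40L, `EMP-like` = 15L, subaortic = 15L)), seed = 1)
sim
#> Simulated IAHC dataset: 2000 genes x 624 cells
#>         EHT    EMP-like          HE mesenchymal      non-HE    preHSC-I
#>          43          15          45          40          27         149
#>   preHSC-II  progenitor   subaortic     YS-HSPC
#>         146         100          15          44
#> mean depth: 12017 UMIs/cell

ds <- downsample_cells(sim$counts, depth = 5000, seed = 2)

pool <- sim$annotation$cell[sim$annotation$population %in%
          c("preHSC-I", "preHSC-II", "progenitor",
            "mesenchymal", "EMP-like", "subaortic")]
pur <- purify(sim$counts[, pool])
length(pur$selected)   # 394 of 465 pool cells kept
head(pur$rejected, 2)
#>            cell            reason
#> 1 preHSCII_c305 contaminant:Fcgr3
#> 2 mesenchymal_c555      low-include

cells <- intersect(colnames(ds$counts),
                   c(setdiff(colnames(sim$counts), pool), pur$selected))
pt <- order_cells(ds$counts[, cells], seed = 3)
cor(pt$pt, sim$truth$cell_time[names(pt$pt)], method = "spearman")
#> 0.967

wde <- windowed_de(ds$counts[, cells], pt, window_spec())
wde[wde$center %in% c(5, 15, 20, 25), ]
#>    center n_a n_b n_sig
#> 1       5  68  15    19
#> 11     15  28 114    30
#> 16     20 114 111    38
#> 21     25 111 217    25
```

The significant-gene count peaks mid-axis, where the transition remodels the
transcriptome most.  Deconvolving a pseudo-bulk of 10 known cells against
438 reference cells:

```r
bulks <- simulate_wiahcs(sim, n_wiahcs = 1, size_range = c(10, 10), seed = 4)
ref <- ds$counts[, intersect(cells, names(sim$truth$cell_population)[
  sim$truth$cell_population %in%
    c("EHT", "preHSC-I", "preHSC-II", "progenitor")])]
dc <- deconvolve(bulks$counts[, 1], ref, 10, decon_config(seed = 5))
dc
#> wIAHC deconvolution: n = 10 members, 100 restarts x 10000 swaps (greedy, log2cp10k)
#> final correlation: mean 0.9853, range [0.9828, 0.9859]

pr <- contribution_probability(dc)
mean(pr[bulks$truth$wiahc_members[[1]]])
#> 0.98   # true members are recovered in ~98% of restarts
```

`run_pipeline(run_config(seed = 1L))` chains all stages and writes every
artifact (Matrix Market counts, TSV tables, GraphML network, JSON
deconvolution results) with a manifest and a seed-logged run log; the same
config and seed reproduce every file byte for byte.

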