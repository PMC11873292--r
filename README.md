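# panrc — pan-marker analysis of growth-plate resting-zone chondrocytes

The resting zone (RZ) of the mammalian growth plate harbors the
slow-cycling chondrocytes that act as the stem-cell reservoir for bone
growth, yet no single published marker labels all of them — the known
stem-cell markers *Pthlh*, *Axin2* and *Foxa2* each tag only small
subsets. `panrc` implements, as a tested R pipeline, the computational
analyses used to establish apolipoprotein E (*Apoe*) as a pan-marker of
resting chondrocytes (RCs):

* **Pan-marker screen** on clustered single-cell UMI counts. A gene
  passes for target cluster *T* when its in-cluster positivity fraction
  (cells with raw count > 0) exceeds 0.90 and its *minimum* pairwise
  log fold-change over every other cluster exceeds 1 (both strict):

      pct_T(g) = |{c ∈ T : x_cg > 0}| / |T|              > 0.90
      min_{O≠T} log2( (ȳ_T,g + 1) / (ȳ_O,g + 1) )        > 1

  with ȳ the cluster mean of depth-normalized (CP10K) expression.
  Passing genes are ranked by minimum logFC.
* **Positivity / co-expression analysis**: raw-count positivity calling,
  joint sign-pattern tables, k-positive counts and conditional
  positivity percentages — including an exact 1 359-cell fixture of the
  published RC-cluster joint table (`build_rc_fixture()`).
* **Zone extents** from labeled axial cell positions by exhaustive
  two-changepoint misclassification minimization.
* **Flow-cytometry gating tree** for the skeletal stem/progenitor
  signatures (SSC / pre-BCSP / BCSP within viable Lin− mCherry+ cells).
* **EdU pulse-chase simulator** for label-retention kinetics of slow- vs
  fast-cycling populations.
* **Simulators with ground truth** for all of the above: clustered
  negative-binomial counts with planted markers, bimodal flow events,
  division histories.

It is aimed at computational biologists who want these statistics as
plain, oracle-tested functions rather than embedded in a monolithic
single-cell framework.

## Worked example

Simulate the default five-cluster growth-plate design — 300 cells per
cluster, 2 000 genes, one planted pan-marker of the resting cluster
(positivity 0.95, fold change 16) and three planted subset markers at
the known stem-cell-marker positivity levels (0.17 / 0.02 / 0.04) — and
screen the RC cluster:

```r
library(panrc)
sim <- generate_counts(synthetic_spec(seed = 1))
scr <- pan_marker_screen(sim$matrix, sim$labels, target = "RC")
head(scr[, c("gene_id", "pct_in", "min_logfc", "passes", "rank")], 5)
#>     gene_id     pct_in min_logfc passes rank
#> 1 panMarker 0.96000000 3.7122302   TRUE    1
#> 2   subsetC 0.04666667 2.5840826  FALSE   NA
#> 3   subsetB 0.02000000 2.3600997  FALSE   NA
#> 4   subsetA 0.14333333 2.0929395  FALSE   NA
#> 5  gene1136 0.41000000 0.3241753  FALSE   NA
```

The planted pan-marker is the sole passing gene (positivity 0.96 > 0.90,
minimum logFC 3.71 > 1) and ranks first; the subset markers are highly
specific (logFC 2.1–2.6) but fail ubiquity, exactly the behavior that
distinguishes a pan-marker from a subset marker.

The published RC co-expression table is rebuilt and summarized by one
call:

```r
fixture_report()
#>                    quantity     value expected matches
#> 1                  pct_Apoe  97.00000       97    TRUE
#> 2                 pct_Pthlh  17.00000       17    TRUE
#> 3                 pct_Axin2   2.00000        2    TRUE
#> 4                 pct_Foxa2   4.00000        4    TRUE
#> 5             pct_Apoe_only  77.00000       77    TRUE
#> 6 pct_single_among_positive  95.01661       95    TRUE
#> 7      pct_Apoe_given_Pthlh  98.00000       98    TRUE
#> 8      pct_Apoe_given_Axin2 100.00000      100    TRUE
#> 9      pct_Apoe_given_Foxa2  89.00000       89    TRUE
```

Row by row: 97% of the 1 359 RCs are Apoe+ while Pthlh/Axin2/Foxa2 mark
only 17/2/4%; 77% of Apoe+ cells express none of the three subset
markers; among Apoe+ cells expressing at least one, 95.0% express
exactly one (the subsets are mutually exclusive); and 98/100/89% of
Pthlh+/Axin2+/Foxa2+ cells are Apoe+ — the subset markers sit almost
entirely inside the Apoe+ population.

The full workflow lives in `analysis/` as numbered drivers
(`01_simulate_screen.R`, `02_fixture_overlap.R`, `03_gating.R`,
`04_edu_kinetics.R`); each prints its findings and writes its tables
under `results/`. The methods vignette
(`vignettes/pan-marker-methods.Rmd`) documents the models, parameters
and design choices.

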