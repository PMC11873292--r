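---
title: "Methods: pan-marker screening and positivity analysis of resting-zone chondrocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-marker screening and positivity analysis of resting-zone chondrocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panrc)
```

## The scientific question

The growth plate of a growing long bone is stratified into a resting zone
(RZ), a proliferative zone (PZ) and a hypertrophic zone (HZ). The small,
round, quiescent chondrocytes of the RZ — resting chondrocytes (RCs) —
act as the stem-cell reservoir that feeds the proliferative columns.
Several genes (*Pthlh*, *Axin2*, *Foxa2*) mark stem cells in the RZ, but
each labels only a subset of RCs, so the RZ is usually delimited by
ambiguous histological criteria. The analyses implemented here ask: **is
there a single gene expressed by essentially all RCs and at much higher
levels than in every other growth-plate population** — a pan-RC marker —
and how do the known subset markers relate to it?

`panrc` implements the computational side of that question as a reusable
pipeline with simulated ground truth, so that every statistic can be
exercised and validated without access to the original sequencing data.

## The pan-marker screen

Given a cells × genes raw UMI count matrix and a per-cell cluster
labeling, a gene $g$ is a pan-marker candidate for target cluster $T$
when it is both

* **ubiquitous**: the positivity fraction
  $\mathrm{pct}_T(g) = \frac{|\{c \in T : x_{cg} > 0\}|}{|T|}$
  exceeds 0.90 (strict), where $x_{cg}$ is the raw count — a cell is
  "positive" when its count is greater than zero, with no threshold or
  normalization; and
* **specific**: the *minimum* pairwise log fold-change over all other
  clusters exceeds 1 (strict),
  $\min_{O \neq T} \log_2 \frac{\bar{y}_{T,g} + 1}{\bar{y}_{O,g} + 1} > 1,$
  where $\bar{y}_{K,g}$ is the mean over cluster $K$ of depth-normalized
  expression (counts scaled to 10 000 per cell; the log1p transform used
  for storage is inverted before averaging, so means are taken on the
  normalized count scale) and the pseudocount 1 stabilizes
  low-expression ratios.

Passing genes are ranked by minimum fold-change descending, ties broken
by positivity descending and then gene id ascending, so output order is
deterministic.

Design choices worth making explicit:

* **Normalization.** Cluster means are formed on depth-normalized counts
  (CP10K). Variance-stabilizing regression models exist for this purpose,
  but the screen's two statistics — positivity on raw counts and a ratio
  of cluster means — are robust to the choice, and a closed-form
  transform keeps the statistic exactly reproducible and testable against
  a brute-force oracle. Base, scale and pseudocount are all arguments.
* **log base 2** for fold-changes, the dominant single-cell convention.
* **Strict inequalities** at both thresholds: "> 90%" and "logFC > 1"
  are bounds, not inclusive cutoffs; a gene at exactly the threshold
  fails (this is asserted by a constructed boundary case in the tests).
* No p-values or multiple-testing correction: the screen is
  threshold-based, not test-based.

## The count simulator

`generate_counts()` provides ground truth for the screen. Its default
design emulates the five growth-plate chondrocyte clusters (RC plus
proliferative, prehypertrophic, hypertrophic and mitochondrial-rich
clusters), 300 cells each, 2 000 genes:

* **Background genes** draw NB(mean = 0.5, size = 2) identically in every
  cluster — realistic sparsity (≈ 65% zeros per gene) and
  overdispersion for shallow UMI data, and a guaranteed null: any
  background gene passing the screen is a false positive.
* **Planted markers** are parameterized by *in-cluster positivity*,
  *fold change* and *background mean* — the three quantities the screen
  measures. In the target cluster each cell is positive with exactly the
  requested probability (a Bernoulli mask), and positive cells draw a
  zero-truncated NB whose mean is solved (by `uniroot` on the truncated
  mean) so the realized cluster mean equals fold change × background
  mean. This mask-plus-truncation construction decouples positivity from
  fold change and realizes extreme designs exactly — positivity 1.0
  with background 0 yields a perfectly separating gene, which a
  post-hoc zero-inflation thinning of NB draws could not. When the
  background mean is 0 the magnitude scale is arbitrary and the
  positive-cell mean defaults to the fold-change value.
* The default plants one pan-marker (positivity 0.95, fold change 16)
  and three subset markers at positivity 0.17 / 0.02 / 0.04 — the
  positivity levels reported for the known RZ stem-cell markers — which
  must *never* pass the screen: they fail ubiquity however specific they
  are.

All randomness flows from the single integer `seed` via R's RNG under
`withr::with_seed`, so a spec plus seed is bit-reproducible. What the
simulator does **not** emulate: ambient RNA, doublets, per-cell depth
gradients, correlated gene modules, or variance-stabilized residual
structure. Passing the recovery tests therefore shows the statistics are
computed correctly and have the designed operating characteristics on
clean NB data — not that the thresholds are optimal on any real dataset.

## The resting-chondrocyte co-expression fixture

The published colocalization analysis of the 1 359-cell RC cluster
reports per-marker positivity for *Apoe*, *Pthlh*, *Axin2*, *Foxa2*, the
pairwise overlaps with *Apoe*, the single-positive fraction among
marker-positive *Apoe*+ cells, and the absence of triple positives.
`rc_fixture_spec()` stores a joint sign-pattern table consistent with
all of those sums, and `build_rc_fixture()` materializes it as a count
matrix (positive cells get count 1 — positivity is count > 0, so
magnitudes are irrelevant downstream).

Two cells of that joint table are *not* published: how the 15 *Apoe*+
double-positive cells split across marker pairs, and whether the 4
*Apoe*− *Pthlh*+ and 6 *Apoe*− *Foxa2*+ cells overlap. The default
assigns all 15 doubles to the Pthlh∩Foxa2 pair and keeps the *Apoe*−
positives disjoint. Any consistent completion yields identical values
for every published quantity; the tests assert only published sums, and
the spec constructor validates the published marginals on any
user-supplied table.

`overlap_analysis()` computes the full pattern table, per-marker
percentages, k-positive counts (restricted to reference-positive cells
when a reference marker is given, as the published analysis restricts to
*Apoe*+ RCs), and conditional positivity for every ordered marker pair.
Percentages are reported raw and rounded half-away-from-zero to integer
percent — the published precision (base R's `round` goes half-to-even,
which would round 2.5% down). Conditionals with an empty denominator are
`NA`, never 0. Internal coherence — pattern sums, marginal consistency,
inclusion–exclusion bookkeeping — is asserted on every construction.

```{r fixture}
fixture_report()
```

## Zone extents

`zone_proportions()` quantifies zone sizes from per-cell axial positions
labeled RZ/PZ/HZ. Because no boundary-fitting procedure is published for
this quantification, the package defines a concrete, testable one: fit
two changepoints minimizing label misclassification under
`pos < b1 → RZ, pos < b2 → PZ, else HZ`, scanning exhaustively over
candidate boundaries at the midpoints between adjacent distinct sorted
positions; ties resolve toward the smaller RZ (smallest `b1`, then
smallest `b2`). Extents are percentages of the span between first and
last cell and always sum to 100. The exhaustive scan is the definition,
and the test suite checks it against an independently written naive
enumeration.

## The gating tree

Flow populations are defined by a tree of Boolean threshold predicates:
viable (viability dye −) → lineage-negative (CD45− Tie2− Ter119−) →
mCherry+ → three leaves defined by surface signatures — BCSP
(CD51+ Thy− 6C3− CD105+), SSC (CD51+ Thy− 6C3− CD105− CD200+), preBCSP
(CD51+ Thy− 6C3− CD105− CD200−). Percentages are reported within the
mCherry+ denominator, matching the published scheme.

Gating conventions: thresholds are explicit per-channel numbers in the
tree (gates are operator-set in practice and none are published; the
synthetic default is 0 on a log-intensity scale with bimodal peaks at
±2, spread 0.5); `+`/`−` are strict — an event exactly at threshold is
negative; the BCSP (CD105+) branch is declared before SSC/preBCSP so the
CD105 decision takes precedence, though the three signatures are already
mutually exclusive by construction. Events are assigned to the first
declared population whose full ancestor chain they satisfy, so
assignment is disjoint and order-invariant.

`generate_flow_events()` draws events whose constrained channels sit
strictly on the required side of threshold (truncated normals), so every
simulated population event satisfies exactly its chain; "other" events
sit inside the denominator gate but are rejection-resampled until they
match no leaf, emulating the mCherry+ cells outside all three
signatures. Recovery of the planted fractions is then a pure binomial
sampling problem, which is what the acceptance property asserts (the
published ~18% / ~29.3% / ~2.8% carry "~" and are treated as simulation
fractions, not numeric targets). No compensation, spillover, doublet
modeling or FCS parsing is attempted.

## EdU pulse-chase kinetics

The label-retention experiment injects EdU daily for 8 days and samples
1, 4 and 14 days after the last injection. The simulator models each
cell as an independent renewal process: log-normal cycle times with the
requested mean and CV (CV 0 gives deterministic cycles), S phase
occupying the middle `s_phase_fraction` of each cycle (default 0.3,
i.e. ≈ 7 h of a 24 h cycle), and the pulse as one continuous window of
`24 × pulse_days` hours.

Labeling and detection rules:

* A cell is labeled when an **S-phase entry** falls inside the pulse
  window. Entry-based bookkeeping (rather than any S-interval overlap)
  gives the correct quiescent limit — a non-cycling population never
  labels — and differs negligibly from overlap for cycles much shorter
  than the 8-day pulse.
* Re-entering S during the pulse refreshes the label and resets the
  division counter.
* The label halves at each division; it is scored undetectable after
  more than `detection_divisions` (default k = 4, the conventional
  ~16-fold dilution limit; no value is published) divisions counted
  strictly after the labeled cycle's own mitosis. Under synchronized
  24 h cycles this yields EdU+ through chase day k and 0 after — the
  closed-form case the tests pin exactly.

The default populations contrast a slow pool (200 h mean cycle,
reporter-positive RCs) with a fast pool (30 h, columnar chondrocytes),
500 cells each, CV 0.25. The acceptance property asserts the designed
qualitative behavior: the fast population's EdU+ fraction is
non-increasing over the chase and falls strictly below the slow
population's by day 14. The published day-4 → day-14 uptick in the slow
population (attributed to divisions of labeled slow cyclers) is a
discussion point, not a quantified mechanism, and is deliberately not a
model requirement; likewise the printed "~" percentages are not numeric
targets. The model has no spatial component — labeled RCs transiting
into the proliferative zone between samplings are not represented.

## Numerical and I/O conventions

* In-memory counts are cells × genes; on-disk MatrixMarket follows the
  10x convention genes × cells (transposed at the I/O boundary), written
  in the 1-based `coordinate integer general` dialect next to
  `genes.tsv` / `barcodes.tsv`. Round-trip identity is property-tested
  on random sparse matrices for both supported formats.
* Identifiers are case-sensitive and whitespace-trimmed; gene symbols
  are not validated against any annotation.
* Validation errors localize the offense: the first bad entry by
  (cell, gene) coordinate, missing files by name, unknown markers by id.
* Problem sizes used by the test suite — 20-seed recovery runs at
  5 × 300 cells × 2 000 genes for the screen, 5 000 events for gating,
  500 cells per population for the pulse-chase, and ≥ 200 randomized
  ≤ 20 × 10 instances for the oracle-equivalence battery — were chosen
  as the package's standard verification conditions: large enough that
  binomial sampling bounds are tight, small enough to run routinely.

## Known limitations

* The screen's fold-change uses CP10K means, not variance-stabilized
  residuals; on real data with strong depth structure the ranking can
  differ from model-based pipelines, though the positivity criterion is
  identical by definition.
* The published end-to-end numbers that require the deposited sequencing
  data or histology images (the 41-gene screen result and its top
  fold-change, FISH percentages, measured zone extents, the measured
  EdU curves) are out of desk-reproducible scope; they are covered by
  the property suites on simulated ground truth, and the co-expression
  quantities are covered exactly by the rebuilt fixture.
* The gating engine classifies; it does not learn thresholds or model
  spillover.
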