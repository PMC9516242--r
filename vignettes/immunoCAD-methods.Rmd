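---
title: "immunoCAD: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{immunoCAD: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(immunoCAD)
```

This vignette documents the models behind each stage of the pipeline,
the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the design decisions taken
where the underlying analysis protocol left the choice open. No
empirical claim here goes beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The synthetic cohort model

CyTOF intensities are approximately log-normal per population; on the
`asinh(x/5)` scale a cell population is well described by a Gaussian.
The generator therefore draws, per cluster, marker values
$z \sim N(\mu_{cm}, \sigma_{cm})$ on the arcsinh scale and maps them
back through $x = 5\sinh(z)$, truncated at zero (raw mass-cytometry
intensities are nonnegative). This makes cluster recovery analytically
checkable: the planted location/dispersion structure is the ground
truth every clustering test compares against.

Cluster **abundances** vary between samples as a Dirichlet draw around
group-level weights, with concentration 200 by default. The source
analysis reports no between-sample variance model at all; 200 gives a
per-cluster frequency CV of roughly 15–25% at typical weights
(0.03–0.15), which is the order observed in published peripheral-blood
CyTOF cohorts. Group effects enter as log-fold shifts of the mixture
weights before renormalisation; marker effects as additive arcsinh
shifts.

Clinical covariates (age, BMI, TC, TG, HDL, LDL and the binary
comorbidities) are drawn per group from the published cohort summary
(means/SDs and rates), so the cohort statistics layer can be exercised
against realistic marginals. Structural channels use fixed stylised
distributions: DNA iridium ~ N(600, 60), event length ~ N(25, 3),
cisplatin viability folded-normal near zero for live cells.

Defaults are desk-scale — 2000 cells/sample, 25–29 markers, 13/38/32
samples per group — not the ~10^6 cells/sample of a real acquisition;
the generator accepts larger values but nothing in the test suite
needs them.

**Not emulated**: mass-channel spillover, barcoding chemistry and
debarcoding errors, acquisition-time cell debris beyond the injected
doublet/dead-cell artifacts, non-Gaussian marker skew within a
population, and zero-inflation from antibody dropout. A green test on
this world establishes that the *pipeline machinery* behaves as
specified, not that the biological conclusions of any real cohort
would reproduce.

## 2. Preprocessing

The chain is fixed as normalize → gate → transform, with gates acting
on **raw** intensities (thresholds quoted in cytometry practice are
raw-scale; transforming first would not change which events pass, but
the configuration would no longer be interpretable).

* **Bead normalization** is a simplified stand-in for reference-bead
  drift correction: bead events are identified on the bead channel
  (above half its maximum, provided beads are present at all), the
  acquisition is split into 10 time windows, and each window's mass
  channels are rescaled so its bead medians match the reference (first
  window, or user-supplied). A 20% linear sensitivity decay is
  inverted to within 1% (tested). The published passing-window
  regression normalizer is deliberately not reimplemented.
* **Gating** keeps events passing all of: event length ≤ max, every
  DNA channel within [min, max], viability ≤ max. The published
  procedure is manual gating in FlowJo with no numeric thresholds;
  the automated default derives them as median ± 4·MAD per channel,
  which tolerates up to ~25% contamination, and every threshold is
  overridable via `gate_config()`. Rules are conjunctive, so removal
  is order-independent; the report attributes removals per rule,
  exclusively and jointly.
* **Transformation** applies `asinh(x/5)` to lineage and functional
  channels only. The cofactor (default 5, the standard CyTOF choice)
  is a parameter; DNA/viability/length/bead channels stay raw.

Debarcoding is out of scope: the generator produces per-sample files,
mirroring an upstream demultiplexing step.

## 3. Clustering and annotation

Phenotypes are found on the pooled (all-samples) arcsinh matrix with a
kNN graph (exact neighbours, default k = 30, inverse-distance weights,
optional weak-edge pruning) partitioned by Leiden modularity, then
merged below a minimum community size (0.1% of events) into the most
strongly connected neighbour community. Per-sample assignments are
recovered by membership, which is what makes frequency tables
comparable across samples.

**Resolution default.** Modularity at resolution 1 on kNN graphs
fragments even a single homogeneous Gaussian blob into several
communities — an artefact of modularity on geometric graphs, not
structure. The package default is 0.3, at which (tested) one blob
yields one cluster, two separated blobs yield exactly two with ARI 1,
and a 15-component mixture at 5000 cells is recovered with ARI 1.
Users analysing data with finer substructure should raise it; it is a
first-class parameter everywhere.

**Annotation** applies ordered rules to each cluster's median profile:
granulocyte (CD66b+) → T (CD3+) → B (CD19+) → NK (CD56+) → myeloid
(CD14/CD33/CD11c/CD16), first match wins, otherwise `unassigned`.
T clusters split into CD4/CD8 × naive/central-memory/effector-memory/
effector (CCR7 × CD45RA), Treg (CD25+CD127−), γδ (TCRγδ+) and
double-negative; monocytes into classical (CD14+CD16−), intermediate
(CD14+CD16+) and non-classical (CD14−CD16+), plus mDC and M-MDSC
(CD14+HLA-DR−CD33+). Marker positivity uses a per-marker threshold:
a 1-D two-component split when the marker is clearly bimodal across
profiles (centres ≥ 1 apart on the arcsinh scale), otherwise a fixed
default of 1 (~raw 5.9), both overridable — an automated, reproducible
stand-in for manual gates.

**Frequency denominators.** Whether published model features were
fractions of total CD45+ cells or of the parent lineage is not stated.
`frequency_table()` computes over any declared label space; the model
layer uses total-CD45+ fractions by default (one closed composition
per sample), and parent-lineage tables can be built by subsetting
labels before the call.

t-SNE (`embed_tsne()`) is visualisation-only; nothing downstream
consumes coordinates.

## 4. Gensini scoring

The score is Σ severity(stenosis) × weight(segment) over 11 coronary
segments. The protocol lists six severity scores (1, 2, 4, 8, 16, 32)
but only four reduction levels; the package adopts the canonical
mapping — 0 → 0, (0,25] → 1, (25,50] → 2, (50,75] → 4, (75,90] → 8,
(90,99] → 16, (99,100] → 32, right-closed — which also guarantees the
published control-group score of exactly 0. Boundary convention and
the absent 90/99 levels are surfaced here rather than silently
resolved. Weights: LM 5; LAD 2.5/1.5/1; diagonals 1/0.5; LCX 2.5/1;
RCA 1/1/1.

## 5. Cohort statistics

* Categorical cohort rows: Pearson chi-squared **without** Yates
  correction (needed to reproduce the published p-values on 3×2
  tables).
* Continuous rows: one-way ANOVA reconstructed from printed
  mean/SD/n. This is exact when the summaries are exact; the printed
  two-decimal rounding is why the acceptance tolerance is ±0.002.
* Feature comparisons: two-sided t tests per group pair with BH
  adjustment. The adjustment family is per feature-set per pair (the
  published protocol does not state the family; it is configurable by
  calling per family). Stars at adjusted 0.05/0.01/0.001/0.0001.
* Correlations: the protocol text says Spearman while the figure
  legends say Pearson; both are implemented and the method is recorded
  in every result, with Pearson the default for figure-facing outputs.
  Correlation networks mask at unadjusted p < 0.05 (as the figures
  do), report the significant-pair count, and exclude the diagonal.

## 6. The risk models

The random forest is implemented in compiled code (no forest package
is assumed): bagged CART, Gini impurity, `floor(sqrt(p))` features per
split, trees grown to purity (min leaf 1, depth cap 25), importance =
node-weighted impurity decrease averaged over trees and normalised to
sum to one. Forest size defaults to 500 trees for final models and
100 inside the stability loop, where averaging across folds × repeats
supplies the variance reduction. All randomness rides on R's RNG, so
`set.seed()` makes every fit reproducible.

**Interpretation choices** (the protocol states the recipe but not
these details):

* "importance > 0.04" is read on the sum-to-one impurity scale — the
  scale on which 0.04 is meaningful for 25–45 features (mean 1/p).
* The balanced subsample is redrawn every repeat; otherwise 1000
  repeats would be vacuous.
* Z-score normalisation is fitted within each repeat's subsample (and,
  for final models, on the training split only) to avoid leakage; the
  protocol says only "after data normalization".
* "Average result of 10 models" = mean predicted probability over the
  10 fold-forests; class decisions threshold that average.
* The 70/30 split is made on **original** samples before any bootstrap
  replication, so no control case appears (as original and replicate)
  on both sides of the split. The published description is ambiguous
  on this point; splitting first is the leakage-free reading.

**A known property of the stability selector.** Because all repeats
resample one fixed cohort, a feature that *spuriously* separates that
cohort's labels keeps clearing the importance cut in most repeats:
subsample stability removes fit-level noise, not cohort-level
sampling luck. In simulated pure-noise worlds a small minority of
features is therefore still selected in some runs (measured in the
test suite), and the same caveat applies to any real cohort of this
size. The planted-signal benchmark bounds this: all four planted
features recovered with at most one false selection in ≥ 90% of runs.

**The benchmark world** (`model_benchmark_design()`): 45 samples
(15/15/15), 30 clusters with uniform base weights, four planted
abundance effects arranged in weight-balanced pairs — the weight
gained by an up-shifted cluster exactly offsets its partner's loss —
so closure of the composition leaves the 26 non-planted clusters as
exact group-level nulls and "false positive" is well defined. Clinical
signal is confined to TC and HDL (published group means); the other
four covariates are held at the control distribution. Published
headline AUCs are deliberately **not** reproduction targets: the
cohort is not deposited, so the model layer is accepted on properties
(planted-feature recovery, combined ≥ single-block AUC within
Monte-Carlo tolerance, permutation-null AUC ≈ 0.5) instead.

## 7. Numerical conventions

* ROC/AUC: trapezoidal integration over tie-grouped thresholds, equal
  by construction to the pairwise concordance estimator with ties
  counted ½ (asserted on random instances in the acceptance suite).
* Net benefit: `TP/N − (FP/N)·pt/(1−pt)`; treat-none ≡ 0; treat-all =
  `prev − (1−prev)·pt/(1−pt)`; thresholds strictly inside (0, 1).
* Best cutoff: maximum Youden's J on the evaluated grid.
* BH: step-up with cumulative minimum, capped at 1; never below the
  raw p-value.
* Degenerate inputs: zero-variance features get p = 1 (comparisons)
  or undefined r (correlations) with warnings, constant features get
  zero forest importance, and empty gates/graphs raise configuration
  errors rather than guessing.

## 8. Limitations

* CSV is the event interchange format; FCS files should be converted
  upstream (no FCS parser is bundled).
* The forest is binary-classification only — all published models are
  binary — and has no missing-value handling; complete feature
  matrices are expected.
* The generator's Gaussian-on-arcsinh populations are separable by
  construction at the default dispersion; clustering scores on it are
  upper bounds, not estimates, of real-data performance.
* Small-community merging assumes the graph is locally connected;
  pathological graphs (many isolated vertices) will leave small
  clusters unmerged rather than invent connectivity.
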