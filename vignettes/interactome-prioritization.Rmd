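---
title: "Prioritizing proximity-labeling interactomes: models, parameters, and design choices"
author: "bioidnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing proximity-labeling interactomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioidnet)
```

## The problem

BioID (proximity-dependent biotin identification) fuses a promiscuous biotin
ligase to a bait protein so that everything within ~10 nm in live cells gets
biotinylated, captured on streptavidin, and identified by mass spectrometry.
The raw readout per protein and sample is a peptide-spectrum-match (PSM)
count — a noisy, semi-quantitative abundance proxy. The analytical problem is
to separate bait-specific neighbors from the abundant background that any
pulldown recovers, and then to decide which of the dozens of surviving
candidates deserve experimental follow-up.

`bioidnet` implements that pipeline in four statistical stages: differential
binding on counts, association-network construction, module discovery, and
phenotype-seeded network propagation, plus a synthetic-data module that
generates every input with planted ground truth so the whole chain is
testable offline.

## Differential binding on PSM counts

Missing observations (peptides absent from a sample or below detection) are
imputed as PSM 0. Counts are then sum-normalized: sample $j$ is scaled by
$\bar{T}/T_j$ where $T_j$ is its total PSM and $\bar{T}$ the grand mean of
totals. The grand-mean target (rather than scaling to 1) keeps the values on
the count scale that the negative binomial model expects.

Detection is a raw-count rule: a protein is testable when its unnormalized
PSM exceeds `min_psm = 2` in at least `min_reps = 2` bait replicates. The
rule describes presence of the labeled protein in the bait pulldown, so
control samples do not participate — a deliberate reading, since carryover
into controls says nothing about detection of a true neighbor.

For protein $i$ with normalized counts $y_{ij}$ the model is NB with log
link, $\mathrm{Var}(Y) = \mu + \phi\mu^2$, full model
$\log\mu_{ij} = \beta_0 + \beta_1\,\mathrm{bait}_j$ against the
intercept-only null, compared by a likelihood-ratio test on 1 df. Because
the only covariate is a binary factor, the fitted means are the condition
sample means and the fits are closed-form; the continuous extension of the
NB likelihood (via the gamma function) accommodates the real-valued
normalized counts. Degenerate all-zero proteins receive $p = 1$ and
fold-change 0 so downstream rankings stay total.

A single dispersion $\phi$ is shared by all proteins — the stable choice at
2–4 replicates per condition. It maximizes the Cox–Reid adjusted profile
likelihood pooled over all filtered proteins, with each protein's
per-condition means profiled out in closed form. The adjustment
($-\tfrac{1}{2}\log\det X^\top W X$ per protein) matters: at 3+3 replicates
the unadjusted MLE is biased low by roughly 40% (0.24 recovered at a true
0.4 in our simulations, versus 0.39 adjusted), which would make the LRT
anticonservative. The plain profile is available as `method = "ml"`.

Fold-change is computed from the condition means after adding a pseudo-count
of 0.5 to each mean, bounding log-fold-changes when controls are all zero.
Candidates require Benjamini–Hochberg `adjp < 0.05` **and** fold-change
strictly `> 3` **and** passage of the detection filter; all three defaults
are the field-standard thresholds for this assay. The fold-change is taken
on normalized means — normalization is exactly what makes the two
conditions comparable.

## Network construction and Markov clustering

Functional association edges are STRING-style `(protein1, protein2,
combined_score)` rows with scores in (0,1]. The intermediate-confidence
cutoff 0.4 is strict (`score > 0.4`), reciprocal duplicates keep the
maximum score (conservative and deterministic), self-edges are dropped, and
degree-0 nodes are pruned before analysis.

MCL treats the weighted adjacency itself as the probability-flow matrix:
self-loops equal to each node's maximum incident edge weight are added (the
standard regularization against period-2 oscillation), columns are
normalized to sum 1, and expansion (matrix squaring) alternates with
inflation (elementwise power `inflation = 2`, renormalization) and pruning
of entries below `1e-5` until the matrix stops changing (sup-norm `1e-8`,
cap 200 iterations; non-convergence is a warning and the final matrix is
interpreted anyway, flagged). Clusters are the attractor systems; a node
reached by several systems goes to the one holding the larger share of its
flow, ties to the smaller id. Cluster ids are renumbered 0, 1, … by
decreasing size with lexicographic tie-breaks, so identical inputs always
produce identical files. Inflation 2 is the canonical MCL default;
granularity under it is pinned by the planted-partition tests rather than
by any external reference.

Topology metrics (degree, average shortest path to reachable nodes,
closeness = reachable/Σdistance within the component) are computed on the
unweighted skeleton, matching their hop-based definitions.

## Heat diffusion and prioritization

Phenotype-associated seed genes get initial heat 1 and diffuse under the
heat kernel

$$h(t) = e^{-Lt}\,h_0, \qquad L = D - W,$$

with $W$ the weighted adjacency — the same weighted view of the graph the
MCL stage uses. The combinatorial Laplacian conserves total heat, which
gives the implementation a sharp internal check (conservation to 1e-8) and
makes scores comparable across runs; a symmetrically normalized variant is
available behind `normalized = TRUE` but is off by default. Diffusion time
`t = 0.25` is the assay's standard setting; at $t\to\infty$ heat
equilibrates within components, at small $t$ it stays seed-local, and the
implementation is linear in the seed vector — all three limits are tested.
Up to 5000 nodes the kernel is applied by symmetric eigendecomposition;
beyond that a scaling-and-squaring Taylor evaluation takes over (the two
paths agree to 1e-10 on shared inputs). Seeds absent from the network are
dropped with a warning rather than added as isolated vertices, which would
silently distort conservation. Ranking ties break lexicographically.

Candidates are then sliced to the `top_k = 30` hottest, annotated against a
bait/control interaction survey (`specific`, `nonspecific`, or `unobserved`
— the potential new interactors), and clusters whose nonspecific fraction
exceeds 0.5 (majority rule, configurable) are excluded, mirroring the
removal of heat-shock/cytoskeleton hub clusters in this assay class. The
top-30 slice is computed over called candidates, not all network nodes; the
alternative reading exists, but ranking the objects the screen actually
produced is the decision-relevant one.

Category over-representation uses a resampling null: size-matched uniform
draws from the universe, $p = (1 + \#\{\mathrm{null} \ge
\mathrm{obs}\})/(n_{\mathrm{resamples}}+1)$. The add-one estimator never
returns 0 and agrees with the exact hypergeometric tail to Monte-Carlo
error, which the tests verify on a closed-form fixture.

## What the synthetic data emulates — and what it does not

`simulate_psm()` draws PSM counts NB with mean
$\mathrm{baseline} \times \mathrm{libsize}_j \times
\mathrm{fold}^{[\mathrm{planted\ \&\ bait}]}$ and dispersion $\phi$, then
zeroes each cell independently with probability `zero_rate`. The defaults
are the study conditions used throughout the tests: 1000 proteins, 60
planted at fold 8, $\phi = 0.3$, baseline mean 20, 3+3 replicates,
log-normal library sizes (sdlog 0.15), dropout 0.02.

Two defaults deserve justification. Baseline 20 puts background binders
comfortably above the detection filter, so the filter removes genuine
absences rather than acting as a hidden significance screen. Dropout 0.02
keeps missingness sporadic — about 11% of proteins show at least one
missing cell across six samples. The dropout mechanism is deliberately the
simplest one (independent of abundance), and that is also its main
infidelity: real missingness concentrates at low abundance ("below
detection level"), whereas uniform dropout occasionally deletes a
high-abundance observation outright, an event no mass spectrometer
produces. At high rates this interacts badly with the NB likelihood — a
zero at mean 160 is essentially impossible under the model and inflates the
pooled dispersion estimate — which is why the default rate is low. Passing
tests on this generator therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to the
abundance-dependent missingness, protein-level dynamic range, or correlated
contamination structure of real BioID tables.

One consequence is worth stating openly because the acceptance suite
reports it: with 6% of proteins planted at fold 8, the planted signal
inflates bait sample totals by ~40%, and sum normalization — which assumes
equal loading — scales it back, shrinking the effective fold from 8 to
about 5.6. At $\phi = 0.3$ (a 55% biological CV) and 3 replicates, that
places a fifth to a third of planted proteins below the BH threshold:
end-to-end recall plateaus near 55–70% (and near 85% even under an
idealized composition-robust normalization), while observed FDR stays at or
near 0%. This is a property of the normalization-and-threshold recipe
itself under bait-heavy compositions, not of its implementation — an
independent NB-GLM implementation calls the identical candidate set on the
same data. The conservative direction of the bias (missed interactors, not
false ones) matches how the recipe behaves on real data.

`simulate_network()` draws a weighted planted-partition graph (4 blocks of
15, $p_{in} = 0.6$, $p_{out} = 0.02$ by default), with edge scores uniform
on (0.41, 1] so the 0.4 construction cutoff never erodes the planted
blocks. Three seeds are placed in block 1; the last block is labeled
nonspecific; 30% of the remaining nodes are withheld from the specificity
reference to exercise the `unobserved` path. `write_fixture_bundle()` ties
both generators together (network nodes = planted interactors), writes
every pipeline input plus a JSON truth manifest, and is byte-reproducible
from its seed; dropout cells are written as empty fields so reading a
bundle exercises imputation.

## Numerical choices

* Dispersion search on $[0, 20]$ by golden-section (`optimize`), boundary
  $\phi = 0$ accepted when the profile is monotone there; a numerical
  gradient check guards against a non-converged interior optimum.
* LRT statistics are clipped at 0 (round-off can make the constrained fit
  infinitesimally "better").
* Eigendecomposition heat is clipped at 0 for the same reason.
* MCL columns that prune to zero mass are pinned to their own diagonal.
* All output tables have a deterministic row order (adjusted p then symbol,
  cluster id then node, heat rank with lexicographic ties), so re-runs are
  byte-identical.
* Problem sizes in the test and acceptance runs — 500–1000 proteins for
  calibration, 60-node networks, 25 × 50-node diffusion oracles, 10,000
  resamples — were chosen as the smallest sizes at which the Monte-Carlo
  bands used by the checks are meaningfully tight.

## Known limitations

* Symbols are matched exactly and case-sensitively; mixed-species symbol
  casing must be resolved upstream.
* The common-dispersion model ignores protein-specific overdispersion; with
  more replicates a per-protein (tagwise) model would dominate.
* Sum normalization is not composition-robust (see above); candidates from
  bait-heavy designs are conservatively undercalled.
* MCL is dense-matrix (fine to a few thousand nodes, not for proteome-scale
  graphs).
* The resampling null treats genes as exchangeable; no covariate matching
  (degree, abundance) is attempted.
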