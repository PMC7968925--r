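# bioidnet

Interactome prioritization from proximity-labeling spectral counts.

BioID screens fuse a promiscuous biotin ligase to a bait protein, label
everything within ~10 nm in live cells, and read the captured proteins out
as peptide-spectrum-match (PSM) counts per protein and sample. The hard part
is downstream: separating bait-specific neighbors from pulldown background,
organizing the survivors into functional modules, and deciding which
candidates matter for a phenotype. `bioidnet` implements that chain for
analysts of bait-vs-control spectral-count experiments:

1. **Differential binding** — impute missing PSM as 0, sum-normalize
   (sample *j* scaled by `mean(totals)/total_j`), require raw PSM > 2 in ≥ 2
   bait replicates, fit a negative binomial GLM (log link, common dispersion
   φ estimated by Cox–Reid adjusted profile likelihood, Var = μ + φμ²) per
   protein, test the condition effect with a 1-df likelihood-ratio test, and
   call candidates at Benjamini–Hochberg adjp < 0.05 and fold-change > 3.
2. **Network construction** — STRING-style weighted edges, combined score
   strictly > 0.4, reciprocal duplicates merged by maximum, unconnected
   nodes pruned.
3. **Module discovery** — Markov clustering (MCL) with the weighted
   association matrix as the probability-flow matrix (inflation 2), plus
   per-node degree, average shortest path, and closeness centrality.
4. **Prioritization** — phenotype seed genes get heat 1 and diffuse under
   the Laplacian heat kernel `h(t) = exp(−(D−W) t) h0` at t = 0.25;
   candidates are ranked by stored heat, annotated against a bait/control
   specificity survey, clusters dominated by nonspecific interactors are
   excluded, and category over-representation is assessed with a
   resampling null (`p = (1 + #{null ≥ obs}) / (n + 1)`).

A synthetic-data module generates every input with planted ground truth —
NB counts with planted interactors at a known fold, planted-module networks
with hot seeds — so the full pipeline is testable offline.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Stage 1
writes a complete synthetic study (1000 proteins, 60 planted interactors at
fold 8, dispersion 0.3, 3+3 replicates; a 4×15-block association network
over the planted set with 3 phenotype seeds in block 1):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_binding.R
```

```
995/1000 proteins pass the detection filter
common NB dispersion phi = 0.3702 (Cox-Reid adjusted profile likelihood)
called 34 candidates: recall 57% of 60 planted, FDR 0.0%
overlap odds ratio = 2435.83 (Haldane-corrected: zero cell), chi-squared p = 2.6e-121
```

The dispersion lands near the simulated 0.3; every called candidate is a
planted interactor (FDR 0%), while recall sits near 57% — sum normalization
is not composition-robust, and with 6% of proteins planted at fold 8 it
shrinks the effective fold enough to leave the weakest planted draws under
the BH line (the methods vignette quantifies this ceiling). The odds ratio
is the candidate-vs-planted 2×2 overlap in the tested universe.

```sh
Rscript analysis/03_network_modules.R
Rscript analysis/04_diffusion_ranking.R
Rscript analysis/05_enrichment.R
```

```
network: 60 nodes, 285 edges after pruning
cluster_assignment: 60 nodes in 4 clusters (sizes 15, 15, 15, 15)
adjusted Rand index vs planted blocks: 1.000

specificity classes: nonspecific=15, specific=31, unobserved=14
3/4 clusters retained after the nonspecific filter
mean heat per planted block (block = seed block first):
     1      4      3      2
0.1799 0.0089 0.0082 0.0029

block_1    overlap 15  p_mc 0.0001  p_hypergeom 0.0000
block_2    overlap  0  p_mc 1.0000  p_hypergeom 1.0000
```

MCL recovers the planted modules exactly (ARI 1.0); the all-nonspecific
block is excluded; the seed block stores ~20× the heat of any other block;
and the 15 hottest nodes are exactly the seed module, with the Monte-Carlo
enrichment p at its 10,000-resample floor and in agreement with the exact
hypergeometric tail.

Stage outputs land under `results/` as TSVs (`differential.tsv`,
`clusters.tsv`, `topology.tsv`, `diffusion.tsv`, `ranked_candidates.tsv`,
`enrichment.tsv`). The same chain is available as one call,
`run_pipeline(default_config(...))`, which also writes a JSON run manifest.

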