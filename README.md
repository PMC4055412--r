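# bowtievar

Signaling pathways share a bow-tie (hourglass) organization: many receptors
converge on a compact signal-transmission core that fans out to many
transcription factors. `bowtievar` provides the statistical machinery to ask
how protein abundance, cross-cell-line abundance **variability**, and
phylogenetic **conservation** distribute over that architecture, and how
somatic versus germline disease mutations track those protein properties.
It is aimed at computational/systems biologists who have (or want to
simulate) a replicated multi-cell-line proteomics panel, per-protein
homology profiles on a weighted species tree, pathway/functional-class
annotations, a protein–protein interaction network, and per-protein
mutation counts.

The package implements:

* **F value** — per-protein abundance variability as the one-way ANOVA
  statistic on standardized intensities with the cell line as the grouping
  factor, `F = (SS_B/(k−1)) / (SS_W/(N−k))`. Normalizing between-cell by
  within-cell variability removes the strong negative dependence of raw
  spread on abundance and gives a calibrated `F(k−1, N−k)` null.
* **Conservation score** — for a protein with homologs in species set `S`
  on a weighted species tree `T = (V, E, w)`, the fraction of total branch
  length spanned by the minimal (Steiner) subtree `E_S` connecting `S`:
  `c = Σ_{e∈E_S} w(e) / Σ_{e∈E} w(e) ∈ [0, 1]`.
* **Bow-tie layer analysis** — unique functional-class assignment
  (ambiguous proteins excluded), pooling into input / transmission / output
  layers, and two-sided Wilcoxon–Mann–Whitney comparisons of every feature
  between layers, classes and their complements, and exclusive vs
  multi-pathway proteins.
* **PPI pair resampling** — |Δ log10 F| distributions over 1000 sampled
  interacting pairs per category (input–transmission, transmission–output,
  within-layer, random) against two nulls: non-interacting
  input–transmission pairs and a link-permutation null.
* **Mutation profiles** — somatic vs germline feature comparisons, binned
  mean-mutation profiles over feature quantiles with an exact count
  identity, and a hypergeometric + Bonferroni enrichment test.
* **A seeded synthetic-data generator** (`world_config()` /
  `generate_world()`) that emulates all six inputs with configurable
  planted effects, making every stage testable as parameter recovery.

## Worked example

```r
library(bowtievar)

world  <- generate_world(world_config(n_proteins = 2000, seed = 42))
report <- run_pipeline(world, seed = 42)
print(report)
```

```
bowtievar pipeline report
  1931 proteins with features (1931 finite F)

Feature correlations:
  pair                      method   estimate   p_value     n
1 conservation_vs_abundance spearman   0.513  2.66e-130  1931
2 conservation_vs_log_f     spearman  -0.0518 2.29e-  2  1931
3 raw_sd_vs_abundance       spearman  -0.494  2.95e-119  1931
4 log_f_vs_abundance        spearman   0.0168 4.61e-  1  1931

Layer comparisons:
  feature        layer_a layer_b      statistic  p_value direction   n_a   n_b
2 conservation   input   transmission     7206. 1.20e-87 lower       280   427
3 conservation   output  transmission     5843  1.42e-68 lower       201   427
5 log10_f        input   transmission    78852  6.94e-13 higher      280   427
6 log10_f        output  transmission    38975  6.34e- 2 none        201   427
...

PPI |d log F| comparisons (vs PPI-IT):
  group_a group_b  statistic  p_value direction   n_a   n_b
4 PPI-IT  Rand-IT    618942  3.24e-20 higher     1000  1000
5 PPI-IT  Perm-IT    588232. 8.33e-12 higher     1000  1000

Somatic vs germline comparisons:
  feature        group_a group_b  statistic  p_value direction
1 conservation   somatic germline  1204381  2.89e-23 higher
```

Reading the output: raw intensity spread falls with abundance
(Spearman −0.49) while log F is flat (0.017) — the F value has removed the
confound; conservation rises with abundance (0.51). Across layers,
variability is highest in the input layer and drops sharply into the
transmission core, while conservation is bell-shaped with its peak in
transmission. Interacting input–transmission pairs differ more in
variability than non-interacting pairs of the same layers (`Rand-IT`) and
than re-paired endpoints (`Perm-IT`), so the wiring itself — variable
receptors attached to stable core proteins — carries signal beyond layer
membership. Proteins carrying somatic mutations are more conserved than
proteins carrying germline disease mutations. All of these are the effects
the demo generator plants; `world$truth` holds the planted parameters.

Each stage is also available on its own (`protein_features()`,
`conservation_score()`, `annotate_layers()`, `layer_feature_summary()`,
`sample_pairs()`, `binned_mutation_profile()`, `enrichment_test()`),
returns tidy tibbles or objects with `tidy()`/`glance()`/`autoplot()`
methods, and the six input tables round-trip through a plain TSV/Newick
dialect (`write_world()` / `read_world()` / `run_pipeline(outdir = ...)`).

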