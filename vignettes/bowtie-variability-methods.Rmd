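---
title: "Methods: variability, conservation and the bow-tie organization of signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variability, conservation and the bow-tie organization of signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`bowtievar` analyses how three per-protein quantities — mean abundance,
cross-cell-line abundance variability, and phylogenetic conservation —
distribute over the functional components and bow-tie layers of human
signaling pathways, and how somatic and germline disease mutations track
those quantities. Because the real inputs (multi-cell-line proteomics,
homology databases, curated pathway and interaction resources, mutation
catalogues) cannot be redistributed, the package pairs every analysis stage
with a seeded synthetic-data generator that plants the corresponding effect,
so the whole pipeline is testable end-to-end as a parameter-recovery
problem.

# The F-value variability statistic

Raw per-protein intensity spread is a poor variability measure in mass
spectrometry: abundant proteins are measured more precisely, so spread and
abundance are strongly negatively associated. The package therefore scores
variability as the classical one-way ANOVA statistic on each protein's
standardized intensities, with the cell line as the grouping factor:

$$F \;=\; \frac{SS_B/(k-1)}{SS_W/(N-k)},$$

where $k$ is the number of cell lines in which the protein was detected and
$N$ its total number of detected measurements. Dividing the between-cell
mean square by the within-cell (replicate) mean square cancels the common
precision scale, removing the abundance dependence; under pure replicate
noise $F$ follows the central $F(k-1,\,N-k)$ distribution, which gives the
statistic a calibrated null (checked by simulation in the test suite at
11 cell lines × 3 replicates, the design of the emulated panel).

Processing conventions, in order:

* **Detection filter.** A protein is kept when detected in at least 50% of
  all sample columns (boundary included). Dropped proteins are counted in
  the pipeline manifest.
* **Log scale.** Intensities are log10-transformed before standardization
  (configurable). MS intensities span decades and are approximately
  log-normal, so column means and standard deviations are only meaningful
  on the log scale.
* **Standardization.** Each sample column is centered and scaled to mean 0,
  sd 1 over its detected entries. A zero-spread column is an error naming
  the sample. Standardizing twice changes nothing (idempotence, tested).
* **Missing values** are excluded pairwise, never imputed; the ANOVA uses
  the actual unbalanced per-line counts. Proteins with fewer than two
  detected lines, or fewer than two lines with replicated detection, are
  flagged and excluded from F distributions, as are proteins with zero
  within-cell spread (infinite F sentinel).
* **Displays and downstream tests use log10 F.**

A consequence of the unbalanced-counts convention worth knowing: with
missingness concentrated in low-abundance proteins, the expected value of
$F$ shifts slightly with the per-line detection pattern, which induces a
small positive association between log F and abundance (Spearman ≈ +0.02 to
+0.04 at the default 5% missingness in the generator). This is a
finite-design property of the ANOVA statistic, not the abundance-precision
confound; the confound-elimination diagnostic in the acceptance suite is
therefore run on a fully observed matrix, which isolates the mechanism the
diagnostic is about.

# The conservation score

Conservation is scored on a weighted species tree $T$ with edge set $E$ and
branch lengths $w(e)$. A protein present (by homology) in a species subset
$S$ (the reference species always included) defines the minimal connected
subtree spanning $S$ — the Steiner subtree of the unrooted topology, with
edge set $E_i$ — and the score is

$$c_i \;=\; \frac{\sum_{e \in E_i} w(e)}{\sum_{e \in E} w(e)} \in [0, 1].$$

The score is 0 for a reference-only protein, 1 for a protein conserved in
all species, and grows with both the number of retained species and the
evolutionary distance separating them. Three properties pin the definition
down and are enforced by property tests:

* **Unrooted (Steiner) semantics.** An edge belongs to $E_i$ exactly when
  both sides of the split it induces contain a retained tip; the path from
  the subtree towards the root is *not* included. Consequently the score is
  invariant to root placement (tested to 1e−12 under re-rooting), monotone
  in $S$, and invariant to rescaling all branch lengths.
* **Exactness.** The split-based computation equals the brute-force union
  of pairwise tip-to-tip paths on random trees, exactly.
* **Tree/table consistency.** Species named in the homology table must be
  tips; tips never queried by the table are an error unless explicitly
  waived, so silent universe mismatches cannot occur.

Whether the original formulation included the edge from the retained clade
toward the root cannot be decided from a single published worked example
without its source tree; the unrooted-Steiner convention was chosen because
the worked example grays out branches leading to non-retained taxa and its
small subtree sum is consistent with no root path. The acceptance suite
exercises the same mammal-clade computation on the package's synthetic
14-species reference tree rather than asserting the published numbers.

# Layers, classes and comparisons

Pathway annotations arrive as rows of (protein, pathway, source, raw class)
with Reactome- and SignaLink-style sources. A protein keeps a functional
class only when its annotations support a single one; conflicting classes
mark it `ambiguous` and exclude it from layer analyses. Classes pool into
bow-tie layers:

| layer | classes |
|---|---|
| input | receptors |
| transmission | kinases, phosphatases, adaptors, GTPase-binding; mediators, cofactors |
| output | transcription factors |
| unassigned | ligands, `none`, ambiguous |

Mediators and cofactors enter transmission only when they are neither
receptors nor transcription factors — automatic under the unique-class
rule, since a conflict produces `ambiguous`.

All group comparisons are two-sided Wilcoxon–Mann–Whitney tests through one
wrapper with fixed conventions: mid-ranks for ties; exact null distribution
when the smaller group has ≤ 10 observations and the pooled sample is
untied, normal approximation with continuity and tie correction otherwise;
p-values never clipped to zero (underflow is flagged at the smallest
representable double); a direction (`higher`/`lower`) is reported only below
the significance threshold, default 0.01. Correlations default to Spearman
(the intensity scale is heavy-tailed); Pearson is available. Exclusive
(single-pathway) versus multi-pathway proteins are compared on all three
features, with per-class overrepresentation among multi-pathway proteins
reported as observed/expected fold ratios.

# Pair resampling and the permutation null

The interaction stage samples `n_pairs` (default 1000, the published
design) protein pairs per category: interacting input–transmission
(`PPI-IT`), interacting transmission–output (`PPI-TO`), interacting
within-layer (`PPI-W`), any interacting pair (`PPI-Rand`, restricted to the
layer-annotated signaling universe), and non-interacting input–transmission
pairs (`Rand-IT`, rejection-sampled against the edge set with a 10×n
attempt cap). Only proteins with a unique layer and a finite log F are
eligible. Sampling is without replacement when enough eligible pairs exist,
with replacement otherwise (recorded in the sample's metadata). Each pair
contributes $|\Delta \log_{10} F|$, and `PPI-IT` is compared against every
other category. The permutation null (`Perm-IT`) keeps the input endpoints
in place and shuffles the transmission endpoints among pairs, preserving
both endpoint multisets and the layer constraint while destroying any
within-pair coupling.

# The synthetic-data generator

`world_config()` defines the study conditions; `generate_world()` draws six
mutually consistent tables from independent per-stage seed streams (so the
same seed reproduces any one table standalone). The defaults are fixed
reference conditions, not tuning knobs:

* **Design**: 11 cell lines × 3 replicates, 2000 proteins in the demo
  configuration; latent log10 abundance N(7, 1).
* **Noise**: baseline between-cell and within-cell sds of 0.25 (log10
  units) at mean abundance, both scaled by `abundance^(−0.2)` to plant the
  abundance-precision confound at roughly the strength seen in published
  panels (raw-sd vs abundance Spearman ≈ −0.55), with independent
  per-protein lognormal jitter (sd 0.8) creating a realistic spread of true
  variabilities.
* **Layers**: fractions 0.15/0.25/0.10/0.50 over
  input/transmission/output/other; between-cell variance multiplied by 4 in
  the input layer (the planted variability gradient).
* **Conservation**: per-species retention is logistic with an intercept of
  1, a decay of 4 per unit scaled tree distance from the reference, a slope
  of 0.8 on standardized abundance (planting the conservation–abundance
  association), and per-layer shifts (−1, +1.5, −1, 0) planting the
  bell-shaped layer profile with its transmission peak.
* **Missingness** is missing-at-low-abundance: a logistic in latent
  abundance with scale 0.25 log10 units, calibrated to a 5% overall rate.
  The sharp scale concentrates missingness in the tail that the 50%
  detection filter removes, which keeps detection-unbalance effects on F
  small (see above).
* **Wiring**: with probability `wiring_assortativity` (default 0.8) an
  input–transmission edge is drawn countermonotonically: the input endpoint
  at variability rank $u$ of its layer, the transmission endpoint at rank
  $1-u$ (with rank positions drawn toward the extremes), so variable inputs
  attach to stable transmission proteins. Pure stratum enrichment —
  sampling endpoints independently from a high- and a low-variability
  stratum — cannot be distinguished from its own permutation null, because
  re-pairing independent endpoints leaves the joint distribution unchanged;
  the anti-rank coupling is the weakest mechanism that makes interacting
  pairs differ from both random pairs and permuted re-pairings, which is
  precisely the published control structure. Setting assortativity to 0
  recovers uniform independent wiring (the type-I configuration).
* **Mutations**: per-protein counts are Poisson with per-bin rates over
  conservation quintiles — somatic bell shifted high (0.5, 1, 2, 3, 1.5),
  germline bell centered (1, 2, 3, 1.5, 0.5), SNP background flatter and
  higher at low conservation (3, 2.5, 2, 2, 1.5) — so profile recovery is a
  clean rank-agreement test.
* **Pathways**: ten canonical labels; each protein gets one pathway plus a
  Poisson number of extras whose rate is boosted 3× in the transmission
  layer, planting the overrepresentation of transmission classes among
  multi-pathway proteins (and, indirectly, their higher conservation).

What the generator does **not** emulate: peptide-level MS artifacts, batch
structure, sequence evolution, realistic pathway or interaction topologies
(edges are stratified random pairs, not a scale-free network), and
annotation noise. Passing recovery tests therefore demonstrates that the
pipeline's statistics detect the planted effects at realistic sizes and are
calibrated under the null — not that the biological conclusions would
survive the messiness of real inputs.

# Numerical and design choices

* Quantile bins are rank-based with ties assigned to the lower bin; each
  bin's occupancy deviates from the equal split by at most the largest
  tie-group size. Requesting more bins than distinct values is an error.
* Binned mutation profiles report mean mutations per protein per bin;
  zero-count proteins contribute zeros, making the totals identity
  $\sum_b n_b \bar m_b = \sum_i m_i$ exact. An optional normalization
  divides each class by its overall mean for cross-class display.
* Enrichment is a one-sided hypergeometric with Bonferroni correction — a
  generic stand-in; no EASE-style score adjustment is attempted.
* Per-stage seeds derive from the master seed by a stable string hash, so
  toggling one stage never perturbs another's randomness; all derived seeds
  stay below 2^31.
* Problem sizes in the test suite (10,000 proteins for null calibration,
  5,000 for confound and mutation recovery, 50 × 2,000 for the layer
  gradient, 200 × 3,000 for pair-test calibration) were chosen as the
  smallest sizes at which the planted effects sit far from their detection
  thresholds while the whole suite stays comfortably interactive. The
  calibration sweep uses 3,000-protein worlds so that 1000 sampled pairs
  reuse individual proteins only a couple of times each, keeping the
  rank-sum test's independence assumption approximately valid.

# Known limitations

* The rank-sum test treats sampled pairs as independent; pairs sharing an
  endpoint are mildly dependent, which inflates the test's effective
  variance slightly at high pair-to-protein ratios. The calibration test
  bounds this empirically.
* The F statistic requires replicates; unreplicated designs (e.g. tissue
  panels) are handled by the separate quartile-based route, which can only
  control abundance by filtering.
* Conservation scores are as good as the homology table; the generator's
  logistic retention model produces plausible but not nested profiles.
* With very few proteins per layer the pipeline warns and skips the
  affected comparisons rather than failing.
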