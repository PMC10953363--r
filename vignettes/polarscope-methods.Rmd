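---
title: "Methods: proteome classification and label-free motility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome classification and label-free motility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarscope)
```

polarscope quantifies two complementary readouts of cultured macrophage
polarization: a TMT-style proteomics processing chain that separates the
*differential* from the *core* proteome across polarized subtypes
(M1, M2a, M2c vs an unstimulated M0 control), and a label-free
phase-contrast imaging chain that segments, tracks and summarizes
spontaneous cell motility. This vignette documents the models behind both
arms, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the numerical choices made where the
design was genuinely open.

## The proteomics model

A multiplexed isobaric-label (TMT) experiment yields a proteins × samples
intensity matrix in which each sample column carries an arbitrary loading
factor, and biological interest lies in per-protein fold changes of each
polarized subtype against the averaged unstimulated controls. The chain is:

1. **Total-abundance normalization** (`normalize_total_abundance()`). Every
   sample column is rescaled so all column totals equal the mean of the
   original totals. Within-sample proportions are preserved exactly, so any
   positive per-sample scale factor (pipetting, labeling efficiency) is
   absorbed; this scale-invariance is asserted to 1e-9 in the tests.
2. **Control-referenced log2 fold change**
   (`log2_fold_change_vs_control()`). Each protein's abundance in every
   non-control sample is divided by the mean abundance of that protein
   across the control samples and log2-transformed. The number of controls
   is arbitrary (n ≥ 1); the emulated design uses two. Proteins whose
   control mean is zero have no defined ratio: they are dropped and
   reported (`dropped_proteins()`) rather than imputed, because no
   pseudo-count rule is part of the workflow being modeled.
3. **Median centering** (`median_center()`). The per-sample column median
   of the log2FC matrix is subtracted. This step matters more than it
   looks: total-abundance normalization leaves a small compositional
   offset per sample whenever planted (or real) regulation changes a
   column's total. When at least half the proteome is unregulated, the
   column median sits exactly on that offset, so centering removes it —
   with noise-free synthetic data the full chain returns planted effects
   *exactly*, a property the test suite asserts at 1e-9.
4. **Per-subtype aggregation** (`mean_by_subtype()`): the arithmetic mean
   across donors. Missing values are ignored when at least one finite
   replicate exists; partially covered means are flagged
   (`incomplete_means()`).
5. **Threshold classification** (`classify_polarity()`). A protein is
   *up* in a subtype when its mean log2FC is ≥ +1, *down* when ≤ −1,
   otherwise *unchanged*; the thresholds and their inclusivity are
   parameters. The *core proteome* (`core_proteome()`) is the set called
   unchanged in every subtype — mean log2FC strictly inside (−1, 1)
   everywhere — and the *differential proteome* is its complement among
   fully observed proteins. The published workflows this models state the
   band both as strict and inclusive inequalities in different places;
   boundary cases are measure-zero in continuous data, so the default is
   inclusive with a `boundary_inclusive` switch rather than a second code
   path.
6. **Surfaceome curation** (`filter_surface()`): case-insensitive
   restriction to an identifier whitelist such as a Cell Surface Protein
   Atlas export, with retained/total reporting. Gene symbols are the
   default namespace; any identifier set works since matching is by
   string.
7. **Structure summaries**: `venn_overlap()` counts differential proteins
   per subtype and per exact subtype combination; `hierarchical_order()`
   returns the leaf order of Euclidean-distance agglomerative clustering
   (complete linkage by default, the common default of the heatmap tooling
   this emulates); `pca_scores()` computes sample scores with features
   (proteins) centered and a deterministic sign convention — the
   largest-magnitude loading of each component is made positive — so
   results do not depend on LAPACK sign choices.

Differential expression here is deliberately operationalized as the
threshold rule, not a significance test: the sets this package reproduces
are defined by the ±1 log2FC cut, and the 5% FDR of the upstream search
engine concerns peptide identification, not per-protein inference. For
users who want one, `compare_groups()` provides the nonparametric
group-comparison contract (below), but it is not part of the canonical
counts.

### The proteome generator

`simulate_proteome()` emulates the statistical structure this chain
assumes: log-normal baseline abundances (log2 mean 10, sd 2, spanning a
realistic TMT dynamic range), a planted ±`effect_log2fc` in exactly one
subtype for each non-core protein, log-normal multiplicative measurement
noise (`noise_sd`, default 0.3 in log2 units), and uniform per-sample
loading factors in `[1 − loading_spread, 1 + loading_spread]`. Defaults
follow the emulated design: three polarized subtypes × three donors plus
two controls (an 11-channel layout); half the proteome core; effect size
2. A random `frac_surface` of proteins is flagged surface-localized and
returned as a synthetic atlas so surfaceome curation is exercisable
end-to-end. What it does **not** emulate: missing-value mechanisms beyond
zero control means, reporter-ion interference or compression, and
correlated regulation across proteins — so passing recovery tests show the
arithmetic of the chain is right, not that it would untangle co-regulated
biology.

## The imaging model

Frames arrive as grayscale phase-contrast stacks (20-minute intervals over
12 h in the emulated protocol; pixel units, no physical calibration). Per
frame, the detection chain is:

1. **Drift correction** (`estimate_drift()`): a translation-only
   registration of each frame against frame 0 by phase correlation with
   parabolic subpixel refinement, honoring the same contract as
   feature-based registration (planted shifts recovered within 0.5 px).
   Frames are aligned by the negated, rounded shifts. Blank frames report
   zero shift with a warning.
2. **Foreground** (`foreground_mask()`): a Gaussian-weighted local
   variance filter (σ = 5 px; a box-window dialect is available via
   `variance_window = "box"`) computed on the raw intensity scale,
   binarized by Otsu's threshold, holes filled. Textured cells stand out
   against the homogeneous background; the mask dilates roughly one window
   σ beyond the true cell edge, which the downstream size rules tolerate.
3. **Landscape** (`dog_landscape()`): difference of Gaussians
   (σ_low = 1 px minus σ = 7 px), inverted, rescaled to the full 8-bit
   range, so cell centers are minima. Single-σ DoG conventions vary
   between tools; both σs are parameters.
4. **Markers** (`extended_minima_markers()`): extended (h-)minima of the
   landscape with depth `minima_depth_h` (default 10 of 255), computed via
   grayscale reconstruction; each connected minima region is one marker.
   The depth is not pinned by the workflow being modeled, so it is exposed;
   on the synthetic fixtures the per-frame counts are verified insensitive
   for h anywhere in [5, 30].
5. **Splitting** (`split_and_label()`): marker-controlled watershed
   (priority flood, deterministic FIFO tie-break) of each foreground
   component smaller than 2000 px², restricted to that component, seeded
   by the markers whose basin lies majority-inside it — a background noise
   basin that merely clips the mask edge must not split an object.
   Components at/above 2000 px² (presumed cell clusters, where watershed
   is unreliable) and components without markers pass through unsplit.
6. **Classification** (`classify_objects()`): objects < 200 px² are
   discarded as noise; [200, 2000) px² are cells; ≥ 2000 px² are clusters.
   The boundaries are exact integer rules, tested at 150/200/2000 px².
   Centroids are mean pixel coordinates, 0-based, x = column, y = row,
   origin top-left.

**Tracking** (`link_tracks()`) is Jaqaman-style frame-to-frame linking:
for each consecutive frame pair, a linear assignment problem minimizes the
total squared centroid distance, with links beyond `max_link_distance`
(default 50 px — well above plausible per-frame displacement at this frame
interval, and configurable) forbidden, and birth/death alternatives priced
at `max_link_distance²`. The solve is delegated to the Hungarian algorithm
(`clue::solve_LSAP`); tests verify optimality against a brute-force
enumeration over all matchings on small instances. Cells and clusters are
linked in separate pools, never to each other. No gap closing by default
(`max_gap = 1` bridges a single missed frame when asked). Tracks observed
in fewer than `min_length = 5` frames are discarded — a 5-frame track is
retained, a 4-frame track is not, exactly.

**Motion statistics** (`track_metrics()`, `field_summary()`): per track,
the mean step length (mean speed, px per frame interval; px/min derivable
via the interval), the total path length, and the Euclidean start-to-end
distance (≤ path length, always). Per imaging field, the arithmetic means
of per-track mean speed and Euclidean distance; fields without tracks are
reported missing, not zero. Cluster tracks are excluded from per-field
means by default and included via `include_clusters = TRUE`.

### The video generator

`simulate_motility_video()` renders textured moving disks with stored
ground truth. Cells are a radial intensity dome (a cell-body thickness
profile) with per-pixel Gaussian speckle (relative sd 0.03) at contrast
0.3 over a background of 0.5 with per-frame Gaussian noise (sd 0.01) and a
faint *static* background texture (sd 0.02) that rides the stage drift —
real fields of view contain static plate features, and translation-based
drift estimation is unidentifiable without any. Motion is a persistent
random walk with exact per-frame step length `speed`, reflecting borders,
and excluded-volume contact avoidance (a step that would interpenetrate
another non-clustered cell is re-aimed; adherent cells do not pass through
each other). A `cluster_fraction` of cells is placed touching an anchor
cell to form merged blobs. Truth tracks record the reflected, drift-free
positions, so pipeline output is compared after drift correction.

Not emulated: phase-contrast halo artifacts, cell shape change and
elongation, division and death, focus drift, and photobleaching — so
passing recovery tests demonstrate the operator chain and its contracts,
not robustness to every optical artifact of real videos.

Default study-scale conditions: 10 cells of radius 12 px (≈452 px², mid
single-cell band) in a 512 × 512 field, 36 frames (12 h at 20-min
intervals), speed 4 px/frame, persistence 0.7. Tests and the acceptance
script use these sizes (40 frames where a longer run is probed); the
proteome recovery runs use 1000 proteins, chosen to estimate recall and
precision at the 0.95 level with comfortable resolution.

## Assay statistics

`auc_trapezoid()` integrates a chemiluminescence respiratory-burst curve
(100 min recorded at 2.5-min intervals in the emulated assay) by the
trapezoidal rule — linear and additive over contiguous subintervals,
exactly. `compare_groups()` is the nonparametric comparison used for
motility and burst readouts: a Kruskal–Wallis omnibus test (delegated to
`stats::kruskal.test`) followed by Dunn's pairwise z statistics on mean
ranks with the standard tie correction and `p.adjust` multiplicity
control (Holm by default). No installed package provides Dunn's test, so
the (textbook) z formula is computed directly and cross-checked in the
tests against an independent recomputation.

## Numerical choices and degenerate inputs

- Constant frames: the variance mask is empty and the DoG landscape flat,
  each with a warning — never an error, so blank videos yield empty object
  tables.
- Zero control means: proteins dropped with a report, never imputed.
- Watershed ties: the priority flood breaks equal-landscape ties
  first-in-first-out, making label maps reproducible bit-for-bit.
- Hierarchical leaf order and PCA signs are deterministic given input
  order (hclust's tie behavior; largest-|loading|-positive convention).
- All generator randomness flows from an explicit `seed` argument through
  a local RNG scope; global RNG state is untouched.
- 16-bit TIFF label maps round-trip losslessly for labels < 65536;
  intensity stacks round-trip to within one 16-bit quantization step.

## Known limitations

The threshold classifier reports counts under the configured rule only; it
deliberately does not attempt the significance-based counts that a
replicate-level test would produce, and provides `compare_groups()`
separately. Segmentation assumes blob-like cells; strongly elongated or
overlapping morphologies (beyond the cluster rule) are out of scope, as is
gap-closing LAP tracking with merge/split costs. The per-field means treat
every retained track equally, with no weighting by track length.
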