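# polarscope

Cultured human macrophages polarize into functionally distinct subtypes —
proinflammatory M1 (IFNγ), alternatively activated M2a (IL-4) and
deactivated M2c (glucocorticoid) — from the same unstimulated M0
precursors. Two quantitative readouts characterize that polarization:
multiplexed (TMT) proteomics, which separates the proteins that shift with
polarity from a stable *core proteome*, and label-free time-lapse imaging,
which captures subtype-specific spontaneous motility. polarscope
implements both analysis arms as tested, reusable R functions, together
with synthetic generators that plant known ground truth so every stage is
verifiable end to end without any external data.

**Who it is for:** researchers processing macrophage (or comparable
immune-cell) TMT abundance tables and phase-contrast motility videos, and
anyone who needs a transparent, scriptable reimplementation of this class
of pipeline with planted-truth validation.

## The methods in brief

*Proteomics.* For abundance matrix $X$ (proteins × samples), each sample
column is rescaled to the mean total abundance; fold changes are computed
against the averaged controls,
$\mathrm{log_2FC}_{ps} = \log_2\!\big(X^{norm}_{ps} / \overline{X^{norm}_{p,\mathrm{ctrl}}}\big)$,
median-centered per sample, and averaged across donors per subtype. A
protein is *differential* in a subtype when $|\overline{\mathrm{log_2FC}}| \ge 1$
(direction by sign, boundary inclusivity configurable) and belongs to the
*core proteome* when it stays inside $(-1, 1)$ in every subtype. Surfaceome
data are curated against a cell-surface protein atlas identifier list.
Venn overlap counts, hierarchical (Euclidean, complete-linkage) leaf
ordering and sample PCA summarize the structure.

*Imaging.* Frames are drift-corrected (translation-only, subpixel), cells
detected by a local-variance filter (σ = 5 px) with Otsu binarization and
hole filling, and touching cells split by marker-controlled watershed on
an inverted difference-of-Gaussian landscape (σ = 7 px) seeded at extended
intensity minima — restricted to foreground components smaller than
2000 px². Objects < 200 px² are noise, [200, 2000) px² cells,
≥ 2000 px² cell clusters. Centroids are linked frame-to-frame by a
Jaqaman-style linear assignment problem (squared-distance cost, 50 px
link cutoff), tracks under 5 frames discarded, and per-track mean speed,
path length and Euclidean start-to-end distance summarized per imaging
field. Trapezoidal AUC and Kruskal–Wallis + Dunn comparisons cover the
functional assay statistics.

## Worked example

Simulate a study-like proteome (three subtypes × three donors, two
controls, half the proteome core), run the full chain, and compare against
the planted truth:

```r
library(polarscope)

sim <- simulate_proteome(n_proteins = 500, frac_core = 0.5,
                         effect_log2fc = 2, noise_sd = 0.3, seed = 42)
sim
#> <proteome_sim> 500 proteins x 11 samples (2 controls); 250 core, 104 surface

res <- run_proteome_pipeline(sim$abundance, sim$design)
res
#> <proteome_result> 500 proteins, subtypes: M1, M2a, M2c
#>   core: 250, differential in >=1 subtype: 250

res$venn
#> <venn_overlap> union of differential sets: 250 proteins
#> # A tibble: 3 × 2
#>   subtype n_differential
#>   <chr>            <dbl>
#> 1 M1                  84
#> 2 M2a                 78
#> 3 M2c                 88
```

All 250 planted core proteins are recovered (the per-subtype differential
counts partition the 250 planted effects across M1/M2a/M2c). The bundled
reference table of myeloid-activation surface markers classifies as
published — complement receptor 1 down in M1 (−3.02), CD63 up in M2c
(+1.48), integrin alpha-L unchanged in M1 (0.66):

```r
calls <- classify_polarity(surface_marker_example()[-2])
dplyr::filter(calls, protein_id %in% c("CR1", "CD63", "ITGAL"))
#> # A tibble: 3 × 4
#>   protein_id M1        M2a       M2c
#>   <chr>      <chr>     <chr>     <chr>
#> 1 CR1        down      unchanged down
#> 2 ITGAL      unchanged unchanged down
#> 3 CD63       up        unchanged up
```

The imaging arm, on a synthetic video with 10 cells moving at 4 px/frame:

```r
vid <- simulate_motility_video(n_cells = 10, frames = 12, speed = 4, seed = 42)
seg <- segment_stack(vid)
seg
#> <segmentation_result> 12 frames, 120 objects (median 10 per frame)

tracks <- link_tracks(seg$objects, max_link_distance = 50, min_length = 5)
field_summary(track_metrics(tracks))
#> # A tibble: 1 × 4
#>   field_id n_tracks mean_speed mean_euclidean_distance
#>   <chr>       <int>      <dbl>                   <dbl>
#> 1 field_1        10       3.98                    40.6

evaluate_against_truth(tracks, vid)
#> <track_evaluation> purity 1.000, recall 1.000, speed bias -0.5% (10 tracks)
```

Ten tracks, planted speed recovered within half a percent, no identity
switches. `autoplot()` methods draw the PCA scores and trajectories;
`tidy()`/`glance()` return tabular summaries of venn overlaps, PCA,
group comparisons and track evaluations.

A command-line surface wraps the same functions
(`inst/scripts/polarscope`): `simulate-proteome`, `simulate-video`,
`proteome`, `segment`, `track`, `summarize`, `evaluate`.

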