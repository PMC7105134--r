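# petseg

Inter-observer variability of PET bulky-tumor segmentation strategies,
as a fully headless, reproducible R pipeline.

Quantitative FDG-PET analysis starts from a segmented tumor volume:
SUVmax, SUVmean, the metabolically active tumor volume (MATV, mL) and
total lesion glycolysis (TLG = MATV × SUVmean) are all read off the VOI.
For bulky tumors (MATV > 300 mL, irregular, heterogeneous) manual
delineation is slow and observer-dependent, and fully automatic methods
fail too often to run unsupervised. This package implements and
evaluates four workflows with decreasing user interaction:

1. **MANUAL** — percent-of-SUVmax shrink of a rough pre-marked mask,
   followed by voxelwise boundary editing;
2. **THRESHOLD** — an interactive percent-of-SUVmax slider (0–100%)
   inside the rough mask;
3. **GRADIENT** — the same slider guided by the PET gradient-magnitude
   image, whose ridges mark uptake boundaries independently of the
   display window;
4. **SELECT_BEST** — choice among four established automatic
   segmentations: 41% SUVmax, SUV > 4, SUV > 2.5, and a
   contrast-adapted method, `T = B + 0.5 (SUVpeak − B)` iterated to its
   fixed point with `B` the local background in a shell around the
   current VOI (SUVpeak = highest mean over the 1 mL / 1.2 cm-diameter
   spherical neighbourhood).

Patient scans are replaced by synthetic EARL-like phantoms with known
ground truth (`make_scenario_suite()`: both clinical voxel grids,
6.5 mm FWHM point-spread function, intra-tumor heterogeneity, adjacent
hot-organ confounders), and the six human raters by parameterised
stochastic observers (`default_observer_panel()`: experience sets bias,
threshold noise and edit rate; strategy sets the variance). The
evaluation machinery is the real thing: majority-vote reference
construction, Jaccard / sensitivity / PPV, percentage MATV and feature
differences, pairwise Kruskal-Wallis tests with Benjamini-Hochberg
correction (FDR 10%), and Wilcoxon signed-rank observer comparisons.

## Worked example

```r
library(petseg)

cfg <- phantom_config(shape = c(32, 32, 32), spacing = c(4, 4, 4),
                      tumor = list(list(center = c(64, 64, 64),
                                        radii = 22, uptake = 10)),
                      seed = 7)
cs <- generate_phantom(cfg)
cs
#> <phantom_case> lesion01: grid 32x32x32 @ 4x4x4 mm, MATV 43.0 mL

pan <- run_auto_panel(cs$image, cs$rough_mask)
pan$AUTO
#> <threshold_result> rule AUTO, threshold 5.367 SUV, 478 voxels (30.59 mL)
#>   converged: TRUE after 8 iterations (background 2.173 SUV)
sapply(pan, function(r) jaccard(r$mask, cs$ground_truth))
#>  41MAX   SUV4 SUV2.5   AUTO
#>  0.967  0.958  0.830  0.711
```

The 44.6 mL sphere voxelises to 43.0 mL; on this lesion the 41% SUVmax
contour is the best of the panel (Jaccard 0.967 against ground truth)
while the contrast-adapted method undersegments the blurred rim
(threshold 5.4 SUV after background correction converged in 8
iterations).

The full simulated study — 20 lesions × 6 observers × 4 strategies —
runs in about 90 s:

```r
study <- run_interobserver_study(n_lesions = 20, seed = 1)
study
#> Simulated PET inter-observer segmentation study
#>   20 lesions x 6 observers x 4 strategies (seed 1, MV: EXPERIENCED_ONLY)
#>   median pairwise Jaccard: SELECT_BEST 1.000, GRADIENT 0.989, THRESHOLD 0.946, MANUAL 0.827
#>   significant strategy comparisons (BH, q = 0.10): JC 5/6, %MATV 4/6
#>   select-the-best preferences: 41MAX 52 (43.3%), SUV2.5 37 (30.8%), SUV4 23 (19.2%), AUTO 8 (6.7%)
```

Inter-observer agreement rises as user interaction falls
(median pairwise Jaccard 0.83 → 1.00 from manual to select-the-best),
select-the-best and gradient are statistically indistinguishable from
each other but significantly better than threshold and manual — the
qualitative pattern the simulation is calibrated to reproduce.
`summary(study)` prints the per-strategy quartile tables, the
BH-corrected comparison matrix and the per-observer Wilcoxon results;
`plot(study)` draws the agreement boxplots. See the vignette
(`vignettes/interobserver-workflows.Rmd`) for the models, parameters and
their rationale.

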