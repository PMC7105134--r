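---
title: "Simulating inter-observer variability of PET bulky-tumor segmentation workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating inter-observer variability of PET bulky-tumor segmentation workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Delineating the metabolically active volume of a tumor on an FDG-PET scan
is the first step of almost every quantitative PET analysis: SUVmax,
SUVmean, MATV and TLG are all read off the segmented volume of interest
(VOI). For *bulky* tumors — large (MATV above 300 mL), irregular,
heterogeneous lesions typical of advanced lymphoma, sarcoma, melanoma or
lung cancer — fully manual delineation is slow and notoriously
observer-dependent, while fully automatic algorithms fail often enough
that unsupervised use is not defensible. A practical middle ground is a
family of workflows that *reduce* user interaction without removing the
user:

* **MANUAL** — shrink a rough pre-marked mask with a percent-of-SUVmax
  threshold, then add and delete voxels by hand;
* **THRESHOLD** — interactively move a percent-of-SUVmax slider
  (0–100%, integer steps) inside the rough mask until the contour looks
  right;
* **GRADIENT** — the same slider, but displayed over the PET
  gradient-magnitude image, whose ridges mark uptake boundaries
  independently of the display window;
* **SELECT_BEST** — pick the most plausible of four precomputed
  segmentations: 41% of SUVmax, fixed SUV 4, fixed SUV 2.5, and a
  contrast-adapted method (50% of SUVpeak with local background
  correction).

This package re-implements that four-workflow comparison as a fully
headless, reproducible pipeline: synthetic PET phantoms with known ground
truth stand in for patient scans, and parameterised stochastic observers
stand in for human raters. Everything downstream of the raters — the
majority-vote reference, the overlap and feature metrics, the
nonparametric statistics — is the real analysis machinery, applied
exactly as it would be to human delineations.

```{r, eval = FALSE}
library(petseg)
study <- run_interobserver_study(n_lesions = 20, seed = 1)
print(study)
summary(study)
plot(study)  # Jaccard by strategy, user-interaction increasing rightward
```

## The segmentation algorithms

All masks are restricted to the rough pre-marking mask, and a voxel is
included when its value is *strictly above* the threshold — the
convention follows the operative wording "higher than"/"above"; ties are
measure-zero on continuous data. One documented consequence: a 100%
threshold yields an empty mask.

**Percent-of-maximum and fixed thresholds.** `threshold_pct_max()` takes
SUVmax inside the rough mask (not the whole image) and keeps voxels
above `pct`/100 × SUVmax; `threshold_fixed()` keeps voxels above an
absolute SUV cut (4 and 2.5 are the conventional values).

**SUVpeak.** `suv_peak()` averages the image over a spherical
neighbourhood of every rough-mask voxel and reports the highest mean.
The neighbourhood is the EANM/UPICT 1 mL sphere, implemented as
voxel-centre membership within a 6 mm radius (the conventional "1.2 cm
diameter"; a volume-exact 1 mL sphere would have diameter 12.4 mm — the
printed diameter wins, and the radius is configurable). Membership is
computed in mm space, so the kernel adapts to anisotropic grids: it
holds 19 voxels on the 4×4×4 mm grid and 39 on the 3.1819×3.1819×2 mm
grid.

**The contrast-adapted AUTO method.** The threshold is the fixed point of

$$T \;=\; B + f\,(P - B),$$

with $P$ = SUVpeak, $f$ = 0.5, and $B$ the local background: the mean
image value over a shell of voxels whose mm-distance from the current VOI
lies in (2 mm, 10 mm]. Iteration starts at $T = fP$ and stops when the
threshold moves by less than `tol_suv` (0.001 SUV) or the VOI repeats
exactly (which pins the fixed point); `max_iter` = 100 guards
non-convergence, an empty shell falls back to $B = 0$ with a warning.
The shell geometry and update rule are this package's concrete
reconstruction of "local background correction" in the
contrast-oriented method family; inner/outer radii, peak fraction and
tolerance are all parameters of `auto_params()` so alternatives can be
swapped in. On noiseless two-level phantoms the iteration recovers
$B + 0.5(P-B)$ to the stated tolerance (this is a test).

**Gradient image.** `gradient_image()` computes the Euclidean magnitude
of spacing-aware Gaussian-derivative filters (σ of one voxel pitch per
axis), in SUV/mm. Plain central differences are noise-dominated on PET;
the Gaussian-derivative scale is configurable. The operator is exact on
linear ramps whatever the voxel spacing (also a test).

No connected-component post-processing is applied by default: adjacent
hot organs really do leak into threshold-based VOIs in practice, and
keeping that failure mode visible is part of the design.

## The phantom generator

`generate_phantom()` builds, in order: a piecewise-constant uptake map
(uniform background, default SUV 1; ellipsoidal tumor components, SUV
4–15; optional hot "organ" confounders); a multiplicative low-frequency
heterogeneity texture inside the tumor (a Gaussian random field smoothed
to a 15 mm correlation length, scaled by `texture_amplitude`, clipped
positive — one knob that produces heterogeneous uptake without
committing to discrete subregions); an isotropic Gaussian point-spread
function (default FWHM 6.5 mm, σ = FWHM/2.3548, matching the
post-reconstruction smoothing of EARL-compliant scans, with reflect
boundary padding); and additive zero-mean Gaussian noise in SUV units
(default SD 0.08, a plausible post-reconstruction noise level — the
emulation is at summary level, not a projection-space simulation). The
ground truth is the pre-blur tumor support; the rough pre-marking mask
is its spacing-aware dilation (default 10 mm), clipped to exclude
confounder organs unless a scenario deliberately includes them.

`make_scenario_suite()` mirrors the study design of twenty scans over
four cancer types, five each, cycling four archetypes:

| archetype | grid | lesion |
|---|---|---|
| lung-like | 4×4×4 mm, 44³ | sphere, r 18–30 mm, SUV 6–12 |
| lymphoma-like | 4×4×4 mm, 48³ | two-lobe ellipsoid, main r 42–46 mm (MATV > 300 mL), SUV 5–9 |
| melanoma-like | 3.1819×3.1819×2 mm, 48×48×72 | sphere, r 14–22 mm, SUV 8–15 |
| sarcoma-like | 3.1819×3.1819×2 mm, 48×48×72 | elongated ellipsoid, SUV 4–10 |

Two cases carry adjacent-organ confounders reproducing the two reported
failure modes: a "heart" partially annexed by the rough mask (so every
non-manual workflow inherits part of it), and a "kidney" outside the
rough mask (so only manual editing can annex it). Tumors sit at least
3 FWHM from the grid edge, which is what makes the blur
mass-conservation property hold and keeps the suite free of boundary
artefacts. Grid sizes are chosen so the full factorial runs in minutes
on one CPU; they are generous relative to the lesions (a 48³ coarse grid
is a 19 cm field of view).

What the phantoms deliberately do **not** emulate: projection-space
noise correlation, scanner-specific reconstruction, respiratory motion,
CT anatomy, and the intensity-window display effects that influence
human raters. Passing tests on these phantoms therefore demonstrate the
*pipeline's* correctness and the *qualitative* behaviour of the
strategies, not clinical performance on real scans.

## The observer model

The six human observers are replaced by `observer_profile()` objects —
this generative model is entirely synthetic, and its knobs map
one-to-one onto the effects the evaluation is meant to measure.

A simulated interactive observer is an *anchored noisy threshold
selector*: the "satisfactory" percent threshold is the overlap-optimal
value for the lesion (the integer slider value maximising Jaccard
against ground truth — anchoring satisfaction to an objective optimum
avoids unfalsifiable perception modelling), plus an experience bias,
plus Gaussian noise with a per-strategy standard deviation, clamped to
[0, 100] and rounded to the integer slider step. Because the slider is
discrete, low-noise observers can coincide *exactly* — agreement has a
point mass at Jaccard 1, for the interactive strategies just as for
select-the-best.

The per-strategy noise encodes how strongly the display anchors the
boundary: `sd_gradient ≤ sd_threshold ≤ sd_manual`. The experience bias
(positive = smaller VOIs, the documented novice tendency) applies to the
manual and threshold workflows but *not* to the gradient workflow: the
gradient display exists precisely to decouple the perceived boundary
from the intensity window, so the window-driven bias is taken as removed
there. Manual observers additionally toggle each voxel of the mask's
morphological boundary shell (one voxel pitch, clipped to the rough
mask) with probability `manual_edit_rate`, and in confounder scenarios
may annex nearby confounder voxels with probability `annex_rate` — the
only way a simulated mask escapes the rough mask, reproducing the
kidney-annexation outliers in the SUVmax feature differences.
Select-the-best observers pick the overlap-optimal panel member with
probability `select_accuracy_p`, otherwise uniformly among the other
three.

The default panel (`default_observer_panel()`):

| | bias (pct) | sd manual/threshold/gradient | edit rate | select accuracy |
|---|---|---|---|---|
| experienced (o1–o3) | 0 | 4 / 3 / 0.8 | 0.05 | 0.85 |
| novice (o4a, o4b, o5) | +3 | 7 / 5 / 1.2 | 0.15 | 0.65 |

with `annex_rate` 0.5 for o4a/o4b. No quantitative observer model can be
read off the study being emulated, so these numbers are calibration
choices: the experience contrasts and the variance ordering are fixed by
the design, and the magnitudes were chosen (once, against the default
20-lesion suite) so that the simulated study reproduces the *qualitative*
orderings of the original findings — agreement improving as user
interaction decreases, select-the-best and gradient statistically
indistinguishable from each other but distinguishable from threshold and
manual. They are validated by exactly that reproduction and nothing
more; absolute agreement levels on these phantoms (median pairwise
Jaccard ≈ 0.83–1.00) are higher than with real tumors and real raters.

Every cell of the lesion × observer × strategy factorial is seeded from
a stable hash of its labels XOR the global seed, so a single cell can be
re-run in isolation bit-identically and adding observers never perturbs
existing cells.

## Reference construction and metrics

With no ground truth in the emulated setting, the reference is the
majority vote (`majority_vote()`): a voxel belongs to the consensus iff
strictly more than half of the included segmentations contain it (3
observers → ≥ 2 votes; 6 → ≥ 4; even-split ties excluded). The default
policy builds it from the experienced observers only (`mv_policy =
"EXPERIENCED_ONLY"`), with `"ALL"` available for comparison. The vote
always lies between the intersection and union of its inputs — the
operational version of "visually checked for plausibility".

Pairwise agreement uses the Jaccard coefficient and a *symmetric*
percentage MATV difference, 100·|v₁−v₂|/mean(v₁,v₂) (observer pairs
have no natural ordering, and the emulated analysis does not state its
denominator). Against the majority vote, sensitivity and positive
predictive value follow the TP/FP/FN forms SE = TP/(TP+FN),
PPV = TP/(TP+FP) — the set-notation variants printed alongside them in
the source material contradict these forms, and the TP-forms are the
internally consistent choice — combined as their arithmetic mean
(PPV/SE). Reference-based feature differences use
100·(ref − obs)/ref, the sign convention under which an observed SUVmax
3.925× the reference scores −292.5%, matching the reported manual
outliers; SUVmax is computed inside the delivered mask, which is what
makes annexed-kidney outliers visible at all. TLG = MATV × SUVmean is
enforced as an identity.

## Statistics

Strategy comparisons use the Kruskal-Wallis rank test applied to pairs
of strategies (a two-group KW is the tie-corrected rank-sum test; a
global four-group KW is also reported for context), with
Benjamini-Hochberg step-up correction at a 10% false discovery rate
applied per metric family (the six Jaccard comparisons are one family,
the six %MATV comparisons another). Observer comparisons use the
Wilcoxon signed-rank test on absolute reference-based %MATV differences,
paired by lesion, BH-corrected within each strategy. Zero differences
are dropped (Wilcoxon's original treatment); the exact distribution is
used up to 25 non-zero untied pairs and a continuity-corrected normal
approximation beyond — with tied differences the approximation is used,
as in standard R. The test engines are `stats::kruskal.test`,
`stats::wilcox.test` and `stats::p.adjust`; the test suite checks them
against written-out rank formulas and exact sign-assignment enumeration
on small instances, and checks the full BH comparison procedure's
false-rejection rate under null simulation.

## Numerical choices and degenerate inputs

* Voxel indices are 1-based in R; all physical computation uses
  voxel-centre coordinates in mm, centre of voxel *i* at (i−0.5)·spacing.
  With two anisotropic grids in play, mm space is the only consistent
  frame — dilation, erosion, the SUVpeak kernel, the AUTO shell and the
  gradient operator all take spacing into account.
* SUV conversion is the bare ratio concentration/(activity/weight);
  decay correction is assumed already applied by reconstruction, and
  converting an already-converted image is an error rather than a silent
  double division.
* Masks written to NIfTI are 0/1 uint8; images are float64, so a write
  → read round trip reproduces values bit-exactly and spacing to float32
  precision (the NIfTI pixdim field). Affines are neither interpreted
  nor needed: nothing in the analysis uses patient-space orientation.
* Centre-sampling rasterisation of spheres carries lattice error: about
  +9% to +20% at a radius of 3 voxel pitches (alignment-dependent),
  below 5% only from roughly 6 pitches. The suite's lesions are all well
  above that; the volume-accuracy property is asserted in that regime.
* Empty rough masks, empty references, both-empty Jaccard, zero
  reference values and non-positive volumes are contract violations and
  raise errors; an all-tied Kruskal-Wallis input returns H = 0, p = 1,
  and an all-zero Wilcoxon difference vector returns p = 1.
* Thresholding uses strict inequality throughout; `pct = 100` is empty
  by construction and documented as such.

## Known limitations

The observer model is the minimal generative mechanism with the right
knobs, not a psychophysical model: no display-window effects, no
learning or fatigue over the session, no inter-observer correlation
beyond the shared lesion. The phantom noise is additive white Gaussian
in SUV units, not reconstruction-correlated. The AUTO background shell
is a declared reconstruction of an under-specified method. Absolute
metric levels therefore transfer to real data only qualitatively; the
package's claims are about the machinery and the ordering of strategies,
which is what the acceptance checks assert.
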