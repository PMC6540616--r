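---
title: "Methods: interaction scoring and image quantification in synquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction scoring and image quantification in synquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synquant)
```

synquant quantifies two kinds of raw data produced by studies of
presynaptic differentiation: microplate growth kinetics from a split-DHFR
protein-complementation assay (PCA), and multi-channel fluorescence images
of co-clustering, coculture and morphology assays. This vignette describes
the models and procedures, the parameters that matter, what the synthetic
generators do and do not emulate, and the numerical choices behind the
implementation.

## The DHFR interaction score

In the PCA, two candidate interaction partners are fused to complementary
fragments of a methotrexate (MTX)-insensitive DHFR. Yeast carrying both
fusions grow in MTX-containing media only to the extent that the partners
bind and reconstitute the enzyme, so the MTX growth rate, relative to
drug-free growth of the same strain, reports interaction strength.

The scoring pipeline is:

1. **Blanking.** The media blank is estimated as the mean of all blank-well
   readings within the first hour of the run (`estimate_blank()`), falling
   back to the global minimum reading on plates without blank wells. The
   assay description says only that readings are blanked; using the early
   readings of dedicated blank wells is standard reader practice and easy
   to validate.
2. **QC.** Wells with reading anomalies are excluded. Such exclusions
   are traditionally done by eye; a repository cannot inspect visually, so
   `qc_wells()` flags a well when any consecutive-reading decrease exceeds
   20% of the prior reading (configurable). Flags are advisory and
   reported, never silently applied, and excluding a flagged well cannot
   change any other well's result (there is no cross-well coupling before
   the ratio stage).
3. **Slope fitting.** Blanked OD600 is log2-transformed and an ordinary
   least-squares slope is fitted over the points whose log2 value lies in
   the closed window [−3, −2] (`fit_linear_slope()`; the alternative
   window [−3, −2.2] is a config option). The window bounds are treated as
   inclusive and at least 3 points are required — the assay description
   does not fix either choice, so both are configurable. Fits agree with a
   brute-force normal-equations evaluation to 1e−10.
4. **Ratios.** For each MTX well, the slope is divided by the mean slope
   of the same strain's DMSO-only wells from the same experiment
   (`mtx_dmso_ratio()`). "Same experiment" is interpreted as same plate.
5. **Scoring.** `interaction_score()` rescales each ratio by the control
   strains measured on the same plate:
   score = (ratio_x − ratio_NC) / (ratio_PC − ratio_NC),
   so 0 is negative-control growth and 1 is wild-type growth. Scores are
   computed per MTX well and then averaged (mean ± SEM via
   `aggregate_scores()`), not computed from averaged slopes — this matches
   the per-well definition of the ratio and propagates replicate scatter
   into the SEM. When two negative-control constructions are present the
   first one (NC1, the bait-side replacement that anchors the score scale)
   is the default; the choice is per-ligand configurable. Controls closer
   than 1e−6 in ratio are reported as a degenerate-controls error for the
   whole experiment rather than producing unstable scores.
6. **Display.** Raw scores are kept unclipped (negative scores and scores
   above 1 occur and are meaningful); `clip_score()` maps to [0, 1] for
   display only, and `bin_for_heatmap()` assigns the five heatmap bins
   with lower-inclusive half-open boundaries ([0.8, 1] closed at the top).
   The usual bin notation does not resolve which side of a boundary a
   tied value falls on; lower-inclusive is documented and configurable by
   pre-shifting if a different convention is needed.
7. **Specificity.** `classify_specificity()` calls a mutant nonspecific
   when its score is below 0.3 (strict inequality) for at least three
   ligands, the rule used to exclude broadly disruptive mutations.

### The plate simulator

No growth model is implied by the assay itself; the simulator needs one
only to produce curves with a clean log-linear window. `growth_params()`
uses a logistic in linear OD space — the standard microplate shape — with
the rate expressed in log2-OD units per hour so simulated rates are
directly comparable to fitted slopes. Defaults: inoculation at
blank-subtracted OD 0.05 (the assay's dilution target), carrying capacity
1.2, lag 2 h, media blank 0.08, additive Gaussian reader noise with SD
0.002 OD truncated at zero, readings every 10 min for 24–30 h, three
replicate wells per strain per media, and four blank wells. The blank-well
count and placement are not specified by the assay description; four is a
simulator choice, not an inference.

Inside the fitting window (OD 0.125–0.25 against capacity 1.2) the
logistic is not exactly exponential, so a fitted slope is attenuated by a
factor of roughly 1 − OD/K averaged over the window. Because the window is
fixed in OD, that factor is the same for every well regardless of rate,
and it cancels in the MTX/DMSO ratio; control anchoring then removes any
residue. This is why noiseless plates score the positive control at
exactly 1 and the negative control at exactly 0, and why simulated rate
ratios are recovered to three decimals.

`inject_artifact()` reproduces the abrupt-drop anomaly that the QC rule
exists to catch, with a configurable time and drop fraction.

Validation problem sizes: score-recovery runs use plates of five strains
(two controls) over 30 h at reader noise SD 0.003, averaged over 20 seeds,
and require the mean recovered score to sit within ±0.05 of the analytic
value (ρ − ρ_NC)/(ρ_PC − ρ_NC).

## Image quantification

All ROIs are binary masks built by four primitives that mirror the
standard FIJI workflow: lower-inclusive intensity thresholds
(`threshold_mask()`; thresholds are explicit per image, with an Otsu
option provided as a clearly-labeled extension for synthetic tests),
Euclidean-disk dilation (`dilate_mask()`, the "Enlarge" operation; a pixel
is set iff its Euclidean distance to the mask is at most the radius,
validated exactly against a distance-transform oracle), inversion
(`invert_mask()`, "Make Inverse") and pixelwise Boolean combination
(`combine_masks()`).

**Rolling-ball background subtraction** (`rolling_ball_subtract()`,
default radius 14 px) estimates the background as the grayscale opening of
the image with a true ball structuring element —
b(dx, dy) = sqrt(r² − dx² − dy²) — and subtracts it, flooring at zero. The
exact ball (no paraboloid approximation, no pre-shrinking) was chosen
because it is the simplest definition that is oracle-testable: the
implementation matches a literal per-pixel erosion-then-dilation to 1e−9,
removes constant images entirely, preserves peaks narrower than the ball
to within 5%, and its background estimate is idempotent. Boundary pixels
use the adjoint convention (out-of-image samples ignored), which
guarantees background ≤ image everywhere.

**HEK co-clustering.** `quantify_hek_scene()` follows the assay recipe:
rolling-ball subtraction on the liprin channel, threshold ROIs from the
cell fill and the background-subtracted liprin channel, then for each cell
the mean of the (never thresholded) V5 channel inside the liprin-positive
ROI divided by the mean over the liprin-negative remainder of the cell
(`coclustering_ratio()`). Two implementation details depart from a purely
literal reading, both to keep partial-volume pixels out of the
denominators: segmented cell masks are eroded by 2 px (membrane edge), and
a 2-px guard ring around the cluster mask is excluded from the
outside-cluster ROI. Without the guard ring, bright cluster-edge pixels
that fall just outside the half-maximum threshold contour inflate the
denominator and bias high ratios downward by ~8%; with it, simulated
ratios of 0.5–4 are recovered to well within 10% at 5% noise, and exactly
when ground-truth masks are supplied on noiseless scenes.

**Coculture contact measures.** `coculture_contact_measures()` builds the
contact ROI as COS ∧ axon ∧ ¬(MAP2 dilated by 5 px) — the dilation
excludes spine-associated native synapses adjacent to dendrites — and the
COS ROI as COS ∧ ¬(dilated MAP2). Synapsin is thresholded high, "to
include only punctate signal"; since no numeric rule is given, the
threshold is explicit config, with an optional punctum size filter (off by
default). Both thresholded-area and integrated-intensity variants are
reported per ROI pixel; area is the default measure. An empty contact ROI
yields NA (absent), never zero. Measures are per transfected COS cell.
`density_from_coverage()` converts an area-coverage measure to a punctum
density through the Boolean-model inversion d = −ln(1 − coverage)/a;
independently placed puncta overlap, so raw coverage saturates and
understates dense ROIs (~10% at the default on-contact density).

**Surface matching and normalization.** `match_surface_expression()` keeps
cells whose mean surface-V5 lies within a percentile band of a reference
group; "high or low" is not quantified in the assay description, so the
default 10th–90th band is an explicit decision (0/100 are unbounded).
`normalize_to_control()` divides each value by its own culture's
control-condition mean, so every culture's control mean is 1 exactly;
cultures lacking the control are flagged, not dropped.

**Field morphology.** `morphology_measures()` reports Tau- and
MAP2-positive area per DAPI nucleus and the Tau/MAP2 area ratio; nuclei
are 4-connected components above 30 px (noise-speck suppression; the size
is configurable and not taken from the assay description).

### The scene generators

Scenes are minimal geometric stand-ins, not photorealistic micrographs:
cells are disks (HEK) or wobbly blobs (COS), axons and dendrites are
random-walk ribbons, puncta and clusters are hard disks with
Gaussian-blurred edges (σ = radius/3) so thresholding behaves realistically.
Noise is additive Gaussian truncated at zero; the liprin channel optionally
carries a constant offset and a linear gradient to exercise rolling-ball
subtraction. Structural coculture channels are rendered crisp so threshold
ROIs equal the ground-truth masks exactly on noiseless scenes, which is
what makes the mask-algebra contracts testable end to end. Poisson punctum
counts scale with the full ROI area while centers are confined to the ROI
interior, so each punctum lies wholly within its class and the expected
punctate area per ROI area is analytic (density × πr²).

What passing these tests shows is that the quantifiers faithfully measure
what the ROI definitions say on images whose statistics are known. It does
not show robustness to the features real micrographs add — point-spread
blur across ROI boundaries, spatially correlated background, segmentation
ambiguity, out-of-focus light — so thresholds on real data remain a
per-image analyst decision, as in the manual workflow. There is no 3D
support: inputs are assumed already projected to a single plane.

Validation problem sizes: HEK scenes are 192 × 192 px with 3 cells and 6
clusters per cell, 20 seeds per recruitment ratio in {0.5, 1, 2, 4};
coculture and field scenes are 256 × 256 px; oracle comparisons run on
32 × 32 images where the literal per-pixel oracles are affordable.

## Group statistics

The bespoke quantities live upstream; group comparison is deliberately
delegated to standard routines. `compare_groups()` uses the Wilcoxon
rank-sum (Mann-Whitney) test for two groups and the Kruskal-Wallis test
followed by Dunn's pairwise z-comparisons for three or more.
`dunn_test()` computes the standard tie-corrected Dunn statistic; it is
validated against `kruskal.test()` through the exact identity z² = H for
two groups, and its optional multiplicity adjustment (default: none beyond
Dunn's own z-tests, since no adjustment method is part of the assay
definition) never decreases a p-value. `check_normality()` provides the
Shapiro-Wilk pre-check that motivates the rank-based choices.

## Known limitations

- The growth model is a single logistic: no diauxic shifts, evaporation,
  or edge effects, so QC sensitivity to those artifact shapes is untested.
- Scene ground truth assumes the generator's geometry; quantifier accuracy
  on real micrographs depends on threshold choices the package cannot
  make.
- Dunn's test uses the large-sample normal approximation (as standard);
  very small groups should be compared with exact methods instead.
- The score scale is anchored per plate; comparing scores across plates
  assumes the controls behaved consistently, which the QC report helps
  verify but cannot guarantee.
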