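---
title: "Methods: IFC mitochondrial phenotyping in mitoifc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IFC mitochondrial phenotyping in mitoifc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoifc)
```

## The measurement model

Imaging flow cytometry captures a multi-channel image of every cell event.
From the channels brightfield, NAO (cardiolipin / mitochondrial mass), TMRM
(membrane potential), DRAQ5 (nucleus) and MitoSox (mitochondrial superoxide),
`mitoifc` computes five per-cell features:

1. **Membrane potential** — TMRM accumulates in polarized mitochondria; the
   residual signal after uncoupling with FCCP is unspecific background, so the
   working quantity is the background-subtracted difference
   ΔMMP = TMRM(untreated) − TMRM(FCCP). Negative differences can arise from
   staining drift; they are retained and marked (`negative_dmmp`) rather than
   clipped, so quality problems stay visible.
2. **Mitochondrial mass** — integrated NAO intensity, read in the
   FCCP-treated tube so that membrane potential does not modulate the dye's
   apparent binding.
3. **Swelling** — the total area (µm²) of the TMRM mask.
4. **Fission/fusion state** — the form factor perimeter²/(4π·area) of
   bright TMRM spots: 1 for a circular fragment, larger for tubular or
   branched networks. Per sample it is computed from the median spot area and
   the median spot perimeter.
5. **ROS** — MitoSox intensity integrated over the cytoplasm only. MitoSox
   binds nucleic acids nonspecifically, so the nuclear mask (from DRAQ5),
   dilated by a 2 px safety margin against edge bleed, is subtracted from the
   cell mask (from brightfield) before integration.

Events enter feature extraction only after three gates, applied in order:
*nucleated* (integrated DRAQ5 above threshold, at least one nuclear
component), *in focus* (normalized gradient energy of the brightfield image
above threshold) and *singlet* (exactly one nuclear component, cell-mask
aspect ratio within bounds). The per-sample summary is the median over gated
cells for every feature; the FCCP response ratio uses the across-cell *mean*
TMRM intensity of the untreated over the FCCP tube, because that composite is
conventionally defined on means. Both aggregation choices are arguments, not
constants.

### The bright-spot mask

The spot mask keeps in-cell pixels whose intensity strictly exceeds both the
(100 − threshold)-th percentile of the in-cell intensity distribution
(threshold 10 → brightest decile boundary) and a robust background floor.
The floor is the in-cell median plus 6 standard deviations of the
sub-90th-percentile values; a MAD-based floor fails here because additive
noise clamped at zero can put more than half of the background pixels at
exactly 0, collapsing the MAD and flooding the mask with noise specks.
Components are labelled at 8-connectivity (configurable to 4) in
deterministic scanline order. For the form-factor mask, components larger
than 2 µm² are removed (`max_area`, interpreted in µm² and disableable with
`max_area = 0`); the total-area (swelling) mask is unbounded.

### Perimeter estimation

Form factors are highly sensitive to perimeter bias: counting pixel edges
overestimates a disc's perimeter by roughly 27% in form-factor terms. The
package therefore measures the 0.5-level marching-squares contour
(`contourLines`) of the Gaussian-smoothed mask. The smoothing sigma grows
with the object's minor bounding-box extent (max(1, extent/16)) so that an
integer-upscaled, blockier rendering of the same shape measures the same
perimeter; with this choice a digitized disc has form factor 0.984 and a
100×10 bar 3.73 (closed form 3.85), and the estimate drifts less than 2%
under 2× upscaling. Specks so small that smoothing pushes their peak below
the contour level are contoured unsmoothed.

## Normalization and flagging

Only two donors are measured per run (a patient and a healthy control), so
absolute intensities carry run-level effects (laser power, staining
efficiency, time since staining). Every feature of every subject is therefore
expressed as percent of the in-run control, which removes any multiplicative
run effect exactly. The six healthy reference lines are each measured against
one designated normalizer control; per feature, the lowest and highest of the
six control percentages form the reference interval, and a value is abnormal
when it falls *strictly* outside ("exceeds" the range read literally —
boundary values are normal). Missing features propagate as missing flags and
are excluded from the any-feature summary rather than treated as normal.

Two readings of the control normalization are possible (against one
designated control, or against each control's own mean); the package
implements the designated-control reading, which keeps control percentages
comparable to patient percentages, and the alternative can be emulated by
passing a different derived table. Composite quantities: the FCCP response
percentage is the subject's mean-intensity ratio over the control's ratio;
ROS-per-mass is the ratio of the normalized MitoSox percentage to the
normalized NAO percentage (1 = ROS in proportion to mass).

`combination_detection()` quantifies the screening value of feature panels:
for each subset S of the five features, the fraction of patients flagged on
at least one member of S, aggregated per subset size to mean/min/max. The
size-5 value is identical to the any-feature fraction by construction, and
minima are monotone in subset size because detection is a union.

## Cohort analysis

Clustering operates on the donors × 5 matrix of normalized percentages with
Euclidean distance and Ward linkage (`hclust`, `ward.D2`); the 2-D UMAP
embedding (8 neighbors, min_dist 0.01, Euclidean, fixed `random_state`) is
visualization only. The number of clusters is chosen as the largest relative
gap between successive merge heights over k ∈ 2..6 — a reproducible stand-in
for visual dendrogram inspection — with mean silhouette widths reported as a
diagnostic and a forced `k` available. Per-feature differences between the
two clusters use Welch's t test; disease subgroups of at least three
patients are compared with the reference controls by two-sided Mann–Whitney
U (exact when the combined sample is ≤ 12 and tie-free, normal approximation
with tie correction otherwise); clinical phenotypes (binary Yes/No, NA
excluded pairwise) enter Spearman correlations and Fisher's exact
cluster–phenotype tests with conditional-MLE odds ratios. Raw p values are
reported; Benjamini–Hochberg q values accompany the Welch panel
side-by-side because no correction is part of the original analysis.
Donors with a missing feature are dropped from clustering by default
(median imputation available).

The UMAP embedding is computed by the `umap-learn` reference implementation
through a bundled python helper; several seeds can be embedded in one
process, which matters because the JIT compilation dominates a single run.

## The synthetic-data module

Two generators make every stage testable with known ground truth.

**Cell renderer** (`render_cell`, `generate_sample`). A fibroblast is a
brightfield disc (default radius 80 px at 0.33 µm/px on a 256×256 canvas,
63× magnification scale) with an off-centre nucleus and
`n_mito_components` mitochondria drawn as persistent random-walk skeletons
(`branch_elongation` steps) dilated by `swelling_scale` px. The three knobs
map one-to-one onto fragmentation (component count), form factor (skeleton
length) and swelling (dilation radius). Placement retries keep components
disjoint with a 2 px gap — or raise, so ground truth never silently disagrees
with the request. TMRM and NAO paint the mitochondrial pixels; under FCCP the
TMRM level is multiplied by `tmrm_fccp_floor` (default 0.2), and both members
of a pair share their geometry exactly (same seed, same RNG stream). MitoSox
covers the cytoplasm with a nuclear confound at 50% of the cytoplasmic level,
so the nucleus-excluding mask measurably changes the readout. Doublets
(second nucleus at 2.6 nuclear radii) and defocus (Gaussian blur, sigma 3)
are injected at configurable rates and recorded in ground truth. Noise is
additive Gaussian clamped at zero; run and donor effects are multiplicative
log-normal. The renderer does not model fluorescence spillover, PSF physics
or camera statistics — tests passing on it demonstrate the correctness of
masks, gates and arithmetic, not robustness to instrument-specific optics.

**Cohort generator** (`cohort_design`, `generate_cohort_table`). The
feature-level fast path emulates the study structure directly: each of the
31 patients shares a run (and its log-normal intensity scale, sd 0.2) with
one of six healthy lines, and each healthy line is additionally measured in
a control run against the designated normalizer. Every raw feature is
baseline × run-scale × donor-effect × log-normal noise, and the planted
percentage (donor effect × noise ratio × 100) is stored as ground truth, so
run-scale cancellation and normalization recovery are testable to floating
point. Default effects encode the two response groups: cluster 1 (16
patients) with membrane potential ×0.80, mild fragmentation (form factor
×0.90) and raised ROS (×1.25); cluster 2 (15 patients) with membrane
potential ×1.25, mass ×1.30, swelling ×1.35 and an exaggerated FCCP response
(×1.6). Healthy measurement noise is 5% (log-sd 0.05) and patient
heterogeneity 10% — values chosen once as plausible for fibroblast assays of
this kind. Under these conditions the six-control min–max ranges are
narrow, so synthetic detection rates (any-feature ≈ 100%, single-feature
≈ 55–90%) run above the rates a real cohort shows; the synthetic cohort is a
correctness instrument, not a power calculation. The image-mode pipeline
maps the same effects onto renderer parameters, with one coarseness: the
dilation radius is integer, so small swelling shifts quantize away at the
default radius (the feature-level path carries them exactly).

## Numerical choices and edge cases

* Percentile and floor use strict inequality, so a blank channel yields an
  empty mask (zero components) rather than an error.
* `form_factor()` returns NA for zero spots or zero median area; downstream
  code propagates NA and reports, never zero-fills.
* A control value ≤ 0 makes the corresponding percentage missing; a run
  without exactly one control is an error naming the run.
* Welch tests on degenerate (constant) groups report missing p with a
  warning; Fisher tables with an empty margin report p = 1 with an undefined
  odds ratio.
* Ward heights from `ward.D2` satisfy height² / 2 = within-cluster
  sum-of-squares increase; the test suite checks the full merge sequence
  against brute-force objective minimization for n ≤ 8.
* All generators and the pipeline are seed-deterministic; `embed_umap` fixes
  `random_state` and records the seed on its output.

## Problem sizes

The test suite and the acceptance script run the default cohort (31 patients,
6 controls) at the feature level, single rendered cells at full 256×256
resolution, miniature image-mode cohorts (6 patients, 3 cells/sample, 96×96
canvas), and 20-seed repetitions for the stochastic clustering and embedding
properties. These sizes were chosen so the full suite completes in about a
minute while still exercising every stage end to end.

## Known limitations

* The bright-spot operator of the original acquisition software is
  proprietary; the percentile-plus-floor re-implementation reproduces its
  semantics deterministically but is not bit-compatible with it.
* The renderer's flat-disc brightfield makes the focus gate trivially
  separable; real defocus is subtler, and the gate threshold is exposed as
  configuration rather than asserted.
* No fluorescence compensation or spillover is modelled; channels are
  rendered independent.
* TMRM efflux kinetics (signal drift over the ~30 min acquisition window)
  are not modelled; the in-run normalization absorbs only their
  run-multiplicative part.
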