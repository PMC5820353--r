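---
title: "Quantifying GABAergic terminal subtypes in 3D fluorescence stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying GABAergic terminal subtypes in 3D fluorescence stacks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cortical GABAergic interneurons fall into largely non-overlapping classes
marked by the calcium-binding proteins calbindin (CB), calretinin (CR) and
parvalbumin (PV). Their axon terminals (boutons) synthesize GABA with two
enzyme isoforms, GAD65 and GAD67, and a terminal may contain either isoform
or both. In postmortem human tissue these quantities are only accessible by
multiplex immunofluorescence: five-channel 3D confocal stacks (marker, vGAT,
GAD65, GAD67, and a lipofuscin autofluorescence channel), imaged at
0.267 × 0.267 × 0.25 µm voxels over a 512 × 512 pixel field.

`gadpuncta` implements the complete quantification pipeline for such stacks —
segmentation of terminal-scale puncta, depth quality control, lipofuscin
exclusion, object-based colocalization classification, laminar density
quantification with hierarchical averaging, and the associated inference —
together with a synthetic-scene simulator that stands in for the raw images,
which are not publicly deposited.

## Segmentation

Each analysis channel is band-passed with a difference of Gaussians
(σ = 0.7 and 2.0 pixels, applied along all three axes; voxel anisotropy is
mild at 0.267 vs 0.25 µm). Negative responses are clipped and the result is
rescaled linearly to the 16-bit range so that the fixed 25-gray-level
threshold increment is meaningful on filtered data regardless of channel
brightness. The filtered channel is used for segmentation only; every
intensity measurement is taken on the unfiltered channel.

The seed threshold is the Ridler–Calvard (ISODATA) fixed point
`T = (mean below T + mean above T) / 2`, computed on an integer gray-level
histogram so each iteration costs O(1). Iteration stops when the update falls
below 0.5 gray levels *and* the integer split level is self-consistent; the
second condition prevents stopping one split level short of the true fixed
point (verified against an exhaustive fixed-point search in the tests).
Constant images are reported as degenerate.

Connected components (26-neighborhood by default) above the seed threshold
are size-gated to 0.05–0.7 µm³ (3–39 voxels at the default geometry).
In-gate components are accepted and frozen; over-gate components are
recursively re-thresholded within their own voxel set at +25 gray levels
until their pieces fall inside the gate or the 16-bit maximum is exceeded
(unsplittable bright debris is discarded); sub-gate fragments are discarded.
Because a threshold step that removes no voxel of a component cannot change
it, the implementation jumps directly to the next voxel-removing multiple of
25 — the result is identical to stepping one increment at a time, which the
tests verify against an exhaustive ladder oracle. Accepted masks are disjoint
by construction, so one physical punctum can never be counted at two
thresholds.

A global per-component ladder was the other plausible reading of the
iterative procedure; per-component recursion was chosen because it freezes
well-formed puncta at the lowest threshold that isolates them instead of
eroding them further while an unrelated bright object is being split.

## Depth-bin quality control

Objects near the axial faces of a stack suffer edge truncation, antibody
penetration gradients and fluorochrome-dependent attenuation. Every mask
centroid is mapped onto a normalized 40-bin depth axis
(`bin = floor(z × 40 / n_planes) + 1`). Normalization conventions sometimes
get written as a rescaling of the z coordinate by `n_planes / 40`; taken as a
multiplication that would expand rather than normalize, so the implementation
divides — the only form that places stacks of different depths on a common
axis.

Per stack and channel, each bin's object count and the mean own-channel
object intensity are profiled. For each channel × metric family (counts for
the four analysis channels; intensity for vGAT and GAD67, both configurable),
a one-way ANOVA across bins — stacks as replicates — gates Tukey HSD pairwise
comparisons: pairs are flagged only when the omnibus test is significant at
α = 0.05 (the conventional post hoc practice; α is configurable). The analysis window is the longest contiguous run of
bins containing no flagged pair for any family, ties broken toward the
coverslip. By default the pipeline pools the profiles of all stacks into one
window (`zbin_scope = "pooled"`): the staining experiments share a single
imaging protocol, so depth artifacts are common to them, and one window keeps
analyzed volumes — the density denominators behind cross-marker proportions —
strictly comparable. Per-experiment windows (`zbin_scope = "experiment"`)
remain available; at desk-scale densities they differ in width between
sparse and dense experiments purely through test power, which leaks a
differential edge bias into marker proportions. The run search is an exhaustive scan, and the tests compare it
against an independently coded oracle built on `stats::aov` +
`stats::TukeyHSD`.

Masks are also restricted to the central 490 × 490 pixels (11-pixel margins
in a 512-pixel field) before profiling. The analyzed volume — the density
denominator — is the cropped XY window times the selected fraction of
z-planes, never the full stack volume.

## Lipofuscin exclusion

Lipofuscin autofluoresces across the visible spectrum, so it appears in all
five channels and must be removed object-wise. The lipofuscin channel is
thresholded with Ridler–Calvard and labeled with **no** size gate. Two
numerical safeguards matter on realistic data: the channel is first smoothed
with a σ = 2 px Gaussian, because the ISODATA fixed point of an almost
unimodal histogram (bright blobs occupying ≪1% of voxels over camera noise)
otherwise lands inside the noise; and if the above-threshold fraction still
exceeds 5% of the volume the channel is declared lipofuscin-free rather than
masking half the stack. Any analysis mask sharing at least one voxel with a
lipofuscin mask is eliminated; masks are never edited.

## Terminal classification

Classification is object-based colocalization by *mutual center overlap*:
masks A and B colocalize when the voxel containing A's centroid (floor of the
continuous centroid — a deterministic convention) belongs to B and vice
versa. Because masks within a channel are voxel-disjoint, a mask's center
lies in at most one partner, making the pairing one-to-one; a defensive
nearest-centroid, lowest-id tie-break covers degenerate inputs.

A vGAT mask is classified `GAD65_67` when it mutually center-overlaps both a
GAD65 and a GAD67 mask; `GAD65` when it mutually center-overlaps a GAD65 mask
and shares **no voxel** with any GAD67 mask; `GAD67` symmetrically; otherwise
it is unclassified and excluded from terminal counts. The exclusion clause
uses any-voxel overlap because the source rule switches from "overlapped each
other's centers" to plain "overlap" within one sentence; the alternative
center-only reading is available via `overlap_mode = "center"`. A marker
punctum becomes a terminal when it mutually center-overlaps a GAD-classified
vGAT mask and inherits that class. Per-terminal intensity is reported per
linked mask on its own channel, both as a sum ("total amount") and a mean
("relative amount"); published contrasts use each section's own quantity.

Somatic mRNA classification is count-based: a neuron expresses a GAD
transcript when its soma contains ≥5 molecules and the somatic density
exceeds 2.5× the neuropil density of that transcript. Spot detection itself
is out of scope; counts are inputs.

## Laminar quantification and statistics

Layers are fractional depth intervals from the pia (L1 0–10%, L2 10–20%, L3
20–50%, L4 50–60%, L5 60–80%, L6 80–100%), half-open at the lower edge with
L6's upper edge closed so the intervals partition [0, 1]. Sampling positions
follow a systematic-random 180 × 180 µm grid: one random offset shared by all
cells, then cells drawn without replacement.

All estimates use strict hierarchical averaging — terminal values averaged
within stack, stack means within layer, layer means within section, section
means within subject — never pooling, with empty cells propagating as missing.
Marker channels never coexist in one section (separate staining experiments),
so marker totals are combined at the proportion level per subject.

Inference on subject-level summaries: one-way ANOVA, Tukey HSD (studentized
range; Tukey–Kramer SE for unbalanced groups), and — for unequal variances —
the Dunnett T3 test: pairwise Welch statistics with Welch–Satterthwaite
degrees of freedom referred to the studentized maximum modulus (SMM)
distribution with m = k(k−1)/2 comparisons. The SMM CDF is computed by
numerical integration of `(2Φ(qu) − 1)^m` against the scaled-chi density
(rel. tol 10⁻⁶); with m = 1 it reduces to the t distribution, and the tests
cross-check it against a Monte-Carlo simulation. Every procedure accepts raw
values or (n, mean, SD) summaries — printed tables are valid inputs — and the
two forms agree exactly. The published df usage mixes Welch (df ≈ 33) and
pooled (df = 38) two-sample forms; both are exposed via the `welch` flag.

## The simulator

`scene_config()`/`generate_scene()`/`render_stack()` emulate one sampling
unit (subject × section × layer × grid position): a Poisson number of
terminals at the configured density, centers uniform with a 0.8 µm minimum
spacing (rejection sampling keeps ground truth resolvable), GAD classes drawn
from the configured mixture, and per-class true volumes and log-normal true
integrated intensities. All channels of a terminal share one center, because
the classification rule is center-based. Terminals are rendered as
anisotropic Gaussian blobs whose half-maximum isosurface encloses the drawn
volume; the discrete kernel is normalized over its in-bounds support so the
rendered mass equals the true intensity exactly (up to integer rounding).
Lipofuscin blobs are peak-amplitude Gaussians added to all five channels.
A linear attenuation ramp (to 20% at the face over the outer 10% of planes)
models z-edge effects, followed by Poisson noise (gain 0.1), a 100-gray
baseline, Gaussian read noise (SD 10), and clipping to 16 bits.

Defaults with no published counterpart are desk-scale assumptions made
once: 20 z-planes per stack (5 µm; real stacks are several-fold deeper),
total terminal density 8 per 1000 µm³ split 50/31/19 across PV/CB/CR (only
the proportions are reported; real cortical bouton densities are an order of
magnitude higher), intensity medians anchored to the published per-class
intensity ratios, punctum volume SD 0.06 µm³ about the published class means
with draws truncated to 0.08–0.65 µm³ so every simulated terminal is inside
the detectable size range, and lipofuscin amplitude 1200 a.u. (~3× terminal
peak brightness). Lipofuscin brightness deserves a note: because it is the
brightest structure in every channel, its amplitude relative to terminals
shapes where the global ISODATA threshold lands. At desk-scale terminal
densities a handful of much brighter blobs can dominate the above-threshold
class and push the threshold over the terminal peaks — an artifact of the
scaled-down scene, not of real tissue, where millions of terminal voxels
anchor the bright class. The default keeps lipofuscin clearly the brightest
object without letting it define the histogram. Terminal intensity scales
with terminal volume (larger boutons hold proportionally more protein), so
peak brightness — what detection actually sees — is approximately
volume-independent within a class. The simulator does not model optics (PSF, spectral bleed-through,
chromatic shift) or deconvolution artifacts; stacks are
deconvolved-equivalent. Passing tests therefore validate the pipeline's
logic, calibration and statistics on data with the assumed structure — not
antibody specificity, deconvolution quality, or segmentation behavior under
optical aberrations absent from the model.

## Reference experiment and problem sizes

`run_reference_experiment()` simulates 5 subjects × 2 sections with 2 stacks
per section for the CB and CR experiments and 1 for the denser PV experiment
(50 stacks of 512 × 512 × 20 voxels — replicates allocated inversely to
per-stack terminal yield, giving at least ~1,700 terminals per marker and
roughly 8,000 in total) with generator mixtures set to the published
total-gray-matter composition, and recovers marker proportions and GAD-class
percentages end to end; `scripts/acceptance.R` reports these numbers. The
test suite asserts recovery within 3 percentage points, segmentation/ground
truth equivalence on 100 noise-free scenes, type-I error calibration of
ANOVA/Tukey/T3 within ±1.5 points of 5% over 10⁴ null replicates
(3 groups × 15), and depth-window agreement with a brute-force oracle.

## Known limitations

- Depth-bin QC power at desk-scale densities is carried almost entirely by
  the intensity metric; per-channel per-bin counts of a few objects are too
  sparse for Tukey's extreme-pair criterion across 40 bins. At realistic
  densities (tens of objects per bin) counts regain power.
- Edge attenuation displaces detections inward: a terminal centered in a
  dimmed face plane is often detected through its unattenuated tail, piling
  centroids into the bins just inside the ramp. The depth QC excludes this
  ridge along with the ramp itself, which is exactly its purpose, but in
  shallow desk-scale stacks the excluded fraction of volume is much larger
  than in real, deeper stacks.
- The simulator's spacing constraint means extreme densities fail loudly
  rather than producing unresolvable ground truth.
- Chandelier vs basket assignment of PV terminals, deconvolution, and
  Nissl-based layer boundary estimation are out of scope; layer labels are
  taken as given.
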