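---
title: "Continuous-HU synthetic CT from Dixon MRI: model, phantom and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-HU synthetic CT from Dixon MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dixonsct)
```

## The problem

MRI-only radiotherapy planning for the pelvis needs a CT-like volume — a
synthetic CT (sCT) — because dose calculation and X-ray-based image
guidance both require electron-density information that MRI does not
provide. Dixon-type acquisitions separate water and fat signal per voxel,
and that two-channel signature carries enough information to assign each
voxel a plausible Hounsfield unit (HU). The classic approach assigns one
bulk HU per tissue class (air, fat, soft tissue, spongy bone, cortical
bone); the method implemented here instead assigns HU *continuously*, which
preserves soft-tissue contrast and intra-bone density gradients.

## The classification model

Every voxel contributes a point $(W, F)$ to the water-vs-fat intensity
scatter plot. Soft tissue concentrates along a segment between a
*water-rich* cluster (muscle-like, high $W$) and a *fat-rich* cluster
(subcutaneous fat, high $F$). The model estimates the two cluster centers
and maps tissue relative to the **classification line** joining them:

* **Soft tissue** — the scalar projection $t$ of $(W, F)$ onto the line
  ($t = 0$ at the water center, $t = 1$ at the fat center) interpolates HU
  linearly from `hu_muscle` (+40 HU) to `hu_fat` (−100 HU), with $t$
  clamped to $[0, 1]$ so HU never extrapolates beyond the endpoints.
* **Bone** — bone is dark on Dixon images, far from the soft-tissue line.
  The perpendicular distance $d$ from the line interpolates HU linearly
  from `hu_spongy` (+100 HU, light spongy bone at $d = 0$) to
  `hu_cortical` (+1500 HU, dense cortical bone at $d \ge d_{max}$).
* **Air outside the body** — fixed `hu_air` (−1000 HU). Air *inside* the
  body outline (e.g. rectal gas) is deliberately mapped as soft tissue;
  this replicates the behaviour of the validated clinical software,
  including its known limitation, and the consequences are quantified
  below.

The HU endpoints are configuration defaults placed in standard tissue
ranges, not calibrated constants: the clinical system tunes its continua
against reference CTs, and the corresponding freedom here is that every
endpoint and $d_{max}$ are arguments of `hu_model()`. The functional form
of the distance-to-HU map is not published; linear is implemented and the
choice is confined to `bone_hu()`.

Cluster estimation (`fit_hu_model()` / `estimate_cluster_centers()`) is a
two-centroid refinement with *deterministic* initialization — the water
seed is the centroid of voxels whose water fraction $W/(W+F)$ exceeds its
90th percentile, the fat seed the centroid below the 10th — so repeated
runs are bit-identical. Iteration stops when centroid motion falls below
$10^{-6}$ of the intensity range (at most 100 iterations). Estimation runs
on the soft-tissue mask only: the line is defined by soft tissue, and bone
would drag both centers darkward. Zero-signal voxels are excluded (they
carry no water-fat information); constant-intensity input raises a
degenerate-cluster error rather than returning an arbitrary split.

```{r model-example}
m <- phantom_model()        # the phantom's generating model
m
soft_tissue_hu(50, 50, m)   # midpoint of the line -> -30 HU
```

## The digital pelvis phantom

No imaging data are distributed with the package; instead
`build_phantom()` constructs a deterministic pelvis-like ground truth:
an ellipsoidal body with a 12 mm subcutaneous fat rind and an 8 mm
fat-fraction ramp into muscle, bladder (near-water HU), rectum with an
optional enclosed gas pocket, two femoral heads and a pelvic-ring torus
(cortical shells at +1500 HU around +400 HU trabecular cores), and a
spherical PTV. Defaults: 64 × 96 × 96 voxels at 2.5 mm — a 160 × 240 ×
240 mm field of view, chosen so the full pipeline runs in seconds while
keeping organ dimensions anatomically plausible.

`simulate_dixon()` is the *exact inverse* of the HU mapping: soft tissue
with fat fraction $FF$ is placed at $t = FF$ on the line with total signal
$S_0 = 100$ (arbitrary units); bone is placed at the perpendicular
distance that inverts its truth HU, on the low-signal side of the line;
air gives zero signal. Gaussian noise (s.d. `noise_sigma` · $S_0$ per
channel, clipped at zero) and an optional smooth multiplicative bias field
are layered on top. The default `noise_sigma = 0.02` corresponds to an
SNR of 50 in soft tissue — a deliberately clean acquisition, matching a
modern scan with no reported inhomogeneity; the bias field defaults to
off for the same reason.

Two consequences of this construction are worth stating plainly:

* **Invertibility bounds the bone scale.** Bone must sit at perpendicular
  distance $d$ with non-negative signals, and the farthest a non-negative
  point can lie from the line is the line's distance from the origin
  ($S_0/\sqrt 2 \approx 70.7$ here). The generating model therefore uses
  $d_{max} = 65$ signal units. For a model *fitted* to data, `hu_model()`
  defaults $d_{max}$ to the center separation — a different, uncalibrated
  scale. This is the honest analogue of the clinical system's CT-guided
  calibration: the demo pipeline passes `d_max = 65` explicitly and labels
  it a calibration constant.
* **What passing tests do and do not show.** Because the forward model
  inverts the mapping by construction, round-trip exactness tests verify
  the *implementation*, not clinical accuracy. Realism enters only through
  the noise, bias, segmentation and geometry perturbations; tests on the
  phantom say nothing about MR physics (relaxation, distortion,
  water-fat swaps) or real anatomical variation.

The default gas pocket sits in the superior rectum, outside the beam
corridor of the default dose comparison, so the end-to-end dose numbers
isolate HU-mapping error; the in-target cavity configuration is exercised
separately (below).

## Segmentation surrogates

The clinical product segments body and bones with a proprietary
constrained shape model, which cannot be reproduced. `segment_body()`
thresholds the in-phase channel at 0.2 × its Otsu threshold, keeps the
largest connected component, closes, and fills holes per axial slice —
merging enclosed gas into the body, as the mapping requires.
`segment_bone_surrogate()` thresholds *dark* voxels (in-phase below 0.35 ×
the body median), excludes a 2-voxel peripheral rind and internal air
(near-zero-signal *connected components* of at least 20 voxels — isolated
noise-dark voxels inside cortical bone are not air), fills cavities
enclosed by the detected cortical shell to recover the trabecular core,
then opens and size-filters. The fill-before-open order matters: the
shell is only 1–2 voxels thick and would not survive an opening on its
own. On the noiseless phantom the surrogates reach Dice 1.00 (body) and
0.996 (bone) against the truth masks; both remain above 0.99 at the
default noise level. The surrogate makes no claim of equivalence to the
shape model — every downstream operation accepts externally supplied
masks, and the truth masks are the reference path.

## Evaluation suite

* `tissue_mae()` — mean absolute HU error over bone, soft tissue and body,
  the standard sCT quality triple. On the default noisy phantom the
  ordering is bone ≫ body > soft, as it is for patient data, because the
  bone continuum's HU-per-signal-unit slope is ~20× the soft-tissue
  slope, so channel noise is amplified correspondingly.
* `compute_drr()` + `pearson_cc()` + `register_drr_2d()` — parallel-beam
  orthographic DRRs and their correlation after exhaustive
  integer-pixel registration with parabolic sub-pixel refinement.
  Parallel geometry replaces the planning system's divergent source: the
  correlation comparison is geometry-agnostic as long as both DRRs share
  one geometry, and divergent geometry would introduce source/panel
  parameters that have no counterpart here.
* `rigid_align_3d()` + `cbct_offset_difference()` — translation-only
  bone-mask NCC alignment (exhaustive integer-voxel search, sub-voxel
  parabolic refinement, ties broken toward zero), emulating on-treatment
  CBCT bone matching; the reported quantity is the per-axis difference of
  CBCT-to-CT and CBCT-to-sCT offsets in (LR, AP, SI) mm. Known shifts up
  to ±5 voxels are recovered within 0.5 voxel, with or without 20 HU
  noise.
* `dose_proxy()` + `dvh_metrics()` + `percent_dose_diff()` — a ray-cast
  exponential attenuation proxy standing in for a clinical dose engine,
  explicitly non-clinical: it exists to exercise the CT-vs-sCT comparison
  workflow. Two deposition conventions are provided. `"fluence"` scores
  the transmitted fluence $d_0 e^{-\sum \mu \Delta l}$ itself;
  `"kerma"` (default) multiplies by the local $\mu/\mu_{water}$, i.e.
  locally absorbed energy. The distinction matters exactly where this
  package needs it: an air cavity scores near-zero dose under `"kerma"`,
  as it would in a real calculation, which is what makes the
  coverage-overestimation analysis below possible. DVH metrics follow the
  standard definitions ($D_x$ = dose received by the hottest $x\%$ of the
  volume, by sorted-dose linear interpolation; $D_{1cc}$ likewise with the
  volume from the grid spacing; $D_{max}$ is the single hottest voxel — no
  volume smoothing, the simplest auditable definition). $D_{53}$ is the
  generic $D_x$ at $x = 53$. Percent differences are normalized by the CT
  metric (the literal reading of "(sCT−CT)/CT"), not by prescription
  dose.

### The rectal-air sign property

Mapping in-body air as soft tissue has a known clinical signature: sCT
dose calculations *overestimate* PTV coverage when gas sits inside the
target. The mechanism is cold spots — on CT, air voxels inside the PTV
absorb almost nothing, dragging down $D_{95}$; on the sCT those voxels are
soft tissue and absorb normally. With an in-target cavity occupying ~2% of
the PTV and opposed lateral beams, the phantom reproduces the positive
$D_{95}$ percent difference deterministically; without the cavity the
difference vanishes. Note this requires the `"kerma"` deposition
convention: under pure transmitted fluence, filling an air cavity with
tissue can only *reduce* dose everywhere downstream, and the sign could
never come out positive.

## Numerical choices and degenerate inputs

* One array convention everywhere: indices (z, y, x) = (SI, AP, RL),
  0-based voxel coordinates, values at voxel centers, LPS world
  coordinates; offsets are reported in (LR, AP, SI) order. Round-trip
  I/O tests assert the convention for NIfTI and MetaImage.
* Clamping: $t$ to $[0,1]$, $d$ to $[0, d_{max}]$ — bounded HU output by
  construction; `generate_sct()` output always lies in
  $[hu_{air}, hu_{cortical}]$.
* Registration ties break toward the smallest shift magnitude, then
  lexicographically; sub-voxel refinement is skipped for exact matches
  (correlation 1), so identical inputs return exactly zero offset.
* Empty bone masks are legal (an sCT with no bone compartment); empty
  compartments in `tissue_mae()` report `NA`, never 0; structures under
  1 cm³ report $D_{1cc} = D_{max}$ with a flag; zero-variance images are
  a correlation error, not a silent `NA`.
* All randomness (noise, CBCT simulation) is seed-parameterized;
  geometry is seed-free.

## Problem sizes

The shipped tests and the evaluation script run the default 64 × 96 × 96
phantom for mapping and dose analyses, a 48 × 64 × 64 variant for the
registration-heavy checks, 8³ grids (100 seeds) for brute-force oracle
equivalence, and 5 000-point-per-cluster mixtures for center recovery —
sizes chosen so a complete run stays in the minutes range on one core
while every claim remains statistically comfortable.

## Known limitations

* The forward Dixon model is a package construction (the inverse of the
  mapping); no quantitative mDixon signal model is published for the
  clinical system.
* The bone surrogate is an intensity-morphology heuristic, not a shape
  model; partial-volume behaviour at bone boundaries is untested against
  any reference.
* The dose proxy has no scatter, buildup, beam hardening or lateral
  transport; percent-difference *signs and orderings* are meaningful,
  absolute magnitudes are not.
* Patient-level headline values from clinical studies (tissue MAEs around
  120/33/39 HU, DRR correlation 0.975, sub-millimetre CBCT offsets) are
  properties of patient cohorts and cannot be reproduced on a phantom;
  the package reproduces their *orderings and signs* and reports its own
  phantom-scale magnitudes.
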