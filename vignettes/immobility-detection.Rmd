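---
title: "Detecting human immobility in visible and thermal video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting human immobility in visible and thermal video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stillwatch)
```

## The problem

In remote triage — for instance a drone hovering over a mass-casualty
scene — a person's consciousness is one of the key parameters deciding
treatment priority, and it must be assessed without contact. `stillwatch`
implements a motion-based surrogate: a person who shows no limb movement
over a 30-second observation window is flagged *nonmoving*, i.e.
potentially unconscious. The tool makes no clinical claim; it outputs a
motion label, with the positive class deliberately chosen as "nonmoving"
so that the rare, dangerous-to-miss case is the one the metrics focus on.

Two imaging modalities are supported: visible light (RGB, high contrast,
usable by day) and infrared thermography (IRT, single low-contrast
channel, usable at night).

## The pipeline

A clip is classified in four stages.

**1. Reference-frame preprocessing.** Only the first frame \(F_0\) is
preprocessed. A person mask is obtained from a pluggable segmentation
backend (any pretrained instance-segmentation model can be adapted; the
test suite and the simulator use ground-truth masks). A white grid
(80 px pitch for RGB, 40 px for IRT) is overlaid on the grayscale frame,
the frame is multiplied by the binary mask so everything outside the body
is zero, the mask's morphological skeleton is painted white, and — for RGB
only — the result is histogram-equalized with the classical
\(T(k) = \lfloor (L-1)\,\mathrm{CDF}(k) \rfloor\) mapping. Grid and
skeleton exist purely to seed trackable corner structure inside otherwise
homogeneous body regions. For IRT the person mask is additionally merged
(pixelwise union) over detections at 0°, +90° and −90° exact frame
rotations, which compensates for weak thermal detections.

The composition order is grid → mask multiplication → skeleton painting →
equalization. Painting the skeleton after masking is the only order in
which the skeleton remains visible in the product (a 0/1 multiplication
cannot convey it), and equalization operates on the full resulting raster
including the zeroed background, since the zeros are part of the image
being equalized.

**2. Feature selection.** Shi–Tomasi corners — pixels whose windowed
gradient structure tensor has min eigenvalue \(R=\min(\lambda_1,\lambda_2)\)
above a quality fraction (0.01) of the strongest response — are sorted by
response and kept greedily subject to a minimum pairwise distance of
10 px, capped at \(N_{\max}=90\), and restricted to the body mask.

**3. Tracking.** The selected points are tracked through the remaining
frames (plain grayscale, no preprocessing) with pyramidal Lucas–Kanade
optical flow: per frame pair, the displacement minimizing the
brightness-constancy residual over a 21×21 window, iterated to
\(\varepsilon = 0.01\) px or 30 iterations, coarse-to-fine over up to 4
pyramid images. Two candidate solves are performed per point: a pyramidal
solve from zero and a base-level solve warm-started from the previous
step's displacement. The warm candidate is preferred unless its window
residual is more than 1.5× the from-scratch candidate's. This hysteresis
matters when a thin moving limb crosses in front of the torso: the limb is
nearly invisible at coarse pyramid scales, so the pyramidal solve latches
onto the static background, while the warm-started solve keeps following
the limb; their residuals are close, and continuity should win close
calls. Points whose solve fails, whose window leaves the frame, or whose
gradient matrix is degenerate are invalid from that step onward; lost
points are never re-detected.

**4. Movement signal and classification.** The tracked span is divided
into \(T = 30\) equal steps (one per second of a 30 s clip). At step
\(t\), each valid point's displacement between the step boundaries,
divided by the step duration ("distance/dt", px/s), is compared with the
relevant-magnitude threshold \(M\) (100 for RGB, 450 for IRT); \(f(t)\)
counts the points strictly above \(M\). The clip is *moving* (label 0)
when \(f(t)>0\) at \(th = 3\) or more steps, else *nonmoving* (label 1).
The continuous score used for precision–recall analysis is
\(1 - |\{t : f(t)>0\}|/T\).

### The time base

The cameras behind this kind of recording run at tens of frames per
second, while the movement signal has one sample per second. Tracking
therefore runs at the clip's native frame rate (where inter-frame
displacements are small enough for window-based optical flow), and the
signal is formed at the 1 Hz step boundaries. For a clip that actually has
one frame per second the two coincide and the step displacement is the
plain per-frame displacement. A threshold of \(M = 100\) px/s is not
reachable as a single tracked jump — a window-based tracker cannot follow
a 100-px inter-frame displacement of a limb-sized structure — which is why
the per-step displacement is accumulated over tracked sub-steps rather
than demanded of a single solve. The IRT threshold (450) being larger
than the RGB one despite the lower thermal resolution mirrors the original
operating points; both are adopted as stated and left config-exposed.

## The scene simulator

All tests run against `render_clip()`, a 2-D articulated-silhouette
renderer that emulates the experimental protocol: one human figure per
clip, postures *sitting* and *laying*, body-axis angles 0°/45°/90°
(in-plane rotation is used as the 2-D proxy for the longitudinal-axis
camera angle), and seven movement classes (*no movement*, *head*, *one
arm*, *both arms*, *one leg*, *both legs*, *slight*), 30 s per clip.

Design choices, fixed once:

* **Geometry.** Torso and limbs are filled rectangles, the head a disc,
  composed in figure coordinates and rotated as a whole. The pipeline
  consumes only masks and gray intensities, so 2-D suffices to exercise
  every stage.
* **Movement model.** The designated limb translates rigidly and
  sinusoidally, perpendicular to its own long axis, with cosine phase
  (zero initial velocity); the limb-centroid peak-to-peak displacement is
  exactly twice `amplitude_px`. Moving parts are painted on top, as a
  waving limb passes in front of the body. Default amplitude for moving
  classes is 150 px at a 4 s period; a 4 s period is in phase with the
  1 Hz movement signal, so every 1 s step displaces the limb by exactly
  its amplitude (≈1.5× the RGB threshold, peak speed ≈ 236 px/s).
  *Slight* defaults to 3 px, deliberately far below threshold — it
  reproduces the characteristic failure mode in which small hand/finger
  movements are missed.
* **Rendering.** RGB-like scenes are high-contrast with sinusoidal
  within-body texture (each part's texture translates rigidly with it)
  over a patterned background, ±3 gray levels of uniform sensor noise,
  and three colour channels. IRT-like scenes are single-channel and
  low-contrast: body ≈ 0.7 and background ≈ 0.5 of the intensity range
  with Gaussian noise of σ = 2% of range.
* **Sampling.** Default 10 frames/s over 30 s (301 frames). The study
  cameras ran at 15/30 fps; 10 Hz keeps the default per-frame limb
  displacement (≤ ~24 px) inside the tracker's capture range while
  keeping clips small enough for study-scale runs on one CPU. Static
  scenes in bulk suites may be rendered at 5 Hz, where rate is
  irrelevant.
* **Nuisance effects.** `add_nuisance()` emulates the two error sources
  reported for outdoor recordings: clothing flutter (a 2-px boundary band
  re-sampled at a random sub-pixel offset per frame) and sudden sunlight
  changes (a global intensity step from a random frame onward, clipped to
  range with a warning). Truth labels are unchanged.
* **Determinism.** Rendering is a pure function of the scene spec: one
  seeded generator drives all randomness, and the caller's RNG state is
  restored. Identical specs re-render bit-identically.

What the simulator does *not* emulate: photorealistic appearance,
segmentation-mask errors (truth masks share the renderer's geometry
exactly), camera motion, occlusion by other objects, and multi-person
scenes. Consequently, passing the synthetic suites shows that the motion
measurement, signal extraction and classification behave correctly given a
correct mask — it does not certify detector robustness on real imagery.

## Evaluation

The dataset the protocol produces is imbalanced 1:6 (one nonmoving class
among seven), so the metric suite is the one appropriate for imbalanced
binary problems: F\(_\beta\) (default β = 1), Cohen's kappa, the Matthews
correlation coefficient, the balanced error rate, and the area under the
precision–recall curve (step integration, no trapezoids), all with
*nonmoving* as the positive class. The MCC uses the standard
square-root-denominator form, which reproduces the published per-angle
table values from their printed confusion matrices to 3 decimals; table
comparisons round half away from zero. ROC-AUC is deliberately not part
of the suite. Degenerate tables (an empty class, a zero marginal) raise
explicit errors rather than returning 0. The continuous score feeding the
PR curve is the classifier's own \(1-\text{active}/T\); the original
study's score definition behind its reported PR-AUC is not stated
anywhere, so PR-AUC values are comparable only in spirit.

Undetermined outcomes (no person found; zero selectable features) are a
distinct result, reported with a reason; in evaluation-compatible mode
they count as nonmoving, the conservative direction for triage.

## Numerical choices and degenerate inputs

* Erosion/dilation use strict set semantics with out-of-raster pixels as
  background (a full raster erodes to full-minus-border).
* Skeletonization is Guo–Hall two-subfield LUT thinning: one-pixel-wide,
  topology-preserving, and pixel-exact against an independent reference
  implementation on random blob masks. An empty mask yields an empty
  skeleton.
* Demosaicing of 16-bit Bayer raws is bilinear with adaptive border
  normalization (constant fields stay constant), followed by integer
  division by 256; grayscale conversion uses BT.601 weights; 16-bit IRT
  frames are rescaled to 8 bits by the per-clip min–max.
* Strict inequality at the magnitude threshold: a displacement of exactly
  \(M\) does not count.
* Corner-score ties and equal-score detections resolve to the first in
  deterministic order.
* Grid lines are 1 px thick and anchored at the raster origin (0-based
  indices `k * spacing`).

## Problem sizes used in the checks

The packaged checks run study-scale simulations scaled to desk size: a
40-clip separation suite (20 clearly-moving clips — 150 px sweeps at a 4 s
period, sampled at 10 Hz, so every 1 s step displaces the limb by about
1.5× the threshold — plus 20 static clips at defaults), a 48-clip
failure-mode suite (slight-movement amplitudes spanning 40–124 px
straddle the threshold over full 30 s clips; the unambiguous cells use
15 s clips), and a 56-clip end-to-end study
(4 subjects × 2 postures × 7 movements at 0°) in the acceptance script.
The original protocol's 840-clip scale is reproduced in manifest
enumeration, not in rendered video.

## Known limitations

* A limb that moves and returns within one 1 s step (oscillation faster
  than ~2 Hz) aliases toward zero step displacement; the original
  per-second signal has the same property.
* Points lost to occlusion crossings are never re-detected (by design —
  selection happens once on \(F_0\)); clips whose motion hides most
  features can under-count movement. The residual-hysteresis tracker
  mitigates but does not eliminate this.
* The IRT threshold \(M = 450\) px/s means only fast limb motion is
  detectable in thermal mode at typical thermal resolutions; this mirrors
  the stated operating point.
* The simulator's truth-mask backend bypasses real segmentation errors;
  conclusions about detector quality on real video require real video.
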