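---
title: "Quantifying nucleolar structure and dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleolar structure and dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleostruct)
```

The nucleolus is a membrane-less organelle built by liquid-liquid phase
separation around actively transcribed ribosomal DNA. Its three nested
compartments — fibrillar center (FC, marked by UBF), dense fibrillar
component (DFC, fibrillarin/FBL) and granular component (GC,
nucleophosmin/NPM1) — reorganize dramatically when RNA polymerase I is
inhibited: the GC condenses into a single round body in interphase cells,
while cells that pass through mitosis without Pol I activity fail to
reassemble a nucleolus at all and scatter their nucleolar proteins into
dispersed puncta. This package implements the three quantitative readouts
used to characterize those phenotypes — FRAP curve fitting, immunogold
particle densitometry, and time-lapse morphometry — together with
synthetic-data generators that produce each data type with known ground
truth, so that every stage of the analysis is testable at the desk.

This vignette documents the models, the estimators, the tunable
parameters, and the design decisions, including what the simulators do
and do not emulate.

## FRAP: constrained two-component recovery

A whole-structure bleach removes all fluorescence from the NPM1-marked
GC; recovery can only come from nucleoplasmic exchange and follows a
single exponential

$$F(t) = P\,\bigl(1 - e^{-t/\tau}\bigr),$$

with plateau $P$ (fraction of pre-bleach intensity recovered) and one
time constant $\tau$. A half-structure bleach additionally recovers by
internal mixing from the unbleached half, giving a double exponential

$$F(t) = P - A_1 e^{-t/\tau_1} - A_2 e^{-t/\tau_2}, \qquad P = A_1 + A_2,$$

where $\tau_1$ is the fast internal-mixing constant and $\tau_2$ the slow
exchange constant. Fitting both constants freely from a half bleach alone
is poorly conditioned, so the protocol fits the whole-bleach curves
first and **fixes** $\tau_2$ in every half-bleach fit to the whole-bleach
value (per-condition mean by default; per-cell pairing is available via
`tau2_mode = "per_cell"`). The constraint $P = A_1 + A_2$ encodes the
fact that a min–max-normalized curve is exactly 0 at the bleach frame.

Numerical choices:

* bounded Levenberg–Marquardt least squares (`minpack.lm::nlsLM`);
  initialization $\tau \leftarrow t_{1/2}/\ln 2$ from the observed time to
  half recovery, plateau from the mean of the last five frames; up to 5
  restarts from jittered starts on failure;
* bounds $\tau \in [\Delta t/10,\; 10\,T]$ ($\Delta t$ = frame interval,
  $T$ = trace duration) and amplitudes in $[0, 1.05]$; a parameter landing
  on a bound flags the fit rather than being silently clipped;
* a post-bleach segment flat at 0 returns a degenerate zero-recovery fit;
* percent recovery is $100 P$ from the fitted plateau; an empirical
  last-five-frames estimate (`empirical_recovery()`) is provided as a
  diagnostic only;
* bleach alignment pads leading frames with `NA` (never fabricated
  values) so that every post-bleach frame remains available for fitting;
* group comparisons use the classical pooled-variance two-sample t test,
  with Welch's variant behind `var_equal = FALSE`.

The generator (`simulate_frap_curve()`) is the model's exact generative
twin on the normalized scale: pre-bleach frames at 1, bleach frame at 0,
recovery following the double exponential, i.i.d. Gaussian noise on every
frame. Defaults mirror the acquisition protocol the models were designed
for: 0.5 s sampling for 2 minutes with 5 pre-bleach frames. The noise sd
(0.02 normalized units) is a generator assumption — the source data's
noise level is not published. Simulated ensembles use fast constants
3.33 s (control) and 9.05 s (Pol I-inhibited) — the regimes the fitter
must separate — and whole-bleach constants of 25 s and 50 s. The
whole-bleach values are package defaults chosen to respect the reported
direction (exchange slows under inhibition) and a clean time-scale
separation ($\tau_2 \ge 5\tau_1$ in both regimes); no published numeric
values exist for them, and parameter-recovery checks grade only the
recovered $\tau_1$ against its own generating value.

What the simulation does *not* model: reaction–diffusion recovery
profiles, bleach-spot geometry, acquisition photofading, or cell-to-cell
amplitude variability. Passing recovery tests therefore demonstrate the
fitting protocol's correctness and conditioning, not robustness to every
optical artifact of real FRAP data.

## Immunogold detection: two-pass scale-normalized LoG

Electron micrographs carry two gold label sizes (12 nm and 6 nm) that
must be counted separately inside a nucleolar outline. Detection uses the
Laplacian-of-Gaussian blob detector with the standard radius relation
$\sigma = d / (2\sqrt{2}\, s)$ for diameter $d$ (nm) at pixel size $s$
(nm/px), sign-adjusted so dark blobs give positive response, and
scale-normalized ($\sigma^2 \nabla^2 G$) so responses are comparable
across scales.

The two-pass procedure mirrors practice: find the 12 nm particles first,
erase an exclusion zone around each (default radius
$1.5 r_{12} + r_6 = 12$ nm — a configurable choice, no published value
exists), then search the remainder at the 6 nm scale. Two additions make
the procedure parameter-light:

* **Characteristic-scale selection.** Both particle sizes respond at both
  scales. A candidate is assigned a class only where that class's
  scale-normalized response dominates the other class's response at the
  same pixel (ties go to the larger class). This separates the classes
  without per-class threshold tuning: on synthetic fields the response
  ratio between the correct and wrong scale is ~2–5 fold.
* **Robust default threshold.** `median + 5 * mad` of the response image,
  with an absolute floor of 1e-8 above the median that absorbs FFT
  rounding on noise-free images. Absolute per-class thresholds can be
  supplied instead.

Same-class duplicates within one particle diameter are suppressed
greedily (highest response wins). Boundary conventions are open:
strictly-closer removes, exactly-at-radius survives. Coordinates are
0-based pixel centers in all tabular outputs. Detections outside the
outline are kept and labeled `in_roi = FALSE` so they remain
inspectable; densities (particles/nm², count divided by mask area times
$s^2$) use the in-ROI subset only.

The EM generator renders particles as anti-aliased uniform dark disks
(no microscope point-spread function, no section-thickness effects, no
stain texture beyond i.i.d. Gaussian noise): LoG detection responds to
blob-scale contrast, which these renderings exercise fully, but
detection-quality numbers on synthetic fields should not be read as TEM
performance claims. Placement is rejection sampling under a same-class
minimum separation; an unplaceable request errors rather than silently
truncating.

## Time-lapse morphometry

The morphometry stage measures, per cell and frame: the number of UBF
and FBL puncta, the total NPM1 area, and the area-weighted mean NPM1
sphericity; tracks cells over time; and classifies each cell's end-point
phenotype.

**Segmentation.** Nuclei are found by Otsu thresholding the
Gaussian-blurred sum of the three channels (blurring with $\sigma$ = 4 px
merges the bright nucleolar bodies into the dimmer nuclear background so
the threshold separates nucleus from cytoplasm instead of latching onto
the bodies), hole-filling, and a 100 px size floor. Within each nucleus,
each channel is thresholded by Otsu (a fixed threshold can be supplied
for reproducibility), and connected components above 4 px (0.16 µm² at
the default 0.2 µm/px) are measured. A channel whose Otsu threshold sits
within 0.1 gray units of the channel minimum is treated as signal-free
and yields an empty component set. No watershed splitting is applied by
default — the generator's components are disjoint by construction; real
clumped data would need it.

**Shape.** In 2-D, "sphericity" is circularity $4\pi A/P^2$ and is
labeled as such in outputs. Perimeter estimation matters here: counting
boundary pixels overestimates $P$ so badly that a disk scores 1.26, and
a Manhattan-edge count corrected by $\pi/4$ is biased for oriented
ellipses. The estimator used traces each component's boundary
(`EBImage::ocontour`), sums chain steps with the Vossepoel–Smeulders
weights (0.948 axial, 1.340 diagonal), and adds $\pi$ because the traced
pixel-center polygon is the true outline eroded by half a pixel. This is
accurate to 1–2% for disks and ellipses at any orientation above ~5 px
radius; digitized disks of radius 5/15/30 px score 0.86/0.95/0.98,
converging to 1 from below. In 3-D, sphericity is
$\Psi = \pi^{1/3}(6V)^{2/3}/S$ with the surface estimated as exposed
voxel faces times 2/3 (the Minkowski correction for isotropic surfaces);
a radius-15 digital ball scores 0.997. Values are clipped at 1.05 to
absorb discretization overshoot; single-pixel components are flagged
degenerate with undefined sphericity.

**Tracking** links nucleus centroids between consecutive frames by
greedy nearest-neighbour assignment under a displacement gate (default
10 µm/frame). A cell that would have to jump beyond the gate terminates
its track instead of swapping identity; unmatched detections start new
tracks. Tracks survive a single missed frame (gap closing with the gate
scaled by the frames skipped): a nucleus whose nucleolar components have
just dissolved at division is dim and can drop out of the frame-global
nucleus threshold for that one frame, and without gap closing every such
cell would be double-counted as two short tracks.

**Population summaries** are per-frame means with t-based 95% confidence
intervals ($\bar x \pm t_{0.975,n-1}\,SE$); t rather than normal because
the reference experiments use ~12–15 cells per condition. Single-cell
frames are flagged with undefined intervals.

**Phenotype classification** is a rule on the end-point NPM1
measurements of each track (end-point, because fragmentation is scored
after division, matching fixed-cell scoring):

* *fragmented*: at least 6 components **and** the largest holds < 50% of
  total NPM1 area;
* *condensed*: exactly 1 component with sphericity ≥ 0.9;
* *normal*: anything else; cells with no NPM1 signal are
  *unclassifiable* and leave the denominator.

Published scoring of this phenotype is by eye; these thresholds are
explicit, configurable stand-ins, not reference values. The fragmented
rule is deliberately conservative in both directions (many components
*and* no dominant body) so that noise-induced oversegmentation of a
normal nucleolus cannot produce a fragmented call.

**Fractions and inference.** `fraction_fragmented()` reports
$100 \cdot \text{fragmented}/\text{classifiable}$ per condition and runs
a one-way ANOVA across conditions when per-replicate percentages are
available for three or more conditions.

## The time-lapse generator and the division model

Each simulated nucleus occupies a 56 px tile (11.2 µm at 0.2 µm/px,
radius 4.4 µm) and performs a small random walk (0.1 µm/frame sd).
NPM1 bodies are rendered as smooth-edged ellipses placed on a ring
around the nucleus center with tangential major axes — a layout that
guarantees disjoint components at every parameter setting the package
uses. UBF (σ = 1.3 px) and FBL (σ = 1.7 px) puncta are Gaussian spots
placed with minimum separations of 6 and 7 px so that neighbouring spots
do not merge above threshold. Default counts (12 UBF, 8 FBL, 2 NPM1
bodies, 12 µm² total NPM1 area) are plausible magnitudes for pluripotent
cells, chosen once; none is a measured value.

Condition `"inhibited"` applies, per frame: a deterministic geometric
area shrink (total ×0.6 over the movie), a linear axis-ratio ramp from
0.55 to 1 (so true sphericity is non-decreasing by construction), a
merge of two NPM1 bodies with probability `condensation_rate`, and
one-punctum losses for UBF/FBL (probabilities 0.25 and 0.2). Condition
`"control"` holds everything stationary.

**Division** is instantaneous at `division_frame`: all nucleolar
components dissolve for exactly one frame, then either reassemble into
1–3 components at 90% of the initial area (normal outcome) or scatter
into `n_fragments` (default 8) small roundish puncta totalling 40% of
the initial area (failed reassembly). Only one daughter is followed;
chromatin, mitotic geometry and nuclear-envelope breakdown are not
modeled.

**Fragmentation probability semantics.** `fragmentation_probability` is
the *population-level* probability that a cell ends fragmented. Because
the fragmented phenotype can only arise through a division, a cell drawn
to fragment always divides (at its configured frame, or the movie
midpoint if it had none). When every cell divides — the synchronized-
release design — this is identical to a per-division failure
probability. The alternative (per-dividing-cell probability) would make
the population fraction depend on the product of the division rate and
the failure rate, which is not what end-point scoring of a fixed culture
reports; the population-level definition lets a measured fragmented
fraction be plugged straight back into the generator as its recovery
target.

**Truth records.** Per cell: final phenotype (`normal` / `condensed` /
`fragmented`) and division frame; per frame: true component counts,
analytic NPM1 area ($\sum \pi a_i b_i$) and area-weighted analytic
(Ramanujan) sphericity; plus nucleus center tracks. The measured
counterparts come from the rendered pixels through the full analysis
chain, so simulator and analyzer share no code path for these
quantities.

Classifier caveat: the classifier's *condensed* recall on rendered data
is limited at the default rendering scale (a condensed single body of
~180 px measures ~0.89–0.95 circularity, straddling the 0.9 rule), and
division-frame measurements are unclassifiable by construction. Neither
affects fragmented-fraction readouts, which depend only on the
fragmented-vs-rest decision.

## Problem sizes and reproducibility

All simulations are seeded and bit-reproducible; generators save and
restore the caller's RNG state. A single run seed expands into per-stage
sub-seeds via `derive_seed()` (stage-name hashing), so one seed
reproduces an entire `run_pipeline()` run and stages can be re-run
independently. Standard problem sizes used by the test-suite and the
acceptance script, chosen to exercise the statistics at single-CPU desk
scale: 30-curve FRAP ensembles; 512×512 px EM fields (2 nm/px) with
30 + 60 in-ROI particles; 200-cell, 21-frame populations for
fragmentation scoring (the classifier's end-point call does not depend
on movie length beyond containing the division); 1000-cell truth-only
populations for binomial calibration checks.

## Known limitations

* 2-D+t only in the renderer; 3-D shape metrics are implemented and
  tested on synthetic voxel masks but no 3-D movie generator is
  provided.
* No optical PSF, camera noise model, drift, or photobleaching during
  acquisition; the noise model is i.i.d. Gaussian everywhere.
* The phenotype rule's thresholds are stand-ins (see above); on real
  data they would need calibration against manual scoring.
* Nucleolar caps (UBF/FBL relocating to the GC rim under inhibition) are
  not geometrically modeled — puncta counts fall, but cap geometry is
  not scored.
* The tracker is nearest-centroid with a gate; it does not handle cell
  contacts, occlusion, or divisions that produce two tracked daughters.
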