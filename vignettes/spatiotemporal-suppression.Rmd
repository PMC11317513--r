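---
title: "Spatiotemporal pRF models of simultaneous suppression: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal pRF models of simultaneous suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(seqsimprf)
```

# The problem

A voxel's response to several stimuli shown at once is typically lower
than its response to the same stimuli shown one at a time — simultaneous
suppression. Two families of population-receptive-field (pRF)
computations could produce it: purely *spatial* subadditivity
(compressive summation across visual space) and *spatiotemporal*
subadditivity (compression applied to sustained and transient neural
channels, so that the number of visual onsets/offsets matters).
`seqsimprf` implements the stimulus protocol that dissociates these
accounts, forward models for both families, the fitting machinery, and
the mixed-model quantification of suppression, all exercisable on
synthetic populations with known ground truth.

# The stimulus world

## Geometry

Each quadrant shows a 2×2 array of squares (side 2° or 4°) with a fixed
0.82° gap, group centre at (±5°, ±5°), i.e. ~7.1° eccentricity. Small
arrays span 2.59°–7.41° in |x| and |y|; big arrays span 0.59°–9.41°.
The two stimulated quadrants (upper-right, lower-left) are point
reflections through fixation. `build_square_layout()` constructs the
geometry; both printed extents are asserted in the tests.

## Timing

Conditions cross presentation mode {SEQ, SIM} × per-square duration
{0.2 s, 1 s} × size {2°, 4°}. Each 332-s run holds 16 8-s blocks
(every condition twice, seeded pseudo-random order differing between
the two unique runs) separated by 12-s blanks; the physical 6-s
countdown is dropped from the analyzed timeline, reconciling the
338-s physical schedule with the 332-s analyzed run and keeping the
last 23-TR analysis window inside the run.

Within a block: short conditions have eight 1-s trial slots; long
conditions have two trials. Sequential trials show the four squares one
at a time in seeded random order with a 33-ms inter-square interval;
simultaneous trials show all four at once, the first trial locked to
block onset; SIM-long trial 2 starts at +4 s; SIM-short trials 2–8 are
uniformly jittered within their slots (constrained to end inside the
slot). Per square and block, total on-time is identical between the SEQ
and SIM members of a pair — the design's core matching property — while
the pooled transient count (onsets + offsets seen by a pRF covering all
four squares) is 16 vs 4 (long) and 64 vs 16 (short): a 4:1 short:long
ratio in both modes.

Two timing choices the protocol description leaves open:

* **SEQ-long trial packing.** Two sequential long trials last
  2 × (4×1000 + 3×33) = 8198 ms, which cannot fit strictly inside
  8000 ms. Trials are laid back-to-back (33-ms ISI across the
  boundary), so the final square ends 8231 ms after block onset,
  spilling ~0.2 s into the blank — consistent with "approximately 8-s"
  blocks and preserving on-time matching.
* **`onset_matched` mode.** For the linear null analysis, a generator
  flag locks SEQ trial onsets to the 0/4-s slots with identity square
  order and disables SIM-short jitter. A pRF confined to the
  first-presented square then receives a bit-identical drive in SEQ and
  SIM blocks, which is the cleanest realization of "no suppression
  under linear summation".

The canonical stimulus representation is the event list (rectangle ×
on/off ms); rasterization to pixel grids exists for oracle tests and
the retinotopy bars. On a 0.01°/pixel grid the pixel boundaries align
exactly with every square edge, making the rasterized dot product an
exact oracle for the closed-form drive; at misaligned resolutions the
binary raster has O(pixel) boundary error, which is why oracle tests
pin the aligned resolution.

# Encoding models

All models share the spatial stage: a unit-volume circular 2-D Gaussian
(centre `x0, y0`, SD `σ`, degrees) whose dot product with the binary
stimulus is the sum of closed-form Gaussian–rectangle overlaps
(products of 1-D normal CDF differences). The drive is exact and
piecewise constant at 1-ms resolution.

* **LSS** is the drive itself.
* **CSS** raises the drive pointwise to `css_n ∈ [0.01, 1]`. For four
  equal overlaps `o`, `(4o)^n < 4o^n` whenever `n < 1` — the spatial
  subadditivity that suppresses SIM relative to SEQ.
* **CST** convolves the drive with three IRFs: a sustained gamma
  (κ = 1, n = 9) and biphasic on/off transients (difference between
  the sustained gamma and a second gamma with τ = 4.93 ms, κ = 1.33,
  n = 10; the off kernel is the negation of the on kernel). Channels
  are half-wave rectified and share one exponent `cst_n ∈ [0.1, 1]`;
  on and off channels are summed after the nonlinearity; `β_s`, `β_t`
  weighting happens at regression. Discrete kernel areas are enforced
  exactly (sustained sums to 1; transient lobes balanced to sum 0).
  Two conventions deserve note:
  * *Sustained time constant.* The source description prints
    τ = 49.3 ms, but the same text requires the peak, `(n−1)κτ`, to lie
    between 40 and 50 ms — impossible with τ = 49.3 (peak 394 ms) and
    consistent with τ = 4.93 (peak 39.4 ms), matching the second
    gamma's printed τ = 4.93. We default to 4.93 ms and expose the
    parameter.
  * *Rectification.* The displayed equation uses |·|, but with |·| the
    on- and off-transient channels would be numerically identical,
    defeating their separation; the accompanying schematic says ReLU.
    We use half-wave rectification.
* **DoG** subtracts a concentric surround Gaussian (same centre,
  `surround_scale` × σ; per-area ratios V1 7.4, V2 6.8, V3 7.3,
  hV4 5.8). Only the size ratio is specified upstream, so an amplitude
  convention is needed: we make both Gaussians unit volume (fully
  balanced surround — the strongest-suppression variant; a full-field
  stimulus drives the pRF to ~0). Temporal behaviour is linear, so
  SEQ/SIM block integrals are exactly equal: DoG predicts no
  simultaneous suppression of block amplitudes.
* **DN-ST** convolves the drive with `t·e^{−t/τ₁}`, then divides
  `|r|^n` by `σ_DN^n + (|r| * e^{−t/τ₂})^n`. Both kernels are
  normalized to unit sum (the gamma kernel's free scale would otherwise
  make `σ_DN` incomparable across τ₁; the exponential's normalization
  makes the denominator a leaky average of `|r|` on the same scale as
  the numerator). 0/0 is defined as 0. The step response converges to
  the closed-form fixed point `o^n/(σ_DN^n + o^n)`, which the tests use
  as a scalar oracle; onset transients may exceed 1 (the delayed
  denominator), so the invariant asserted is finite and non-negative.

For every model except CSS, the spatial σ fed to the model should be
the *effective* size `σ/√css_n` when parameters come from a compressive
retinotopy fit; CSS uses `(σ, css_n)` as estimated.

# Hemodynamics

A canonical double-gamma HRF (peak delay 6 s, undershoot delay 16 s,
dispersions 1 s, ratio 1:6, 32-s support, unit integral) is convolved
with the neural prediction and box-car averaged within each 1-s TR
(mean-conserving). Numerically, the convolution runs at a 10-ms
internal step: the neural series is box-integrated into 10-ms bins
(exact for piecewise-constant drives) and the kernel bin-summed. The
HRF varies on a seconds timescale, so this midpoint quadrature deviates
from the exact 1-ms path by < 2×10⁻³ relative on SEQ-SIM predictions
(measured in the tests) while being ~8× faster; `conv_dt_ms = 1`
restores the exact path. One global HRF is used; per-voxel HRF fitting
is out of scope.

# Fitting

Predictions for the concatenated two unique runs (all eight conditions
jointly) are max-normalized per regressor; an offset column is added;
β-weights are estimated by OLS separately on the averaged odd and
averaged even halves, and each half's scaled prediction is scored on
the other half with frozen weights. cv-R² uses `1 − SS_res/SS_tot` with
`SS_tot` centred on the test-half mean (the standard coefficient of
determination; the alternative uncentred convention is not used), and
values and β's are averaged across directions. The adjusted variant
penalizes by time points and regressors. The CST exponent is grid-fit
(0.10–1.00, step 0.05; channel convolutions computed once per voxel,
only the static nonlinearity and HRF stage repeated per grid value);
ties break toward the smallest exponent.

Split-half reliability — the noise ceiling and the ≥ 10% inclusion
filter — is the squared correlation between the averaged odd and even
halves, in percent: 100 for identical halves, ~0 in expectation for
pure noise, monotone decreasing in noise level. (A cross-prediction
residual form was rejected because pure noise scores −100%, which does
not match the intended "~0 for non-responsive voxels" semantics.)

The CSS retinotopy fitter is two-stage: stage 1 scores an exhaustive
coarse grid — centres on a 1° lattice inside the 24° aperture, σ ∈
{0.5, 1, …, 8}, exponent ∈ {0.05, 0.25, 0.5, 0.75, 1} — using the fact
that the drive of a pRF centred at a pixel equals the Gaussian-blurred
stimulus frame at that pixel (separable kernel, so all centres for one
σ cost two small matrix products per frame). Stage 2 refines from the
coarse optimum with Nelder-Mead on the continuous forward model
(exponent clipped to [0.01, 1]). With bar stimuli σ and the exponent
trade off along the `σ/√n` ridge: centres and *effective* sizes are
identified to high precision (tests assert centre error < 0.1° and
effective-size error < 10% noiselessly), but `(σ, n)` individually are
not — a known property of compressive fits to sweeping bars.

# Suppression quantification

Run series (averaged across split halves) are segmented into 23-TR
windows, −4 to +18 s around block onset, and averaged across the four
repeats per condition. Per condition, the area-level grand-mean window
is re-baselined to the mean of the four pre-onset TRs and clipped at
zero (the source does not state baseline handling; this makes the rule
robust to negative baselines), and the first post-onset second at which
the cumulative sum exceeds 10% of its total maps the 9-TR averaging
window to 4–12 s (crossing ≤ 4 s) or 5–13 s (later). Each voxel's
amplitude per condition is the mean of its own window over those TRs.

The suppression model regresses each voxel's SIM amplitude on its SEQ
amplitude with fixed intercept and slope per condition and random
per-condition intercepts and slopes within participant, fitted by
maximum likelihood via `lme4`. We use cell-means coding (per-condition
dummies and their products with SEQ), so per-condition slopes are
reported directly instead of being reconstructed from interaction
contrasts. The full 8×8 random-effect covariance has 45 model df; on
singularity (common at small simulated scales) the model refits with a
diagonal covariance and flags it. The three simpler comparison variants
(single slope + random intercept; per-condition fixed effects with one
or with per-condition random intercepts) have 4, 10, and 19 df. Slope
CI95s use t quantiles with participants − 1 df: with ≤ 10 participants
the Wald z interval measurably under-covers (≈ 88% vs the nominal 95%
in generative recovery simulations), and the t correction is the
standard small-sample fix.

Bootstrap parameter summaries resample values 1000× with replacement
within participant × area (median for sizes, exponents, and time
constants, whose distributions are skewed; mean for β-weights), then
average across participants with SEM.

# The synthetic world

`area_profile()` states a population: centres uniform in (a sub-box of)
the 0.59°–9.41° quadrant box, effective sizes and exponents uniform in
ranges chosen per emulated area (V1-like ~0.5–1°, near-linear; VO-like
2–4°, exponent ~0.3; TO-like 3–6°, exponent ~0.3 — spanning the
reported 1°-to-7.8° range of mean effective sizes), response amplitudes
0.5–2.5% signal change. Noise is independent Gaussian per TR
(the analysis operates on block averages, where temporal autocorrelation
matters little for recovery testing), with SD calibrated in closed form
to a target split-half reliability:
`σ² = r·S·(1−√ρ)/√ρ` for signal variance `S` and `r` repeats per half —
validated by simulation (±0.05 at targets 0.5 and 0.9). Participant
structure enters as a truncated-normal shift of the compressive
exponent per participant, exercising the LMM's random slopes.

What a green test does establish: the pipeline recovers known
generating parameters, the linear null yields slopes of 1, and the
compressive orderings emerge from the stated populations. What it does
not: physiological noise structure, HRF variability across voxels,
retinotopic parameter distributions of real areas, or the actual
magnitudes of suppression in data — the synthetic world's slopes depend
on the chosen parameter ranges.

## A non-obvious interaction worth knowing

With large pRFs (σ ≳ 4°) and strong compression, the *far* quadrant
leaks into the drive: an overlap of 10⁻⁵ becomes 0.03 after `x^0.3`.
Because square timing is randomized independently per quadrant,
SIM-short blocks contain moments where only the far quadrant is on,
inflating SIM-short energy relative to SEQ-short; removing the far
quadrant restores exact equality of the SIM/SEQ energy ratio across
timings. Consequently the CSS model's hallmark — equal suppression for
long and short timings at matched size — holds to ±0.05 for VO-like
populations (σ 2–4°) but degrades to differences of 0.04–0.09 for
TO-like ones (σ 3–6°). The acceptance suite therefore checks CSS timing
equality on a VO-like population and the CST orderings on a TO-like
population; both choices are fixed and documented here.

A second, smaller effect: block windows extend −4 to +18 s, so BOLD
from neighbouring blocks (whose identity differs across the four
repeats of a condition) bleeds into windows and baselines. This leaves
the linear-null slopes at 1.000 ± ~0.005 rather than exactly 1 even
with near-zero noise.

# Numerical conventions

* Degrees of visual angle, fixation at origin, x rightward, y upward;
  rectangles are closed sets; pixel-centre membership for rasters.
* All kernels truncated where the analytic tail mass < 10⁻⁸.
* Seeds: every stochastic element derives from one master seed through
  a fixed modular hash, keeping derived seeds within 32-bit range;
  identical (seed, config) pairs give byte-identical outputs.
* Degenerate inputs: zero-area rectangles overlap 0 with a warning;
  zero-variance data give `NA` cv-R²; non-positive grand-mean windows
  default to the 4-s start with a warning; singular LMM fits fall back
  to diagonal covariance; rank-deficient designs use the pseudo-inverse
  with a warning.

# Known limitations

* CST temporal constants and DN-ST parameters are taken as given, not
  fitted (the grid-fit covers only the CST exponent, as specified).
* The DoG surround amplitude convention (unit volume) is one of several
  defensible choices; suppression-free block integrals hold under any
  linear convention, but absolute drive values differ.
* NIfTI ingestion is not implemented (no NIfTI reader in the supported
  dependency set); long-format TSV is the interchange format.
* The retinotopy protocol models binary bar apertures only; carried
  image content and its contrast filtering are out of scope.
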