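---
title: "Graphene-induced energy transfer as an axial ruler: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graphene-induced energy transfer as an axial ruler: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Graphene quenches nearby fluorophores by radiationless electromagnetic
coupling to its plasmons, with an efficiency that falls off roughly as
$d^{-4}$ over the first few tens of nanometers. Because a single graphene
sheet is almost transparent and the quenching range (about 3–25 nm)
matches the size of large membrane protein complexes, the effect can be
used as a spectroscopic ruler for the *axial* position of a fluorophore
above a graphene-supported lipid monolayer. `gietr` implements the
complete computational chain: the electromagnetic model that predicts the
distance dependence, its inversion into calibrated distances with
uncertainties, the geometric calibration against DNA nanorulers, and the
time-resolved single-molecule analysis that turns intensity traces into
conformational states and transition kinetics.

## The emission-power model

An excited fluorophore is treated as an ideal oscillating electric dipole
in the aqueous half-space above a planar stack
(glass | graphene | lipid monolayer | water). Expanding the dipole field
in plane waves, the total dissipated power relative to free space is an
integral over the normalized in-plane wavenumber
$u = k_\parallel / (n_1 k_0)$, with $w = \sqrt{1 - u^2}$
($\mathrm{Im}\, w \ge 0$) and $z$ the width of the aqueous gap between
the monolayer surface and the emitter:

$$
\frac{S_\perp}{S_0} = 1 + \tfrac{3}{2}\,\mathrm{Re}\!\int_0^\infty
  \frac{u^3}{w}\, r_p(u)\, e^{2 i k_1 w z}\, du, \qquad
\frac{S_\parallel}{S_0} = 1 + \tfrac{3}{4}\,\mathrm{Re}\!\int_0^\infty
  \frac{u}{w} \left[ r_s(u) - w^2 r_p(u) \right] e^{2 i k_1 w z}\, du,
$$

where $r_s, r_p$ are the generalized Fresnel coefficients of the stack
seen from the water side and $k_1 = n_1 k_0$. Because linker flexibility
and rotational diffusion randomize the dipole orientation on the
fluorescence timescale, the package reports the isotropic average
$S = (S_\perp + 2 S_\parallel)/3$ by default. The quantum yield $\phi$
mixes the modified radiative/non-radiative decay into the observable
lifetime ratio

$$
\frac{\tau_G}{\tau_0} \;=\; \frac{S_0}{(1-\phi)\, S_0 + \phi\, S(d)},
$$

the only reading of the ratio formula with the correct physical limit
$\tau_G/\tau_0 \to 1$ as $d \to \infty$. In the absence of static
quenching the relative intensity $I_G/I_0$ follows the same curve, so
intensity ratios and lifetime ratios are interchangeable inputs.

### Stack, fluorophores, and the distance convention

The default stack is glass ($n = 1.52$), a 0.34 nm graphene slab with
complex index $2.68 + 1.21i$ (520 nm emission band) or $2.76 + 1.40i$
(670 nm band), a 2.5 nm lipid monolayer ($n = 1.44$) and water
($n = 1.33$). Graphene is modeled as a homogeneous absorbing film with
the tabulated band indices; other emission wavelengths require a
user-supplied index — the package deliberately refuses to interpolate
between the two tabulated values. Emission is treated as monochromatic
at the fluorophore's emission maximum. Four fluorophore presets are
bundled (emission max, quantum yield, unquenched lifetime): FAM
(518 nm, 0.75, 3.0 ns), EGFP (507 nm, 0.60, 2.1 ns), mNeonGreen
(517 nm, 0.80, 2.8 ns) and Dy647P1 (667 nm, 0.27, 1.3 ns).

The axial coordinate $d$ follows the convention of the published GIET
calibrations that this package reproduces: $d$ equals the width of the
aqueous gap between the monolayer surface and the emitter, and heights
above the monolayer are reported as $h = d - 2.5$ nm. With this
convention the computed curves reproduce the published ratio–distance
anchor points (for example FAM $\tau_G/\tau_0 = 0.49$ inverts to
$d = 10.9$ nm) to better than 0.1 nm; referencing the gap to the
graphene surface instead changes $S(d)$ by factors of 2–5 at short
range and is incompatible with those anchors. The emitter must sit in
the water half-space at $d \ge 2.5$ nm; the theory for a dipole inside
a finite layer is out of scope.

### Numerics

The $u$-integral is split at the branch point $u = 1$. The propagating
part is mapped by $u = \sin t$, which removes the integrable $1/w$
singularity exactly; the evanescent tail is mapped by $u = \cosh s$,
exploiting the $e^{-2 k_1 z \sinh s}$ damping, and truncated where the
exponent reaches $-45$ (integrand tail below $10^{-19}$). Both pieces
use adaptive quadrature (`stats::integrate`) at a relative tolerance of
$10^{-8}$, comfortably inside the $10^{-6}$ contract; the test suite
checks the adaptive result against a half-million-node fixed-grid
trapezoid rule at $10^{-5}$ relative. Reflection coefficients are
computed by the recursive Fresnel (scattering) method, whose phase
factors $e^{2 i k_z t}$ stay bounded deep into the evanescent region;
the characteristic-matrix formulation overflows there (hyperbolic
growth of $\cos\delta$, $\sin\delta$ for complex $\delta$) and is not
used.

Calibration curves are tabulated on a grid of at most 0.1 nm (0.05 nm
in the bundled presets) and wrapped in a monotone shape-preserving
piecewise-cubic interpolant (`splinefun(method = "monoH.FC")`).
Monotonicity of the sampled ratios is asserted at build time, so the
interpolant is strictly invertible and ratio inversion reduces to
bracketed root finding at $10^{-4}$ nm tolerance. Measurement
uncertainty is propagated by inverting ratio $\mp$ s.d. (an asymmetric
interval, matching the bracket convention of the ensemble analysis)
rather than by a linearized delta method, which would be misleading on
the strongly curved short-distance branch.

## Nanoruler tilt calibration

Membrane-anchored DNA duplexes place a dye at contour length
$l_\mathrm{DNA}$ from the anchor; electrostatic repulsion keeps them
extended but not upright, so the vertical dye position is
$d = l_\mathrm{DNA} \sin\alpha + l_\mathrm{ML}$ with a single global
tilt angle $\alpha$ and monolayer thickness $l_\mathrm{ML} = 2.5$ nm.
`fitTiltAngle()` minimizes the unweighted sum of squared ratio
residuals against a GIET curve by bounded scalar minimization on
$(0°, 90°]$; inverse-variance weighting by the measurement s.d. is
available as an option. A single $\alpha$ is shared by all ruler
lengths and label ends; per-ruler tilt is deliberately out of scope.
Because no analytic standard error is available for this nested
nonlinear fit, uncertainty comes from a seeded bootstrap over
measurements (200 replicates by default).

Intensity-mode and lifetime-mode datasets may be fitted jointly or
separately; the joint fit is the default and is the configuration
behind the $\pm 1°$ recovery envelope asserted in the tests — with a
single 7-point mode at 3% multiplicative noise the estimator's spread
is about $0.7°$ (1 s.d.), and pooling both modes brings it within the
envelope. The synthetic ruler generator applies multiplicative Gaussian
noise to the ideal ratios, the natural model for a ratio of two
intensity measurements with constant coefficient of variation.

## Single-molecule pipeline

The single-molecule branch follows the standard TIRF workflow at 30
frames/s (32 ms exposure, 107 nm pixels):

1. **Localization.** Candidate spots are local maxima above the frame
   median plus `detection_threshold` (default 5) robust noise s.d.
   (MAD), de-duplicated by non-maximum suppression, then refined by the
   iterative Gaussian-mask centroid until the shift falls below 0.01 px
   (at most 50 iterations). The reported intensity is the mask-weighted
   background-subtracted sum. Coordinates are continuous and 0-based
   with the origin at the top-left pixel centre, converted to nm.
2. **Trace building.** Localizations are greedily linked to the nearest
   running-mean anchor within 150 nm, with at most one localization per
   trace per frame (assignment by increasing distance, so the result is
   independent of within-frame input order). Traces shorter than 100
   frames are discarded, and pairs of anchors closer than 500 nm are
   both removed to exclude crosstalk.
3. **Segmentation (STaSI).** Each trace is segmented by recursive
   change-point detection: a segment is split where the Student-t
   statistic of the two-sided mean difference exceeds its critical
   value (Bonferroni-corrected over candidate split points,
   $\alpha = 0.01$), with the noise s.d. estimated from the median
   absolute successive difference scaled by $1/(\sqrt{2}\cdot0.6745)$
   — an estimator blind to the steps themselves. Segment means are then
   merged agglomeratively, and the state count is chosen by minimum
   description length: Gaussian fit cost plus $\tfrac12\log_2 N$ per
   state mean and change point plus $\log_2 K$ per segment for the
   segment-to-state assignment code. The assignment term matters: with
   long segments, a two-part MDL without it oversplits states whose
   segment means scatter by more than their standard error. The
   noise model is homoscedastic; under the constant-CV emission noise
   of real traces the brightest state is occasionally split, which is
   harmless here because STaSI only ranks traces and seeds the HMM —
   the hidden Markov model with user-set $K$ is the final arbiter,
   mirroring the two-stage design of the original analysis.
4. **HMM.** The best-fitting third of the traces (smallest normalized
   residual variance of the piecewise-constant fit — a scale-free
   criterion) initializes a Gaussian-emission hidden Markov model:
   state means/s.d.s from clustering the STaSI state means, transition
   pseudo-counts from the labelled frames. Baum–Welch runs on all
   traces pooled as independent sequences, with log-space
   forward–backward recursions (implemented in C++ for speed),
   convergence at $10^{-6}$ relative log-likelihood or 1000
   iterations, and a variance floor at $10^{-3}$ of the pooled data
   s.d. (hitting it flags the state as degenerate). States are sorted
   ascending by mean — the low/medium/high convention. Viterbi
   decoding breaks ties toward the lower state index.
5. **Kinetics.** Dwell times are maximal constant runs of the decoded
   paths; the first and last run of every trace are censored (their
   boundaries were not observed) and excluded. The exit rate is
   $1/\tau$ from a least-squares fit of the log empirical survival
   function of the complete dwells (at least 5 required; otherwise the
   rate is reported as `NA` with its counts), and pairwise rates split
   the exit rate by observed transition counts, so the pair rates of a
   state sum to its exit rate by construction. Two small biases are
   inherent and documented rather than hidden: interior dwells in a
   finite trace are length-truncated (rates biased high by roughly
   $\tau/T$), and sampling a continuous-time chain at 32 ms mildly
   contracts fast exit rates ($1 - e^{-k\,\Delta t}$ vs $k\,\Delta t$).
   Both are at the few-percent level for the second-to-subsecond
   kinetics this assay targets when traces are tens of seconds long.
6. **Heights and precision.** State means divided by the mean on-glass
   intensity give per-state $I_G/I_0$, inverted on the Dy647P1 curve
   with the state s.d. propagated through the same bracket convention
   as the ensemble analysis. The axial precision estimate is the
   per-trace RMSD/mean of on-glass traces, pooled across traces; since
   two independent intensities enter the ratio, the ratio's relative
   error is $\sqrt{2}$ times the pooled value (7.5% per intensity
   gives 10.6% on the ratio — the quadrature reading, which matches
   the reported number; the plain product would give 15%).

## Synthetic data: what it emulates, and what it does not

Every pipeline stage is testable without experimental data through
three generators, all driven by one explicit seed (stage sub-seeds are
derived deterministically from it):

* `simulateTraces()` samples a $K$-state continuous-time Markov chain
  at the frame interval, maps state heights through a GIET curve to
  mean intensities ($\mu_k = I_0 \cdot \mathrm{curve}(h_k + 2.5)$) and
  adds Gaussian noise with constant coefficient of variation (default
  7.5%, the value implied by the measured single-molecule precision).
  Optional single-step photobleaching to background reflects the
  single-bleach selection applied to real traces. Ground-truth paths
  are returned so every downstream stage can be scored.
* `simulateImageStack()` renders immobile spots as 2D Gaussian PSFs
  (default $\sigma = 1.3$ px) with Poisson photon noise, constant
  background and optional Gaussian read noise, at surface densities in
  the 0.2–1 µm$^{-2}$ regime of the real assay and with a configurable
  minimum separation.
* `simulateRulerData()` produces nanoruler ratio tables at the seven
  calibration contour lengths (1.7–17.0 nm) under multiplicative
  Gaussian noise (default 3%).

The trace generator uses constant-CV Gaussian emission noise — matching
the RMSD/mean framing of the precision analysis — rather than a full
photon-counting model; the image generator, conversely, is
Poisson-based, so both noise regimes are covered. Not emulated:
emitter diffusion, z-dependent PSF shape, EM-CCD gain statistics,
spectral crosstalk, and drift. Passing tests therefore demonstrate
correctness of the estimators under the stated noise models, not
robustness to every instrumental artifact of a real TIRF recording.

## Problem sizes and test design

The recovery tests run at sizes chosen to make their tolerances
statistically meaningful rather than generous: three-state end-to-end
recovery uses 150 traces of 800 frames (about $1.2\times10^5$ frames,
roughly 4000 transitions, so the 15% rate tolerance sits at about
three standard errors), and two-state dwell recovery uses 300 traces
of 1000 frames. Curves in the test suite are tabulated at 0.1 nm
(interpolation error well under the 0.5% contract); the bundled
acceptance script uses 0.05 nm.

## Known limitations

* Angular emission patterns, NA-dependent collection efficiency and
  detection-side corrections are not modeled; the observable is the
  total dissipated power.
* Graphene is a homogeneous slab with a band-tabulated bulk index; a
  surface-conductivity (Kubo) model is out of scope.
* The emitter must be in the aqueous half-space; fluorophores inside
  the lipid or closer than 2.5 nm are rejected rather than
  extrapolated.
* Spectral averaging over the emission band is not performed; for the
  bundled dyes the band-averaged curve differs negligibly from the
  monochromatic one at the emission maximum.
* The published curves may or may not include an effective-index
  correction for a dense protein layer above the monolayer; the
  four-layer stack is used exactly as printed, which reproduces all
  published anchor points.
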