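---
title: "Models, conventions and design choices in dtcmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and design choices in dtcmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtcmr)
```

# Scope

`dtcmr` implements a complete DT-CMR analysis chain — phantom simulation,
preprocessing, tensor estimation, cardiac-coordinate mapping, quality
statistics, sequence theory, gradient design, strain and group statistics
— with every stage testable against known ground truth. This vignette
records the models and the design decisions that were genuinely open,
in enough detail that a maintainer can judge them.

# The phantom and its forward model

The phantom is a single mid-ventricular short-axis slice: a circular
annulus between an endocardial radius $R_i$ and an epicardial radius
$R_o$, both prescribed per cardiac phase (defaults: 17/30 mm at
end-systole, 20/31 mm at the sweet spot, 24/32 mm at diastasis — typical
healthy dimensions). Geometry is 2D; the longitudinal direction is the
slice normal. Pixel coordinates are 0-based and pixel-centred; the
default grid is 48 × 48 at 2.8 mm, matching a typical zone-selected EPI
acquisition.

At each myocardial pixel the local orthonormal cardiac triad is
$(\hat r, \hat c, \hat z)$ (outward radial, counter-clockwise
circumferential, slice normal) and the transmural depth $d \in [0, 1]$
runs from the epicardium (0) to the endocardium (1). The ground-truth
tensor is built from its eigensystem:

* primary eigenvector $e_1 = \cos(\mathrm{HA})\,\hat c +
  \sin(\mathrm{HA})\,\hat z$ with
  $\mathrm{HA}(d) = \mathrm{HA}_{epi} + d\,(\mathrm{HA}_{endo} -
  \mathrm{HA}_{epi})$;
* secondary eigenvector tilted out of the wall-tangent plane towards
  $\hat r$ by the per-phase sheetlet angle:
  $e_2 = \cos(\mathrm{E2A})\,\hat w + \sin(\mathrm{E2A})\,\hat r$ with
  $\hat w = \hat r \times e_1$;
* eigenvalues $(\lambda_1, \lambda_2, \lambda_3) =
  (1.6, 1.0, 0.6)\times 10^{-3}\,\mathrm{mm^2\,s^{-1}}$.

The transmural HA range (+60° endocardium to −60° epicardium) and the
eigenvalues are literature-typical values for healthy myocardium — they
are parameters of `lv_phantom_spec()`, not constants, because healthy
ranges vary between studies. E2A defaults are 60° in systole and 20° in
diastole, consistent with a sheetlet mobility of ~40°; the sweet-spot
value defaults to their midpoint.

Each simulated frame follows $S = S_0 e^{-b\, g^\top D g}$ with one frame
per (shell, direction, average). Rician noise is the modulus of the
complex signal after adding independent $\mathcal N(0, \sigma^2)$ noise
per channel, $\sigma$ given in image units relative to $S_0 = 100$. The
RR interval of each frame's encoding beat is a truncated Gaussian with a
default jitter SD of 5 ms (the typical intra-subject RR variability);
for STEAM the *true* encoding b scales with the drawn beat through the
Stejskal–Tanner factor $(\Delta - \delta/3)$ with $\Delta = RR$ and
$\delta = 2.4$ ms, while the *stored* nominal b does not — exactly the
situation the beat-to-beat correction has to fix. The blood pool carries
a constant signal of 3 × myocardial $S_0$ with no diffusion attenuation,
emulating incompletely nulled, flow-refreshed blood; a constant bright
pool (rather than an attenuated tensor signal) keeps the
intensity-threshold nulling stage well-posed at the main shell.

**What the phantom does not emulate:** EPI/SENSE reconstruction, coil
sensitivities, eddy currents, partial-volume at the wall boundary,
through-plane motion, restricted diffusion and diffusion-time effects,
and 3D ventricular geometry. Passing round-trip tests therefore
establishes the *correctness of the analysis chain*, not the in-vivo
accuracy of either sequence; in particular the diffusion-time difference
between STEAM and M2-SE — a dominant source of in-vivo discrepancy — is
deliberately outside the signal model.

# Preprocessing

* **Blood nulling.** Pixels above `threshold_factor` (default 2) times
  the per-frame median myocardial intensity are zeroed before
  registration and restored afterwards, displaced by the rounded applied
  translation. The factor is a default of this implementation; the
  criterion it automates is qualitative ("very high signal intensity").
* **Registration.** Rigid translation only. The similarity metric is
  normalized cross-correlation against the pixelwise median image of the
  series (NCC is invariant to the global intensity differences between
  shells and directions), searched over ±10 px integer shifts and refined
  by parabolic interpolation of the NCC surface. Subpixel refinement on
  clean but non-identical frames legitimately returns small non-zero
  corrections (the NCC surface need not be symmetric about the integer
  peak); only identical frames are guaranteed exact zeros.
* **Frame rejection.** An automated surrogate for visual quality control:
  a frame is dropped when its correlation with the median image of its
  (b, direction) condition (series-wide median for conditions with fewer
  than three frames) falls below 0.80. Both the grouping and the
  threshold are configurable; they stand in for expert visual assessment
  and were not tuned to any reference reading.
* **b correction.** $b_i' = b\,(RR_i - \delta/3)/(RR_0 - \delta/3)$ for
  STEAM frames only; M2-SE passes through because its diffusion time is
  set by the gradient lobes, not the beat.
* **Tensor fit.** Ordinary least squares of $\ln S$ on
  $[1, -\mathbf b_{row}]$ per pixel, all frames entering individually.
  The reference shell is b = 150 s·mm⁻², not b = 0, so the fit spans two
  shells in the same six directions. No weighting, no iterative
  reweighting, no Rician bias correction — matching a plain linear
  least-squares inversion. Pixels with any non-positive signal are
  flagged invalid rather than log-clipped. Imaging/crusher cross-terms in
  the b-matrix are ignored; the nominal (b, g) pair is used as recorded.

# Cardiac coordinates and angle maps

For segmentation-driven data the radial direction comes from the gradient
of the inter-contour distance field ($d_{endo} - d_{epi}$), which stays
meaningful for non-circular walls; depth is
$d_{epi}/(d_{epi} + d_{endo})$. For the circular phantom the analytic
annulus coordinates are exact.

All angles are axial quantities (eigenvectors are sign-arbitrary) and are
folded to (−90°, 90°]:

* **HA** — angle between $\hat c$ and the projection of $e_1$ onto the
  wall-tangent plane, positive towards $+\hat z$. The positive-HA
  convention (helix rising counter-clockwise viewed from the base, giving
  a positive HA at the endocardium for the default phantom) is a
  documented convention of this package; studies differ, and the sign
  can be flipped by negating the longitudinal axis.
* **TA** — same construction in the short-axis plane, positive towards
  $+\hat r$.
* **E2A** — the absolute angle, within the cross-myocyte plane, between
  the projection of $e_2$ and the plane's in-wall axis. Two published
  constructions of that plane exist: spanned by the radial direction and
  the in-wall normal to the *projected* $e_1$ (default here,
  `plane = "cross_myocyte"`), or the plane orthogonal to $e_1$ itself
  (`plane = "e1_orthogonal"`). They coincide exactly when $e_1$ lies in
  the tangent plane — which is how the phantom is built — and differ only
  through transverse tilt of $e_1$; the default was chosen because it
  keeps E2A a pure sheetlet measure under small HA fitting errors.

Degenerate pixels are flagged rather than guessed: $e_1$ parallel to the
radial direction has no HA; $e_1$ parallel to the slice normal has no TA;
an $e_2$ projection below 1e−8 has no E2A. Negative eigenvalues are *not*
clamped before MD (clamping would bias MD downward and distort the
linear-fit statistics) but the pixel is excluded from FA/mode/angle
summaries.

# Transmural profiles, HAG and scoring

Profiles are sampled on 72 spokes (5° steps — the spoke count is a
default of this package) from the LV centre; along each spoke the depth
field is inverted to find the radii of fixed depth fractions (10–90 % in
9 steps) and HA is sampled there bilinearly. HAG is the **mean of
per-spoke OLS slopes** of HA against depth (%), not the slope of the
pooled samples; the pooled alternative is available
(`method = "pooled"`). Mean-of-spokes was chosen because it weights each
wall sector equally regardless of how many samples survive masking. The
$R^2$ of a zero-variance regression is defined as 0.

The HA-map score automates a visual rubric: a spoke is "normal" when its
transmural fit has $R^2 \ge 0.3$ and a slope of the expected sign, and
the normal fraction $f$ maps to $f > 0.95 \to 3$, $f > 0.75 \to 2$,
$f \ge 0.5 \to 1$, else 0 (failure; failed acquisitions are excluded from
downstream statistics). The $R^2$ threshold is a surrogate for expert
judgement — the rubric thresholds themselves are fixed, the normality
criterion is configurable.

# Sequence theory and gradient design

The closed-form SNR ratio assumes ideal flip angles, matched readouts and
a monoexponential tensor signal; it reduces to the bare stimulated-echo
½ penalty when echo times, b-values and recovery terms are matched and
the mixing time vanishes. Diffusion distance uses the 1D convention
$\sqrt{2D\Delta}$ by default (it reproduces the familiar ~75 µm per
cardiac cycle and ~10 µm per 20 ms for free water at body temperature);
the 3D convention $\sqrt{6D\Delta}$ is available via `dims = 3`.
Breath-hold arithmetic counts preparation shots once per breath-hold,
each shot costing TR in RR intervals.

Gradient moments are integrated exactly per linear segment with polarity
flips at refocusing pulses, about $t = 0$ at the waveform start and
evaluated at the echo. Once $M_0 = 0$, $M_1$ is reference-independent,
and once $M_0 = M_1 = 0$ so is $M_2$ — so the nulling conditions do not
depend on the reference choice. The b-value integrates the piecewise
quartic $q(t)^2$ in closed form (γ = 2.675 × 10⁸ rad·s⁻¹·T⁻¹).

The motion-compensated design uses the asymmetric paired-lobe family:
physical lobes $[+\delta_1, -\delta_2]$ before the refocusing pulse and
$[-\delta_2, +\delta_1]$ after, making the *effective* waveform
antisymmetric about its midpoint. Antisymmetry nulls $M_0$ and $M_2$
identically, leaving a single $M_1 = 0$ condition solved for
$\delta_2/\delta_1$ by root finding on the exact moments (for rectangular
lobes with no gap the ratio is $1 + \sqrt 2$). The short-lobe duration is
then solved so b hits the target at maximum amplitude with slew-limited
trapezoids; targets below the minimum-duration b are reached by scaling
the amplitude (nulling is preserved — moments are linear in amplitude).
"Nulled" means $|M_1|, |M_2| \le 10^{-6}$ of the corresponding
single-lobe magnitude. The design targets b and hardware constraints, not
any particular printed lobe durations, which also depend on per-axis
amplitudes after direction scaling.

# Strain

The displacement generator deforms the diastolic reference ring through
the radial map $\rho(R)^2 = \alpha R^2 - c$. A purely 2D incompressible
map ($\alpha = 1$) cannot reach the physiological pairing of ~0.50 radial
thickening with ~−0.177 circumferential shortening — in-plane area
preservation ties the two together (a −0.177 circumferential strain would
force a mean radial strain near 0.27). The second parameter lets
through-plane motion absorb the volume change, as long-axis shortening
does in the real ventricle. Both parameters are solved at every timeframe
so the *area-weighted mean* Green–Lagrange radial and circumferential
strains over the annulus equal the prescribed peaks scaled by a
triangular time profile (zero at the first and last frames, peak at
mid-series; an odd frame count places a frame exactly at the peak). The
map is extended C¹-continuously inside the cavity (odd cubic) and outside
the epicardium (exponentially relaxing slope) so finite differences see
no kink at the contours.

The strain stage computes $F = I + \partial u/\partial X$ by central
differences, projects $E = (F^\top F - I)/2$ onto the reference radial
and circumferential directions, and averages over the myocardium.
Green–Lagrange is the default measure (the convention of
displacement-encoded cine analysis); engineering strain
($\sqrt{1 + 2E} - 1$ per direction) is available. Peak radial strain is
the maximum over time, peak circumferential the signed minimum. The
default cine grid is 1 mm — finer than the diffusion grid, as
displacement-encoded acquisitions are reconstructed on their own grid —
and recovery of the prescribed peaks is within 2 % there, converging as
the grid is refined.

# Group statistics

Sequences are compared with paired Wilcoxon signed-rank tests (zero
differences dropped; exact distribution up to 25 untied pairs, normal
approximation with continuity correction otherwise — the test suite
checks the exact branch against full sign-pattern enumeration). Phases
are compared with a Friedman test followed, when significant at 0.05, by
pairwise Wilcoxon tests against the Bonferroni threshold 0.05/3 ≈ 0.0167.
A fully tied Friedman statistic is undefined; it is reported as no
evidence (p = 1). Strain correlations are Pearson on **signed** metric
differences (systole − diastole within a sequence, or STEAM − M2-SE at a
phase) against peak strains, with non-simultaneous 95 % confidence bands
from the linear fit; score–RR correlations are Spearman with midranks.
E2A is summarised by its LV median (it is bounded and skewed), everything
else by the mean.

# The cohort driver

`run_study()` enumerates subjects × {STEAM, M2-SE} × {systole,
sweet-spot, diastole}, drawing per-subject heart rate
($\mathcal N(970, 140^2)$ ms, truncated positive), a ±4 % geometric
scale, peak strains around (0.50, −0.177), and a diastolic E2A around
20°. Systolic E2A is generated as diastolic E2A plus a mobility term
proportional to the subject's peak radial strain (40° at the reference
strain of 0.50, plus 3° residual noise) — encoding the physiological link
between sheetlet rotation and wall thickening so the strain-correlation
stage has a real signal to find. Per-cell seeds derive from the master
seed; rerunning with the same seed reproduces the summary table exactly.
Cells that fail (processing error or HA-map score 0) are recorded and
excluded from statistics without aborting the cohort.

Default problem sizes — 48 × 48 diffusion grids, 54 frames (STEAM) or
108 (M2-SE) per cell, 72 spokes, 1 mm cine grids with 21 frames — were
chosen so a 15-subject cohort simulates and analyses in a few minutes on
one core while leaving several hundred myocardial pixels per slice; the
unit tests use a 32 px grid where only the chain's algebra, not its
resolution, is under test.

# Known limitations

* Registration is translation-only; rotation or deformation in the data
  will alias into frame rejection.
* The rejection criterion and HA-map scoring are automated surrogates for
  expert reading; their thresholds are sensible defaults, not validated
  equivalents.
* The tensor fit is unweighted log-linear least squares: at low SNR the
  Rician floor biases FA upward (the test suite demonstrates this
  deliberately) and MD estimates inherit log-domain noise asymmetry.
* Strain is 2D; torsion and through-plane shear are invisible to the
  generator and the estimator alike.
* The in-vivo SNR ratio of the two sequences depends on myocardial
  relaxation times and on the diffusivity entering $e^{-bD}$; the theory
  function evaluates whatever parameters it is given and makes no claim
  about which in-vivo values are correct.
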