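---
title: "Thickening and settling models for secondary clarifiers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thickening and settling models for secondary clarifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(settleflux)
```

This vignette documents the science implemented in `settleflux`, the
assumptions behind each model, the parameter conventions, the numerical
choices that were genuinely open, and what the synthetic-data generators do
and do not establish.

## 1. The thickening model

A batch thickening test records the sludge concentration at the bottom of a
settling column over time. `settleflux` models it as a power law,

$$X_d(t_s) = a\,t_s^{\,b},$$

with $t_s$ the thickening time in minutes, $a$ (g/L) the concentration
reached after 1 minute and $b$ (dimensionless) the thickening exponent,
typically a few percent. The return sludge concentration is
$X_r = k X_d$, where $k$ accounts for dilution by turbulence at the
withdrawal point: $k = 0.7$ for scraped bottoms and $k \in [0.5, 0.7]$ for
suction withdrawal. These $k$ conventions are enforced by
`return_sludge_spec()`.

**Fitting scale.** `fit_power_law()` fits by ordinary least squares on
$\ln X_d \sim \ln t_s$. This is exact maximum likelihood under
multiplicative lognormal noise — the natural error model for a
concentration probe — and is the field convention for power laws. $R^2$ and
the two-sided $t$-test $p$-value of the slope are reported on that fitted
scale. An optional nonlinear refinement (`refine = TRUE`) re-minimizes
squared error on the original scale, initialized from the log–log solution;
diagnostics intentionally stay on the fitting scale to avoid mixing
incommensurable $R^2$ definitions. With only $n = 3$ points the slope test
has a single degree of freedom and the $p$-value is fragile; it is reported
anyway, and is `NA` for perfect (zero-residual) fits where the test is
undefined.

**Domain conventions.** The power law is degenerate at $t_s = 0$, so points
at zero time are excluded from fitting and predictions require
$t_s \ge 1$ min (the scale at which $a$ is defined). Predictions below the
feed concentration $X_0$ are physically impossible — the blanket cannot be
more dilute than what fed it — and are clamped to $X_0$ with a `clamped`
flag rather than silently returned. A fitted $b$ outside $(0,1)$ triggers a
warning but is never altered: diagnostics over coercion.

**Mass balance.** Assuming a homogeneous compression zone, the blanket
obeys $x\,X_d = x_0 X_0$ at all times, giving the height curve
$x(t_s) = x_0 X_0 / (a t_s^{\,b})$ (`sludge_height()`). Because the clamped
prediction is used, the identity holds exactly (to $10^{-12}$ relative,
tested) on both sides of the clamp.

**Sensitivity to $b$.** Since plants share a narrow range of exponents, one
may adopt a fleet-mean $b$. The relative sensitivity of the prediction is
$S = (\partial X_d/\partial b)(b/X_d) = b \ln t_s$, which at $b = 0.0465$
stays below the conventional 0.2 acceptability bound up to roughly an hour
($S(60\,\mathrm{min}) \approx 0.19$) and exceeds it by 90 min
($S \approx 0.21$). The closed form is verified against centered finite
differences in the tests.

## 2. The SVI link

Across plants, the 1-minute coefficient $a$ decreases with the sludge
volume index: `fit_svi_link()` fits $a = \alpha \ln(\mathrm{SVI}) + \beta$
by OLS. The natural logarithm is used as in the published form of the
relation; a base-10 variant is available (`log_base = "log10"`) for
sensitivity analysis, since neither base reproduces the published
calibration panel exactly.

Two presets ship, provenance-tagged so the discrepancy between them stays
visible:

- `svi_link_printed()` — the published coefficients
  $(\alpha, \beta) = (-5.754, 26.862)$ with their published $R^2 = 0.988$,
  validity ranges (SVI 59.3–248.4 mL/g, $X_d$ 7.95–14.81 g/L) and fleet
  mean $b = 0.0465$. These coefficients are internally inconsistent with
  the four-plant panel they are attributed to: they predict
  $a = 3.37$ g/L at SVI = 59.3 mL/g where the panel records 11.73 g/L.
- `svi_link_refit()` — the default: OLS refit of the built-in panel
  (`calibration_plants()`), which is reproducible from published data
  ($\alpha \approx -3.96$, $\beta \approx 27.7$, $R^2 \approx 0.995$).

The package never guesses which data produced the published coefficients;
it exposes both and defaults to the reproducible one. Validity ranges for
the refit are the data envelope: the panel's SVI range, and for $X_d$ the
span from the smallest $a_i$ (1-minute concentration) to the largest
$a_i \cdot 90^{b_i}$ (90-minute test end).

## 3. Compression settling and the integrated law

Differentiating the blanket height gives the compression settling velocity
in time form,

$$v_{cs} = -\frac{dx}{dt_s} = \frac{b\,x_0 X_0}{a}\,t_s^{-1-b},$$

and, eliminating $t_s$ through the thickening law, in concentration form,

$$v_{cs} = \frac{b\,x_0 X_0}{a}\left(\frac{X}{a}\right)^{-(1+b)/b}.$$

At $b = 0.0465$ the exponent $(1+b)/b$ is 22.5: compression velocity
collapses steeply as the blanket concentrates. The two forms are
algebraically identical; the tests verify the identity to $10^{-12}$ and
both against a centered-difference derivative of the height curve to
$10^{-6}$.

**Units.** Column heights are metres and thickening time minutes, so the
raw law yields m/min; Vesilind velocities are conventionally m/h. All
public velocities in `settleflux` are m/h, with the ×60 conversion applied
inside the compression functions. (The published form of the WWTP-5
compression law carries a leading coefficient of 0.477 with base 6.439;
direct evaluation of the general law with $a = 6.493$, $b = 0.0465$,
$x_0 = 1$ m, $X_0 = 6.6$ g/L gives $b x_0 X_0/a = 0.0473$ m/min with base
6.493 — the package therefore always derives coefficients from the general
law and never hard-codes that printed instance.)

**Domain.** The law describes the compression zone, so
`compression_velocity()` requires $X \ge X_0$ by default. Its "unit base"
$X = a$ can sit slightly below $X_0$ (6.493 vs 6.600 for the reference
plant); evaluating there is an explicit extrapolation via
`check_domain = FALSE`.

**Integrated model.** `integrated_settling_model()` combines a Vesilind fit
($v = v_0 e^{-nX}$, calibrated by `fit_vesilind()` from log-linear least
squares of batch-test hindered velocities on initial concentration) with
the compression law, switching at the onset concentration $X_c$. No
continuity condition is imposed at $X_c$: the branches genuinely disagree
there, compression being slower, and the model reports the jump
(`continuity_gap()`) instead of rescaling either branch to hide it.

## 4. Compression-onset detection

The onset is located on a batch settling curve by the classical graphical
construction: the intersection of the curve with the bisector of the angle
between the tangents to the hindered and compression zones, after which
$X_c = x_0 X_0 / h_c$ by mass balance.

Numerical choices, all of which were open:

- **Hindered tangent.** The hindered zone starts at the beginning of the
  record, so the window is anchored at the earliest start (within the first
  third, allowing a short lag) whose minimal 4-point window achieves
  $R^2 \ge 0.95$, grown forward while $R^2$ holds, keeping the longest
  prefix within $10^{-3}$ of the best $R^2$. Two simpler rules fail:
  maximizing $R^2$ alone always selects a minimal, noise-unstable window
  (and "finds" linear zones on purely convex curves), while maximizing
  length alone absorbs the gently sloped compression tail, which on long
  records beats the true hindered segment. The $R^2 \ge 0.95$ threshold and
  the 4-point minimum window are the acceptance criteria for a genuine
  linear zone; curves with no qualifying window raise a typed
  `no_linear_zone_error`.
- **Compression tangent.** A linear fit to the points in the final 25% of
  the record in log-time (minimum 4 points); log-time spacing reflects the
  power-law tail.
- **Normalization.** Angles are not affine-invariant, so the bisector is
  constructed in the fixed normalized coordinates $(t/t_{\max},\, h/x_0)$ —
  the aspect ratio in which such curves are conventionally plotted. The
  interior bisector direction is the sum of unit vectors pointing backward
  along the hindered tangent and forward along the compression tangent;
  symmetric slopes therefore give a vertical bisector (tested).
- **Degenerate curves.** A record whose single straight line explains
  everything ($R^2 \ge 0.999$), or whose two tangent slopes differ by less
  than 5% of the hindered slope, has no distinct compression zone and
  raises `no_onset_error`; a bisector that never crosses the interpolated
  curve raises `no_intersection_error`.

The implementation is validated two ways: recovery of constructed
transitions within ±15% over a 20-curve seeded ensemble, and agreement with
an independent oracle that finds the bisector as the equal-perpendicular-
distance locus of the two tangents on a dense grid. Whether $X_c$ should be
taken as the test's initial concentration (the convention when the test is
charged at the blanket concentration) or re-estimated per curve is left to
the caller: both paths are supported, since `integrated_settling_model()`
accepts any $X_c$.

## 5. Solids-flux analysis

The total flux through a settler cross-section is $G(X) = (v(X) + u)X$ with
underflow velocity $u$; g/L × m/h is numerically kg/(m²·h), so no unit
factor appears. `flux_curve()` evaluates both the integrated and the
hindered-only variant; `limiting_flux()` minimizes each over
$X > X_c$ (grid bracketing plus golden-section refinement) and reports the
relative overestimation of the hindered-only analysis. Because the
compression branch is far slower than the Vesilind extrapolation above
$X_c$, the integrated limiting flux is never larger — the inequality is
verified pointwise in the tests. With the steep exponent $-22.5$ the
compression contribution to flux is nearly negligible above onset, so the
integrated minimum typically sits at the $X_c$ boundary; this raises the
documented `boundary_minimum_warning` rather than being hidden.

## 6. Floc morphometry

Fractal dimensions are estimated from log–log scaling against perimeter:
$A \propto P^{D_2}$, $V \propto P^{D_3}$, $A \propto P^{2/D_B}$, each
fitted by OLS with standard errors ($D_B$ by the delta method).

- **Volume is not observable in a 2D image.** $V$ is modeled as the volume
  of the area-equivalent sphere, $V = \tfrac43\pi r_{eq}^3$,
  $r_{eq} = \sqrt{A/\pi}$. This is a documented convention, replaceable by
  supplying measurement tables with independently determined volumes.
- **$D_2$ and $D_B$ from one regression are algebraically linked**
  ($D_2 D_B = 2$). Field practice nevertheless quotes both, derived from
  differently operationalized perimeters, and reference values for a single
  sludge (e.g. $D_2 = 1.2$, $D_B = 1.6$, product ≠ 2) confirm the
  operationalizations differ. The package reports both estimators side by
  side and leaves the reconciliation to the analyst; with its single
  perimeter definition the product is exactly 2.
- **Perimeter estimator.** Marching squares with subpixel edge
  interpolation on a 3×3 box-smoothed component mask. Plain marching
  squares on the binary mask overestimates a digitized disk's perimeter by
  ~7% (the staircase-with-cut-corners bias); the smoothed, interpolated
  contour is accurate to ≤1.5% across disk radii 8–32, which the tests pin
  down. Area is the raw pixel count (bias well under 1%).
- **Segmentation defaults.** Otsu global threshold, 8-connectivity,
  border-touching components discarded (they are truncated flocs),
  `min_area = 10` px². All configurable.

`svi_fractal_trend()` regresses each dimension on SVI across plants and
reports signed slopes with $p$-values — a descriptive summary (compact,
low-porosity flocs at low SVI), not a causal model.

## 7. Synthetic data: what it emulates, and what a green test establishes

The generators produce data with exactly the statistical structure the
models assume: power-law thickening curves with multiplicative lognormal
noise (positivity-preserving, log-spaced sampling mirroring the power law's
information content), two-phase settling curves (hindered line joined
*continuously* to the mass-balance tail, additive Gaussian height noise),
log-linear SVI panels, and flocs with Fourier-perturbed radial boundaries
(`roughness` = relative sd of the boundary perturbation, harmonic
amplitudes ∝ 1/k). Defaults mirror the reference setting: 1 m columns,
90-minute tests, $X_0 = 6.6$ g/L, $b$ centred on 0.0465 with spread 0.004
(the spread of the calibration panel), 1% concentration noise, 2 mm height
noise.

Ground truth always accompanies generated data, so every fitting operation
is tested closed-loop. Each generator is bit-reproducible under a fixed
seed and restores the caller's RNG state.

Limits of this evidence: a green recovery test establishes that the
estimators invert the assumed data-generating process at realistic noise —
not that real sludge follows a power law, that real settling curves have
additive Gaussian noise, or that real flocs are Fourier-perturbed disks.
Real thickening curves can show lag phases and denitrification-driven
rising sludge that the generators deliberately omit. The floc-roughness
study in particular probes the $D_B$ estimator's monotone response to
boundary irregularity via errors-in-variables attenuation of the area–
perimeter regression; synthetic blobs are not scale-invariant fractals, so
absolute $D_B$ values from the generator are close to 1 and only their
ordering is meaningful.

## 8. Known limitations

- No dynamic settler hydraulics, layered 1D transport solver, or
  Takács-style double-exponential velocity; the models are steady-state
  descriptions driven by $t_s$ and SVI.
- The SVI link is purely empirical; extrapolation outside the calibration
  envelope warns but cannot be validated from within the package.
- The $p$-value of a 2-parameter fit on 3 points has one degree of freedom
  and should not be taken seriously (it is flagged in the documentation).
- Raster I/O is plain-text PGM; PNG/TIFF must be converted externally.
- The published reference values for floc fractal dimensions are used only
  as plausibility context; the raw images behind them are unavailable, so
  the package makes no attempt to reproduce them numerically.
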