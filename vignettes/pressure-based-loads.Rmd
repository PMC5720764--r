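---
title: "Pressure-based estimation of locomotor loads: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pressure-based estimation of locomotor loads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pivload)
```

## The model and its assumptions

The load exerted by a fluid on an immersed body is the surface integral
of pressure and viscous stresses. At the chord Reynolds numbers of
fish-like swimming (order $10^4$–$10^6$) the viscous surface terms are
small, and the package estimates loads from pressure alone:

$$\mathbf F(t) = -\oint p\,\mathbf n\,\mathrm dA, \qquad
  T_z(t) = -\oint p\,[(\mathbf r - \mathbf r_0)\times\mathbf n]_z\,\mathrm dA,$$

discretized on a closed 200-point loop with the local span supplying the
third dimension of $\mathrm dA$. Two assumptions are load-bearing:

1. **Pressure dominance.** Shear is omitted from the load integral (the
   integrator returns an explicit all-zero `shear` component so reports
   can state "pressure-only"). For statically held bodies or very slow
   motion this approximation fails by design — drag on a static plate is
   almost purely viscous and the method will not see it.
2. **Planar flow.** Velocity is measured in one horizontal plane. The
   out-of-plane fraction $V_z^* = |V_z|/\sqrt{V_x^2+V_y^2+V_z^2}$ is the
   diagnostic: values approaching a few tens of percent (near spanwise
   edges and tip vortices) mark regions where the 2D reconstruction is
   no longer trustworthy.

Viscosity is *retained* in the pressure-gradient evaluation
($\nabla p = -\rho(\partial_t\mathbf u + (\mathbf u\cdot\nabla)\mathbf u)
+ \rho\nu\nabla^2\mathbf u$); omitting shear from the load integral is a
separate approximation from the flow physics used to obtain $p$. A
`viscous` toggle exists for ablation only.

## Pressure reconstruction

Pressure is obtained by integrating the pressure gradient along straight
rays and median-polling the per-ray estimates — not by solving a
pressure-Poisson problem.

**Ray families.** Eight families by default: the four grid axes and the
four diagonals (a 4-family axes-only mode exists). The published
description of the underlying algorithm names neither the count nor the
routing; eight evenly rotated families are this package's choice, giving
every node estimates from genuinely different sweep directions so the
median is meaningful.

**A shared gauge for all rays.** Each ray is seeded at its domain-edge
starting node. If every ray started at an arbitrary zero, the families
would disagree by the (unknown) edge-pressure differences and the median
would mix incompatible gauges. The package therefore first integrates
the tangential gradient around the outer ring of the domain (both
orientations, averaged, with the closure drift distributed linearly) and
seeds every ray with its edge node's ring value. After polling, the
gauge is fixed so the *median* pressure on the outermost valid ring is
zero — a far-field gauge appropriate for a flume cross-section. Only
pressure differences are physical; the gauge choice cancels in the load
integrals over closed loops.

**Median polling.** Node value = median of the available per-family
estimates; for an even count, the mean of the two central values (R's
`median`). A single corrupted family of eight moves the result by far
less than the corruption (tested: 5-sigma noise on one family changes a
solid-body pressure field by < 5% of its range).

**Masks are opaque.** Rays terminate at masked or invalid nodes; nothing
is bridged — a ray blocked by the body contributes no estimates on the
far side (`cumsum` NA-propagation implements this exactly). Nodes inside
the mask are undefined in the output.

**Stencils near masks.** First derivatives fall back to one-sided
differences next to the mask or the domain edge, so pressure stays
defined right up to the control surface (which sits only ~1.6
boundary-layer thicknesses from the midline). Where no one-sided
second-difference stencil fits, the (small) viscous term is dropped at
that node rather than invalidating it.

**Calculation interval.** `pressure_sequence()` subsamples the velocity
sequence to `dt_calc` (default 0.01 s) before differencing in time —
the interval at which load traces keep their trends while computation
stays cheap; finer intervals mostly admit high-frequency noise that a
low-pass filter removes again. Temporal differences are central where
both neighbours exist and one-sided at sequence ends.

**Verification.** Solid-body rotation (all derivatives linear) is
recovered to machine precision; a decaying Taylor–Green vortex — which
exercises the unsteady, convective and viscous terms together — is
recovered to ~0.03% of the pressure range on a 128×128 grid, and the
error decreases monotonically under grid refinement. The Taylor–Green
pressure expression itself is verified in the tests by brute-force
substitution of the closed forms into the momentum equations (residual
< $10^{-6}$ of the convective scale).

## Body geometry

`delta99(x, Re) = 5x/√Re` is the flat-plate 99% boundary-layer
(shear-layer) thickness at chord length `x`. The mask loop sits at
`1.1 δ99` from the midline (enough to swallow body-contaminated velocity
vectors) and the force-calculation loop at `1.64 δ99` (far enough that
pressure is defined everywhere on it, close enough that no additional
fluid terms are needed). `surface_sweep()` reproduces the
placement-sensitivity construction (1.5–4.0 δ99, nested loops).

**Two offset pathways.** The reference procedure is image-based:
rasterize the midline, binary-dilate by the halfwidth, trace the
boundary. The package's default is exact geometric buffering (side
offsets plus semicircular end caps), which is resolution-independent;
the raster pathway is kept as a cross-check and the two agree in area to
within one raster-cell band around the perimeter. Loops are resampled to
200 equally spaced points, smoothed with a 5-point circular moving
average (x and y separately, wrap-around at the seam), and — a package
choice — resampled once more, because the moving average contracts
segments near the high-curvature caps and would otherwise break the
equal-spacing property. Normals are recomputed from the smoothed loop
(perpendicular of the central-difference tangent, oriented away from the
nearest midline point) rather than smoothed themselves.

**Segment lengths.** `dl_i` is the centered chord
$|\mathbf p_{i+1}-\mathbf p_{i-1}|/2$, not the forward distance to the
next point. Paired with the central-difference normal, the loop sum
$\sum_i p_i \mathbf n_i\,dl_i$ equals the exact polygon surface integral
for linear pressure fields (summation by parts); the forward distance
would overweight the end caps of a stadium-shaped loop by about 1% at
200 points. This choice is what makes the loop-integral and
divergence-theorem routes agree to well under 1% and keeps load changes
under 0.5% when the point count doubles.

**Spans.** Each surface point is projected to its nearest midline arc
position and the span profile is evaluated there; a scalar span covers
rectangular bodies, a function of arc position covers tail-like
planforms.

**Pixels.** `detect_midline()` (intensity-weighted column centroids)
returns pixel coordinates; all physical routines require meters, and the
caller supplies the pixel scale explicitly. No camera-specific
pixel-to-δ99 equivalence is hardcoded.

## Synthetic world

The generators state the validation world; their defaults are the
experimental conditions of the flapping-foil apparatus the method was
characterized with: chord 0.18 m, heave amplitude 15 mm, frequency
1.5 Hz, flow speed 0.3 m/s, Re = 54 000, fresh water
(ρ = 1000 kg m⁻³). Two motion programs exist: pure sinusoidal heave
(pitch identically zero) and the 0° angle-of-attack program, where pitch
continuously aligns the leading edge with the instantaneous relative
flow, $\theta(t) = -\arctan(\dot y_{LE}/U)$. The exact pitch law of the
original apparatus controller is not published; leading-edge alignment
is this package's reading, flagged as such. Positive pitch is
counter-clockwise viewed from +z.

`make_plate_scene()` is the end-to-end fixture: a rigid plate moving
under a program, a *prescribed* analytic pressure law around it, and the
loads that pressure must produce, computed by an independent
divergence-theorem route from the shoelace area and centroid of the
control-surface polygon. Its velocity field is uniform plumbing — it is
deliberately *not* dynamically consistent with the prescribed pressure,
because the fixture isolates the geometry/sampling/integration chain
from the solver (which has its own closed-form oracles). Consequently a
green end-to-end test establishes that the chain reproduces known loads
from known pressure around a moving body; it does not establish anything
about vortex shedding, flow separation, or emergent foil bending, none
of which are simulated. Midline bending is available only as a
prescribed quadratic curvature envelope (default off, i.e. rigid).
Gaussian velocity noise is an option for robustness studies and demands
an explicit seed — there is no silent default randomness.

Under the linear-in-x law the analytic streamwise force of a rigid plate
is constant in time (uniform gradient, constant enclosed area), so
correlation against it is undefined; end-to-end comparisons use the
torque trace, which varies because the chord centroid rotates about the
leading edge, and hold constant components to an RMS-error bound
instead.

## Measured-trace processing and metrics

- **Sensor-axis resolution**: rotation through the pitch angle; also
  used with a constant angle to undo a deliberate static sensor
  misalignment.
- **Rod subtraction**: the sensor sees rod+body; the rod-only series is
  linearly interpolated onto the assembly timestamps and subtracted.
  Filtering is applied before subtraction by default (the processing
  order alongside which subtraction was described); both orders are
  available since the original order is not fully specified.
- **Filtering**: second-order Butterworth, applied forward and backward
  so phase shifts cancel. Cascading lowers the −3 dB point, so each pass
  is designed at $f_c/(2^{1/p}-1)^{1/2n}$; for the default (order 2, two
  passes) a desired 7 Hz cutoff becomes 8.73 Hz per pass. No DSP package
  ships in the target environment, so the design (analog Butterworth
  poles, bilinear transform, second-order sections) and the zero-phase
  filter (odd-reflection padding, steady-state initial conditions so a
  constant passes unchanged) are implemented here and tested against the
  cascade's analytic transfer function.
- **Correlation**: Pearson r with the Fisher 95% interval,
  $\tanh(\operatorname{atanh} r \pm 1.96/\sqrt{n-3})$. At r = 0.9,
  n = 200 the exact interval is (0.86988, 0.92343); a commonly printed
  4-d.p. lower bound of 0.8694 is 5×10⁻⁴ off the exact back-transform.
- **RMSE%**: RMS error normalized by the *reference* trace's range —
  beware that for near-zero-amplitude components (streamwise force in
  pure heave) this metric explodes without the estimate being useless.
- **Phase lag**: cross-correlation within ± one period, reported as % of
  the cycle; positive = estimate lags measurement (the sign convention
  is echoed in every report since it is not standardized). The estimator
  uses the Pearson correlation of the overlapping windows rather than
  the raw product sum: an exact-match lag then scores exactly 1
  independent of overlap length, so window-composition effects cannot
  favour a wrong lag; among numerically tied maxima (a delay of τ on
  periodic data is indistinguishable from an advance of period − τ) the
  smallest |lag| is reported.
- **Phase averaging** folds replicate cycles into a pointwise mean and
  sample standard deviation. Comparisons default to filtered,
  concatenated replicates (not phase-averaged), with the raw route
  available.

## Numerical choices and degenerate inputs

- Medians of even counts: mean of the two central values.
- Grids must be complete regular rectangles; files declare units, and a
  missing unit header is an error, not a guess.
- `dt_calc` must be an integer multiple of the acquisition step; the
  error names both values.
- Empty fields (all nodes masked), constant series handed to
  correlation/RMSE%, flat series handed to the lag estimator, zero total
  velocity in $V_z^*$: all hard errors, never NaN propagation.
- Sampling on the control surface is bilinear with renormalized weights
  over defined nodes; if all four corners are undefined the nearest
  defined node within two cells is used and *counted* — the fallback
  count is logged as a data-quality signal (properly sized masks keep it
  at zero). Beyond two cells, an error names the offending point.
- Output numerics are written in scientific notation with 9 significant
  digits; identical configuration and seed give byte-identical outputs,
  and every file carries the package version and a hash of the
  scientific configuration (output paths excluded).

## Known limitations

- No DPIV: the package consumes exported velocity fields.
- No 3D reconstruction; the span profile is a geometric bookkeeping
  device, not a flow model.
- No added-mass decomposition and no viscous load term.
- The ray-family geometry is an implementation of the described
  behaviour of the published algorithm, not a bit-level clone of its
  distributed executable; absolute agreement with that executable on
  shared inputs has not been established.
- The synthetic plate scenes cannot stand in for real separated,
  three-dimensional flapping-foil flow; quantitative claims about such
  flows require measured velocity data.
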