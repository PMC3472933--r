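---
title: "TG-43 dosimetry of the GZP6 cobalt-60 unit: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TG-43 dosimetry of the GZP6 cobalt-60 unit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gzp6dose)
```

## The problem

High-dose-rate brachytherapy delivers dose from a small sealed
radioactive source placed in or near the target volume.  The GZP6
afterloading unit is unusual in carrying six distinct ⁶⁰Co source
braids, one per channel: ordered packings of active cobalt pellets and
inert steel spacers in a steel spring cover, differing in how many
active pellets they hold and where.  The single-pellet braid (source
No. 3) is the natural characterization anchor.  Once its dose
distribution and TG-43 parameters are known, the distribution of any
other braid follows by superimposition: shift the single-pellet dose
matrix to each active pellet position, weight by that pellet's activity
relative to the reference source, and sum.

The package implements both layers — the TG-43U1 formalism for the
single source, and the matrix-shift superimposition for the braids —
together with an analytic "synthetic kernel" that stands in for Monte
Carlo dose data in every test.

## The dose model

The dose rate at P(r, θ), with r in cm from the source center and θ in
degrees from the source long axis, is

$$\dot D(r,\theta) = S_K \,\Lambda\,
  \frac{G_L(r,\theta)}{G_L(r_0,\theta_0)}\, g_L(r)\, F(r,\theta),
  \qquad (r_0, \theta_0) = (1\ \mathrm{cm}, 90^\circ).$$

`reconstruct_dose_rate()` evaluates this product from a
`tg43_parameter_set()`.  At the reference point every factor except
$S_K \Lambda$ is identically 1, and the implementation preserves that
identity exactly (no interpolation noise at the anchor).

### Geometry function

The line-source geometry function is

$$G_L(r,\theta) = \frac{\beta}{L\,r\sin\theta}
 \quad (\theta \ne 0),\qquad
 G_L(r,0) = \left(r^2 - L^2/4\right)^{-1},$$

where $\beta$ is the angle subtended by the active length $L$ at P,
computed in arctangent form.  Numerical choices:

* **On-axis branch.** The arctangent form is singular at
  $\sin\theta = 0$; angles within $10^{-6}$ degrees of the axis use the
  closed on-axis form.  A continuity test bounds the relative jump
  across the switch below $10^{-4}$ for all radii in 0.25–20 cm.
* **Mirror symmetry.** Angles above 90° are mapped to $180^\circ -
  \theta$ before evaluation, so $G(r,\theta) = G(r,180^\circ-\theta)$
  holds bit-exactly, matching the symmetry of the tabulated data.
* **Active length.** $L$ defaults to 0.19 cm: the 2 mm pellet length
  includes 0.05 mm of nickel plating at each end, and only the bare
  core is radioactive.  This is the only value under which the
  normalized function $G_L\cdot r^2$ reproduces the packaged reference
  table at all 110 cells to three decimals, which the acceptance suite
  verifies.
* The tests also check $G$ against direct numerical integration of the
  defining line integral, independently of the closed-form branches.

`geometry_function_normalized()` returns $G_L \cdot r^2$ — the
tabulated, dimensionless convention (relative to an ideal point source
at the same distance); note it is *not* normalized to the reference
point, whose entry is 0.997, not 1.

### Radial dose function and anisotropy function

`radial_dose_function()` and `anisotropy_function()` implement

$$g_L(r) = \frac{\dot D(r,\theta_0)}{\dot D(r_0,\theta_0)}
           \frac{G_L(r_0,\theta_0)}{G_L(r,\theta_0)},\qquad
  F(r,\theta) = \frac{\dot D(r,\theta)}{\dot D(r,\theta_0)}
           \frac{G_L(r,\theta_0)}{G_L(r,\theta)}.$$

Both set their defining normalization ($g(r_0) = 1$, $F(r,\theta_0)=1$)
exactly rather than leaving it to floating-point cancellation.  Missing
(r, θ) combinations are carried as `NA` and excluded from
interpolation; the packaged anisotropy table genuinely has such holes
(nine angles at r = 1 cm, one at r = 2 cm), and its small asymmetries
about 90° — Monte Carlo noise in the original data — are preserved
verbatim, not symmetrized.

### Interpolation and extrapolation policy

Reconstruction interpolates $g$ linearly in $r$.  $F$ is interpolated
along each tabulated radius column linearly in θ over the *available*
angles (holes skipped, ends clamped), then linearly between the two
bracketing radius columns.  Below the smallest tabulated radius the
nearest node/column is used with a warning — near-source TG-43 tables
are always sparse, and inventing a trend there would be worse.  Above
the largest radius, `mode = "strict"` (default) raises an error and
`mode = "lenient"` clamps with a warning.

### Quintic radial fit

`fit_radial_polynomial()` is unweighted ordinary least squares of $g$
on powers of $r$ (degree 5 by default), with
$R^2 = 1 - SS_{res}/SS_{tot}$ on the fitted nodes.  On the packaged
18-point table it yields $R^2 = 0.99894$ and intercept $a_0 = 1.00865$.
Published coefficient lists for such fits are typically printed heavily
rounded (e.g. $a_1 = -0.01$), so the tests enforce agreement only on
the intercept (±0.015) and require the OLS $R^2$ to be at least that of
the printed coefficient set — least squares cannot do worse than any
hand-supplied quintic on the same nodes.

## Dose grids and contours

`dose_grid` objects hold a (z × y) matrix of dose rate (cGy/h/U) or
dose (Gy) on strictly increasing axes, with a per-cell missing mask.
The CSV dialect (`# gzp6dose-grid v1 unit=...` header, `z_cm\y_cm`
column header) serializes at full double precision, so
read-after-write is bit-exact; `-` and empty cells both load as masked,
which lets the published 2D dose table load unmodified (its on-axis
cells near the source, 18 of them, were never tabulated).  Files may
store z descending, as dose tables are usually printed; the loader
normalizes to ascending.  Cylindrical symmetry is assumed throughout:
only y ≥ 0 is stored and negative y mirrors onto |y|.

Polar resampling (`grid_to_polar_samples()`) uses bilinear
interpolation with two guarantees: points coinciding with an unmasked
grid node (within $10^{-9}$ cm, absorbing trigonometric round-off in
the polar mapping) return that node's value exactly, and masked cells
are never used as stencil nodes — a masked corner triggers a
nearest-unmasked fallback with a warning.

Isodose contours (`extract_isodose_contours()`) are marching-squares
level sets with linear edge interpolation, delegated to
`grDevices::contourLines()`; masked cells break contours rather than
being guessed through.  Contour vertices satisfy
$|{\rm interp}(v) - {\rm level}| \le 10^{-6}\cdot$level against an
independent bilinear evaluation, and on an analytic inverse-square
field the contour radii match $\sqrt{A/\mathrm{level}}$ within one cell
diagonal.  The default level list {1, 2, 5, 10, 15, 20} Gy matches
standard display practice for these sources.

## Superimposition

`superimpose()` implements the four-step matrix-shift algorithm:
translate the single-pellet kernel along z to each active pellet offset
(`shift_grid()`), scale by the pellet's relative activity, sum, and
(optionally) contour.  Design choices:

* **Alignment.** With the natural GZP6 spacing of 0.65 cm and a 0.05 cm
  grid, shifts are exact 13-cell row copies, and the summed matrix
  equals brute-force per-pellet evaluation of the analytic kernel to
  $10^{-12}$ relative at every unmasked cell — the grid-level
  restatement of the claim that superimposed and directly simulated
  distributions coincide.  Fractional shifts are supported via linear
  interpolation along z (monotonicity-preserving); their error obeys
  the standard second-difference bound $h^2 f''/8$, which the tests
  check against the analytic kernel.
* **Mask propagation.** A cell masked in *any* contributing shifted
  matrix is masked in the sum (conservative: a partial sum would
  silently under-report dose near the axis).  Vacated rows at the grid
  ends are likewise masked.
* **Weights** are relative to the kernel source's activity;
  no absolute-activity bookkeeping is attempted.  The braid geometry is
  configuration-driven (JSON/YAML): the exact pellet arrangements and
  activities of the multi-pellet clinical braids are not public, so the
  shipped multi-pellet configurations are labelled examples, not
  certified clinical geometries.  Generated layouts center the active
  centroid at z = 0, the convention of the reference dose matrix.
* Absolute dose levels (Gy) imply an irradiation time and source
  activity that are the caller's business; the superimposed grid stays
  in the kernel's unit.

## The synthetic kernel

`kernel_spec()` defines a single-pellet kernel with *exact* TG-43
multiplicative structure ($S_K = 1$ U):

$$D(r,\theta) = \Lambda \frac{G_L(r,\theta)}{G_L(r_0,\theta_0)}
  \exp\!\left(c_1(r-1) + c_2(r-1)^2\right)
  \left[1 - a(r)\cos^2\theta\,(1 + b\cos^2\theta)\right],$$

optionally times multiplicative Gaussian noise $(1 + \sigma N(0,1))$,
truncated at $-0.9$ to preserve positivity — the form in which Monte
Carlo tally uncertainties are reported.  One integer seed governs a
whole generation; equal seeds give identical grids.

The `"gzp6-no3"` preset mimics the real source: Λ = 1.104 cGy/h/U,
L = 0.19 cm, $c_1, c_2$ fitted once to the packaged radial table
(−0.01239, −0.00103; recorded in `inst/extdata/preset_gzp6_no3.json`),
$a(r)$ taken as $1 - F(r, 0^\circ)$ from the packaged anisotropy
table's polar column, and $b = 0$ (the sharpening term is available but
the recovery experiments do not need it).  The default noise level for
stochastic experiments, σ = 0.005, corresponds to the ~0.5% tally
error typical of the radial-dose-function simulations this surrogate
stands in for.

Because the structure is exactly multiplicative, extraction inverts
generation to machine precision at σ = 0 — `recovery_experiment()`
demonstrates max relative errors below $10^{-10}$ — and with noise the
rms recovery error of n-averaged datasets falls as $n^{-1/2}$ (the
validation fits a log–log slope over n ∈ {1, 2, 5, 10, 25, 50} from 200
seeds, pooling Λ, g and F node errors, and requires −0.5 ± 0.1).

**What the surrogate does not emulate:** photon transport, dose
build-up, scatter, capsule and spacer attenuation, the dose-vs-kerma
distinction near the source, or inter-pellet shielding in multi-pellet
braids.  Passing tests therefore demonstrate that the *extraction,
reconstruction and superimposition machinery* is exact and stable —
not that any physical source obeys the parametric forms.  Real
characterization data enter only through the packaged reference
tables.

## Validation problem sizes

The shipped test suite uses grids of 0.05 cm resolution spanning ±4 cm
axially and 0.25–4 cm transversally (161 × 76 cells) for
superimposition checks, a 121 × 241 cell inverse-square field for
contour checks, and 200 noise replicates for the stochastic recovery
experiment; the whole suite runs in a few seconds.  The packaged 2D
reference grid is a 29 × 15 excerpt of the original 0.05 cm mesh and is
treated as point samples.

## Known limitations and data caveats

* The packaged 2D dose grid's reference-point cell (0.98796 cGy/h/U at
  y = 1, z = 0) is about 10% below Λ = 1.104; the two reference tables
  are not mutually consistent, and the package documents rather than
  reconciles this (no cross-table consistency is enforced).
* A published air-kerma-strength figure for this source carries
  internally inconsistent units; the package treats $S_K$ as a
  user-supplied scalar in U everywhere and never uses that number.
* Pellets are axial point anchors: no 3D pellet shape, no 1D anisotropy
  factor $\varphi_{an}(r)$ (not part of this characterization), no
  dwell-time optimization for the stepping source (a stepping treatment
  is representable as a braid of time-weighted offsets, but planning is
  out of scope), and no DICOM-RT export.
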