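---
title: "Models and methods behind thermoseedr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermoseedr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thermoseedr)
```

`thermoseedr` simulates the calorimetric characterization of magnetic
scaffold (MagS) thermoseeds: a homogeneous ferromagnetic cylinder embedded
in an agar tissue-mimicking phantom, centred in a single-layer induction
coil, heated by an alternating magnetic field and monitored by fiber-optic
probes.  This vignette records the models, the tunable parameters, the
numerical choices and the limitations — in particular which features of a
real bench experiment the simulator does and does not emulate.

## The physical scene

The reference geometry (`default_scene()`) is a 20 mm × 20 mm cylinder of
iron-loaded PLA composite ("PP", 40 wt% iron microparticles) inside a
25 mm × 40 mm agar cylinder.  Material properties are stored in SI but
entered in the units materials tables usually print:

| material | ε_r | σ (S/m) | k (W/m/K) | C_p (J/g/K) | ρ (g/cm³) |
|----------|-----|---------|-----------|-------------|-----------|
| agar     | 70  | 0.2     | 0.48      | 4.2         | 1.0       |
| PP       | 3   | 1e-5    | 0.47      | 1.2         | 2.7       |
| PLA      | 2.5 | 1e-6    | 0.29      | 1.8         | 0.9       |
| water    | 78  | 5.5e-6  | 0.60      | 4.18        | 1.0       |

Water is a handbook addition for the in-water exposure mode.  The PP
density of 2.7 g/cm³ is unusually high for a filled polymer but is taken
as tabulated for this composite.

The coil is described only loosely by vendors of 8-turn induction heads,
so its bore and height are package defaults, all configurable:
`inner_radius` 25 mm, 8 turns evenly spaced over 48 mm (pitch 48/7 mm),
conductor radius 2 mm.  The coordinate origin sits at the coil's
geometric centre with `z` along the axis; the sample is "centred" when
its centroid coincides with this origin.  In placement sweeps the
scaffold and phantom move **rigidly together** — the phantom holds the
embedded scaffold — so containment never breaks.

## Coil field

The excitation field is computed as free-space Biot–Savart superposition
of filamentary circular loops, using the exact complete-elliptic-integral
closed form per loop (`loop_field()`, via `pracma::ellipke`).  This
replaces a finite-element solution of the full time-harmonic problem and
is justified in the dilute-loading regime: the scaffold's magnetic
nonlinearity enters the *loss* model only, not the field solution, so
field distortion by the permeable sample is neglected.  That choice makes
every field value verifiable against direct quadrature of the
Biot–Savart integrand (the test suite checks 1e-8 relative agreement) at
the cost of underestimating placement sensitivity in the transverse
plane: near the axis of any solenoid the free-space |B| varies only as
O((r/R)²), about 0.3 % over ±3 mm for the default coil, whereas a
permeable off-centre sample would add its own asymmetric perturbation.
The radial-misplacement temperature spread computed by
`scripts/acceptance.R` should be read with that structural caveat.

Conventions: all field amplitudes are **peak**, never RMS.  The drive
current is set by `calibrate_current()` so that |B| at the coil centre
equals the rated 30 mT; by linearity this is a single division.  Field
homogeneity `xi = mean(|H|) / sd(|H|)` over the sample voxels uses the
sample (n−1) standard deviation, and |H| magnitude rather than a single
component; a perfectly uniform field reports `xi = Inf` with a flag.

The induced azimuthal electric field follows Faraday's law for an
axisymmetric excitation, `|E_φ| = ω |Φ(r, z)| / (2πr)` with `Φ` the flux
of `B_z` through the coaxial disc of radius `r`, evaluated by trapezoidal
quadrature along radial rays; `E_φ → 0` on the axis.

## Magnetic loss

Hysteresis heating is `P_m = f · A_hyst` with `A_hyst` the per-cycle BH
loop area (J/m³).  Measured loops can be supplied as two-branch CSV
tables; the synthetic stand-in (`synth_bh_loop()`) uses sigmoid branches
`B = Bs · tanh((H ± Hc)/w)` closed at ±H_max, which reproduce the shape
of a soft ferromagnetic composite's magnetization curve.

To spatialize the loss over an inhomogeneous field, each voxel's drive
amplitude selects an **amplitude-truncated minor loop**: the loop
restricted to ±|H_local| and closed vertically at the truncation points,
whose area is `∫(B_desc − B_asc) dH` over that interval.  The map from
amplitude to area is continuous, monotone non-decreasing (implemented
through the cumulative antiderivative, so monotone by construction),
vanishes at zero amplitude and reduces to the full loop area at H_max —
hence exactly to `f · A_hyst` under a uniform field.  This rule is a
package design choice; bench practice rarely states how minor loops are
handled.  Superparamagnetic seeds, whose loss law differs, are out of
scope for the shipped loop model.

**Calibration of the default loop.**  No tabulated loop for the reference
composite is available, so the default (`default_bh_loop()`) is a
constructed fixture calibrated once, by a fixed principle: Bs = 0.095 T
(40 wt% iron at ~70 A·m²/kg in a 2.7 g/cm³ matrix), w = 120 kA/m (the
30 mT drive sits far below saturation, as loops measured to ±1 T imply),
H_max = 800 kA/m, and the coercivity solved (`uniroot`, ≈ 26 A/m) so
that the **adiabatic initial-slope SAR at the rated exposure equals
1.0 W/g** with the agar C_p in the estimator — the order of magnitude of
measured scaffolds of this class.  The calibration anchors the scale of
every simulated temperature; it is a fixture choice, never a result.

The dielectric/eddy channel is `P_e = σ|E|²/2` per voxel with the
region's conductivity.  For the default scene it deposits roughly 3 % of
the total power (the test suite asserts `P_m > 10 · P_e`), yet it is kept
because it heats the *phantom*, where the out-of-scaffold probe sits.

## Heat transport

`solve_transient()` integrates
`ρC_p ∂T/∂t = ∇·(k∇T) + P_e + P_m` by a finite-volume scheme on an
isotropic voxel grid (harmonic-mean interface conductivities), with:

* backward-Euler stepping at fixed Δt = 0.1 s — unconditionally stable,
  so accuracy, not stability, sets the step; an explicit CFL-limited mode
  exists purely as a cross-check and the suite verifies the two agree;
* sources active for `t < t_off` and zero after;
* a Robin boundary `-k ∂T/∂n = h_a (T − T_a)` on exterior faces, with
  half-cell conduction in series; ambient air is never meshed.
  `h_a = 10 W/m²/K` (free convection) by default — the coefficient is
  cited but not printed in the source literature, so it is a configurable
  default here;
* uniform initial condition at `T_a = 19 °C`.

With `h_a = 0` the scheme conserves enthalpy to machine precision
(column sums of the conduction operator vanish), and a uniform source in
an insulated body reproduces the exact adiabatic ramp — both are tested.

**Surface observable.**  The in-air setup is monitored by an IR camera,
which sees the *surface*.  `surface_average()` therefore reports the mean
**boundary-face temperature**, each face temperature recovered from the
discrete flux balance (conductance-weighted interface value between
regions; the Robin balance against ambient on exterior faces).  A naive
mean over boundary *voxels* was rejected: at 2 mm resolution two-thirds
of the scaffold's voxels touch its boundary and the "surface" reading
collapses onto the volume average, whereas the face-temperature mean is
grid-converged (it changes by under 2 % between 2 mm and 1 mm for the
in-air contrast).  In-air runs default to 1 mm voxels because the
surface–volume contrast is a boundary-layer quantity.

**In-water mode.**  The convective term is not resolved as fluid flow;
water voxels get an effective conductivity `k_eff = k_w · Nu` with
`Nu = max(1, C · Ra^1/4)`, the Rayleigh number built on the radial
water-gap width and the instantaneous scaffold–water temperature
difference, re-evaluated every 2 s of simulated time.  `C = 0.18`, the
classic enclosure-correlation coefficient, was selected as the
calibration of this surrogate — it lands the conduction-vs-convection
peak contrast near the few-degree scale reported for such setups.  This
is the softest model in the package: a one-parameter stand-in for
buoyant flow, adequate for effect-size studies, not for quantitative
convection prediction.  Forcing the enhancement factor to 1 reproduces
the conduction-only solution exactly, which is how the effect is
isolated.

## Thermometry and SAR estimation

Virtual probes (default layout: C at the scaffold centre, L/R at ±7 mm
on x, T at +9 mm on z, all inside the scaffold; O at +20 mm, in the
phantom above the scaffold) are sampled at 1 Hz by trilinear
interpolation with seeded Gaussian noise (SD 0.1 °C — typical fiber-optic
thermometry).  Probe coordinates are package defaults: bench protocols
drill symmetric holes but rarely dimension them.  O sits axially because
the 2.5 mm radial agar annulus of the reference phantom cannot host a
probe ~1 cm away radially.

`initial_slope()` is the OLS slope over a window from field-on; the
window is not standardized in practice, so the default is 30 s and
`sar_average()` re-evaluates the mean SAR over {10, 30, 60} s windows
into the result object.  On a saturating curve the OLS window slope is
biased low by ≈ `window/(2τ)` relative to the true tangent slope; the
test suite quantifies this against the synthetic generator.
`corrected_slope()` removes that bias by fitting the Box–Lucas model
`T = T₀ + ΔT_max(1 − e^{−t/τ})` to the heating branch (via
`minpack.lm`), returning `ΔT_max/τ`; the cooling branch is fitted with
its own exponential and the ratio of time constants is reported as a
consistency diagnostic — it is deliberately *not* folded into the
heating fit, so the heating estimate never depends on the cooling model.

`subtract_background()` removes common-mode drift (coil self-heating,
room drift) using a non-magnetic control record, restoring the control's
initial baseline so that a flat control is a no-op and self-subtraction
yields a flat trace.

The multi-probe averaging reports mean ± sample SD over the selected probes
(default C, R, L, T — the probes inside the scaffold); the spread
convention (n−1) is stated because reported "±" values in this field
rarely define it.

## Synthetic-data generator

`generate_temperature_log()` draws saturating-exponential heating and
exponential cooling per probe from known slopes (default pack: four
inside-probe slopes whose averaged SAR lands near 1.2 ± 0.2 W/g with
C_p = 4.2, plus a lower out-probe — constructed, never measured data),
with τ = 250 s, 1 Hz sampling and 0.1 °C noise.  Cooling may use its own
time constant (real calorimetry is asymmetric); the default is equal.
Every generator is a pure function of (spec, seed).

What the generator does **not** emulate: probe thermal lag, radiative
losses, scaffold porosity and anisotropy, drift nonlinearity, or the
diffusion-induced curvature differences between probe sites that a full
transient solution produces (those come from the PDE pipeline instead).
Estimator tests passing on generated logs therefore validate the
*estimators* under their stated noise model, not the realism of any
bench record.

## Placement studies

`axial_sweep()` (default offsets 0, 1, 2 cm) and `radial_sweep()`
(default ±3 mm grid, 1 mm step) rerun the whole pipeline per placement
and tabulate xi, peak volume-average temperature, centre-probe SAR, and
reference-relative differences.  "Relative SAR variation" is always the
signed percentage `(SAR(offset) − SAR(0)) / SAR(0) × 100`; the report
header restates this.  The radial sweep exploits the exact symmetry
group of the problem (coil axisymmetry plus the grid reflections
`x → −x`, `y → −y`, `x ↔ y`): only one representative per orbit is
simulated — 10 runs for the 7×7 grid — and the metrics are mirrored,
flagged in the `mirrored` column.  A boundary-membership tolerance in
the voxelizer keeps labeling exactly translation-equivariant, so
mirrored and directly simulated placements agree to solver precision.

## Numerical choices and problem sizes

* Thermal grid 2 mm for reference runs and sweeps (≈ 2 400 active
  voxels), 1 mm for the in-air surface observable and refinement checks;
  the peak volume-average temperature moves by < 3 % between 2 mm and
  1 mm.
* Δt = 0.1 s; 620 s simulated for a 600 s exposure (the volume average
  peaks at switch-off, and 20 s of cooling confirms it).
* Total deposited power is grid-independent to 0.3 % between 1 mm and
  0.5 mm voxelizations.
* Degenerate inputs: uniform fields flag `xi = Inf` rather than erroring;
  drive amplitudes above a loop's H_max are clamped with a warning;
  `r = 0` takes the analytic `E_φ = 0` limit; voxel centres exactly on a
  region boundary are classified with a 1e-9 relative tolerance so that
  classification is stable under rigid shifts.

## Known limitations

* Free-space field: no scaffold-induced field distortion, no coil
  proximity/skin effects, no supply impedance — transverse placement
  sensitivity is a lower bound (see above).
* Robin-only boundary, no radiation: a body heated >100 °C in air loses
  a comparable flux radiatively; with pure `h_a = 10` convection the
  600 s in-air transient remains well short of its internal quasi-steady
  profile, so the simulated surface–volume contrast is conservative.
* Homogeneous cylinder: real scaffolds are porous lattices; architecture
  effects on heat transfer are out of scope.
* No temperature-dependent material properties, no perfusion term.
* The water surrogate replaces buoyant flow by a scalar conductivity
  enhancement; cooling-branch dynamics in water are therefore only
  qualitatively right.
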