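---
title: "Modeling frozen-zone dynamics under a cryoapplicator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling frozen-zone dynamics under a cryoapplicator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A flat copper cryoapplicator cooled by liquid nitrogen (about -196 °C) is
pressed against a sample — 5% gelatin hydrogel, the standard transparent
phantom for soft tissue, or skin over subcutaneous fat over muscle.  A frozen
hemiellipsoid grows under the probe; clinicians steer cryotherapy by watching
the surface with a thermal imager, but the therapeutically decisive
isotherms (conventionally -40 °C for cell death) live below the surface.
`cryofront` computes the full temperature field in axisymmetric (z, r)
geometry so that surface observations can be related to the frozen depth.

# Model

## Heat equation with temperature-dependent properties

The field obeys the nonlinear heat equation

$$\rho(T)\,C_p(T)\,\frac{\partial T}{\partial t}
  = \nabla\!\cdot\!\big(k(T)\,\nabla T\big),$$

in cylindrical coordinates with polar symmetry.  Density, conductivity and
heat capacity of every medium are piecewise functions of temperature
spanning -196 °C to body temperature; between the frozen and unfrozen states
they change several-fold (frozen hydrogel conducts about 4x better than
unfrozen), so constant-property models misplace the front.  The built-in
material library (`material_library()`) carries 5% gelatin hydrogel, skin,
subcutaneous fat, muscle, and a configurable effective-air medium; each
property is a branch table of polynomial plus $(-T)^p$, $1/T$ and
$1/(T_0-T)^2$ terms, the functional forms the published fits for these
media use.  Users can supply their own library as JSON
(`write_material_library()` documents the schema).

## Phase change as an effective heat capacity

Gels and tissues freeze over a temperature interval, not at a point: ice
forms from pure water, the residual solution concentrates, and its freezing
point keeps falling.  Between the cryoscopic temperature $T_f$ (first ice)
and the initial melting temperature $T_m$ (freezable water exhausted) the
latent heat $L_\mathrm{eff}$ is released gradually.  Rather than tracking a
sharp Stefan front, the solver folds the latent heat into an *effective*
capacity,

$$C_p^\mathrm{eff}(T) = C_p(T) + L_\mathrm{eff}\, g(T),
  \qquad \int_{T_m}^{T_f} g(T)\,\mathrm{d}T = 1 .$$

The default weight is $g(T) \propto |T_f|/T^2$, normalized by
$1-T_f/T_m$ so the integral is exactly 1: most of the latent heat is
released just below $T_f$, which is where ice actually forms in a
freezing solution (for hydrogel, 97% of it above -2.8 °C).  `uniform` and
`linear` weights are available behind `mushy_weight` for sensitivity
studies; the binding contract, enforced by tests, is the unit normalization,
not the shape.  For hydrogel $L_\mathrm{eff} = L\,f_{FW}\,w$ (latent heat
of water x freezable water fraction x moisture content = 295 kJ/kg); for
skin and fat the tissue latent heats are used directly; for muscle the
published capacity table already embeds the latent contribution and is used
unchanged.

Two transcription oddities in the source property tables are reproduced
as printed and flagged in comments: the hydrogel density's mushy-range
branch is discontinuous with its outer branches at $T_f$, and the frozen
muscle conductivity contains $(T+T_f)$ where $(T-T_f)$ would be
conventional.

## Geometry and boundary conditions

Depth $z$ points down from the undisturbed surface; the applicator of radius
$r_\mathrm{ap}$ (default 4 mm) is pressed in to $z_\mathrm{ap}$ (default
1 mm).  During **freezing**: all nodes with $r \le r_\mathrm{ap}$,
$z < z_\mathrm{ap}$ are held at $T_N$ (default -196 °C) — they are skipped
by the update, never overwritten, so their outgoing fluxes are physical;
the bottom row is a thermal bath at $T_b$ (deep-tissue heat supply); sides
and surface are no-flux.  During **thawing** the applicator volume becomes a
no-flux void and the whole sample-air interface is insulated; the bath
remains.  No-flux boundaries are implemented by the one-node
zero-conductivity ghost contour around the storage array; a zero pair
conductivity blocks flux exactly.

An optional *effective air* layer (rows above the surface, with the cold
applicator column continuing through them) models the observed extra surface
cooling from the probe's non-insulated side walls: conduction, convection
and vapor condensation lumped into an effective conductivity
`k * multiplier` and volumetric capacity `rho_cp`.  Such effective
parameters are setup-specific and only meaningful once calibrated against
thermography of the actual rig, so the defaults here are plain still-air
properties (`multiplier = 1`), the
layer is **off by default**, and no quantitative result in this package
depends on it; it exists to reproduce the qualitative surface frozen ring
and for users with their own calibration data.

# Numerics

## Scheme

Forward-Euler in time; five-point second-order stencil on a cell-centered
grid, $r_j = (j+\tfrac12)\Delta r$, $z_i = (i+\tfrac12)\Delta z$.  The
radial term uses the half-shifted radii $r_\pm = r_j \pm \Delta r/2$:

$$T' = T + \Delta t\,\Big[\frac{k^+_z(T_{i+1,j}-T) + k^-_z(T_{i-1,j}-T)}
  {\Delta z^2} + \frac{k^+_r r_+ (T_{i,j+1}-T) + k^-_r r_- (T_{i,j-1}-T)}
  {r_j\,\Delta r^2}\Big]\Big/\big(\rho(T)\,C_p^\mathrm{eff}(T)\big).$$

Cell-centering keeps $1/r_j$ finite on the axis, and the innermost ring has
$r_- = 0$, so the symmetry condition is satisfied identically.  On this
grid the $r_\pm/r_j$ weights *are* the exact finite-volume form
($r_\pm$ times face flux over cell volume $\propto r_j \Delta r$), so the
scheme conserves energy: fluxes between neighbours cancel pairwise because
the pair conductivity

$$k_\mathrm{eff} = \frac{2 k_1 k_2}{k_1 + k_2}$$

(two half-cells in series, the parallel-resistor analogy) is symmetric.  The
conductivity field is refreshed from the current temperatures before every
update (two-pass stepping), as required for flux continuity when $k$
depends on $T$.

## Stability

The explicit scheme requires
$\Delta t \le \big[\,2\alpha(1/\Delta z^2 + 1/\Delta r^2)\,\big]^{-1}$ with
$\alpha = k/(\rho C_p^\mathrm{eff})$ at its worst case.
`stable_timestep()` scans each material's tabulated range on a 0.05 °C grid
(0.005 °C inside the mushy range, where the capacity spikes) for the
maximum $\alpha$ — which occurs in the deeply frozen state, where
conductivity is high and capacity low — and applies a safety fraction
(default 0.5, used by `dt = "auto"`).  The factor-2 headroom also covers
the worst-case pair conductivity at material interfaces.

## Property lookup tables and the latent-heat spike

The compiled kernel evaluates properties from dense lookup tables (0.01 °C
resolution, clamped linear interpolation) built in R from the exact branch
formulas, so kernel and library share one source of truth.  Away from
branch seams the interpolation error is below $10^{-5}$ relative — orders
of magnitude below the uncertainty of the property data.  The latent term is
*bin-averaged* from the closed-form cumulative of $g$ rather than sampled
pointwise: the $|T_f|/T^2$ spike concentrates ~9% of the hydrogel's latent
heat in the final 0.01 °C below $T_f$, and pointwise sampling can miss or
double-count it depending on grid alignment.  Bin-averaging (the
apparent-heat-capacity regularization standard for enthalpy methods) makes
the tabulated capacity integrate to the exact latent heat to better than
0.5% regardless of alignment; the test suite checks this energy budget.

Out-of-range temperatures (below -160 °C for hydrogel, -50 °C for tissues —
the limits of the measured property data; the applicator itself sits at
-196 °C) are clamped to the boundary value.  The R evaluators warn once per
session; the kernel clamps silently.

## Conservation diagnostics

`total_enthalpy()` integrates $\rho(T) H(T)$ over the volume with
$H(T)=\int_{T_\mathrm{ref}}^{T} C_p^\mathrm{eff}$.  On closed
constant-property domains the scheme conserves it to round-off
($<10^{-9}$ relative over $10^3$ steps).  Two intrinsic caveats for
temperature-dependent media, visible in the tests and worth knowing when
using the diagnostic: (i) each step commits an
$O(\delta T^2 \cdot \partial C_p/\partial T)$ error because the capacity is
evaluated at the pre-step temperature ($\delta T$ = per-step change;
shrinks with $\Delta t$); (ii) when density itself varies with temperature
the scheme conserves $\int \rho C_p\, \mathrm{d}T$ rather than
$\rho(T)H(T)$ — physically, the model has no mass transport, so a
temperature-dependent density is a local property fit, not an advected
quantity.

## Oracles

The `validation` functions are deliberately independent of the solver:
`semi_infinite_profile()` (erf solution for constant-property half-space
cooling), `neumann_params()`/`neumann_front_position()` (the classical
two-phase sharp-front solution, solved by bracketed root search to
$10^{-12}$ residual), and `reference_step_dense()` (a plain loop-per-node
re-implementation of the update rule).  The solver matches the erf profile
within 1%, and with constant per-phase properties and the mushy interval
narrowed to 0.2 °C it reproduces the Neumann front within 2% for
$t \in [5, 50]$ s — the error falls linearly with grid spacing, confirming
it is discretization, not model error.  The dense reference agrees with the
compiled kernel to $10^{-12}$, isolating the stencil, masks and radial
weights from any property-evaluation concern.

# Output analysis

## Isotherm tracking

`isotherm_radius()` takes, per grid row, the outermost linear-interpolated
crossing of the level and maximizes over all rows (the widest frozen extent
can sit below the surface); `isotherm_depth()` reads the innermost cell ring
— the axis proxy on a cell-centered grid — downward from the undisturbed
surface, so the reported depth *includes* the 1 mm press-in region.
Crossings are exact for piecewise-linear fields; nesting of isotherm levels
follows from the discrete maximum principle and is asserted in tests.

## The logarithmic growth laws and their datums

During freezing both the radius and the depth of the -40 °C isotherm are
well described by $a\,\ln(t+1)$ ($t$ in seconds, the form used as-is
although dimensionally informal).  The offsets are **fixed at the applicator
boundary, never fitted**: the radius law starts from the applicator radius,
$R(t) = r_\mathrm{ap} + b\ln(t+1)$, and the depth law from the applicator
tip, $D(t) = z_\mathrm{ap} + a\ln(t+1)$.  The tip datum for depth is the
only reading consistent with a zero-offset logarithmic law: depth measured
from the surface starts at $z_\mathrm{ap}$ (the pre-frozen plug) at $t=0$,
not at 0.  With the default 30 s hydrogel run the package obtains
$a \approx 1.27$ and $b \approx 0.86$ mm per ln(s); the radius coefficient
is sensitive to the uncalibrated surface air cooling discussed above (which
widens the frozen zone near the surface), and conduction-only runs sit at
the low end of its plausible range.

## Thermograms and shape

`surface_thermogram()` exports the surface-row profile and renders the
concentric-circle image a thermal camera would record.
`hemiellipsoid_metrics()` reports $D/R$; under a flat 4 mm applicator the
frozen zone is a flattened hemiellipsoid with depth roughly 20% smaller than
radius, which is how a surface radius read from a thermogram translates to
depth.

# Problem sizes used by tests and scripts

The package's reference runs were sized to make the full cycle reproducible
on a single CPU in minutes: the 30 s hydrogel freeze uses a 256 x 256 grid
over 12 x 12 mm (0.047 mm spacing; halving the spacing moves the 30 s
frozen depth by under 1%), and the 30 min run uses 192 x 168 over
33.6 x 29.4 mm (0.175 mm; the -10 °C radius at 15 s changes by under 0.2%
between 0.125 and 0.06 mm spacing).  Domains are at least 1.3x the final
frozen extent in each direction so the no-flux sides approximate a
semi-infinite medium.  Unit tests use 16-64 node grids, where a time step is
microseconds of wall time.

# Known limitations

* No blood perfusion or metabolic heat source: appropriate for short
  freezes and for gel phantoms, but long in vivo exposures will thaw faster
  and freeze slower than this model predicts.
* No contact resistance at the applicator and no nucleation undercooling:
  the model applies the full -196 °C from $t=0$, so the first seconds of
  simulated growth outpace bench measurements (visible ice at 15 s is
  over-predicted by roughly a quarter against published morphometry, while
  the 30 min extent agrees within ~10-15%).
* The effective air layer is qualitative until calibrated against the
  user's own thermography.
* Properties below the tabulated ranges are clamped extrapolations.
* Axisymmetry: no lateral heterogeneity (e.g. a large vessel to one side).
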