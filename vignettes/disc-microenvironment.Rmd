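---
title: "Modelling the disc nutrient microenvironment with ivdmicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the disc nutrient microenvironment with ivdmicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ivdmicro)
```

# The model

The intervertebral disc is avascular: oxygen and glucose reach its cells
by diffusion from the vertebral capillaries through the cartilage
endplates (CEP) and from the periphery through the outer annulus fibrosus
(AF), while lactate — the end product of the predominantly glycolytic
disc-cell metabolism — accumulates toward the centre and acidifies the
nucleus pulposus (NP). `ivdmicro` represents this balance with a
steady-state reaction–diffusion problem per species
(oxygen, glucose, lactate),

$$\nabla \cdot \left( D_i(\mathbf{x}) \nabla c_i \right) = R_i(\mathbf{x}, c_i),$$

on an idealized disc geometry, plus a set of supporting models that
connect the tissue scale to the culture experiments that supply its
parameters.

## Geometry

The disc is an elliptic cylinder: anterior–posterior half-width $a$,
lateral half-width $b$, height $h$. The NP is a coaxial elliptical core
(fraction `np_fraction` of each half-width), the AF is the surrounding
ring, and the CEP forms two layers of thickness `cep_thickness` capping
the NP and the inner AF. One quadrant is discretized on a regular
node-centred grid (default spacing 0.25 mm for disc-scale runs); the two
cut planes are zero-flux symmetry planes.

Two geometric choices were genuinely open:

* **Quadrant in 3-D, not axisymmetric.** The disc cross-section is
  elliptical, so an axisymmetric reduction cannot represent the distinct
  anterior–posterior and lateral half-widths; a full 3-D quadrant grid is
  used.
* **CEP lateral extent.** The endplate covers the NP and the inner AF;
  its in-plane boundary is set to the ellipse at fraction
  `(np_fraction + 1)/2` of the half-widths (configurable via
  `cep_fraction`). Top/bottom faces outside that extent carry the outer
  AF boundary value — peripheral AF attaches to bone and ligament rather
  than endplate cartilage.

The default dimensions (a = 10 mm, b = 12.5 mm, h = 4 mm, CEP 0.6 mm,
NP fraction 0.5) are *placeholders* of caprine lumbar-disc scale: the
measured L3–4 dimensions behind the original geometry are not part of
this package's sources. Every disc-scale conclusion the package draws is
therefore an ordering or shape statement (degenerated vs healthy, centre
vs boundary), never an absolute position-by-position prediction.

## Transport and metabolism

Diffusivities are piecewise constant per region (mm²/h), with the AF
anisotropic — "radial" (in-plane) and "axial" (through-height) values —
and the CEP diffusivity reduced in the degenerated scenario
(`diffusion_table()`). Dirichlet concentrations sit on the outer AF
surface and CEP faces (`boundary_table()`): oxygen 15%/12% in both
scenarios, glucose and lactate scenario-specific.

Reaction terms come from per-cell rates measured in culture:

* a per-cell rate $r$ (nmol per 10⁶ cells per hour) times the active
  cell density $\rho_\text{active} = \rho_\text{total} \times v$
  (cells/mm³, viability $v$ = 0.40 degenerated / 0.80 healthy) gives a
  volumetric rate in nmol/mm³/h, which is numerically equal to mM/h;
* glucose consumption is tied to lactate production by the anaerobic
  stoichiometry (one glucose to two lactate): GCR = LPR/2;
* the CEP is treated as acellular (no sink);
* pH is a linear function of lactate. The map's default coefficients
  (intercept 7.496, slope 0.0997 pH/mM) are the line through the two
  anchor pairs (0.465 mM, pH 7.45) and (5.379 mM, pH 6.96) reported for
  caprine NP tissue; both coefficients are configurable because the
  underlying calibration is external to this package.
* oxygen is carried in percent units throughout (boundaries and results
  are conventionally quoted in %); 1% ≡ 0.00925 mM for conversion.

Zeroth-order consumption can drive a linear solution negative where
supply is poor, so consumed species carry a Michaelis-type depletion
clamp $R(c) = R_0\, c/(c + K_m)$ with small half-saturations (O₂ 0.1%,
glucose 0.05 mM) — a numerical guard, deliberately far below every
boundary value so the linear regime dominates; the clamp can be disabled
per species (`km = NULL`) for linearity studies. Lactate production is a
constant source, not clamped: the model treats lactate as a metabolic
by-product (no consumption by AF cells).

Per-cell OCR and LPR magnitudes for the two scenarios are *user inputs*,
not package constants: they are measured quantities, and the only
published anchor carried in examples is the caprine NP OCR of
≈3.8 nmol/10⁶ cells/h. One consequence deserves emphasis: because
degenerated viability halves the active density, a degenerated per-cell
OCR must exceed **twice** the healthy per-cell OCR before the
*volumetric* consumption — the quantity that shapes the gradients — is
actually elevated. The package's scenario-comparison examples use
degenerated rates above that threshold (OCR 9.5 vs 3.8), consistent with
the elevated consumption that depresses central oxygen in the degenerated
state.

## Numerics

The operator is discretized with a 7-point finite-difference stencil.
Interface diffusivities are harmonic means of the neighbouring node
values, which conserves flux across the NP/AF/CEP discontinuities (and
makes exterior contact natural: the harmonic mean with a zero
diffusivity vanishes, giving zero flux). The resulting system is
symmetric positive definite and is factorized with a sparse Cholesky
(CHOLMOD, through `Matrix`); the clamp nonlinearity is handled by fixed
point, linearizing $R_0/(c_\text{prev}+K_m)$ onto the matrix diagonal.
That linearization keeps every iterate non-negative (M-matrix argument)
and converges in ~10–15 iterations to the default tolerance of 1e-8 on
the relative change; the factor's symbolic analysis is reused across
iterations. Unclamped species solve in a single factorization.

Verification is against closed forms rather than other software: the 1-D
constant-sink slab parabola $c(x) = c_0 - \tfrac{R}{2D}x(L-x)$ is
reproduced to machine precision at 101 nodes, the spherical bead profile
$c(r) = c_s - \tfrac{R}{6D}(a^2 - r^2)$ to ~1e-6 relative, discrete
boundary influx balances interior consumption to ~1e-9 relative, and
zero-sink problems return uniform fields (discrete maximum principle).
Grid convergence is checked on a geometry whose flat interfaces align at
both resolutions (0.25 vs 0.125 mm): NP-centre values move by <1%. The
0.25 mm disc-scale default is the coarsest spacing that still resolves
the NP with at least 10 nodes across each direction for the default
4 mm disc height.

## Boundary calibration

Boundary tables of this kind are built by iterative adjustment until the
model reproduces target NP-centre conditions. `calibrate_boundaries()`
implements the minimal faithful scheme: per species, a secant iteration
on a *single* scale factor multiplying both the AF and the CEP value,
preserving their initial ratio (the published boundary pairs fix one
pair per species, not two independent trajectories; a two-parameter
search would be under-determined by a single centre target). pH targets
are converted to lactate targets through the pH–lactate map before
calibration. Because the NP-centre value is affine in the boundary scale
up to the mild clamp, the secant converges in a handful of solves;
convergence tolerances default to 0.1% O₂, 0.05 mM glucose and 0.05 pH.
The calibrated table is self-verifying: re-solving with it reproduces
the targets within tolerance, and already-satisfying inputs return with
zero update iterations.

## GAG accumulation

NP matrix dynamics follow a conservation-of-mass balance for GAG
density $G$ (µg/mm³):

$$\frac{dG}{dt} = s\,\rho_\text{active} - k\,G,$$

with synthesis $s$ = 25.9 (degenerated) / 25.4 (healthy) pg/cell/day
(measured over a 24-day culture) and first-order degradation
$k$ = 0.086/year for both scenarios. Two outputs are reported side by
side, because a single convention cannot produce both published summary
numbers for such trajectories:

* **cumulative synthesis** $S\,t$ with
  $S = s\,\rho_\text{active} \times 365 \times 10^{-6}$ µg/mm³/year —
  the headline "accumulation" (10-year values ≈232 µg/mm³ degenerated,
  ≈455 µg/mm³ healthy; the healthy value is known to sit ~4% below its
  published counterpart of 475, a convention gap that is documented
  rather than absorbed);
* **net content**, the solution of the balance above
  ($G(t) = S/k + (G_0 - S/k)e^{-kt}$), which is what degradation leaves
  in the tissue.

Defaults: 365-day years, zero initial content (the starting GAG density
is not fixed by this package's sources), degradation *not* scaled by
viability — the tabulated rate is 8.6%/year for both scenarios — but a
`degradation_viability_scaling` switch exposes that variant. Integration
is classical Runge–Kutta at 1-day steps; against the closed form the
10-year net content is accurate to ~1e-13 relative, and since active
density and synthesis are spatially uniform in the NP, GAG does not
diffuse and the field snapshot paints a single trajectory value across
the NP nodes. Healthy-to-degenerated slope *ratios* (≈1.96, tracking
$S_h/S_d$) are meaningful; absolute slope values depend on the unstated
fitting convention behind published figures and are not asserted.

## The bead culture well

`simulate_well()` checks that a single alginate bead in 2 mL of media
actually experiences the microenvironment its group prescribes between
media changes. The bead interior is a 1-D spherically symmetric
finite-volume discretization (default 25 shells) with the same per-cell
sinks as the disc model at the seeding density of 2.5×10⁶ cells/mL; the
media is a well-mixed reservoir exchanging mass-conservatively with the
bead surface; media oxygen relaxes to the incubator setpoint with a
first-order gas-exchange time constant; and media-change events (every
3–4 days) reset glucose/lactate to nominal and oxygen to the 20%
handling level. Media pH is derived from accumulated media lactate
relative to the condition's set pH. The stiff shell system is integrated
with `deSolve::ode` (lsoda, rtol 1e-9).

Bead radius (1.25 mm), alginate diffusivities (water-like: O₂ 7.2,
glucose 2.3, lactate 3.0 mm²/h) and the 2 h gas-exchange time constant
are configurable placeholders — the culture protocol fixes the needle
gauge, media volume and seeding density but not these constants. The
model's conclusions at defaults are the protocol-level ones: worst-case
centre-to-media gradients of a few percent for oxygen and glucose, media
glucose staying within ~1% of nominal over a 3-day interval, and
osmolarity carried as an inert label (no transport model).

## Rate extraction from flux traces

`ocr_from_trace()` and `lpr_from_trace()` implement the computation that
turns raw extracellular-flux traces into the per-cell rates the disc
model consumes: per-cycle least-squares slopes of O₂ (mmHg/h) or pH
(pH/h), subtraction of the matched blank-well slope (background drift is
removed exactly, never assumed zero — a missing blank is an error),
conversion to molar flux through the O₂ solubility (default
1.3×10⁻³ mM/mmHg) or the medium buffering coefficient (mM lactate per pH
unit, required configuration with a documented placeholder default of
10), multiplication by the effective chamber volume (default 22.7 µL),
and normalization per 10⁶ cells with cell numbers from DNA
(7.7 pg/cell). Negative corrected rates are flagged, not clipped. The
default trace layout is three 20-minute cycles of 15 samples.

## The synthetic generator

`generate_design()` emits the full 2×3×2×2 factorial (24 groups, group 1
= 2% O₂, pH 6.5, 0.5 mM glucose, 350 mOsm; osmolarity nested innermost,
oxygen outermost). `generate_readouts()` draws per-donor random effects
and per-bead readouts with the qualitative effect structure the
experiment established: viability dominated by pH (means 0.40 / 0.60 /
0.80 at pH 6.5 / 6.8 / 7.1 — the two outer anchors are the measured
scenario viabilities, the middle is interpolated), DNA and GAG scaling
with realized viability, and collagen (via hydroxyproline × 7.69) flat
across groups — the null finding. Dispersions (donor SD 0.03, residual
SD 0.04 on viability, 10% CV on biochemistry) are order-of-magnitude
choices; published variability is figure-only, so every statistical test
on synthetic data is generator-relative, never a claim about the real
assay's power. `generate_traces()` emits cell/blank well pairs sharing a
drift term, so blank subtraction inverts the generator exactly at zero
noise; the generator's noise parameter is an absolute SD in the
measurement unit, and "2% measurement noise" in the recovery studies
means an SD of 2% of the ambient O₂ reading.

What passing tests on these data do show: the pipeline's algebra (design
balance, unit chains, blank correction, effect recovery, a standard
`aov` screen flagging pH as dominant). What they cannot show: anything
about real measurement error structure, donor biology, or histology —
the generator produces numbers with the *assumed* statistical shape, not
images or mechanisms.

# Problem sizes and runtimes

Disc-scale runs use the 0.25 mm grid (41×51×17 nodes, ~27k tissue
nodes); a three-species scenario solve takes tens of seconds and a
three-species boundary calibration a couple of minutes on one core.
Property tests run on a laterally reduced disc (half-widths 5/6 mm,
~9k nodes, seconds per solve). Monte-Carlo checks use 100–200 seeds
with the small trace/readout generators. These sizes are the package's
defaults for its own verification; finer grids (0.125 mm) were used to
establish the grid-convergence behaviour reported above.

# Known limitations

* Geometry, bead constants, buffering and solubility coefficients, and
  the scenario OCR/LPR magnitudes are configuration with documented
  placeholder defaults, for the reasons given above; results that depend
  on them are ordering/shape predictions.
* No mechanics: no convective transport, disc-height change, dynamic
  loading, or osmotic coupling of GAG to water content.
* Lactate is a pure by-product; AF lactate consumption is not modelled.
* The GAG model is spatially uniform in the NP and does not couple back
  to the nutrient fields.
* Degeneration enters only through diffusivities, boundary values,
  viability and rates — the geometry is held fixed.
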