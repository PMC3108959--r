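---
title: "Modelling interstitial fluid pressure and flow in solid tumors"
author: "ifpsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling interstitial fluid pressure and flow in solid tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifpsim)
```

## The model

Solid tumors lack functional lymphatics, so fluid filtered out of their
leaky microvasculature has nowhere to drain. The interstitial fluid
pressure (IFP) rises until it chokes off filtration in the core, leaving a
thin, well-filtered rim — a central obstacle for drug delivery, since the
outward convective flow washes extravasated drug away from the periphery
while the pressurised core receives almost none.

`ifpsim` treats the tumor and any surrounding normal tissue as rigid,
isotropic porous media. Interstitial fluid velocity obeys Darcy's law,

$$ \mathbf{u} = -K \nabla p , $$

with $K$ the interstitial hydraulic conductivity
(cm^2 mmHg^-1 s^-1). Mass balance at steady state couples the flow to a
Starling transcapillary source and a lymphatic sink, both affine in the
local pressure $p$:

$$ \nabla \cdot \mathbf{u} = \phi_B - \phi_L, \qquad
   \phi_B = L_p \tfrac{S}{V}\,\bigl(p_v - p - \sigma(\pi_v - \pi_i)\bigr), \qquad
   \phi_L = L_{p,L} \tfrac{S_L}{V}\,(p - p_L). $$

Two derived pressures organise everything. The *effective pressure*
$p_e = p_v - \sigma(\pi_v - \pi_i)$ is the IFP at which net filtration
stops; the *steady-state pressure*
$p_{ss} = (L_p \tfrac{S}{V} p_e + L_{p,L}\tfrac{S_L}{V} p_L) /
(L_p \tfrac{S}{V} + L_{p,L}\tfrac{S_L}{V})$ balances vascular efflux
against lymphatic influx and collapses to $p_e$ in lymph-free tissue.
Substituting Darcy's law into the balance gives one linear elliptic
equation for $p$; in a uniform sphere of radius $R$ it nondimensionalises
to

$$ \frac{1}{\bar r^2}\frac{d}{d\bar r}\Bigl(\bar r^2 \frac{dP}{d\bar r}\Bigr)
   = \alpha^2 (P - 1), \qquad
   \alpha = R\sqrt{\frac{L_p S/V + L_{p,L} S_L/V}{K}}, $$

with $P = (p - p_{surr})/(p_e - p_{surr})$. The single dimensionless
group $\alpha$ — the ratio of interstitial to vascular flow resistance —
controls how sharply the IFP plateaus at $p_e$: the closed-form solution
$P(\bar r) = 1 - \sinh(\alpha\bar r)/(\bar r \sinh\alpha)$ has
$P(0) = 1 - \alpha/\sinh\alpha$, which tends to 1 rapidly as $\alpha$
grows. A necrotic core (no functioning vessels) simply drops both source
terms: pressure there obeys the spherical Laplace equation, whose regular
solution is a constant, so the core is flow-free and sits at the pressure
of its boundary.

Tissue regions are assumed time-independent over the transport time scale,
and the necrotic core keeps the conductivity of viable tumor — necrosis
switches off sources, not the porous matrix.

## Parameters

All quantities use cm, s and mmHg; velocities are additionally reported in
µm/s, the natural scale of tumor rim flow.

| key | meaning | baseline tumor | baseline normal |
|-----|---------|---------------:|----------------:|
| `K` | interstitial hydraulic conductivity (cm²/mmHg/s) | 4.13e-8 | 8.53e-9 |
| `Lp` | vessel-wall hydraulic conductivity (cm/mmHg/s) | 2.8e-7 | 3.6e-8 |
| `SV` | vascular surface density (1/cm) | 200 | 70 |
| `pv` | vascular pressure (mmHg) | 15.6 | 15.6 |
| `sigma` | osmotic reflection coefficient | 0.82 | 0.91 |
| `pi_v` | plasma osmotic pressure (mmHg) | 20 | 20 |
| `pi_i` | interstitial osmotic pressure (mmHg) | 15 | 10 |
| `lymph_coeff` | lymphatic filtration coefficient (1/mmHg/s) | 0 | 0 |
| `pL` | lymphatic pressure (mmHg) | 0 | 0 |

These are the classic Jain–Baxter values shipped in
`inst/extdata/baseline.yaml`; they give $p_e = 11.5$ mmHg and
$\alpha = 36.8$ for a 1 cm tumor. Tissue properties vary greatly between
organs, so the configuration loader expects users to supply their own
values for new applications. The lymphatic coefficient is stored as the
single product $L_{p,L} S_L/V$ because only that product enters the model;
the baseline sets it to zero for both tissues (the source material table
provides no lymphatic values), which makes the shipped "normal" tissue a
conservative, drainage-free shell — users with lymphatic data should set
`lymph_coeff` and `pL` explicitly.

## Solvers and their numerical choices

**Closed forms** (`solve_isolated_uniform()`, `solve_necrotic()`,
`solve_embedded()`). The hyperbolic solutions are evaluated through ratios
such as $\sinh(\alpha\bar r)/\sinh\alpha =
e^{\alpha(\bar r - 1)}(1 - e^{-2\alpha\bar r})/(1 - e^{-2\alpha})$, which
stay finite for arbitrarily large $\alpha$, and the removable singularity
at the center is evaluated by its series limit rather than a small-offset
hack. The necrotic shell uses a basis centred on the core radius,
$\alpha r_n \cosh\bigl(\alpha(\bar r - \bar r_n)\bigr) +
\sinh\bigl(\alpha(\bar r - \bar r_n)\bigr)$, which satisfies the
zero-flux core condition identically and keeps every exponent bounded by
$\alpha(1 - \bar r_n)$. The embedded (tumor-in-normal-tissue) solution
imposes pressure and Darcy-flux continuity at the interface and a far-field
Dirichlet value at a finite outer radius, solving a well-conditioned 3×3
system in a basis of decaying exponentials; a region with no sources at
all (a fully necrotic tumor, or a shell with `Lp = lymph_coeff = 0`)
degenerates to the Laplace equation and gets the $\{1, 1/r\}$ basis
instead.

**Radial finite volumes** (`build_radial_grid()`, `solve_radial()`). The
grid snaps the necrotic and tumor radii onto cell faces so region
boundaries are conservative flux interfaces; spacing is uniform within each
region. Fluxes use exact spherical face areas and harmonic-mean face
conductivities (which preserve flux continuity across conductivity jumps);
the affine source is kept implicit in the matrix, so the discrete system is
solved in one shot — no outer iteration is needed for a source that is
linear in $p$. The outer Dirichlet flux uses a second-order one-sided
gradient through the boundary value and the last two cell centers (falling
back to the half-cell two-point form when the last two cells differ in
region or spacing); this keeps the observed convergence order at 2 and the
error constant small even for boundary layers at $\alpha \sim 35$. The
default linear solver is direct tridiagonal elimination; red-black SOR
sweeps with relaxation factor 0.75 are provided to mirror the reference
numerical treatment, which used under-relaxed SOR with a
six-orders-of-magnitude residual reduction — that reduction (`tol = 1e-6`)
is the default stopping rule here too. Note that a relaxation factor below
1 is strictly *under*-relaxation despite the SOR name; both
$\omega < 1$ and $\omega > 1$ are accepted.

**Voxel finite volumes** (`voxelize_sphere()`, `solve_3d()`). The 3-D
solver uses a structured voxel grid with the usual seven-point conservative
stencil rather than the unstructured tetrahedral element-based mesh of the
original treatment: the physics and the conservation structure are
identical, and a structured grid is far easier to verify against the
spherical closed forms. Voxels are labeled deterministically by center
distance; voxels beyond the outer radius are held at the boundary pressure,
so the Dirichlet surface is a sphere carved out of the box (the box faces
are Dirichlet too, at half-voxel distance). The symmetric
positive-definite system is solved by Jacobi-preconditioned conjugate
gradients by default, with red-black SOR available. The original numerical
treatment invoked the SIMPLE pressure–velocity coupling algorithm; steady
Darcy flow with an affine source is a single linear elliptic equation with
no velocity–pressure coupling loop, so this package solves the elliptic
system directly — SIMPLE would add an iteration level without changing the
fixed point.

Discrete conservation is checked on every solve: the volume-integrated net
source must equal the boundary outflux (a telescoping identity of the
scheme), to ~1e-13 for the direct radial solve and to the linear-solver
residual for iterative solves. When a conservation audit tighter than the
default 1e-6 residual is wanted in 3-D, pass a tighter `tol` (the shipped
checks use 1e-12).

## Critical radii

Two scalar outputs summarise the sweeps. The *critical tumor radius* is
the smallest $R$ at which the center pressure reaches the effective
pressure; the *critical necrotic radius* is the largest core radius at
which the center pressure still equals its non-necrotic maximum. Since
"reaches" is never exact for finite $\alpha$, both are operationalised
with a tolerance: $P(0) \ge 1 - \varepsilon$, default
$\varepsilon = 0.01$ (1% of $p_e - p_{surr}$). That default reproduces the
qualitative classification of the four standard simulated radii (0.1,
0.25, 0.5, 1 cm): only the 0.1 cm tumor stays sub-critical. Both maps are
provably monotone ($P(0)$ is strictly increasing in $\alpha$,
non-increasing in the necrotic radius — the shell denominator
$\alpha\bar r_n\cosh(\alpha(1-\bar r_n)) + \sinh(\alpha(1-\bar r_n))$ has
a non-positive derivative in $\bar r_n$), so bisection is exact to its
bracket; the test-suite cross-checks against dense brute-force scans.
$\varepsilon$ is a configuration knob (`analysis.eps`) and every report
states the value used.

## What the geometry generator does and does not emulate

`voxelize_sphere()` produces the study geometries: a centered sphere with
an optional concentric necrotic core and surrounding shell, labeled
deterministically with no randomness anywhere (tests would reject any).
This captures the idealised geometry under which the model's analytical
structure is known, which is exactly what makes the solver verifiable.
Real tumors differ in ways the fixtures deliberately omit: vasculature is
spatially heterogeneous (here each region is uniformly perfused),
transport properties can be anisotropic and patient-specific (here scalar
per region), tissue deforms under pressure (here rigid), and boundaries
are irregular (here spherical, though `solve_3d()` accepts arbitrary
labeled masks). Passing tests therefore demonstrate correctness of the
numerics for the stated model, not predictive accuracy for any particular
tumor; parameter values must come from measurements for quantitative use.

## Problem sizes and tolerances used in the shipped checks

The radial solver is exercised at $N = 100$–2000 cells (convergence-order
studies at 100–800, closed-form comparisons at 1000, embedded two-region
runs at 3000–8000) and the voxel solver at $16^3$–$64^3$, sizes at which
every check runs comfortably on a laptop while leaving the asymptotic
regime clearly visible. The default embedded outer radius, when a
configuration does not specify one, is $R_{out} = 3R$: for baseline
parameters the normal-tissue screening length $1/\lambda_n \approx 0.06$
cm is tiny compared to the shell, and doubling $R_{out}$ changes the
center pressure by far less than 0.1%.

## Known limitations

- Steady state only; no transient pressure evolution or tumor growth.
- No solute/drug concentration transport — drug delivery is discussed only
  through its pressure and filtration surrogates.
- Scalar, pressure-independent conductivities; no DTI-derived anisotropy.
- No two-phase (nanoparticle) flow.
- The voxel solver's staircase boundary limits pointwise accuracy near the
  outer sphere; radially averaged comparisons converge cleanly (errors at
  $24^3$, $48^3$, $64^3$, $96^3$ decrease monotonically) but sub-percent
  pointwise accuracy at the rim needs finer grids than the defaults.
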