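---
title: "The pump-chamber model: assumptions, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pump-chamber model: assumptions, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pumpflow)
```

## The physical model

Fluid-feeding insects couple two hydraulic elements: a long, narrow food
canal in the proboscis, and a shallow muscle-driven pump chamber in the
head. `pumpflow` implements the lubrication-theory model of this pair.

**Chamber.** The pump chamber is a cylinder of rectangular (length $L$,
width $W$) or circular (radius $R$) footprint whose roof — the plunger —
sits at height $h(t)$ above a rigid flat floor. Because $h \ll L, W$, the
Stokes equations reduce to Hele-Shaw flow: the depth-averaged in-plane
velocity is $\mathbf{V} = -\tfrac{h^2}{12\eta}\nabla p$ and mass
conservation turns the pressure into the solution of a Poisson problem,
$\nabla^2 p = \tfrac{12\eta}{h^3}\dot h$, with $\nabla p \cdot \mathbf{n}
= 0$ on the impermeable walls. Three assumptions stand behind this
reduction, and the package exposes the screening numbers for each:

* *Quasi-steadiness.* The Womersley number $\mathrm{Wo} = h\sqrt{2\pi f
  \rho/\eta}$ (pump beat rate $f$) must be below one; `womersley()`
  computes it. For a kissing-bug-sized pump ($h = 0.16$ mm, 3 beats/s,
  water-like fluid) it is about 0.7, and it only falls as the gap closes.
* *Thin-gap kinematics.* The in-plane/trans-plane velocity ratio scales as
  $L/h$; `velocity_scales()` reports it together with the in-plane speed
  estimate $Q/(Wh)$. For the packaged species this ratio is a moderate
  2–6 at *maximum* expansion — an order-of-magnitude justification, not a
  sharp bound — and grows as $h$ shrinks during the stroke.
* *Laminarity of the canal flow*, which at these scales (micrometre bores,
  mm/s velocities) is uncontroversial.

**Canal coupling.** The food canal is a straight tube (length $l_p$,
diameter $d_p$) in Hagen–Poiseuille flow. Volume conservation,
$Q = -A\,\dot h$, fixes the junction pressure
$P_p = -A \tfrac{128\eta l_p}{\pi d_p^4}\dot h$ (`coupling_pressure()`),
which enters the chamber problem as a Dirichlet condition on the opening
AB. The esophagus-side stroke is the mirror case (sign change) and is not
modelled separately.

**Dimensionless split.** With the yardstick $l_r = L$ or $l_c = R$ and the
pressure scale $\tfrac{12\eta l_i^2}{h^3}\dot h$, the dimensionless
pressure is assembled (`assemble_pressure()`) as
$$P = P_\mathrm{squeeze} + \tilde P + K,$$
where $P_\mathrm{squeeze}$ is $X^2/2 - 1/8$ (rectangle) or
$\tilde r^2/4 - 1/4$ (disk), $K = -\tfrac{32 h^3 l_p A}{3 l_i^2 \pi d_p^4}$
is the uniform coupling pressure, and the harmonic correction $\tilde P$
solves the mixed problem: $\tilde P = 0$ on the opening,
$\nabla\tilde P\cdot\mathbf{n} = -\tfrac12$ on the $X = \pm\tfrac12$ walls
and the wall arc, zero flux on the $Y = \pm W/2L$ sides.

A note on the sign convention: we read the wall condition as an *outward*
normal flux of $-1/2$ on both $X$-walls. This is the only reading under
which the total pressure satisfies the no-flux wall condition given the
squeeze part above, and it reproduces the full-opening closed form
$\tilde P = -X/2 - 1/4$, which the test suite checks to machine precision.

**Forces and impulse.** Integrating the dimensional pressure over the
plunger gives (`plunger_force()`)
$$F_r = \frac{12\eta}{h^3}\dot h\, L^4\Big[C_r - \frac{W}{12L}\Big]
 - \dot h\,\frac{128\eta l_p}{\pi d_p^4}(LW)^2,$$
with shape constant $C_r = \iint \tilde P\,dX\,dY$ (and the analogous
circular form with $R^4[C_c - \pi/8]$). We implement the bracket as
$L^4[C_r - W/(12L)]$: direct integration of the assembled pressure forces
this form, and the force-consistency test (quadrature of the nodal
pressure field against the closed form, 1%) holds only with it. Likewise
the impulse–height relation is normalized as $\Pi d_p^2/(6\eta l_i^4)$ —
dimensional analysis of $-\int F\,dt$ admits no other power of $d_p$ — and
the path-independence test (three different monotone $h(t)$ trajectories,
trapezoid quadrature, 0.1%) pins it down numerically. Because the Stefan
term diverges as $h^{-3}$ while its time integral stays finite, the
biologically meaningful control variable is the impulse, and
`height_from_impulse()` inverts the relation by bracketed root finding
(the relation is strictly increasing since $C < W/(12L) < \pi/8$).

**Classification.** `classify_species()` runs the three-step procedure:
derive $(W/L, g)$ or $\theta$; solve for the shape constant and the
boundary value $f_r$ or $f_c$; compare $f = l_p h_\mathrm{max}^3/d_p^4$.
Ties within 1% (configurable) are labelled `boundary` rather than forced
into a regime.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tol` (refinement) | 0.005 | – | relative change of the shape constant between adaptive passes; 0.5% is well below the 2% spread the rounded input morphometrics themselves induce |
| `max_refinements` | 30 | – | a generous cap; typical geometries converge in 2–8 passes from the graded base mesh |
| `mark_frac` | 0.25 | – | triangles with gradient indicator above this fraction of the maximum are bisected; smaller values refine more per pass |
| `base_nphi` | 256 | segments | disk boundary polygonization at the base level (area error $\sim 10^{-4}$) |
| `base_nx` | 40 | columns | rectangle base grid; the $Y$ grid always carries lines exactly at the opening endpoints |
| `tie_tol` | 0.01 | – | boundary band of the regime comparison |
| `fit range` | 0.05–0.8 | rad | default $\theta$ window of the $C_c$ log fit; beyond $\theta \approx 2$ the fitted line would cross zero while the true constant stays negative, so `empirical_cc_fit()` refuses $\theta \ge 2$ |
| `eta`, `rho` | $10^{-3}$, $10^3$ | Pa s, kg/m³ | water-like reference fluid |

Internal units are SI throughout; the CSV reader converts from the tabular
conventions (mm for proboscis length, µm for everything else). This
eliminates silent unit bugs in the two quantities that mix large and small
scales, the B-factor and $K$.

## Numerical choices

**Meshing.** The base mesh is structured: a tensor grid for the rectangle
(with grid lines exactly at the opening endpoints $\pm g/2$) and polar
rings × angular sectors for the disk (rings graded toward the rim as
$1-(1-j/m)^{1.7}$, nodes exactly at $\varphi = \pm\theta$). On top of it,
adaptive refinement bisects the longest edge of marked triangles
(Rivara's algorithm), which keeps the mesh conforming and bounds angle
degradation without hanging-node bookkeeping. The refinement indicator is
$|\nabla \tilde P|\sqrt{\text{area}}$ per triangle, which concentrates
work at the opening corners A and B where the mixed boundary condition
makes the gradient behave like $r^{-1/2}$. The corner singularity is
handled *only* by refinement — no singular enrichment — because the
quantities of interest ($C_r$, $C_c$, fluxes, forces) are integrals and
converge without it. New boundary nodes of circular meshes are projected
back to the unit circle; edge tags are inherited by the two half-edges.

**Solver.** Linear (P1) elements; the Dirichlet-reduced stiffness matrix is
symmetric positive definite and solved by sparse Cholesky (`Matrix`). The
solver path contains no randomness: results are bitwise reproducible. A
relative residual above $10^{-8}$ aborts with the residual reported.
Boundary fluxes are evaluated from the discrete reaction at the Dirichlet
nodes ($K u - b$ summed over opening nodes), the flux-consistent
alternative to sampling raw gradients at the singular corners;
`opening_flux()` builds the conservation check on it.

**Quadrature.** Shape constants use vertex-average quadrature — triangle
area times the mean of the three vertex values — exact for the P1 fields
being integrated.

**Cross-checking.** `fd_oracle()` solves the same boundary-value problem by
an independent structured-grid method: a conservation-form (control-volume)
five-point scheme on grids graded toward the opening corners, with the
known wall flux imposed exactly on boundary faces and the polar axis
handled by a single center unknown. The test suite requires < 1% relative
$L^2$ agreement between the two methods across the nine rectangular and
three circular configurations of the illustrative parameter grid. During
development the graded control-volume form replaced a uniform-grid ghost
scheme whose corner error converged only at first order; the conservation
form restores the accuracy needed for a meaningful 1% comparison.

**Convergence bookkeeping.** `refine_until_converged()` stops when the
shape constant changes by less than `tol` between passes, records the full
constant history, and *flags* (warning + `converged = FALSE`) rather than
silently accepts a run that exhausts `max_refinements`. `tol = Inf`
degenerates to exactly one pass, which the tests use as the loop contract.

**Degenerate inputs.** Openings requested wider than the chamber
(`g > W/L`, `theta > pi`) are clamped to the full-opening limit with a
warning. A mesh with no opening edge is rejected (the pure Neumann problem
is singular). `l_p = 0` is a legitimate state (separated galeae): the
f-factor is 0, the force's column term vanishes, but Poiseuille discharge
and the crossover height are undefined and error explicitly. The all-open
disk $\theta = \pi$ yields the zero correction field and $C_c = 0$ exactly.

## Geometry conventions and open choices

* **Circular radius default $R = L/2$.** Morphometric tables measure a
  single pump length; equating it with the disk diameter makes $g$ and
  $\theta$ numerically equal, consistent with reporting a single opening
  column. A per-record `R` override exists.
* **$\theta$ as chord ratio.** For morphometric records
  $\theta = d_p/(2R)$ (a small-angle identification, since $d_p \ll R$
  in practice); wide-opening configurations up to $\theta = \pi$ are
  expressed directly via `chamber_geometry(..., theta = )`.
* **Default chamber shape: rectangular**, because it uses both measured
  pump dimensions. `classify_species(shape = "both")` reports both
  idealizations and warns on disagreement instead of resolving it.
* **Doubled canal.** One packaged species has unlinked galeae: two open
  half-canals rather than one sealed tube. `derive_dimensionless(canals =
  2)` exposes the doubled-opening variant (which matches that species'
  printed opening fraction), and the species table carries a `galeae`
  column; `separated` records classify with effective $l_p = 0$, since
  capillarity fills the intergaleal gap at negligible viscous cost.
* **Proboscis length ranges.** Where a range is reported (Manduca sexta,
  50–70 mm) the packaged table carries the lower endpoint; the B-factor at
  the upper endpoint follows by linearity in $l_p$.

## The synthetic fixtures

`generate_fixtures()` writes, besides the measured table, a synthetic
morphometrics sweep: 36 species on a log grid of f-factors from $10^{-2}$
to $10^7$ with deterministic lognormal jitter from a single recorded seed.
The construction splits $f = (l_p/d_p)(h/d_p)^3$ between a proboscis
slenderness in [8, 1500] and a gap ratio, with canal diameters in 20–300 µm
and pump dimensions a small multiple of the gap — dimensionally plausible
insects, not real ones. The sweep exists to exercise the classifier on both
sides of every boundary curve; passing those tests demonstrates the
*pipeline* (geometry validation → solve → boundary comparison) over the
full dynamic range, not that any real species sits at those coordinates.
The generator does not emulate measurement error correlations, allometric
scaling between pump and proboscis, or non-rectangular chamber outlines —
conclusions about real data rest on the measured table, which ships
verbatim.

## Problem sizes used by the packaged checks

The test suite and the acceptance script solve each chamber problem on
meshes of roughly 3–6·10³ nodes (2–8 adaptive passes from the structured
base mesh) and compare against finite-difference grids of up to
$\sim 10^5$ unknowns; the shape-constant sweep behind the log fit uses 20
openings in [0.05, 0.8] rad at the 0.5% tolerance. These sizes were chosen
so that every reported quantity is converged one decade below the
tolerance it is compared at.

## Known limitations

* The chamber floor and plunger are flat and rigid; real cibaria are
  U-shaped in cross-section and compliant. The model captures the scaling
  structure (the $h^{-3}$ Stefan term, the $d_p^{-4}$ canal term), not
  organ-accurate pressure maps.
* The plunger's `h(t)` is prescribed, not solved from muscle mechanics;
  only quadrature along given paths is provided (no plunger ODE).
* One valve is open at a time; valve dynamics and the esophagus stroke are
  out of scope beyond the sign symmetry.
* P1 elements with refinement-only treatment of the corner singularity
  give integral quantities to the stated tolerances but pointwise
  gradients near A and B remain inaccurate at any fixed mesh; velocity
  exports therefore use area-weighted nodal averaging.
* The finite-difference oracle shares the *problem statement* with the
  finite-element path but not its discretization; agreement bounds
  discretization error, not modelling error.
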