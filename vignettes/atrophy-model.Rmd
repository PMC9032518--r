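---
title: "Coupled biomarker spreading and morphoelastic brain atrophy: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled biomarker spreading and morphoelastic brain atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the continuum model and its assumptions, the parameters that matter, what
the synthetic phantom does and does not emulate, the numerical choices,
and the design decisions taken where the problem was genuinely open.

## The coupled model

Cerebral atrophy — the progressive loss of brain tissue with age, and its
acceleration in Alzheimer's disease (AD) — is treated here as a coupled
multiphysics problem on a labeled domain with five regions: white matter
(WM), gray matter (GM), hippocampus, ventricles, and cerebrospinal fluid
(CSF).

**Spreading.** A normalized misfolded-protein concentration $c \in [0,1]$
obeys the Fisher–Kolmogorov equation
$$\partial_t c = d\,\Delta c + \alpha\, c\,(1-c),$$
with isotropic diffusivity $d$ per region (zero in the fluid regions, so
they exchange no diffusive flux) and logistic growth rate $\alpha$. The
growth rate is the reparameterization of a two-species kinetic model
(healthy protein produced at $k_0$, cleared at $k_1$; misfolded protein
cleared at $\tilde k_1$ and recruited at conversion rate $k_{12}$):
$\alpha = k_{12}k_0/k_1 - \tilde k_1$, exposed as `kinetic_alpha()`.
Zero-flux conditions hold on the exterior boundary: the protein stays in
the intracranial space. In AD mode the field is seeded at $c_0 = 0.3$ in
the hippocampus; healthy mode never solves the spreading problem.

**Atrophy kinetics.** The atrophy factor $\vartheta \in (0,1]$ is the
fraction of local tissue measure retained. It decays at a constant
healthy rate that switches to an accelerated rate once the local
biomarker exceeds a critical load $c^{\mathrm{crit}}$:
$$\dot\vartheta = -\bigl[G_h + G_c\,H(c - c^{\mathrm{crit}})\bigr],
\qquad H(x) = \frac{1}{1+e^{-\beta x}}.$$
The smooth step $H$ *increases* with $c$ — activation by biomarker load —
which is the orientation demanded by the two-branch definition of the
rate ($G_h$ below threshold, $G_h + G_c$ above). Two printed-source sign
conventions in circulation are corrected here on that ground: the decay
form above (atrophy shrinks, $\vartheta \le 1$, as every reported result
shows) and the increasing step. $\vartheta$ is integrated pointwise by
one explicit finite-difference update per increment,
$\vartheta_{n+1} = \vartheta_n - [G_h + G_c H]\,\Delta t$, stored as a
quadrature-point state variable.

**Mechanics.** Atrophy is negative growth in the morphoelastic sense: the
deformation gradient splits multiplicatively,
$$\mathbf F = \mathbf F^e \mathbf F^a, \qquad
\mathbf F^a = \vartheta^{1/\mathrm{dim}}\,\mathbf I,$$
so $\det\mathbf F^a = \vartheta$ exactly and only the elastic part
$\mathbf F^e$ generates stress, through the atrophy-weighted compressible
neo-Hookean energy
$$\Psi_0 = \vartheta\Bigl[\tfrac{\mu}{2}\bigl(\mathbf F^e{:}\mathbf F^e
 - \mathrm{dim} - 2\ln J^e\bigr) + \tfrac{\lambda}{2}\ln^2 J^e\Bigr].$$
The first Piola–Kirchhoff stress is the *exact* derivative
$\mathbf P = \partial\Psi_0/\partial\mathbf F$, which carries a
$\vartheta^{1-1/\mathrm{dim}}$ prefactor on the intermediate-configuration
stress through the chain rule $\mathbf F^e = \vartheta^{-1/\mathrm{dim}}\mathbf F$
(and requires the compressible term to involve $\mathbf F^{e-T}$, not
$\mathbf F^{eT}$). We do not rely on getting this algebra right by eye: a
finite-difference work-conjugacy test ($10^3$ random states, relative
error $<10^{-6}$) pins the implementation to the energy. Quasistatic
equilibrium $\mathrm{Div}\,\mathbf P = \mathbf 0$ holds with zero body
force; the only essential boundary condition is zero displacement on the
outer surface of the CSF layer, a skull proxy that suspends the brain
rather than pinning interior structures. `cauchy_stress_and_tangent()`
additionally exposes $\boldsymbol\sigma = J^{-1}\mathbf P\mathbf F^T$ and
the Jaumann-rate spatial tangent (material push-forward plus
stress-geometric terms), verified against finite differences of the
Kirchhoff stress under symmetric velocity-gradient perturbations.

**Coupling direction.** The driver is a one-way staggered loop per time
increment: advance $c$ (AD only), update $\vartheta$ from $c$ interpolated
at the element quadrature point, re-solve equilibrium. Deformation does
not feed back into diffusion; the spreading problem lives on the
reference configuration. This matches the usual operator-split treatment
of slow growth problems, and at atrophy rates of order $10^{-3}$/yr the
neglected geometric feedback over 40 years is a few percent of a field
that is itself diffusively smeared.

## Parameters

| Region | $\lambda$ [kPa] | $\mu$ [kPa] | $G_h$ [1/yr] | $G_c$ [1/yr] | $c^{\mathrm{crit}}$ | $d$ [mm²/yr] | $\alpha$ [1/yr] |
|---|---|---|---|---|---|---|---|
| WM | 64.67 | 2 | 0.0015 | 0.0035 | 0.5 | 15 | 0.09 |
| GM | 32.33 | 1 | 0.001 | 0.002 | 0.5 | 15 | 0.09 |
| Hippocampus | 32.33 | 1 | 0.001 | 0.002 | 0.5 | 15 | 0.09 |
| Ventricles | 29.77 | 15.34 | — | — | — | 0 | 0.09 |
| CSF | 7.22 | 14.43 | — | — | — | 0 | 0.09 |

`default_materials()` reproduces this table. Notes on the entries and on
values we had to decide:

* **Units of $d$.** The diffusivity is stated in the source literature in
  thermal-analogy units that do not convert unambiguously. We read
  $d = 15$ mm²/yr: with $\alpha = 0.09$/yr this gives a front speed
  $2\sqrt{d\alpha} = 2.32$ mm/yr, i.e. ~93 mm in 40 years — the scale of
  whole-brain infiltration over a disease course. This is a declared
  interpretation, not a measured fact.
* **$\beta = 50$** (transition width $\approx 0.1$ in $c$): sharp enough
  that the accelerated branch is effectively on/off, smooth enough for
  implicit solvers. No published value exists; it is configurable.
* **Atrophy floor 0.5.** $\vartheta$ is clamped (with a warning) at 0.5
  to keep $\det\mathbf F^a$ away from zero. At tabulated rates the
  40-year maximum loss is 0.2, so the floor is never active in the study
  conditions; it only guards pathological configurations.
* **Fluid stiffness.** The tabulated ventricle/CSF shear moduli exceed
  GM's by an order of magnitude, while the narrative description of the
  same simulations calls the CSF an ultrasoft, highly compressible
  suspension. Which was actually run cannot be recovered. The package
  default follows the table literally; `materials_ultrasoft_csf()`
  provides the suspension reading ($\mu = 0.01$ kPa fluids). The
  consequences are discussed under *Limitations* — several morphometric
  trends flip between the two regimes.

Simulation defaults: 40 simulated years at $\Delta t = 0.1$ yr (400
increments), Newton tolerance $10^{-8}$ on the residual infinity norm.

## The phantom

Subject-specific meshes derived from MRI are not reproducible artifacts;
the phantom is. `build_brain_phantom()` builds, deterministically from
its parameters, a coronal-slice analog with the anatomical structure the
physics and the morphometry need:

* nested star-shaped rings stitched into a conforming triangle mesh
  (~5100 elements at the default 2.15 mm target edge, inside the
  2.0–2.3 mm band used for the reference meshes);
* an elliptical ventricular cavity meshed as a solid subdomain (the
  material table assigns the ventricles elastic constants, so they are a
  region, not a hole);
* a WM core whose outer boundary carries `n_folds = 5` sinusoidal gyral
  folds; feasibility is validated (offset curvature and inter-gyral gap
  `fold_gap > 0`), so the pial surface never self-contacts — gyral
  separation under atrophy stays representable, at the cost of wide,
  shallow folds (see *Limitations*);
* a GM ribbon of spatially constant thickness (3 mm) offset outward
  along the WM boundary normal — the same "inflate the WM surface"
  construction used for the reference geometry;
* a hippocampal crescent: WM elements within `hippocampus_radius` of a
  center placed against the inferior ventricular boundary. The default
  radius (14 mm) is deliberately generous — a stand-in for the whole
  medial-temporal complex — and is sized at the Fisher length
  $\sqrt{d/\alpha} \approx 12.9$ mm of the spreading problem. A much
  smaller seed at this domain scale is annihilated by diffusive dilution
  (measured: a 6 mm seed never reaches $c^{\mathrm{crit}}$ in 40 years),
  which would silently turn AD mode into healthy mode. With the default,
  threshold crossing begins at $\approx 37$ yr — accelerated atrophy
  switches on late in the simulated span, the qualitative analog of AD
  trajectories diverging from healthy aging in late life;
* a 5 mm CSF layer whose outer boundary is a *partially smoothed*
  envelope of the pial folds (`csf_smoothing`, default 2.5 mm of
  amplitude decay): sulcal troughs hold thicker fluid wedges than
  crests, as a smoothed fluid envelope should. Full smoothing to a
  convex envelope is impossible without violating the uniform element
  size, because the crest-side fluid would become thinner than one
  element;
* named sulcal pockets: the CSF elements inside the convex hull of the
  pial surface, partitioned by nearest inter-gyral trough and given the
  five classical sulcus names, so widening can be summed per sulcus;
* `dimension = 3` extrudes the slice into a conforming tetrahedral slab
  (consistent prism splitting by a node-index diagonal rule); all
  solvers are dimension-agnostic.

What the phantom does **not** emulate: deep, narrow, nearly-touching
sulci (excluded by the no-self-contact constraint plus the uniform edge
length); left-right hemispheric anatomy; any subject-specific geometry.
Consequently, absolute morphometric values (gyrification index
$\approx 1.03$ versus $\approx 2.5$ for a human brain; thickness maps;
displacement magnitudes) are not comparable to imaging studies — only
mechanisms, orderings, and relative changes are meaningful, and tests are
written accordingly.

## Numerics

* **Space.** Linear simplicial elements (P1), single-point quadrature —
  the element family used by the reference simulations. Assembly is
  vectorized over elements; tangents are exact (the same closed-form
  $\partial\mathbf P/\partial\mathbf F$ verified by finite differences),
  so Newton converges quadratically and typically needs two iterations
  per increment with warm starts.
* **Time.** Backward Euler for the spreading equation with Newton on the
  logistic source; measured against the closed-form logistic, the
  homogeneous solve at $\Delta t = 0.01$ yr stays within $3.5\times
  10^{-5}$ of the exact solution over 40 years — inside the $10^{-4}$
  oracle budget, so no higher-order scheme is needed.
* **Bounds.** A lumped (diagonal) mass matrix plus clipping to $[0,1]$
  after each step; clipped mass beyond $10^{-6}$ is reported. Galerkin
  transport can overshoot and the model's meaning requires
  $c \in [0,1]$; with lumping the clip is a safety net, not a crutch.
* **2D convention.** Plane strain, with
  $\mathbf F^a = \vartheta^{1/2}\mathbf I_2$, so $\vartheta$ measures
  in-plane *area* loss in 2D exactly as it measures volume loss in 3D.
* **Equilibrium.** Newton with a backtracking line search on the residual
  norm; on failure the driver bisects the atrophy increment (up to four
  levels) and retries. Dirichlet dofs are eliminated by reduction.
* **Degenerate inputs.** Element inversion ($\det\mathbf F \le 0$) stops
  the solve with the offending element; infeasible phantom geometry
  (self-intersecting offsets, non-positive fold gap, hippocampus not
  adjacent to the ventricle) is rejected at parameter validation with a
  descriptive message.
* **Morphometry.** In 2D the gyrification index is the exact polygon
  ratio (pial contour length over convex-hull perimeter); rasterization
  is used only for 3D slices, at 0.5 mm pixels, where the mask contour
  carries a few percent of staircase bias — the same bias any
  binary-image pipeline has. Cortical thickness is the two-way
  nearest-node measure $t_c = \tfrac12(d_{ij} + d_{jk})$ between pial
  and WM surfaces, computed with a grid-bucket nearest-neighbor search
  whose exactness is enforced against an $O(n^2)$ oracle. Volume
  fractions are emitted under both denominators ("brain" =
  WM+GM+hippocampus+ventricles, and "intracranial" including CSF)
  because the conventions in cross-sectional reports are inconsistent;
  outputs are labeled.
* **Front-speed measurements.** Pulled Fisher–Kolmogorov fronts approach
  $2\sqrt{d\alpha}$ only like $1/t$ (the logarithmic front shift), an
  offset of $\tfrac{3}{2t}\sqrt{d/\alpha} \approx 0.4$ mm/yr at
  $t = 45$ yr. Speed checks therefore fit the front trajectory late — on
  a 400 mm bar over $t \in [100, 160]$ yr — where the measured speed sits
  within 10% of the asymptote. Early windows under-read the speed by
  >20% regardless of discretization.

Problem sizes used throughout the tests: the ~5k-element default phantom
with 400 increments for the coupled 40-year runs (a few minutes each), a
coarse ~1.5k-element phantom for unit tests, and sub-second analytic
fixtures elsewhere.

## Limitations and known behavior

* **Late biomarker activation.** At desk scale with $d = 15$ mm²/yr,
  even the Fisher-length seed crosses $c^{\mathrm{crit}} = 0.5$ only at
  ~37 of 40 years, so the AD/healthy contrast is concentrated in the
  final years: the minimum atrophy factor reaches ~0.93 rather than the
  accelerated-limit bound $1 - (G_h+G_c)\cdot 40 = 0.80$. A comparison
  principle makes this unavoidable under the activation-consistent step
  orientation: no point can cross $c^{\mathrm{crit}}$ before the uniform
  logistic from $c_0 = 0.3$ does (9.4 yr), which already bounds the
  40-year minimum above 0.83; published figures below that bound can
  only arise from the inverted (as-printed) step orientation that
  accelerates atrophy *below* threshold.
* **Fluid-stiffness regime trade-off.** With the literal (stiff) fluid
  table, the anchored CSF tethers the cortex: the ventricle inflates
  (expansion factor ~1.05 over 40 years), tissue volume is replaced by
  fluid, and all sulcal pockets widen monotonically — but the gyral
  crests are held while troughs sink, so folds *deepen* slightly (GI
  +0.2% instead of decreasing) and the stretched GM ribbon reads as
  mildly thickened. With the ultrasoft preset the brain contracts freely:
  cortical thinning and stronger sulcal widening appear, and the AD
  hippocampus shrinks more than the healthy one — but the ventricular
  cavity now *shrinks* with the contracting brain. Ventricular
  enlargement and gyral smoothing thus require mutually incompatible
  fluid regimes on this phantom; the subject-scale geometry with deep
  folds may reconcile them, the shallow-fold slice cannot. Tests assert
  the orderings under the default (stiff) table and the GI ordering is
  the known failure.
* **No contact mechanics.** The fold gap is sized so shrinkage never
  produces interpenetration; a geometric self-intersection check exists,
  but touching gyri are out of scope by construction.
* **One-way coupling** (no advection of the biomarker by deformation, no
  back-reaction), isotropic diffusion only (no fiber-tract anisotropy),
  single-species biomarker.
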