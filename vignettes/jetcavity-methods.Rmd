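---
title: "Models and methods behind jetcavity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind jetcavity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jetcavity)
```

## The physical problem

A micrometre-scale liquid jet (diameter 50-120 um, speed 8-69.5 m/s)
strikes a capillary bridge: a millimetre-scale droplet or agarose gel
volume held between two parallel walls 1 mm apart by surface tension. The
impact opens an air cavity that expands, stops, and collapses; depending
on the impact Weber number and the target's rheology the collapse either
retracts cleanly or pinches off and traps bubbles. This geometry is a
model for needle-free injection into confined or wrinkled tissue, where
agarose gels are the standard skin surrogate and entrained bubbles spoil
the injection.

The package covers the quantitative chain end to end: material records
and dimensionless groups; forward models of cavity expansion; a
traverse/embed criterion; seal-regime classification; wettability
energetics on the walls; shadowgraph metrology; and a seeded synthetic
renderer that closes the loop for testing.

## Dimensionless groups

For a jet (density $\rho_0$, diameter $D_0$, speed $U_0$) impacting a
target (density $\rho_{cb}$, viscosity $\mu_{cb}$, surface tension
$\gamma_{cb}$):

$$\mathrm{We} = \frac{\rho_0 D_0 U_0^2}{\gamma_{cb}}, \qquad
\mathrm{Fr} = \frac{U_0^2}{g D_0}, \qquad
\mathrm{Oh}(D) = \frac{\mu_{cb}}{\sqrt{\rho_{cb}\gamma_{cb} D}}.$$

The Weber number deliberately mixes jet inertia with the *target's*
surface tension — that is the form used throughout. The Ohnesorge number
is computed at two scales: the jet diameter (`Oh`) and the bridge
diameter (`Oh_cb`). The seal-regime rules are stated on the bridge scale:
on the jet scale water sits at $\mathrm{Oh}\approx 0.012$ and could never
satisfy the low-viscosity surface-seal bound $\mathrm{Oh}\lesssim 0.004$,
whereas on the bridge scale water gives $0.0015$ and the 78 wt% glycerol
solution $0.063$, exactly separating the materials that do and do not
show surface seal. Both numbers are reported so the user can choose.

The viscoelastic targets carry a Deborah number
$\mathrm{De} = \lambda/\tau_c$. The capillary time defaults to the
dimensionally consistent $\tau_c = \sqrt{\rho_{cb} D_{cb}^3/\gamma_{cb}}$;
the literal combination $\rho_{cb}D_{cb}/\gamma_{cb}$ (which is not a
time) is available behind `form = "literal"` for comparison with sources
that print it that way. Gels carry the elastic Froude number
$\mathrm{Fr_e} = \rho_{cb}U_0^2/G$.

Agarose surface tension and viscosity follow the linear relations
$\gamma = 0.001022\,G + 0.072292$ (N/m) and
$\mu = 6.005\times 10^{-5}\,G + 0.00834$ (Pa s). These were calibrated on
dilute gels ($G \lesssim 200$ Pa); the bundled material table stores the
*measured* values and never recomputes them from the relations, because
extrapolating the surface-tension relation to stiff gels is the leading
suspect for the traversal misfit there (see below).

## Cavity expansion models

**Inertial parabolic profile.** During expansion ($\mathrm{We}\gg 1$,
$\mathrm{Re}\gg 1$) the cavity front advances linearly,
$H_c(t) = U_c t$ with $U_c \approx U_0/2$, and each axial station $x$
starts expanding radially when the front passes it at $t_0(x) = x/U_c$.
Momentum conservation of the radial flow makes $R^2$ grow linearly in
time:
$$R(x,t)^2 = C_R\, D_0\,(U_c t - x), \qquad C_R = 1 \text{ (default)},$$
a parabola with its apex at the front. Note that the alternative
normalisation $t_0 = (x/H_c)\,t$ coincides with $x/U_c$ identically under
linear front growth, so no separate option is needed.

**2D Rayleigh equation.** The radial dynamics oracle is the cylindrical
(two-dimensional) Rayleigh equation with a logarithmically cut-off
inertia,
$$\rho\,\ln(R_\infty/R)\,(R\ddot R + \dot R^2)
  = p(t) - \frac{\gamma}{R} - \frac{4\mu\dot R}{R},$$
integrated with `deSolve::lsoda` at relative tolerance $10^{-8}$ and
absolute tolerance $10^{-12}$. After an impulsive driving the coasting
solution conserves $R\dot R$, i.e. $R\propto (t-t_0)^{1/2}$ — the law the
parabolic profile is built on; the test suite verifies the fitted
log-log exponent is $0.50 \pm 0.02$ and that halving the output step
changes the solution by less than $10^{-6}$ relative. $R_\infty$ is the
outer cutoff of the radial flow (physically the confinement scale); the
predictions depend on it only logarithmically, but it must exceed any
radius reached (the integrator validates this).

**Viscous droplet cavity and train superposition.** For viscous targets
the jet is replaced by its droplet-train equivalent. A drop of radius
$r_d$ at speed $U_d$ drives the cavity with its impact-pressure scale
$\rho_0 U_d^2$ for the crossing time $2r_d/U_d$, after which the cavity
coasts against the boundary-layer shear term $4\mu\dot R/R$. Each drop's
cavity starts from rest at $R(0) = 10^{-3} r_d$; surface tension is off
by default during the forced expansion (the impacts of interest have
$\mathrm{We}\gg 1$, and at the $10^{-3} r_d$ initial scale a capillary
term would unphysically forbid the cavity from opening).

Volume equivalence fixes the train geometry: $r_{cyl} = D_0/2$,
$r_d = r_{cyl}\sqrt{3/(2f)}$, $h_{cyl} = 2r_d/f$, where $f$ is the train
frequency parameter ($f = 1/2$ default). The train's cavity speed comes
from a duty-cycle momentum balance at the front — drops strike over their
own cross-section a fraction $f$ of the time —
$$f\rho (U_d - U_c)^2 = \rho U_c^2 \;\Rightarrow\;
U_c = U_d\frac{\sqrt f}{1+\sqrt f},$$
which recovers the continuous-jet $U_c = U_d/2$ at $f = 1$; $U_d$ is then
chosen so the train reproduces the jet's $U_c$ (exactly, by
construction). The composite profile time-shifts successive drops by
$h_{cyl}/U_d$, places them at the instantaneous front, and combines
contributions by pointwise maximum — a rule chosen because it preserves
non-negativity and monotone growth. The front of the composite equals the
inertial front by construction; its mouth radius carries an $O(1)$
prefactor set by the logarithmic cutoff, and agrees with the parabolic
profile within a factor of order unity rather than to a few percent. That
looseness is inherent to the log-cutoff ambiguity and is asserted as such
in the tests.

**Cavity-velocity prediction.** The measured $U_c/U_0$ lies below the
ideal 1/2 for every target. The model balances stagnation pressures with
viscous normal stresses on both sides of the front,
$$\rho_0(U_0-U_c)^2 - \frac{C\mu_0 (U_0-U_c)}{D_0}
  = \rho_{cb}U_c^2 + \frac{C\mu_{cb}U_c}{D_0},\quad C = 4,$$
solved for $U_c$ by bisection to $10^{-12}$. It recovers $U_0/2$ in the
density-matched inviscid limit, is strictly decreasing in target
viscosity, and predicts $U_c/U_0 < 0.5$ for every bundled material.
Wall-confinement dissipation (which lowers the measured ratios further)
is *not* modelled; neither are jet break-up and the enlarged jet head,
which make the real mouth radius larger than the parabolic prediction.

## Traverse or embed

Surface tension dominates the collapse. The jet front leaves the cavity
wall a radial impulse per unit area of order $\rho_{cb}D_0U_c$; the
capillary pressure at the jet scale, $2\gamma_{cb}/D_0$, removes it in
$$t_c = \frac{\rho_{cb} D_0^2 U_c}{2\gamma_{cb}},$$
about 0.6 ms at the study's conditions. The maximum depth is
$H_{max} = (U_0/2)\,t_c$, and requiring $H_{max} = D_{cb}$ defines the
critical Weber number
$$\mathrm{We}^* = 8\,\frac{\rho_0}{\rho_{cb}}\,\frac{D_{cb}}{D_0},$$
exactly self-consistent with the depth criterion (verified to $10^{-9}$
in the tests). The classifier uses the boundary
$\mathrm{We}/\mathrm{We}^* \ge 0.7$ (traverse), the value established for
unconfined pendant droplets; the boundary is closed (a ratio exactly at
the threshold traverses) and configurable, since confinement is known to
raise the true boundary. Assessments of viscoelastic targets and stiff
gels carry explicit caveats (deviations of ~50%, ~30%, and one order of
magnitude respectively for the PEO solutions, the 536 Pa gel and the
3961 Pa gel) encoded in a small misfit registry.

## Seal regimes and bubbles

Observed cavities are partitioned in definitional order: **surface seal**
if an overarching dome closes on the entry side while the front still
advances; else **deep seal** if any pinch lies deeper than $L_{max}/3$;
else **shallow seal** if any pinch occurred (operationalised as
$x_p \le L_{max}/3$, the complement that makes the partition exhaustive
and exclusive); else **no seal**. Pinches beyond $L_{max}$ are rejected
as inconsistent.

The predictive rule applies material class first: gels always
shallow-seal; viscoelastic solutions deep-seal inside their observed
Weber windows (closed intervals: 500-600, 400-700, 500-900 for the three
PEO solutions, union 400-900 when the solution is not named); Newtonian
liquids with $\mathrm{Oh}_{cb}\le 0.004$ and $\mathrm{We}\le 700$ are
surface-seal candidates; everything else no-seal. The upper Weber bound
for surface seal is implemented as stated even though surface seal
classically appears at *high* We — within the studied window the stated
bound is what the data show. In the no-seal population, the collapse time
grows linearly with the maximum cavity area; `fit_collapse_scaling()`
fits that law by least squares and the tests verify slope recovery within
two standard errors on seeded noisy draws.

Expected bubble outcomes per regime are qualitative bands: none for no
seal; several pinch bubbles with area ratio at most 0.6 for deep seal;
several small bubbles at a ratio near 0.5 for shallow seal; one large
bubble at a ratio near 1 for surface seal.

## Wettability energetics

The Laplace pressure of the bridge uses the axial-curvature form
$$\Delta P = -\frac{2\gamma_{cb}\cos\theta_E}{H},$$
negative for a concave (hydrophilic) bridge and positive for a convex
(hydrophobic) one. The variant with the in-plane term
$+\gamma_{cb}/R_c$ is available behind `form = "full"`, but the
axial-only form is the default because it is the one that reproduces both
measured adhesion forces: with $\gamma = 72.1$ mN/m, $H = 1$ mm,
$$F_a = 2\pi\gamma_{cb}R_c\sin\theta_E - \pi R_c^2\,\Delta P$$
gives $+3.05$ mN on glass ($\theta_E = 23^\circ$, $R_c = 2.5$ mm) and
$-1.24$ mN on the hydrophobic coating ($\theta_E = 160^\circ$,
$R_c = 1.9$ mm), against measured values of about $+3$ and $-1.2$ mN
(the in-plane variant gives 2.48 and $-1.67$ mN and is rejected).

Contact-angle hysteresis sets the contact-line pinning force
$\Phi_{cl} = |2\pi R_c\gamma_{cb}(\cos\theta_a - \cos\theta_r)|$ (units
of force; $1.39\times10^{-4}$ N for an 18-degree hysteresis split
symmetrically about $23^\circ$). Converting it to an energy requires a
contact-line travel distance that is a property of the individual
collapse event; `dissipation_energy()` takes it as an explicit input
rather than assuming one. A Worthington jet is deemed energetically
favourable when that dissipation energy is below half the jet kinetic
energy $E_k = (\pi/8)\rho_0U_0^2D_0^2L_0$ *and* the adhesion force is
non-attractive — true for hydrophobic walls, false for hydrophilic ones,
and categorically false for mixed hydrophilic-hydrophobic walls, where
the cavity collapses asymmetrically (encoded as a rule, not simulated).

## Shadowgraph metrology

Frames are grayscale matrices in $[0,1]$, rows transverse, columns axial,
dark = liquid/gel; defaults follow the study's recording: 50k frames per
second and 10 um per pixel (768 px span 7.7 mm, comfortably holding a
6 mm bridge). Segmentation is Otsu or a fixed threshold, established on
the first frame and reused across the stack for consistency. The cavity
profile is measured columnwise: for each 1-px axial bin the half-width is
half the bright run at the axis row, accepted only when the run is
bounded by dark bridge material on **both** sides, and averaged over the
two sides. The front is the furthest bin with cavity present; the front
velocity is the slope of a linear fit over the expansion frames with a
strictly advancing front (plateau frames at a saturated front would bias
the slope low and are excluded). Analysis windows end at the first
closed-cavity frame after opening, so post-collapse bubble frames never
contaminate the cavity kinematics.

Pinches are interior runs (at least 2 px) of closed columns between open
ones; gap centres are clustered within 50 um into distinct events. Bubble
metrology on the final frame follows the optical rules of the study: the
detection floor is 100 um (10 px); clusters with gaps below the floor are
merged by morphological closing with a disk of radius half the floor; a
merged bubble is counted when its spatial extent or equivalent diameter
reaches the floor, and its reported area is the combined *original* area
of the cluster. The total area $A_{total}$ is the dark area including
bubble interiors (hole filling), and $A_{bubbles}/A_{total} \in [0,1]$ by
construction. All outputs scale exactly with `pixel_size` and `dt`, and
re-running on identical input is bit-identical.

## The synthetic generator

`sample_experiment()` draws the study's conditions: a material uniformly
from the bundled table, $U_0 \sim U[8, 69.5]$ m/s,
$D_0 \sim U[50, 120]$ um, a 6 mm bridge between walls 1 mm apart. Truth
kinematics come from the package's own models ($U_c$ from the
cavity-velocity model, depth from the traversal model, regime from the
predictive seal rule with $\mathrm{Oh}_{cb}$); the rendered depth is
floored so the expansion spans at least 8 frames (front-velocity
metrology needs a fittable expansion) and capped at 75% of the bridge.
The collapse time follows the linear area law with slope 600 s/m^2 — a
value chosen once to put millimetre-square cavities at millisecond
collapse times, the scale of the study's events — floored at 8 frames.

`render_stack()` draws, per frame: the bright background (gray 0.88), the
dark bridge disk (0.12) vertically cropped by the 328-px sensor as in the
real field of view, the incoming jet column, the parabolic cavity clipped
one pixel inside the local bridge chord (so every cavity column keeps a
dark wall), the regime's seal event (a 7-px pinch gap appearing during
retraction at the planned $x_p$; or a dome closing the mouth at 60% of
the expansion for surface seal), two guaranteed closed-bridge frames
after collapse, and finally the entrained bubbles (non-overlapping bright
disks, radius at least 8 px, mutual gaps above the merge floor). Bubble
content targets the regime's area-ratio band; when random packing cannot
place the requested area the radii shrink, and the truth records what was
*actually drawn* — pixel-exact areas, counts, times — so closed-loop
comparisons are against the rendered scene, not the plan. Noise is
additive clipped Gaussian in gray levels (0-255 scale), seeded and
reproducible.

What the renderer does **not** emulate: jet break-up and the enlarged jet
head, surface waves on the cavity, refraction and lighting gradients,
antibubbles, Worthington-jet droplets, and area ratios near 1 for surface
seal (a strictly interior bubble cannot cover the whole dark area; the
rendered ratios for surface seal sit near 0.2-0.7). Passing closed-loop
tests therefore demonstrate the correctness of the metrology chain on
idealised scenes, not robustness to every artefact of real shadowgraphs.

## Numerical choices and limitations

* ODE tolerances $10^{-8}$/$10^{-12}$; profile grids default to 512 axial
  samples; thresholds and variants (0.7 boundary, 100 um floor,
  $f = 1/2$, Laplace form) are all surfaced in configuration.
* The traversal model is exact only in its own terms: the registry warns
  that measured thresholds deviate ~50% for viscoelastic targets, ~30%
  for the 536 Pa gel, and an order of magnitude for the 3961 Pa gel
  (attributed to surface-tension over-extrapolation, not modelled here).
* Test problem sizes: the closed-loop suite uses 100 seeded experiments
  of up to 250 frames at the full 768 x 328 resolution; the ODE oracles
  use a few hundred output points. These sizes were chosen to exercise
  every regime while keeping the full suite comfortably runnable on one
  CPU.
* The equations printed here are the package's own derivations of
  standard results (2D Rayleigh cavity dynamics, water-entry momentum
  balances, capillary-bridge statics); prefactors such as $C_R$, $C$ and
  the collapse-time constant are order-one choices exposed as arguments,
  not fitted quantities.

## Worked micro-example

```{r example}
water <- as_material("water")
jet <- jet_spec(U_0 = 19.6, D_0 = 93e-6)
dimensionless_set(jet, water)
assess_traversal(jet, water)
```
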