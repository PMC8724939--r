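---
title: "Inverse estimation of loss factor and moisture diffusivity during microwave drying"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse estimation of loss factor and moisture diffusivity during microwave drying}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedwave)
```

## The problem

A seed in a microwave cavity heats volumetrically while it dries. How strongly
it couples to the field is set by its dielectric loss factor
$\varepsilon''$, and how fast moisture leaves is set by its effective
moisture diffusivity $D$. Both change continuously during processing because
both depend on temperature and moisture content — and measuring them directly
over the whole $(T, M)$ path a kernel traverses in a few minutes is
impractical. `seedwave` instead treats the two routinely measured process
curves — mean surface temperature and moisture content of a thin drying layer
of red lentil — as the data of an inverse problem: find parametric models
$\varepsilon''(T', M)$ and $D(T, M)$ such that a physics-based forward
simulation of a single kernel reproduces both curves.

## Forward model

A lentil seed is idealised as a biconvex lens (two spherical caps, default
diameter 4.4 mm, thickness 2.2 mm), homogeneous and isotropic, with no
shrinkage. On the axisymmetric cross-section the coupled balance equations
are

$$\rho C_p \frac{\partial T}{\partial t}
  = \nabla\cdot(k_{eff}\nabla T) + q_{MW} - H_{evap} M_v,
  \qquad
  \frac{\partial M}{\partial t} = \nabla\cdot(D\,\nabla M),$$

with $q_{MW} = 2\pi f \varepsilon_0 \varepsilon'' E^2$ the microwave source
(uniform field: the penetration depth in lentil, ~2 cm at 2.45 GHz, far
exceeds the 2.2 mm kernel thickness) and $M_v = -\rho\,\partial M/\partial t$
the volumetric evaporation rate, which dominates liquid transport during
intense thin-layer microwave drying. Density, specific heat, conductivity and
latent heat follow published lentil correlations (`lentil_density()` etc.).
Both curved faces exchange heat and moisture with the cavity air through
Robin conditions parameterised by Biot numbers, $h = Bi_c\,k/L$ and
$h_m = Bi_m\,D/L$, with $L = V/A = 0.48$ mm the characteristic length of the
default geometry; the equilibrium moisture content is zero and the ambient
air is 296.15 K. Biot numbers are held constant through the process while the
transfer coefficients track the evolving local $k$ and $D$ (a config flag
freezes them at their initial values instead).

Two unit conventions deserve emphasis because the source correlations mix
them: the specific-heat and loss-factor polynomials take temperature in
degrees Celsius, while both exponentials of the diffusivity model take
kelvin. The specific heat evaluated in kelvin would exceed 4 kJ/kg/K for
moist lentil — close to liquid water and implausible for a starchy seed —
which is why the Celsius reading is used. Likewise the Arrhenius pairing is
$E_a\,[\mathrm{kJ/mol}] \times 10^3 / (8.3143\,T)$: this reproduces
diffusivities of order $10^{-8}$–$10^{-7}$ m$^2$/s, the documented range for
legumes, whereas other unit pairings miss by orders of magnitude.

The parametric property models are
$$\varepsilon'' = g_0 + g_1 T' + g_2 T'^2 + 100\,g_3 M + 100\,g_4 M T'
   + g_5 A + g_6 A^2 + g_7 A T', \qquad A = \frac{\mathrm{ash}_{db}}{1+M},$$
$$D = D_0\,e^{-E_a 10^3/(R T)}\, e^{(a_0 T - a_1) M}.$$
The ash content enters on a wet basis (dry-basis ash is conserved during
drying, so $A$ varies only through $M$). Its value is configurable and
defaults to 2.6 % d.b., a typical red-lentil ash content; with the packaged
average coefficients it places the loss factor in the 1.4–4.0 band expected for moist red lentil at these states
and yields $\varepsilon'' \approx 3.97$ at the hottest treatment's final
state, at the hottest final state. Because the ash terms are constant up
to the slow $1/(1+M)$ drift, individual $g$ coefficients are only meaningful
jointly with the assumed ash content — one reason the package's recovery
contracts are stated on the $\varepsilon''$ *trajectory*, not on raw
coefficients.

The electric field strength comes from the magnetron available power and the
cavity reflection coefficient, $E = \sqrt{2 P_{av}/(1-|S_{11}|^2)}$ in V/cm
(converted to V/m). The alternative rendering
$\sqrt{2P_{av}(1-|S_{11}|^2)}$ and a direct `E` override are selectable;
since a constant field miscalibration is absorbed by a rescaling of the
fitted $g$ coefficients, the inverse estimates of the *heating trajectory*
are invariant to this choice.

### Discretisation

Linear (P1) triangles on a mapped structured mesh of the half cross-section
(`generate_mesh()`): radial node columns scaled to the cap profile, collapsing
to a single rim node, curved boundary tagged convective and the axis tagged
symmetric. The default edge length (0.1 mm) gives 507 nodes and 946
triangles. All axisymmetric integrals carry the $2\pi r$ weight; the
r-weighted lumped mass (row sums of the consistent mass matrix, exact for
linear $r$) and a one-point radial quadrature for the stiffness (exact for P1
gradients) make insulated mass conservation hold to machine precision, which
the tests assert at $10^{-8}$ per step. Time marching is segregated backward
Euler — one implicit moisture step, then one implicit heat step per
$\Delta t$ (default 0.5 s), with property coefficients lagged to the start of
the step; the coupling through $D(T, M)$, $\varepsilon''(T', M)$ and the
evaporative sink is smooth, so lagging keeps each step linear at first-order
cost. The evaporation sink is applied nodewise from the discrete moisture
rate. Linear systems (~500 unknowns) are solved directly; below 400 unknowns
a dense LAPACK path avoids sparse-construction overhead, which matters when
the optimiser calls the solver thousands of times. Runs abort with
diagnostics if $|T| > 600$ K or $M < -10^{-6}$ (dielectric runaway after
complete dry-out is physical — drying is normally stopped once the moisture
returns to 0.10 d.b., and `run_forward(stop_below_M =)` mirrors that).

Validation is oracle-based rather than reference-based: at small Biot
numbers the solution must collapse to lumped capacitance, and it does —
within 1 % (mass) and 2 % of the rise (heat) of independently integrated
lumped ODEs; energy bookkeeping on insulated runs closes to 1 %; halving the
time step or the mesh size moves the end state by well under 1 %. One caveat
on "near-uniform" internal fields: with a volumetric source the steady
centre-to-surface gap is $\sim q\,(t/2)^2/(2k)$ regardless of how small the
Biot number is, and at the calibrated field strength this is several kelvin
(≈8 % of the body-to-ambient difference). The tests therefore assert
near-uniformity at 10 %, and leave the small-Biot *validation* to the lumped
oracles.

## The two-stage inverse estimation

Fourteen quantities could in principle be estimated per treatment: eight
$g$'s, four diffusivity coefficients, and the two Biot numbers. The
estimation (`estimate_treatment()`) proceeds in two stages.

**Stage 1 — decoupled lumped fits.** Assuming the kernel uniform at the
measured state, the mass balance collapses to
$dM/dt = -(Bi_m D(T(t), M)/L^2)(M - M_e)$ and the energy balance to its
lumped analogue including the evaporative sink. Both measured series are
first smoothed by a five-harmonic Fourier series with free fundamental
frequency (`fit_fourier()`; for fixed frequency the problem is linear, so the
frequency is profiled on a grid and refined — deterministic, no starting-value
sensitivity). The smoothed curves drive the lumped models; initial
coefficients come from linearisations (a log-decay regression for $D$; a
pointwise inversion of the energy balance followed by *bounded* linear least
squares for $\varepsilon''$ — the polynomial basis is so collinear along a
single trajectory that unconstrained least squares followed by clipping would
destroy the fit), then a bound-clipped Nelder–Mead simplex minimises each SSE.
The smoothing is only ever used here, never reported as a result.

**Stage 2 — goal attainment through the coupled FEM.** With goals set to the
stage-1 SSEs and unit weights, the refinement solves

$$\min_{C,\gamma} \gamma \quad \text{s.t.} \quad F_i(C) - w_i\gamma \le
goal_i,\quad \varepsilon'' > 0 \text{ on the trajectory},\quad lb \le C \le ub,$$

through its exact minimax scalarisation
$\gamma(C) = \max_i (F_i(C)-goal_i)/w_i$. The temperature SSE (order
10–100 °C²) and moisture SSE (order $10^{-5}$ d.b.²) are incommensurate, so
the moisture objective is rescaled by $(\Delta T_{obs}/\Delta M_{obs})^2$
before attainment (configurable). The search runs two phases: block damped
Gauss–Newton sweeps — finite-difference Jacobians of the temperature
residuals over the $g$ block and of the moisture residuals over the
diffusivity block, accepted only when $\gamma$ does not increase — followed
by a joint bound-clipped simplex polish of $\gamma$ that stops when the
simplex step norm falls below twice the step tolerance ($10^{-6}$). The
iteration trace (objective pair, $\gamma$, step norm) is recorded; $\gamma$
is non-increasing across accepted iterations by construction. Loss-factor
positivity is enforced as an exact penalty on the minimum of
$\varepsilon''$ over the simulated mean and surface state trajectories, and
an infeasible start is repaired by shrinking toward mid-bounds. Bounds
default to the packaged per-treatment table columns expanded by ±50 % of the
endpoint magnitudes, with Biot numbers in $(10^{-4}, 0.1)$.

**Identifiability.** From a single mean-moisture curve only the product
$Bi_m \cdot D$ is identified — rescaling one and inversely rescaling the
other leaves the lumped decay (and, at these Biot numbers, the FEM output)
essentially unchanged. The default therefore fixes the Biot numbers at their
configured per-treatment values (`estimation_control(fit_biot = FALSE)`) so
that "recover $D(T,M)$" is a well-posed contract; `fit_biot = TRUE` adds both
Biot numbers to the optimised vector for the full original behaviour. For the
same reason all recovery tests assert on the property trajectories
$D(T(t), M(t))$ and $\varepsilon''(T'(t), M(t))$, never on raw coefficients.

## Synthetic data and what the tests show

No measured drying curves are distributed with the package, so the test bed
is the synthetic generator (`make_bench_scenarios()`,
`generate_record()`): six presets — 0.35 and 0.70 kW nominal power (available
powers 308/616 W, reflection coefficients 0.694/0.421) crossed with tempering
moistures 0.20, 0.35 and 0.50 d.b. — using the packaged per-treatment
coefficient tables as ground truth, the treatment Biot numbers (0.043 heat,
0.038 for the hottest treatment; 0.015/0.016 mass), initial seed temperature
4.5 °C (mid-range of the reported 3–6 °C), 15 s sampling, and drying run
until the mean moisture returns to 0.10 d.b. (capped at 30 min). Measurement
noise is i.i.d. Gaussian per channel, default σ = 0.5 °C (camera sensitivity
0.1 °C plus handling error) and 0.003 d.b. (0.01 g balance on ~50 g samples,
with margin); the tempered initial moisture is treated as known, not
measured. Records are generated at a finer time step (1 s) than the
estimation objective uses, so the inverse stage never sees an exact replica
of its own discretisation.

On noise-free records the full pipeline recovers the diffusivity trajectory
within 5 % and the loss-factor trajectory within 10 % at every traversed
state (in practice ~3 % and ~2 %); with σ = 1 °C / 0.005 d.b. noise the
worst-case trajectory deviation stays within 15 % in expectation over five
seeded replicates. The weak spot is always the trajectory's starting corner
(cold, wet), which the seed crosses in seconds: a handful of noisy samples
carry all the information about ε″ and D there, so individual replicates can
graze the bound at that single state while remaining a few percent everywhere
else. What this does *not* show: real seeds shrink, have
moisture-dependent contact with the tray, experience the 20 s out-of-oven
measurement interruptions as cooling transients, and may carry
heteroscedastic measurement error — none of which the generator emulates.
Passing recovery tests demonstrate the estimator inverts its own physics
faithfully, not that the physics exhausts reality.

## Problem sizes and numerical defaults

The estimation objective runs on a coarse mesh (edge 0.4 mm, 57 nodes) with
a 2 s step: at Biot numbers well below 0.1 the summary trajectories move by
far less than the measurement noise between this and the default resolution,
while each coupled forward solve stays in the hundreds of milliseconds —
the refinement needs a few hundred of them per treatment. Forward
simulations for reporting use the default 0.1 mm / 0.5 s discretisation.
Other defaults: ash 2.6 % d.b.; finite-difference step $10^{-4}$ of the
bound range (Jacobians), simplex displacement 0.04 of the bound range; three
deterministic perturbed restarts if a stage-1 search hits non-finite
objectives; stage-2 budget 200 objective evaluations.

## Known limitations

- Goal attainment is local; with bounds spanning ±50 % of the table columns
  and stage-1 initialisation this is adequate on synthetic data, but nothing
  guards against distant optima under model misfit. No uncertainty
  quantification is attempted.
- The loss-factor coefficients are reported individually but are only jointly
  identified with the ash content and field calibration (see above).
- The mean relative percentage error is computed by the conventional
  $\frac{100}{n}\sum |o_i - p_i|/|o_i|$ on the reporting scale, with
  zero-valued observations excluded and counted. Published MRPE figures for
  temperature series computed by other conventions can differ by an order of
  magnitude; compare R² and RMSE instead.
- A single kernel represents the drying layer (its measured record is the
  layer average); kernel-to-kernel variation is out of scope.

## A worked example

```{r, eval = FALSE}
library(seedwave)

# synthesise a bench-like record for the hottest treatment, then re-estimate
scn <- make_bench_scenarios(seed = 1)[["0.70kW-50"]]
rec <- generate_record(scn)
fit <- estimate_treatment(rec)
glance(fit)
autoplot(fit)
plot_property_trajectories(fit, reference = list(loss = scn$loss,
                                                 diff = scn$diff))
```
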