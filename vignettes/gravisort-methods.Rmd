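---
title: "Models and numerics behind gravisort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind gravisort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the assumptions
behind each model, the tunable parameters and their defaults, the
numerical choices, and what the validation suite does and does not
establish about real devices. No empirical claim is made here beyond what
the tests and the acceptance script compute.

## 1. The force balance and its estimators

A swimming worm in a viscous liquid is approximated as a sphere of Stokes
radius $r_s$ in quasi-static force balance,

$$(\rho_w - \rho_f)\,V_w\,g \;+\; 6\pi\mu r_s U \;+\; F_p \;=\; 0,$$

justified because the particle Reynolds number is small (about 0.04 in
the working blend; about 0.24 in plain buffer, where the approximation is
marginal — both values are reported by `reynolds_number()`, not hidden).
Internally the package stores the *reduced weight*
$W = (\rho_f-\rho_w)V_w g$ as one signed scalar with $+z$ up (positive =
the body floats), which removes the double-negation errors that plague
mixed sign conventions. All computation is strict SI; configuration
values may carry unit suffixes (`"1.09 g/mL"`, `"0.5 mm/s"`, `"0.58 nN"`)
that `parse_quantity()` converts once, at the boundary, because the
source quantities arrive in at least four unit systems and conversion
bugs are the main practical hazard.

Key parameters and defaults:

| parameter | meaning | default | unit |
|---|---|---|---|
| $V_w$ | effective body volume | 5.96e-12 | m^3 |
| $\rho_w$ | body density | 1080 | kg/m^3 |
| $r_s$ | Stokes radius | estimated (0.37e-3 in scenarios) | m |
| $\mu$ | blend / buffer viscosity | 4.78e-3 / 1.0e-3 | Pa s |
| $\tau_r$ | reorientation time | 4.65 | s |
| $g$ | gravitational acceleration | 9.81 (configurable) | m/s^2 |

Two estimator choices deserve comment:

* `estimate_thrust()` uses the **velocity-difference form**
  $F_p = 6\pi\mu r_s\,(U_\text{directed}-U_\text{passive})$, obtained by
  subtracting the balance of a passive settler from that of a directed
  swimmer with the same body. It needs neither the density difference nor
  the body volume — the two least certain inputs. The single-strain form
  is provided (`estimate_thrust_single_strain()`) but documented as
  sensitive to those inputs.
* `estimate_stokes_radius()` exposes the fluid properties explicitly and
  hard-codes nothing: with a measured 0.52 mm/s settling speed and
  nominal buffer values ($\Delta\rho = 80$ kg/m^3, $\mu = 1$ mPa s) it
  returns 0.48 mm, not the 0.37 mm in circulation for this system — the
  inputs behind that figure are not pinned, so the package treats $r_s$
  as an input everywhere and uses 0.37 mm only inside the canned
  scenarios.

`mixture_density()` is ideal (volume-additive) mixing and is documented
as an estimate only: the working blend measures 1.09 g/mL where ideal
mixing of its components predicts 1.07, so final densities should be
measured, not computed.

## 2. The unit-cell Stokes solve

The device flow is solved on the $x$–$z$ cross-section of **one vertical
column plus half a pitch of feed and collection conduit on either side**.
The 3 mm depth is treated as invariant (the sorting physics is planar);
the ten columns tile periodically at the 4.1 mm pitch. At device scale
$Re = \rho U L/\mu \approx 0.34$, so the inertial terms are dropped and
the steady **Stokes** equations are solved in stream-function/vorticity
form,

$$\nabla^2\psi = -\omega, \qquad \nabla^2\omega = 0,$$

with: fully developed plane-Poiseuille profiles (mean 0.5 mm/s) on the
four conduit ports; no-slip walls with Thom's wall-vorticity closure,
$\omega_w = 2(\psi_w-\psi_{w+1})/h^2$; and **zero net flux through the
column** imposed by setting all interior wall stream-function constants
to the conduit flux. The zero-crossflow constraint is an observed
property of the hardware (equal-rate dual-syringe pumping; dye tracing
shows the outlets discharge unmixed fluid; collected volumes balance
within 3%), not a modeling convenience.

Numerics: the two Poisson problems share one sparse SPD matrix,
factorized once (Cholesky, `Matrix`); the outer iteration relaxes the
Thom update until the relative change in $\psi$ falls below 1e-8
(iteration cap 5000). The stable under-relaxation range shrinks roughly
linearly with grid spacing; the default `0.4 * h / 1e-3` sits inside it
at every spacing used here, and a divergence guard halves the factor and
restarts if the residual ever grows two orders above its best. The
working grid is $h = 0.1$ mm (the column-wall positions snap to the
nearest node, preserving the 3 mm opening width); halving $h$ changes the
peak in-column speed by under 10% and the test suite checks this at
$h = 0.05$ mm.

Diagnostics: `vortex_diagnostics()` reports the maximum speed over
column-interior nodes and the **penetration depth** — the distance from
the feed-side mouth at which the horizontal-slice maximum speed first
falls below 1% of its mouth value. The 1% threshold is a package choice
(the qualitative expectation is only "same order as the column width");
it is configurable and echoed in the output. On the solved field the
slice maximum decays nearly exponentially with depth, as expected for
Stokes flow driven at the end of a slot, and the depth comes out at
2.9 mm on the working grid. `check_flux_balance()` integrates the
numerical velocity across cuts one node inside each port and across a
mid-column cut; mismatches are a few 1e-4 of the conduit flux, far inside
the 3% experimental bound. A degenerate geometry with
`column_height = 0` collapses the cell to a straight conduit whose
mid-channel profile must match plane Poiseuille (within 2% at
$h = 0.05$ mm) — the solver's analytic limit. `build_geometry()` (the
configuration path) rejects a zero column height, since a configured
*device* needs real columns; the degenerate limit is reserved for
programmatic use.

`analytic_fallback_field()` provides a cheap divergence-consistent
stand-in (Poiseuille in the conduits, still columns) for fast agent runs;
it omits the junction vortices.

## 3. The particle simulation

Particles are **overdamped point tracers**: velocity is the algebraic sum
of the local fluid velocity and $(F_p\hat n + W\hat z)/C_f$, integrated
with explicit Euler. No inertia is integrated ($Re \ll 1$), and particles
do not feed back on the flow. Positions are 3-D; the planar field is
tiled periodically across the device length, and $y$-motion (from thrust
heading only) reflects at the 3 mm depth walls.

* **Time step.** `sim_config()` enforces
  $dt \le 0.1\,\min(\tau_r,\ h/v_\max)$ and refuses coarser steps with an
  explanation. The scenario default is $dt = 10$ ms; halving it changes
  exit fractions by less than the binomial standard error of the run.
* **Reorientation.** Deficient particles resample their heading uniformly
  on the unit sphere. The default is a **fixed 4.65 s interval**, the
  observed reorientation period; an exponential waiting time with mean
  $\tau_r$ is available and matches the interpretation of $\tau_r$ as a
  mean persistence time. (The two differ in their long-time diffusivity:
  Poisson tumbling gives $D = U^2\tau_r/3$, a strict clock gives half
  that; the free-space validation therefore uses the exponential scheme.)
* **Walls.** Specular reflection with heading preserved, at a standoff of
  **half a grid cell** from every wall. The standoff is numerical — it
  keeps the bilinear interpolation stencil inside the fluid — and was
  chosen over a body-sized (Stokes-radius) standoff after simulation
  showed the latter holds buoyant particles 0.37 mm off the conduit
  ceiling, in the fast core of the Poiseuille stream, where they sweep
  past every column mouth and exit at the wrong end. Point tracers that
  can linger near walls reproduce the intended device behavior: near-wall
  fluid is slow, so rising particles dwell under the column mouths and
  enter the columns. A finite-size standoff remains available via
  `wall_offset`. Wall-attraction bias (bordertaxis) is not modeled.
* **Injection.** A pulse distributed uniformly over the feed-inlet
  cross-section at $t=0$; a distributed-feedline mode exists. The
  horizon default is 1800 s, the 30 min operating window; particles still
  inside are reported as `timed_out`, never dropped.
* **Quiescence.** A two-state Markov switch: active → quiescent with a
  (possibly time-dependent) hazard in min$^{-1}$, quiescent → active at
  $1/\text{mean bout}$. Quiescent particles keep weight and drag but lose
  thrust, which is the mechanism by which sorting efficiency declines
  with residence time. With zero hazard the RNG stream is untouched, so
  a zero-hazard run is bit-identical to the base phenotype.
* **Determinism.** All draws route through R's RNG seeded from
  `config$seed`; identical configurations give bit-identical outcomes.

With the scenario parameters (thrust 0.81 nN downward > buoyancy
0.58 nN), the net force on a competent particle is downward at all
times, so no competent particle can climb a column: the simulated
specificity is exactly 100% for any seed, and the suite verifies this
over five. About 3% of deficient particles exit at the bottom — they
traverse the feed line (about 6 s per mouth) without entering a column,
the same false-negative mechanism expected in hardware.

## 4. Sorting statistics

The ratio definitions are
$\varepsilon^C = N^C_b/N^C_0$, $\varepsilon^D = N^D_T/N^D_0$,
$S_p = N^D_T/(N^D_T+N^C_T)$, and the $K$-round cumulative efficiency
$1-\prod_k(1-\varepsilon_k)$, which the tests verify against exhaustive
path enumeration for $K\le4$ and against re-sorted simulation runs. The
multi-round semantics re-sorts the animals *not recovered at the bottom*
after each round, matching the cumulative-recovery quantity.

The efficiency decline with residence time is modeled by the 4-parameter
logistic $\varepsilon(t) = a/(1+\exp(-b(t-d))) + c$ (time in minutes;
$b<0$ declines from plateau $a+c$ to $c$). This parameterization is
recorded in the model's `form_id` because several logistic variants are
in circulation; with coefficients $a=0.49$, $b=-3.29$, $c=0.41$,
$d=3.3$ the plateaus are 0.90 and 0.41. `fit_logistic_decline()` uses
multi-start Levenberg–Marquardt; the recovery harness samples every
0.2 min over 0–20 min because the transition width $1/|b|$ is about
0.3 min — on a sparser grid the rate parameter is simply not
identifiable, which is worth knowing before designing a decline
experiment. At noise $\sigma=0.01$ over 20 seeds all four parameters
recover with bias under 5%.

`two_sample_t_from_summary()` defaults to Welch's test, two-tailed, with
pooled and one-tailed options, since published comparisons often state
only (mean, sd, n) and not the variant; with the gait summaries
(3.50 ± 0.46 Hz vs 3.62 ± 0.35 Hz, n = 150 each) it gives
$|t| \approx 2.54$, $p \approx 0.011$ two-tailed and $0.006$ one-tailed.

## 5. Synthetic data, and what passing tests show

`generate_settling_tracks()` emulates the cuvette assays: straight
vertical drift with per-animal speeds $\mathcal N(U,\sigma_U)$ and
isotropic Gaussian position noise (default 0.05 mm; the camera pixel
scale is not documented) at 16 Hz. A published "± 0.02 mm/s" for $N=30$
is read as a standard error, so the per-animal spread used in emulation
is $0.02\sqrt{30}$ mm/s. `generate_run_tumble_tracks()` produces
constant-speed runs with stored headings. `estimate_tau_r()` fits
$e^{-\Delta t/\tau_r}$ to the ensemble heading autocorrelation by
*nonlinear* least squares over a window set by the $1/e$ crossing
(re-derived once) — a log-linear fit is badly biased by the noisy
near-zero tail. With 32 tracks of 90 s the aggregate recovery is within
a few percent (individual cohorts scatter about ±10%, matching the
sizable uncertainty quoted for the 4.65 s measurement itself).

These generators share the estimators' *assumed* structure: Gaussian
noise, ideal exponential or clocked tumbling, no wall effects, no
body-shape or imaging artifacts. Passing round trips therefore
demonstrate correctness of the inference machinery, not that real
cuvette data satisfy the assumptions. Likewise the particle simulation
validates the sorting *mechanism* under its stated idealizations — rigid
spheres, planar flow, specular walls — and its quantitative outputs
(e.g. 100% specificity) inherit those idealizations; bench runs with
live animals include quiescence, bordertaxis, and handling losses that
the defaults deliberately exclude unless switched on.

## 6. Problem sizes and other fixed choices

The validation suite runs the full 600 + 600 scenario over five seeds at
the 0.1 mm working grid, uses 0.05 mm only for refinement checks, and
sizes Monte-Carlo ensembles (150–300 particles or tracks, 20 seeds for
recovery harnesses) so that 3-sigma bands are decisive. The quiescence
monotonicity check uses onset hazards of 0, 0.75, and 3 min$^{-1}$ with
30 s bouts — chosen once so the three regimes (never quiescent, marginal,
mostly quiescent) are well separated. Ties in `vortex_diagnostics()` are
impossible on a converged field; degenerate inputs (zero inflow, zero
particles, constant decline data, empty top outlet) return exact zeros or
explicit flags rather than NaN.

## 7. Known limitations

* The flow is 2-D Stokes, standing in for a full 3-D finite-element
  solve. Agreement is at the order-of-magnitude level for vortex
  speed and penetration depth, which is the level the design arguments
  need.
* Worms are rigid spheres: no undulatory kinematics, no
  worm–wall or worm–worm hydrodynamics, no bordertaxis torque (an
  optional heading bias is deliberately not implemented because no
  quantitative model accompanies the observation).
* The thrust–gait-frequency relation is used only as a linear scaling.
* `mixture_density()` ignores non-ideal mixing.
* The logistic decline is a description of the efficiency curve, not a
  mechanistic quiescence model; the Markov quiescence module is the
  mechanistic counterpart and is validated only qualitatively (monotone
  decline with hazard).
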