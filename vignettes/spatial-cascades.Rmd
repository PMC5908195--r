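---
title: "Spatial modeling of membrane-cytosolic signaling cascades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial modeling of membrane-cytosolic signaling cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocascade)
```

## The model

Protein-kinase cascades relay a signal from cell-surface receptors to the
nucleus through consecutive activation steps. cytocascade models a linear
cascade of `N` inter-convertible kinases in which the first `M` levels are
tethered to the cell membrane and the remaining `N - M` diffuse in the
cytosol, as a bulk-surface reaction-diffusion system:

* membrane-bound levels live on the cell surface, diffuse laterally with
  coefficient $D_\mathrm{mem}$ (Laplace-Beltrami operator) and are measured
  in nM·μm (areal density; 1 μM·μm ≈ 602 molecules/μm², see
  `membrane_density()`);
* cytosolic levels diffuse with $D_\mathrm{cyt}$ in the volume between the
  cell membrane and a nucleus that excludes the cytosol, and are measured
  in nM;
* the membrane-cytosolic interface is a Robin flux condition: the first
  cytosolic level is produced at the membrane at rate $\alpha$ times the
  upstream membrane level and may be inactivated there at rate $\gamma$
  (μm/s); all kinetics are linearized, $v^a_n = \alpha_n P_{n-1}$,
  $v^d_n = \beta_n P_n$;
* optionally the last level is imported into the nucleus at rate
  $\epsilon$ (zero by default, matching every quantitative scenario the
  package ships).

Two arrangements are distinguished throughout: the **mixed
membrane-cytosolic (MMC)** cascade (`n_membrane = 2`, one cytosolic level)
and the **pure cytosolic (PC)** cascade (`n_membrane = 0`, activation of
level 1 as a boundary flux). A homogeneous stimulus keeps all fields
radially symmetric on spheres and discs, which is what makes the analytic
and one-dimensional radial treatments below exact.

Internal units are fixed: nM, nM·μm, μm, s. Typical parameter ranges (the
defaults in the packaged scenarios sit inside them) are
$D_\mathrm{cyt} \in [1, 10]$ μm²/s, $D_\mathrm{mem} \in [10^{-3}, 0.1]$
μm²/s, $\alpha \in [1, 10]$ 1/s, $\beta \in [0.1, 100]$ 1/s,
$\gamma \in [0.1, 100]$ μm/s, $R_\mathrm{cell} \in [2, 50]$ μm.

## Closed-form steady states on spheres

For the MMC cascade the membrane levels equilibrate level by level
(`mmc_membrane_steady()`), and the interface species obeys
$D_\mathrm{cyt}\Delta \bar P = \beta \bar P$, whose radially symmetric
solutions are the modified spherical Bessel functions
$i_0(r/L)$ and $k_0(r/L)$ with the gradient length
$L = \sqrt{D_\mathrm{cyt}/\beta}$. We fix the conventions
$i_0(x) = \sinh(x)/x$ and $k_0(x) = e^{-x}/x$ (the textbook $\pi/2$
prefactor is absorbed into the coefficient of the decaying branch). The
two coefficients are obtained by numerically solving the 2×2 linear system
given by the Robin condition at the membrane and the flux condition at the
nucleus, rather than transcribing closed-form coefficient expressions:
the linear solve is convention-robust and is anchored by residual and
cross-solver checks in the test suite. Without a nucleus the decaying
branch drops out (regularity at the origin). Large Bessel arguments are
handled with exponentially scaled evaluations and boundary-normalized
basis functions, so cells up to hundreds of gradient lengths in radius stay
well conditioned.

The PC cascade with equal deactivation rates expands in the basis
$r^{k-2}e^{\pm r/L}$: the operator $D\Delta - \beta$ maps this family
triangularly onto itself, so the source coefficients of each level follow
a short recursion from the upstream level and only the two homogeneous
coefficients per level are solved from the boundary conditions
(`pc_steady()`). Unequal rates, or a vanishing nuclear radius (where this
basis degenerates), are served by the sparse numeric solver instead.

Heterogeneous membrane stimuli on spheres are handled per spherical-
harmonic mode (`signal_harmonics()`, `harmonic_mode_steady()`): membrane
levels respond algebraically with $D_\mathrm{mem}\,l(l+1)/R^2$ added to
their deactivation — which is why higher-order spatial detail is damped
more strongly — and cytosolic levels solve the order-$l$ modified
spherical Bessel equation with the same boundary structure. A linear
stimulus gradient is exactly an $l=0$ plus $l=1$ superposition.
`front_back_gradient()` evaluates the reconstructed field at the stimulus
poles.

## Scale diagnostics and the average-concentration estimator

`scale_report()` collects the quantities that need no PDE solve:

* gradient length $L$ and Thiele modulus $\Phi = R_\mathrm{cell}/L$
  (gradients are steep for $\Phi \gg 1$, the cytosol is well mixed for
  $\Phi \ll 1$);
* the surface-to-volume ratio $|M_\mathrm{cell}|/|V_\mathrm{cell}|$
  ($3/R$ for a solid sphere), which sets the effective global activation
  rate of cytosolic levels;
* the membrane-source/cytosolic-sink estimator
  $\Lambda = \alpha|M|\bar P_M^\mathrm{avg} / (\gamma|M| + \beta|V|)$,
  exact for $\gamma = 0$ in arbitrary shapes and sandwiched between the
  spatial average and maximum on spheres for $\gamma > 0$ — the
  `"abstract"` geometry kind exists precisely so that $\Lambda$ and the
  average relations can be used with user-supplied measures of any cell
  shape, without a mesh;
* the variance-propagation constant
  $C_n = \alpha_n\beta_n\,/\,\big(D_\mathrm{cyt}/(C_s^2 d^2) + \beta_n\big)^2$,
  where $C = C_s d$ is the Poincaré constant of the cell ($C_s = 1/\pi$
  for convex shapes) and $d$ the diameter. The Poincaré rate $D/C^2$ is an
  effective mixing rate that adds to deactivation; this reading is pinned
  by a unit test against the value ≈ 0.30 for $D = 3$, $\alpha=\beta=1$,
  $d = 6$, and it bounds how fast the normalized spatial variance decays
  along a cytosolic cascade ($\mathrm{NV}_n \le C_n\,\mathrm{NV}_{n-1}$,
  verified on random parameter sweeps);
* the signaling time $\tau = \sum_n 1/\beta_n$ of the well-mixed
  reduction — phosphatases, not kinases, set the time scale.

The normalized variance itself (`normalized_variance()`) integrates the
squared deviation from the spatial mean and divides by mean times volume,
the continuous analogue of the localization measure used in image
analysis. We implement the displayed normalization (mean to the first
power); dividing by the squared mean would make the measure dimensionless
and is an equally defensible alternative the function does not currently
expose.

## Well-mixed reductions and the feedback oscillator

For $\gamma = 0$ the spatial averages obey a closed linear ODE system in
which $|M|/|V|$ multiplies the activation at the interface level
(`simulate_average_odes()`, `steady_state_averages()`); with $\gamma > 0$
the same reduction is returned with an explicit approximation note rather
than an error. The MMC and PC reductions produce identical last-level
trajectories for matched rates, and the steady average of the last level is
$(|M|/|V|)\prod_n(\alpha_n/\beta_n)\,P_0$ regardless of where the
interface sits.

Negative feedback closes the loop by replacing the first activation with a
Hill-repressed rate $P_0/(1+(P_N/K_m)^p)$. The classical three-identical-
stage ODE loop can only destabilize when the loop gain exceeds the secant
bound $\sec^3(\pi/3) = 8$; `goodwin_instability_threshold()` finds the
minimal destabilizing Hill exponent by bisection over an eigenvalue scan
of the 3×3 Jacobian at the (unique, bracketed) positive steady state,
minimized over the stimulus ratio $P_0/K_m$. The test suite cross-checks
the scan against the hand-derived loop-gain identity
$g = \beta\,p\,u^p/(1+u^p)$ at the steady state, whose supremum over the
stimulus ratio gives exactly 8.

## The radial numerical solver

`simulate_linear_cascade()`, `simulate_feedback()` and
`steady_state_numeric()` share one discretization: method of lines on a
uniform radial grid with the spherical $(1/r^2)\partial_r(r^2\partial_r)$
or polar $(1/r)\partial_r(r\partial_r)$ Laplacian in non-conservative
form, Robin and flux boundary conditions eliminated with second-order
ghost-node stencils, membrane scalars and boundary nodes coupled in one
sparse operator, and the symmetric stencil at the origin when there is no
nucleus. The assembled operator is used three ways: sparse direct solve
for steady states, matrix-vector product inside the stiff adaptive
integrator (lsoda) for dynamics, and one extra sparse solve for the
resolvent form of accumulation times. Spatial convergence is second order
(verified against the analytic solution); steady-state solves default to
256 nodes, dynamic runs to 64-128, and the analytic/numeric agreement at
256 nodes is below $10^{-3}$ relative L2 across random parameter sweeps.

Nonlinear feedback runs resolve the Hill term inside the adaptive
implicit integrator rather than by a hand-rolled per-step fixed-point
iteration; the `nonlinear` field of `solver_config()` is recorded in the
output metadata for provenance but both settings route to the same stiff
scheme. Negative concentrations are never clipped: values below
$-\max(10\,\mathrm{atol}, 10^{-9}\max|P|)$ raise a hard error, because
silent clipping hides discretization bugs.

Because all feedback stimuli considered are homogeneous, the
two-dimensional disc problem is rotation-invariant and its one-dimensional
radial reduction (with the polar metric $r\,\mathrm{d}r$ in averages) is
mathematically identical to a full planar solve — the package therefore
never needs an unstructured mesh. Non-radial stimuli are served
semi-analytically by the harmonic-mode machinery instead, and arbitrary
cell shapes only through the `"abstract"` geometry's measure-based
estimators.

## Timing: local accumulation times

The local accumulation time
$\tau_n(r) = \int_0^\infty \rho_n(r,t)\,\mathrm{d}t$ with
$\rho_n = (\bar P_n - P_n(t))/\bar P_n$ measures, pointwise, how long the
steady state takes to build up after a step stimulus from a zero initial
state (the zero initial condition is required for $\rho(r, 0) = 1$). The
default method integrates the simulated relaxation by trapezoidal
quadrature until the residual falls below $10^{-6}$ and adds an
exponential tail $\rho_\mathrm{end}/\hat\lambda$ estimated by a log-linear
fit over the last decade of decay. Because the semi-discrete system is
linear, $\int_0^\infty (\bar y - y)\,\mathrm{d}t = -L^{-1}\bar y$ for the
assembled operator $L$, so a single extra sparse solve gives the exact
(to discretization) answer; this `"resolvent"` method is exposed and used
as an independent cross-check of the quadrature route. On the membrane the
second level's accumulation time is exactly $1/\beta_1 + 1/\beta_2$, and
in small cells ($\Phi \to 0$) every location approaches
$\sum_n 1/\beta_n$; accumulation is faster at the membrane than at the
nucleus, increasingly so for larger cells and more strongly for the MMC
than for the PC arrangement.

## Oscillation analysis and the sustained/decaying classifier

`oscillation_metrics()` discards a burn-in (200 s by default, long enough
for the feedback scenarios' initial peak to pass), resamples uniformly at
0.5 s, removes the mean and takes the FFT. The dominant frequency is the
spectral argmax excluding DC; the amplitude is the peak converted to a
half peak-to-peak value. A Hann window is the reporting default (less
leakage for frequencies between bins); a rectangular window is available
and is what the synthetic-sinusoid tests use for bin-exact recovery.

Classifying *sustained* versus *decaying* oscillations needs care near a
Hopf boundary, where decay is slow. The classifier splits the post-burn-in
series into **three** equal windows and calls the series sustained when the
peak-to-peak amplitude of the last window holds at least half that of the
middle window and exceeds 1% of the mean level. The first window is
deliberately sacrificed: after the burn-in the trajectory of a genuine
limit cycle still carries a decaying overshoot whose amplitude can be
twice the final cycle's, and a two-window comparison starting at the
burn-in would misclassify such limit cycles as decaying no matter how long
the horizon. With the three-window rule and the default sweep horizon of
2000 s, the window ratios of the packaged feedback scenarios separate
cleanly (≈ 0.9 and above for limit cycles, ≈ 0.4 and below for decays) and
the classification is unchanged under halving the grid spacing or doubling
the horizon — the stability the acceptance checks require.

`extinction_radius()` sweeps the cell radius at fixed nuclear radius
(1 μm in the packaged feedback scenario), simulates each disc, classifies,
and reports the largest oscillating radius together with the full
per-radius table of frequency and amplitude. In the packaged parameter set
($\beta = 0.125$ 1/s, $D_\mathrm{cyt} = 1$ μm²/s, $K_m = 100$ nM,
$p = 10$, $P_0 = 100$ nM·μm) the grid-converged radial solution sustains
MMC oscillations at $R_\mathrm{cell} = 2$ μm but not at 2.5 μm — at 2.5 μm
the post-peak oscillation decays geometrically window over window at every
tested resolution and horizon — while the PC variant sustains up to
3.0 μm and decays at 3.5 μm. Near the boundary the decay is slow, so short
horizons (a few hundred seconds) cannot distinguish a slowly decaying
transient from a limit cycle; this sensitivity is why the package fixes
the long default horizon. The PC loop oscillates at a larger amplitude and
higher mean concentration than the MMC loop in the same small cell, with
frequencies within about ten percent of each other.

## What the packaged scenarios emulate — and what they do not

The packaged parameter sets (`study_bundle()`, and the YAML configs under
`inst/extdata/`) represent three archetypal conditions for a three-level
cascade in a yeast-sized cell: a steep-gradient steady state
($\alpha = 1.5$, $\beta = 1$, $\gamma = 10$, $D_\mathrm{cyt} = 3$, sphere
$R = 6$/$R_\mathrm{nuc} = 2$), a decaying-stimulus timing scenario
($\alpha = 1$, $\beta = 0.5$, $\gamma \in \{0, 1\}$, stimulus
$100\,e^{-t}$ nM·μm) and a negative-feedback oscillator on a disc
($R_\mathrm{nuc} = 1$, initial levels 10 nM(-μm)). They are exact model
inputs, not data: passing tests demonstrates internal correctness of the
solvers and closed forms under linearized kinetics, radial symmetry and
homogeneous or low-order stimuli. Real cells add what the model leaves
out: saturating (Michaelis-Menten) kinetics, crowding and
position-dependent diffusion, non-spherical shapes with protrusions (only
the measure-based estimators apply there), stochasticity at low copy
number, and receptor-level dynamics upstream of the stimulus. Conclusions
about real data should lean on the shape-general quantities ($\Lambda$,
normalized variance, $\tau$) rather than on the geometry-specific closed
forms.

## Numerical choices, in one place

* Avogadro constant kept at full precision (602.214 molecules/μm² per
  μM·μm), never rounded internally.
* Analytic evaluation is grid-free; profiles default to 512 radii.
* Integrator: lsoda, rtol $10^{-8}$/atol $10^{-10}$ for linear runs,
  rtol $10^{-6}$ for the long feedback sweeps (classification verified
  identical at $10^{-8}$).
* Steady solves: sparse LU on the assembled operator; singularity is
  reported, never regularized.
* Goodwin bisection tolerance $10^{-4}$ on the Hill exponent, stimulus
  ratios scanned log-uniformly over $[10^{-1}, 10^{5}]$.
* Ties and degenerate inputs: zero signal gives identically zero fields;
  $\gamma = 0$ makes the upper interface bound infinite (a documented
  return, not an error); $\beta = 0$ at a level with a steady-state
  request is an error.

## Known limitations

* No unstructured meshes: arbitrary shapes are served only through
  measure-based estimators, not fields.
* The PC closed form requires equal deactivation rates and a nonvanishing
  nucleus; other cases route to the numeric solver.
* The harmonic machinery is restricted to axisymmetric modes (order
  $m = 0$); general $(l, m)$ stimuli would need no new mathematics but are
  not wired through `signal_spec()`.
* Oscillation classification near the Hopf boundary is intrinsically
  horizon-limited; the defaults resolve the packaged scenarios robustly
  but very slowly decaying transients in other parameter regions may need
  a longer `t_max`.
* Accumulation-time quadrature assumes a monotone-enough tail for the
  log-linear fit; the resolvent method is the fallback of choice when in
  doubt.
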