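---
title: "Linearly transformed particles for the aggregation equation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linearly transformed particles for the aggregation equation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltpagg)
```

## Model and discretization

The package solves the 1D aggregation equation
$$\partial_t \rho + \partial_x(\rho u) = 0, \qquad u = -W' * \rho,$$
a nonlocal continuity equation in which every mass element moves down the
gradient of the potential field generated by all the others. For smooth
potentials ($W'$ Lipschitz) measure solutions are globally well posed; for
attractive potentials with a power-type singularity at the origin
($|W'(x)| \sim |x|^{a-1}$, $1 < a < 2$) solutions concentrate toward Dirac
masses, and attractive–repulsive combinations produce bounded steady
profiles or Dirac clusters depending on the repulsion exponent. These are
exactly the regimes the experiment layer reproduces.

A particle state is $(x_k^n, \omega_k, D_k^n, h_k^n)$ and the density
reconstruction is
$$\rho_h^n(x) = \sum_k \frac{\omega_k}{h_k^n}
  \varphi\!\Big(\frac{D_k^n(x - x_k^n)}{h}\Big),$$
with $\varphi$ a hat function or cubic B-spline (partition of unity, unit
integral, compact support — the three properties every reconstruction
argument uses; `check_partition_of_unity()` verifies the first to
$10^{-12}$). One explicit Euler step evaluates
$u_k = -(W' * \rho_h^n)(x_k^n)$ and $A_k = (W'' * \rho_h^n)(x_k^n)$, then
$$x_k^{n+1} = x_k^n + \Delta t\, u_k,\quad
  J_k^n = e^{-\Delta t A_k},\quad
  D_k^{n+1} = D_k^n (J_k^n)^{-1},\quad
  h_k^{n+1} = \det(J_k^n)\, h_k^n.$$
$D_k^n$ approximates the backward Jacobian of the flow at the particle, so
each shape is the push-forward of its initial shape along an affine
approximation of the flow. Because the weights are never touched, discrete
mass is conserved exactly (bitwise); because the exponential map is used,
$\det J_k^n > 0$ unconditionally, so volumes stay positive no matter how
violent the contraction. The identity $h_k^n \det(D_k^n) = h^d$ is an
algebraic consequence of the update and is asserted after every step.

Only explicit Euler is provided: the method's interest lies in the space
discretization, and higher-order time integrators would complicate the
Jacobian bookkeeping without changing the spatial behaviour under study.
Remapping/resampling of deformed particles is likewise out of scope.

## Initialization

`build_initial_ensemble()` places particles at the lattice $x_k = kh$ with
$D_k^0 = I$, $h_k^0 = h$, and weights from one of two schemes:

* **cell integrals** $\omega_k = \int_{x_k+[-h/2,h/2]} \rho^0$ — non-negative
  weights, mass summing exactly to $\int \rho^0$, second-order $L^p$
  accuracy for smooth densities;
* **dual kernel** $\omega_k = \int \tilde\varphi((x-x_k)/h)\rho^0$ with the
  piecewise-constant kernel bi-orthogonal to the hat shape ($3/2$ on
  $[-1/2,1/2]$, $-1/2$ on the flanks) — possibly negative weights, exact
  reproduction of affine densities on the interior, second-order accuracy in
  a dual (weak) norm even for rough densities. No dual kernel is shipped for
  the B3 spline: a compactly supported bi-orthogonal partner is documented
  for the hat shape only, and we do not invent one.

Cell integrals use composite Gauss–Legendre quadrature (5 nodes on 4
sub-panels per cell), with cells clipped at the declared support endpoints
of the density. The clipping matters: two of the built-in profiles are
discontinuous exactly at $\pm 1$, and quadrature across the jump would
contaminate the $10^{-9}$-level mass identity that initialization otherwise
satisfies. By default the initial profile is normalized to unit mass (the
standing assumption of the underlying theory); the unnormalized printed
forms are kept available via `fixture_density(..., normalize = FALSE)`.

## Velocity evaluation

The convolutions $W' * \rho_h$ and $W'' * \rho_h$ must be approximated; the
three strategies in `velocity_evaluator()` are interchangeable and are used
for both convolutions consistently:

* **blob** — replace the transformed shapes by a fixed blob
  $\zeta_\varepsilon$ and sum $-\sum_{k'} \omega_{k'}
  W'_\varepsilon(x_k - x_{k'})$ with $W_\varepsilon = W * \zeta_\varepsilon$
  evaluated by Gauss–Legendre quadrature on the mollifier support. Default
  $\zeta$ = the ensemble's shape, $\varepsilon = h$. Cost $O(N^2)$.
  The self term uses $W'_\varepsilon(0) = 0$ (odd kernel). For linear $W'$
  the mollification is exact, which is why the quadratic-potential
  contraction rate comes out exact to machine precision in this mode.
* **quadrature** (default) — tabulate $\rho_h$ on a uniform grid (default
  spacing $h/4$, covering all particle supports plus one support radius,
  composite-trapezoid weights) and apply the quadrature sum at each
  particle. Cost $O(N \cdot N_{grid})$.
* **grid_fft** — the same sums evaluated at the grid nodes as one
  zero-padded *linear* convolution (`stats::convolve`, no periodic wrap),
  then interpolated linearly to the particles. Cost
  $O(N_{grid}\log N_{grid})$. Agrees with the direct double sum to
  $10^{-12}$ relative — it is the same formula, reorganized.

Singular kernels are handled by three conventions chosen once: $W'(0) = 0$
(odd-symmetry limit), grid nodes offset half a spacing from the particle
lattice, and non-finite kernel values (the $W''(0) = \infty$ sentinel of
singular potentials) dropped from quadrature sums — they occur only on a
measure-zero set of lags, and the convolutions being approximated are
finite. On smooth problems the three strategies agree to the blob/grid
resolution; no claim is made about which one a given published figure used.

The trapezoid rule was chosen for the grid weights because it keeps the FFT
kernel Toeplitz; the default grid spacing $h/4$ sub-resolves the particle
shapes without dominating the cost. Piecewise-linear interpolation back to
particles matches the overall first-order spatial accuracy of the scheme.

## Error metrics

Errors are measured on a shared uniform grid with spacing $h_{\min}/8$, so
the metric resolves the particle shapes and the measured error is the
method's, not the grid's. Besides $L^1$, $L^p$ and $L^\infty$ norms,
`d_bl_1d()` implements the 1D bounded-Lipschitz distance as the $L^1$ norm
of the CDF difference (cumulative trapezoid, densities *not* renormalized).
For equal-mass densities this coincides with the Wasserstein-1 distance,
and the tests check it against an independent sorted-quantile oracle. The
CDF formula is specific to 1D; no multi-dimensional $d_{BL}$ is attempted.

## Study conditions and what the tests show

The experiment layer fixes its conditions once:

* **Validation (quadratic potential).** Fixture `rho1` (asymmetric double
  bump), B3 shapes, $t = 0.5$; the exact solution
  $\rho(t,x) = \rho^0((x-\lambda)e^{2t}+\lambda)e^{2t}$ is the reference.
  The convergence study uses $h \in \{0.2, 0.1, 0.05, 0.025\}$ with the
  parabolic coupling $\Delta t = h^2/4$ — small enough that the $O(\Delta
  t)$ time error never masks the spatial rate on these grids. Measured
  $L^1$ orders land around 1.8 (the a-priori guarantee is first order;
  smooth data do better). The initialization-only study uses the
  $C^\infty$ bump `rho4` and recovers order 2.
* **LTP vs SP.** Same validation setting at $h = \varepsilon = 0.04$: the
  fixed-width reconstruction of the *same* particles is ~5× worse in $L^1$
  at $t=0.5$, because the uniform $\varepsilon$ cannot follow the
  $e^{-2t}$ contraction of the inter-particle distance. Widths
  $\varepsilon \in \{h/4, h, 4h\}$ display the classic failure modes:
  oscillation (total variation above the exact profile's) and
  over-spreading (collapsing $L^\infty$).
* **Qualitative regimes.** `power:1.5` from the plateau `rho2`
  ($h = 0.02$, $\Delta t = 0.01$): volumes shrink monotonically and the
  concentration guard ($\max_k 1/h_k > 10^6$) fires near $t \approx 2.2$,
  the Dirac-collapse signature; $T = 5$ comfortably covers the collapse
  time. `attrep:3,1.5` from `rho3` reaches $T = 3$ with bounded density —
  the steady-$L^1$-profile regime. These sizes complete in seconds while
  sitting in the same parameter neighbourhood as the published experiments
  ($h = \Delta t = 0.01$); scenario objects accept the full-size parameters
  unchanged.

The synthetic inputs are closed-form profiles, so passing tests demonstrate
correctness of the discretization, conservation laws, convergence rates and
regime phenomenology — not robustness to measurement noise, unresolved
multi-scale data, or dimensions above one. The deterministic pipeline
contains no randomness; repeated runs are bit-identical.

## Numerical choices and degenerate inputs

* Jacobians: scalar exponential in 1D; scaling-and-squaring
  (`Matrix::expm`) for the dimension-generic API. The `linearized` mode
  $J = I - \Delta t A$ differs by $O(\Delta t^2)$ (the measured gap ratio
  under $\Delta t$-halving is $\approx 4$) and *errors out* on a
  non-positive determinant rather than clamping — clamping would silently
  change the method.
* Time step: scenarios warn when a singular potential is run with
  $\Delta t > 100 h^2$, the parabolic-type restriction regime; the smooth
  case needs only $\Delta t = O(h)$.
* Pruning: particles with $|\omega_k| < 10^{-15}\max|\omega|$ are dropped
  at initialization (the infinite lattice must be truncated; zero-weight
  particles never contribute).
* Snapshot times snap to the nearest step; no interpolation in time.
* The blow-up guard ceiling ($\max_k 1/h_k$, default $10^8$) is a
  diagnostic threshold, not a model parameter: once volumes reach
  $10^{-8}$ the state is numerically a Dirac comb and further steps are
  meaningless.
* Degenerate requests fail loudly: non-positive `eps`/`h`/`dt`, zero total
  mass in `center_of_mass()`, density support exceeding the
  initialization bounds, a dual kernel for the B3 spline, `exact_quadratic`
  on non-unit mass.

## Known limitations

Grid-based velocity strategies and the experiment layer are 1D (the state
containers and Jacobian updates are dimension-generic, but only $d = 1$ is
exercised); no remapping, so very long runs with strong shear would
eventually need resampling that is not provided; the Newtonian endpoint of
the singular family is excluded; `d_bl_1d` compares equal-mass densities
meaningfully but is only a pseudo-metric on general gridded data.
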