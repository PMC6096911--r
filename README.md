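# ltpagg

Simulation of the one-dimensional **aggregation equation**

```
∂t ρ + ∂x (ρ u) = 0,     u(t, x) = −(W' ∗ ρ)(t, x),
```

with the **linearly transformed particle (LTP) method**. The aggregation
equation is the mean-field model for swarming, granular media and
chemotaxis-type collective dynamics: infinitesimal mass elements attract (or
repel) each other through a pairwise interaction potential `W`, and,
depending on `W`, solutions either collapse toward Dirac masses in finite
time or relax to bounded steady profiles. The package is aimed at numerical
analysts and modellers who want a particle solver whose *density* (not just
its trajectories) converges strongly, together with the diagnostics needed
to study blow-up and steady states.

## The method

The initial density is sampled on a Cartesian grid of spacing `h` as
`ρ⁰_h = Σ_k ω_k φ_{h,k}`, where `φ` is a hat function or cubic B-spline and
the weights are either cell integrals `ω_k = ∫_cell ρ⁰` or bi-orthogonal
dual-kernel integrals (second-order accurate in a dual norm, possibly
negative). Each particle then carries, besides its position `x_k^n`, a
deformation matrix `D_k^n` and volume `h_k^n`, and the reconstruction is

```
ρ_h^n(x) = Σ_k (ω_k / h_k^n) φ( D_k^n (x − x_k^n) / h ).
```

One explicit-Euler step with rate matrix `A_k = (W'' ∗ ρ_h^n)(x_k^n)` reads

```
x_k^{n+1} = x_k^n − Δt (W' ∗ ρ_h^n)(x_k^n),      J_k^n = exp(−Δt A_k),
D_k^{n+1} = D_k^n (J_k^n)^{-1},                  h_k^{n+1} = det(J_k^n) h_k^n,
```

so each shape follows the linearization of the flow around its particle:
the particle size adapts automatically in time *and* space, which is exactly
what fixed-width smooth-particle (SP) reconstructions cannot do. Weights
never change, so the discrete mass `Σ ω_k` is conserved bitwise. The
convolutions are evaluated by one of three interchangeable strategies
(pairwise mollified-kernel **blob** sums, grid **quadrature**, or a
zero-padded **FFT** grid convolution with linear interpolation back to the
particles).

Built-in potentials: `quadratic` (`W = x²`, closed-form solution available),
attractive power laws `power:a` (`W = |x|^a/a`, singular for `1 < a < 2`),
and attractive–repulsive `attrep:a,b` (`W = |x|^a/a − |x|^b/b`). Error
reporting covers `L¹`/`L^p`/`L^∞` norms and the 1D bounded-Lipschitz
distance `d_BL(ρ₁, ρ₂) = ‖F₁ − F₂‖_{L¹}` of the CDFs.

## Worked example

Validation against the exact quadratic-potential solution
`ρ(t,x) = ρ⁰((x−λ)e^{2t}+λ) e^{2t}`:

```r
library(ltpagg)
sc  <- scenario(fixture = "rho1", potential = "quadratic",
                h = 1/25, dt = 1e-3, t_end = 0.5, shape = "b3")
res <- run_scenario(sc)
res$run
#> <ltp_run>  500 steps of dt = 0.001 (t = 0.5)
#> <particle_ensemble>  51 particles (d = 1), h = 0.04, shape 'b3', step n = 500
#>   total mass 1, volumes in [0.0147, 0.0147]
res$errors
#>     t    h    dt     l1     lp p   linf      dbl
#> 1 0.0 0.04 0.001 0.0265 0.0300 2 0.0775 0.002387
#> 2 0.5 0.04 0.001 0.0257 0.0482 2 0.2034 0.000854
```

Every particle volume ends at `0.04·e^{-1} ≈ 0.0147`: for `W = x²` with unit
mass the flow contracts uniformly at rate `e^{-2t}`, and the LTP volumes
track it exactly. The `L¹` error stays at the few-percent level while the
density steepens by `e ≈ 2.7`; `d_BL` (the weak-norm error) even decreases.
Comparing with a fixed-width SP reconstruction of the *same* particles
(`ε = h = 0.04`):

```r
compare_ltp_sp(scenario(fixture = "rho1", potential = "quadratic",
                        h = 0.04, dt = 1e-3, t_end = 0.5, shape = "b3"))
#>   method    h  eps     l1     lp p  linf      dbl
#> 1    ltp 0.04   NA 0.0257 0.0482 2 0.203 0.000854
#> 2     sp 0.04 0.04 0.1428 0.2567 2 1.046 0.005019
```

The transported shapes are ~5× more accurate in `L¹`: by `t = 0.5` the
inter-particle distance has shrunk to `0.37 h`, so the uniform width `ε = h`
over-smooths.

Blow-up diagnostics for the singular attractive potential `W = |x|^{1.5}/1.5`
(collapse to a Dirac mass; the run stops itself):

```r
run_scenario(scenario(fixture = "rho2", potential = "power:1.5",
                      h = 0.02, dt = 0.01, t_end = 5, blowup_ceiling = 1e6))
#> concentration detected at step 218 (t = 2.18): max 1/h_k = 2.82e+36 > 1e+06; stopping
```

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/ltpsim.R --mode converge --hs 0.2,0.1,0.05,0.025
Rscript inst/cli/ltpsim.R --mode run --potential attrep:3,1.5 --fixture rho3 \
    --h 0.02 --dt 0.01 --T 3 --outdir out/
```

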