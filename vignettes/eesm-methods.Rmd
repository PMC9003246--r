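---
title: "Equivalent-energy springs for real-time soft-tissue simulation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent-energy springs for real-time soft-tissue simulation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Classic spring–mass models (SMM) are fast enough for interactive surgical
simulation but, being built on Hooke's law, they only represent soft tissue
faithfully below roughly 10% elongation. Real parenchyma — liver is the
reference tissue throughout this package — stiffens strongly with stretch,
softens after its first loading (the Mullins effect), and unloads to a
nonzero residual stretch. Finite-element solutions of a full hyperelastic
constitutive law capture all of this but are far too slow for haptic frame
rates.

The equivalent-energy spring model (EESM) implemented here takes a hybrid
route: a full strain energy density function (SEDF) is evaluated *offline*
and converted into a table of stretch-dependent spring stiffnesses chosen so
that a one-dimensional spring stores exactly the tissue energy density at
every stretch. At run time each mesh edge performs one table lookup per
step, so the cost is that of a plain spring–mass mesh.

## The constitutive model

For incompressible uniaxial extension the principal stretches are
$(\lambda, \lambda^{-1/2}, \lambda^{-1/2})$, with invariants
$I_1 = \lambda^2 + 2/\lambda$ and $I_3 = 1$. The total energy density is a
mixture of an isotropic matrix phase and an "isotropized" fibre phase,

$$W_T = (1 - f)\,W_{\mathrm{iso}} + f\,W_{\mathrm{aniso}},$$

with the non-Gaussian (finite-extensibility) matrix energy

$$W_{\mathrm{iso}} = \mu\left[N\left(\beta\lambda_r +
\ln\frac{\beta}{\sinh\beta}\right) - \ln(\beta\lambda_r)\right] + c,
\qquad
\lambda_r = \frac{\lambda_{\mathrm{chain}}}{\sqrt N},\quad
\lambda_{\mathrm{chain}} = \sqrt{I_1/3},$$

where $\beta$ is the inverse Langevin function of $\lambda_r$, evaluated
through the Puso approximant $\beta = 3\lambda_r/(1-\lambda_r^3)$, and the
fibre energy is quadratic in $(I_1 - 3)$:

$$W_{\mathrm{aniso}} = \frac{A_1}{3}(I_1-3) + \frac{A_2}{9}(I_1-3)^2
- \frac{2A_1}{3}\ln\sqrt{I_3},$$

whose logarithmic term vanishes identically under the incompressible
kinematics used here. Stress softening multiplies the stress by

$$\mathcal{F}(m, M) = e^{-b\sqrt{M-m}}\sqrt{m/M},\qquad
m = \sqrt{\lambda^4 + 2\lambda^{-2}},\quad M = m(\lambda_{\max}),$$

and residual strains enter through the gradient terms
$g_k = -4\lambda_k(\lambda_{\max,k}^{\,n} - \lambda_k^2)$ scaled by
$\mu C$. Engineering stresses are always formed as Cauchy stress
*differences* with traction-free lateral faces, so the hydrostatic pressure
never appears as data.

### Design choices in the constitutive layer

Several pieces of this family of models are conventionally written with
ambiguities that an implementation must resolve; the choices made here are:

* **Integration constant $c$.** Set so that $W_{\mathrm{iso}}(\lambda=1)=0$.
  Zero rest energy is what makes the stiffness conversion below well behaved
  near $\lambda = 1$.
* **Response function.** The virgin stress uses
  $\aleph = (\mathrm{d}W_{\mathrm{iso}}/\mathrm{d}\lambda_r)/(3N\lambda_r)$
  evaluated as the *exact* derivative of the energy as implemented, which
  adds a $\beta'(\lambda_r - L(\beta))$ correction that would vanish if
  $\beta$ were the exact inverse Langevin. Correctness is defined by
  agreement with the central-difference derivative of $W_T$; the measured
  agreement is ~1e-7 relative over $\lambda \in [1.01, 1.29]$ (the package
  contract is 1e-3).
* **Softening variables.** $m$ and $M$ are read with the radical
  ($m = \sqrt{\lambda^4 + 2\lambda^{-2}}$) and $M \equiv m(\lambda_{\max})$,
  which guarantees $m = M$, hence $\mathcal{F} = 1$, exactly at the reversal
  point — a property the model needs to make unloading start from the virgin
  curve. The factor lives behind a single function
  (`softening_factor()`) so an alternative reading is a one-line change.
* **Residual-strain gradient.** $g_k$ is the partial derivative of
  $\Phi = \sum_a (\lambda_{\max,a}^{\,n} - \lambda_a^2)^2$ with respect to
  $\lambda_k$, validated against finite differences of $\Phi$.
* **Continuity at reversal.** With $n = 1$ the $C g_k$ term does *not*
  vanish at $\lambda = \lambda_{\max}$, so the softened branch starts a
  small step above the virgin curve (about 1.1% of the virgin stress, or
  1.67 kPa, for the liver constants at $\lambda_{\max} = 1.3$;
  `reversal_stress_gap()` reports it). The model is implemented as written
  rather than patched; everywhere below the immediate vicinity of the
  reversal point the softened stress is dominated by the virgin stress, and
  the tests check dominance on that interior while asserting the analytic
  value of the gap.
* **Chain lock guard.** $\lambda_r \ge 0.999999$ raises an error instead of
  returning `Inf`; stiffness tables must stop short of the lock stretch
  (about 1.5045 for $N = 1.1974$).

The reference constants, estimated from porcine-liver loading/unloading
tensile tests, are available as `liver_params()`:
$\mu = 0.1$ kPa, $N = 1.1974$, $b = 3.3389$, $A_1 = 9.6754$ kPa,
$A_2 = 7543.6$ kPa, $C = 9.5273$ kPa, $f = 0.2755$, $n = 1$.

## Equivalent-energy stiffness tables

The hybrid step equates the SEDF with the stored energy of a spring of
stretch-dependent stiffness $k_s$ (units: newtons, with the force law
$F = k_s(\lambda_s)\lambda_s$):

$$W_s = \frac{k_s \lambda_s(\lambda_s - 1)}{2\nu_{ij}} = W_T(\lambda_s)
\quad\Longrightarrow\quad
k_s(\lambda) = \frac{2\nu_{ij} W_T(\lambda)}{\lambda^2 - \lambda},$$

where $\nu_{ij}$ is the transversal-area parameter (the liver reference
value is $3.569\times10^{-5}$ m²). Tables are dense arrays on a stretch
grid (default spacing $10^{-3}$ from $1+10^{-6}$ to $\lambda_{\max}$),
precomputed once at initialization and interpolated linearly at run time —
never rebuilt inside the simulation loop. Numerical details:

* The $\lambda \to 1$ limit of the ratio is $0$ (both $W_T$ and the stress
  vanish at rest, so $W_T = O((\lambda-1)^2)$); lookups below the first
  grid node interpolate through the analytic anchor $k_s(1) = 0$.
* The identity $k_s\lambda(\lambda-1)/(2\nu_{ij}) = W_T(\lambda)$ is exact
  by construction at every node and is asserted to 1e-10 relative in the
  tests (numerator and denominator use the same `lam * (lam - 1)`
  expression, so the round trip cancels exactly in floating point).
* Lookups beyond the tabulated maximum raise an error — extrapolating the
  energy equivalence past the reversal stretch is unsafe — while the
  simulator treats that condition as an instability diagnostic.

**Unloading branch.** The softened branch needs a stored-energy function of
its own, which the constitutive layer does not define directly. It is taken
as the work along the unloading path: the softened engineering stress is
integrated from the residual stretch $\lambda_{\mathrm{res}}$ (its
zero-stress crossing; 1.0469 for the liver constants at
$\lambda_{\max}=1.3$) up to $\lambda$, and the same conversion is applied.
The integrand has a square-root cusp at the reversal point (from
$e^{-b\sqrt{M-m}}$), so the cumulative trapezoid uses a grid refined to
$\mathrm{d}l/32$, which keeps it within ~1e-5 relative of adaptive
quadrature. Below $\lambda_{\mathrm{res}}$ the stored energy and stiffness
are zero: an unloaded element is slack below its permanent set. One
unloading table is built per distinct reversal stretch actually reached,
cached with the reversal stretch quantized *upward* to $10^{-3}$ so the
cached table always covers the element's stretch.

## Spring–mass simulation

Each mesh edge is an element with rest length from the initial geometry.
Node masses are lumped proportionally to incident rest length with a
default tissue density of 1060 kg/m³. The integrator is semi-implicit
(symplectic) Euler with mass-proportional velocity damping; velocity Verlet
is provided for conservation studies. None of this is constrained by the
constitutive model — they are standard simulation choices:

* **Force convention.** Default `energy-consistent`, $F = k_s\lambda_s$,
  under which the tabulated energy identity is exact and a single element's
  tension test reproduces the secant stress $2W_T(\lambda)/(\lambda-1)$
  exactly. The classic Hooke-style form $F = k_s(\lambda_s - 1)$ (stiffness
  $k_s/L$ in N/m) is available as `hooke-extension`.
* **Compression.** The energy-equivalence formula is undefined for
  $\lambda < 1$; elements respond with the linear tangent extrapolated from
  the first table nodes, which avoids unphysical zero resistance while
  staying outside the constitutive model's claims.
* **Mullins history.** Each element tracks its historical maximum stretch
  (non-decreasing by construction); at or above it the virgin table is
  used (and the maximum updated), below it the unloading table for that
  maximum. Disabling `mullins` in `sim_config()` makes the force field
  conservative, which is how the Verlet energy-drift test is run (drift
  below 1% over $10^4$ steps on a two-element chain at a stable step).
* **Stability.** `stable_dt()` estimates the stiffest element mode from the
  maximum tabulated force slope and the lightest node and suggests a
  conservative fraction of the stability limit. Divergence is detected
  (non-finite state or out-of-table stretch) and aborts with the offending
  element and a suggestion to reduce `dt`.

**Virtual tension tests.** `run_virtual_uniaxial_test()` ramps the driven
face of a mesh quasi-statically to each target stretch and back, relaxing
the interior with damped substeps at every increment until the free-node
force residual is small relative to the boundary reaction (floored at 0.1%
of the table's maximum force so the slack unloading tail also converges),
and warm-starting each increment with an affine axial rescale of the mesh
so boundary-adjacent elements are never kicked. Kinetic-to-elastic energy
ratios are monitored online and stay far below the 1% quasi-static
criterion. For the beam consistency check the lattice is generated without
face diagonals: homogeneous axial extension is then an exact equilibrium,
making the mesh response directly comparable to the single-element
prediction (agreement to ~1e-14 in practice; diagonal lattices add shear
stiffness and lateral coupling and are the default for general use).

## Fitting

`fit_material_params()` estimates $(\mu, N, b, A_1, A_2, C, f)$ (with $n$
fixed at 1) by plain least squares on engineering stress, both branches
pooled; a relative-error loss is available behind a flag. The optimizer is
BFGS in a transformed space — log scales for the positive constants, logit
for $f$, and $N = N_{\min} + e^{\theta}$ with $N_{\min}$ fixed by requiring
the chain lock stretch to stay beyond the largest stretch in the data —
with 20 Latin-hypercube multi-starts (deterministic given the seed) plus a
Nelder–Mead/BFGS polish of the winner.

On one test direction the model is over-parameterized: for example only the
product $\mu C$ is identified by the residual-strain behaviour, and
$(\mu, N)$ trade off against $(A_1, A_2, f)$ in the stiffening response.
Fits are therefore judged by *predictive recovery* — whether the fitted
model reproduces the generating stress curves — rather than by raw
parameter values; the returned correlation diagnostics flag the weakly
identified combinations. On noiseless synthetic cycles the fitted model
reproduces the generating curves to ~5e-7 of full scale; at 2%
multiplicative noise predictions stay within ~2% of the generating model
(the acceptance band is 5%).

## Synthetic data

`gen_uniaxial_cycles()` emulates the cyclic tensile protocol: three
loading/unloading cycles to increasing reversal stretches (1.15, 1.23,
1.30 — the canonical set used for the liver spring tests), each unloading
branch sampled down to its residual stretch where real samples go slack,
and reloading following the softened branch of the previous reversal until
the historical maximum is exceeded (the standard Mullins idealization).
Noise is multiplicative lognormal with mean 1 and configurable coefficient
of variation (stress data are positive and heteroscedastic); additive
Gaussian noise is available behind a flag. Defaults: 40 points per branch,
2% CV.

What the generator does *not* emulate — machine compliance, grip slippage,
preconditioning, rate dependence, specimen-to-specimen heterogeneity —
bounds what passing tests show: they demonstrate correctness of the model
and pipeline on data from the model's own class, not robustness to the full
physics of a wet-lab tensile test.

## Problem sizes and runtime

The test and acceptance workloads use deliberately desk-scale problems: a
$4\times2\times2$-cell beam (45 nodes, 96 elements) for the mesh-level
consistency checks, 240-sample curves with 20 multi-starts for the fits,
and a subdivision-4 icosahedral ellipsoid (7680 elements) as the
organ-scale stability demonstration, on which per-step wall times are
logged but never asserted — frame rates are hardware facts, not model
properties.

## Known limitations

* Only incompressible uniaxial kinematics: no general 3D stress states, no
  volumetric constraint on the mesh (element-wise model only).
* Single homogeneous material per mesh; per-axis stiffness tables are
  supported (`axis_stiffness()`) but the isotropized liver model shares one
  table across axes.
* The stress step at the reversal point discussed above is a property of
  the constitutive form with $n = 1$, reported rather than hidden.
* No viscoelasticity, collision handling, or haptic/rendering integration.
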