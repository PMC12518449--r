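---
title: "Methods: models, numerics and design choices in shiftpeaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, numerics and design choices in shiftpeaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`shiftpeaks` studies the non-local selection–mutation equation

$$
\partial_t n_\varepsilon - \varepsilon^2\partial_{xx} n_\varepsilon
 = n_\varepsilon\,(a(x,t) - \rho_\varepsilon(t)),\qquad
\rho_\varepsilon = \int n_\varepsilon\,dx,
$$

for a density $n_\varepsilon(x,t)$ of individuals with trait $x$ (arbitrary
trait units) at time $t$ (units of inverse per-capita growth). Mutation is a
diffusion with rate $\varepsilon^2$; competition is uniform across traits, so
the only non-linearity is the scalar $\rho_\varepsilon$. The fitness
landscape is a sum of compactly supported polynomial bumps
$(h - (x - x_0)^p)^+$ minus a constant death rate $d$, each bump shifting
linearly at the trait-scaled speed $\varepsilon c$. Two regimes are
supported: a common speed (Case 1) and two bumps diverging at
$c_1 < 0 < c_2$ (Case 2).

The structural assumptions the theory needs — negative fitness outside a
bounded support, finitely many isolated global maxima, an exponentially
bounded initial density, and the exact count of crossings of the lag level
$a_M - c^2/4$ (two between consecutive peaks, one behind the outermost
peak) — are all checkable with `validate_assumptions()`, which probes a
dense grid and reports each item with locations rather than failing
silently.

Why bumps only: every published experiment this package reproduces uses the
$(h - (x-x_0)^p)^+$ family, whose maxima, curvatures and support edges have
closed forms; that makes the spectral predictions exact rather than
themselves numerical. Arbitrary callables are accepted via
`custom_landscape()` (used internally for flat-landscape oracles); their
maxima and curvatures then come from grid refinement with one Richardson
extrapolation of central second differences (step $10^{-3}$), which is
accurate to $O(10^{-8})$ for smooth shapes but inherits no exactness
guarantees.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| $\varepsilon$ | mutation scale; diffusion is $\varepsilon^2$ | 0.1 (0.05 for the overlapping-peaks preset) | the caption values of the experiments being reproduced |
| $c$, $(c_1, c_2)$ | shift speed(s) in the scaling $\tilde c = \varepsilon c$ | preset-specific (1; $-1$ and 2.5; $\mp 6/5$) | caption values |
| $d$ | constant death rate | $1/2$ (presets `fig6`/`fig7` carry the printed $-1/2$) | see "The sign of d" below |
| $L$, $N_x$ | trait domain $[0, L]$ and node count | 80, 1600 ($\Delta x = 0.05$) | supports sit at $x \approx 28$–52 and must stay $\ge 5$ units from the Dirichlet boundary over the whole run |
| $\Delta t$ (FD) | explicit Euler step | $\min(0.9\,\Delta x^2/(2\varepsilon^2),\ 0.05)$ | diffusion CFL plus a reaction bound keeping the update positive |
| $R$ | eigenproblem ball radius | 30, centred on the landscape | the eigenvector decays like $e^{-\kappa|x|/\varepsilon}$, so $\lambda_R$ stabilizes to $10^{-8}$ well before $R = 30$ |
| eigen $\Delta x$ | eigen grid spacing | $\varepsilon/10$ | resolves the $O(\sqrt\varepsilon)$ eigenvector width |
| $w$ | mass-window half-width | $3\sqrt\varepsilon$ | three standard deviations of the $O(\sqrt\varepsilon)$-wide concentration profile |

## What the generator emulates — and what it does not

The landscape/initial-condition module *is* the data generator: there is no
external data, and nothing in the pipeline is random (experiments are
bit-identical across reruns; the only seeded randomness in the repository is
the choice of probe points in the representation-formula oracle tests).

It emulates: compact fitness ranges with one or two optima, deterministic
linear environmental drift, Gaussian founding populations
($n_0 = \tfrac1{10}e^{-(x-37.5)^2/10^2}$, the printed initial condition),
and the rare-mutation scaling in which selection and mutation interact at
order $\varepsilon$.

It does not emulate: demographic stochasticity (the PDE is deterministic, so
"extinction" means $\rho \to 0$, not absorption), trait-dependent
competition kernels, periodic or random environments, higher-dimensional
traits, or non-diffusive mutation kernels. A green test therefore
establishes agreement between two *deterministic* computations (simulation
and spectral theory), not robustness of the biology to noise.

Two caption gaps are filled by package choices, once: the
overlapping-peaks preset (`fig8`) prints no initial condition and reuses the
Gaussian above; the limit scheme needs an $\varepsilon$-free initial phase
and uses $v_0 = u_0(\cdot;\varepsilon = 0.1) - \min u_0$, which satisfies the
constraint $\min v_0 = 0$ exactly.

## Numerical choices

**Finite-difference solver.** Forward Euler with centred second differences
on $[0, L]$, Dirichlet rows at both ends. The default mode implements the
full model: $\varepsilon^2$ on the diffusion term and the competition
$-\rho^k n$ subtracted explicitly at the current step (growth evaluated at
$t_{k+1}$, as printed); a `paper_literal` mode preserves the shorthand
update exactly as printed, for auditability. Mass uses the rectangle rule
$\Delta x \sum_j n_j$, matching the scheme's own discrete mass. Runs abort
rather than proceed when the shifted support comes within 5 units of the
boundary, because the Dirichlet truncation is only harmless while the
solution concentrates away from it.

**Eigenproblems.** The stationary problems are solved on interior nodes of a
ball *centred on the landscape* (the landscapes live at $x\approx 28$–52, so
an origin-centred ball of the usual radii would miss them; nesting — and
hence monotonicity of $\lambda_R$ — is preserved because all radii share the
centre). The symmetric tridiagonal operator's smallest eigenpair comes from
shifted inverse iteration: the shift starts just below the Rayleigh bound
$\lambda \ge -\max V$ and switches to Rayleigh-quotient shifts once the
residual is small (the Rayleigh quotient minus the residual cannot cross the
ground state, so the iteration cannot lock onto an excited state). The drift
problem is solved by the discrete Liouville similarity — solve for
$a - c^2/4$, scale by $e^{-c(x - x_{\mathrm{ref}})/(2\varepsilon)}$ in log
space — which preserves the eigenvalue *exactly*; a direct nonsymmetric
solve (centred drift differences, real spectrum for
$\Delta x < 2\varepsilon/c$) is kept as a cross-check and agrees to
$O(\Delta x^2)$.

**Eigenvector tails.** Iterative eigensolvers leave a relative noise floor
near machine precision, which is *far above* the true
$e^{-\kappa|x|/\varepsilon}$ tails; naively multiplying by the exponential
Liouville weight would amplify that noise into a spurious left tail. The
tails are therefore re-solved from the converged eigenvalue as an anchored
boundary-value problem on the tail subdomain (diagonally dominant there, so
well conditioned). This matters for the decay-envelope checks and for the
mass identity $\int a\,p_\varepsilon = -\lambda_\varepsilon$, which holds to
$5\times10^{-5}$ once the tails are clean.

**Hamilton–Jacobi schemes.** The phase $u = -\varepsilon\log N$ obeys, in
the slow time $\tau = \varepsilon t$,
$\partial_\tau u + |u_x - c/2|^2 = \varepsilon u_{xx} -
(a - c^2/4 - \rho)$. Deriving this from the co-moving PDE fixes two details
the shorthand formulas leave ambiguous: the source enters with a minus sign
(the phase must *decrease* where fitness exceeds $\rho$), and one HJ time
unit equals $1/\varepsilon$ PDE time units — verified numerically by
matching the scheme against the co-moving FD density at $\tau = \varepsilon
t$. The Hamiltonian is the monotone Godunov-type
$\max\{H^+(D^-u - c/2), H^-(D^+u - c/2)\}$; both one-sided slopes use one
ghost node of linear extrapolation. The time step respects the gradient CFL
for the *stationary* slope bound $S = \sqrt{a_M - a_m} + |c|/2$ (the slopes
grow from their initial values to the eikonal slopes $\approx 2$, so a step
sized from the initial phase alone blows up), with an additional diffusion
bound for $\varepsilon > 0$. In the limit scheme, the multiplier $P_{n+1}$
is the root of a per-node-affine function of $J$ with slope $+\Delta t$, so
the closed form $P_{n+1} = \max_i [a_i - c^2/4 + H_i - v_i/\Delta t]$ is
exact; a bisection cross-check is retained. The constraint
$\min_i v_i^{n+1} = 0$ then holds to rounding and the $10^{-16}$-scale
residue is subtracted so the invariant is exact.

**Phase minimizer.** The argmin tracker refines the discrete `which.min` by
the standard 3-point parabolic interpolation, removing the $\pm\Delta x$
quantization. At $\varepsilon = 0.1$ the *physical* stationary density peak
sits $\approx 0.06$ ahead of the $\varepsilon\to0$ lagged optimum (computed
independently from the exact drift eigenvector), so comparisons against the
limiting prediction are made at the stationarity horizon $\tau = 8$, where
$P_n$ has converged, rather than in the transient.

**Representation formula.** The geodesic cost
$-|\int_x^y \sqrt{a_M - a}\,|$ uses adaptive quadrature (absolute tolerance
$10^{-10}$) split at support edges and peak locations, where the integrand
has integrable kinks; the independent oracle is a dynamic-programming sum
over monotone grid paths (optimal in one dimension for a nonnegative
integrand), and the two agree to $O(\Delta x)$.

**Ties and degenerate inputs.** Peaks tied in $|a''|$ (to $10^{-9}$) are all
reported as shallowest; the theory leaves their Dirac weights undetermined
and so does the package. Dominance below a 0.5 mass fraction, or eigenvalues
tied to $10^{-6}$ in the two-speed classification, return "undetermined"
rather than an arbitrary winner. $c = 0$ collapses lagged optima onto the
peaks; a lag level below the off-support fitness returns an empty candidate
set (the extinction regime).

## The sign of d

The two-speed experiment captions print $d = -1/2$ although the model
declares $d$ a positive constant. The presets carry the caption value so the
published parameter sets are reproduced verbatim, and `validate_assumptions()`
warns (rather than errors) when $d \le 0$. All Case-2 *conclusions* exercised
by the tests — the dominant-index crossover at $c_2 = 2$ and the transient
overtaking — are invariant to $d$, which shifts both eigenvalues equally.

## Run lengths

Scaled-down horizons are fixed from time-scale estimates, not tuned: the
mass relaxes logistically at rate $\approx \rho_\infty$ (a few time units);
peak selection separates subpopulations at the eigenvalue gap
$\approx \varepsilon\sqrt{|a''|/2}$, giving
$t \approx \log(20)/0.05 \approx 60$–80 for the two-peak presets at
$\varepsilon = 0.1$. Hence $T = 60$ (single peak), 80 (two peaks), 40
(diverging peaks), 25 (extinction, decay rate $\ge d$), and $\tau = 8$ for
the HJ schemes ($\,= 80$ PDE time units). Everything completes in seconds
per run on one CPU.

## Known limitations

* First-order schemes: the FD solver is $O(\Delta t + \Delta x^2)$ and the
  HJ schemes $O(\Delta x)$ near kinks; no ENO/WENO or implicit stepping.
* The whole-line eigenvalue is the stabilized ball value (threshold
  $10^{-8}$); no convergence *rate* in $R$ is claimed, matching the theory,
  which gives none.
* Dirac weights $\alpha_i$ of the limiting measure are not computed — the
  theory leaves them undetermined, and the package reports mass fractions in
  finite windows instead.
* The decay-envelope check is restricted to nodes where the (tail-refined)
  eigenvector is numerically meaningful and outside a 2-unit boundary
  layer, with a 5% log-scale slack; it validates the printed envelope
  constants, not sharper ones.
* Case 2 is simulated in the lab frame only; a co-moving formulation exists
  per group but is not implemented (each group would need its own frame).
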