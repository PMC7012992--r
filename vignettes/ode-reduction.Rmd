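---
title: "Exact ODE reduction of structured population models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact ODE reduction of structured population models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pspmreduce)
```

## The model class

A physiologically structured population model (PSPM) describes a population
by a measure $m$ over an individual-state (i-state) space
$\Omega \subset \mathbb{R}^n$ — think of $x$ as size or age.  Its
ingredients are

* a deterministic i-state growth rate $g(x, E)$,
* a death rate $\mu(x, E)$,
* a birth law, restricted here to a finite Dirac mixture
  $\beta(x, E, \cdot) = \sum_i \beta_i(E)\,\alpha_i(x)\,\delta_{b_i}$:
  offspring appear at fixed states $b_i$, at per-capita rates that factor
  into an environment part and a parent-state weight,
* output weight functions $\gamma_i$, so that outputs are
  $\langle m, \gamma_i\rangle = \int_\Omega \gamma_i\,dm$.

The environment $E$ (food, predation pressure, temperature) enters only
through named scalar *atoms* — opaque functions of $E$ such as a functional
response `f` or a background death rate `mu0`.  The package never evaluates
$E$; it substitutes numbers for atoms.  Feedback through a shared
environment is what later couples populations into community models, so the
single-population model is treated as a state-linear input–output system
with $E$ as input.

The question the package answers: for which ingredient combinations can the
infinite-dimensional model be replaced — *exactly*, with no loss of output
information — by a finite ODE system $dN/dt = K(E)N$ with
$N = \langle m, \Psi\rangle$ for a finite vector of weight functions
$\Psi = (\psi_1,\dots,\psi_k)$?

## The backward operator and the TEST

The generator of the weight-function (clan-average) dynamics is the backward
operator

$$(\bar A(E)\psi)(x) = \nabla\psi(x)\cdot g(x,E) \;-\; \mu(x,E)\,\psi(x)
  \;+\; \sum_i \psi(b_i)\,\beta_i(E)\,\alpha_i(x).$$

A reduction exists if and only if some finite, $E$-independent function
space containing the outputs is invariant under $\bar A(E)$ for every $E$.
`run_test()` implements the classical search: start from the span $V_0$ of
the output weights (plus every birth weight $\alpha_i$, which the Dirac
restriction puts on a par with the outputs), apply $\bar A$, and adjoin any
component that escapes the current span, repeating until the span closes or
a cap is hit.  "For every $E$" is made finite by the separated form: each
image is a finite sum of (atom monomial) × (i-state function) terms, and
each i-state part is tested for span membership separately.

On closure the matrices are assembled by expressing each image in the basis:
$K(E)$ from $\bar A$, $H(E)$ from the transport–death part alone,
$M = K - H$ (the birth coupling; cross-checkable directly via
`assemble_M()`), and $Q(E)$ expressing the outputs.  The defining residual
$\bar A(E)\Psi - K(E)\Psi$ is then re-verified symbolically; a nonzero
residual degrades the status rather than passing silently.

```{r}
model <- fixtures()$daphnia$model
res <- run_test(model, seed = 1)
res$status
vapply(res$basis, sf_format, character(1))
```

Exceeding the cap yields status `not_reduced_within_cap`, never a claim of
irreducibility: deciding true non-reducibility may need unboundedly many
iterations, so the cap (default 12) only bounds the search.

## The symbolic engine

Everything above rests on exact symbolic manipulation: derivatives of weight
functions, products with rates, and — crucially — deciding that a residual
is *identically zero*.  The package implements a small, closed expression
algebra (`symf`): finite sums of terms

$$c \cdot \prod_f f^{p_f} \cdot e^{P},$$

where each factor $f$ is a plain symbol or one of the kernels
$u^r$ (general powers of multi-term expressions), $\log u$, $\sin u$,
$\cos u$, $\tan u$, and $P$ is the merged argument of a single exponential
factor.  This class is closed under addition, multiplication, integer
powers, substitution and differentiation — exactly the operations iterated
application of $\bar A$ requires — and exponential arguments merge
($e^{u}e^{v} = e^{u+v}$, $e^{c\log u} = u^c$), so equality of two
expressions reduces to equality of canonical coefficients.  "Simplifies to
zero" therefore means: every canonical coefficient vanishes relative to the
expression's own coefficient scale (tolerance $10^{-9}$ relative, needed
because coefficients are floating point).  It is not a sampling heuristic
and cannot be fooled by aliasing.

Antidifferentiation (needed by the catalogue, below) is supported for the
classes that the catalogue formulas actually produce: polynomials, real
powers $x^r$ and $(a+bx)^r$ (including logarithmic cases), and
polynomial × linear-argument exponentials, with integration by parts for
$x^n e^{\alpha x}$.  Integrands outside this class raise an integration
error rather than silently switching to quadrature: a spline-backed weight
function could not take part in the exact zero tests that the TEST and the
identity checks require, so the symbolic class is a deliberate boundary of
the package.

## Linear independence: a two-path certificate

Finite-precision "linear independence" needs a protocol.  The primary path
evaluates the candidate functions at $\max(3k, 12)$ seeded interior points
and counts singular values above $10^{-8}$ of the largest.  For
one-dimensional analytic inputs a secondary path computes the symbolic
Wronskian, whose identical vanishing characterises dependence for analytic
functions.  The two verdicts must agree; disagreement raises an error for
manual review instead of picking a side.  Every certificate records the
seed, the points and the singular values.

Span membership during the TEST follows the same philosophy: a seeded
least-squares fit proposes coefficients, and acceptance requires the
*symbolic* residual (candidate minus fitted combination) to vanish in
canonical form.  Numeric-only acceptance is never final.  Newly accepted
candidates are row-reduced against the pivots of the existing basis — an
exact elimination that leaves the span unchanged but produces the clean,
reproducible bases seen above ($x^3, x^2, x, 1$ rather than arbitrary
combinations), and with it a stable layout for $K(E)$.

## The catalogue of reducible one-dimensional models

For one-dimensional i-states and Dirac-mixture births, the reducible
transport–degradation models form exactly three families, parametrised by
functions $\gamma_0(x)$, $\mu_0(E)$, $v_0(x)$, $v_{1,2,3}(E)$ with
$\zeta(x) = \int_{x_b}^x dy/v_0(y)$ and survival factor
$\mathscr{G}(x) = \exp\int_{x_b}^x \gamma_0$:

* **F1** (`make_f1()`): $k = 1$, any $g$,
  $\mu = \gamma_0 g + \mu_0(E)$, $w = \mathscr{G}$, $H = -\mu_0$.
* **F2** (`make_f2()`): physiological age, $g = v_0(x)v_1(E)$,
  $w = \mathscr{G}\,e^{\zeta\Lambda}w(x_b)$,
  $H = v_1(E)\Lambda - \mu_0(E)I$.  Non-degeneracy needs (H2) — every
  eigenvalue of $\Lambda$ has geometric multiplicity one — and (H3) — the
  expansion of $w(x_b)$ hits the highest-rank generalised eigenvector of
  every Jordan chain (`check_h2_h3()`).
* **F3** (`make_f3()`): generalised von Bertalanffy,
  $g = v_0(x)\,(v_1 + v_2\zeta + v_3\zeta^2)$,
  $\mu = \gamma_0 g + \mu_0 + (k-1)v_3\zeta$,
  $w_j = \mathscr{G}\zeta^{j-1}$, with the banded $H_0$ (subdiagonal
  $(i{-}1)v_1$, diagonal $(i{-}1)v_2$, superdiagonal $-(k{-}i)v_3$).
  The von Bertalanffy, logistic and Gompertz growth laws all fit after an
  i-state transformation.

`verify_identity()` checks the defining identity
$g\,w' = (H(E) + \mu I)\,w$ by the canonical-coefficient zero test, with a
seeded 50-point numeric evaluation as fallback for instances (such as
Möbius-transformed ones) whose equal canonical forms differ structurally.

Design choices worth recording:

* **Real eigenvalues only in F2 weight construction.**  The
  matrix-exponential action $e^{\zeta\Lambda}w(x_b)$ is built by Putzer's
  recursion, whose scalar functions stay in the symbolic class for real
  eigenvalues.  Complex pairs would require trigonometric weights; that
  branch is exposed through the dedicated trigonometric constructions
  (`trig_matrix()`, `trig_solution()`, and the tan-substitution view of
  F3), so `make_f2()` refuses complex spectra explicitly rather than
  approximating.
* **Jordan-chain conventions.**  Chains are detected numerically
  (clustered eigenvalues, SVD null spaces); "highest rank" means the chain
  generator, the vector mapped longest before annihilation.  (H3) is tested
  as: $w(x_b)$ must not lie in the span of the lower-rank part of each
  chain together with all other generalised eigenspaces.
* **$v_3$ defaults to 0 in generators.**  The quadratic-in-$\zeta$ growth
  term requires a $k$-specific compensation term in the death rate and has
  no biological reading; constructors support it fully (and the Möbius
  reparametrisation `mobius_reparam()` mixes it into $v_1, v_2$), but
  randomized instance generators leave it at zero unless asked.

The Möbius transformation $\eta = (a\zeta+b)/(c\zeta+d)$ maps F3 instances
to equivalent F3 instances with the same weight span.  The package's
parameter-update formulas keep $g$ and $\mu$ invariant as functions (to
machine precision), which fixes the normalisation of the $\tilde\mu_0$
update as $\mu_0 - (k-1)(acv_1 - bcv_2 + bdv_3)/(ad-bc)$.

The special matrices connect F3's complex branch to classical spectral
theory: the Kac–Sylvester tridiagonal matrix has eigenvalues
$2j - k - 1$, its trigonometric companion has eigenvalues $(2j-k-1)i$ via
the diagonal similarity $S = \mathrm{diag}(i^{j-1})$, and
$\tilde\Phi_j(t) = \sin^{j-1}t\,\cos^{k-j}t$ solves the companion ODE
system exactly — an identity the test suite verifies symbolically.

## Age structure and the linear chain trick

For age ($g \equiv 1$, births at age 0) the birth measure has
one-dimensional range, F3 collapses into F2 (`Lambda = H_0`, with
$\gamma_0$ absorbing the $(k-1)v_3\zeta$ term), and
`age_structured_reduce()` gives
$dN/dt = (M(E) + \Lambda - \mu_0(E)I)N$ with
$M_{ij}(E) = w_i(0)\tilde\beta_j(E)$.  The Erlang chain
($\Lambda$ with diagonal $-\alpha$, subdiagonal $\alpha$,
$w(0) = (\alpha, 0, \dots)$) recovers the classical stage-structured
system, with stage weights $w_j(x) = \alpha^j x^{j-1}e^{-\alpha x}/(j-1)!$
— the linear chain trick.

Because the birth law has one-dimensional range, the full age density is
recoverable from the reduced trajectory for ages born after the start:

$$n(t,x) = e^{-\int_0^x\gamma_0}\;e^{-\int_{t-x}^t \mu_0(E)}\;
  \sum_j \tilde\beta_j(E(t{-}x))\,N_j(t{-}x), \qquad x < t.$$

`recover_age_density()` evaluates this with the $\gamma_0$ integral in
closed form and the $\mu_0$ survival integral by a fixed-step midpoint rule
accumulated once on a grid (step $10^{-3}$ time units by default).  Ages
$x \ge t$ belong to founder cohorts and are deliberately not recoverable.

## Cross-validation by cohort simulation

The reduction is an exact statement; the package realises it numerically by
simulating the structured model directly and comparing.  The population is
a finite list of point masses (cohorts).  Per step of size `dt`:

* positions follow $dx/dt = g(x, E(t))$ by classical RK4;
* masses decay by the exact exponential of the midpoint death rate;
* each birth term spawns one pooled cohort per step (linearity makes the
  pooling exact for outputs).  The midpoint birth flux is corrected by a
  small implicit solve, $(I - \tfrac{dt}{2}B)\,\text{rate} = \text{base}$
  with $B_{ij} = \beta_i(b_j)$, which accounts for reproduction by
  individuals born earlier in the same step; newborn cohorts are advanced
  by their expected half step of growth and survival.  Both corrections are
  needed for the scheme to be genuinely second order; without them the
  birth handling carries an $O(dt)$ flux bias.
* cohorts below $10^{-14}$ of total mass merge into their nearest
  neighbour (mass conserving), and positions may be clipped onto $\Omega$
  only within $10^{-9}$ — larger overshoots abort, since they indicate a
  growth law inconsistent with the declared i-state space.

The closed-loop community (a Daphnia-style consumer on an unstructured
resource, $dE/dt = h(E) - f(E)N_2$) is integrated twice: the 5-dimensional
reduced system by RK4, and the cohort system with the resource advanced by
frozen-coefficient RK4 within each step (operator-splitting error
$O(dt^2)$, measured by the convergence ladder rather than assumed).

What the fixtures emulate — and what they do not.  The built-in models are
the worked examples of the theory: exact separated-form ingredients, Dirac
births, smooth rates, a scalar resource.  They exercise every code path of
the reduction machinery, but passing them says nothing about data-driven
concerns (measurement noise, misspecified rates, non-Dirac birth kernels,
stochastic i-state movement), all of which are outside the model class by
assumption.  Numeric parameters for the Daphnia fixture
(`daphnia_params()`: $\delta = 1$, $\varepsilon = 0.5$, $\alpha = 0.75$,
$\mu = 0.1$, $x_b = 0.5$, $\Omega = [0.5, 2.5]$) were chosen once so that
the growth asymptote $\delta f/\varepsilon = 2$ at the operating point
$f = 1$ lies inside $\Omega$ and growth is positive on all of $\Omega$ at
the reference valuation $f = 2$ (the reachability assumption).

Problem sizes used by the validation suite: open-loop agreement over
$t \in [0, 10]$ with a three-rung ladder $dt = 4, 2, 1 \times 10^{-3}$
(about $10^4$ cohorts at the finest rung), the closed loop at
$dt = 10^{-3}$, and density recovery on an 8-time-unit horizon with a
$2\times10^{-3}$ age grid.  These sizes make every comparison sharp
(observed agreement is at the $10^{-5}$–$10^{-7}$ level, far inside the
1–2 % acceptance bands) while keeping the full suite around a minute.

## Numerical choices, tie-breaks, degenerate inputs

* Candidate extraction follows insertion order of basis elements and
  canonical (lexicographic) order of atom monomials — the iteration trace
  and matrix layouts are deterministic for a given seed.
* Coefficient solves reuse the same seeded sample points as the
  independence certificates, so all linear systems see the same geometry.
* The zero expression has an empty term list; empty birth lists, zero
  outputs and $k = 1$ degenerate catalogue instances (F3 with $k=1$ is F1)
  are all legal and tested.
* Atoms may appear only polynomially (default degree cap 2) and never
  inside transcendental kernels of i-state quantities; violations raise a
  dedicated non-separability error, signalling the model is outside the
  supported class rather than mis-reducing it.
* Birth-state positions are environment-independent.  Positions depending
  smoothly on $E$ would turn $\psi(b_i(E))$ into a new composite atom;
  that extension is rejected with a clear error.

## Known limitations

* The catalogue (and hence classification) is one-dimensional;
  multi-dimensional reducible models are handled by the TEST directly, as
  in the built-in 2-D and 3-D examples, but no completeness statement
  attaches to them.
* `classify_ingredients()` is a semi-decision procedure with `v0 = 1`
  normalisation: a `"none"` verdict is advisory and `run_test()` remains
  the authority, since catalogue membership is only defined up to i-state
  transformations that pattern matching cannot exhaust.
* Symbolic integration boundaries as described above; weight constructions
  requiring complex matrix exponentials or non-closed-form $\zeta$ must be
  supplied explicitly (the test suite does exactly this for the
  Riccati-$\zeta$ age instance).
* The cohort solver is a validation instrument, not a production EBT
  implementation: no within-cohort moments, no PDE fallback, no
  steady-state or bifurcation analysis.
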