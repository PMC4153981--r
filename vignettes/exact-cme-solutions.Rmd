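---
title: "Exact solutions of the chemical master equation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact solutions of the chemical master equation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmexact)
```

## The model

A well-stirred reaction network of $n$ species and $m$ reactions, observed
at low copy numbers, is a continuous-time Markov chain on the lattice of
molecule-count vectors $\mathbf{s} \in \mathbb{N}^n$. Each reaction $k$
fires with propensity $a_k(\mathbf{s})$ — probability per unit time — and
shifts the state by the $k$-th column of the stoichiometric matrix
$\mathbf{N}$ ($n_{ij} = \beta_{ij} - \alpha_{ij}$). The probability
$p(\mathbf{s}, t)$ of occupying each state evolves under the chemical
master equation (CME)

$$\frac{d}{dt}\,\mathbf{p}(t) = \mathcal{A}\,\mathbf{p}(t),$$

where the $w \times w$ generator $\mathcal{A}$ carries transition
propensities off the diagonal and minus the total outflow propensity on
the diagonal. `cmexact` computes $\mathbf{p}(t)$ in closed form along two
routes, and ships a Gillespie direct-method simulator so every analytical
claim can be cross-checked against sampled trajectories.

### Route 1: spectral solution for any finite-state network

When $\mathcal{A}$ (or any rate matrix $\mathbf{A}$) has simple
eigenvalues $\lambda_\ell$, the solution of $\dot{\mathbf{y}} =
\mathbf{A}\mathbf{y}$ observed through a selection matrix $\mathbf{C}$ is

$$\mathbf{y}(t) = \sum_{\ell=1}^{n} \vartheta_\ell\,
  e^{\lambda_\ell t}\, \mathbf{M}(\lambda_\ell)\,\mathbf{e}_0,
  \qquad
  \vartheta_\ell = \prod_{k \neq \ell} (\lambda_\ell - \lambda_k)^{-1},$$

where $\mathbf{M}(\lambda)$ is $\mathbf{C}$ applied to the adjugate
(transposed cofactor matrix) of $\lambda \mathbf{I} - \mathbf{A}$
(`spectral_solution()`, `cofactor_columns()`, `theta_coefficients()`).
When the initial vector has a single nonzero entry — a deterministic
initial state, the common case for a CME — only one adjugate column is
needed. The formula trades a matrix exponential for eigenvalues plus
cofactors, and for tridiagonal $\mathbf{A}$ (unbranched chains) the
adjugate comes from the $O(n^2)$ Usmani $\theta/\phi$ recursions
(`tridiagonal_adjugate()`), whose $\theta_n$ is $\det$ — so the recursion
is valid even at eigenvalues, where the shifted matrix is singular by
construction.

### Route 2: Poisson ⊛ Multinomial solution for monomolecular networks

For networks built only from conversions $S_i \to S_j$, syntheses
$0 \to S_i$ and degradations $S_i \to 0$ (`mono_network()`), the mean
dynamics are linear, $\dot{\mathbf{c}} = \mathbf{A}\mathbf{c} +
\mathbf{b}$, and the CME started from the deterministic state
$\boldsymbol{\xi}$ has the exact solution

$$p(\cdot, t) = \mathcal{P}(\cdot, \boldsymbol{\nu}(t)) \ast
  \mathcal{M}(\cdot, \xi_1, \mathbf{q}^1(t)) \ast \cdots \ast
  \mathcal{M}(\cdot, \xi_n, \mathbf{q}^n(t)),$$

a convolution of one product-Poisson and one Multinomial per initially
populated species. The parameters solve $n$-dimensional linear ODEs —
$\dot{\mathbf{q}}^j = \mathbf{A}\mathbf{q}^j$ from the $j$-th unit vector,
and $\dot{\boldsymbol{\nu}} = \mathbf{A}\boldsymbol{\nu} + \mathbf{b}$
from zero — which `cmexact` evaluates with the Route-1 spectral formula.
The payoff is dimensionality: the ODEs are of order $n$ (species), not $w$
(states), and marginals over a subset $\mathcal{I}$ of species come from
simply restricting each parameter vector to the entries in $\mathcal{I}$
(`marginal_distribution()`) — no full distribution is ever formed. For an
unbranched chain queried on its first and last species this reduces an
arbitrarily long chain to a two-dimensional lattice problem.

Closed conservative topologies get explicit equilibria: chains via the
product formula over forward/backward rates (`chain_equilibrium()`,
accumulated as sums of logs so hundred-species chains cannot overflow),
rings via row sums of the inverse linear-rate map (`ring_equilibrium()`).

### Assumptions

* Mass-action propensities of at most second order (the four kinds of
  `reaction()`); no Hill or Michaelis–Menten propensities.
* The convolution solution requires a deterministic initial state
  $\delta_{\boldsymbol{\xi}}$; distributional initial conditions are out
  of scope.
* The spectral formula requires simple eigenvalues; see the fallback
  below.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cap` (open-network truncation) | none (required) | molecules/species | open state spaces are infinite; the leak is tracked, never hidden |
| Poisson truncation `tol` | `1e-12` | mass/axis | keeps convolution supports finite with auditable remainder |
| eigenvalue simplicity `tol` | `1e-8` (relative gap) | — | below this, partial fractions amplify rounding; fall back to the matrix exponential |
| `leak_tol` | `1e-9` | mass | validation threshold on distributions summing to one |
| `eta` (CLI comparison grid) | 50 | time points | benchmark convention for the transient error metric |
| horizon `relaxation_time()` | $6/\vert\lambda_{\max}\vert$ | time | six slow time constants equilibrate the transient |

Rate constants are always stored in stochastic (propensity) units;
`convert_rate()` is an explicit helper and is never applied implicitly,
because a silently double-converted bimolecular rate is the classic
unit bug in this field. Species order everywhere is declaration order.

## Numerical choices

* **State enumeration.** Closed networks (no reaction increases the total
  count) enumerate *every* nonnegative vector within the initial total —
  including dynamically unreachable combinations, which carry zero
  probability. This inclusive reading matches the published worked
  example; reachability-only enumeration would change state indices and
  make printed generators irreproducible. Canonical order is graded
  lexicographic; an explicit ordering can be supplied because published
  orderings are often ad hoc.
* **Adjugate evaluation.** Tridiagonal input always uses the Usmani
  recursions (exact at singular shifts; prefix products of off-diagonals
  are bypassed entry-wise when an off-diagonal vanishes). Dense input up
  to $n = 12$ uses cofactor expansion via LU determinants of minors.
  Larger dense matrices use $\det \cdot \mathrm{inverse}$, and at
  (near-)singular shifts a two-point average at $\pm\varepsilon$
  diagonal offsets, which cancels the $O(\varepsilon)$ term of the
  polynomial dependence; this branch is a convenience for large dense
  problems and is tested at its own, looser tolerance.
* **Repeated eigenvalues.** The spectral formula assumes simple
  eigenvalues. When computed eigenvalues come closer than the relative
  tolerance — which happens systematically for CME generators of
  conservative chains, whose spectra are sums of rate-matrix eigenvalues —
  `spectral_solution()` silently switches to a scaling-and-squaring matrix
  exponential and flags the switch in the `"fallback"` attribute. A
  confluent (Jordan-form) closed form is not implemented.
* **Complex spectra.** Tridiagonal Metzler matrices are similar to
  Hermitian matrices, so their spectra are provably real: rounding-level
  imaginary parts are discarded. Ring rate matrices may have genuinely
  complex pairs; the spectral sum is then evaluated in complex arithmetic
  and the (provably real) result is taken after checking the residual
  imaginary part.
* **Negative masses.** Floating-point cancellation in the spectral sums
  can produce tiny negative pmf values; anything above $-10^{-12}$ is
  clipped to zero, anything below raises an error rather than being
  hidden.
* **Truncation accounting.** Probability mass outside a truncated
  support is carried as `truncation_mass` through every convolution and
  CME solve, and is reported, never renormalized away.
* **Badly scaled rings.** Calcium-binding rates in the gating case study
  span ~35 orders of magnitude, so the ring-equilibrium linear solve is
  row-equilibrated first; when the linear-rate map is exactly singular
  (detailed-balance rings) the equilibrium is recovered from the
  one-dimensional null space of the rate matrix.

## What the case-study generators emulate

`autoactivation()` regenerates the published two-species nonlinear
mechanism with its explicit 10-state ordering, so the printed generator
matrix is reproduced entry for entry. `random_chain()` implements the
benchmark protocol for unbranched chains: rates drawn uniformly from
$[0, 1]$ and initial counts drawn as integers uniformly from
$\{1, \dots, 10\}$ (counts must be integral, so the integer reading of the
protocol is adopted), or the fixed benchmark rate set
$\{k_f, k_b, k_d, k_s\} = \{1.396, 0.465, 0.851, 0.398\}\,\mathrm{s}^{-1}$
with 10 molecules per species. `ryr_ring()` builds the four-state
ryanodine-receptor gating ring with base rates
$\{0.06, 0.005, 35\gamma^2, 0.5\gamma\}\,\mathrm{ms}^{-1}$ (forward) and
$\{35\gamma^2, 0.5\gamma, 0.06, 0.005\}\,\mathrm{ms}^{-1}$ (backward),
$\gamma = 10^{-3}/(\mathcal{N}\mathcal{V})$, volume one microlitre, and
the calcium count $\kappa$ entering as the displayed $\kappa$ and
$\kappa^2$ factors; $\kappa$ is a constant parameter, not a species. With
100 gates starting inactive and no gate synthesis, the infinite-time
marginal over (inactive, open) collapses to a single Multinomial
(`ryr_steady_marginal()`).

These generators emulate idealized well-mixed kinetics with known,
constant rates. They do not emulate features of real single-molecule
data: cell-to-cell rate variability, measurement noise, non-exponential
waiting times, or spatial effects. Tests passing on them show the
*formulas and their implementation* are consistent with each other and
with simulation — not that any particular biological system follows
monomolecular kinetics.

## Verification strategy and problem sizes

Three independent routes are held against each other: the convolution
solution vs. the directly solved CME (total variation $<10^{-7}$ on
chains and rings with up to 3 species and 5 molecules, where the full
state space is cheap to enumerate); restricted-parameter marginals vs.
lumped full distributions ($<10^{-9}$); and analytical marginals vs.
empirical SSA frequencies on a 5-species fixed-rate chain, where the
log10 time-averaged L1 error over a 50-point grid falls below $-1.5$ at
$10^4$ runs and shrinks with the run count as Monte-Carlo scaling
predicts. Equilibria are checked as fixed points ($\|\mathbf{A}\bar{\mathbf{c}}
+ \mathbf{b}\|_\infty < 10^{-10}$ at order-one rates) and, for the stiff
gating ring, against implicit (BDF) long-time ODE integration. These
sizes keep the whole suite under a minute while exercising every code
path; the formulas themselves are dimension-agnostic, and the chain
machinery is routinely run at $n = 50$.

## Known limitations

* The number of CME states explodes combinatorially with molecules and
  species; the general spectral route is for small $w$ (hundreds). No
  Krylov/uniformization large-$w$ solver is provided.
* Truncation of open systems is a plain reachability cap with leak
  accounting — not a certified finite-state-projection error bound.
* Repeated eigenvalues are handled by fallback, not by confluent
  closed forms.
* In extremely stiff spectra (rates spanning $>15$ orders of magnitude)
  eigenvalues smaller than $\varepsilon_{\mathrm{mach}} \cdot
  \|\mathbf{A}\|$ are numerically indistinguishable from zero, so
  `relaxation_time()` and the transient (not equilibrium) formulas
  degrade; equilibria remain well-conditioned after row equilibration.
* No SBML import/export; configs are plain JSON/YAML.

## A worked consistency check

```{r consistency}
net <- chain_network(k_f = c(0.6, 0.3), k_b = c(0.2, 0.5),
                     k_d = c(0.3, 0.1, 0.2))
xi <- c(2L, 2L, 1L)
t_half <- relaxation_time(linear_structure(net)) / 2

full <- full_distribution(net, xi, t_half)
ss <- enumerate_states(net, xi)
ref <- solve_cme(build_generator(net, ss), xi, t_half)[[1]]
tv_distance(full, ref)

marg <- marginal_distribution(net, xi, c(1, 3), t_half)
tv_distance(marg, project_dist(full, c(1, 3)))
```
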