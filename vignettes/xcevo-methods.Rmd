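---
title: "Evolving symbolic enhancement factors: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving symbolic enhancement factors: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcevo)
```

## The model

Semilocal exchange–correlation (XC) functionals in Kohn–Sham DFT can be
written as three dimensionless *enhancement factors* multiplying local
density approximation (LDA) energy densities,

$$E_{xc}^{sl}[\rho] = \int \left( e_x^{LDA} F_x + e_{c\text{-}ss}^{LDA}
F_{c\text{-}ss} + e_{c\text{-}os}^{LDA} F_{c\text{-}os} \right)
\, d\mathbf{r},$$

discretized here as a quadrature sum over fixed grids.  The enhancement
factors are functions of dimensionless density features: the squared reduced
density gradient $x^2$ (with $x = 2^{1/3} |\nabla\rho| / \rho^{4/3}$), its
finite-domain transform $u = \gamma x^2 / (1 + \gamma x^2) \in [0, 1)$, and a
bounded kinetic-energy-density feature $w \in [-1, 1]$ whose values $-1$, $0$
and $1$ are conventionally associated with weak, metallic and covalent
bonding character.  Because the LDA kernels are fixed, a functional form is
fully determined by its three enhancement factors, and the search problem is
a symbolic regression over them.

xcevo represents each enhancement factor as a short **instruction program**:
a workspace of features, scalar parameters and variables (all variables
initialized to zero, with a distinguished readout variable `F`), plus an
ordered list of elementary instructions — binary arithmetic (`+`, `-`, `*`,
`/`), multiply–accumulate `s = s + p*q`, powers `s = p^n` with
$n \in \{2, 3, 4, 6, 1/2, 1/3\}$, and the finite-domain building block
`s = gamma*p/(1 + gamma*p)` whose $\gamma$ is a parameter bound to the
instruction.  The canonical example is the B97 form
$F = c_0 + c_1 u + c_2 u^2$, which takes five instructions:

```{r}
bp <- b97_functional()
bp$functional$programs$x
```

## The search

The outer loop is **regularized evolution**: a bounded FIFO population
(default cap 100) of fitted functionals; each step draws a tournament
(default 25, 10 for the proof-of-principle space) uniformly without
replacement, mutates the fittest member by exactly one rule — insert, remove,
change-operation or change-argument, drawn uniformly by default — fits the
child's scalar parameters on the training split, scores it by validation
error, and inserts it; once the population exceeds its cap the *oldest*
member is evicted, regardless of fitness.  Aging eviction (rather than
worst-member eviction) is what makes the evolution "regularized": good but
brittle forms cannot squat in the population indefinitely.  Fitness is the
negative validation WRMSD in kcal/mol; children whose programs evaluate to
non-finite values anywhere are inserted with fitness $-\infty$ rather than
discarded, so the aging clock ticks identically for them.

The inner loop is **multi-restart CMA-ES** over the scalar parameters,
minimizing the weighted root-mean-square deviation

$$J_S = \sqrt{\tfrac{1}{N} \sum_{i \in S} w_i (E_i - E_i^{ref})^2},$$

where each data point is a signed combination of per-system energies and
$w_i$ is a per-type sample weight (defaults: TCD 0.1; TCE, AE18 1; NCD, ID,
BH 10; NCE, IE 100; RG10 10000).  All parameters are treated as nonlinear —
there is no linear-subproblem shortcut even for forms linear in some
coefficients — with restarts initialized from a unit Gaussian and every
parameter constrained to $[-10, 10]$.  Ten restarts are used in the
proof-of-principle search and five by default elsewhere.

**Equivalence caching.**  Mutation freely creates syntactic variants of one
function (dead instructions, renamed intermediates, reassociated sums).
Before fitting, each child is canonicalized by backward dependency slicing
from `F` (dead-code elimination), evaluated on a fixed pseudo-random probe
set — 64 feature tuples ($x^2$ log-uniform on $[10^{-4}, 10^4]$, $w$ uniform
on $[-1, 1]$) under 4 standard-normal parameter draws — and the outputs,
quantized to 8 significant digits, are hashed.  A digest hit reuses the
cached fit, so equivalent forms are trained once.  Equivalence under
re-parameterization (e.g. $c_0^2 + c_1 (c_2 + u)^2$ versus
$b_0 + b_1 u + b_2 u^2$) is deliberately *not* detected: such forms are
distinct points of the search space and are trained independently.  Whether
a syntactic or a numeric cache key is preferable is genuinely open; the
numeric key was chosen because it also collapses variable renamings and
reassociations at no extra cost, at the price of a quantization-collision
false-positive probability that is negligible at 64 probe points and 8
digits.

## Tunable parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `population_size` | 100 | FIFO cap; larger = more diversity, slower turnover |
| `tournament_size` | 25 (10 in the small space) | selection pressure |
| `max_instructions` | 6 (small space) | program-length cap per factor |
| `param_budget` | 4 | workspace parameter symbols per program |
| `n_restarts` | 5 / 10 | CMA-ES restarts per child |
| `sigma0` | 0.3 | initial CMA-ES step size (unitless; parameters are O(1)) |
| `bounds` | [-10, 10] | box constraint on every parameter |
| `max_evals_per_dim` | 200 (2000 in the demo fixture) | objective budget per restart per dimension |
| type weights | see above | sample weights per data type (dimensionless) |

## The synthetic-data generator

No external dataset is downloaded.  `generate_dataset()` emulates the
*shape* of MGCDB84-style data: multiple data types with per-type weights;
data points that are single energies, pairwise differences, or 3–4-term
signed combinations of system energies; and 60/20/20
train/validation/test splits (optionally assigned by whole data type, to
mirror transferability-stressing partitions).  Grids are random — density
log-uniform on $[10^{-2}, 10]$ a.u., $x^2$ log-uniform on
$[10^{-4}, 10^4]$ (covering the physically relevant $s \in [0, 3]$ regime
and beyond), $w$ uniform on $[-1, 1]$, positive quadrature weights — and
reference energies are computed from a chosen ground-truth functional.
Noise defaults to zero so that recovery experiments are well-posed.

What this does *not* emulate: real molecular densities (grids are iid
samples, not atomic shells), basis sets, self-consistency, the nonlocal
dispersion term, or the empirical error structure of benchmark
thermochemistry.  Passing tests therefore demonstrate that the *search and
fitting machinery* behaves correctly — that the representation can express
the target forms, that the optimizer recovers known parameters from
noiseless data, that the evolution finds known forms — not that any
functional discovered here is chemically accurate.  Published test-set
errors on real benchmark data are out of desk scope for the same reason.

**LDA kernels.**  The exchange kernel is full-range LDA exchange,
$e_x = -\tfrac{3}{4} (3/\pi)^{1/3} \rho^{4/3}$ (the range-separated
short-range variant used by range-separated hybrids is intentionally out of
scope).  The same-spin/opposite-spin correlation split is a deliberately
simple analytic surrogate, $e_c = -c\,\rho^{4/3}$ ($c_{ss} = 0.02$,
$c_{os} = 0.06$), which is *not* a physical correlation functional; the
energy-density provider is a plug-in argument (`lda =`) throughout, and the
search machinery is agnostic to which kernel is installed as long as it is
fixed across a run.

## The proof-of-principle experiment

`b97_demo_fixture()` pins the from-scratch rediscovery setting: search space
of four instructions (`s = p + q`, `s = s + p*q`, `s = p^2`,
`s = gamma*p/(1+gamma*p)`), at most six instructions, a workspace of one
feature ($x^2$), four parameters and three variables, tournament size 10,
population 100, ten CMA-ES restarts per child.  Reference energies come from
the B97 exchange enhancement factor ($c_0 = 0.8094$, $c_1 = 0.5073$,
$c_2 = 0.7481$, $\gamma = 0.004$) on synthetic grids; only the exchange
channel is mutable, matching an exchange-only ground truth.  Success is
declared when the best-by-validation individual renders to a form
algebraically equivalent to $c_0 + c_1 u + c_2 u^2$ — checked by regressing
the program's fitted output on $(1, u(\gamma), u(\gamma)^2)$ with the
*effective* $\gamma$ located numerically (evolved members of the family
often hide it inside rescaled or nested transforms, so the fitted bound
parameter alone is not enough), rejecting the $\gamma \to 0$ degeneracy in
which $u$ is merely proportional to $x^2$ — *and*
its validation error is below $10^{-3}$ of the data scale (the WRMSD of the
zero prediction).  Absolute error targets from real thermochemistry data are
not reproducible on synthetic grids, which is why the success criterion is
relative.

Problem sizes were chosen once at desk scale: 40 systems of 6 grid points,
200 data points, mutation budgets of a few thousand.  The rediscovered form
is typically not the textbook encoding — re-parameterized equivalents such
as $(c_1^2 + c_2 u)^2 + c_0 c_1$ appear, exactly as expected when
equivalence under re-parameterization is not collapsed.

## Numerical choices

* **Invalid evaluations.** Division by (near-)zero, fractional powers of
  negative arguments, and overflow mark the whole evaluation invalid (no
  complex arithmetic, no exceptions); the fitting layer maps invalid to a
  worst-case objective, and the evolution inserts such children as unfit.
  The strict evaluator checks finiteness after every instruction.
* **Batched fitting objective.** CMA-ES evaluates its whole candidate
  population in one vectorized pass (features tiled per candidate).  In that
  fast path validity is judged from the finiteness of the final datapoint
  energies; the winning candidate's reported error is always recomputed with
  the strict per-instruction check.  The two can disagree only when an
  intermediate infinity cancels to a finite readout (e.g. `1/Inf`), which
  affects optimizer guidance, never reported numbers.
* **CMA-ES.** Standard $(\mu/\mu_w, \lambda)$ strategy,
  $\lambda = 4 + \lfloor 3 \ln d \rfloor$, rank-one + rank-$\mu$ updates,
  cumulative step-size adaptation.  Box constraints by evaluating at the
  clipped point plus a quadratic out-of-bounds penalty.  Restarts stop early
  on stagnation (no relative improvement $> 10^{-8}$ over 30 iterations),
  ill-conditioning, or a configurable training-error floor (`j_stop`), and
  remaining restarts are skipped once the floor is reached — the floor in
  the demo fixture is $10^{-6}$ of the training data scale, far below any
  success threshold.
* **Ties** in tournaments break toward the most recent insertion.
* **Transform gammas.** Each transform instruction owns a bound $\gamma$
  parameter; inserting a transform allocates a fresh $\gamma$ while the
  workspace parameter budget allows and reuses an existing one otherwise.
  Gamma parameters are never sampled as free arguments.  In the
  proof-of-principle workspace the budget (4) is exhausted by
  $c_0, c_1, c_2, \gamma_0$, so all transforms share $\gamma_0$.
* **Exponents** serialize by exact label (`"1/2"`, `"1/3"`), so JSON round
  trips are lossless.
* **The opposite-spin GAS22 term.** The printed opposite-spin form carries a
  novel reduced-gradient term whose exponent is implemented as $x^{3/2}$
  (encoded as $x \cdot \sqrt{x}$ in instructions); the exponent is a field
  of the shipped coefficient table should a different reading be needed.
* **Power-series coefficients** of the semilocal starting-point functional
  are transcribed from its original publication and shipped as a versioned
  JSON data file; the channel term subsets are enforced at evaluation time.

## Design decisions that were genuinely open

* **Feature set for large searches.** The proof-of-principle space exposes
  $x^2$ only; meta-GGA searches need $w$ as well.  The default feature set
  for configurable searches is $\{x^2, w\}$, extensible through the run
  configuration.
* **$w$ as a direct input.** The map from kinetic energy density $\tau$ to
  $w$ is not needed for any desk-scale experiment, so $w$ is accepted
  directly in $[-1, 1]$; a conventional adapter
  (`w_from_tau()`, $w = (t-1)/(t+1)$ with $t = \tau^{LDA}/\tau$) is provided
  but nothing load-bearing uses it.
* **Spin-unpolarized formalism only.**  The spin-polarized generalization
  changes the LDA kernels and doubles the feature set without exercising any
  additional search machinery.
* **Worker parallelism.** The evolution supports process-level parallel
  mutate+fit rounds with sequential, atomic insert+evict (identical
  population semantics to the serial mode); the default is one worker, which
  is bit-reproducible.  A distributed cluster scheduler is a non-goal.
* **No crossover.** The evolution is mutation-only; rule-selection and
  argument-sampling distributions are uniform, as nothing suggested
  otherwise.

## Known limitations

* The correlation-channel LDA surrogate is non-physical by construction;
  results on the correlation channels exercise machinery, not chemistry.
* Numeric fingerprinting can in principle collide (quantization on a finite
  probe set); collisions silently reuse a fit.  At the default probe size
  the probability is negligible, but it is not zero.
* `is_b97_equivalent()` certifies membership of the quadratic-in-$u$ family
  numerically (regression residual on a dense grid, with a golden-section
  search for the effective $\gamma$), not by computer algebra.
* Rediscovery time is stochastic: mutation counts at first success vary by
  a factor of a few across seeds, and the median over three seeds is itself
  noisy.
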