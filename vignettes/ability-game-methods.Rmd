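---
title: "Methods: the ability game, its adaptive dynamics, and the simulation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ability game, its adaptive dynamics, and the simulation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abilitygame)
```

## The model

Each individual carries a heritable ability trait $a \in [0, 1]$. Individuals
meet pairwise at random and play a public goods game: each chooses an effort
$e \ge 0$, the pair produces a common benefit that depends on the *sum* of
efforts, and each privately pays a cost that depends on its own effort and
ability. The payoff to a focal individual of ability $a$ exerting effort $e$
against a partner exerting $e'$ is

$$W_a(e, e') = B(e + e') - K(a, e),$$

with

$$B(e_{tot}) = \begin{cases} 2 e_{tot} - e_{tot}^2 & e_{tot} < 1 \\ 1 & e_{tot} \ge 1 \end{cases}
\qquad K(a, e) = (2 - a)\, e^p, \quad p > 1.$$

The benefit has diminishing returns and saturates; the cost accelerates in
effort and is lower for high ability — high-ability individuals have a
*comparative advantage* in effort. The cost exponent $p$ controls how fast
marginal cost rises, and turns out to control everything interesting in the
model.

Within a pair, efforts are assumed to be in Nash equilibrium: each effort
maximises its owner's payoff given the partner's effort. Because marginal
benefit is strictly decreasing and marginal cost strictly increasing, the
best response to any partner effort is unique, and the slope of the
best-response function (obtained by implicit differentiation of the
first-order condition) lies strictly in $(-1, 0)$: individuals *partially
compensate* for a lazy partner. That compensation is the engine of the whole
story — a low-ability individual contributes little, its partner picks up
part of the slack, and the low-ability individual pockets most of the
benefit at little cost. Whether this makes low ability *advantageous*
depends on how strong the compensation is, i.e. on $p$: responsiveness at
the symmetric equilibrium is stronger for $p = 1.25$ than for $p = 2$.

## Nash solver

`nash_efforts()` (and the vectorised internal path used everywhere) solves
the joint first-order conditions

$$2 - 2(e_1 + e_2) = (2 - a_i)\, p\, e_i^{p-1}, \quad i = 1, 2$$

by a guarded Newton iteration started from the $p = 2$ closed form
($e_i = (1 - s)/(2 - a_i)$, $s = (u + v)/(1 + u + v)$, $u = 1/(2 - a_1)$,
$v = 1/(2 - a_2)$), with steps pulled back to half the current effort if
they would drive it nonpositive. Any entry whose residual is not below
$10^{-10}$ falls back to alternating best responses, each found by 60
bisection steps on its bracketed first-order condition — the contraction
property of the best-response map (|slope| < 1) guarantees that path
converges. In practice the Newton path converges in 1–15 iterations for
$p \in [1.1, 5]$ and the fallback never triggers; the test suite
cross-checks the two paths against each other and against a brute-force
grid-search oracle.

Two structural facts keep the solver simple: the unique root always has both
efforts positive and total effort strictly below the benefit saturation
point (the left side of the FOC must be positive at the root), so the
unsaturated linear branch of the marginal benefit is the correct one
throughout, and the kink of $B$ at $e_{tot} = 1$ (where we adopt the
right-derivative convention, slope 0) never binds at equilibrium.

Choices worth stating: $e^p$ at $e = 0$ is taken as 0 (continuous
extension); cost exponents within $10^{-6}$ of 1 are rejected rather than
solved, since the curvature that the solver and the responsiveness formula
divide by vanishes as $p \to 1$; solver tolerance is $10^{-10}$ on the FOC
residual with an iteration cap of 10 000 on the fallback path.

## Invasion analysis

A rare mutant of ability $\tilde a$ in a resident population of ability $a$
almost always meets residents, so its invasion fitness is its payoff at the
Nash equilibrium of the $(\tilde a, a)$ pairing:

$$V(\tilde a, a) = B(e^*(\tilde a, a) + e^*(a, \tilde a)) - K(\tilde a, e^*(\tilde a, a)).$$

The selection gradient $D(a) = \partial V/\partial \tilde a|_{\tilde a = a}$
is computed by central finite differences with step $10^{-5}$ (one-sided
second-order stencils at the trait bounds). The solver tolerance of
$10^{-10}$ leaves roughly five digits of headroom below the squared step, and
the numeric gradient matches the $p = 2$ analytic form
$D(a) = u^2/(1 + 2u)^3$, $u = 1/(2-a)$ (derived by hand from the closed-form
efforts; at $a = 0.5$ it equals exactly $12/343$) to $10^{-6}$ in the tests.

`find_attractors()` scans $D$ on a grid (default 201 points), reports a
boundary attractor when the gradient points into a bound (negative at 0,
positive at 1), and refines interior sign changes by bisection to
$|D| < 10^{-8}$. `classify_singular()` then separates two different second
derivatives, and the distinction is what makes evolutionary branching
possible:

* **convergence stability** — the slope of $D$ across the singular point
  (evaluated at $a^* \pm 10^{-3}$): negative slope means nearby residents
  evolve towards $a^*$;
* **evolutionary stability** — the mutant-direction curvature
  $\partial^2 V/\partial \tilde a^2$ at the point (central difference, step
  $10^{-4}$): positive curvature means the point is a fitness *minimum* and
  selection there is disruptive.

A convergence-stable point with positive mutant curvature is labelled a
branching point. Near-zero plateaus of the scanned gradient are reported as
a diagnostic rather than collapsed into roots.

The three cost regimes behave qualitatively differently: for $p = 1.25$ the
gradient is negative on all of $(0,1)$, so $a = 0$ is the unique attractor —
social compensation is strong enough that selection *reduces* ability; for
$p = 2$ the gradient is positive everywhere and $a = 1$ is the attractor;
for $p = 1.5$ there is a single interior convergence-stable point (the
package's computed location is $a^* \approx 0.6667$, pinned in the tests as
a regression value, not an external ground truth) with positive mutant
curvature — a branching point with disruptive selection.

One fine point the single-mutant analysis turned up: at $p = 1.25$ against a
resident at $a = 0.5$, the mutant's payoff $V(\tilde a, 0.5)$ falls with
mutant ability over most of the trait range but is convex, with a shallow
interior minimum near $\tilde a \approx 0.85$ and a small rise (about 0.008
payoff units) towards $\tilde a = 1$. The rise never reaches the resident
payoff, so no high-ability mutant invades a 0.5 resident; the same convexity
is why *some* high-ability mutants can invade when the resident ability is
low. The package reports the curve as computed (three independent solution
paths agree) rather than forcing the commonly quoted "payoff decreases with
ability" onto it; that statement is exact only up to the interior minimum.

## Evolutionary simulation

`run_evolution()` is a discrete-generation agent-based model: each
generation every individual is matched once, uniformly at random, into
pairs; each pair plays its Nash equilibrium (all pairs solved in one
vectorised call); and the next generation is sampled with fitness weights
$\exp(k W_i)$ under one of two inheritance modes:

* **sexual** — the infinitesimal model: offspring trait = midparent mean of
  two independently sampled parents + Gaussian segregation deviation
  (sd `segregation_sd`), clipped to $[0,1]$. Midparent averaging keeps the
  trait distribution unimodal even under disruptive selection.
* **asexual** — clonal copy of one sampled parent, perturbed with
  probability `mutation_prob` by a Gaussian of sd `mutation_sd`, clipped.
  Clonal inheritance lets disruptive selection split the population into two
  trait clusters.

Clipping (not reflection) is used at the bounds because the trait is defined
on a hard interval; a run owns a single seeded RNG and draws from it in a
fixed order (matching, parent sampling, segregation/mutation noise), so runs
are bit-reproducible.

### Parameter defaults and why

| parameter | default | units | rationale |
|---|---|---|---|
| `selection_intensity` $k$ | 20 | per payoff unit | see below |
| `segregation_sd` | 0.04 | trait units | see below |
| `mutation_prob` | 0.02 | per offspring | see below |
| `mutation_sd` | 0.08 | trait units | see below |
| `n_individuals` | 1000 | individuals | smooth quantile series at desk scale |
| `n_generations` | 10001 | generations | long enough for every regime to settle |

The inheritance and selection parameters are **declared assumptions**: the
model that motivated this package does not pin them down. They were
calibrated once, against the package's own invasion analysis, so that the
simulated dynamics resolve the analytically predicted attractors and
branching at desk scale, and then frozen.

Two calibration findings shaped them. First, weighting parents by *raw*
payoff (classic fitness-proportionate selection) ties the strength of
selection to the payoff baseline: payoffs here sit around 0.6–0.8 with
differentials of order 0.01, giving relative selection of order 1%. Measured
against that pressure, no segregation sd balances the books — small sds make
the approach to an attractor take tens of thousands of generations, large
sds let boundary clipping park the stationary median 0.15–0.3 away from a
boundary attractor. Exponential weights $\exp(k W)$ decouple intensity from
baseline (only payoff *differences* matter); $k = 20$ makes a population of
500 reach either boundary attractor within roughly a thousand generations
while keeping the stationary median within about 0.08 of it. Second, with
branching resolved by $k$, the asexual mutation kernel (0.02, 0.08) keeps
both emerging trait clusters populated: with rarer or smaller mutations one
branch frequently goes extinct by drift at $N = 500$ before the valley
between the modes is established.

The scaled study configuration used throughout the tests is $N = 500$,
2000 generations, five seeds per condition; full-size runs
($N = 1000$, 10 001 generations) use the same defaults and are supported but
not exercised by the test suite.

### Detecting bimodality

`bimodality_index()` is a fit-free valley statistic: counts on 20 equal bins
over $[0,1]$; among local maxima the two highest non-adjacent peaks are
taken, and the index is $1 - v/m$ with $v$ the minimum count strictly
between them and $m$ the smaller peak. A local maximum only qualifies as a
peak if it holds at least 5% of the sample (and two observations): without
that rule a single stray observation in an otherwise empty tail bin
registers as a second mode and pushes the index to 1 for plainly unimodal
samples. Calibration on reference samples — uniform draws ($n = 1000$) and
truncated Gaussians ($n = 500$), 1000 replicates each — puts the 95th
percentile of the index at or below 0.45 for unimodal references while
well-separated two-component mixtures score essentially 1, so **0.5** is the
package's decision threshold for calling a distribution bimodal. The
threshold was fixed from these reference calibrations before the
evolutionary runs were evaluated against it.

### What the simulation does and does not emulate

The generator reproduces the *mechanism* the analysis is about: random
pairwise interaction, equilibrium behaviour within pairs, payoff-dependent
reproduction, and the two extreme inheritance architectures. It does not
emulate features real populations have: overlapping generations, diploid
genetics with explicit loci and linkage, environmental effects on the trait,
fitness consequences of ability outside the focal game, partner choice, or
any within-pair negotiation process (efforts are equilibrium values, not a
real-time bargaining outcome). Passing tests therefore show that the
mechanism produces the predicted attractors and distribution shapes under
the model's assumptions — not that real populations will.

## Known limitations

* The adaptive-dynamics analysis assumes an essentially monomorphic resident
  population; the invasion machinery is not meaningful once the asexual
  population has split into two abundant clusters.
* Selection intensity, segregation sd and the mutation kernel are
  assumptions (above); quantitative features of the simulations — time to
  convergence, stationary spread around an attractor, the depth of the
  bimodal valley — move with them. The qualitative attractor structure is
  set by $p$ alone and is what the tests pin down.
* `classify_singular()` uses fixed finite-difference steps; singular points
  within ~$10^{-3}$ of a trait bound would need smaller `delta_conv` to
  classify reliably (none arise in the studied regimes).
* The CLI config format is a deliberately minimal flat `key = value` file,
  not a full TOML parser.

## Worked example

```{r example, eval = FALSE}
par <- ability_params(p = 1.5)
nash_efforts(1, 0, ability_params(2))      # closed-form checkable case
find_attractors(par)                       # one interior branching point

cfg <- sim_config("asexual", n_individuals = 500, n_generations = 2000,
                  initial_ability = 1, record_every = 50, seed = 1)
res <- run_evolution(cfg, par)
summary(res)                               # bimodal final distribution
plot(res)
```
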