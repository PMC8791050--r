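---
title: "Optimal institutional incentives in finite populations: model and methods"
author: "coopcost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal institutional incentives in finite populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopcost)
```

## The problem

An external institution wants a well-mixed population of `N` self-regarding
players to cooperate, and is willing to pay for it: rewarding each
cooperator with `theta` per interaction round, or fining each defector by
`theta`. Incentives are costly, so the institution faces a constrained
minimization: spend as little as possible in expectation while keeping the
long-run frequency of cooperation at or above a target `omega`.

`coopcost` solves this exactly for two canonical dilemmas:

* the **Donation game** (DG): a cooperator pays `c` to give `b > c` to the
  partner;
* the **Public Goods game** (PGG): groups of `n` players; contributions `c`
  are multiplied by `r` (`1 < r < n`) and shared.

Both have the special property that the average payoff difference between a
cooperator and a defector,
`delta = Pi_C(i) - Pi_D(i)`, does not depend on the number of cooperators
`i`: `delta = -(c + b/(N-1))` in the DG and
`delta = -c (1 - r(N-n)/(n(N-1)))` in the PGG, always negative. A
per-capita incentive `theta` simply shifts this difference to
`delta + theta`, which is what makes an exact analysis possible. Games
where the difference depends on the composition (general Prisoner's
Dilemma, collective-risk games) are out of scope.

## The cost model

Evolution follows pairwise comparison with the Fermi rule: a player copies
a random other player with probability `1/(1 + exp(-beta * df))` where `df`
is their payoff difference and `beta >= 0` is the intensity of selection.
In the small-mutation limit the population is monomorphic almost always;
when a mutant appears (equally likely in either monomorphic state), the
interim dynamics is a birth–death Markov chain on the cooperator count
`i = 0, ..., N` with absorbing ends and transition probabilities

```
u_{i,i±1} = (N-i)/N * i/N * (1 + exp(∓ beta (delta + theta)))^{-1}.
```

The fundamental matrix `(I - U)^{-1}` of the transient block gives the
expected sojourn counts; averaging the two mutant entry points, the
expected number of visits to state `i` is
`v_i = (n_{1,i} + n_{N-1,i})/2`, with the convention that the starting
state counts as one visit. Spending is `theta * i` per update under reward
and `theta * (N - i)` under punishment, so the expected total cost per
mutant invasion is

```
E(theta) = theta * sum_i w_i v_i,   w_i = i (reward) or N - i (punishment).
```

Both schemes drive identical dynamics (the incentive enters only through
`delta + theta`), so they share one visit profile and differ only in the
weights; in particular `Er + Ep = theta * N * sum_i v_i` and
`Er = Ep` exactly at `theta = -delta`.

The long-run cooperation frequency follows from fixation probabilities:
the ratio `rho_DC / rho_CD` telescopes to
`exp(beta (N-1) (delta + theta))`, so the frequency is a logistic in
`theta` and the constraint "frequency at least `omega`" inverts in closed
form to

```
theta >= theta0(omega) = log(omega/(1-omega)) / ((N-1) beta) - delta.
```

## The phase transition and the decision procedure

`E(theta)` is not always monotone. There is a threshold intensity
`beta_star` (depending on the game, `N` and the scheme) such that:

* for `beta <= beta_star`, `E` is non-decreasing in `theta`, so the
  constrained optimum is simply the bound: `theta* = theta0(omega)`;
* for `beta > beta_star`, `E` rises to a local maximum `theta1`, falls to
  a local minimum `theta2`, and rises again. The optimum is then either
  `theta0` or `theta2`: `theta2` wins exactly when it is feasible
  (`theta2 > theta0`) and strictly cheaper (`E(theta2) < E(theta0)`; ties
  go to `theta0`).

The intuition: past the transition, a moderately larger incentive tips the
Fermi probabilities enough that the chain spends far less time in the
costly interior states, so total spending can *fall* as `theta` grows.

`coopcost` does not reproduce the symbolic characterization of
`beta_star` via auxiliary polynomials; instead it uses the equivalent
numerical characterizations, which the worked examples pin down:

* `beta_star(...)`: bisection (relative tolerance `1e-4`) on a
  monotonicity predicate that scans `E` on a 2000-point grid over
  `(0, -delta + 50/beta]`. The window is where all stationary points live:
  they satisfy `theta = log(u)/beta - delta` with `u` an O(1) root, so the
  non-monotone region concentrates near `-delta` with width `O(1/beta)`.
* `theta_two(...)`: sign changes of a central-difference derivative
  (`h = max(1e-6, 1e-4 theta)`) are bracketed on the same grid and refined
  by `uniroot` to `1e-6`. More than two sign changes triggers a warning:
  the two-sign-change structure is numerically verified up to `N = 100`,
  and `optimize_incentive()` flags results for larger `N` rather than
  refusing them.

A grid can only detect a decreasing segment wider than its spacing;
doubling the resolution leaves the located threshold unchanged at the
reported tolerance (tested), and a round-off guard of
`1e-12 * max|E|` on grid differences prevents false dips from floating-
point noise in the flat regions.

```{r example}
g <- game_dg(b = 1.8, c = 1)
optimize_incentive(g, N = 3, beta = 10, mode = "reward", omega = 0.7)
```

## Asymptotic limits

Closed forms bound and anchor the exact computation (`H_N` is the harmonic
number `sum_{j<N} 1/j`):

* finite-`N` sandwich, any `beta`:
  `N^2 theta/2 (H_N + 1/(N-1)) <= E <= N(N-1) theta (H_N + 1)`;
* weak selection: `E -> N^2 theta H_N` as `beta -> 0`, identical for both
  schemes;
* strong selection: piecewise-linear limits with a three-way branch at
  `theta = -delta`; reward is cheaper below `-delta`, punishment above —
  at any `beta`, not only in the limit (`compare_schemes()`);
* large population: `E / (N^2 theta/2 (log N + gamma))` tends to
  `1 + exp(-beta |theta + delta_inf|)` with `delta_inf` the infinite-`N`
  payoff difference (`-c` for DG, `-c(1 - r/n)` for PGG).

Two numerical caveats, both verified in the test suite. First, the
strong-selection branch at `theta = -delta` is selected by exact
floating-point comparison; callers wanting the knife edge must pass
`-delta` literally. Second, the large-`N` ratio converges only at rate
`O(1/log N)` — at `N = 2000` it is still ~10% above its limit — so the
convergence test fits the `a + b/(log N + gamma)` tail on
`N = 1e3..1e5` and compares the intercept with the limit constant (2%),
rather than pretending a fixed `N` is "large enough".

## What the Monte Carlo oracle does and does not establish

`simulate_cost()` replays the same chain stochastically: walks from a
single mutant (either end with probability 1/2, matching the analytic
visit convention) to absorption, accumulating one cost increment per
update *including the initial state*, with self-loops simulated explicitly
so sojourn counts follow the fundamental-matrix convention. It emulates
exactly the stated world of the analytic model — small-mutation limit,
well-mixed population, constant `theta` — and none of the features of real
incentive systems (assessment errors, budget caps, network structure,
larger mutation rates). Agreement within Monte Carlo error (the tests use
3 standard errors at fixed seeds, accepting the implied false-positive
rate) therefore validates the *implementation* of the cost formula, not
the model's realism. R's Mersenne-Twister with an explicit recorded seed
makes every simulation bit-reproducible.

The "per generation" spending is interpreted as per Markov-chain step (one
pairwise-comparison event); this convention, together with counting the
initial state, is pinned down empirically by reproducing the worked cost
values 23.602 / 25.6124 / 26.446 at `N = 3`, `beta = 10`.

## Design choices made where the design was open

* **Production vs oracle paths.** Visit counts: O(N) Thomas tridiagonal
  solves of `(I-U)^T y = e_1, e_{N-1}`, vectorised across the `theta`
  grid (the optimizer evaluates `E` thousands of times); dense inversion
  survives only as a test oracle. Fixation: log-domain accumulation with
  saturating logistic factors, so `beta = 1e3` is routine; the explicit
  product is the oracle. PGG payoffs: closed forms in production, the
  hypergeometric sums (with out-of-range binomials contributing zero) as
  oracle.
* **`beta = 0`** is accepted by the cost and visit functions solely so the
  weak-selection limit can be checked; `theta_min()` and
  `optimize_incentive()` refuse it (under neutral drift incentives cannot
  change the outcome, and `theta0` is undefined).
* **`N = 2`** is accepted by the game-level functions but flagged: with a
  single transient state the cost pipeline degenerates. The full pipeline
  requires `N >= 3`.
* **Efficiency ratios** of providing reward and punishment are fixed at 1
  (unit conversion between institutional spending and payoff shift);
  non-unit ratios rescale `theta` only.
* **Payoffs are not rescaled**; rescaling the payoff matrix is equivalent
  to rescaling `beta`.

## Limitations

Beyond the model assumptions above: only the two monomorphic end states
carry stationary mass (small-mutation limit), so the cooperation frequency
is exact only in that regime; `theta1` (the local maximum) is reported
among the stationary points but plays no role in the decision; and for
`N > 100` the exactly-two-stationary-points structure is conjectural, so
results carry a warning flag rather than a guarantee.
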