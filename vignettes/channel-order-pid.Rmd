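---
title: "Redundancy from channel preorders: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redundancy from channel preorders: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pidchannels)
```

## The model

Partial information decomposition (PID) splits the information that a pair of
sources carries about a target,

$$I(T;(Y_1,Y_2)) = R + U_1 + U_2 + S,$$

into redundant, unique and synergistic parts.  Classical information theory
does not fix these terms; one further choice is needed, and a convenient one
is a *redundancy* (intersection-information) measure, since
$U_i = I(T;Y_i) - R$ and $S$ then follow from the total.

This package takes the channel view.  A discrete system $p(t, y_1, \dots,
y_n)$ defines a row-stochastic channel $K^{(i)}[t, y] = p(y_i = y \mid T=t)$
from the target to each source.  Given a preorder $\preceq$ between channels
that respects informativeness, redundancy is the largest amount of target
information available to a variable that sits *below every source*:

$$I_\cap(Y_1,\dots,Y_n) \;=\; \max_{K_Q:\; Q \preceq Y_i\ \forall i} I(Q;T).$$

Any preorder satisfying three axioms (monotonicity of mutual information,
reflexivity, and boundedness between the constant variable and the full
tuple) yields a measure obeying the Williams–Beer axioms; the property suite
in `tests/testthat/test-acceptance.R` exercises exactly those axioms.

Four orders are implemented:

* **degradation (Blackwell)** — $W \preceq_d V$ iff $W = V K_U$ for some
  row-stochastic $K_U$.  Decidable by linear/quadratic feasibility
  (`degradation_check()`), and the resulting measure `ii_degradation()` is a
  convex maximization over a polytope, hence exactly solvable at a vertex.
* **less noisy** — $W \preceq_{ln} V$ iff the chi-squared divergence between
  output distributions contracts no more through $V$ than through $W$ for
  *every* pair of target distributions.  Uncountably many constraints; a
  simplex grid certifies violations (`less_noisy_check()`), never the order.
* **more capable** — $W \preceq_{mc} V$ iff $I(p,W) \le I(p,V)$ for every
  target distribution $p$; same grid treatment plus a projected-gradient
  refinement of the worst grid point (`more_capable_check()`).
* **degradation/supermodularity** — chains of degradation steps and
  *JoinMeet* column operations $\diamond_{i,j}$ (entrywise max into column
  $i$, min into column $j$).  The reachable JoinMeet set is finite because
  each row's multiset of entries is invariant, so it is enumerated by
  breadth-first search (`supermodular_closure()`).  No complete decision
  procedure for the combined order is known; `ds_check()` is deliberately
  sound-but-incomplete and answers HOLDS or UNKNOWN, never VIOLATED.

## How each measure is computed

**Degradation.**  Writing $K_Q = K^{(i)} K_U^{(i)}$ for all $i$ makes the
feasible set a polytope in the stacked $K_U^{(i)}$ with $I(Q;T)$ convex in
$K_Q$, so the maximum sits at a vertex.  When the polytope dimension and the
number of candidate bases are within the `ii_opts()` caps, every vertex is
enumerated and the result is exact (status `EXACT`).  Larger instances fall
back to multistart feasible ascent inside the polytope's affine hull and are
reported as `LOWER_BOUND`.  Because the objective is convex, each line
search jumps straight to the feasible boundary.

**Less noisy / more capable.**  The defining constraint families are
uncountable, so the optimizer solves a *sampled* relaxation: constraints are
imposed on the full simplex grid (step `grid_step`, default 0.1 — the same
resolution as the published experiments), on the problem's own target
marginal, and on seeded uniform-Dirichlet draws.  The sampled optimum upper
bounds the true measure; it is approached by multistart ascent.  Certified
*lower* bounds come from feasible constructions:

* the constant variable (always feasible, value 0);
* the maximal common random variable (below, Gács–Körner);
* the degradation argmax (valid because $\preceq_d$ implies both orders);
* any source that passes the grid order-check against all other sources
  *and* satisfies the sampled constraints.

The result is a bracket `[lower, upper]`; it collapses to `EXACT` when the
bounds meet within `collapse_tol` (default `1e-4`).  The reported `value` is
always the certified lower bound, so a consumer who ignores the bracket
still gets an achievable number.  Including the target marginal in the
constraint sample has a useful side effect: any feasible candidate for the
more-capable relaxation obeys $I(Q;T) \le \min_i I(T;Y_i)$, so that upper
bound can never exceed the minimum-mutual-information cap.

**Degradation/supermodularity.**  Sandwiched between the degradation and
more-capable measures, so the bracket is `[max(degradation value, sources
certified by ds_check), more-capable upper bound]`.  For the classic
3-by-2 example pair, a single JoinMeet step certifies the second source as
feasible and the bracket collapses; for the binary counterexample pair it
stays open — matching the published tables, which leave that entry
unresolved.

**Deterministic redundancy and Gács–Körner.**  The maximal variable that is
a deterministic function of every source is the connected-component label of
the support graph linking source outcomes that co-occur with positive
probability (components computed with igraph).  Any other common function
coarsens it, and coarsening cannot raise $I(Q;T)$, so `ii_deterministic()`
is exact; `gacs_korner()` is the entropy of the same label distribution.

## Tunable parameters

All optimizer knobs live in `ii_opts()`; the defaults are chosen for
desk-scale problems (alphabets up to a handful of symbols):

* `q_cap` — output alphabet of $Q$; defaults to $\sum_i |Y_i| - n + 1$,
  the support size known to suffice for the degradation measure.  Whether
  the same cap suffices for the less-noisy / more-capable measures is an
  open question, which is why it is configurable rather than hard-wired.
* `grid_step = 0.1` — simplex resolution for both the order checks and the
  constraint samples; grid checks can certify only violations, and the
  status name `NO_VIOLATION_AT_RESOLUTION` keeps that explicit.  Refining
  the grid can only move a verdict from no-violation to violation, never
  back, because finer grids (at steps dividing the coarser one) contain the
  coarser points.
* `n_sample = 500`, `n_pairs = 500`, `max_pairs = 4000` — sampled-constraint
  sizes; beyond `max_pairs` the pair set is subsampled with the run's seed.
* `restarts = 12`, `max_iter = 40`, `n_dirs = 6` — multistart budget.  The
  published table values are all reached through the deterministic warm
  starts (constant, sources, common part, degradation argmax), so this
  budget controls only how tight the upper bounds are on *other* problems;
  raising it never loosens a bracket.
* `tol = 1e-7` — infinity-norm residual below which a degradation
  certificate counts as exact.
* `seed` — all randomness (Dirichlet draws, restart directions,
  subsampling) flows through this one seed, and generators restore the
  caller's RNG state.

## Numerical conventions

* All information quantities are in bits.  The published gate table
  (0.311, 0.5, 1) pins the base-2 convention.
* $0 \log 0 = 0$ throughout; the chi-squared divergence uses
  $0/0 = 0$ and $x/0 = +\infty$ for $x > 0$, and an infinite value on the
  dominating side counts as satisfying the contraction inequality.
* Probabilities are accepted when they sum to 1 within $10^{-6}$ and are
  renormalized; internal identities are asserted at $10^{-9}$.
* Outcome labels are sorted with locale-independent (radix) order, so every
  derived matrix is reproducible bit for bit.
* Target outcomes with zero mass have no defined channel row; they are
  dropped from the channel input alphabet and recorded in a
  `dropped_inputs` attribute.  Every measure here is insensitive to
  zero-mass rows, which is why dropping beats imputing.
* Specific information is computed as
  $I(Y;T=t) = \sum_y p(y|t)\,[\log_2 p(t|y) - \log_2 p(t)]$, the
  per-outcome quantity whose $p(t)$-expectation is $I(T;Y)$.  (The source
  literature cites it without a formula; this is the standard
  Williams–Beer form.)
* Degradation feasibility is solved as a ridge-regularized least-squares
  program over row-stochastic matrices (quadprog), then polished by an
  exact equality-constrained solve on the active set, so the reported
  residual carries no regularization bias.  An infinity-norm linear program
  would make the same HOLDS/VIOLATED decision; least squares was chosen
  because a robust QP solver is available while no LP solver is.

## What the fixtures emulate — and what they do not

`gate_joint()` reproduces the canonical bivariate PID testbed: AND, SUM,
XOR, identity and copy targets with independent equiprobable binary inputs,
using exact dyadic probabilities.  `counterexample1()` and `ds_example()`
are the two published channel pairs that separate the orders (less-noisy
without degradation; degradation/supermodularity without degradation).
`random_joint()` and `random_degraded_pair()` draw Dirichlet(1) tables for
property tests.  These are *exact discrete distributions*: nothing here
emulates sampling noise, estimation error, or continuous marginals, so a
green suite establishes correctness of the decompositions on known
distributions, not robustness to empirical estimation.

## Known limitations

* The less-noisy and more-capable upper bounds carry two gaps: the sampled
  relaxation over-admits candidates, and multistart ascent may undershoot
  the relaxation's own optimum.  Brackets are therefore honest but not
  guaranteed tight; whether grid-sampled bounds converge to the true
  measures under refinement is open.
* `ds_check()` cannot return VIOLATED; consequently `ii_ds()` can stay a
  bracket even when the truth is one of its endpoints (the binary
  counterexample pair is exactly such a case).
* Upper bounds from sampled constraints depend (within the bracket) on the
  seed and on the order in which warm starts are explored; the certified
  lower bounds are deterministic and permutation-invariant, which is what
  the symmetry tests assert.
* Alphabets beyond roughly ten symbols per variable make vertex enumeration
  infeasible and the measure falls back to lower-bound mode; the package
  targets the desk-scale regime of the worked examples.
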