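# pidchannels

Partial information decomposition (PID) for finite discrete systems, built
on preorders between communication channels.

## The problem

Given a target variable `T` and sources `Y1, Y2` with joint distribution
`p(t, y1, y2)`, PID asks how the total information splits into

    I(T; (Y1, Y2)) = R + U1 + U2 + S

— redundancy `R` (in both sources), unique informations `U1`, `U2`, and
synergy `S` (only in the pair).  Classical information theory does not fix
these components; a redundancy measure has to be chosen, and the rest
follows from `Ui = I(T; Yi) − R`.  This matters wherever one asks *which*
parts of a system carry the same signal about an outcome — gene-regulatory
and neural circuits, financial networks, security analyses.

`pidchannels` implements the family of *intersection-information* measures
defined through channel preorders.  Each source corresponds to a channel
`K(i)[t, y] = p(yi = y | T = t)`; given a preorder `⪯` between channels,
redundancy is the most target information available to any variable lying
below every source:

    I∩(Y1, …, Yn) = max { I(Q; T) : K_Q ⪯ K(i) for all i }.

Four orders are provided, each with a decision procedure that returns
machine-checkable certificates:

| order | meaning of `W ⪯ V` | checker | measure |
|---|---|---|---|
| degradation (Blackwell) | `W = V·KU` for a stochastic `KU` | exact (feasibility) | `ii_degradation()` — exact on small problems |
| less noisy | chi-squared contraction through `V` dominates `W` for all input pairs | grid (violations only) | `ii_less_noisy()` — bracket |
| more capable | `I(p,W) ≤ I(p,V)` for every input `p` | grid + refinement | `ii_more_capable()` — bracket |
| degradation/supermodularity | chains of degradation and JoinMeet column steps | sound, incomplete | `ii_ds()` — bracket |

Reference measures `ii_mmi()` (minimum mutual information), and
`ii_deterministic()` / `gacs_korner()` (maximal common deterministic part
via connected components of the support graph) complete the comparison set.
`pid()` assembles a full bivariate decomposition from any of them.

## Worked example

The AND gate with independent equiprobable binary inputs:

```r
library(pidchannels)
fit <- pid(gate_joint("AND"), "degradation")
fit
#> bivariate PID (degradation measure), all values in bits
#>   I(T;(Y1,Y2)) = 0.8113
#>   redundancy R = 0.3113 (EXACT)
#>   unique U1    = 0.0000
#>   unique U2    = 0.0000
#>   synergy S    = 0.5000
```

Both sources see the AND output through the same channel, so all 0.311 bits
of single-source information are redundant; the remaining 0.5 bits of the
0.811-bit target entropy require the pair jointly — pure synergy.

Order checks come with certificates.  For the classic 3x2 pair where the
JoinMeet operation (column max/min exchange) relates channels that no
post-processing can:

```r
k <- ds_example()
degradation_check(k$K4, k$K3)$status   # "VIOLATED": no stochastic KU works
ds_check(k$K4, k$K3)$status            # "HOLDS": one JoinMeet step suffices
ii_ds(c(0.3, 0.3, 0.4), list(k$K3, k$K4))
#> I_cap[ds] = 0.3219 bits (EXACT)
```

That certificate makes `Q = Y4` feasible, so the ds redundancy equals
`I(T;Y4) = 0.322` bits even though the degradation redundancy of the pair
is 0 — the decompositions genuinely differ.

Measures whose defining constraint set is uncountable (less noisy, more
capable, ds) return a certified `[lower, upper]` bracket rather than a
pretend point value; `value` is always the certified lower bound, and the
bracket collapses to `EXACT` when the bounds meet.

A thin command-line interface mirrors the R API
(`inst/cli/pidchannels measure|decompose|order-check|fixtures …`), writing
one JSON report per call.

## Acceptance script

`scripts/acceptance.R` recomputes, from the package's own fixtures, the
headline quantities of the underlying study: the logic-gate redundancy
table, the printed mutual informations of the two counterexample channel
pairs, and their degradation / more-capable / ds decomposition entries.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The `--seed` argument drives every stochastic component (constraint
sampling and multistart restarts); the headline values are reached through
deterministic warm starts and do not depend on it.

## Further reading

The methods vignette (`vignettes/channel-order-pid.Rmd`) documents the
optimization strategies, the bracket semantics, all tolerances and
conventions, and known limitations.
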