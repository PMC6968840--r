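---
title: "Coalescent methods for fixation under death-Birth updating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent methods for fixation under death-Birth updating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalfix)
```

## The model

A population of `N` haploid individuals sits on a connected, weighted,
undirected graph with no self-loops; `w[i, j] >= 0` is the edge weight
between vertices `i` and `j`. Mutants have constant fitness `r > 0`,
residents fitness 1. Death-Birth (dB) updating repeats two steps: a vertex
is chosen uniformly at random to die, and the vacancy is filled by a copy of
a neighbor chosen with probability proportional to fitness times edge
weight. The process starts from a single mutant at a uniformly random
vertex and ends at all-mutant (fixation) or all-resident (loss); the
fixation probability is $\rho_G(r)$.

Three independent routes to $\rho$ are implemented:

1. **Exact chain** (`rho_exact`): the full $2^N$-state absorbing Markov
   chain over mutant configurations, solved as one linear system. States
   are encoded as bitmasks; the absorption system is solved by dense LU up
   to about $10^4$ transient states and sparse LU beyond. The default size
   cap is `N <= 14`; in practice `N <= 12` is comfortable on a desktop
   (a solve at `N = 12` takes a couple of seconds) and `N <= 10` is
   instantaneous.
2. **Closed forms** (`rho_complete`, `rho_star`, `rho_cycle`,
   `rho_fan_limit`, `rho_sh_limit`, `rho_si_limit`, and the
   many-blade/many-island limits `rho_sh_inf`, `rho_si_inf`): analytic
   expressions for the named families, the last four in the limit of
   vanishing hub-edge weight.
3. **Monte Carlo** (`simulate_fixation`): forward simulation of the update
   rule, with the per-trial loop in C++ and all randomness drawn from R's
   RNG stream so a seed makes the whole run bit-reproducible.

The test suite keeps all three routes in agreement: closed forms are
checked against the chain solver to 1e-10 on the exact families, and to
$O(\epsilon)$ on hub-weight-$\epsilon$ graphs with $\epsilon = 10^{-6}$;
simulation estimates are required to fall within four binomial standard
errors of the chain.

## Weak selection and the effective population size

Writing $r = 1 + \delta$, fixation probability expands as
$$\rho_G(1+\delta) = \frac{1}{N} + \delta\,\frac{N_{\mathrm{eff}}-2}{2N}
+ O(\delta^2),\qquad N_{\mathrm{eff}} = \sum_i \pi_i \tau_i,$$
where $\pi_i = w_i / \sum_j w_j$ is the stationary distribution of the
ancestral random walk (step probabilities $p_{ij} = w_{ij}/w_i$) and
$\tau_i$ is the remeeting time of two independent walkers launched from
vertex $i$. Remeeting times derive from the pairwise coalescence times
$\tau_{ij}$, the unique solution of
$$\tau_{ii} = 0,\qquad
\tau_{ij} = 1 + \tfrac12\sum_k\left(p_{ik}\tau_{jk} + p_{jk}\tau_{ik}\right).$$

`coalescence_times()` assembles this as one linear system in the
$N(N-1)/2$ unordered-pair unknowns (exploiting the symmetry
$\tau_{ij}=\tau_{ji}$). Two identities serve as built-in diagnostics:
Kac's return-time formula $\sum_i \pi_i^2 \tau_i = 1$, and the covariance
identity
$$\frac{N - N_{\mathrm{eff}}}{N^2}
= \overline{\pi_i \cdot \pi_i\tau_i} - \overline{\pi_i}\,\cdot
\overline{\pi_i\tau_i},$$
so a graph amplifies weak selection exactly when $\pi_i$ and
$\pi_i\tau_i$ are negatively correlated across vertices.

Since `N_eff = N` for every isothermal graph (all weighted degrees equal —
the weak-selection analogue of the isothermal theorem), amplifiers of weak
selection can be constructed by perturbing an isothermal graph so as to
lower the relative degree of vertices with large remeeting time.
`construct_amplifier()` implements this: it finds the vertex with the
largest $\tau_i$ (smallest index on ties) and reduces the weight of the
incident edge with the largest analytic gradient
$-\sum_i \tau_i\, d\pi_i/d\epsilon$ (`neff_gradient`, with
$d\pi_i/d\epsilon$ computed exactly from the degree perturbation rather
than by finite differences; the caller can override the neighbor choice).
On random 3-regular graphs of size 12 this reliably produces
$N_{\mathrm{eff}} > N$ for moderate reductions (around half the edge
weight). Removing the edge entirely does not always preserve
amplification — the first-order argument only guarantees a window of small
perturbations — so the packaged examples use $\epsilon = 0.5$.

## Numerical choices

* **Linear solves.** Both the pair system and the absorbing chain are
  assembled sparsely (Matrix) but factorized densely (LAPACK/BLAS) while
  they fit in memory — up to 6000 pair unknowns and $10^4$ chain states —
  because both systems have enough fill-in that sparse LU is slower at
  these sizes. Above the thresholds, sparse LU takes over. One to three
  passes of iterative refinement bound the maximum equation residual by
  1e-9 (it is typically at machine precision); graphs with near-degenerate
  edge weights (hub weights around $10^{-6}$) need the refinement passes.
  Dense weight storage caps graphs at `N = 2000`.
* **Removable singularities.** Every closed form with a $0/0$ point at
  $r = 1$ switches to its first-order expansion
  $1/N + (r-1)(N_{\mathrm{eff}}-2)/(2N)$ inside $|r-1| < 10^{-6}$; at the
  window edge the two branches agree to about $10^{-9}$, so curves are
  continuous across the seam.
* **Classification.** `classify_full()` compares $\rho_G$ with the
  complete-graph baseline on a log-spaced grid (default 200 points on
  $[0.05, 50]$). All curves are tangent to the baseline at $r = 1$, so
  grid points where the difference is below a relative tolerance of
  $10^{-9}$ are treated as ties and excluded from the sign pattern.
  A transient amplifier must show exactly one sign change above $r = 1$;
  the crossing $r^*$ is then refined by bisection to $10^{-8}$. Verdicts
  are grid-bounded: behavior beyond $r = 50$ is not probed, and sign
  patterns matching no definition yield `indeterminate` with the pattern
  reported. The tolerances live in one place, `coalfix_tolerances()`.
* **eps = 0 is rejected by constructors.** The hub-edge families are
  disconnected at $\epsilon = 0$ (fixation is then impossible), so the
  constructors require $\epsilon > 0$ and the $\epsilon \to 0$ behavior is
  served exclusively by the closed-form functions.

## Graph families and generators

Deterministic constructors cover the complete graph, star, cycle, Fan
(one hub, `n` blades of `m` vertices, hub edges of weight $\epsilon$;
isothermal at $\epsilon = (m-1)/(nm-1)$), Separated Hubs (`h` mutually
unconnected hubs; the Fan is `h = 1`), and Star of Islands (a hub clique
joined weakly to `n` island cliques). Hub vertices always occupy the lowest
indices, which keeps symmetry arguments and closed-form cross-checks
stable. In the $\epsilon \to 0$ limit the families classify by parameter
regime: Separated Hubs is a suppressor for `n <= h`, a reducer for
`n = h + 1`, and a transient amplifier for `n >= h + 2`; Star of Islands
is a suppressor for `m <= h - 1`, a reducer for `m = h`, and a transient
amplifier for `m >= h + 1`; the 2-blade Fan is a reducer and Fans with
three or more blades (of two vertices) are transient amplifiers, the
many-blade limit crossing the well-mixed curve at the golden ratio.

Random ensembles (Erdős–Rényi with $p = \langle k\rangle/(N-1)$,
Barabási–Albert growth from a complete seed of `m + 2` vertices, and
random `k`-regular graphs) are delegated to igraph behind the same
`weighted_graph` interface, with seeds fixed per draw. Disconnected
Erdős–Rényi and regular draws are rejected and redrawn by default —
$N_{\mathrm{eff}}$ is undefined on disconnected graphs — with the redraw
count attached to the result; `require_connected = FALSE` exposes the
unconditioned distribution. These ensembles consistently suppress weak
selection, and the mean-field approximation
$N_{\mathrm{eff}} \approx N\mu_1^2/\mu_2$ (degree moments $\mu_1, \mu_2$;
for Erdős–Rényi, the binomial-degree prediction
$(N-1)p/[(N-2)p+1]$) tracks the exact ratio to within about 10% on
average at the sizes the tests use. The approximation never exceeds $N$
(Cauchy–Schwarz), so it cannot detect amplifiers.

## What the tests do and do not show

The suite runs entirely on synthetic graphs: the named families at desk
sizes (chains up to $N \le 10$ routinely, $N = 12$ occasionally), random
ensembles up to $N = 60$ with 100 graphs per model, and $10^5$-trial
Monte Carlo runs. That scale is enough to pin the identities (Kac,
covariance, isothermal tangency) to 1e-8 and the closed forms to 1e-10,
and to exhibit every classification regime. It does not probe behavior at
$N$ in the thousands, degree distributions of real contact networks, or
classification of curves whose crossing points lie beyond $r = 50$.
Limit-family verdicts describe the $\epsilon \to 0$ curves, not any fixed
positive $\epsilon$; at small but positive $\epsilon$ the finite graph's
curve deviates from the limit by $O(\epsilon)$, and fixation times (not
analyzed here) diverge as $\epsilon \to 0$.

## Known limitations

* Birth-death (Bd) updating, arbitrary initial mutant configurations, and
  fixation-time statistics are out of scope; step counts are recorded by
  the simulator but not analyzed.
* The exact chain is exponential in `N` by nature; it exists to validate
  the polynomial-time weak-selection machinery, not to scale.
* Closed-form Separated Hubs effective sizes at arbitrary $\epsilon$ are
  not implemented; the numeric solver covers any $\epsilon > 0$ and the
  analytic forms cover the limit.
* Whether every isothermal graph is a reducer is an open question; the
  package reports numerical evidence per graph and asserts nothing
  globally.
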