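---
title: "Stationary distributions of stochastic reaction networks by decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stationary distributions of stochastic reaction networks by decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crndecomp)
```

## The model

A chemical reaction network (CRN) is a triple $(\mathcal S, \mathcal C,
\mathcal R)$ of species, complexes (nonnegative integer combinations of
species) and reactions $\nu \to \nu'$ between distinct complexes, each with
a positive rate constant $\kappa$. In the stochastic interpretation the
copy-number vector $X(t) \in \mathbb Z^n_{\ge 0}$ is a continuous-time
Markov chain that jumps from $x$ to $x + \nu' - \nu$ with intensity
$$\lambda_{\nu\to\nu'}(x) \;=\; \kappa_{\nu\to\nu'}\,
  \prod_i \prod_{j=0}^{\nu_i - 1} \theta_i(x_i - j),$$
where the per-species rate functions $\theta_i$ vanish exactly on
$x \le 0$. Mass-action kinetics is $\theta_i(x) = x$, which makes the
product a falling factorial $x!/(x-\nu)!$; Hill type I
($x^m/(k^m + x^m)$) and Hill type II ($k_1^m/(k_2^m + x^m)$, forced to $0$
at $x \le 0$) cover the saturating kinetics common in mathematical
biology.

On a finite irreducible component $\Gamma$ (a set of mutually accessible
states closed under the dynamics) the stationary distribution $\pi_\Gamma$
is the unique probability solution of the master equation $\pi Q = 0$.
Conservative networks — those admitting a strictly positive species
weighting preserved by every reaction — have finite components, so a
direct solve is always available there as ground truth.

## Why decomposition

Explicit stationary distributions are known only for special families:
complex-balanced networks carry Poisson-type product forms
$\pi(x) \propto \prod_i c_i^{x_i}/\prod_{l\le x_i}\theta_i(l)$ at a point
of complex balance $c$, and certain two-species exchange/autocatalytic
motifs have closed-form per-species functions. The package's central
device extends these islands: write the network as a reaction-disjoint
union $\mathcal G = \mathcal G_1 \cup \dots \cup \mathcal G_s$ of
*essential* parts (every state of the part's lattice belongs to some
irreducible component — certified reaction-wise by checking that each
reactant complex is accessible from its product complex). If each part has
a product-form stationary distribution on the projections of $\Gamma$, and
for every species shared between two parts the two per-species functions
are proportional, then
$$\pi(x) \;=\; \frac 1Z \prod_{i} f_i(x_i)$$
is stationary for the union, and is *generalized balanced* for the
partition $\{(\mathcal R_j, \mathcal R_j)\}_j$: the master equation holds
already within each part's reaction set. The package verifies this balance
property explicitly on every assembly rather than trusting the theory —
a nonzero residual would expose an implementation defect.

## What the solver does

`solve_by_decomposition()` proceeds in four steps.

1. **Search.** Candidate decompositions into essential parts. The default
   search groups reversible reaction pairs by their exact species support:
   for joins of two-species motifs (the tractable family) each motif's
   four reactions share a two-species support, so the natural split is
   found without enumerating the $2^{|\mathcal R|}-1$ bipartitions. We
   chose support-grouped reversible pairs over linkage-class atoms because
   the single-molecule complexes of all glued motifs lie in one linkage
   class, which can never separate the parts. An exhaustive bipartition
   search (deterministic order: by subset size, then lexicographic) backs
   the heuristic up for networks with at most 12 reactions, and the
   trivial one-part decomposition is always tried last so that a network
   that is itself a registered family is solved in closed form.

2. **Per-part solvers**, tried in order:
   * *transfer/motif*: two-species parts whose jumps all transfer one
     molecule between the species $U$ and $W$, with inflow reactions
     containing exactly one $W$ and outflow reactions pure in $U$. This
     covers the exchange motif $U \rightleftharpoons W$,
     $2U \rightleftharpoons U + W$ and its autocatalytic generalisations
     $W + (m-1)U \to mU$. The per-species functions follow from the
     one-dimensional reaction-vector-balance recursion:
     $f_W(x) = d^x / \prod_{l \le x}\theta_W(l)$ and
     $$f_U(x) = \frac{d^x}{\prod_{l\le x}\theta_U(l)} \prod_{l=1}^{x}
       \frac{G_{\mathrm{in}}(l-1)}{G_{\mathrm{out}}(l)},$$
     with $G_{\mathrm{in}}, G_{\mathrm{out}}$ the aggregate inflow/outflow
     rate factors. For the plain motif under mass-action this is
     $(d^x/x!)\prod_l (\kappa_{\mathrm{in}} + \kappa'_{\mathrm{in}}(l-1))/
     (\kappa_{\mathrm{out}} + \kappa'_{\mathrm{out}}(l-1))$, where the
     numerator collects the rates of the reactions producing $U$ and the
     denominator those consuming it. (The orientation matters; it is fixed
     by the recursion and verified against null-space solves in the test
     suite.)
   * *complex balanced*: a point of complex balance is computed from the
     kernel of the kinetic Laplacian per linkage class (Matrix-Tree
     structure; kernel vectors of strongly connected classes are positive)
     followed by a log-linear solve for $c$, and accepted only when the
     complex-balance residual vanishes numerically. The part then carries
     Poisson-type functions $c_i^x / \prod_{l\le x}\theta_i(l)$.
   * *direct + factorise*: small conservative parts are solved directly
     and the log-probabilities regressed on per-species terms; a maximal
     log-residual below $10^{-8}$ certifies the product form and the
     fitted tables become the part's functions.

3. **Matching.** On a component with a conservation relation, re-tilting
   all of a part's functions by $d^{x}$ leaves the normalised distribution
   unchanged, so each conservative part carries one free constant $d$.
   Shared-species functions must agree as *ratio sequences*
   $\rho(l) = f(l)/f(l-1)$ up to one common factor per part; the assembler
   roots each connected block of the part graph (preferring a part with no
   tilt freedom, whose $d$ is pinned to 1), propagates the implied tilts,
   and demands exact consistency (relative tolerance $10^{-10}$ — the
   proportionality hypothesis is exact, so least-squares matching would
   mask genuine failures). Any inconsistency refuses the assembly with a
   message naming the shared species; `force = TRUE` overrides this purely
   so that tests can demonstrate the refused product violates the master
   equation.

4. **Assembly and verification.** $\pi \propto \prod_i f_i$ is normalised
   over the component (log-space accumulation; factorial-type factors
   underflow quickly on the natural scale), generalized balance with the
   per-part partition is checked, and the master-equation residual
   $\|\pi Q\|_\infty$ is reported. On truncated components the normalising
   sum is taken over the explored box and summability of the infinite sum
   is judged by the ratio test on the per-species ratio limits — verdicts
   `summable` / `divergent` / `inconclusive`, the last being an honest
   outcome since the ratio test is only sufficient.

## Numerical choices

* **Direct solves** replace one row of $Q^\top$ with the normalisation
  constraint; dense LU below 2000 states, sparse LU above. Residuals above
  $10^{-10}$ (scaled by the maximal intensity) raise an error: a finite
  closed communicating class has a unique stationary distribution, so a
  defect signals a bug, not a borderline case.
* **Deficiency** uses an exact integer (fraction-free) rank of the
  reaction-vector matrix, so no floating-point rank decision can produce a
  negative deficiency.
* **Conservation vectors** come from a linear program over $c_i \ge 1$
  (positivity is scale-invariant), with the floating-point solution
  rounded to small rationals and re-verified in integer arithmetic.
* **Exploration caps.** Accessibility on an unbounded lattice is only
  semi-decidable. Reachability searches are capped per species — by the
  conservation law when one exists (components are then finite and the
  cap is exact), otherwise by the seed plus a margin of 10 — and any
  suppressed jump marks the result `truncated`, downgrading essentiality
  verdicts to `inconclusive` rather than guessing.
* **States** are integer vectors in the species order of first appearance
  in the input; this ordering is deterministic and survives write/parse
  round trips.

## The fixture generator

`generate_fixture()` builds the reference networks used throughout the
tests (the reversible three-species deficiency-two join, the
gene-expression motif, the non-essential chain, the detailed-balance
counterexample, the open motif-plus-exchange joins) plus randomised
families with known answers:

* `motif_chain`: $L$ exchange motifs glued over one shared fast species,
  rates drawn log-uniformly from $[0.1, 10]$ — the family for which
  assembly succeeds for *every* draw, since both shared functions are
  $d^x/x!$ up to tilt. Components are conservative simplices; tests use
  total counts $N \in 3..6$ and $L \in 2..3$, sizes at which a direct
  solve is exact and fast enough to serve as the oracle for hundreds of
  draws.
* `example5`-type open joins: two motif-plus-exchange branches sharing the
  autocatalytic species. Here the exchange subnetworks pin the tilts to
  their complex-balance values, so matching imposes genuine rate
  conditions — the family used to exercise refusal behaviour.

The generator emulates exactly the structural situations the theory
distinguishes (conservative vs open, matched vs mismatched, mass-action vs
Hill kinetics). It does not emulate features of experimental reaction
systems — multiscale rate constants spanning many orders of magnitude,
large species counts, or sloppy/unknown kinetics — so passing tests
demonstrate correctness of the mathematics and the implementation, not
robustness on empirical network reconstructions.

## Simulation

`ssa_trajectory()` implements the exact stochastic simulation algorithm
(exponential waiting times at the total intensity; selection by
cumulative-sum inversion with ties broken in reaction file order, so a
fixed seed reproduces trajectories bit for bit). `empirical_stationary()`
estimates $\pi$ by *time-weighted* occupancy after a burn-in fraction —
the stationary law of a CTMC weights states by holding times, so event
counting would be biased toward short-lived states. Standard errors are
binomial-style on the post-burn-in event count; they understate the error
for strongly autocorrelated chains, which is acceptable for the
consistency checks they serve here (agreement within total variation 0.05
at $10^5$ events on ten-state components).

## Known limitations

* The decomposition search is sufficient-condition machinery: a refusal
  means the proportionality hypothesis failed for the decompositions
  tried, not that no product form exists. Characterising decomposability
  is open territory.
* Only reaction-disjoint decompositions are searched. Unions that glue
  over shared reactions (rates adding) are supported by the union
  constructor, but the space of such decompositions is uncountable and is
  deliberately not enumerated.
* Per-part solvers cover the printed closed-form families plus small
  conservative parts via direct factorisation; general autocatalytic
  parameterisations beyond the two-species transfer family are out of
  scope.
* On truncated components all statements are relative to the explored
  box; tail mass control is the caller's responsibility (the acceptance
  checks use caps with Poisson tail mass below $10^{-12}$).
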