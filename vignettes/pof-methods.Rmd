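---
title: "Probability-of-failure analysis of metabolic networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability-of-failure analysis of metabolic networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pofkit)
```

## The model

`pofkit` treats a metabolic network as a binary-state system: each of its
$r$ reactions is either functional or knocked out, and the network as a
whole either grows (produces biomass flux at steady state) or does not.
Loss-of-function (LOF) mutations strike reactions independently at a
per-reaction rate $p$ per unit of evolutionary exposure. The probability
of failure is

$$F \;=\; \sum_{d=1}^{r} w_d\, f_d, \qquad
  w_d = \binom{r}{d} p^d (1-p)^{r-d},$$

where $f_d$ is the failure frequency: the fraction of the
$\binom{r}{d}$ possible deletion sets of size $d$ that abolish growth. A
deletion set is lethal precisely when it contains a **minimal cut set
(MCS)** — a minimal set of reactions whose joint removal stops biomass
production. Essential reactions are the MCSs of cardinality 1, synthetic
lethal pairs those of cardinality 2, and so on.

The assumptions baked into this definition are worth stating. Reactions
fail independently and completely (no partial activity, no gene-level
structure such as isozymes or multi-functional enzymes); growth is judged
by steady-state flux balance, so regulatory and kinetic effects are out of
scope; and $p$ is uniform across reactions. Under these assumptions $F$ is
a pure function of the MCS family — two networks with the same cut sets
have the same PoF regardless of their size, which is what makes the metric
comparable across reconstructions.

## From cut sets to probabilities

Writing the lethality event as a union over MCSs and expanding by
inclusion–exclusion gives

$$F \;=\; \sum_{\emptyset \ne J \subseteq \{1..m\}} (-1)^{|J|-1}
  \, p^{\,|M_J|},$$

with $M_J$ the union of the cut sets indexed by $J$. Only the union's
composition matters, so the package first distils the power set into a
**union profile**: the net signed count of subsets per union descriptor
(`union_profile()`). For uncompressed collections the descriptor is the
union's cardinality; the profile is then a polynomial in $p$ with integer
coefficients (`pof_polynomial()`), and $f_d$ follows from

$$f_d = \sum_u S_u \,\frac{\binom{r-u}{\,d-u\,}}{\binom{r}{d}}.$$

The power set is walked by a canonical recursion: cut sets are sorted by
ascending cardinality (ties keep input order — the tie-break is
documented, stable, and property-tested to be irrelevant to results), and
each subset is reached exactly once by extending with indices strictly
below its current minimum. Two devices keep the walk tractable:

* **Pruning.** Unions only grow along a branch, so once a union needs more
  than $d_0$ deletions the entire branch is discarded.
* **Sign cancellation.** If a cut set with index below the subset's
  minimum is already contained in the current union, toggling that index
  pairs every descendant with a twin of opposite sign and identical union;
  the branch's net contribution is zero and it is skipped. Correctness of
  this lemma is established by an equivalence property test against the
  shortcut-free walk, not assumed.

## Truncation and the error bound

Genome-scale models only ever yield the low-cardinality MCSs (up to some
$d_m$, typically 3), and the weighted sum is truncated at a depth $d_0$:

$$\tilde F_{d_0}^{d_m} = \sum_{d=1}^{d_0} w_d f_d^{d_m},$$

where $f_d^{d_m}$ is computed from the known cut sets only, so
$f_d^{d_m} \le f_d$ and the estimate is a lower bound. In the worst case
every combination of $d_m + 1$ deletions not yet known to be lethal is
lethal, i.e. $f_d = 1$ for all $d > d_m$; the gap to that worst case is

$$\varepsilon_{\max} = 1 - \tilde F_{d_0}^{d_m}
  - \sum_{d=0}^{d_m} w_d\,(1 - f_d^{d_m}),$$

which uses only the exactly known frequencies ($d \le d_m$) and is
therefore independent of $d_0$. Every `pof()` result carries this bound,
and the sandwich $\tilde F \le F \le \tilde F + \varepsilon_{\max}$ is
property-tested across thousands of randomized truncations. When only
essential reactions are known the estimate collapses to the closed form
$1-(1-p)^{m_1} \approx m_1 p$ (`essential_only_pof()`).

## Parameters and defaults

* `p` (dimensionless rate per reaction): default `1e-4`, the conventional
  order of magnitude for deleterious LOF rates in bacteria; comparative
  analyses depend on relative differences, so the exact value matters less
  than using one value consistently.
* `d_m`: a property of the input collection — the cardinality up to which
  its cut set list is complete. Enumeration cost grows steeply with it;
  3 is the usual practical ceiling.
* `d_0` (truncation depth): default 10. Deeper sums only add terms of
  order $w_d \le \binom{r}{d} p^d$, negligible for small $p$; the error
  bound is unaffected by the choice.
* `threshold` (growth): biomass flux at or above `1e-6` (absolute, with
  media on a unit-to-tens uptake scale) counts as growth. Lethality is a
  threshold question and the cutoff is configurable on every function
  that solves a growth problem.

## Growth testing and enumeration

Growth questions are linear feasibility problems: steady state
$S v = 0$, flux bounds with knocked-out reactions fixed to zero in both
directions (reaction-level knockout semantics), the medium applied as
uptake bounds on exchange reactions. The package solves these with its own
dense bounded-variable two-phase primal simplex using Bland's rule for
both pivots. That choice is deliberate: the knockout problems this package
must judge are routinely *degenerate* (a lethal knockout shrinks the flux
space to a point), and an anti-cycling exact method with a freshly
factorized basis at every iteration is robust there at negligible cost for
networks of tens of reactions. Infeasibility is reported distinctly from
solver breakdown, so "no growth" can never be an artifact of a failed
solve.

`enumerate_mcs()` finds all MCSs up to $d_m$ by testing deletion subsets
in order of increasing size; the level order makes minimality automatic,
and supersets of found cut sets are skipped without solving. By default
**every** reaction is knockable, including exchanges and the biomass
reaction itself (which is then trivially essential). This convention was a
genuinely open design point: for genome-scale work one often excludes
boundary reactions, because nutrient availability is modeled by the
medium, but the package's reference six-reaction network counts its
substrate inlets and its biomass drain among the cut sets, and silently
dropping them would change every reported $m_i$. The `exclude` argument
makes the convention explicit per call.

`make_consistent()` removes flux-incapable reactions (flux variability
analysis at biomass fraction 0, or 1 for optimal-growth consistency).
Any-growth consistency cannot change the MCS family — a blocked reaction
never participates in a lethal combination — which is tested directly.

## Linear compression and weighted cut sets

Reactions whose fluxes are fully coupled (fixed ratio in every steady
state: unbranched chains, enzyme subsets) are merged by
`linear_compress()` into lumps of weight $w$ = number of members, detected
as proportional rows of the nullspace of $S$ (proportionality tolerance
`1e-9`). The biomass reaction is exempt. Cut sets over lumps use the
generalized summand $\prod_{\text{lumps}} (1-(1-p)^w)$, which reduces to
$p^{|M_J|}$ at unit weights; failure frequencies use inclusion–exclusion
over untouched lumps. Truncation prunes on the union's *minimal-hit size*
(one deletion per lump), the conservative choice that never discards a
union contributing to depths $\le d_0$.

One bookkeeping decision deserves a note. A lump of weight $w$ in a cut
set stands for $w$ interchangeable single-reaction choices, so the
original-space cardinality of a compressed cut set is its **lump count**,
and that is what the package compares against $d_m$ and tallies in `m_i`;
the weight sum (reactions spanned) remains available as
`mcs_cardinality()`. Using the weight sum for the completeness bound would
make compressing a collection of chain essentials impossible and would
corrupt the error bound's meaning. Whether the reference implementations
of this metric decompress first or work lump-wise is not observable from
their outputs; `pofkit` works lump-wise and guarantees equivalence by a
property test: the PoF polynomial of a compressed collection equals that
of its decompressed expansion, coefficient by coefficient, in exact
integer arithmetic.

## Numerical choices

* All signed union counts and failure-frequency numerators are exact
  integers; whenever $\binom{r}{d}$ is exactly representable in a double
  ($\le 2^{52}$) the quotient is taken once at the end, otherwise a
  stable falling-factorial product is used. Frequencies must land in
  $[0,1]$ and be non-decreasing by construction; a violation beyond
  `1e-9` raises an internal error rather than being clipped, because an
  out-of-range value indicates a bug, not noise.
* Binomial weights are evaluated in log space via `dbinom()`, so there is
  no overflow for large $r$ and $\sum_d w_d = 1$ to machine precision.
* $1-(1-p)^w$ is computed as `-expm1(w * log1p(-p))` to preserve
  precision at small $p$.
* Growth-rate matching (`match_growth_rate()`) bisects the carbon uptake
  bound to a relative tolerance of `1e-6` with the conventional
  $\pm 10{,}000$ relaxation ceiling; the matching tolerance is a package
  choice, as no canonical value exists.

## Synthetic generators, and what tests do and do not show

`toy_network()` is the fixed six-reaction reference: two substrate
inlets, one reversible interconversion, two convergent routes, one
biomass drain; its MCS family (one essential, two pairs, two triplets)
and PoF polynomial $p + 2p^2 - 7p^4 + 7p^5 - 2p^6$ anchor the end-to-end
tests. The stoichiometry is a reconstruction constrained by that printed
cut set family and reaction count — any network with the same cut sets is
equivalent for every quantity this package computes.

`random_mcs_collection()` draws valid cut set families with prescribed
$m_1, m_2, m_3$ and an overlap dial controlling how much
inclusion–exclusion cancellation occurs; `random_layered_network()` and
the chain-of-chains test fixture generate growing models with tunable
parallel redundancy and lumpable chains. All randomness flows from
explicit seeds. The randomized suites run on hundreds of collections with
$r \le 12$, $m \le 8$ and on networks of at most 15 reactions — sizes
chosen so that the *independent oracles* (exhaustive bitmask enumeration
of all deletion sets, the full $2^m - 1$ power-set walk, and definitional
minimality checking of every candidate cut set) remain exact and fast.
Passing them shows the combinatorics, the estimator, the bounds, and the
compression algebra are correct; it says nothing about gene–protein–
reaction structure, kinetic regulation, or the statistical properties of
real genome-scale reconstructions, none of which the generators emulate.

## Known limitations

* Reaction-level only: duplicated genes, isozymes and GPR rules are
  invisible; a gene-level analysis would need gene-level cut sets.
* The exact evaluator refuses collections beyond `max_m = 25` cut sets
  (the power set is $2^m$); larger collections must use the truncated
  estimator, whose error bound is then the honest statement of
  uncertainty.
* The brute-force enumerator is exponential in $d_m$ by design and
  guarded by an explicit budget; genome-scale enumeration requires
  dedicated MILP-based tooling and is out of scope.
* The SBML reader covers Level 3 core with FBC flux bounds and
  objectives — the subset needed for constraint-based models — not the
  full SBML feature set.
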