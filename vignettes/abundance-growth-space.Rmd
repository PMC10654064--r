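---
title: "Methods: abundance-growth space analysis of community metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: abundance-growth space analysis of community metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agspace)
```

## The model

`agspace` studies the metabolic phenotypes a microbial community can display
as a function of its composition and growth rate, using constraint-based
modeling. A community of $N$ members is represented as a single
compartmentalized stoichiometric system: each organism keeps its own
metabolites and reactions (renamed `<organism>_<reaction>`), and a shared
*pool* compartment collects every metabolite present in the extracellular
space of at least one member. Former member exchange reactions become
transports between that member's extracellular compartment and the pool, and
one community exchange reaction per pool metabolite (`EX_<met>_e`, uptake
negative) controls what the environment supplies or absorbs.

Fluxes are expressed per gram dry weight of *community* biomass. Because the
single-organism bounds are per gDW of the organism, the bounds of every
reaction of member $i$ are scaled by its relative abundance $f_i$
($\sum_i f_i = 1$):

$$ f_i\,LB_r \le v_r \le f_i\,UB_r, \qquad r \in R_i. $$

Pool exchange bounds are *not* scaled: they cap the community as a whole.
Under balanced growth — the standard assumption that the composition is
maintained over time, so all members grow at the community rate $\mu$ — each
member's biomass flux is pinned:

$$ v_{biom,i} = f_i\,\mu, \qquad \mu = \sum_i v_{biom,i}. $$

We encode the pinning as an equal lower and upper bound, which keeps the
whole system a plain linear program. For fixed $(F, \mu)$ the feasible flux
distributions form a polytope $P_{F,\mu}$; the **abundance-growth space** is
the set of pairs $(F,\mu)$ with $P_{F,\mu} \neq \emptyset$. It is generally
non-convex as a whole, but sections at fixed $F$ (varying $\mu$) or fixed
$\mu$ (varying $F$) are convex, which the test suite asserts on every toy
grid.

## The grid

`build_grid(community, l)` discretizes the space: $\ell$ equidistant
abundance values spanning $[0,1]$ per coordinate, filtered to the simplex;
$\ell$ equidistant growth values spanning $[0, \mathrm{MAXbiomass}]$, where
MAXbiomass is the largest `max_growth` over the abundance points themselves
(not a continuous optimum). Grid endpoints $f_i \in \{0, 1\}$ and $\mu = 0$
are included; $f_i = 0$ simply forces all of that member's fluxes to zero.
Every candidate is tested by solving its feasibility LP; candidates above
the per-abundance growth maximum are pruned without a solve, which is exact
because no feasible point can exceed that maximum by definition. Iteration
order is deterministic (lexicographic in $(\mu, f_1, \dots)$), so repeated
runs produce byte-identical output.

For $N = 2$ this gives $\ell^2$ candidate points and the space can be drawn
in the $(f_1, \mu)$ plane.

## Qualitative states and plasticity

At each feasible grid point, flux variability analysis (two LPs per
reaction) yields the range $[\min_{F,\mu}(r), \max_{F,\mu}(r)]$ over
$P_{F,\mu}$ for every selected reaction. The range is classified into one of
eight categories: `0` (blocked here), `-`/`+` (fixed nonzero: mandatory, no
plasticity), `--`/`++` (variable, sign-definite: mandatory with *flux
plasticity*), `-0`/`0+`/`-+` (range touching or spanning zero: optional,
*structural plasticity*, i.e. alternative routes could replace the
reaction).

Two numerical choices make the classification stable. Endpoints within
`eps` of zero are snapped to zero, and ranges narrower than `eps` are
collapsed to a point *before* sign snapping, so solver noise of order
1e-12 cannot turn a pinned flux into a "variable" state. The default
`eps = 1e-9` matches the LP feasibility tolerance; no zero tolerance is
inherent to the classification itself, so `eps` is exposed as a parameter.
Classification is total and exclusive — exactly one category applies to any
legal range — which the suite checks against an independent predicate table
over randomized and boundary ranges.

The selected reaction set $R'$ defaults to the community exchange reactions
(the community's interface with its environment); `rxns = "all"` analyzes
every reaction.

## Partition, cluster-partition, consensus

Two complementary partitions of the grid are computed. The **exact
partition** groups points with identical categorical vectors over $R'$;
reconstructing vectors from zone descriptors reproduces the matrix exactly.
Because the number of exact zones can explode with $|R'|$, the
**cluster-partition** groups *similar* vectors: each point's states are
one-hot encoded as (reaction, category) indicators, pairwise binary Jaccard
distances are computed, and average-linkage agglomerative clustering is cut
at $k$ clusters.

Design choices that were genuinely open:

* a Jaccard distance on categorical vectors is not uniquely defined; we
  one-hot encode (reaction, category) pairs and use the standard binary
  Jaccard, which preserves category identity;
* linkage is configurable (`single`, `complete`, `average`, `ward.D2`) with
  `average` (UPGMA) as a robust default;
* distances are rounded to 12 decimals before linkage so dendrogram ties
  break deterministically by point order.

Each cluster gets a **consensus descriptor**: per reaction, the state held
by *strictly more than* 80% of the cluster's points, otherwise no-consensus
(an empty cell in tables). For choosing $k$, each reaction is scored by the
fraction of points whose state equals the *modal* (plurality) state of
their cluster, and the smallest $k$ at which every reaction scores at least
0.80 is selected. Scoring against the modal state rather than the strict
consensus keeps the score well defined when a cluster has no >80% state; the
strict rule still governs what descriptor tables display. Both thresholds
are configurable. With $k$ equal to the number of distinct vectors, the
cluster-partition coincides with the exact partition (zero distances merge
first), a property the suite asserts.

Clusters are displayed ordered by mean growth rate, then mean abundance of
the first member, so tables read from low to high growth.

## Quantitative flux coupling

The qualitative states do not capture the *degree* of coupling between
reactions. `coupling_envelope` fixes an abundance-growth point, spans the
FVA range of a first reaction with 50 homogeneous values (both extremes
included; a fixed reaction degenerates to a single sample), and runs FVA on
the second reaction at each value. Organism-owned fluxes are divided by the
owner's $f_i$ to express them per gDW of that organism; community-level
exchanges are reported unnormalized with a unit tag, and a zero-abundance
owner is an error directing the caller to raw units. The conditional
minimum (maximum) is a convex (concave) piecewise-linear function of the
pinned flux, and every conditional interval nests inside the global FVA
range — both checked by midpoint tests on the toys.

## Scenarios

* **Substrate split** $\lambda$: community uptake bounds set to
  $-\lambda\,\mathrm{Max}_{Fe(II)}$ and $-(1-\lambda)\,\mathrm{Max}_{tsul}$
  with reference caps 150 and 10 mmol/gDW$_{com}$/h — energetically
  equivalent convex combinations of the two inorganic sources.
* **Biomass recycling** $\alpha \in [0, 1)$: every member biomass reaction
  additionally produces one unit of a community-biomass pseudo-metabolite
  per gDW; pseudo-reactions split it into a degraded fraction $\alpha$
  converted to 6.169 mmol glucose equivalents in the pool and a net
  fraction removed by a sink. Recycling is pure mass bookkeeping with
  pseudo-metabolites; $\mu$ stays *gross* growth ($\sum_i v_{biom,i}$), as
  the balanced-growth constraint implies. With $\alpha = 0$ the feasible
  space is identical to a model without the block (tested by grid
  comparison).
* **Amino-acid supplementation**: community amino-acid exchanges are closed
  (lower bound 0) by default and opened to $-0.01$ mmol/gDW$_{com}$/h when
  supplemented; member glucose uptake is capped at 10 and amino-acid export
  at 0.2 mmol/gDW$_{org}$/h, applied before abundance scaling.
* **Energy efficiency**: "sum of fluxes" is interpreted as the sum of
  absolute fluxes via non-negative forward/reverse splitting (a signed sum
  is meaningless under direction conventions). $S_{min}$ is recomputed at
  every grid point — the constraint involves $F$ and $\mu$, so a single
  space-wide minimum would be ill-defined — and
  $\sum_r |v_r| \le factor \cdot S_{min}$ restricts the polytope before FVA.
  Factors 1.1, 1.2, 1.5 correspond to 10/20/50% deviation from the
  parsimonious optimum; shrinking the factor yields nested ranges.

## Linear programming

No external LP solver is assumed: the package ships a dense two-phase
tableau simplex with Bland's anti-cycling rule, written for the small LPs
that community toys and moderate models generate. Variables with equal
bounds are substituted out first (the balanced-growth pins), upper bounds
become explicit rows, and the final solution is re-solved from the optimal
basis by QR factorization, so reported optima carry machine-precision
accuracy rather than accumulated tableau error. Feasibility is declared at
a scaled 1e-9 tolerance with no slack relaxation — reproducibility over
generosity. Infinite input bounds are replaced by the conventional
$\pm 1000$ caps at model construction, making every polytope bounded; a
range endpoint at $\pm 1000$ therefore means "no finite bound was set".
The simplex is cross-checked in the test suite against an independent
implementation (`pracma::linprog`) on random bounded LPs and against a
vertex-enumeration oracle on the toys.

## The toy communities and what they show

Because the framework's behavior must be verifiable without large model
downloads, the package ships two fully analyzable two-member fixtures whose
defaults encode the study conditions of the analyses they emulate:

* **Cross-feeding pair** (`make_crossfeeding_pair`): two glucose-consuming
  auxotrophs, each required to import 1 mmol/gDW of a metabolite only the
  partner exports, with export capped at $p = 0.2$ and glucose at 10
  mmol/gDW/h. The maximal growth has the closed form
  $\mu_{max}(F) = \min(f_2 p / f_1,\; f_1 p / f_2,\; \mu_{cap})$ — a concave
  triangle over abundance peaking at the balanced composition — which
  `max_growth` recovers to 1e-8 across a 21-point sweep. The substrate cap
  never binds as long as it exceeds $2p$, which the defaults guarantee.
* **Chemolithotroph pair** (`make_chemolithotroph_pair`): two members
  oxidizing an iron-like and a thiosulfate-like source, the second also able
  to assimilate pool glucose released by biomass recycling. Yields (0.001
  and 0.015 gDW per mmol) are calibrated so either source alone at its
  reference cap sustains 0.15 1/h, so the $\lambda = 0.5$ reference case has
  a known maximal growth of exactly 0.15.

Fixtures are emitted as genuine SBML files in tests, exercising the same
I/O path as real models, and all fixture generation is deterministic. A
brute-force oracle (`brute_force_ranges`) recomputes flux ranges by
enumerating the polytope's vertices in nullspace coordinates — no code
shared with the simplex FVA path — and agrees with it to 1e-6 at a hundred
grid points.

The toys reproduce the *structural* features that matter to the method:
mandatory cross-feeding, competition for shared substrates, facultative
heterotrophy, recycling, and the qualitative geometry of the space. They do
not emulate genome-scale redundancy (thousands of reactions, alternative
pathways, cofactor coupling), so passing tests demonstrate correctness of
the machinery, not biological conclusions about any real community; on
genome-scale inputs the same operations apply unchanged but category counts
can be sensitive to `eps`.

## Problem sizes and determinism

The shipped analyses use grids of $\ell$ = 5–10 on the toys (25–100
candidate points, 19–23 reactions), where the full pipeline — grid, FVA at
every feasible point, both partitions, envelopes — completes in seconds;
the implementation is the same for any $\ell$, and larger grids scale as
$\ell^2$ LP solves for $N = 2$. There is no randomness anywhere in the
pipeline; randomized property tests draw their cases under fixed seeds.

## Known limitations

* Hierarchical clustering with ties can place genuinely equidistant points
  differently under row permutation; determinism is guaranteed for a fixed
  input order (distances rounded, Bland-style tie-breaks), not under
  relabeling.
* The vertex-enumeration oracle is exponential in the polytope's degrees of
  freedom and refuses models beyond a size guard; it is a test oracle, not
  an analysis tool.
* Only two-member communities can be plotted; the analysis itself supports
  any $N$.
* The printed cluster counts of genome-scale analyses (e.g. how many
  clusters "accurately represent" a space) depend on the unstated binary
  encoding and linkage of the original analyses; with this package's
  documented choices, results are reproducible but not guaranteed
  bit-identical to other implementations.
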