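---
title: "Flux graphs from genome-scale models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux graphs from genome-scale models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxgraph)
```

This vignette is the package's own account of what it computes and why the
open design questions were settled the way they were. The reference manual
documents each function; here the focus is the model, the algorithms, the
tunable parameters and the limits of what the test suite demonstrates.

## The constraint-based model

A genome-scale metabolic model (GEM) is a stoichiometric matrix $S$
(metabolites $\times$ reactions), flux bounds $lb \le v \le ub$
(mmol gDW$^{-1}$ h$^{-1}$), and an objective vector $c$, usually an indicator
of the biomass reaction. Flux balance analysis (FBA) assumes the internal
metabolite pools are at steady state and solves

$$\max_v\; c^\top v \quad \text{s.t.} \quad S v = 0,\; lb \le v \le ub .$$

Species flagged with the SBML boundary condition are excluded from the
mass-balance rows (exchange reactions are unbalanced by construction) but kept
as displayable nodes. Reaction knockouts force $lb = ub = 0$ for the selected
reactions, which can only shrink the feasible region — the optimal objective
is monotonically non-increasing in the knockout set, a property the tests
check on randomized models.

**Degeneracy.** The optimal *objective value* of an LP is unique; the optimal
*flux vector* generally is not. Everything downstream (edge weights, tree
shapes, path costs) is a function of the particular optimal vertex returned,
so the solver is pinned to a fully deterministic configuration: the same model
always yields the same vertex, and two runs of the whole pipeline produce
byte-identical files. Assertions about individual fluxes are only made on
models engineered to have a unique optimum (such as the `TOY6` fixture).

**Solver.** `optimizeFlux()` shifts the problem to $x = v - lb \ge 0$ and
solves it with `pracma::linprog`. Two quirks of that routine are handled
explicitly: its pivot tie-breaking consumes the R random stream, so the call
runs under a pinned RNG state (this is also why it never perturbs the
caller's stream), and its big-M phase has no anti-cycling safeguard and can
stall on degenerate bases. Any non-success return is therefore re-solved by an
internal two-phase dense simplex using Bland's rule, which terminates by
construction and yields a definitive `optimal` / `infeasible` status. Upper
bounds become explicit slack rows, so the boxed problem is never unbounded.
Declared infinite bounds are clamped to $\pm 10^6$ before solving.

Numerical tolerances: mass-balance residuals of an accepted solution are
checked against $10^{-6}$; `zeroTolerance` (default $10^{-9}$, the solver
noise floor) defines which fluxes count as zero for the display filters.

## The bipartite flux graph

Nodes are metabolites and reactions; each participation of a metabolite in a
reaction is one directed edge. Direction follows *net* flux: a reversible
reaction carrying negative flux has its reactant/product roles swapped before
the `consumed-by` / `produced-by` role is assigned, and its weight uses
$|v|$. A zero-flux reversible reaction keeps its declared direction — there is
no flux evidence to overrule the model author.

Edge weight is the product of the selected factors — $|v|$, the
stoichiometric coefficient, and the metabolite molecular weight — with weight
exactly 1 when no factor is selected. A metabolite without a computable weight
contributes a factor of 1 rather than dropping the edge. Molecular weights are
computed from the model's own Hill-notation formulas with a standard
atomic-weight table; formulas with polymeric groups (`R`, `X`, `*`,
parentheses) are treated as not computable. Computing weights from formulas
keeps the package fully offline; it can disagree with database-pooled values
for protonation variants, which is accepted.

Filters: `excludeZeroFlux` drops reactions with $|v| \le$ `zeroTolerance`;
`excludeCofactors` drops metabolite nodes tagged by the cofactor list;
`mergeCompartments` merges metabolites sharing a base id (trailing
`_<compartment>` or `[<compartment>]` suffix removed, plus a leading `M_`
species prefix — the BiGG conventions) and unions their edges; reactions are
never merged. Nodes left without edges are pruned, matching what a drawing
should show. Both filters can only shrink the graph, which the tests assert.

The default cofactor list (ATP/ADP/AMP, NAD(P)(H), FAD(H2), CoA, water,
protons, CO2, O2, ammonium, phosphates, sulfate, quinones, glutathione) is a
plain-text file under `inst/extdata/` and is overridable per call, per CLI
flag, or via the YAML config — the "right" currency-metabolite set is
organism- and question-dependent, so it is data, not code.

## Greedy spanning tree and the ordering of ties

The spanning tree starts at the root (by default the objective reaction) and
repeatedly attaches, over all edges joining a tree node to a new node, the
best candidate under the ordering

1. higher edge weight,
2. smaller prospective depth (tree-endpoint depth + 1),
3. flux direction toward the root (producers before consumers),
4. alphabetical new-node id, 5. alphabetical tree-endpoint id
   (and, for parallel edges after compartment merging, input order).

Two remarks on this ordering, which was the one genuinely open design point.
First, "shortest path to the root" is evaluated *online* as the prospective
depth of the new node — the tree is still under construction when ties occur,
so a global graph distance would be ill-defined at that moment. Second, the
producers-first rule sits *below* weight and depth. Placing it above weight
would attach an arbitrarily weak producing edge before an arbitrarily strong
consuming one and, at unit weights, would let long producer chains insert
nodes far deeper than their graph distance to the root. With the ordering
above, the unit-weight tree is exactly an alphabetically sorted breadth-first
search with producers-first precedence within each level, and node depth
equals the edge-count distance from the root — a property the test suite
verifies against an independent queue-based BFS on every generated graph, and
the full greedy result against a brute-force oracle that rescans the entire
frontier at every step.

The complete tree reuses the same frontier ordering but never discards an
edge: an edge reaching an already-placed node adds a duplicate *leaf* instance
of that node (duplicates do not expand). Every edge of the root's component is
placed exactly once, so instances = unique nodes + (edges − spanning edges).

## k-shortest loopless paths

Path costs are per edge: $1/w$ under the weighted metric (so high-flux edges
are cheap and zero-weight edges are impassable at cost $\infty$), or $1$ per
edge unweighted. The inverse transform is a design choice — it is monotone,
maps "highest flux" to "shortest", and unlike $-\log w$ stays positive for
$w > 1$ as well as $w < 1$, which a Dijkstra-based search requires.

The search keeps a found-set initialized with the Dijkstra shortest path
(ties in the priority queue broken by lexicographic node id), then removes
every edge of every found path one at a time — paths in discovery order,
edges in path order — re-running the search on each reduced graph and adding
any new distinct path (distinctness by node sequence). `first_k` stops as soon
as $k$ paths are known and is a heuristic: it can return paths out of true
rank order. `best_k` exhausts all removals reachable through the growing
found-set and returns the $k$ cheapest, which is optimal *for this removal
scheme*. The scheme is simpler than the classic spur-node formulation of
Yen's algorithm and can miss paths that only appear after removing two or
more edges; the tests therefore compare against exhaustive depth-first
enumeration on small graphs and assert that reported costs are never *below*
the true $i$-th shortest, with exact equality on the toy family, rather than
pretending the scheme is complete.

## Layouts

* **Tidy tree**: depth on the horizontal axis, root at maximum $x$, leaves
  left. Leaves get consecutive breadth positions in insertion order; every
  parent sits at the midpoint of its children's extent. Because descendant
  leaf intervals of same-depth nodes are disjoint, same-depth nodes are always
  at least one breadth unit apart.
* **Dendrogram**: all leaves share $x = 0$ and are equally spaced; an internal
  node sits at $x$ equal to its height (edges to its deepest descendant), so
  the root is rightmost.
* **Radial**: $(\text{depth}, \text{breadth}) \mapsto (r, \theta)$ with
  $r = \text{depth} \cdot \text{step}$ and $\theta$ the breadth normalized to
  $[0, 2\pi)$ over span + 1 units, which keeps the first and last branch from
  overlapping; the root lands at the origin.
* **Layered**: longest-path layering from the sources (cycles are an error
  naming an offending node — path unions are DAGs in practice), then eight
  alternating barycenter sweeps; the best ordering seen is kept, so the final
  crossing count never exceeds the initial one. Crossings are counted between
  edges sharing a layer pair.
* **Force**: velocity Verlet integration with inverse-square pairwise
  repulsion (constant 30), springs on edges (stiffness 0.05 toward rest
  length 30), a weak centering pull (0.005) and velocity decay 0.9 per step,
  `dt = 0.5`, 300 steps by default from seeded uniform starting positions.
  The constants are fixed defaults chosen so that a single edge settles
  within a few percent of the rest length (the closed-form equilibrium
  balances spring, centering and repulsion terms) and the integration is
  comfortably inside the Verlet stability region; with decay < 1 the kinetic
  energy decays geometrically near equilibrium. Disconnected components repel
  each other and separate into clusters — asserted as centroid separation
  exceeding intra-component spread, deliberately not as any specific picture.

All drawing is deterministic: a fixed seed fixes the force layout, every other
layout is seed-free, and SVG/GraphML/JSON/DOT writers format numbers at full
precision (`%.17g`), so identical inputs give byte-identical files. GraphML
exports re-import exactly.

## Synthetic models: what they do and do not show

`makeToyGEM()` provides the two fixed fixtures. `TOY6` has a hand-solvable
unique optimum (objective 5, uptake saturated at 10, both branches at 5), an
ATP/ADP cofactor pair whose exclusion isolates a reaction, and a branch point
that forces exactly one duplicate in the complete tree. `TOY6Z` adds a
dead-end uptake whose flux is forced to zero by mass balance, exercising the
zero-flux filter without any tuning.

`makeRandomGEM(nPathways, pathwayLength, nExtraEdges, seed)` builds parallel
uptake-to-biomass chains — guaranteeing feasibility and a nonzero optimum
equal to the smallest uptake bound when no extras reroute flux — and sprinkles
random conversion reactions, about a third of them reversible, between random
metabolites. Uptake bounds are uniform on 1–10 mmol gDW$^{-1}$ h$^{-1}$ and
internal bounds 0/±1000, the conventional COBRA defaults. The generator is a
pure function of its arguments and never touches the caller's RNG stream.

These models emulate the *structural* features the algorithms depend on —
branching, reversibility, cofactor pairs, dead ends, degenerate alternate
optima — at sizes of roughly 5–30 graph nodes (the unit suites), 200 graphs
for the tree-oracle sweep and 100 models for the knockout sweep. They do not
emulate real GEM scale (thousands of reactions), realistic stoichiometric
coefficients, compartmentalized organelle structure, or biologically
meaningful cofactor wiring. Passing tests therefore demonstrate algorithmic
correctness and determinism, not biological validity of any particular
layout or pathway on a real reconstruction; the parsers and the pipeline
accept real BiGG-style SBML, but no downloaded model is part of the test
conditions.

## Known limitations

* FBA only: no flux variability analysis, parsimonious FBA, MOMA or growth
  medium editing; the objective is always maximized.
* The k-shortest scheme is the single-edge-removal variant described above;
  completeness beyond what it generates is not claimed.
* Gene–protein–reaction rules are stored verbatim, never evaluated.
* `first_k` is explicitly heuristic; use `best_k` when optimality matters.
* SBML Layout Extension information is ignored; layouts are always
  recomputed.
* Raster image export is out of scope; SVG covers vector output, and the
  GraphML/JSON/DOT exporters feed external tools.
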