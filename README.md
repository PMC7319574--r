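# fluxgraph

Genome-scale metabolic models (GEMs) describe every known reaction of an
organism as a stoichiometric network with flux bounds and a biomass objective.
Flux balance analysis (FBA) predicts a steady-state flux distribution by
solving the linear program

```
max  c'v    subject to    S v = 0,   lb <= v <= ub
```

where `S` is the stoichiometric matrix (metabolites x reactions), `v` the flux
vector and `c` the objective coefficients. The resulting networks hold
thousands of reactions, and extracting the pathways that matter from them is a
visualization and graph-analysis problem as much as an optimization one.

`fluxgraph` is a headless R toolkit for exactly that step. It is aimed at
systems biologists and metabolic engineers who want, from any SBML model and
without a web service:

* **FBA with knockouts** — a deterministic LP solve of the model (any number
  of reactions forced to zero flux to simulate gene deletions), giving the
  growth rate and the flux of every reaction.
* **Flux-weighted bipartite graphs** — metabolites and reactions as two node
  kinds, one edge per participation, edge direction following the *net* flux
  (reversible reactions running backward are flipped), and edge weights from
  any combination of |flux|, stoichiometric coefficient and metabolite
  molecular weight. Zero-flux reactions, cofactors/currency metabolites (ATP,
  NAD(H), water, protons, ...) and compartment duplicates can be filtered or
  merged.
* **Greedy flux spanning tree** — rooted at the biomass reaction (or any
  node), grown by repeatedly attaching the frontier edge with the highest
  weight, ties broken by shortest path to the root, then producers-first, then
  alphabetically. With unit weights this is exactly an alphabetically sorted
  breadth-first search, so the tree shows the shortest route from every
  metabolite to the root; with flux weights the highest-flux pathways attach
  first.
* **Complete (duplicated) tree** — the same breadth-first traversal, but every
  graph edge is drawn exactly once: an edge reaching an already-placed node
  creates a duplicate leaf instance.
* **k-shortest loopless paths** — between any two nodes, by iterative
  single-edge removal around Dijkstra searches; edge cost is `1/weight`
  (high-flux edges are cheap, zero-flux edges impassable) or `1` per edge.
  `best_k` mode exhausts all removals and is guaranteed optimal for the
  scheme; `first_k` stops early.
* **Five layouts and exporters** — tidy tree, dendrogram, radial variants,
  layered (barycenter crossing minimization) and a velocity-Verlet force
  simulation; SVG rendering plus GraphML / node-link JSON / DOT export, all
  byte-deterministic for fixed seeds.

SBML Level 3 + fbc v2 is read natively; legacy COBRA-dialect Level 2 files
(kinetic-law bounds, notes-based formulas) and gzip compression are handled
transparently.

## Worked example

`makeToyGEM("TOY6")` builds a six-reaction model with a unique optimum: uptake
`UPT` (bound 10) feeds `A -> B`, which splits into two branches making `C`
(ATP-coupled) and `D`; biomass `BIO` consumes one of each, and `REG`
regenerates the ATP/ADP pair.

```r
library(fluxgraph)

gem <- makeToyGEM("TOY6")
fs  <- optimizeFlux(gem)
fs
#> FluxState: status optimal, objective 5
#> 6 reactions, 6 carrying flux
round(fluxes(fs), 3)
#> UPT  R1  R2  R3 REG BIO
#>  10  10   5   5   5   5
```

The growth objective is 5: the uptake saturates at 10 and each branch carries
half. Knocking out either branch kills growth entirely, because biomass needs
both `C` and `D`:

```r
objectiveValue(optimizeFlux(gem, knockouts = "R3"))
#> [1] 0
```

Build the flux graph without the cofactor pair, take the spanning tree rooted
at the biomass reaction, and list the k-shortest paths from `A`:

```r
g <- buildFluxGraph(gem, fs, excludeCofactors = TRUE)
g
#> FluxGraph: 9 nodes (4 metabolites, 5 reactions), 9 edges

tree <- spanningTree(g, "BIO")
tree@insertionOrder
#> [1] "BIO" "C"   "D"   "R2"  "R3"  "B"   "R1"  "A"   "UPT"

kShortestPaths(g, "A", "BIO", k = 3, weighted = FALSE)
#> PathSet A -> BIO (best_k, unweighted): 2 of 3 requested paths
#>   [1] cost 5: A -> R1 -> B -> R2 -> C -> BIO
#>   [2] cost 5: A -> R1 -> B -> R3 -> D -> BIO
```

The tree's insertion order is the greedy certificate: both producers of the
root (`C`, then `D` alphabetically) attach before anything deeper. Rendering
and export:

```r
renderSVG(tree, tidyLayout(tree), renderStyle(), file = "toy6-tree.svg")
exportGraph(g, "graphml", file = "toy6.graphml")
writeSBML(gem, "toy6.xml")
```

A command-line wrapper covers the same pipeline
(`inst/cli/fluxgraph`):

```sh
fluxgraph fba toy6.xml
fluxgraph tree toy6.xml --root BIO --exclude-cofactors --svg tree.svg
fluxgraph paths toy6.xml --from A --to BIO -k 2 --exclude-cofactors
```

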