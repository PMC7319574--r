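# programmatic fixtures shared across test files

# a random flux graph from the full pipeline (model -> FBA -> graph), with
# seed-determined weight options; node count stays small (<= ~30)
randomFluxGraph <- function(seed, unitWeights = FALSE) {
  gem <- makeRandomGEM(nPathways = 1 + seed %% 3,
                       pathwayLength = 2 + seed %% 3,
                       nExtraEdges = seed %% 6, seed = seed)
  fs <- optimizeFlux(gem)
  stopifnot(solverStatus(fs) == "optimal")
  opts <- if (unitWeights) weightOptions() else
    weightOptions(flux = seed %% 2 == 0, stoichiometry = TRUE,
                  molecularWeight = seed %% 3 == 0)
  buildFluxGraph(gem, fs, opts)
}

# hand-built bipartite FluxGraph from an explicit edge list
syntheticGraph <- function(edges) {
  mets <- unique(edges$metabolite)
  rxns <- unique(edges$reaction)
  nodes <- rbind(
    data.frame(id = mets, kind = "metabolite", label = mets,
               compartment = "c", flux = NA_real_, stringsAsFactors = FALSE),
    data.frame(id = rxns, kind = "reaction", label = rxns,
               compartment = NA_character_, flux = 1,
               stringsAsFactors = FALSE))
  edges$from <- ifelse(edges$role == "consumed-by", edges$metabolite,
                       edges$reaction)
  edges$to <- ifelse(edges$role == "consumed-by", edges$reaction,
                     edges$metabolite)
  new("FluxGraph", nodes = nodes, edges = edges, options = list())
}

# random bipartite DAG (edges always from earlier to later topological slot)
randomBipartiteDAG <- function(seed, nMet = 5, nRxn = 5, nEdge = 12) {
  set.seed(seed)
  mets <- sprintf("m%02d", seq_len(nMet))
  rxns <- sprintf("r%02d", seq_len(nRxn))
  slot <- stats::setNames(sample(seq_len(nMet + nRxn)), c(mets, rxns))
  rows <- list()
  for (k in seq_len(nEdge)) {
    m <- sample(mets, 1); r <- sample(rxns, 1)
    role <- if (slot[m] < slot[r]) "consumed-by" else "produced-by"
    rows[[k]] <- data.frame(metabolite = m, reaction = r, role = role,
                            stoich = 1, weight = stats::runif(1, 0.5, 2),
                            stringsAsFactors = FALSE)
  }
  ed <- unique(do.call(rbind, rows))
  syntheticGraph(ed)
}

# two disconnected complete bipartite blocks ("cliques") in one graph
twoCliqueGraph <- function() {
  rows <- list()
  for (blk in c("a", "b"))
    for (m in 1:3) for (r in 1:3)
      rows[[length(rows) + 1]] <- data.frame(
        metabolite = sprintf("%sm%d", blk, m),
        reaction = sprintf("%sr%d", blk, r),
        role = if ((m + r) %% 2 == 0) "consumed-by" else "produced-by",
        stoich = 1, weight = 1, stringsAsFactors = FALSE)
  syntheticGraph(do.call(rbind, rows))
}

emptyFluxGraph <- function() {
  new("FluxGraph",
      nodes = data.frame(id = character(), kind = character(),
                         label = character(), compartment = character(),
                         flux = numeric(), stringsAsFactors = FALSE),
      edges = data.frame(metabolite = character(), reaction = character(),
                         role = character(), stoich = numeric(),
                         weight = numeric(), from = character(),
                         to = character(), stringsAsFactors = FALSE),
      options = list())
}

# legacy COBRA-dialect SBML Level 2 document (bounds and objective in
# kinetic-law parameters, formula/charge/GPR in notes)
legacySBML <- function() {
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="legacy_toy">
    <listOfCompartments>
      <compartment id="c" name="cytosol"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_glc_c" name="glucose" compartment="c" boundaryCondition="false">
        <notes><body xmlns="http://www.w3.org/1999/xhtml">
          <p>FORMULA: C6H12O6</p><p>CHARGE: 0</p>
        </body></notes>
      </species>
      <species id="M_pyr_c" name="pyruvate" compartment="c" boundaryCondition="false">
        <notes><body xmlns="http://www.w3.org/1999/xhtml">
          <p>FORMULA: C3H3O3</p><p>CHARGE: -1</p>
        </body></notes>
      </species>
      <species id="M_glc_b" name="glucose boundary" compartment="c" boundaryCondition="true"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R_GLCup" name="glucose uptake" reversible="false">
        <listOfReactants>
          <speciesReference species="M_glc_b" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_glc_c" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="8"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R_GLYC" name="glycolysis lump" reversible="true">
        <notes><body xmlns="http://www.w3.org/1999/xhtml">
          <p>GENE_ASSOCIATION: (g1 and g2) or g3</p>
        </body></notes>
        <listOfReactants>
          <speciesReference species="M_glc_c" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_pyr_c" stoichiometry="2"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="-1000"/>
            <parameter id="UPPER_BOUND" value="1000"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R_BIO" name="biomass" reversible="false">
        <listOfReactants>
          <speciesReference species="M_pyr_c" stoichiometry="2"/>
        </listOfReactants>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="1"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'
}
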