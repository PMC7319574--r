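#' @import methods
NULL

#' Genome-scale metabolic model
#'
#' In-memory representation of a constraint-based metabolic model: an ordered
#' table of metabolites, an ordered table of reactions with flux bounds and
#' objective coefficients, and per-reaction stoichiometry (signed coefficients,
#' negative for reactants, positive for products). The stoichiometric matrix S
#' over non-boundary metabolites is recoverable exactly via
#' [stoichiometricMatrix()].
#'
#' @slot modelId single model identifier string.
#' @slot compartments named character vector mapping compartment id to display
#'   name.
#' @slot metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula`, `charge`, `molecularWeight`, `isCofactor`, `isBoundary`.
#' @slot reactions data.frame with columns `id`, `name`, `lowerBound`,
#'   `upperBound`, `objectiveCoefficient`, `geneAssociation`.
#' @slot stoichiometry named list (one entry per reaction id) of named numeric
#'   vectors mapping metabolite id to signed stoichiometric coefficient.
#' @slot objectiveReactionId character of length 0 (no objective declared) or 1.
#'
#' @seealso [readSBML()], [makeToyGEM()], [optimizeFlux()]
#' @exportClass GEM
setClass("GEM",
  slots = c(
    modelId = "character",
    compartments = "character",
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "list",
    objectiveReactionId = "character"
  )
)

setValidity("GEM", function(object) {
  m <- object@metabolites
  r <- object@reactions
  msgs <- character()
  needMet <- c("id", "name", "compartment", "formula", "charge",
               "molecularWeight", "isCofactor", "isBoundary")
  needRxn <- c("id", "name", "lowerBound", "upperBound",
               "objectiveCoefficient", "geneAssociation")
  if (!all(needMet %in% names(m)))
    return(paste("metabolites is missing columns:",
                 paste(setdiff(needMet, names(m)), collapse = ", ")))
  if (!all(needRxn %in% names(r)))
    return(paste("reactions is missing columns:",
                 paste(setdiff(needRxn, names(r)), collapse = ", ")))
  if (anyDuplicated(m$id) || any(!nzchar(m$id)))
    msgs <- c(msgs, "metabolite ids must be unique and non-empty")
  if (anyDuplicated(r$id) || any(!nzchar(r$id)))
    msgs <- c(msgs, "reaction ids must be unique and non-empty")
  if (any(r$lowerBound > r$upperBound))
    msgs <- c(msgs, "every reaction must have lowerBound <= upperBound")
  if (!setequal(names(object@stoichiometry), r$id) && nrow(r) > 0)
    msgs <- c(msgs, "stoichiometry must have exactly one entry per reaction id")
  badRef <- vapply(object@stoichiometry, function(s)
    any(!names(s) %in% m$id), logical(1))
  if (any(badRef))
    msgs <- c(msgs, paste("stoichiometry references unknown metabolites in:",
                          paste(names(badRef)[badRef], collapse = ", ")))
  if (length(object@objectiveReactionId) > 1)
    msgs <- c(msgs, "objectiveReactionId must have length 0 or 1")
  if (length(object@objectiveReactionId) == 1) {
    oid <- object@objectiveReactionId
    if (!oid %in% r$id)
      msgs <- c(msgs, sprintf("objective reaction '%s' is not in the model", oid))
    else if (r$objectiveCoefficient[match(oid, r$id)] == 0)
      msgs <- c(msgs, sprintf("objective reaction '%s' has zero coefficient", oid))
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of a flux-balance optimization
#'
#' @slot fluxes named numeric vector of reaction fluxes (mmol gDW^-1 h^-1);
#'   empty unless `status == "optimal"`.
#' @slot objectiveValue optimal objective value (growth rate, h^-1, for a
#'   biomass objective); `NA` unless optimal.
#' @slot status one of `"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"no_objective"`.
#' @slot knockedOut reaction ids whose bounds were forced to zero.
#' @slot zeroTolerance fluxes with absolute value at or below this are treated
#'   as zero by downstream filters.
#'
#' @exportClass FluxState
setClass("FluxState",
  slots = c(
    fluxes = "numeric",
    objectiveValue = "numeric",
    status = "character",
    knockedOut = "character",
    zeroTolerance = "numeric"
  ),
  prototype = list(objectiveValue = NA_real_, status = "no_objective",
                   knockedOut = character(), zeroTolerance = 1e-9)
)

setValidity("FluxState", function(object) {
  ok <- object@status %in% c("optimal", "infeasible", "unbounded", "no_objective")
  if (!ok) return("status must be optimal, infeasible, unbounded or no_objective")
  if (length(object@zeroTolerance) != 1 || object@zeroTolerance < 0)
    return("zeroTolerance must be a single non-negative number")
  TRUE
})

#' Edge-weight options for flux graphs
#'
#' Selects which factors enter each edge weight. The weight of an edge is the
#' product of the selected factors (absolute reaction flux, stoichiometric
#' coefficient, metabolite molecular weight); with no factor selected every
#' edge has weight exactly 1.
#'
#' @slot useFlux multiply by the absolute reaction flux.
#' @slot useStoichiometry multiply by the stoichiometric coefficient.
#' @slot useMolecularWeight multiply by the metabolite molecular weight
#'   (a metabolite without a computable weight contributes a factor of 1).
#'
#' @exportClass WeightOptions
setClass("WeightOptions",
  slots = c(useFlux = "logical", useStoichiometry = "logical",
            useMolecularWeight = "logical"),
  prototype = list(useFlux = FALSE, useStoichiometry = FALSE,
                   useMolecularWeight = FALSE)
)

#' Construct edge-weight options
#'
#' @param flux,stoichiometry,molecularWeight logical flags, see
#'   [WeightOptions-class].
#' @return a `WeightOptions` object.
#' @examples
#' weightOptions(flux = TRUE, stoichiometry = TRUE)
#' @export
weightOptions <- function(flux = FALSE, stoichiometry = FALSE,
                          molecularWeight = FALSE) {
  new("WeightOptions", useFlux = isTRUE(flux),
      useStoichiometry = isTRUE(stoichiometry),
      useMolecularWeight = isTRUE(molecularWeight))
}

#' Directed weighted bipartite flux graph
#'
#' Nodes are metabolites or reactions; each edge records the participation of
#' a metabolite in a reaction, with the role resolved by the sign of the
#' reaction flux (`consumed-by`: metabolite feeds the reaction, drawn
#' metabolite -> reaction; `produced-by`: reaction -> metabolite).
#'
#' @slot nodes data.frame with columns `id`, `kind` (`"metabolite"` or
#'   `"reaction"`), `label`, `compartment`, `flux` (`NA` for metabolites).
#' @slot edges data.frame with columns `metabolite`, `reaction`, `role`,
#'   `stoich` (positive), `weight` (non-negative), `from`, `to`.
#' @slot options list recording the weight options and filters used.
#'
#' @exportClass FluxGraph
setClass("FluxGraph",
  slots = c(nodes = "data.frame", edges = "data.frame", options = "list")
)

setValidity("FluxGraph", function(object) {
  n <- object@nodes; e <- object@edges
  if (nrow(e)) {
    km <- n$kind[match(e$metabolite, n$id)]
    kr <- n$kind[match(e$reaction, n$id)]
    if (any(is.na(km)) || any(is.na(kr)))
      return("edges reference nodes absent from the node table")
    if (any(km != "metabolite") || any(kr != "reaction"))
      return("every edge must join one metabolite node and one reaction node")
    if (any(e$weight < 0)) return("edge weights must be non-negative")
    if (any(e$stoich <= 0)) return("edge stoichiometric coefficients must be positive")
    if (!all(e$role %in% c("consumed-by", "produced-by")))
      return("edge role must be consumed-by or produced-by")
  }
  TRUE
})

#' Greedy flux-weighted spanning tree
#'
#' Rooted tree over a [FluxGraph-class], grown by repeatedly attaching the
#' frontier edge that is best under the ordering: flux toward the root first,
#' then larger weight, then smaller prospective depth, then alphabetical node
#' id. Each graph node appears at most once.
#'
#' @slot root node id of the tree root.
#' @slot nodes node table (subset of the source graph's nodes reached from the
#'   root).
#' @slot edges data.frame with one row per tree edge: `node`, `parent`,
#'   `metabolite`, `reaction`, `role`, `stoich`, `weight`, `towardRoot`.
#' @slot depth named integer vector, distance in tree edges from the root.
#' @slot insertionOrder node ids in the order they entered the tree (root
#'   first).
#'
#' @exportClass SpanningTree
setClass("SpanningTree",
  slots = c(root = "character", nodes = "data.frame", edges = "data.frame",
            depth = "integer", insertionOrder = "character")
)

setValidity("SpanningTree", function(object) {
  e <- object@edges
  n <- length(object@insertionOrder)
  if (n && object@insertionOrder[1] != object@root)
    return("insertionOrder must start at the root")
  if (nrow(e) != max(0L, n - 1L))
    return("a tree over n nodes must have n - 1 edges")
  if (nrow(e) && anyDuplicated(e$node))
    return("every non-root node must have exactly one parent")
  TRUE
})

#' Breadth-first complete tree with duplicated nodes
#'
#' Tree covering every edge of a [FluxGraph-class] exactly once: a
#' breadth-first traversal from the root in which an edge that reaches an
#' already-placed node creates a duplicate leaf instance of that node.
#'
#' @slot root node id of the root.
#' @slot instances data.frame with columns `instance`, `node`, `kind`,
#'   `label`, `isDuplicate`, `depth`.
#' @slot edges data.frame with columns `parentInstance`, `childInstance`,
#'   `metabolite`, `reaction`, `role`, `stoich`, `weight`, `towardRoot`.
#'
#' @exportClass DuplicatedTree
setClass("DuplicatedTree",
  slots = c(root = "character", instances = "data.frame", edges = "data.frame")
)

setValidity("DuplicatedTree", function(object) {
  i <- object@instances
  if (nrow(object@edges) != max(0L, nrow(i) - 1L))
    return("a duplicated tree over n instances must have n - 1 edges")
  if (nrow(i) && anyDuplicated(i$instance))
    return("instance ids must be unique")
  TRUE
})

#' A single loopless metabolic path
#'
#' @slot nodes alternating metabolite/reaction node ids from source to target.
#' @slot edges data.frame of traversed edges (`from`, `to`, `metabolite`,
#'   `reaction`, `role`, `weight`, `cost`).
#' @slot cost total path cost under the metric it was computed with.
#' @slot rank 1-based rank within its [PathSet-class].
#'
#' @exportClass Path
setClass("Path",
  slots = c(nodes = "character", edges = "data.frame", cost = "numeric",
            rank = "integer")
)

#' A set of k-shortest loopless paths
#'
#' @slot source,target node ids the paths join.
#' @slot kRequested number of paths asked for.
#' @slot mode `"first_k"` (stop as soon as k distinct paths are known) or
#'   `"best_k"` (exhaust all single-edge removals, guaranteed optimal).
#' @slot weighted whether the inverse-weight cost metric was used.
#' @slot paths list of [Path-class], sorted by nondecreasing cost.
#' @slot nodes node table (id, kind, label) for all nodes on any path, for
#'   rendering.
#'
#' @exportClass PathSet
setClass("PathSet",
  slots = c(source = "character", target = "character", kRequested = "integer",
            mode = "character", weighted = "logical", paths = "list",
            nodes = "data.frame")
)

setValidity("PathSet", function(object) {
  if (!object@mode %in% c("first_k", "best_k"))
    return("mode must be first_k or best_k")
  costs <- vapply(object@paths, function(p) p@cost, numeric(1))
  if (is.unsorted(costs)) return("paths must be sorted by nondecreasing cost")
  keys <- vapply(object@paths, function(p) paste(p@nodes, collapse = "\r"),
                 character(1))
  if (anyDuplicated(keys)) return("paths must have pairwise distinct node sequences")
  if (length(object@paths) > object@kRequested)
    return("more paths than requested")
  TRUE
})

#' 2-D coordinates for drawable node instances
#'
#' @slot coords data.frame with columns `instance`, `node`, `x`, `y`.
#' @slot layoutKind one of `"tidy"`, `"dendrogram"`, `"radial_tidy"`,
#'   `"radial_dendrogram"`, `"layered"`, `"force"`.
#' @slot bounds numeric of length 4: xmin, ymin, xmax, ymax.
#' @slot diagnostics list of layout-specific diagnostics (e.g. kinetic-energy
#'   history for the force layout, crossing counts for the layered layout).
#'
#' @exportClass LayoutResult
setClass("LayoutResult",
  slots = c(coords = "data.frame", layoutKind = "character",
            bounds = "numeric", diagnostics = "list"),
  prototype = list(diagnostics = list())
)

setValidity("LayoutResult", function(object) {
  if (nrow(object@coords)) {
    if (any(!is.finite(object@coords$x)) || any(!is.finite(object@coords$y)))
      return("all coordinates must be finite")
    b <- object@bounds
    if (length(b) != 4) return("bounds must be xmin, ymin, xmax, ymax")
    if (any(object@coords$x < b[1] - 1e-9) || any(object@coords$x > b[3] + 1e-9) ||
        any(object@coords$y < b[2] - 1e-9) || any(object@coords$y > b[4] + 1e-9))
      return("bounds must contain all coordinates")
  }
  TRUE
})

#' Rendering style for SVG output
#'
#' Defaults follow the usual bipartite convention: yellow metabolite nodes,
#' green reaction nodes, blue edges carrying flux toward the tree root and red
#' edges coming from it.
#'
#' @slot metaboliteColor,reactionColor node fill colors (CSS color strings).
#' @slot towardRootEdgeColor,fromRootEdgeColor tree edge colors.
#' @slot edgeEmphasis `"width"`, `"opacity"` or `"none"`: how edge weight is
#'   visually encoded.
#' @slot labelMode `"id"`, `"name"`, `"flux"`, `"localization"` or `"none"`.
#'
#' @exportClass RenderStyle
setClass("RenderStyle",
  slots = c(metaboliteColor = "character", reactionColor = "character",
            towardRootEdgeColor = "character", fromRootEdgeColor = "character",
            edgeEmphasis = "character", labelMode = "character"),
  prototype = list(metaboliteColor = "yellow", reactionColor = "green",
                   towardRootEdgeColor = "blue", fromRootEdgeColor = "red",
                   edgeEmphasis = "width", labelMode = "id")
)

setValidity("RenderStyle", function(object) {
  if (!object@edgeEmphasis %in% c("width", "opacity", "none"))
    return("edgeEmphasis must be width, opacity or none")
  if (!object@labelMode %in% c("id", "name", "flux", "localization", "none"))
    return("labelMode must be id, name, flux, localization or none")
  TRUE
})

#' Construct a rendering style
#'
#' @param metaboliteColor,reactionColor,towardRootEdgeColor,fromRootEdgeColor
#'   CSS color strings.
#' @param edgeEmphasis how edge weight is encoded: `"width"`, `"opacity"` or
#'   `"none"`.
#' @param labelMode node label content.
#' @return a `RenderStyle` object.
#' @export
renderStyle <- function(metaboliteColor = "yellow", reactionColor = "green",
                        towardRootEdgeColor = "blue", fromRootEdgeColor = "red",
                        edgeEmphasis = "width", labelMode = "id") {
  new("RenderStyle", metaboliteColor = metaboliteColor,
      reactionColor = reactionColor,
      towardRootEdgeColor = towardRootEdgeColor,
      fromRootEdgeColor = fromRootEdgeColor,
      edgeEmphasis = edgeEmphasis, labelMode = labelMode)
}
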