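#' Construct a GEM from component tables
#'
#' Low-level constructor used by [readSBML()] and the fixture generators.
#' Molecular weights are computed from each metabolite's formula with
#' [molecularWeight()].
#'
#' @param modelId model identifier.
#' @param compartments named character vector, compartment id -> display name.
#' @param metabolites data.frame with at least `id`; missing columns are
#'   filled with defaults (`name = id`, `formula = NA`, `charge = NA`,
#'   `isBoundary = FALSE`).
#' @param reactions data.frame with at least `id`; missing columns filled
#'   (`lowerBound = 0`, `upperBound = 1000`, `objectiveCoefficient = 0`).
#' @param stoichiometry named list of named numeric vectors (reaction id ->
#'   (metabolite id -> signed coefficient)).
#' @return a validated [GEM-class].
#' @export
GEM <- function(modelId = "model", compartments = character(),
                metabolites = data.frame(id = character()),
                reactions = data.frame(id = character()),
                stoichiometry = list()) {
  m <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  r <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(m$name)) m$name <- m$id
  if (is.null(m$compartment)) m$compartment <- rep(NA_character_, nrow(m))
  if (is.null(m$formula)) m$formula <- rep(NA_character_, nrow(m))
  if (is.null(m$charge)) m$charge <- rep(NA_integer_, nrow(m))
  m$molecularWeight <- molecularWeight(m$formula)
  if (is.null(m$isCofactor)) m$isCofactor <- rep(FALSE, nrow(m))
  if (is.null(m$isBoundary)) m$isBoundary <- rep(FALSE, nrow(m))
  if (is.null(r$name)) r$name <- r$id
  if (is.null(r$lowerBound)) r$lowerBound <- rep(0, nrow(r))
  if (is.null(r$upperBound)) r$upperBound <- rep(1000, nrow(r))
  if (is.null(r$objectiveCoefficient)) r$objectiveCoefficient <- rep(0, nrow(r))
  if (is.null(r$geneAssociation)) r$geneAssociation <- rep(NA_character_, nrow(r))
  m <- m[, c("id", "name", "compartment", "formula", "charge",
             "molecularWeight", "isCofactor", "isBoundary")]
  r <- r[, c("id", "name", "lowerBound", "upperBound",
             "objectiveCoefficient", "geneAssociation")]
  rownames(m) <- NULL; rownames(r) <- NULL
  stoichiometry <- stoichiometry[r$id]
  oid <- r$id[r$objectiveCoefficient != 0]
  new("GEM", modelId = modelId, compartments = compartments,
      metabolites = m, reactions = r, stoichiometry = stoichiometry,
      objectiveReactionId = if (length(oid) >= 1) oid[1] else character())
}

#' @rdname accessors
#' @export
setMethod("metabolites", "GEM", function(x) x@metabolites)

#' @rdname accessors
#' @export
setMethod("reactions", "GEM", function(x) x@reactions)

#' @rdname accessors
#' @export
setMethod("stoichiometry", "GEM", function(x) x@stoichiometry)

#' @rdname accessors
#' @export
setMethod("compartments", "GEM", function(x) x@compartments)

#' @rdname accessors
#' @export
setMethod("modelId", "GEM", function(x) x@modelId)

#' @rdname accessors
#' @export
setMethod("objectiveReaction", "GEM", function(x) x@objectiveReactionId)

#' @rdname accessors
#' @export
setMethod("fluxes", "FluxState", function(x) x@fluxes)

#' @rdname accessors
#' @export
setMethod("objectiveValue", "FluxState", function(x) x@objectiveValue)

#' @rdname accessors
#' @export
setMethod("solverStatus", "FluxState", function(x) x@status)

#' @rdname accessors
#' @export
setMethod("graphNodes", "FluxGraph", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("graphEdges", "FluxGraph", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("graphNodes", "SpanningTree", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("graphEdges", "SpanningTree", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("graphNodes", "DuplicatedTree", function(x) x@instances)

#' @rdname accessors
#' @export
setMethod("graphEdges", "DuplicatedTree", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("pathList", "PathSet", function(x) x@paths)

#' @rdname accessors
#' @export
setMethod("coordinates", "LayoutResult", function(x) x@coords)

#' Stoichiometric matrix of a model
#'
#' Builds the matrix S whose rows are metabolites and columns reactions, with
#' S[m, r] the signed coefficient of metabolite m in reaction r. By default
#' boundary metabolites are excluded, matching the mass-balance rows of the
#' flux-balance problem S v = 0.
#'
#' @param gem a [GEM-class].
#' @param includeBoundary keep boundary-condition metabolites as rows.
#' @return a dense numeric matrix with dimnames.
#' @export
stoichiometricMatrix <- function(gem, includeBoundary = FALSE) {
  m <- gem@metabolites
  if (!includeBoundary) m <- m[!m$isBoundary, , drop = FALSE]
  r <- gem@reactions
  S <- matrix(0, nrow(m), nrow(r), dimnames = list(m$id, r$id))
  for (j in seq_len(nrow(r))) {
    s <- gem@stoichiometry[[r$id[j]]]
    s <- s[names(s) %in% m$id]
    if (length(s)) S[names(s), j] <- s
  }
  S
}

setMethod("show", "GEM", function(object) {
  cat(sprintf("GEM '%s': %d metabolites, %d reactions, %d compartments\n",
              object@modelId, nrow(object@metabolites),
              nrow(object@reactions), length(object@compartments)))
  if (length(object@objectiveReactionId))
    cat("objective:", object@objectiveReactionId, "\n")
  else cat("objective: <none>\n")
  nc <- sum(object@metabolites$isCofactor)
  if (nc) cat("cofactors tagged:", nc, "\n")
})

setMethod("show", "FluxState", function(object) {
  cat(sprintf("FluxState: status %s", object@status))
  if (object@status == "optimal")
    cat(sprintf(", objective %.6g", object@objectiveValue))
  cat("\n")
  if (length(object@knockedOut))
    cat("knocked out:", paste(object@knockedOut, collapse = ", "), "\n")
  if (length(object@fluxes)) {
    nz <- sum(abs(object@fluxes) > object@zeroTolerance)
    cat(sprintf("%d reactions, %d carrying flux\n", length(object@fluxes), nz))
  }
})

setMethod("show", "FluxGraph", function(object) {
  k <- table(factor(object@nodes$kind, c("metabolite", "reaction")))
  cat(sprintf("FluxGraph: %d nodes (%d metabolites, %d reactions), %d edges\n",
              nrow(object@nodes), k[["metabolite"]], k[["reaction"]],
              nrow(object@edges)))
})

setMethod("show", "SpanningTree", function(object) {
  cat(sprintf("SpanningTree rooted at '%s': %d nodes, %d edges, max depth %d\n",
              object@root, length(object@insertionOrder), nrow(object@edges),
              if (length(object@depth)) max(object@depth) else 0L))
})

setMethod("show", "DuplicatedTree", function(object) {
  cat(sprintf(
    "DuplicatedTree rooted at '%s': %d instances (%d duplicates), %d edges\n",
    object@root, nrow(object@instances), sum(object@instances$isDuplicate),
    nrow(object@edges)))
})

setMethod("show", "PathSet", function(object) {
  cat(sprintf("PathSet %s -> %s (%s, %s): %d of %d requested paths\n",
              object@source, object@target, object@mode,
              if (object@weighted) "weighted" else "unweighted",
              length(object@paths), object@kRequested))
  for (p in object@paths)
    cat(sprintf("  [%d] cost %.6g: %s\n", p@rank, p@cost,
                paste(p@nodes, collapse = " -> ")))
})

setMethod("show", "LayoutResult", function(object) {
  cat(sprintf("LayoutResult (%s): %d instances, bounds [%.3g, %.3g] x [%.3g, %.3g]\n",
              object@layoutKind, nrow(object@coords), object@bounds[1],
              object@bounds[3], object@bounds[2], object@bounds[4]))
})
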