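#' Accessors for model and graph objects
#'
#' @param x a [GEM-class], [FluxGraph-class] or related object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))

#' @rdname accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname accessors
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' @rdname accessors
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))

#' @rdname accessors
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))

#' @rdname accessors
#' @export
setGeneric("objectiveReaction", function(x) standardGeneric("objectiveReaction"))

#' @rdname accessors
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname accessors
#' @export
setGeneric("solverStatus", function(x) standardGeneric("solverStatus"))

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setGeneric("pathList", function(x) standardGeneric("pathList"))

#' @rdname accessors
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))

#' Render a graph, tree or path set to SVG
#'
#' @param x a [FluxGraph-class], [SpanningTree-class], [DuplicatedTree-class]
#'   or [PathSet-class].
#' @param layout a [LayoutResult-class] covering every drawable instance of
#'   `x`.
#' @param style a [RenderStyle-class].
#' @param file optional output path; when given the document is written there.
#' @return the SVG document as a single character string, invisibly when
#'   `file` is given.
#' @export
setGeneric("renderSVG", function(x, layout, style = renderStyle(), file = NULL)
  standardGeneric("renderSVG"))

#' Export a graph or tree to a standard graph-exchange format
#'
#' @param x a [FluxGraph-class], [SpanningTree-class] or
#'   [DuplicatedTree-class].
#' @param format `"graphml"`, `"json"` (node-link) or `"dot"`.
#' @param file optional output path.
#' @return the document as a character string, invisibly when `file` is given.
#' @export
setGeneric("exportGraph", function(x, format = c("graphml", "json", "dot"),
                                   file = NULL)
  standardGeneric("exportGraph"))
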