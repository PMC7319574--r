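#' Weight of a metabolite-reaction edge
#'
#' The weight is the product of the selected factors: absolute reaction flux,
#' stoichiometric coefficient, and metabolite molecular weight (a missing
#' molecular weight contributes a factor of 1). With no factor selected every
#' edge weighs exactly 1.
#'
#' @param flux signed reaction flux; its absolute value is used (the sign is
#'   consumed by the edge role).
#' @param stoich positive stoichiometric coefficient.
#' @param mw metabolite molecular weight in g/mol, or `NA`.
#' @param opts a [WeightOptions-class].
#' @return a non-negative scalar (vectorized over its numeric arguments).
#' @examples
#' edgeWeight(5, 2, NA, weightOptions(flux = TRUE, stoichiometry = TRUE))  # 10
#' edgeWeight(5, 2, NA, weightOptions())                                   # 1
#' @export
edgeWeight <- function(flux, stoich, mw, opts = weightOptions()) {
  w <- rep(1, max(length(flux), length(stoich), length(mw)))
  if (opts@useFlux) w <- w * abs(flux)
  if (opts@useStoichiometry) w <- w * stoich
  if (opts@useMolecularWeight) w <- w * ifelse(is.na(mw), 1, mw)
  w
}

#' Build the weighted bipartite flux graph of a model
#'
#' One node per reaction and per (optionally compartment-merged) metabolite;
#' one directed edge per metabolite-reaction participation. For a reaction
#' carrying negative flux the declared reactant/product roles are swapped
#' before role assignment, so edge directions follow net flux; a zero-flux
#' reversible reaction keeps its declared direction. Edge weights come from
#' [edgeWeight()]. Nodes left without any edge after filtering are pruned.
#'
#' @param gem a [GEM-class].
#' @param flux a [FluxState-class] covering every reaction, or `NULL` (then
#'   flux-dependent options are unavailable).
#' @param opts a [WeightOptions-class]; default: flux x stoichiometry when a
#'   flux state is supplied, unit weights otherwise.
#' @param excludeZeroFlux drop reactions whose absolute flux is at or below
#'   `flux@zeroTolerance`.
#' @param excludeCofactors drop metabolite nodes tagged by [tagCofactors()]
#'   together with their edges.
#' @param mergeCompartments collapse metabolites sharing a base id (see
#'   [metaboliteBaseId()]) into a single node, unioning their edges; reaction
#'   nodes are never merged.
#' @return a [FluxGraph-class].
#' @examples
#' gem <- makeToyGEM("TOY6")
#' g <- buildFluxGraph(gem, optimizeFlux(gem))
#' nrow(graphNodes(g)); nrow(graphEdges(g))  # 12 nodes, 13 edges
#' @export
buildFluxGraph <- function(gem, flux = NULL, opts = NULL,
                           excludeZeroFlux = FALSE, excludeCofactors = FALSE,
                           mergeCompartments = FALSE) {
  if (is.null(opts))
    opts <- if (is.null(flux)) weightOptions()
            else weightOptions(flux = TRUE, stoichiometry = TRUE)
  if (is.null(flux)) {
    if (opts@useFlux)
      stopf("weight option 'flux' requires a FluxState; run optimizeFlux() first")
    if (excludeZeroFlux)
      stopf("excludeZeroFlux requires a FluxState; run optimizeFlux() first")
  } else {
    missing <- setdiff(gem@reactions$id, names(flux@fluxes))
    if (length(missing))
      stopf("flux state does not cover reaction(s): %s",
            paste(missing, collapse = ", "))
  }

  m <- gem@metabolites
  r <- gem@reactions
  v <- if (is.null(flux)) stats::setNames(rep(0, nrow(r)), r$id)
       else flux@fluxes[r$id]
  ztol <- if (is.null(flux)) 0 else flux@zeroTolerance
  if (excludeZeroFlux) r <- r[abs(v[r$id]) > ztol, , drop = FALSE]

  metNode <- stats::setNames(m$id, m$id)
  if (mergeCompartments)
    metNode <- stats::setNames(
      metaboliteBaseId(m$id, names(gem@compartments)), m$id)

  edges <- vector("list", nrow(r))
  for (j in seq_len(nrow(r))) {
    rid <- r$id[j]
    s <- gem@stoichiometry[[rid]]
    if (!length(s)) next
    coef <- if (v[[rid]] < -ztol) -s else s  # negative flux swaps roles
    mw <- m$molecularWeight[match(names(s), m$id)]
    edges[[j]] <- data.frame(
      metabolite = unname(metNode[names(s)]),
      reaction = rid,
      role = ifelse(coef < 0, "consumed-by", "produced-by"),
      stoich = abs(unname(s)),
      weight = edgeWeight(v[[rid]], abs(unname(s)), mw, opts),
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges))
    edges <- data.frame(metabolite = character(), reaction = character(),
                        role = character(), stoich = numeric(),
                        weight = numeric(), stringsAsFactors = FALSE)

  if (excludeCofactors) {
    cof <- m$id[m$isCofactor]
    cofNodes <- unique(metNode[cof])
    edges <- edges[!edges$metabolite %in% cofNodes, , drop = FALSE]
  }

  # node tables; metabolite nodes possibly merged across compartments
  mk <- data.frame(id = unname(metNode), orig = m$id, stringsAsFactors = FALSE)
  metTab <- do.call(rbind, lapply(split(mk$orig, mk$id), function(origs) {
    i <- match(origs, m$id)
    data.frame(id = metNode[[origs[1]]],
               kind = "metabolite",
               label = m$name[i[1]],
               compartment = if (length(unique(m$compartment[i])) == 1)
                 m$compartment[i[1]] else NA_character_,
               flux = NA_real_, stringsAsFactors = FALSE)
  }))
  rxnTab <- data.frame(id = r$id, kind = "reaction", label = r$name,
                       compartment = NA_character_,
                       flux = unname(v[r$id]), stringsAsFactors = FALSE)
  nodes <- rbind(metTab, rxnTab)
  rownames(nodes) <- NULL
  if (excludeCofactors)
    nodes <- nodes[!(nodes$kind == "metabolite" &
                       nodes$id %in% unique(metNode[m$id[m$isCofactor]])), ,
                   drop = FALSE]

  # prune isolated nodes
  used <- unique(c(edges$metabolite, edges$reaction))
  nodes <- nodes[nodes$id %in% used, , drop = FALSE]
  nodes <- nodes[orderBy(match(nodes$id, c(mk$id, r$id))), , drop = FALSE]
  rownames(nodes) <- NULL

  # direction of each edge after flux-sign resolution
  edges$from <- ifelse(edges$role == "consumed-by", edges$metabolite,
                       edges$reaction)
  edges$to <- ifelse(edges$role == "consumed-by", edges$reaction,
                     edges$metabolite)
  rownames(edges) <- NULL

  new("FluxGraph", nodes = nodes, edges = edges,
      options = list(weights = opts, excludeZeroFlux = excludeZeroFlux,
                     excludeCofactors = excludeCofactors,
                     mergeCompartments = mergeCompartments))
}
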