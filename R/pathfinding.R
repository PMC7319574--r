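#' Cost of traversing an edge
#'
#' Under the weighted metric the cost is the reciprocal of the edge weight, so
#' high-flux edges are cheap and a zero-weight edge is impassable (cost
#' `Inf`). Under the unweighted metric every edge costs 1 and the path cost
#' counts graph edges (two per traversed reaction).
#'
#' @param weight non-negative edge weight(s) from a [FluxGraph-class].
#' @param weighted use the inverse-weight metric (`TRUE`) or unit costs.
#' @return positive numeric vector, possibly `Inf`.
#' @examples
#' edgeCost(5, TRUE)    # 0.2
#' edgeCost(5, FALSE)   # 1
#' edgeCost(0, TRUE)    # Inf
#' @export
edgeCost <- function(weight, weighted = TRUE) {
  if (weighted) ifelse(weight > 0, 1 / weight, Inf) else rep(1, length(weight))
}

# Dijkstra over the directed edge list, with deterministic tie-breaking: the
# settled node is the unsettled node with minimal distance, ties broken by
# lexicographic node id; predecessors update on strict improvement only.
# excludeEdges: edge indices removed for this solve.
.dijkstra <- function(nodes, e, cost, source, excludeEdges = integer()) {
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  outAdj <- stats::setNames(vector("list", n), nodes)
  keep <- setdiff(seq_len(nrow(e)), excludeEdges)
  keep <- keep[is.finite(cost[keep])]
  for (i in keep) outAdj[[e$from[i]]] <- c(outAdj[[e$from[i]]], i)

  dist <- rep(Inf, n); names(dist) <- nodes
  predEdge <- rep(NA_integer_, n); names(predEdge) <- nodes
  done <- rep(FALSE, n); names(done) <- nodes
  dist[source] <- 0
  sortedIds <- nodes[orderBy(nodes)]
  repeat {
    open <- !done & is.finite(dist)
    if (!any(open)) break
    d <- dist[open]
    u <- names(d)[orderBy(d, match(names(d), sortedIds))][1]
    done[u] <- TRUE
    for (i in outAdj[[u]]) {
      wv <- dist[u] + cost[i]
      v <- e$to[i]
      if (wv < dist[v]) { dist[v] <- wv; predEdge[v] <- i }
    }
  }
  list(dist = dist, predEdge = predEdge)
}

.tracePath <- function(e, cost, dres, source, target, rank = 1L) {
  if (!is.finite(dres$dist[target])) return(NULL)
  nodesSeq <- target
  edgesIdx <- integer()
  v <- target
  while (v != source) {
    i <- dres$predEdge[[v]]
    edgesIdx <- c(i, edgesIdx)
    v <- e$from[i]
    nodesSeq <- c(v, nodesSeq)
  }
  ed <- e[edgesIdx, c("from", "to", "metabolite", "reaction", "role",
                      "weight"), drop = FALSE]
  ed$cost <- cost[edgesIdx]
  ed$index <- edgesIdx
  rownames(ed) <- NULL
  new("Path", nodes = nodesSeq, edges = ed,
      cost = unname(dres$dist[target]), rank = as.integer(rank))
}

#' Shortest path between two nodes of a flux graph
#'
#' Dijkstra's algorithm over the directed bipartite graph with the
#' [edgeCost()] metric; ties in the priority queue are broken by lexicographic
#' node id, making the result deterministic.
#'
#' @param graph a [FluxGraph-class].
#' @param source,target node ids (metabolite or reaction).
#' @param weighted use inverse-weight edge costs (`TRUE`) or count edges.
#' @return a [Path-class], or `NULL` if the target is unreachable.
#' @examples
#' gem <- makeToyGEM("TOY6")
#' g <- buildFluxGraph(gem, optimizeFlux(gem), excludeCofactors = TRUE)
#' shortestPath(g, "A", "BIO", weighted = FALSE)
#' @export
shortestPath <- function(graph, source, target, weighted = TRUE) {
  nodes <- graph@nodes$id
  for (nd in c(source, target))
    if (!nd %in% nodes) stopf("node '%s' is not in the graph", nd)
  if (source == target)
    return(new("Path", nodes = source,
               edges = data.frame(from = character(), to = character(),
                                  metabolite = character(),
                                  reaction = character(), role = character(),
                                  weight = numeric(), cost = numeric(),
                                  index = integer()),
               cost = 0, rank = 1L))
  e <- graph@edges
  cost <- edgeCost(e$weight, weighted)
  dres <- .dijkstra(nodes, e, cost, source)
  .tracePath(e, cost, dres, source, target)
}

#' k-shortest loopless paths between two nodes
#'
#' Maintains a found-set initialized with the shortest path, then repeatedly
#' removes every edge of every found path, one edge at a time (paths in
#' discovery order, edges in path order), re-running the shortest-path search
#' on each reduced graph and adding any new distinct path. In `"first_k"` mode
#' the search stops as soon as `k` distinct paths are known; in `"best_k"`
#' mode all single-edge removals reachable through the growing found-set are
#' exhausted and the `k` cheapest paths are returned, which is guaranteed
#' optimal for this removal scheme at the expense of more solves. Paths found
#' by Dijkstra are simple, so every returned path is loopless.
#'
#' @param graph a [FluxGraph-class].
#' @param source,target node ids.
#' @param k maximum number of paths (>= 1).
#' @param weighted use inverse-weight edge costs; see [edgeCost()].
#' @param mode `"best_k"` (default) or `"first_k"`.
#' @return a [PathSet-class], sorted by cost then lexicographic node sequence;
#'   it holds fewer than `k` paths when the removal scheme finds fewer (an
#'   unreachable target yields an empty set).
#' @examples
#' gem <- makeToyGEM("TOY6")
#' g <- buildFluxGraph(gem, optimizeFlux(gem), excludeCofactors = TRUE)
#' kShortestPaths(g, "A", "BIO", k = 2, weighted = FALSE)
#' @export
kShortestPaths <- function(graph, source, target, k, weighted = TRUE,
                           mode = c("best_k", "first_k")) {
  mode <- match.arg(mode)
  if (!is.numeric(k) || length(k) != 1 || k < 1)
    stopf("k must be a positive integer")
  k <- as.integer(k)
  nodes <- graph@nodes$id
  for (nd in c(source, target))
    if (!nd %in% nodes) stopf("node '%s' is not in the graph", nd)
  e <- graph@edges
  cost <- edgeCost(e$weight, weighted)

  pathKey <- function(p) paste(p@nodes, collapse = "\r")
  pathEdgeIdx <- function(p) p@edges$index

  first <- shortestPath(graph, source, target, weighted)
  found <- list(); keys <- character()
  if (!is.null(first)) { found <- list(first); keys <- pathKey(first) }

  i <- 1L
  while (i <= length(found)) {
    if (mode == "first_k" && length(found) >= k) break
    for (ei in pathEdgeIdx(found[[i]])) {
      dres <- .dijkstra(nodes, e, cost, source, excludeEdges = ei)
      p <- .tracePath(e, cost, dres, source, target)
      if (!is.null(p) && !pathKey(p) %in% keys) {
        found <- c(found, list(p))
        keys <- c(keys, pathKey(p))
        if (mode == "first_k" && length(found) >= k) break
      }
    }
    i <- i + 1L
  }

  costs <- vapply(found, function(p) p@cost, numeric(1))
  seqs <- vapply(found, function(p) paste(p@nodes, collapse = "\r"),
                 character(1))
  ord <- orderBy(costs, seqs)
  found <- found[ord][seq_len(min(k, length(found)))]
  for (j in seq_along(found)) found[[j]]@rank <- j

  onPath <- unique(unlist(lapply(found, function(p) p@nodes)))
  ninfo <- graph@nodes[graph@nodes$id %in% onPath, c("id", "kind", "label")]
  rownames(ninfo) <- NULL
  new("PathSet", source = source, target = target, kRequested = k,
      mode = mode, weighted = weighted, paths = found, nodes = ninfo)
}

#' Plain-text report of a path set
#'
#' One block per path: rank, cost, and the alternating metabolite/reaction
#' sequence with per-reaction fluxes (when the graph carries them).
#'
#' @param ps a [PathSet-class].
#' @param graph the [FluxGraph-class] the paths were computed on (for
#'   reaction fluxes); optional.
#' @return character vector of report lines.
#' @export
pathReport <- function(ps, graph = NULL) {
  fluxOf <- function(id) {
    if (is.null(graph)) return(NA_real_)
    i <- match(id, graph@nodes$id)
    if (is.na(i)) NA_real_ else graph@nodes$flux[i]
  }
  out <- sprintf("k-shortest paths %s -> %s (%s, %s): %d found",
                 ps@source, ps@target, ps@mode,
                 if (ps@weighted) "weighted" else "unweighted",
                 length(ps@paths))
  for (p in ps@paths) {
    out <- c(out, sprintf("[%d] cost %.6g", p@rank, p@cost))
    kinds <- if (nrow(ps@nodes)) ps@nodes$kind[match(p@nodes, ps@nodes$id)]
             else rep(NA_character_, length(p@nodes))
    lab <- vapply(seq_along(p@nodes), function(i) {
      id <- p@nodes[i]
      if (identical(kinds[i], "reaction") && !is.na(fluxOf(id)))
        sprintf("%s (flux %.6g)", id, fluxOf(id))
      else id
    }, character(1))
    out <- c(out, paste("   ", paste(lab, collapse = " -> ")))
  }
  out
}
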