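# Greedy frontier ordering shared by spanningTree() and completeTree().
# A candidate attaches a child node to a tree endpoint through one graph edge;
# candidates are ranked by:
#   1. larger weight first,
#   2. smaller prospective depth (tree-endpoint depth + 1) first,
#   3. edges whose flux-resolved direction points toward the tree (the child
#      feeds the tree endpoint, i.e. it helps produce the root side) first,
#   4. lexicographically smaller child node id,
#   5. lexicographically smaller tree-endpoint id,
#   6. (parallel edges only) smaller edge index.
# With unit weights this reduces to (depth, producers-first, alphabetical):
# an alphabetically sorted breadth-first search with producers-first
# precedence, whose depth map equals the edge-count distance from the root.
.rankCandidates <- function(toward, weight, pdepth, child, parent, edge) {
  orderBy(-weight, pdepth, !toward, child, parent, edge)
}

#' Greedy flux-weighted spanning tree of a flux graph
#'
#' Grows a tree from the root by repeatedly attaching, among all edges joining
#' a tree node to a node not yet in the tree, the best edge under the
#' ordering: highest weight first; on equal weight the smallest prospective
#' depth (shortest path to the root); on equal depth, precedence to edges
#' whose flux points toward the root (producers added before consumers); then
#' alphabetical child id, then alphabetical tree-endpoint id. Every reachable
#' graph node appears exactly once; unreachable nodes are omitted. With all
#' weight options off the result is an alphabetically ordered breadth-first
#' search with producers-first precedence, so node depth equals the edge-count
#' distance from the root.
#'
#' @param graph a [FluxGraph-class].
#' @param root node id (metabolite or reaction) to root the tree at.
#' @return a [SpanningTree-class].
#' @examples
#' gem <- makeToyGEM("TOY6")
#' g <- buildFluxGraph(gem, optimizeFlux(gem), excludeCofactors = TRUE)
#' spanningTree(g, "BIO")
#' @export
spanningTree <- function(graph, root) {
  nodes <- graph@nodes$id
  if (!root %in% nodes) stopf("root node '%s' is not in the graph", root)
  e <- graph@edges
  nE <- nrow(e)

  incident <- .incidenceList(nodes, e)
  inTree <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  depth <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  inTree[root] <- TRUE; depth[root] <- 0L
  order_ <- root
  treeRows <- list()

  # candidate pool: one row per (edge, orientation); stale rows filtered lazily
  cand <- data.frame(edge = integer(), parent = character(),
                     child = character(), toward = logical(),
                     stringsAsFactors = FALSE)
  addCandidates <- function(u) {
    idx <- incident[[u]]
    if (!length(idx)) return()
    other <- ifelse(e$from[idx] == u, e$to[idx], e$from[idx])
    keep <- !inTree[other]
    if (!any(keep)) return()
    cand <<- rbind(cand, data.frame(
      edge = idx[keep], parent = u, child = other[keep],
      toward = e$to[idx[keep]] == u, stringsAsFactors = FALSE))
  }
  addCandidates(root)

  while (nrow(cand)) {
    cand <- cand[!inTree[cand$child], , drop = FALSE]
    if (!nrow(cand)) break
    rk <- .rankCandidates(cand$toward, e$weight[cand$edge],
                          depth[cand$parent] + 1L, cand$child, cand$parent, cand$edge)
    best <- cand[rk[1], ]
    x <- best$child; u <- best$parent
    inTree[x] <- TRUE
    depth[x] <- depth[u] + 1L
    order_ <- c(order_, x)
    treeRows[[length(treeRows) + 1L]] <- data.frame(
      node = x, parent = u,
      metabolite = e$metabolite[best$edge], reaction = e$reaction[best$edge],
      role = e$role[best$edge], stoich = e$stoich[best$edge],
      weight = e$weight[best$edge], towardRoot = best$toward,
      stringsAsFactors = FALSE)
    cand <- cand[cand$child != x, , drop = FALSE]
    addCandidates(x)
  }

  edges <- if (length(treeRows)) do.call(rbind, treeRows) else
    data.frame(node = character(), parent = character(),
               metabolite = character(), reaction = character(),
               role = character(), stoich = numeric(), weight = numeric(),
               towardRoot = logical(), stringsAsFactors = FALSE)
  keep <- graph@nodes[graph@nodes$id %in% order_, , drop = FALSE]
  rownames(keep) <- NULL
  new("SpanningTree", root = root, nodes = keep, edges = edges,
      depth = depth[order_], insertionOrder = order_)
}

.incidenceList <- function(nodes, e) {
  inc <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(e)) {
    byFrom <- split(seq_len(nrow(e)), e$from)
    byTo <- split(seq_len(nrow(e)), e$to)
    for (u in names(byFrom)) inc[[u]] <- c(inc[[u]], byFrom[[u]])
    for (u in names(byTo)) inc[[u]] <- c(inc[[u]], byTo[[u]])
  }
  inc
}

#' Breadth-first complete tree with duplicated nodes
#'
#' Traverses the graph from the root with the same frontier ordering as
#' [spanningTree()], but every graph edge is placed exactly once: an edge
#' whose far endpoint is already in the tree creates a duplicate leaf instance
#' of that node (duplicates never expand further), so the drawing shows all
#' edges.
#'
#' @param graph a [FluxGraph-class].
#' @param root node id to root the traversal at.
#' @return a [DuplicatedTree-class]. The number of instances equals the number
#'   of reachable nodes plus one per extra (non-tree) edge.
#' @examples
#' gem <- makeToyGEM("TOY6")
#' g <- buildFluxGraph(gem, optimizeFlux(gem), excludeCofactors = TRUE)
#' completeTree(g, "BIO")  # 10 instances, one duplicate, 9 edges
#' @export
completeTree <- function(graph, root) {
  nodes <- graph@nodes$id
  if (!root %in% nodes) stopf("root node '%s' is not in the graph", root)
  e <- graph@edges
  incident <- .incidenceList(nodes, e)

  placed <- stats::setNames(rep(FALSE, length(nodes)), nodes)   # as original
  depth <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  dupCount <- stats::setNames(rep(0L, length(nodes)), nodes)
  usedEdge <- rep(FALSE, max(1L, nrow(e)))

  placed[root] <- TRUE; depth[root] <- 0L
  instances <- data.frame(instance = root, node = root, isDuplicate = FALSE,
                          depth = 0L, stringsAsFactors = FALSE)
  edgeRows <- list()

  cand <- data.frame(edge = integer(), parent = character(),
                     child = character(), toward = logical(),
                     stringsAsFactors = FALSE)
  addCandidates <- function(u) {
    idx <- incident[[u]]
    idx <- idx[!usedEdge[idx]]
    if (!length(idx)) return()
    other <- ifelse(e$from[idx] == u, e$to[idx], e$from[idx])
    cand <<- rbind(cand, data.frame(
      edge = idx, parent = u, child = other,
      toward = e$to[idx] == u, stringsAsFactors = FALSE))
  }
  addCandidates(root)

  while (nrow(cand)) {
    cand <- cand[!usedEdge[cand$edge], , drop = FALSE]
    if (!nrow(cand)) break
    rk <- .rankCandidates(cand$toward, e$weight[cand$edge],
                          depth[cand$parent] + 1L, cand$child, cand$parent, cand$edge)
    best <- cand[rk[1], ]
    x <- best$child; u <- best$parent
    usedEdge[best$edge] <- TRUE
    if (!placed[x]) {
      inst <- x
      placed[x] <- TRUE
      depth[x] <- depth[u] + 1L
      isDup <- FALSE
      addCandidates(x)
    } else {
      dupCount[x] <- dupCount[x] + 1L
      inst <- sprintf("%s#%d", x, dupCount[x] + 1L)
      isDup <- TRUE
    }
    instances <- rbind(instances, data.frame(
      instance = inst, node = x, isDuplicate = isDup,
      depth = depth[u] + 1L, stringsAsFactors = FALSE))
    edgeRows[[length(edgeRows) + 1L]] <- data.frame(
      parentInstance = u, childInstance = inst,
      metabolite = e$metabolite[best$edge], reaction = e$reaction[best$edge],
      role = e$role[best$edge], stoich = e$stoich[best$edge],
      weight = e$weight[best$edge], towardRoot = best$toward,
      stringsAsFactors = FALSE)
  }

  edges <- if (length(edgeRows)) do.call(rbind, edgeRows) else
    data.frame(parentInstance = character(), childInstance = character(),
               metabolite = character(), reaction = character(),
               role = character(), stoich = numeric(), weight = numeric(),
               towardRoot = logical(), stringsAsFactors = FALSE)
  ninfo <- graph@nodes[match(instances$node, graph@nodes$id), ]
  instances$kind <- ninfo$kind
  instances$label <- ninfo$label
  instances <- instances[, c("instance", "node", "kind", "label",
                             "isDuplicate", "depth")]
  rownames(instances) <- NULL
  new("DuplicatedTree", root = root, instances = instances, edges = edges)
}
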