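# Independent oracle implementations used to cross-check the package's
# algorithms. They deliberately share no code with the implementations: the
# spanning-tree oracle recomputes the full frontier from scratch at every
# step, the path oracle enumerates all simple paths by depth-first search, and
# the BFS oracle is a plain queue-based traversal.

# brute-force greedy spanning tree: full frontier scan + stable sort per step
oracleSpanningTree <- function(graph, root) {
  e <- graphEdges(graph)
  inTree <- root
  depth <- stats::setNames(0L, root)
  rows <- list()
  repeat {
    cands <- NULL
    for (i in seq_len(nrow(e))) {
      for (orient in 1:2) {
        u <- if (orient == 1) e$from[i] else e$to[i]
        x <- if (orient == 1) e$to[i] else e$from[i]
        if (u %in% inTree && !(x %in% inTree))
          cands <- rbind(cands, data.frame(
            i = i, u = u, x = x, toward = orient == 2,
            w = e$weight[i], d = depth[[u]] + 1L, stringsAsFactors = FALSE))
      }
    }
    if (is.null(cands)) break
    cands <- cands[order(-cands$w, cands$d, !cands$toward, cands$x, cands$u,
                         cands$i, method = "radix"), ]
    b <- cands[1, ]
    inTree <- c(inTree, b$x)
    depth[b$x] <- b$d
    rows[[length(rows) + 1]] <- data.frame(node = b$x, parent = b$u,
                                           weight = b$w,
                                           stringsAsFactors = FALSE)
  }
  list(insertionOrder = inTree, depth = depth,
       edges = if (length(rows)) do.call(rbind, rows) else
         data.frame(node = character(), parent = character(),
                    weight = numeric()))
}

# plain queue BFS giving undirected edge-count distances from the root
bfsDistance <- function(graph, root) {
  nodes <- graphNodes(graph)$id
  e <- graphEdges(graph)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(e))) {
    adj[[e$from[i]]] <- c(adj[[e$from[i]]], e$to[i])
    adj[[e$to[i]]] <- c(adj[[e$to[i]]], e$from[i])
  }
  d <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  d[root] <- 0L
  q <- root
  while (length(q)) {
    u <- q[1]; q <- q[-1]
    for (v in adj[[u]]) if (is.na(d[v])) { d[v] <- d[u] + 1L; q <- c(q, v) }
  }
  d
}

# exhaustive DFS enumeration of all simple (loopless) directed paths
enumerateSimplePaths <- function(graph, source, target, weighted) {
  e <- graphEdges(graph)
  cost <- edgeCost(e$weight, weighted)
  out <- list()
  walk <- function(v, visited, acc) {
    if (v == target) {
      out[[length(out) + 1]] <<- list(nodes = visited, cost = acc)
      return()
    }
    for (i in which(e$from == v)) {
      w <- e$to[i]
      if (!w %in% visited && is.finite(cost[i]))
        walk(w, c(visited, w), acc + cost[i])
    }
  }
  walk(source, source, 0)
  out[order(vapply(out, function(p) p$cost, numeric(1)),
            vapply(out, function(p) paste(p$nodes, collapse = "\r"),
                   character(1)), method = "radix")]
}

# straight replay of the greedy certificate: each tree edge must be maximal
# under the frontier ordering among all frontier candidates at its step
greedyCertificateHolds <- function(graph, tree) {
  e <- graphEdges(graph)
  inTree <- tree@root
  depth <- stats::setNames(0L, tree@root)
  for (k in seq_len(nrow(tree@edges))) {
    step <- tree@edges[k, ]
    cands <- NULL
    for (i in seq_len(nrow(e))) {
      for (orient in 1:2) {
        u <- if (orient == 1) e$from[i] else e$to[i]
        x <- if (orient == 1) e$to[i] else e$from[i]
        if (u %in% inTree && !(x %in% inTree))
          cands <- rbind(cands, data.frame(
            i = i, u = u, x = x, toward = orient == 2, w = e$weight[i],
            d = depth[[u]] + 1L, stringsAsFactors = FALSE))
      }
    }
    if (is.null(cands)) return(FALSE)
    cands <- cands[order(-cands$w, cands$d, !cands$toward, cands$x, cands$u,
                         cands$i, method = "radix"), ]
    if (cands$x[1] != step$node || cands$u[1] != step$parent) return(FALSE)
    inTree <- c(inTree, step$node)
    depth[step$node] <- cands$d[1]
  }
  TRUE
}
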