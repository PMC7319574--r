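# uniform node-instance / edge view of the drawable objects
.asNodeLink <- function(x) {
  if (is(x, "FluxGraph")) {
    nodes <- data.frame(instance = x@nodes$id, node = x@nodes$id,
                        kind = x@nodes$kind, label = x@nodes$label,
                        compartment = x@nodes$compartment,
                        flux = x@nodes$flux, stringsAsFactors = FALSE)
    e <- x@edges
    edges <- data.frame(from = e$from, to = e$to, metabolite = e$metabolite,
                        reaction = e$reaction, role = e$role,
                        stoich = e$stoich, weight = e$weight,
                        towardRoot = rep(NA, nrow(e)),
                        stringsAsFactors = FALSE)
    return(list(nodes = nodes, edges = edges))
  }
  if (is(x, "SpanningTree")) {
    ninfo <- x@nodes[match(x@insertionOrder, x@nodes$id), ]
    nodes <- data.frame(instance = x@insertionOrder, node = x@insertionOrder,
                        kind = ninfo$kind, label = ninfo$label,
                        compartment = ninfo$compartment,
                        flux = ninfo$flux, stringsAsFactors = FALSE)
    e <- x@edges
    edges <- data.frame(
      from = ifelse(e$towardRoot, e$node, e$parent),
      to = ifelse(e$towardRoot, e$parent, e$node),
      metabolite = e$metabolite, reaction = e$reaction, role = e$role,
      stoich = e$stoich, weight = e$weight, towardRoot = e$towardRoot,
      stringsAsFactors = FALSE)
    return(list(nodes = nodes, edges = edges))
  }
  if (is(x, "DuplicatedTree")) {
    i <- x@instances
    nodes <- data.frame(instance = i$instance, node = i$node, kind = i$kind,
                        label = i$label, compartment = NA_character_,
                        flux = NA_real_, stringsAsFactors = FALSE)
    e <- x@edges
    edges <- data.frame(
      from = ifelse(e$towardRoot, e$childInstance, e$parentInstance),
      to = ifelse(e$towardRoot, e$parentInstance, e$childInstance),
      metabolite = e$metabolite, reaction = e$reaction, role = e$role,
      stoich = e$stoich, weight = e$weight, towardRoot = e$towardRoot,
      stringsAsFactors = FALSE)
    return(list(nodes = nodes, edges = edges))
  }
  stopf("unsupported object of class %s", class(x)[1])
}

# parent/children shape of a tree object, children in placement order
.treeShape <- function(tree) {
  if (is(tree, "SpanningTree")) {
    instances <- tree@insertionOrder
    parent <- stats::setNames(tree@edges$parent, tree@edges$node)
    depth <- tree@depth
  } else if (is(tree, "DuplicatedTree")) {
    instances <- tree@instances$instance
    parent <- stats::setNames(tree@edges$parentInstance,
                              tree@edges$childInstance)
    depth <- stats::setNames(tree@instances$depth, tree@instances$instance)
  } else {
    stopf("expected a SpanningTree or DuplicatedTree, got %s", class(tree)[1])
  }
  children <- stats::setNames(vector("list", length(instances)), instances)
  for (ch in instances) {
    p <- parent[ch]
    if (!is.na(p)) children[[p]] <- c(children[[p]], ch)
  }
  root <- if (is(tree, "SpanningTree")) tree@root else tree@instances$instance[1]
  list(instances = instances, parent = parent, children = children,
       depth = depth, root = root)
}

.layoutResult <- function(coords, kind, diagnostics = list()) {
  bounds <- if (nrow(coords))
    c(min(coords$x), min(coords$y), max(coords$x), max(coords$y))
  else c(0, 0, 0, 0)
  new("LayoutResult", coords = coords, layoutKind = kind, bounds = bounds,
      diagnostics = diagnostics)
}

# breadth coordinate: leaves get consecutive integers in drawing order,
# each internal node sits at the midpoint of its children's extent
.treeBreadth <- function(shape) {
  y <- stats::setNames(rep(NA_real_, length(shape$instances)), shape$instances)
  counter <- 0
  assign_ <- function(v) {
    ch <- shape$children[[v]]
    if (is.null(ch)) {
      y[v] <<- counter
      counter <<- counter + 1
    } else {
      for (c_ in ch) assign_(c_)
      y[v] <<- (min(y[ch]) + max(y[ch])) / 2
    }
  }
  assign_(shape$root)
  y
}

#' Tidy tree layout
#'
#' Hierarchical drawing in the tidy (Reingold-Tilford) family: depth maps to
#' the horizontal axis with the root at maximum x and leaves toward the left,
#' leaves are separated by at least one breadth unit, and every parent is
#' centered on the midpoint of its children's extent.
#'
#' @param tree a [SpanningTree-class] or [DuplicatedTree-class].
#' @return a [LayoutResult-class] with `layoutKind = "tidy"`.
#' @export
tidyLayout <- function(tree) {
  shape <- .treeShape(tree)
  y <- .treeBreadth(shape)
  maxDepth <- max(shape$depth)
  coords <- data.frame(instance = shape$instances,
                       node = .instanceNode(tree, shape$instances),
                       x = as.numeric(maxDepth -
                                        unname(shape$depth[shape$instances])),
                       y = as.numeric(unname(y[shape$instances])),
                       stringsAsFactors = FALSE)
  .layoutResult(coords, "tidy")
}

#' Dendrogram layout
#'
#' All leaves share the same x coordinate on the left side and are equally
#' spaced in y; each internal node is centered over its descendants and placed
#' at x equal to its height (edges to its deepest descendant leaf), so the
#' root is rightmost.
#'
#' @param tree a [SpanningTree-class] or [DuplicatedTree-class].
#' @return a [LayoutResult-class] with `layoutKind = "dendrogram"`.
#' @export
dendrogramLayout <- function(tree) {
  shape <- .treeShape(tree)
  y <- .treeBreadth(shape)
  height <- stats::setNames(rep(0, length(shape$instances)), shape$instances)
  walk <- function(v) {
    ch <- shape$children[[v]]
    if (is.null(ch)) return(0)
    h <- 1 + max(vapply(ch, walk, numeric(1)))
    height[v] <<- h
    h
  }
  walk(shape$root)
  coords <- data.frame(instance = shape$instances,
                       node = .instanceNode(tree, shape$instances),
                       x = as.numeric(unname(height[shape$instances])),
                       y = as.numeric(unname(y[shape$instances])),
                       stringsAsFactors = FALSE)
  .layoutResult(coords, "dendrogram")
}

.instanceNode <- function(tree, instances) {
  if (is(tree, "DuplicatedTree"))
    tree@instances$node[match(instances, tree@instances$instance)]
  else instances
}

#' Radial transform of a tree layout
#'
#' Maps a tidy or dendrogram layout to polar coordinates: the depth axis
#' becomes the radius (root at the origin) and the breadth axis the angle,
#' normalized to `[0, 2*pi)`. Useful as a more compact representation of
#' large trees.
#'
#' @param layout a [LayoutResult-class] of kind `"tidy"` or `"dendrogram"`.
#' @param step radial distance per depth unit.
#' @return a [LayoutResult-class] with kind `"radial_tidy"` or
#'   `"radial_dendrogram"`.
#' @export
radialTransform <- function(layout, step = 1) {
  if (!layout@layoutKind %in% c("tidy", "dendrogram"))
    stopf("radialTransform expects a tidy or dendrogram layout, got '%s'",
          layout@layoutKind)
  co <- layout@coords
  depth <- max(co$x) - co$x
  span <- max(co$y) - min(co$y)
  angle <- if (span > 0) 2 * pi * (co$y - min(co$y)) / (span + 1) else
    rep(0, nrow(co))
  out <- data.frame(instance = co$instance, node = co$node,
                    x = depth * step * cos(angle),
                    y = depth * step * sin(angle),
                    stringsAsFactors = FALSE)
  .layoutResult(out, paste0("radial_", layout@layoutKind),
                diagnostics = list(radius = depth * step, angle = angle))
}

#' Layered (Sugiyama-style) layout for acyclic graphs
#'
#' Longest-path layering from the sources, followed by a fixed number of
#' alternating barycenter sweeps to reduce edge crossings between consecutive
#' layers; the best ordering encountered is kept, so the final crossing count
#' never exceeds the initial one. Layers run along x; positions within a
#' layer along y.
#'
#' @param x a [PathSet-class] (the union of its paths) or an acyclic
#'   [FluxGraph-class].
#' @param sweeps number of barycenter sweeps.
#' @return a [LayoutResult-class] with `layoutKind = "layered"`; its
#'   `diagnostics` hold `initialCrossings` and `finalCrossings`.
#' @export
layeredLayout <- function(x, sweeps = 8) {
  if (is(x, "PathSet")) {
    ed <- unique(do.call(rbind, lapply(x@paths, function(p)
      p@edges[, c("from", "to")])))
    nodes <- unique(unlist(lapply(x@paths, function(p) p@nodes)))
    if (is.null(ed)) ed <- data.frame(from = character(), to = character())
  } else if (is(x, "FluxGraph")) {
    ed <- unique(x@edges[, c("from", "to")])
    nodes <- x@nodes$id
  } else stopf("layeredLayout expects a PathSet or FluxGraph")
  nodes <- nodes[orderBy(nodes)]
  rownames(ed) <- NULL

  # Kahn's algorithm: topological order, cycle detection
  indeg <- stats::setNames(rep(0L, length(nodes)), nodes)
  for (v in ed$to) indeg[v] <- indeg[v] + 1L
  queue <- nodes[indeg == 0]
  topo <- character()
  indeg2 <- indeg
  while (length(queue)) {
    queue <- queue[orderBy(queue)]
    u <- queue[1]; queue <- queue[-1]
    topo <- c(topo, u)
    out <- ed$to[ed$from == u]
    for (v in out) {
      indeg2[v] <- indeg2[v] - 1L
      if (indeg2[v] == 0L) queue <- c(queue, v)
    }
  }
  if (length(topo) < length(nodes))
    stopf("graph is not acyclic: cycle involving node '%s'",
          setdiff(nodes, topo)[1])

  layer <- stats::setNames(rep(0L, length(nodes)), nodes)
  for (u in topo) {
    inn <- ed$from[ed$to == u]
    if (length(inn)) layer[u] <- max(layer[inn]) + 1L
  }

  # within-layer positions, initially lexicographic
  pos <- stats::setNames(rep(0, length(nodes)), nodes)
  for (l in unique(layer)) {
    ids <- nodes[layer == l]
    pos[ids[orderBy(ids)]] <- seq_along(ids) - 1
  }
  crossings <- function(pos) {
    if (!nrow(ed)) return(0L)
    total <- 0L
    grp <- paste(layer[ed$from], layer[ed$to])
    for (g in unique(grp)) {
      idx <- which(grp == g)
      if (length(idx) < 2) next
      a <- pos[ed$from[idx]]; b <- pos[ed$to[idx]]
      for (i in seq_along(idx)[-1]) for (j in seq_len(i - 1))
        if ((a[i] - a[j]) * (b[i] - b[j]) < 0) total <- total + 1L
    }
    total
  }
  best <- pos
  bestCross <- initialCross <- crossings(pos)
  lay <- sort(unique(layer))
  for (s in seq_len(sweeps)) {
    forward <- s %% 2 == 1
    for (l in if (forward) lay else rev(lay)) {
      ids <- nodes[layer == l]
      bary <- vapply(ids, function(v) {
        nb <- if (forward) ed$from[ed$to == v] else ed$to[ed$from == v]
        if (length(nb)) mean(pos[nb]) else pos[[v]]
      }, numeric(1))
      pos[ids[orderBy(bary, pos[ids], ids)]] <- seq_along(ids) - 1
    }
    cr <- crossings(pos)
    if (cr < bestCross) { bestCross <- cr; best <- pos }
  }
  pos <- best
  coords <- data.frame(instance = nodes, node = nodes,
                       x = as.numeric(unname(layer[nodes])),
                       y = as.numeric(unname(pos[nodes])),
                       stringsAsFactors = FALSE)
  .layoutResult(coords, "layered",
                diagnostics = list(initialCrossings = initialCross,
                                   finalCrossings = bestCross,
                                   layer = layer))
}

#' Force-directed layout (velocity Verlet integration)
#'
#' Physics simulation: all node pairs repel with an inverse-square force,
#' edges act as springs toward a rest length, a weak centering force keeps the
#' drawing around the origin, and velocities decay each step. Positions are
#' integrated with the velocity Verlet scheme for a fixed number of steps from
#' seeded random starting positions, so the result is fully deterministic for
#' a given seed. Disconnected components repel each other and separate into
#' visible clusters.
#'
#' @param x a [FluxGraph-class], [SpanningTree-class] or
#'   [DuplicatedTree-class].
#' @param iterations number of integration steps.
#' @param seed integer seed for the initial positions.
#' @param repulsion,springConstant,restLength,centering,decay,dt simulation
#'   constants; the defaults give near-rest-length edges for small graphs.
#' @return a [LayoutResult-class] with `layoutKind = "force"`; `diagnostics`
#'   hold the per-step total kinetic energy.
#' @export
forceLayout <- function(x, iterations = 300, seed = 1L, repulsion = 30,
                        springConstant = 0.05, restLength = 30,
                        centering = 0.005, decay = 0.9, dt = 0.5) {
  nl <- .asNodeLink(x)
  ids <- nl$nodes$instance
  n <- length(ids)
  ei <- match(nl$edges$from, ids)
  ej <- match(nl$edges$to, ids)

  pos <- withSeed(seed, matrix(stats::runif(2 * max(n, 1), -50, 50), ncol = 2))
  if (n == 0)
    return(.layoutResult(data.frame(instance = character(),
                                    node = character(), x = numeric(),
                                    y = numeric()), "force"))
  vel <- matrix(0, n, 2)
  forces <- function(p) {
    f <- -centering * p
    if (n > 1) {
      dx <- outer(p[, 1], p[, 1], "-")
      dy <- outer(p[, 2], p[, 2], "-")
      d2 <- pmax(dx^2 + dy^2, 1)
      inv <- repulsion / (d2 * sqrt(d2))
      diag(inv) <- 0
      f[, 1] <- f[, 1] + rowSums(dx * inv)
      f[, 2] <- f[, 2] + rowSums(dy * inv)
    }
    if (length(ei)) {
      dx <- p[ej, 1] - p[ei, 1]
      dy <- p[ej, 2] - p[ei, 2]
      d <- pmax(sqrt(dx^2 + dy^2), 1e-9)
      mag <- springConstant * (d - restLength) / d
      fx <- mag * dx; fy <- mag * dy
      for (k in seq_along(ei)) {
        f[ei[k], ] <- f[ei[k], ] + c(fx[k], fy[k])
        f[ej[k], ] <- f[ej[k], ] - c(fx[k], fy[k])
      }
    }
    f
  }
  ke <- numeric(iterations)
  acc <- forces(pos)
  for (it in seq_len(iterations)) {
    pos <- pos + vel * dt + 0.5 * acc * dt^2
    accNew <- forces(pos)
    vel <- (vel + 0.5 * (acc + accNew) * dt) * decay
    acc <- accNew
    ke[it] <- 0.5 * sum(vel^2)
  }
  coords <- data.frame(instance = ids, node = nl$nodes$node,
                       x = pos[, 1], y = pos[, 2], stringsAsFactors = FALSE)
  .layoutResult(coords, "force", diagnostics = list(kineticEnergy = ke))
}
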