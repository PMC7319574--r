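chainTree <- function(n = 5) {
  # a straight metabolite/reaction chain m1 -> r1 -> m2 -> ...
  ids <- character(0); rows <- list()
  for (i in seq_len(n - 1)) {
    met <- sprintf("m%d", (i + 1) %/% 2 + (i + 1) %% 2)
    rows[[i]] <- if (i %% 2 == 1)
      data.frame(metabolite = sprintf("m%d", (i + 1) / 2),
                 reaction = sprintf("r%d", (i + 1) / 2),
                 role = "consumed-by", stoich = 1, weight = 1,
                 stringsAsFactors = FALSE)
    else
      data.frame(metabolite = sprintf("m%d", i / 2 + 1),
                 reaction = sprintf("r%d", i / 2),
                 role = "produced-by", stoich = 1, weight = 1,
                 stringsAsFactors = FALSE)
  }
  spanningTree(syntheticGraph(do.call(rbind, rows)), "m1")
}

toyTree <- function() {
  gem <- makeToyGEM("TOY6")
  spanningTree(buildFluxGraph(gem, optimizeFlux(gem),
                              excludeCofactors = TRUE), "BIO")
}

test_that("tidy layout centers parents and spaces siblings", {
  tr <- toyTree()
  lay <- tidyLayout(tr)
  co <- coordinates(lay)
  rownames(co) <- co$instance
  # root at maximum x
  expect_equal(co["BIO", "x"], max(co$x))
  # depth maps to x: each child one unit left of its parent
  e <- graphEdges(tr)
  for (i in seq_len(nrow(e)))
    expect_equal(co[e$node[i], "x"], co[e$parent[i], "x"] - 1)
  # parent centered on the midpoint of its children's extent
  for (p in unique(e$parent)) {
    ch <- e$node[e$parent == p]
    expect_equal(co[p, "y"], (min(co[ch, "y"]) + max(co[ch, "y"])) / 2,
                 tolerance = 1e-9)
  }
  # nodes sharing a depth are at least one breadth unit apart
  for (d in unique(co$x)) {
    ys <- sort(co$y[co$x == d])
    if (length(ys) > 1) expect_gte(min(diff(ys)), 1)
  }
})

test_that("degenerate tidy layouts: single node and unbranched chain", {
  solo <- new("SpanningTree", root = "solo",
              nodes = data.frame(id = "solo", kind = "metabolite",
                                 label = "solo", compartment = "c",
                                 flux = NA_real_, stringsAsFactors = FALSE),
              edges = spanningTree(syntheticGraph(data.frame(
                metabolite = "m1", reaction = "r1", role = "consumed-by",
                stoich = 1, weight = 1)), "m1")@edges[0, ],
              depth = c(solo = 0L), insertionOrder = "solo")
  for (l in list(tidyLayout(solo), dendrogramLayout(solo),
                 radialTransform(tidyLayout(solo)))) {
    co <- coordinates(l)
    expect_equal(nrow(co), 1)
    expect_equal(unname(unlist(co[1, c("x", "y")])), c(0, 0))
  }
  lay <- tidyLayout(chainTree(5))
  co <- coordinates(lay)
  expect_equal(length(unique(co$y)), 1)          # collinear
  expect_identical(sort(co$x), as.numeric(0:4))  # equally spaced in depth
})

test_that("dendrogram layout puts all leaves on one vertical line", {
  tr <- toyTree()
  lay <- dendrogramLayout(tr)
  co <- coordinates(lay)
  rownames(co) <- co$instance
  e <- graphEdges(tr)
  leaves <- setdiff(tr@insertionOrder, e$parent)
  expect_lte(max(co[leaves, "x"]) - min(co[leaves, "x"]), 1e-9)
  expect_equal(min(co[leaves, "x"]), 0)
  expect_equal(co["BIO", "x"], max(co$x))
  # leaves equally spaced
  expect_equal(sort(co[leaves, "y"]), seq(0, length(leaves) - 1))
  # a balanced two-level star: root with two reaction children, four leaves
  ed <- data.frame(
    metabolite = c("root", "root", "l1", "l2", "l3", "l4"),
    reaction = c("ra", "rb", "ra", "ra", "rb", "rb"),
    role = c("consumed-by", "consumed-by", "produced-by", "produced-by",
             "produced-by", "produced-by"),
    stoich = 1, weight = 1, stringsAsFactors = FALSE)
  lay2 <- dendrogramLayout(spanningTree(syntheticGraph(ed), "root"))
  co2 <- coordinates(lay2)
  ly <- sort(co2$y[co2$instance %in% c("l1", "l2", "l3", "l4")])
  expect_equal(ly, 0:3)
})

test_that("radial transform sends the root to the origin, depths to rings", {
  tr <- toyTree()
  lay <- radialTransform(tidyLayout(tr))
  expect_identical(lay@layoutKind, "radial_tidy")
  co <- coordinates(lay)
  rownames(co) <- co$instance
  expect_equal(unname(unlist(co["BIO", c("x", "y")])), c(0, 0))
  r <- sqrt(co$x^2 + co$y^2)
  names(r) <- co$instance
  # all depth-1 nodes equidistant from the origin
  d1 <- names(tr@depth)[tr@depth == 1]
  expect_lte(max(r[d1]) - min(r[d1]), 1e-9)
  # radius grows linearly with depth
  expect_equal(unname(r[tr@insertionOrder]),
               unname(tr@depth[tr@insertionOrder]), tolerance = 1e-9)
  # angles increase with breadth order
  ang <- lay@diagnostics$angle
  y <- coordinates(tidyLayout(tr))$y
  expect_true(all(diff(ang[order(y)]) >= 0))
  expect_error(radialTransform(lay), "tidy or dendrogram")
})

test_that("layered layout respects layering and never adds crossings", {
  gem <- makeToyGEM("TOY6")
  g <- buildFluxGraph(gem, optimizeFlux(gem), excludeCofactors = TRUE)
  ps <- kShortestPaths(g, "A", "BIO", k = 2, weighted = FALSE)
  lay <- layeredLayout(ps)
  co <- coordinates(lay)
  rownames(co) <- co$instance
  # layer(u) < layer(v) for every edge
  for (p in pathList(ps))
    for (i in seq_len(nrow(p@edges)))
      expect_lt(co[p@edges$from[i], "x"], co[p@edges$to[i], "x"])
  # single path: one node per layer, no crossings
  one <- layeredLayout(kShortestPaths(g, "A", "BIO", k = 1,
                                      weighted = FALSE))
  expect_equal(one@diagnostics$finalCrossings, 0)
  expect_false(anyDuplicated(coordinates(one)$x) > 0)
  # node-disjoint parallel tracks separate without crossings
  ed <- data.frame(
    metabolite = c("x1", "y1", "x2", "y2"),
    reaction = c("p1", "p1", "p2", "p2"),
    role = c("consumed-by", "produced-by", "consumed-by", "produced-by"),
    stoich = 1, weight = 1, stringsAsFactors = FALSE)
  lay2 <- layeredLayout(syntheticGraph(ed))
  expect_equal(lay2@diagnostics$finalCrossings, 0)
  # barycenter sweeps never increase crossings on random DAGs
  for (s in 1:30) {
    dag <- randomBipartiteDAG(s, nMet = 4 + s %% 3, nRxn = 4 + (s + 1) %% 3,
                              nEdge = 10 + s %% 6)
    l <- layeredLayout(dag)
    expect_lte(l@diagnostics$finalCrossings, l@diagnostics$initialCrossings)
  }
})

test_that("layered layout rejects cyclic graphs naming an offending node", {
  gem <- makeToyGEM("TOY6")
  g <- buildFluxGraph(gem, optimizeFlux(gem))  # REG/R2 form an ATP/ADP cycle
  expect_error(layeredLayout(g), "not acyclic")
})

test_that("force layout is seed-deterministic and relaxes to rest length", {
  ed <- data.frame(metabolite = "m1", reaction = "r1", role = "consumed-by",
                   stoich = 1, weight = 1, stringsAsFactors = FALSE)
  g <- syntheticGraph(ed)
  l1 <- forceLayout(g, seed = 11)
  l2 <- forceLayout(g, seed = 11)
  expect_identical(coordinates(l1), coordinates(l2))
  l3 <- forceLayout(g, seed = 12)
  expect_false(identical(coordinates(l1), coordinates(l3)))
  # two nodes joined by one edge settle within 5% of the rest length
  co <- coordinates(l1)
  d <- sqrt(diff(co$x)^2 + diff(co$y)^2)
  expect_lt(abs(d - 30) / 30, 0.05)
  # kinetic energy is non-increasing over the last tenth of the run
  ke <- l1@diagnostics$kineticEnergy
  tail10 <- ke[(length(ke) - 29):length(ke)]
  expect_true(all(diff(tail10) <= 1e-9))
})

test_that("disconnected cliques separate under the force layout", {
  g <- twoCliqueGraph()
  lay <- forceLayout(g, iterations = 500, seed = 3)
  co <- coordinates(lay)
  blk <- substr(co$instance, 1, 1)
  centA <- c(mean(co$x[blk == "a"]), mean(co$y[blk == "a"]))
  centB <- c(mean(co$x[blk == "b"]), mean(co$y[blk == "b"]))
  inter <- sqrt(sum((centA - centB)^2))
  intra <- function(b) {
    pts <- co[blk == b, c("x", "y")]
    mean(dist(pts))
  }
  expect_gt(inter, max(intra("a"), intra("b")))
  ke <- lay@diagnostics$kineticEnergy
  tail10 <- ke[(length(ke) - 49):length(ke)]
  expect_true(all(diff(tail10) <= 1e-9))
})

test_that("force layout also accepts trees and stays within bounds", {
  lay <- forceLayout(toyTree(), seed = 5)
  co <- coordinates(lay)
  expect_equal(nrow(co), 9)
  b <- lay@bounds
  expect_true(all(co$x >= b[1] & co$x <= b[3] & co$y >= b[2] & co$y <= b[4]))
})
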