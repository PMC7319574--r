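toyPathGraph <- function() {
  gem <- makeToyGEM("TOY6")
  buildFluxGraph(gem, optimizeFlux(gem), excludeCofactors = TRUE)
}

test_that("edge costs invert weights and make zero-weight edges impassable", {
  expect_equal(edgeCost(5, weighted = TRUE), 0.2)
  expect_equal(edgeCost(c(1, 4), weighted = TRUE), c(1, 0.25))
  expect_identical(edgeCost(0, weighted = TRUE), Inf)
  expect_equal(edgeCost(c(0, 5, 100), weighted = FALSE), c(1, 1, 1))
})

test_that("unweighted shortest path from A to BIO breaks the tie toward R2", {
  g <- toyPathGraph()
  p <- shortestPath(g, "A", "BIO", weighted = FALSE)
  expect_identical(p@nodes, c("A", "R1", "B", "R2", "C", "BIO"))
  expect_equal(p@cost, 5)
  # degenerate cases
  self <- shortestPath(g, "A", "A")
  expect_identical(self@nodes, "A")
  expect_equal(self@cost, 0)
  expect_error(shortestPath(g, "NOPE", "BIO"), "NOPE")
})

test_that("unreachable targets give no path and an empty path set", {
  gem <- makeToyGEM("TOY6Z")
  g <- buildFluxGraph(gem, optimizeFlux(gem))
  # E is a dead end: nothing consumes it, so no directed path E -> ... -> BIO
  expect_null(shortestPath(g, "E", "BIO"))
  ps <- kShortestPaths(g, "E", "BIO", k = 3)
  expect_length(pathList(ps), 0)
})

test_that("k-shortest on TOY6 finds exactly the two simple routes", {
  g <- toyPathGraph()
  ps <- kShortestPaths(g, "A", "BIO", k = 2, weighted = FALSE, mode = "best_k")
  expect_length(pathList(ps), 2)
  costs <- vapply(pathList(ps), function(p) p@cost, numeric(1))
  expect_equal(costs, c(5, 5))
  seqs <- lapply(pathList(ps), function(p) p@nodes)
  expect_identical(seqs[[1]], c("A", "R1", "B", "R2", "C", "BIO"))
  expect_identical(seqs[[2]], c("A", "R1", "B", "R3", "D", "BIO"))
  # k beyond the number of simple paths is not an error
  expect_length(pathList(kShortestPaths(g, "A", "BIO", k = 10,
                                        weighted = FALSE)), 2)
  # k = 1 degenerates to the single shortest path
  one <- kShortestPaths(g, "A", "BIO", k = 1, weighted = FALSE)
  expect_identical(pathList(one)[[1]]@nodes,
                   shortestPath(g, "A", "BIO", weighted = FALSE)@nodes)
})

test_that("returned paths are valid: loopless, connected, cost-consistent, sorted", {
  for (s in 1:15) {
    g <- randomFluxGraph(1300 + s)
    ps <- kShortestPaths(g, graphNodes(g)$id[1], "BIO", k = 4,
                         weighted = s %% 2 == 0)
    e <- graphEdges(g)
    key <- paste(e$from, e$to)
    costs <- vapply(pathList(ps), function(p) p@cost, numeric(1))
    expect_false(is.unsorted(costs))
    seqs <- vapply(pathList(ps), function(p) paste(p@nodes, collapse = ">"),
                   character(1))
    expect_false(anyDuplicated(seqs) > 0)
    for (p in pathList(ps)) {
      expect_false(anyDuplicated(p@nodes) > 0)
      if (nrow(p@edges)) {
        expect_true(all(paste(p@edges$from, p@edges$to) %in% key))
        expect_identical(p@edges$from, p@nodes[-length(p@nodes)])
        expect_identical(p@edges$to, p@nodes[-1])
        expect_equal(sum(p@edges$cost), p@cost)
      }
    }
  }
})

test_that("best_k is never cheaper than exhaustive enumeration, equal on TOY6", {
  # exhaustive DFS enumeration is the ground truth on small graphs; the
  # single-edge-removal scheme may miss paths but must never undercut
  for (s in 1:20) {
    gem <- makeRandomGEM(1, 3, 1 + s %% 3, seed = 1400 + s)  # <= 12 nodes
    fs <- optimizeFlux(gem)
    g <- buildFluxGraph(gem, fs)
    expect_lte(nrow(graphNodes(g)), 12)
    src <- "M1_1"
    truth <- enumerateSimplePaths(g, src, "BIO", weighted = FALSE)
    ps <- kShortestPaths(g, src, "BIO", k = 5, weighted = FALSE,
                         mode = "best_k")
    got <- vapply(pathList(ps), function(p) p@cost, numeric(1))
    for (i in seq_along(got))
      expect_gte(got[i], truth[[i]]$cost - 1e-9)
  }
  # on the TOY6 family the scheme recovers the enumeration exactly
  g <- toyPathGraph()
  truth <- enumerateSimplePaths(g, "A", "BIO", weighted = FALSE)
  ps <- kShortestPaths(g, "A", "BIO", k = 10, weighted = FALSE)
  expect_equal(length(pathList(ps)), length(truth))
  for (i in seq_along(truth)) {
    expect_equal(pathList(ps)[[i]]@cost, truth[[i]]$cost)
    expect_identical(pathList(ps)[[i]]@nodes, truth[[i]]$nodes)
  }
})

test_that("first_k costs dominate best_k costs rank by rank", {
  for (s in c(4, 9, 13)) {
    g <- randomFluxGraph(1500 + s)
    first <- kShortestPaths(g, graphNodes(g)$id[1], "BIO", k = 3,
                            weighted = TRUE, mode = "first_k")
    best <- kShortestPaths(g, graphNodes(g)$id[1], "BIO", k = 3,
                           weighted = TRUE, mode = "best_k")
    fc <- vapply(pathList(first), function(p) p@cost, numeric(1))
    bc <- vapply(pathList(best), function(p) p@cost, numeric(1))
    expect_lte(length(fc), length(bc))
    for (i in seq_along(fc)) expect_gte(fc[i], bc[i] - 1e-9)
  }
})

test_that("including a cofactor bridge shortens paths", {
  # a currency-metabolite shortcut: X -> RA -> cof -> RB -> Z is shorter than
  # the honest carbon route X -> R1 -> Y -> R2 -> Z ... when cofactors stay in
  ed <- data.frame(
    metabolite = c("X", "Y", "Y", "Z", "X", "cof", "cof", "Z"),
    reaction = c("R1", "R1", "R2", "R2", "RA", "RA", "RB", "RB"),
    role = c("consumed-by", "produced-by", "consumed-by", "produced-by",
             "consumed-by", "produced-by", "consumed-by", "produced-by"),
    stoich = 1, weight = 1, stringsAsFactors = FALSE)
  withCof <- syntheticGraph(ed)
  p1 <- shortestPath(withCof, "X", "Z", weighted = FALSE)
  noCof <- syntheticGraph(ed[ed$metabolite != "cof", ])
  p2 <- shortestPath(noCof, "X", "Z", weighted = FALSE)
  expect_equal(p1@cost, 4)
  expect_equal(p2@cost, 4)
  # make the cofactor route strictly shorter by weighting it up
  ed2 <- ed
  ed2$weight[ed2$metabolite == "cof" | ed2$reaction %in% c("RA", "RB")] <- 10
  wc <- syntheticGraph(ed2)
  pw <- shortestPath(wc, "X", "Z", weighted = TRUE)
  expect_true("cof" %in% pw@nodes)
  expect_lt(pw@cost, 4 * 1)
})

test_that("zero-weight edges never carry a weighted path", {
  ed <- data.frame(metabolite = c("X", "Y"), reaction = c("R1", "R1"),
                   role = c("consumed-by", "produced-by"),
                   stoich = 1, weight = c(1, 0), stringsAsFactors = FALSE)
  g <- syntheticGraph(ed)
  expect_null(shortestPath(g, "X", "Y", weighted = TRUE))
  expect_identical(shortestPath(g, "X", "Y", weighted = FALSE)@nodes,
                   c("X", "R1", "Y"))
})
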