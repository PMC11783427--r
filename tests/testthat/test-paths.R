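test_that("Floyd-Warshall reproduces worked examples", {
  g2 <- makeTestGraph(2, data.frame(i = 1, j = 2, w = 0.7))
  expect_equal(as.matrix(floydWarshall(g2))[1, 2], 0.7)

  # A-B(1), B-D(1), A-C(1.5), C-D(1.5), A-D(5): best A->D is A-B-D = 2
  g4 <- makeTestGraph(4, data.frame(i = c(1, 2, 1, 3, 1),
                                    j = c(2, 4, 3, 4, 4),
                                    w = c(1, 1, 1.5, 1.5, 5)))
  D <- as.matrix(floydWarshall(g4))
  expect_equal(D[1, 4], 2)
  expect_equal(D[1, ], c(0, 1, 1.5, 2))

  # disconnected pairs are infinite
  g3 <- makeTestGraph(3, data.frame(i = 1, j = 2, w = 1))
  expect_identical(as.matrix(floydWarshall(g3))[1, 3], Inf)

  # negative weights are refused
  gn <- makeTestGraph(2, data.frame(i = 1, j = 2, w = 1))
  gn@edges$weight <- -0.1
  expect_error(floydWarshall(gn), "negative")
})

test_that("distances satisfy metric invariants and match igraph", {
  skip_if_not_installed("igraph")
  for (seed in 1:25) {
    rg <- randomTestGraph(seed)
    D <- as.matrix(floydWarshall(rg$graph))
    expect_equal(diag(D), rep(0, rg$n))
    expect_equal(D, t(D))
    # triangle inequality
    for (k in seq_len(rg$n))
      expect_true(all(D <= outer(D[, k], D[k, ], `+`) + 1e-9))
    ig <- igraph::graph_from_data_frame(
      rg$edges[c("i", "j", "w")], directed = FALSE,
      vertices = data.frame(name = seq_len(rg$n)))
    Dig <- igraph::distances(ig, weights = igraph::E(ig)$w)
    expect_equal(unname(D), unname(Dig[as.character(seq_len(rg$n)),
                                       as.character(seq_len(rg$n))]),
                 tolerance = 1e-9)
  }
})

test_that("reconstructed optimal paths have the reported length", {
  for (seed in 1:10) {
    rg <- randomTestGraph(seed + 100)
    apd <- floydWarshall(rg$graph)
    D <- as.matrix(apd)
    wOf <- function(i, j) {
      e <- rg$edges
      e$w[(e$i == min(i, j)) & (e$j == max(i, j))]
    }
    for (j in 2:rg$n) {
      p <- reconstructPath(apd, 1, j)
      len <- sum(vapply(seq_len(length(p) - 1),
                        function(k) wOf(p[k], p[k + 1]), numeric(1)))
      expect_equal(len, D[1, j], tolerance = 1e-9)
    }
  }
})

test_that("bounded enumeration reproduces the triangle examples", {
  tri <- makeTestGraph(3, data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                                     w = c(1, 1, 2.5)))
  ps <- suboptimalPaths(tri, 1, 3, pathParams(delta = 1, topK = 10))
  expect_equal(ps@lOpt, 2)
  expect_equal(ps@countWithinCutoff, 2)
  expect_equal(pathList(ps), list(c(1L, 2L, 3L), c(1L, 3L)))
  expect_equal(pathLengths(ps), c(2, 2.5))

  ps2 <- suboptimalPaths(tri, 1, 3, pathParams(delta = 0.4, topK = 10))
  expect_equal(ps2@countWithinCutoff, 1)

  ps0 <- suboptimalPaths(tri, 1, 3, pathParams(delta = 0, topK = 10))
  expect_equal(pathList(ps0), list(c(1L, 2L, 3L)))

  # unreachable sinks are reported with component context
  disc <- makeTestGraph(4, data.frame(i = 1, j = 2, w = 1))
  expect_error(suboptimalPaths(disc, 1, 4, pathParams()), "no sink reachable")
})

test_that("enumeration equals the exhaustive oracle on random graphs", {
  for (seed in 1:40) {
    rg <- randomTestGraph(seed + 300)
    src <- 1; snk <- rg$n
    apd <- floydWarshall(rg$graph)
    lOpt <- as.matrix(apd)[src, snk]
    for (delta in c(0, 0.5, 2)) {
      ps <- suboptimalPaths(rg$graph, src, snk,
                            pathParams(delta = delta, topK = 1e6), apd)
      expect_identical(pathKeys(ps),
                       oraclePathSet(rg$n, rg$edges, src, snk, lOpt + delta))
      expect_equal(ps@countWithinCutoff, length(pathKeys(ps)))
    }
  }
})

test_that("the cutoff is monotone and edge strengthening shortens optima", {
  rg <- randomTestGraph(7)
  apd <- floydWarshall(rg$graph)
  psA <- suboptimalPaths(rg$graph, 1, rg$n, pathParams(delta = 0.5), apd)
  psB <- suboptimalPaths(rg$graph, 1, rg$n, pathParams(delta = 2), apd)
  expect_true(all(pathKeys(psA) %in% pathKeys(psB)))

  # lowering one edge weight never increases the optimal length
  for (r in seq_len(nrow(rg$edges))) {
    e2 <- rg$edges
    e2$w[r] <- e2$w[r] / 2
    g2 <- makeTestGraph(rg$n, e2)
    expect_lte(as.matrix(floydWarshall(g2))[1, rg$n],
               as.matrix(apd)[1, rg$n] + 1e-9)
  }
})

test_that("sink sets terminate paths at any member with the minimum optimum", {
  # chain 1-2-3-4 with sinks {3, 4}
  g <- makeTestGraph(4, data.frame(i = 1:3, j = 2:4, w = c(1, 1, 1)))
  ps <- suboptimalPaths(g, 1, c(3, 4), pathParams(delta = 10, topK = 10))
  expect_equal(ps@lOpt, 2)
  ends <- vapply(pathList(ps), function(p) p[length(p)], integer(1))
  expect_setequal(unique(ends), c(3L, 4L))
})

test_that("path statistics and reference comparisons follow the arithmetic", {
  tri <- makeTestGraph(3, data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                                     w = c(1, 1, 2.5)))
  ps <- suboptimalPaths(tri, 1, 3, pathParams(delta = 1, topK = 10))
  st <- pathStatistics(ps)
  expect_equal(st$countWithinCutoff, 2)
  expect_equal(st$meanLength, mean(c(2, 2.5)))

  top1 <- suboptimalPaths(tri, 1, 3, pathParams(delta = 1, topK = 1))
  expect_equal(pathStatistics(top1)$meanLength, 2)

  expect_equal(compareToReference(70, 100), -30)
  expect_equal(compareToReference(3000, 100), 2900)
  expect_equal(compareToReference(5, 5), 0)
  expect_error(compareToReference(1, 0), "zero")
})

test_that("the maxPaths safety bound sets the truncation flag", {
  # complete graph on 7 nodes has many simple paths between any pair
  pairs <- which(upper.tri(matrix(0, 7, 7)), arr.ind = TRUE)
  g <- makeTestGraph(7, data.frame(i = pairs[, 1], j = pairs[, 2], w = 1))
  ps <- suboptimalPaths(g, 1, 7, pathParams(delta = 10, topK = 5,
                                            maxPaths = 20))
  expect_true(ps@truncated)
  expect_lte(length(pathList(ps)), 5L)
})
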