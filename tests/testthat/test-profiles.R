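test_that("utilization percentages follow the path-membership counts", {
  # diamond: 1 -> {2, 3} -> 4 plus a direct shortcut, sink 4
  g <- makeTestGraph(4, data.frame(i = c(1, 2, 1, 3, 1),
                                   j = c(2, 4, 3, 4, 4),
                                   w = c(1, 1, 1, 1, 2.2)))
  ps <- suboptimalPaths(g, 1, 4, pathParams(delta = 1, topK = 10))
  # paths: 1-2-4 (2), 1-3-4 (2), 1-4 (2.2), 1-2-... none else simple
  u <- residueUtilization(ps)
  expect_equal(attr(u, "kEffective"), ps@countWithinCutoff)
  expect_equal(u$utilization[u$id == 2], 100 / 3, tolerance = 1e-9)
  expect_equal(u$utilization[u$id == 3], 100 / 3, tolerance = 1e-9)
  # source and sink are excluded from the table
  expect_false(any(u$id %in% c(1, 4)))

  # a node on every path reads 100%
  chain <- makeTestGraph(3, data.frame(i = 1:2, j = 2:3, w = c(1, 1)))
  pc <- suboptimalPaths(chain, 1, 3, pathParams(delta = 5, topK = 10))
  uc <- residueUtilization(pc)
  expect_equal(uc$utilization[uc$id == 2], 100)
})

test_that("utilization equals the exhaustive counting oracle", {
  for (seed in 1:15) {
    rg <- randomTestGraph(seed + 500)
    apd <- floydWarshall(rg$graph)
    lOpt <- as.matrix(apd)[1, rg$n]
    ps <- suboptimalPaths(rg$graph, 1, rg$n,
                          pathParams(delta = 1.5, topK = 1e6), apd)
    all <- oracleAllSimplePaths(rg$n, rg$edges, 1)
    ends <- vapply(all$paths, function(p) p[length(p)], integer(1))
    keep <- all$paths[ends == rg$n & all$lengths <= lOpt + 1.5 + 1e-9]
    counts <- tabulate(unlist(keep), nbins = rg$n)
    u <- residueUtilization(ps)
    for (r in seq_len(nrow(u)))
      expect_equal(u$utilization[r], 100 * counts[u$id[r]] / length(keep))
  }
})

test_that("utilization conserves total node visits exactly", {
  for (seed in c(2, 9, 17)) {
    rg <- randomTestGraph(seed + 700)
    ps <- suboptimalPaths(rg$graph, 1, rg$n,
                          pathParams(delta = 2, topK = 1000))
    u <- residueUtilization(ps)
    k <- attr(u, "kEffective")
    visits <- sum(u$utilization) * k / 100
    expected <- sum(vapply(pathList(ps)[seq_len(k)], function(p)
      sum(!p %in% c(ps@source, ps@sinks)), numeric(1)))
    expect_equal(round(visits), expected, tolerance = 1e-9)
  }
})

test_that("helix aggregates report traversal and mean residue utilization", {
  g <- makeTestGraph(4, data.frame(i = c(1, 2, 1, 3, 1),
                                   j = c(2, 4, 3, 4, 4),
                                   w = c(1, 1, 1, 1, 2.2)))
  ps <- suboptimalPaths(g, 1, 4, pathParams(delta = 1, topK = 10))
  ann <- data.frame(name = c("mid"), start = 2, end = 3)
  u <- residueUtilization(ps, helixAnnotation = ann)
  expect_equal(attr(u, "helixUtilization")[["mid"]], 200 / 3,
               tolerance = 1e-9)   # 2 of 3 paths touch residues 2-3
  expect_equal(attr(u, "helixMeanUtilization")[["mid"]], 100 / 3,
               tolerance = 1e-9)   # mean of the two 33.3% residues
})

test_that("shortest-distance profiles extract the source row in order", {
  g4 <- makeTestGraph(4, data.frame(i = c(1, 2, 1, 3, 1),
                                    j = c(2, 4, 3, 4, 4),
                                    w = c(1, 1, 1.5, 1.5, 5)))
  apd <- floydWarshall(g4)
  prof <- shortestDistanceProfile(apd, 1)
  expect_equal(prof$distance, c(0, 1, 1.5, 2))
  expect_equal(prof$distance[prof$id == 1], 0)

  # unreachable nodes surface as Inf and as empty TSV fields
  g3 <- makeTestGraph(3, data.frame(i = 1, j = 2, w = 1))
  prof3 <- shortestDistanceProfile(floydWarshall(g3), 1)
  expect_identical(prof3$distance[prof3$id == 3], Inf)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeProfileTSV(prof3, tsv)
  lines <- readLines(tsv)
  expect_true(any(grepl("\t$", lines[-1])))
})

test_that("profiles never lengthen when an edge is strengthened", {
  rg <- randomTestGraph(42)
  base <- shortestDistanceProfile(floydWarshall(rg$graph), 1)$distance
  for (r in seq_len(nrow(rg$edges))) {
    e2 <- rg$edges
    e2$w[r] <- e2$w[r] * 0.5
    d2 <- shortestDistanceProfile(floydWarshall(makeTestGraph(rg$n, e2)),
                                  1)$distance
    expect_true(all(d2 <= base + 1e-9))
  }
})

test_that("well detection finds planted minima and ignores monotone profiles", {
  mkProf <- function(vals) {
    data.frame(resid = seq_along(vals), distance = vals)
  }
  # V-shaped profile: one well at the vertex
  v <- mkProf(c(8:1, 2:8))
  w <- detectWells(v, window = 5, depth = 0.5)
  expect_equal(nrow(w), 1L)
  expect_equal(w$minResid, 8L)

  # monotone profile: no wells
  expect_equal(nrow(detectWells(mkProf(1:20), window = 5, depth = 0.5)), 0L)

  # two planted wells separated by a plateau
  prof <- mkProf(c(6, 6, 6, 2, 2, 6, 6, 6, 6, 6, 6, 3, 3, 6, 6, 6))
  w2 <- detectWells(prof, window = 5, depth = 0.5)
  expect_equal(nrow(w2), 2L)
  expect_equal(w2$startResid, c(4L, 12L))
  expect_equal(w2$endResid, c(5L, 13L))

  # absolute criterion: the shallow well is dropped when maxAbove binds
  w3 <- detectWells(prof, window = 5, depth = 0.5, maxAbove = 0.5)
  expect_equal(nrow(w3), 1L)
  expect_equal(w3$minResid, 4L)

  # a window wider than the profile is an error
  expect_error(detectWells(mkProf(1:5), window = 9), "window")
})
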