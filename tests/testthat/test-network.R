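twoNodeEnsemble <- function(dists) {
  atoms <- rbind(atomRow("CA", "C", 1, "ALA"), atomRow("CA", "C", 5, "ALA"))
  frames <- lapply(dists, function(d) rbind(c(0, 0, 0), c(d, 0, 0)))
  scriptedFrames(frames, atoms)
}

test_that("contact occupancy and the 75% threshold follow the stated rules", {
  nodes2 <- function(e) defineNodes(e, "protein")

  ens <- twoNodeEnsemble(rep(4, 10))
  cmap <- contactMap(ens, nodes2(ens))
  expect_equal(as.matrix(cmap)[1, 2], 1)
  expect_true(as.matrix(cmap, "adjacency")[1, 2])

  half <- twoNodeEnsemble(c(rep(4, 5), rep(6, 5)))
  cmap <- contactMap(half, nodes2(half))
  expect_equal(as.matrix(cmap)[1, 2], 0.5)
  expect_false(as.matrix(cmap, "adjacency")[1, 2])

  # occupancy exactly at the threshold is included
  atThr <- twoNodeEnsemble(c(rep(4, 3), 6))
  cmap <- contactMap(atThr, nodes2(atThr))
  expect_equal(as.matrix(cmap)[1, 2], 0.75)
  expect_true(as.matrix(cmap, "adjacency")[1, 2])

  # sequence neighbours are excluded despite permanent contact
  atoms <- rbind(atomRow("CA", "C", 10, "ALA"), atomRow("CA", "C", 11, "ALA"))
  neigh <- scriptedFrames(list(rbind(c(0, 0, 0), c(3.8, 0, 0)),
                               rbind(c(0, 0, 0), c(3.8, 0, 0))),
                          atoms)
  cmap <- contactMap(neigh, defineNodes(neigh, "protein"))
  expect_equal(as.matrix(cmap)[1, 2], 1)
  expect_false(as.matrix(cmap, "adjacency")[1, 2])
})

test_that("the ligand node is exempt from sequence-neighbour exclusion", {
  # ligand shares resid 1 with a protein residue on another chain; the
  # pair is held in permanent contact
  atoms <- rbind(atomRow("CA", "C", 1, "ALA"),
                 atomRow("C1", "C", 1, "LIG", chain = "L"))
  ens <- scriptedFrames(list(rbind(c(0, 0, 0), c(4, 0, 0)),
                             rbind(c(0, 0, 0), c(4, 0, 0))), atoms)
  nodes <- defineNodes(ens, "protein", "ligand")
  cmap <- contactMap(ens, nodes)
  expect_true(as.matrix(cmap, "adjacency")[1, 2])
})

test_that("contact map agrees with the exhaustive distance oracle", {
  spec <- syntheticSpec(2, 5, bundleSpacing = 5,
                        ligand = list(position = c(0, 0, 3)),
                        baseSD = 0.6, nFrames = 40, seed = 13)
  ens <- sampleTrajectory(spec)
  nodes <- defineNodes(ens, "protein", "ligand")
  cmap <- contactMap(ens, nodes)

  xyz <- coords(ens)
  mem <- nodeMembers(nodes)
  nn <- nNodes(nodes)
  occ <- matrix(0, nn, nn)
  for (i in seq_len(nn - 1)) for (j in (i + 1):nn) {
    hits <- 0
    for (f in seq_len(nFrames(ens))) {
      dmin <- Inf
      for (a in mem[[i]]) for (b in mem[[j]])
        dmin <- min(dmin, oracleDist(xyz, f, a, b))
      if (dmin <= 4.5) hits <- hits + 1
    }
    occ[i, j] <- occ[j, i] <- hits / nFrames(ens)
  }
  expect_equal(as.matrix(cmap), occ, tolerance = 1e-12)
})

test_that("filter monotonicity: thresholds only remove, cutoffs only add", {
  ens <- smallBundle(nFrames = 60, seed = 21)
  nodes <- defineNodes(ens, "protein")
  a1 <- as.matrix(contactMap(ens, nodes, occupancyThreshold = 0.5),
                  "adjacency")
  a2 <- as.matrix(contactMap(ens, nodes, occupancyThreshold = 0.9),
                  "adjacency")
  expect_true(all(a1 | !a2))          # raising threshold never adds edges
  c1 <- as.matrix(contactMap(ens, nodes, distanceCutoff = 4.5),
                  "adjacency")
  c2 <- as.matrix(contactMap(ens, nodes, distanceCutoff = 6.0),
                  "adjacency")
  expect_true(all(c2 | !c1))          # raising cutoff never removes edges
})

test_that("graph weights transform correlation as -log|C| with a cap", {
  atoms <- rbind(atomRow("CA", "C", 1, "ALA"), atomRow("CA", "C", 5, "ALA"),
                 atomRow("CA", "C", 9, "ALA"))
  frames <- lapply(1:4, function(f)
    rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)))   # edges 1-2 and 2-3 only
  ens <- scriptedFrames(frames, atoms)
  nodes <- defineNodes(ens, "protein")
  cmap <- contactMap(ens, nodes)

  mkC <- function(v12, v23) {
    C <- diag(3)
    C[1, 2] <- C[2, 1] <- v12
    C[2, 3] <- C[3, 2] <- v23
    new(Class = "CorrelationMatrix", C = C, labels = cmap@labels,
        nFrames = 4L, zeroVariance = rep(FALSE, 3))
  }
  g <- buildGraph(cmap, mkC(1, 0.5))
  e <- edgeTable(g)
  w <- function(i, j) e$weight[e$i == i & e$j == j]
  expect_equal(nrow(e), 2L)
  expect_equal(w(1, 2), 0)                       # -log 1
  expect_equal(w(2, 3), 0.6931, tolerance = 1e-4)

  gc <- buildGraph(cmap, mkC(1, 0))
  ec <- edgeTable(gc)
  expect_equal(ec$weight[ec$i == 2 & ec$j == 3], 20)  # |C| = 0 capped
  expect_true(ec$capped[ec$i == 2 & ec$j == 3])
  expect_false(any(ec$capped[ec$weight < 20]))

  # node-order mismatches are refused
  other <- mkC(1, 0.5)
  other@labels <- rev(other@labels)
  expect_error(buildGraph(cmap, other), "node order")
})

test_that("replicate averaging combines occupancy before adjacency", {
  # replicate 1 always in contact, replicate 2 never: averaged occupancy
  # 0.5 is below the threshold, so no edge survives
  always <- twoNodeEnsemble(rep(4, 10))
  never <- twoNodeEnsemble(rep(6, 10))
  nodes <- defineNodes(always, "protein")
  cmap <- contactMap(list(always, never), nodes)
  expect_equal(as.matrix(cmap)[1, 2], 0.5)
  expect_false(as.matrix(cmap, "adjacency")[1, 2])
})

test_that("averaged correlation matrices keep invariants and pool flags", {
  ens1 <- smallBundle(nFrames = 80, seed = 1)
  ens2 <- smallBundle(nFrames = 80, seed = 2)
  nodes <- defineNodes(ens1, "protein")
  c1 <- computeCorrelation(ens1, nodes)
  c2 <- computeCorrelation(ens2, nodes)
  avg <- averageCorrelation(list(c1, c2))
  expect_equal(as.matrix(avg),
               (as.matrix(c1) + as.matrix(c2)) / 2, tolerance = 1e-12)
  expect_equal(avg@nFrames, 160L)
})
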