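test_that("pair distances agree with coordinate arithmetic in all modes", {
  atoms <- rbind(atomRow("CA", "C", 1, "ALA"),
                 atomRow("CB", "C", 1, "ALA"),
                 atomRow("CA", "C", 5, "GLY"))
  frames <- list(rbind(c(0, 0, 0), c(2, 0, 0), c(3, 4, 0)),
                 rbind(c(0, 0, 0), c(2, 0, 0), c(0, 0, 7)))
  ens <- scriptedFrames(frames, atoms)

  d <- pairDistance(ens, "name CA and resid 1", "name CA and resid 5",
                    mode = "atom")
  expect_equal(d$distances, c(5, 7))
  expect_error(pairDistance(ens, "resid 1", "resid 5", mode = "atom"),
               "single-atom")

  # com of two unit-mass atoms at x = 0 and x = 2 against a point at the
  # midpoint x = 1
  atomsM <- rbind(atomRow("C1", "C", 1, "LIG"), atomRow("C2", "C", 1, "LIG"),
                  atomRow("CA", "C", 2, "ALA"))
  ensM <- scriptedFrames(list(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 0, 0))),
                         atomsM)
  dm <- pairDistance(ensM, "resid 1", "resid 2", mode = "com")
  expect_equal(dm$distances, 0)

  # mass weighting shifts the centre towards the heavy partner
  atomsW <- atomsM; atomsW$mass <- c(3, 1, 1)
  ensW <- scriptedFrames(list(rbind(c(0, 0, 0), c(2, 0, 0), c(0.5, 0, 0))),
                         atomsW)
  dw <- pairDistance(ensW, "resid 1", "resid 2", mode = "com")
  expect_equal(dw$distances, 0)
})

test_that("min-heavy distances yield the contact fraction", {
  atoms <- rbind(atomRow("C1", "C", 1, "LIG"),
                 atomRow("H1", "H", 1, "LIG"),
                 atomRow("CA", "C", 2, "PHE"))
  # hydrogen closer than the heavy atom: must be ignored
  frames <- c(lapply(1:80, function(f)
                rbind(c(4, 0, 0), c(1, 0, 0), c(0, 0, 0))),
              lapply(1:20, function(f)
                rbind(c(6, 0, 0), c(1, 0, 0), c(0, 0, 0))))
  ens <- scriptedFrames(frames, atoms)
  d <- pairDistance(ens, "resid 1", "resid 2", mode = "min_heavy")
  expect_equal(d$distances[1], 4)
  expect_equal(d$summary$contactFraction, 0.80)
})

test_that("hydrogen-bond occupancy applies inclusive distance and angle cutoffs", {
  frames <- c(lapply(1:97, function(f) hbondFrame(2.9, 170)),
              lapply(1:3, function(f) hbondFrame(5.0, 170)))
  ens <- scriptedFrames(frames, hbondAtoms())
  occ <- hbondOccupancy(ens, "name OD", "name OA", hydrogen = "name HD")
  expect_equal(occ, 0.97)

  # all frames far: zero occupancy
  far <- scriptedFrames(lapply(1:10, function(f) hbondFrame(5, 170)),
                        hbondAtoms())
  expect_equal(hbondOccupancy(far, "name OD", "name OA",
                              hydrogen = "name HD"), 0)

  # exactly at 3.0 A and 135 degrees counts (inclusive boundary)
  edge <- scriptedFrames(list(hbondFrame(3.0, 135)), hbondAtoms())
  expect_equal(hbondOccupancy(edge, "name OD", "name OA",
                              hydrogen = "name HD"), 1)

  # angle criterion requested without a hydrogen is an error
  expect_error(hbondOccupancy(edge, "name OD", "name OA",
                              requireAngle = TRUE),
               "distance-only")

  # monotonicity in the cutoffs
  mixed <- scriptedFrames(c(lapply(1:5, function(f) hbondFrame(2.8, 160)),
                            lapply(1:5, function(f) hbondFrame(3.3, 140))),
                          hbondAtoms())
  o1 <- hbondOccupancy(mixed, "name OD", "name OA", hydrogen = "name HD",
                       distanceCutoff = 3.0)
  o2 <- hbondOccupancy(mixed, "name OD", "name OA", hydrogen = "name HD",
                       distanceCutoff = 3.5)
  expect_lte(o1, o2)
  a1 <- hbondOccupancy(mixed, "name OD", "name OA", hydrogen = "name HD",
                       angleCutoff = 150)
  a2 <- hbondOccupancy(mixed, "name OD", "name OA", hydrogen = "name HD",
                       angleCutoff = 135)
  expect_lte(a1, a2)
})

test_that("ring centroid distances follow constructed geometry", {
  atoms <- rbind(phenylAtoms(340), phenylAtoms(370))
  mk <- function(c2) rbind(hexRing(c(0, 0, 0)), hexRing(c2))
  ens <- scriptedFrames(list(mk(c(5.8, 0, 0))), atoms)
  d <- ringDistance(ens, "resid 340", "resid 370")
  expect_equal(d$distances, 5.8, tolerance = 1e-12)

  coincident <- scriptedFrames(list(mk(c(0, 0, 0))), atoms)
  expect_equal(ringDistance(coincident, "resid 340",
                            "resid 370")$distances, 0)

  lifted <- scriptedFrames(list(mk(c(5.8, 0, 2))), atoms)
  expect_equal(ringDistance(lifted, "resid 340", "resid 370")$distances,
               sqrt(5.8^2 + 2^2), tolerance = 1e-12)

  # a missing ring atom is reported by name
  broken <- atoms[-3, ]
  ensB <- scriptedFrames(list(mk(c(5.8, 0, 0))[-3, ]), broken)
  expect_error(ringDistance(ensB, "resid 340", "resid 370"), "CD2")
})

test_that("distances are invariant under global rigid motion of a frame", {
  atoms <- rbind(phenylAtoms(340), phenylAtoms(370))
  base <- rbind(hexRing(c(0, 0, 0)), hexRing(c(5.8, 0, 0)))
  ens <- scriptedFrames(list(base, rigidMotion(base, 5)), atoms)
  d <- ringDistance(ens, "resid 340", "resid 370")
  expect_equal(d$distances[2], d$distances[1], tolerance = 1e-9)
})

test_that("named panels evaluate and aggregate across replicates", {
  atoms <- rbind(atomRow("CA", "C", 1, "ALA"), atomRow("CA", "C", 5, "GLY"))
  mkEns <- function() scriptedFrames(list(rbind(c(0, 0, 0), c(3, 4, 0))),
                                     atoms)
  panels <- list(
    span = list(type = "distance", selA = "resid 1", selB = "resid 5",
                mode = "atom"),
    hb = list(type = "hbond", donor = "resid 1", acceptor = "resid 5"))
  rep <- namedPanels(list(mkEns(), mkEns()), panels)
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$mean[rep$panel == "span"], 5)
  expect_equal(rep$sd, c(0, 0))
  expect_equal(rep$mean[rep$panel == "hb"], 0)   # 5 A > 3 A cutoff

  expect_warning(empty <- namedPanels(mkEns(), list()), "empty")
  expect_equal(nrow(empty), 0L)

  expect_error(namedPanels(mkEns(), list(bad = list(type = "distance",
                                                    selA = "resid 1",
                                                    selB = "resid 99",
                                                    mode = "atom"))),
               "bad")
})
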