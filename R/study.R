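#' Planted-coupling rerouting study: the bundled desk-scale experiment
#'
#' A three-helix bundle plus ligand that reproduces, at desk scale, the
#' rerouting mechanism by which a ligand that strengthens coupling
#' between two helices redirects communication through them: a "sink"
#' helix S carrying the distal sink residue, a helix playing the H5
#' role, and a helix playing the H7 role that the ligand contacts
#' directly.  The ligand sits outside the bundle against the S/H7
#' interface, so its only *contacts* are S and H7 — the H5 route exists
#' purely through H7, exactly the coupled-helix relay under study.
#'
#' The coupling strength `rho` applies to both ligand-H7 and H5-H7
#' blocks (the pair the mechanism sweeps); all other couplings are
#' fixed: 0.9 within helices, S-H5 0.30, S-H7 0.40, S-ligand 0.15, and
#' H5-ligand 0.55 (the latter has no geometric contact and therefore
#' produces no edge; it is held at a value that keeps the implied node
#' correlation positive semidefinite across the sweep).
#'
#' Geometry uses the generator defaults (rise 1.5 A, radius 2.3 A,
#' twist 100 deg) with helix axes 4.8 A apart so that inter-helix
#' C-alpha contact ladders percolate, and per-node fluctuation 0.25 A
#' so the contact topology is stable across seeds.
#'
#' @param rho swept coupling in [0, 0.85]: correlation planted between
#'   ligand and H7 and between H5 and H7.
#' @param seed integer seed.
#' @param nFrames frames per trajectory (default 3000).
#' @param residuesPerHelix default 12.
#' @return a [syntheticSpec()].
#' @seealso [runCouplingStudy()]
#' @export
couplingStudySpec <- function(rho, seed, nFrames = 3000,
                              residuesPerHelix = 12L) {
  stopifnot(rho >= 0, rho <= 0.85)
  cp <- diag(0.9, 4)
  cp[1, 2] <- cp[2, 1] <- 0.30   # S - H5
  cp[1, 3] <- cp[3, 1] <- 0.40   # S - H7
  cp[2, 3] <- cp[3, 2] <- rho    # H5 - H7 (swept)
  cp[1, 4] <- cp[4, 1] <- 0.15   # S - ligand
  cp[2, 4] <- cp[4, 2] <- 0.55   # H5 - ligand (no contact; PSD anchor)
  cp[3, 4] <- cp[4, 3] <- rho    # ligand - H7 (swept)
  cp[4, 4] <- 1
  spacing <- 4.8
  ringR <- spacing / (2 * sin(pi / 3))
  a <- 300 * pi / 180            # exterior bisector of the S/H7 interface
  pos <- c((ringR + 2.6) * cos(a), (ringR + 2.6) * sin(a),
           1.5 * (residuesPerHelix - 1) * 0.35)
  syntheticSpec(nHelices = 3, residuesPerHelix = residuesPerHelix,
                bundleSpacing = spacing, baseSD = 0.25,
                ligand = list(position = pos), nFrames = nFrames,
                seed = seed, coupling = cp)
}

#' Helix annotation of the rerouting study bundle
#'
#' @param residuesPerHelix as passed to [couplingStudySpec()].
#' @return data.frame with `name`, `start`, `end` for the S, H5 and H7
#'   blocks (contiguous residue numbering along the single chain).
#' @export
couplingStudyHelices <- function(residuesPerHelix = 12L) {
  n <- residuesPerHelix
  data.frame(name = c("S", "H5", "H7"),
             start = c(1L, n + 1L, 2L * n + 1L),
             end = c(n, 2L * n, 3L * n))
}

#' Run one arm of the planted-coupling rerouting study
#'
#' Samples the ensemble, builds the correlation-weighted contact
#' network, enumerates ligand-to-sink suboptimal paths (delta = 3 above
#' the optimum, top 25 retained), and summarises H5 involvement and the
#' shortest-distance profile.  The sink is the residue two positions
#' below the top of the sink helix, which has robust contact-ladder
#' entries from both the H5 and the H7 side.
#'
#' @param rho,seed,nFrames,residuesPerHelix see [couplingStudySpec()].
#' @param delta,topK path enumeration parameters (defaults 3 and 25:
#'   generous enough to include the competing route family on a
#'   ~40-node graph).
#' @return a list: `lOpt`, `pathCount`, `meanLength`,
#'   `h5Traversal` (percent of top-k paths touching H5),
#'   `h5MeanUtilization` (mean per-residue utilization over the H5
#'   block), `wells` (detected with window 7, depth 0.3, maxAbove 1),
#'   `h5Well` (logical: some well minimum lies in the H5 block),
#'   `profile`, `nEdges`.
#' @export
runCouplingStudy <- function(rho, seed, nFrames = 3000,
                             residuesPerHelix = 12L, delta = 3,
                             topK = 25L) {
  spec <- couplingStudySpec(rho, seed, nFrames, residuesPerHelix)
  ens <- sampleTrajectory(spec)
  nodes <- defineNodes(ens, "protein", "ligand")
  corr <- computeCorrelation(ens, nodes)
  graph <- buildGraph(contactMap(ens, nodes), corr)
  n <- nNodes(graph)
  sinkLabel <- sprintf("A:ALA:%d", residuesPerHelix - 2L)
  apd <- floydWarshall(graph)
  ps <- suboptimalPaths(graph, n, sinkLabel,
                        pathParams(delta = delta, topK = topK), apd)
  st <- pathStatistics(ps)
  ann <- couplingStudyHelices(residuesPerHelix)
  util <- residueUtilization(ps, helixAnnotation = ann)
  prof <- shortestDistanceProfile(apd, n)
  finite <- prof[prof$chain == "A" & is.finite(prof$distance), ,
                 drop = FALSE]
  wells <- detectWells(finite, window = 7L, depth = 0.3, maxAbove = 1)
  h5 <- ann[ann$name == "H5", ]
  list(lOpt = st$lOpt, pathCount = st$countWithinCutoff,
       meanLength = st$meanLength,
       h5Traversal = attr(util, "helixUtilization")[["H5"]],
       h5MeanUtilization = attr(util, "helixMeanUtilization")[["H5"]],
       wells = wells,
       h5Well = any(wells$minResid >= h5$start & wells$minResid <= h5$end),
       profile = prof, nEdges = nrow(edgeTable(graph)))
}
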