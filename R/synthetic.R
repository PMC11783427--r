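#' SyntheticSpec: parametric description of a planted-correlation ensemble
#'
#' Describes a helical-bundle toy system whose C-alpha fluctuations carry a
#' known block correlation structure, so that every downstream stage
#' (correlation, contact map, weighted graph, path enumeration, profiles)
#' can be validated against exact oracles without molecular dynamics
#' trajectories.  Blocks are the helices plus, optionally, a single-node
#' ligand with rigid pseudo-atoms.
#'
#' Fluctuations are rank-1 per node: a scalar latent drawn from a
#' zero-mean multivariate normal with the block correlation, scaled by
#' `baseSD` and applied along a fluctuation axis.  With the default
#' `directionMode = "shared"` every node fluctuates along one common
#' seeded random axis, which makes the node-node correlation of the
#' fluctuation *vectors* analytically equal to the latent correlation
#' (with independent per-node axes it would be attenuated by the cosine
#' between axes; that mode is available as `"per-node"` for stress
#' testing, but it has no exact correlation oracle).
#'
#' @param nHelices number of helices in the bundle.
#' @param residuesPerHelix residues (one C-alpha each) per helix.
#' @param helixRise rise per residue along the helix axis (Angstrom).
#' @param helixRadius C-alpha circle radius (Angstrom).
#' @param twist rotation per residue (degrees).
#' @param bundleSpacing separation between adjacent helix axes (Angstrom).
#'   Helices sit on a ring of radius `bundleSpacing / (2 sin(pi/nHelices))`
#'   so adjacent axes are exactly `bundleSpacing` apart.
#' @param ligand `NULL` for no ligand, or a list with optional elements
#'   `position` (3-vector, Angstrom; default the bundle axis at
#'   mid-height) and `nPseudoAtoms` (default 5, placed within 1.5 Angstrom
#'   of the position and moving rigidly with the ligand node).
#' @param baseSD per-node fluctuation standard deviation (Angstrom).
#' @param coupling symmetric `nBlocks x nBlocks` matrix of target
#'   correlations in (-1, 1]; blocks are helices 1..nHelices then the
#'   ligand.  Off-diagonal entry (a, b) is the planted correlation between
#'   any node of block a and any node of block b; the *diagonal* entry
#'   (a, a) is the planted correlation between two distinct nodes of the
#'   same block (each node always has self-correlation 1).  Default:
#'   0.9 within helices, 0 between blocks.
#' @param nFrames frames to sample.
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   ensemble.
#' @param directionMode `"shared"` (default) or `"per-node"`; see Details.
#' @return an object of class `SyntheticSpec`.
#' @seealso [buildMeanStructure()], [sampleTrajectory()]
#' @export
syntheticSpec <- function(nHelices, residuesPerHelix, helixRise = 1.5,
                          helixRadius = 2.3, twist = 100,
                          bundleSpacing = 10, ligand = NULL, baseSD = 0.5,
                          coupling = NULL, nFrames = 100, seed = 1L,
                          directionMode = c("shared", "per-node")) {
  directionMode <- match.arg(directionMode)
  nBlocks <- nHelices + as.integer(!is.null(ligand))
  if (is.null(coupling)) {
    coupling <- diag(0.9, nBlocks)
    if (!is.null(ligand)) coupling[nBlocks, nBlocks] <- 1
  }
  if (!is.null(ligand)) {
    ligand <- utils::modifyList(
      list(position = NULL, nPseudoAtoms = 5L), ligand)
  }
  new("SyntheticSpec", nHelices = as.integer(nHelices),
      residuesPerHelix = as.integer(residuesPerHelix),
      helixRise = helixRise, helixRadius = helixRadius, twist = twist,
      bundleSpacing = bundleSpacing,
      ligand = if (is.null(ligand)) list() else ligand,
      baseSD = baseSD, coupling = coupling,
      nFrames = as.integer(nFrames), seed = as.integer(seed),
      directionMode = directionMode)
}

#' @rdname syntheticSpec
#' @slot nHelices,residuesPerHelix,helixRise,helixRadius,twist,bundleSpacing
#'   bundle geometry; see the constructor.
#' @slot ligand list (empty for no ligand).
#' @slot baseSD,coupling,nFrames,seed,directionMode sampling parameters.
#' @export
setClass("SyntheticSpec",
  representation(nHelices = "integer", residuesPerHelix = "integer",
                 helixRise = "numeric", helixRadius = "numeric",
                 twist = "numeric", bundleSpacing = "numeric",
                 ligand = "list", baseSD = "numeric", coupling = "matrix",
                 nFrames = "integer", seed = "integer",
                 directionMode = "character"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nHelices < 1L) msg <- c(msg, "nHelices must be >= 1")
  if (object@residuesPerHelix < 1L)
    msg <- c(msg, "residuesPerHelix must be >= 1")
  nBlocks <- object@nHelices + as.integer(length(object@ligand) > 0)
  cp <- object@coupling
  if (!all(dim(cp) == nBlocks))
    msg <- c(msg, sprintf("coupling must be %d x %d (helices%s)",
                          nBlocks, nBlocks,
                          if (length(object@ligand)) " + ligand" else ""))
  else {
    if (max(abs(cp - t(cp))) > 1e-12) msg <- c(msg, "coupling must be symmetric")
    if (any(cp <= -1) || any(cp > 1))
      msg <- c(msg, "coupling entries must lie in (-1, 1]")
    ev <- tryCatch(min(eigen(.nodeCorrelation(object), symmetric = TRUE,
                             only.values = TRUE)$values),
                   error = function(e) NA_real_)
    if (is.na(ev) || ev < -1e-8)
      msg <- c(msg, sprintf(
        "implied node correlation matrix is not positive semidefinite (smallest eigenvalue %.3g)",
        ev))
  }
  if (object@baseSD <= 0) msg <- c(msg, "baseSD must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d helix(es) x %d residues%s, %d frames, seed %d\n",
    object@nHelices, object@residuesPerHelix,
    if (length(object@ligand)) " + ligand" else "",
    object@nFrames, object@seed))
})

# block index of every node (helices 1..H, ligand = H + 1), ligand last
.nodeBlocks <- function(spec) {
  blocks <- rep(seq_len(spec@nHelices), each = spec@residuesPerHelix)
  if (length(spec@ligand)) blocks <- c(blocks, spec@nHelices + 1L)
  blocks
}

# node-level correlation matrix implied by the block coupling
.nodeCorrelation <- function(spec) {
  blocks <- .nodeBlocks(spec)
  C <- spec@coupling[blocks, blocks, drop = FALSE]
  diag(C) <- 1
  C
}

#' Build the mean (reference) structure of a synthetic spec
#'
#' Places one C-alpha per residue on an ideal helix
#' `(r cos(theta_i), r sin(theta_i), rise * i)` in each helix's local
#' frame, arranges the helix axes on a ring so adjacent axes are
#' `bundleSpacing` apart, and adds the ligand pseudo-atoms if requested.
#' The mean structure depends only on the geometry fields, never on the
#' seed.
#'
#' @param spec a [syntheticSpec()].
#' @return a single-frame [Ensemble].
#' @export
buildMeanStructure <- function(spec) {
  validObject(spec)
  H <- spec@nHelices; n <- spec@residuesPerHelix
  ringR <- if (H >= 2) spec@bundleSpacing / (2 * sin(pi / H)) else 0
  xyz <- matrix(0, H * n, 3)
  for (h in seq_len(H)) {
    phi <- 2 * pi * (h - 1) / H
    center <- ringR * c(cos(phi), sin(phi), 0)
    i <- seq_len(n) - 1
    theta <- spec@twist * pi / 180 * i
    local <- cbind(spec@helixRadius * cos(theta),
                   spec@helixRadius * sin(theta),
                   spec@helixRise * i)
    xyz[(h - 1) * n + seq_len(n), ] <- sweep(local, 2, center, `+`)
  }
  atoms <- data.frame(
    name = "CA", element = "C", mass = 1,
    resid = seq_len(H * n), resname = "ALA", chain = "A",
    isHeavy = TRUE, stringsAsFactors = FALSE)
  if (length(spec@ligand)) {
    pos <- spec@ligand$position
    if (is.null(pos))
      pos <- c(0, 0, spec@helixRise * (n - 1) / 2)
    k <- spec@ligand$nPseudoAtoms
    off <- .ligandOffsets(k)
    xyz <- rbind(xyz, sweep(off, 2, pos, `+`))
    atoms <- rbind(atoms, data.frame(
      name = paste0("C", seq_len(k)), element = "C", mass = 1,
      resid = 1L, resname = "LIG", chain = "L", isHeavy = TRUE,
      stringsAsFactors = FALSE))
  }
  coords <- array(0, dim = c(1L, nrow(atoms), 3L))
  coords[1L, , ] <- xyz
  new("Ensemble", atoms = atoms, coords = coords,
      provenance = list(source = "synthetic mean structure",
                        aligned = TRUE))
}

# deterministic pseudo-atom offsets, all within 1.5 A of the placement
.ligandOffsets <- function(k) {
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(-0.5, 0.866, 0),
                c(-0.5, -0.866, 0), c(0, 0, 1), c(0, 0, -1),
                c(0, 1, 0.5), c(0, -1, 0.5))
  if (k > nrow(base)) stop("at most ", nrow(base), " ligand pseudo-atoms")
  base[seq_len(k), , drop = FALSE]
}

#' Sample a trajectory with the planted correlation structure
#'
#' Draws per-node scalar latents from a zero-mean multivariate normal
#' whose correlation is implied by the spec's block coupling, scales them
#' by `baseSD`, and applies them along the fluctuation axis (shared by
#' default; see [syntheticSpec()]).  Ligand pseudo-atoms move rigidly
#' with the ligand node.  Fluctuation axes are drawn from the seeded
#' stream before any frame is sampled, so changing `nFrames` does not
#' change them.  The resulting ensemble fluctuates about a fixed mean and
#' is therefore already aligned.
#'
#' @param spec a [syntheticSpec()]; `nFrames` must be at least 2 (no
#'   fluctuation is definable from a single frame).
#' @return an [Ensemble] with `spec@nFrames` frames; bit-identical for
#'   identical spec + seed.
#' @export
sampleTrajectory <- function(spec) {
  validObject(spec)
  if (spec@nFrames < 2L)
    stop("nFrames must be >= 2: no fluctuations are definable from ",
         spec@nFrames, " frame")
  mean_ens <- buildMeanStructure(spec)
  meanXYZ <- coords(mean_ens, frame = 1L)
  atoms <- atomTable(mean_ens)
  blocks <- .nodeBlocks(spec)
  nNode <- length(blocks)
  Cnode <- .nodeCorrelation(spec)
  ed <- eigen(Cnode, symmetric = TRUE)
  L <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), nNode)

  out <- .withSeed(spec@seed, {
    # axes first (fixed per spec+seed, independent of nFrames)
    if (spec@directionMode == "shared") {
      u <- matrix(.randomUnit(1), nNode, 3, byrow = TRUE)
    } else {
      u <- .randomUnit(nNode)
    }
    Z <- matrix(stats::rnorm(spec@nFrames * nNode), spec@nFrames, nNode)
    list(u = u, latents = Z %*% t(L))
  })

  # map node displacement onto atoms (ligand pseudo-atoms move rigidly)
  nodeOfAtom <- integer(nrow(atoms))
  isLig <- atoms$resname == "LIG"
  nodeOfAtom[!isLig] <- seq_len(sum(!isLig))
  if (any(isLig)) nodeOfAtom[isLig] <- nNode

  coords <- array(0, dim = c(spec@nFrames, nrow(atoms), 3L))
  disp <- spec@baseSD * out$latents            # frames x nodes
  for (ax in 1:3) {
    dAx <- disp * rep(out$u[, ax], each = spec@nFrames)   # frames x nodes
    coords[, , ax] <- rep(meanXYZ[, ax], each = spec@nFrames) +
      dAx[, nodeOfAtom, drop = FALSE]
  }
  new("Ensemble", atoms = atoms, coords = coords,
      provenance = list(source = "synthetic trajectory", seed = spec@seed,
                        spec = spec, aligned = TRUE))
}

# uniformly distributed unit vectors, n x 3
.randomUnit <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# run expr under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build an ensemble from explicitly scripted frames
#'
#' Fixture builder for geometry tests: the per-frame coordinates are used
#' exactly as given, so distances, angles and occupancies downstream equal
#' the scripted values with no sampling error.
#'
#' @param frames list of `n_atoms x 3` coordinate matrices (Angstrom),
#'   one per frame; every frame must place the same atom set.
#' @param atoms atom table data.frame with columns `name`, `element`,
#'   `resid`, `resname`, `chain` (and optionally `mass`); `mass` defaults
#'   to 1 and `isHeavy` is derived from the element.
#' @return an [Ensemble] with `length(frames)` frames.
#' @export
scriptedFrames <- function(frames, atoms) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  dims <- vapply(frames, function(f) dim(as.matrix(f)), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != 3L))
    stop("inconsistent atom sets across frames: every frame must be an ",
         dims[1, 1], " x 3 matrix")
  atoms <- .completeAtomTable(atoms)
  if (nrow(atoms) != dims[1, 1])
    stop("atom table has ", nrow(atoms), " rows but frames place ",
         dims[1, 1], " atoms")
  coords <- array(0, dim = c(length(frames), nrow(atoms), 3L))
  for (f in seq_along(frames)) coords[f, , ] <- as.matrix(frames[[f]])
  new("Ensemble", atoms = atoms, coords = coords,
      provenance = list(source = "scripted frames", aligned = TRUE))
}

.completeAtomTable <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("name", "element", "resid", "resname", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$mass)) atoms$mass <- 1
  atoms$isHeavy <- atoms$element != "H"
  atoms$resid <- as.integer(atoms$resid)
  atoms[c("name", "element", "mass", "resid", "resname", "chain", "isHeavy")]
}
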