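#' @import methods
NULL

#' Ensemble: a multi-frame coordinate set with a shared atom table
#'
#' The central container of the package: `n_frames x n_atoms x 3` Cartesian
#' coordinates (Angstrom) plus a per-atom table shared by every frame.
#' Ensembles come from [loadEnsemble()] (PDB / multi-model PDB / DCD),
#' from the synthetic generator ([sampleTrajectory()]), or from
#' [scriptedFrames()] for exact geometric fixtures.
#'
#' @slot atoms data.frame with columns `name`, `element`, `mass`, `resid`,
#'   `resname`, `chain`, `isHeavy` (one row per atom; identical across
#'   frames).
#' @slot coords numeric array, dim `c(nFrames, nAtoms, 3)`, Angstrom.
#' @slot provenance list recording the source (files, or a
#'   [SyntheticSpec] plus seed) and processing steps (stride, stripping,
#'   alignment).
#' @export
setClass("Ensemble",
  representation(atoms = "data.frame", coords = "array",
                 provenance = "list"))

setValidity("Ensemble", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "coords must be an n_frames x n_atoms x 3 array")
  else {
    if (d[1] < 1L) msg <- c(msg, "at least one frame required")
    if (d[2] != nrow(object@atoms))
      msg <- c(msg, sprintf("coords has %d atoms but atom table has %d rows",
                            d[2], nrow(object@atoms)))
  }
  if (!all(is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  need <- c("name", "element", "mass", "resid", "resname", "chain", "isHeavy")
  miss <- setdiff(need, names(object@atoms))
  if (length(miss))
    msg <- c(msg, paste("atom table missing columns:",
                        paste(miss, collapse = ", ")))
  if (!length(miss) &&
      !identical(object@atoms$isHeavy, object@atoms$element != "H"))
    msg <- c(msg, "isHeavy flag must equal (element != 'H')")
  if (length(msg)) msg else TRUE
})

#' NodeSet: the network nodes of an ensemble
#'
#' One node per protein residue (represented by its C-alpha), one node for
#' the ligand (represented by the geometric centroid of its heavy atoms),
#' and one node per coregulator-peptide residue.  Member sets hold the
#' heavy atoms used by contact-map construction.
#'
#' @slot nodes data.frame with columns `id` (1-based, contiguous), `kind`
#'   (`"residue"`, `"ligand"` or `"peptide-residue"`), `resid`, `resname`,
#'   `chain`, `label` (chain:resname:resid), `repAtom` (C-alpha atom index,
#'   `NA` for centroid-represented ligand nodes).
#' @slot members list of integer vectors: heavy-atom indices per node
#'   (pairwise disjoint).
#' @export
setClass("NodeSet",
  representation(nodes = "data.frame", members = "list"))

setValidity("NodeSet", function(object) {
  msg <- character()
  n <- nrow(object@nodes)
  if (length(object@members) != n)
    msg <- c(msg, "one member set per node required")
  if (n && !identical(object@nodes$id, seq_len(n)))
    msg <- c(msg, "node ids must be 1..n_nodes")
  all_members <- unlist(object@members)
  if (anyDuplicated(all_members))
    msg <- c(msg, "node member sets must be disjoint")
  if (any(lengths(object@members) == 0L))
    msg <- c(msg, "every node needs at least one member atom")
  if (length(msg)) msg else TRUE
})

#' CorrelationMatrix: normalized cross-correlation of node fluctuations
#'
#' `C[i, j] = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)` over frames,
#' where `dr` is the deviation of the node representative (C-alpha or
#' ligand centroid) from its time mean.
#'
#' @slot C numeric matrix, symmetric, unit diagonal, entries in [-1, 1].
#' @slot labels character node labels (chain:resname:resid).
#' @slot nFrames integer, frames used.
#' @slot zeroVariance logical per node: TRUE where a node never moved
#'   (its off-diagonal correlations are set to 0 and it is excluded from
#'   network edges).
#' @export
setClass("CorrelationMatrix",
  representation(C = "matrix", labels = "character", nFrames = "integer",
                 zeroVariance = "logical"))

setValidity("CorrelationMatrix", function(object) {
  msg <- character()
  C <- object@C
  if (nrow(C) != ncol(C)) msg <- c(msg, "C must be square")
  if (length(object@labels) != nrow(C))
    msg <- c(msg, "one label per node required")
  if (nrow(C)) {
    if (max(abs(diag(C) - 1)) > 1e-9 &&
        !all(object@zeroVariance[abs(diag(C) - 1) > 1e-9]))
      msg <- c(msg, "diagonal must be 1 (except flagged zero-variance nodes)")
    if (max(abs(C - t(C))) > 1e-9) msg <- c(msg, "C must be symmetric")
    if (max(abs(C)) > 1 + 1e-9) msg <- c(msg, "entries must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' ContactMap: per-pair contact occupancy and the filtered adjacency
#'
#' Nodes i, j are "in contact" in a frame when the minimum heavy-atom
#' distance between their member sets is at most `distanceCutoff`;
#' occupancy is the fraction of frames in contact.  The adjacency keeps
#' pairs with occupancy >= `occupancyThreshold`, excluding sequence
#' neighbours (|resid_i - resid_j| <= `neighborExclusion` on the same
#' chain); ligand and peptide nodes are never sequence neighbours of
#' protein nodes.
#'
#' @slot occupancy numeric matrix (symmetric, zero diagonal).
#' @slot adjacency logical matrix.
#' @slot params list: `distanceCutoff` (Angstrom, default 4.5),
#'   `occupancyThreshold` (default 0.75), `neighborExclusion` (default 1).
#' @slot labels character node labels.
#' @export
setClass("ContactMap",
  representation(occupancy = "matrix", adjacency = "matrix",
                 params = "list", labels = "character"))

setValidity("ContactMap", function(object) {
  msg <- character()
  occ <- object@occupancy
  if (any(dim(occ) != dim(object@adjacency)))
    msg <- c(msg, "occupancy and adjacency dimensions differ")
  if (nrow(occ)) {
    if (max(abs(occ - t(occ))) > 1e-12) msg <- c(msg, "occupancy not symmetric")
    if (any(diag(occ) != 0)) msg <- c(msg, "occupancy diagonal must be zero")
    if (min(occ) < 0 || max(occ) > 1)
      msg <- c(msg, "occupancy must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' WeightedGraph: the correlation-weighted communication network
#'
#' Edges exist only where the contact-map adjacency is TRUE; the weight is
#' `-log(|C_ij|)` (so strong correlation gives a short edge), capped at
#' `wCap` when the correlation is 0 or the transform exceeds the cap.
#'
#' @slot nodes data.frame carried over from the [NodeSet] (`id`, `kind`,
#'   `resid`, `resname`, `chain`, `label`).
#' @slot edges data.frame: `i`, `j` (node ids, i < j), `occupancy`,
#'   `correlation`, `weight`, `capped` (logical).
#' @slot wCap numeric weight cap (default 20).
#' @export
setClass("WeightedGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 wCap = "numeric"))

setValidity("WeightedGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (nrow(e)) {
    if (any(e$weight < 0) || any(!is.finite(e$weight)))
      msg <- c(msg, "edge weights must be finite and non-negative")
    if (any(e$i >= e$j)) msg <- c(msg, "edges must be stored with i < j")
    n <- nrow(object@nodes)
    if (any(e$i < 1L) || any(e$j > n))
      msg <- c(msg, "edge endpoints out of range")
  }
  if (length(msg)) msg else TRUE
})

#' AllPairsDistances: optimal path lengths between every node pair
#'
#' Computed by Floyd-Warshall on the [WeightedGraph]; `Inf` marks
#' unreachable pairs.  The next-hop matrix allows reconstruction of one
#' optimal path per pair.
#'
#' @slot D numeric matrix of optimal path lengths (zero diagonal,
#'   symmetric for the undirected graphs built here).
#' @slot nextHop integer matrix: `nextHop[i, j]` is the node after `i` on
#'   an optimal i -> j path (`NA` if unreachable).
#' @slot labels character node labels.
#' @export
setClass("AllPairsDistances",
  representation(D = "matrix", nextHop = "matrix", labels = "character"))

setValidity("AllPairsDistances", function(object) {
  msg <- character()
  D <- object@D
  if (nrow(D) != ncol(D)) msg <- c(msg, "D must be square")
  if (nrow(D) && any(diag(D) != 0)) msg <- c(msg, "diagonal of D must be 0")
  if (nrow(D) && any(D < 0)) msg <- c(msg, "distances must be non-negative")
  if (length(msg)) msg else TRUE
})

#' PathSet: bounded enumeration of source-to-sink communication paths
#'
#' All simple paths whose length (sum of edge weights) is within `delta`
#' of the optimal length, enumerated by branch-and-bound depth-first
#' search.  The optimal path is included.  The `topK` shortest are
#' retained for utilization profiles; ties are broken by lexicographic
#' node sequence so the retained set is deterministic.
#'
#' @slot source integer node id.
#' @slot sinks integer node ids (paths may end at any of them).
#' @slot paths list of integer node-id vectors, sorted by non-decreasing
#'   length (ties lexicographic).
#' @slot lengths numeric path lengths, aligned with `paths`.
#' @slot lOpt numeric optimal length.
#' @slot countWithinCutoff numeric count of simple paths with length
#'   <= lOpt + delta (equals the enumerated total unless truncated).
#' @slot truncated logical: TRUE if the `maxPaths` safety bound was hit.
#' @slot delta,topK,maxPaths the [PathParams] used.
#' @slot labels character node labels.
#' @export
setClass("PathSet",
  representation(source = "integer", sinks = "integer", paths = "list",
                 lengths = "numeric", lOpt = "numeric",
                 countWithinCutoff = "numeric", truncated = "logical",
                 delta = "numeric", topK = "integer", maxPaths = "numeric",
                 labels = "character"))

setValidity("PathSet", function(object) {
  msg <- character()
  if (length(object@paths) != length(object@lengths))
    msg <- c(msg, "one length per path required")
  if (length(object@paths)) {
    if (is.unsorted(object@lengths)) msg <- c(msg, "lengths must be sorted")
    starts <- vapply(object@paths, `[`, integer(1), 1L)
    ends <- vapply(object@paths, function(p) p[length(p)], integer(1))
    if (any(starts != object@source))
      msg <- c(msg, "every path must start at the source")
    if (!all(ends %in% object@sinks))
      msg <- c(msg, "every path must end at a sink")
    if (any(vapply(object@paths, anyDuplicated, integer(1)) > 0L))
      msg <- c(msg, "paths must be simple (no repeated node)")
    if (!object@truncated &&
        abs(object@lengths[1] - object@lOpt) > 1e-9)
      msg <- c(msg, "first path must have the optimal length")
    if (any(object@lengths > object@lOpt + object@delta + 1e-9))
      msg <- c(msg, "retained lengths must be within the cutoff")
  }
  if (length(msg)) msg else TRUE
})
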