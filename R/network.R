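#' Contact map: heavy-atom distance and occupancy filtering
#'
#' Two nodes are "in contact" in a frame when the minimum distance over
#' their heavy-atom member pairs is at most `distanceCutoff` (4.5
#' Angstrom by default); the occupancy of a pair is the fraction of
#' frames in contact.  The adjacency keeps pairs whose occupancy reaches
#' `occupancyThreshold` (inclusive, 0.75 by default), excluding sequence
#' neighbours — same-chain residue nodes with
#' `|resid_i - resid_j| <= neighborExclusion` — while ligand and peptide
#' nodes are never sequence neighbours of protein nodes.
#'
#' When a list of ensembles (replicate trajectories) is given, occupancy
#' is computed per replicate and averaged, and the adjacency is applied
#' to the averaged occupancy.
#'
#' @param ensemble an [Ensemble], or a list of replicate ensembles
#'   sharing the atom table.
#' @param nodes a [NodeSet].
#' @param distanceCutoff,occupancyThreshold,neighborExclusion the
#'   filtering parameters.
#' @return a [ContactMap].
#' @export
contactMap <- function(ensemble, nodes, distanceCutoff = 4.5,
                       occupancyThreshold = 0.75, neighborExclusion = 1L) {
  ensembles <- if (is.list(ensemble)) ensemble else list(ensemble)
  occ <- NULL
  for (e in ensembles) {
    o <- .occupancyMatrix(e, nodes, distanceCutoff)
    occ <- if (is.null(occ)) o else occ + o
  }
  occ <- occ / length(ensembles)

  tab <- nodeTable(nodes)
  nn <- nrow(tab)
  adjacency <- occ >= occupancyThreshold
  isRes <- tab$kind %in% c("residue", "peptide-residue")
  sameChain <- outer(tab$chain, tab$chain, `==`)
  neigh <- abs(outer(tab$resid, tab$resid, `-`)) <= neighborExclusion
  excl <- outer(isRes, isRes, `&`) & sameChain & neigh
  adjacency[excl] <- FALSE
  diag(adjacency) <- FALSE

  new("ContactMap", occupancy = occ, adjacency = adjacency,
      params = list(distanceCutoff = distanceCutoff,
                    occupancyThreshold = occupancyThreshold,
                    neighborExclusion = as.integer(neighborExclusion)),
      labels = tab$label)
}

.occupancyMatrix <- function(ensemble, nodes, cutoff) {
  xyz <- coords(ensemble)
  mem <- nodeMembers(nodes)
  if (any(vapply(mem, function(m)
        any(!atomTable(ensemble)$isHeavy[m]), logical(1))))
    stop("node member sets must contain heavy atoms only")
  nn <- length(mem); nf <- dim(xyz)[1]
  cut2 <- cutoff^2
  occ <- matrix(0, nn, nn)
  for (i in seq_len(nn - 1L)) {
    mi <- mem[[i]]
    for (j in seq.int(i + 1L, nn)) {
      mj <- mem[[j]]
      minD2 <- rep(Inf, nf)
      for (a in mi) for (b in mj) {
        d2 <- (xyz[, a, 1] - xyz[, b, 1])^2 +
              (xyz[, a, 2] - xyz[, b, 2])^2 +
              (xyz[, a, 3] - xyz[, b, 3])^2
        minD2 <- pmin(minD2, d2)
      }
      occ[i, j] <- occ[j, i] <- mean(minD2 <= cut2)
    }
  }
  occ
}

#' Average correlation matrices over replicate trajectories
#'
#' @param cms list of [CorrelationMatrix] objects with identical node
#'   order.
#' @return a [CorrelationMatrix] with the entrywise mean (clamped to
#'   [-1, 1]); a node is flagged zero-variance if it is in any replicate.
#' @export
averageCorrelation <- function(cms) {
  stopifnot(length(cms) >= 1L)
  labs <- cms[[1]]@labels
  for (cm in cms)
    if (!identical(cm@labels, labs))
      stop("replicate correlation matrices have different node orders")
  C <- Reduce(`+`, lapply(cms, function(x) x@C)) / length(cms)
  zero <- Reduce(`|`, lapply(cms, function(x) x@zeroVariance))
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  C[C > 1] <- 1; C[C < -1] <- -1
  new(Class = "CorrelationMatrix", C = C, labels = labs,
      nFrames = sum(vapply(cms, function(x) x@nFrames, integer(1))),
      zeroVariance = zero)
}

#' Build the correlation-weighted communication graph
#'
#' Keeps an edge wherever the contact adjacency is TRUE and both nodes
#' have variance, with weight `-log(|C_ij|)` so that strongly correlated
#' contacts are short.  Zero correlation would give an infinite weight;
#' such edges are kept at the finite cap `wCap` and flagged, keeping
#' connectivity decisions explicit rather than silently dropping edges.
#'
#' @param contacts a [ContactMap].
#' @param C a [CorrelationMatrix] in the same node order.
#' @param wCap weight cap (default 20, i.e. |correlation| ~ 2e-9).
#' @return a [WeightedGraph].
#' @export
buildGraph <- function(contacts, C, wCap = 20) {
  if (!identical(dim(contacts@occupancy), dim(C@C)))
    stop("contact map is ", nrow(contacts@occupancy), " nodes but ",
         "correlation matrix is ", nrow(C@C))
  if (!identical(contacts@labels, C@labels))
    stop("contact map and correlation matrix have different node orders")
  adj <- contacts@adjacency
  nn <- nrow(adj)
  zero <- C@zeroVariance
  if (any(zero)) { adj[zero, ] <- FALSE; adj[, zero] <- FALSE }
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  corr <- C@C[idx]
  w <- ifelse(abs(corr) > 0, -log(abs(corr)), Inf)
  capped <- w > wCap
  w[capped] <- wCap
  nodes <- data.frame(id = seq_len(nn), label = contacts@labels,
                      stringsAsFactors = FALSE)
  # carry residue metadata when labels follow chain:resname:resid
  parts <- strsplit(contacts@labels, ":", fixed = TRUE)
  if (all(lengths(parts) == 3L)) {
    nodes$chain <- vapply(parts, `[`, character(1), 1L)
    nodes$resname <- vapply(parts, `[`, character(1), 2L)
    nodes$resid <- suppressWarnings(
      as.integer(vapply(parts, `[`, character(1), 3L)))
  }
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      occupancy = contacts@occupancy[idx],
                      correlation = corr, weight = w, capped = capped)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  new("WeightedGraph", nodes = nodes, edges = edges, wCap = wCap)
}

#' Write the weighted edge list as TSV
#'
#' Columns: node labels, occupancy, correlation, weight, capped flag.
#'
#' @param graph a [WeightedGraph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeListTSV <- function(graph, path) {
  e <- graph@edges
  out <- data.frame(node_i = graph@nodes$label[e$i],
                    node_j = graph@nodes$label[e$j],
                    occupancy = e$occupancy, correlation = e$correlation,
                    weight = e$weight, capped = e$capped)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
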