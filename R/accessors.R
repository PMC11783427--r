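#' @rdname Ensemble-class
#' @aliases nFrames,Ensemble-method
setMethod("nFrames", "Ensemble", function(x) dim(x@coords)[1])

#' @rdname Ensemble-class
setMethod("nAtoms", "Ensemble", function(x) dim(x@coords)[2])

#' @rdname Ensemble-class
setMethod("atomTable", "Ensemble", function(x) x@atoms)

#' @rdname coords
setMethod("coords", "Ensemble", function(x, frame = NULL) {
  if (is.null(frame)) return(x@coords)
  stopifnot(length(frame) == 1L, frame >= 1L, frame <= dim(x@coords)[1])
  m <- x@coords[frame, , , drop = FALSE]
  dim(m) <- dim(x@coords)[2:3]
  colnames(m) <- c("x", "y", "z")
  m
})

setMethod("show", "Ensemble", function(object) {
  p <- object@provenance
  cat(sprintf("Ensemble: %d frame(s), %d atoms, %d residues\n",
              nFrames(object), nAtoms(object),
              length(unique(paste(object@atoms$chain, object@atoms$resid)))))
  if (!is.null(p$source)) cat("  source:", p$source, "\n")
  if (isTRUE(p$aligned)) cat("  aligned: yes\n")
})

#' @rdname NodeSet-class
setMethod("nNodes", "NodeSet", function(x) nrow(x@nodes))

#' @rdname NodeSet-class
setMethod("nodeTable", "NodeSet", function(x) x@nodes)

#' @rdname NodeSet-class
setMethod("nodeMembers", "NodeSet", function(x) x@members)

#' @rdname nodeLabels
setMethod("nodeLabels", "NodeSet", function(x) x@nodes$label)

setMethod("show", "NodeSet", function(object) {
  k <- table(object@nodes$kind)
  cat(sprintf("NodeSet: %d nodes (%s)\n", nrow(object@nodes),
              paste(sprintf("%s: %d", names(k), k), collapse = ", ")))
})

#' @rdname nodeLabels
setMethod("nodeLabels", "CorrelationMatrix", function(x) x@labels)

#' @rdname as.matrix
#' @param ... unused.
setMethod("as.matrix", "CorrelationMatrix", function(x, ...) x@C)

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix: %d nodes, %d frames", nrow(object@C),
              object@nFrames))
  nz <- sum(object@zeroVariance)
  if (nz) cat(sprintf(", %d zero-variance node(s) flagged", nz))
  cat("\n")
})

#' @rdname nodeLabels
setMethod("nodeLabels", "ContactMap", function(x) x@labels)

#' @rdname as.matrix
setMethod("as.matrix", "ContactMap",
  function(x, which = c("occupancy", "adjacency"), ...) {
    which <- match.arg(which)
    slot(x, which)
  })

setMethod("show", "ContactMap", function(object) {
  cat(sprintf(
    "ContactMap: %d nodes, %d edges (cutoff %.2f A, occupancy >= %.2f)\n",
    nrow(object@occupancy), sum(object@adjacency[upper.tri(object@adjacency)]),
    object@params$distanceCutoff, object@params$occupancyThreshold))
})

#' @rdname WeightedGraph-class
setMethod("edgeTable", "WeightedGraph", function(x) x@edges)

#' @rdname nodeLabels
setMethod("nodeLabels", "WeightedGraph", function(x) x@nodes$label)

#' @rdname WeightedGraph-class
setMethod("nNodes", "WeightedGraph", function(x) nrow(x@nodes))

setMethod("show", "WeightedGraph", function(object) {
  cat(sprintf("WeightedGraph: %d nodes, %d edges", nrow(object@nodes),
              nrow(object@edges)))
  nc <- sum(object@edges$capped)
  if (nc) cat(sprintf(" (%d capped at w = %g)", nc, object@wCap))
  cat("\n")
})

#' @rdname as.matrix
setMethod("as.matrix", "AllPairsDistances", function(x, ...) x@D)

#' @rdname nodeLabels
setMethod("nodeLabels", "AllPairsDistances", function(x) x@labels)

setMethod("show", "AllPairsDistances", function(object) {
  finite <- is.finite(object@D[upper.tri(object@D)])
  cat(sprintf("AllPairsDistances: %d nodes, %.1f%% pairs connected\n",
              nrow(object@D), 100 * mean(finite)))
})

#' @rdname PathSet-class
setMethod("pathList", "PathSet", function(x) x@paths)

#' @rdname PathSet-class
setMethod("pathLengths", "PathSet", function(x) x@lengths)

#' @rdname nodeLabels
setMethod("nodeLabels", "PathSet", function(x) x@labels)

setMethod("show", "PathSet", function(object) {
  cat(sprintf(
    "PathSet: %s -> {%s}\n  L_opt = %.4f, %g path(s) within delta = %g, %d retained%s\n",
    object@labels[object@source],
    paste(object@labels[object@sinks], collapse = ", "),
    object@lOpt, object@countWithinCutoff, object@delta,
    length(object@paths),
    if (object@truncated) " [TRUNCATED]" else ""))
})
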