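#' @rdname Ensemble-class
#' @param x an object.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Ensemble-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Ensemble-class
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' Coordinates of an ensemble
#'
#' @param x an [Ensemble].
#' @param frame optional frame index; when given, returns an
#'   `n_atoms x 3` matrix instead of the full array.
#' @return numeric array `n_frames x n_atoms x 3`, or a matrix for a
#'   single frame.
#' @export
setGeneric("coords", function(x, frame = NULL) standardGeneric("coords"))

#' @rdname NodeSet-class
#' @param x an object.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname NodeSet-class
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname NodeSet-class
#' @export
setGeneric("nodeMembers", function(x) standardGeneric("nodeMembers"))

#' Node labels (chain:resname:resid)
#' @param x an object carrying node labels.
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' Extract the numeric matrix from a matrix-like analysis object
#' @param x a [CorrelationMatrix], [ContactMap] or [AllPairsDistances].
#' @param which for [ContactMap]: `"occupancy"` or `"adjacency"`.
#' @export
setGeneric("as.matrix")

#' @rdname WeightedGraph-class
#' @param x an object.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname PathSet-class
#' @param x an object.
#' @export
setGeneric("pathList", function(x) standardGeneric("pathList"))

#' @rdname PathSet-class
#' @export
setGeneric("pathLengths", function(x) standardGeneric("pathLengths"))
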