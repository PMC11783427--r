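#' Superpose all frames onto an iteratively refined mean structure
#'
#' Each frame is rigid-body least-squares fitted (optimal rotation +
#' translation, Kabsch) onto the running mean of the fitted frames; the
#' mean is then recomputed and the fit repeated.  Two refinement passes
#' are used, after which the RMSD to the mean is stationary for all
#' practical ensembles.  Fitting is a prerequisite for meaningful
#' fluctuation covariances on raw trajectories; synthetic ensembles are
#' generated about a fixed mean and are already aligned.
#'
#' @param ensemble an [Ensemble].
#' @param fitSelection selection expression for the fit atoms (default
#'   `"name CA"`); must resolve to at least 3 non-collinear atoms.
#' @param passes mean-refinement passes (default 2).
#' @return the aligned [Ensemble] (provenance records the alignment).
#' @export
superpose <- function(ensemble, fitSelection = "name CA", passes = 2L) {
  fit <- resolveSelection(ensemble, fitSelection)
  if (length(fit) < 3L)
    stop("fit selection must resolve to at least 3 atoms")
  xyz <- coords(ensemble)
  ref <- xyz[1, fit, , drop = TRUE]
  dim(ref) <- c(length(fit), 3L)
  sv <- svd(scale(ref, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("fit selection is collinear or degenerate; cannot define a ",
         "unique superposition")
  nf <- dim(xyz)[1]
  for (pass in seq_len(passes)) {
    for (f in seq_len(nf)) {
      fr <- xyz[f, , , drop = TRUE]; dim(fr) <- dim(xyz)[2:3]
      xyz[f, , ] <- .kabschFit(fr, ref, fit)
    }
    ref <- apply(xyz[, fit, , drop = FALSE], c(2, 3), mean)
  }
  prov <- ensemble@provenance
  prov$aligned <- TRUE
  prov$fitSelection <- fitSelection
  initialize(ensemble, coords = xyz, provenance = prov)
}

# rigid-body fit of `frame` (n x 3) onto `ref` (length(fit) x 3) using the
# fit atoms; returns the transformed full frame
.kabschFit <- function(frame, ref, fit) {
  A <- frame[fit, , drop = FALSE]
  ca <- colMeans(A); cr <- colMeans(ref)
  H <- crossprod(sweep(A, 2, ca), sweep(ref, 2, cr))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(frame, 2, ca) %*% t(R), 2, cr, `+`)
}

#' Normalized cross-correlation of node fluctuations
#'
#' Computes `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)` over
#' frames, where `dr` is the deviation of each node representative
#' (C-alpha, or ligand heavy-atom centroid) from its time mean.  The
#' ensemble should be superposed first (see [superpose()]); synthetic
#' ensembles are generated aligned.
#'
#' @param ensemble an [Ensemble] with at least 2 frames.
#' @param nodes a [NodeSet].
#' @return a [CorrelationMatrix].  Nodes that never move are flagged
#'   zero-variance; their off-diagonal correlations are 0 and
#'   [buildGraph()] gives them no edges.
#' @export
computeCorrelation <- function(ensemble, nodes) {
  if (nFrames(ensemble) < 2L)
    stop("at least 2 frames are required to compute fluctuations")
  if (!isTRUE(ensemble@provenance$aligned))
    warning("ensemble not marked aligned; call superpose() first unless ",
            "frames share a fixed reference")
  rc <- nodeCoordinates(ensemble, nodes)
  nn <- dim(rc)[2]
  S <- matrix(0, nn, nn)
  for (ax in 1:3) {
    dev <- scale(rc[, , ax], scale = FALSE)
    S <- S + crossprod(dev)
  }
  v <- diag(S)
  zero <- v <= 1e-12
  denom <- sqrt(outer(pmax(v, 1e-300), pmax(v, 1e-300)))
  C <- S / denom
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  C[C > 1] <- 1; C[C < -1] <- -1
  new(Class = "CorrelationMatrix", C = C, labels = nodeLabels(nodes),
      nFrames = nFrames(ensemble), zeroVariance = zero)
}

#' Block (helix-helix) correlation summary
#'
#' Extracts the cross-block submatrix of a correlation matrix (for
#' example H5 rows against H7 columns) and summarises it.
#'
#' @param C a [CorrelationMatrix].
#' @param blockA,blockB node index vectors (1-based, in `C`'s node
#'   order), or character vectors of node labels.  Blocks must be
#'   disjoint and non-empty.
#' @return a list of class `blockSummary`: `submatrix`, `mean`,
#'   `fractionPositive`, `min`, `max`, and the block index vectors.
#' @export
blockCorrelation <- function(C, blockA, blockB) {
  ia <- .resolveNodeBlock(C, blockA)
  ib <- .resolveNodeBlock(C, blockB)
  if (length(intersect(ia, ib)))
    stop("blocks overlap at node(s): ",
         paste(C@labels[intersect(ia, ib)], collapse = ", "))
  sub <- C@C[ia, ib, drop = FALSE]
  dimnames(sub) <- list(C@labels[ia], C@labels[ib])
  structure(list(submatrix = sub, mean = mean(sub),
                 fractionPositive = mean(sub > 0),
                 min = min(sub), max = max(sub),
                 blockA = ia, blockB = ib),
            class = "blockSummary")
}

.resolveNodeBlock <- function(C, block) {
  if (is.character(block)) {
    idx <- match(block, C@labels)
    if (anyNA(idx))
      stop("unknown node label(s): ",
           paste(block[is.na(idx)], collapse = ", "))
    return(idx)
  }
  idx <- as.integer(block)
  if (!length(idx) || any(idx < 1L) || any(idx > nrow(C@C)))
    stop("block must resolve to >= 1 valid node index")
  idx
}

#' @export
print.blockSummary <- function(x, ...) {
  cat(sprintf(
    "Block correlation: %d x %d entries, mean %.4f (range %.4f..%.4f), %.1f%% positive\n",
    nrow(x$submatrix), ncol(x$submatrix), x$mean, x$min, x$max,
    100 * x$fractionPositive))
  invisible(x)
}

#' Write a correlation matrix as labelled TSV
#'
#' @param C a [CorrelationMatrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCorrelationTSV <- function(C, path) {
  m <- as.data.frame(C@C)
  names(m) <- C@labels
  utils::write.table(cbind(node = C@labels, m), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
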