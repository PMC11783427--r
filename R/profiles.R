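#' Per-residue utilization of the top-k communication paths
#'
#' For each node, the percentage of the `k` shortest retained paths that
#' pass through it.  The source and sink nodes are excluded from the
#' table: they appear in every path by construction and would dominate
#' the histogram.  With a helix annotation, per-helix aggregates (the
#' percentage of paths traversing at least one residue of the helix) are
#' attached.
#'
#' @param pathset a [PathSet] with at least one retained path.
#' @param k number of paths to use (default: all retained; capped at the
#'   number retained, reported as `kEffective`).
#' @param helixAnnotation optional data.frame with columns `name`,
#'   `start`, `end` (residue-number intervals, e.g. H5 = 330-340).
#' @return data.frame of class `UtilizationProfile` with columns `id`,
#'   `label`, `resid`, `nPaths`, `utilization` (percent), for every
#'   non-source, non-sink node; attributes `kEffective`,
#'   `helixUtilization` (if annotated), `excluded` (source/sink labels).
#' @export
residueUtilization <- function(pathset, k = NULL, helixAnnotation = NULL) {
  nPaths <- length(pathset@paths)
  if (!nPaths) stop("path set is empty")
  if (is.null(k)) k <- nPaths
  kEff <- min(k, nPaths)
  use <- pathset@paths[seq_len(kEff)]

  n <- length(pathset@labels)
  counts <- tabulate(unlist(use), nbins = n)
  excluded <- c(pathset@source, pathset@sinks)
  keep <- setdiff(seq_len(n), excluded)
  resid <- suppressWarnings(as.integer(sub("^.*:", "", pathset@labels)))
  out <- data.frame(id = keep, label = pathset@labels[keep],
                    resid = resid[keep], nPaths = counts[keep],
                    utilization = 100 * counts[keep] / kEff,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "kEffective") <- kEff
  attr(out, "excluded") <- pathset@labels[excluded]
  if (!is.null(helixAnnotation)) {
    stopifnot(all(c("name", "start", "end") %in% names(helixAnnotation)))
    helixU <- vapply(seq_len(nrow(helixAnnotation)), function(r) {
      inHelix <- which(!is.na(resid) &
                       resid >= helixAnnotation$start[r] &
                       resid <= helixAnnotation$end[r])
      inHelix <- setdiff(inHelix, excluded)
      100 * sum(vapply(use, function(p) any(p %in% inHelix),
                       logical(1))) / kEff
    }, numeric(1))
    names(helixU) <- helixAnnotation$name
    attr(out, "helixUtilization") <- helixU
    # mean per-residue utilization over the block: a graded aggregate that
    # does not saturate once every path merely touches the helix
    helixM <- vapply(seq_len(nrow(helixAnnotation)), function(r) {
      rows <- which(!is.na(out$resid) &
                    out$resid >= helixAnnotation$start[r] &
                    out$resid <= helixAnnotation$end[r])
      if (!length(rows)) return(NA_real_)
      mean(out$utilization[rows])
    }, numeric(1))
    names(helixM) <- helixAnnotation$name
    attr(out, "helixMeanUtilization") <- helixM
  }
  class(out) <- c("UtilizationProfile", "data.frame")
  out
}

#' Shortest-distance profile from a source node
#'
#' Extracts the source row of the all-pairs optimal path lengths: for
#' every node, the length of the optimal path from the source (an
#' adjacent node's value is simply the edge weight when that is already
#' optimal).  Wells — local minima regions — of this profile mark the
#' communication conduits out of the binding pocket.
#'
#' @param apd an [AllPairsDistances].
#' @param source node id or label (typically the ligand node).
#' @return data.frame of class `DistanceProfile` with columns `id`,
#'   `label`, `resid`, `distance` (`Inf` where unreachable), ordered by
#'   residue number within chain; attribute `source`.
#' @export
shortestDistanceProfile <- function(apd, source) {
  src <- .resolveNodeId(apd@labels, source)
  d <- apd@D[src, ]
  parts <- strsplit(apd@labels, ":", fixed = TRUE)
  chain <- vapply(parts, `[`, character(1), 1L)
  resid <- suppressWarnings(as.integer(sub("^.*:", "", apd@labels)))
  out <- data.frame(id = seq_along(d), label = apd@labels,
                    chain = chain, resid = resid, distance = d,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resid), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source") <- apd@labels[src]
  class(out) <- c("DistanceProfile", "data.frame")
  out
}

#' Detect wells (local-minimum regions) in a shortest-distance profile
#'
#' Sliding-window scan: a residue is a well candidate when its value is
#' the minimum of the window centred on it; contiguous candidates are
#' merged into intervals, and an interval is kept when its minimum lies
#' at least `depth` below the medians of the flanking windows on *both*
#' sides (intervals touching the profile boundary are discarded — a
#' monotone profile has no well).  A reporting heuristic: window and
#' depth only shape how the plotted wells are segmented, not any path
#' statistic.
#'
#' @param profile a [shortestDistanceProfile()] result (or any
#'   data.frame with `resid` and `distance` columns); the scanned range
#'   must be finite.
#' @param window odd window width in residues (default 7).
#' @param depth minimum depth below both flanking medians, in
#'   path-length units (default 0.5).
#' @param maxAbove additionally require the well minimum to lie within
#'   `maxAbove` of the global profile minimum (default `Inf`, i.e.
#'   purely local detection).  Wells in the established sense are the
#'   regions with the *lowest* shortest-distance values, so comparative
#'   analyses typically set a finite value (the bundled pipeline uses 1
#'   path-length unit).
#' @return data.frame of class `WellSet`: one row per well with columns
#'   `startResid`, `endResid`, `minResid`, `minValue`, `leftMedian`,
#'   `rightMedian`.
#' @export
detectWells <- function(profile, window = 7L, depth = 0.5,
                        maxAbove = Inf) {
  stopifnot(all(c("resid", "distance") %in% names(profile)))
  prof <- profile[is.finite(profile$distance) & !is.na(profile$resid), ,
                  drop = FALSE]
  v <- prof$distance
  n <- length(v)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window > n)
    stop("window (", window, ") larger than the finite profile (", n, ")")
  hw <- (window - 1L) %/% 2L

  cand <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - hw); hi <- min(n, i + hw)
    v[i] <= min(v[lo:hi]) + 1e-12
  }, logical(1))

  runs <- rle(cand)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  wells <- list()
  for (r in which(runs$values)) {
    a <- starts[r]; b <- ends[r]
    if (a - 1L < 1L || b + 1L > n) next   # touches the boundary
    leftIdx <- seq.int(max(1L, a - window), a - 1L)
    rightIdx <- seq.int(b + 1L, min(n, b + window))
    medL <- stats::median(v[leftIdx]); medR <- stats::median(v[rightIdx])
    mn <- min(v[a:b])
    if (medL - mn >= depth && medR - mn >= depth &&
        mn <= min(v) + maxAbove) {
      wells[[length(wells) + 1L]] <- data.frame(
        startResid = prof$resid[a], endResid = prof$resid[b],
        minResid = prof$resid[a:b][which.min(v[a:b])],
        minValue = mn, leftMedian = medL, rightMedian = medR)
    }
  }
  out <- if (length(wells)) do.call(rbind, wells) else
    data.frame(startResid = integer(0), endResid = integer(0),
               minResid = integer(0), minValue = numeric(0),
               leftMedian = numeric(0), rightMedian = numeric(0))
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "depth") <- depth
  class(out) <- c("WellSet", "data.frame")
  out
}

#' Write a per-residue profile as TSV
#'
#' Percentages and distances are written to full precision; `Inf`
#' distances (unreachable nodes) become empty fields.
#'
#' @param profile a `UtilizationProfile` or `DistanceProfile` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProfileTSV <- function(profile, path) {
  out <- as.data.frame(profile)
  if ("distance" %in% names(out))
    out$distance[!is.finite(out$distance)] <- NA
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
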