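#' All-pairs optimal path lengths (Floyd-Warshall)
#'
#' Runs Floyd-Warshall on the weighted communication graph.  The
#' resulting optimal path length between two nodes is the "shortest
#' distance" of the analysis: either the weight of a direct edge or the
#' length of the cheapest multi-edge path, whichever is smaller.
#' Unreachable pairs are `Inf`.
#'
#' @param graph a [WeightedGraph] (non-negative finite weights; asserted,
#'   although the `-log|C|` construction cannot produce negatives).
#' @return an [AllPairsDistances] with a next-hop matrix for path
#'   reconstruction.
#' @export
floydWarshall <- function(graph) {
  e <- edgeTable(graph)
  if (nrow(e) && any(e$weight < 0))
    stop("negative edge weight encountered")
  n <- nNodes(graph)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  nxt <- matrix(NA_integer_, n, n)
  if (nrow(e)) {
    # undirected: seed both directions; keep the lighter of parallel edges
    for (r in seq_len(nrow(e))) {
      i <- e$i[r]; j <- e$j[r]; w <- e$weight[r]
      if (w < D[i, j]) {
        D[i, j] <- D[j, i] <- w
        nxt[i, j] <- j; nxt[j, i] <- i
      }
    }
  }
  diag(nxt) <- seq_len(n)
  for (k in seq_len(n)) {
    alt <- outer(D[, k], D[k, ], `+`)
    upd <- alt < D
    if (any(upd)) {
      D[upd] <- alt[upd]
      hopK <- matrix(nxt[, k], n, n)
      nxt[upd] <- hopK[upd]
    }
  }
  new("AllPairsDistances", D = D, nextHop = nxt,
      labels = graph@nodes$label)
}

#' Reconstruct one optimal path between two nodes
#'
#' @param apd an [AllPairsDistances].
#' @param from,to node ids or labels.
#' @return integer vector of node ids, or `NULL` if unreachable.
#' @export
reconstructPath <- function(apd, from, to) {
  i <- .resolveNodeId(apd@labels, from)
  j <- .resolveNodeId(apd@labels, to)
  if (!is.finite(apd@D[i, j])) return(NULL)
  path <- i
  while (i != j) {
    i <- apd@nextHop[i, j]
    path <- c(path, i)
  }
  path
}

.resolveNodeId <- function(labels, x) {
  if (is.character(x)) {
    id <- match(x, labels)
    if (anyNA(id)) {
      # allow bare resid or resname:resid shorthand against full labels
      hits <- lapply(x[is.na(id)], function(s)
        grep(paste0("(^|:)", s, "$"), labels))
      bad <- vapply(hits, length, integer(1)) != 1L
      if (any(bad))
        stop("cannot resolve node '", x[is.na(id)][bad][1],
             "' to exactly one node")
      id[is.na(id)] <- vapply(hits, `[`, integer(1), 1L)
    }
    return(as.integer(id))
  }
  as.integer(x)
}

#' Path enumeration parameters
#'
#' @param delta length offset above the optimal path length; all simple
#'   paths with length within `lOpt + delta` are counted.  The classic
#'   network-analysis default is 100 (a dimensionless path-length offset;
#'   appropriate for full-size receptor graphs, far too permissive for
#'   toy graphs).
#' @param topK number of shortest paths retained for profiles
#'   (default 1000).
#' @param maxPaths safety bound on the enumeration (default 5e6); hitting
#'   it sets the `truncated` flag and invalidates count comparisons.
#' @return a list of class `PathParams`.
#' @export
pathParams <- function(delta = 100, topK = 1000L, maxPaths = 5e6) {
  stopifnot(delta >= 0, topK >= 1)
  structure(list(delta = delta, topK = as.integer(topK),
                 maxPaths = maxPaths),
            class = "PathParams")
}

#' Enumerate optimal and suboptimal source-to-sink paths
#'
#' Finds every simple path from the source to any sink whose length (sum
#' of edge weights) is at most `lOpt + delta`, by depth-first enumeration
#' with branch-and-bound pruning: a partial path is abandoned as soon as
#' its length plus the optimal remaining distance to the nearest sink
#' exceeds the cutoff.  The count of such paths is the "communication
#' path count"; the `topK` shortest (ties broken by lexicographic node
#' sequence, so the set is deterministic) are retained for utilization
#' profiles.  The optimal path is always included.
#'
#' @param graph a [WeightedGraph].
#' @param source source node (id or label), typically the ligand node.
#' @param sinks sink node(s) (ids or labels): a single residue (e.g. the
#'   AF-2 surface residue) or a set such as all peptide-residue nodes,
#'   in which case paths may terminate at any of them and the optimal
#'   length is the minimum over sinks.
#' @param params a [pathParams()].
#' @param apd optional precomputed [floydWarshall()] result (reused for
#'   the pruning bound).
#' @return a [PathSet].
#' @export
suboptimalPaths <- function(graph, source, sinks, params = pathParams(),
                            apd = NULL) {
  labels <- graph@nodes$label
  src <- .resolveNodeId(labels, source)
  snk <- unique(.resolveNodeId(labels, sinks))
  snk <- setdiff(snk, src)
  if (!length(snk)) stop("at least one sink distinct from the source required")
  if (is.null(apd)) apd <- floydWarshall(graph)
  sinkDist <- apply(apd@D[, snk, drop = FALSE], 1, min)
  lOpt <- sinkDist[src]
  if (!is.finite(lOpt)) {
    comp <- .componentOf(graph, src)
    stop("no sink reachable from source '", labels[src],
         "'; its connected component holds ", length(comp),
         " node(s) and no sink")
  }
  bound <- lOpt + params$delta + 1e-9

  n <- nNodes(graph)
  e <- edgeTable(graph)
  nbr <- vector("list", n)
  wts <- vector("list", n)
  for (r in seq_len(nrow(e))) {
    i <- as.integer(e$i[r]); j <- as.integer(e$j[r]); w <- e$weight[r]
    nbr[[i]] <- c(nbr[[i]], j); wts[[i]] <- c(wts[[i]], w)
    nbr[[j]] <- c(nbr[[j]], i); wts[[j]] <- c(wts[[j]], w)
  }
  for (v in seq_len(n)) {
    if (length(nbr[[v]])) {
      o <- order(nbr[[v]])
      nbr[[v]] <- nbr[[v]][o]; wts[[v]] <- wts[[v]][o]
    }
  }

  env <- new.env(parent = emptyenv())
  env$paths <- vector("list", 1024L)
  env$lengths <- numeric(1024L)
  env$count <- 0L
  env$truncated <- FALSE
  isSink <- logical(n); isSink[snk] <- TRUE
  visited <- logical(n)

  record <- function(path, len) {
    env$count <- env$count + 1L
    if (env$count > length(env$lengths)) {
      env$paths <- c(env$paths, vector("list", length(env$paths)))
      env$lengths <- c(env$lengths, numeric(length(env$lengths)))
    }
    env$paths[[env$count]] <- path
    env$lengths[env$count] <- len
  }

  dfs <- function(v, path, len) {
    if (env$truncated) return()
    if (isSink[v]) {
      record(path, len)
      if (env$count >= params$maxPaths) { env$truncated <- TRUE; return() }
    }
    nb <- nbr[[v]]; wv <- wts[[v]]
    for (t in seq_along(nb)) {
      u <- nb[t]
      if (visited[u]) next
      len2 <- len + wv[t]
      if (len2 + sinkDist[u] > bound) next
      visited[u] <<- TRUE
      dfs(u, c(path, u), len2)
      visited[u] <<- FALSE
      if (env$truncated) return()
    }
  }
  visited[src] <- TRUE
  dfs(src, src, 0)

  cnt <- env$count
  paths <- env$paths[seq_len(cnt)]
  lens <- env$lengths[seq_len(cnt)]
  key <- vapply(paths, function(p) paste(sprintf("%06d", p), collapse = ""),
                character(1))
  o <- order(lens, key)
  keep <- o[seq_len(min(params$topK, cnt))]
  new("PathSet", source = src, sinks = snk,
      paths = paths[keep], lengths = lens[keep], lOpt = lOpt,
      countWithinCutoff = as.numeric(cnt), truncated = env$truncated,
      delta = params$delta, topK = params$topK, maxPaths = params$maxPaths,
      labels = labels)
}

.componentOf <- function(graph, v) {
  n <- nNodes(graph)
  e <- edgeTable(graph)
  seen <- logical(n); seen[v] <- TRUE
  frontier <- v
  while (length(frontier)) {
    nxt <- unique(c(e$j[e$i %in% frontier], e$i[e$j %in% frontier]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

#' Summary statistics of a path set
#'
#' @param pathset a [PathSet] with at least one path.
#' @return a list: `countWithinCutoff` (all paths within the cutoff),
#'   `lOpt`, `lengths` (of the retained top-k paths), `meanLength` (mean
#'   over the retained paths), `kEffective`, `truncated`.
#' @export
pathStatistics <- function(pathset) {
  if (!length(pathset@paths)) stop("path set is empty")
  list(countWithinCutoff = pathset@countWithinCutoff,
       lOpt = pathset@lOpt,
       lengths = pathset@lengths,
       meanLength = mean(pathset@lengths),
       kEffective = length(pathset@paths),
       truncated = pathset@truncated)
}

#' Signed percent change of a statistic against a reference
#'
#' `100 * (variant - reference) / reference`: the mutant-versus-wild-type
#' comparison applied to path counts and mean path lengths.
#'
#' @param variant,reference numeric scalars; the reference must be
#'   non-zero.
#' @return signed percent change.
#' @examples
#' compareToReference(70, 100)    # -30
#' compareToReference(3000, 100)  # +2900 (a "30-fold" increase)
#' @export
compareToReference <- function(variant, reference) {
  stopifnot(is.numeric(variant), is.numeric(reference))
  if (reference == 0) stop("reference statistic is zero; percent change undefined")
  100 * (variant - reference) / reference
}

#' Dump retained paths as text (one path per line)
#'
#' @param pathset a [PathSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePathDump <- function(pathset, path) {
  lines <- vapply(seq_along(pathset@paths), function(k)
    paste0(sprintf("%.6f", pathset@lengths[k]), "\t",
           paste(pathset@labels[pathset@paths[[k]]], collapse = "\t")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
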