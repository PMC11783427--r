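# Independent oracles used across the suite.  These are deliberately
# naive (exhaustive enumeration, direct coordinate arithmetic) and share
# no code with the package internals they check.

# Build a WeightedGraph directly from an edge table (i, j, w).
makeTestGraph <- function(n, edges, wCap = 20) {
  labels <- sprintf("A:ALA:%d", seq_len(n))
  nodes <- data.frame(id = seq_len(n), label = labels,
                      chain = "A", resname = "ALA", resid = seq_len(n),
                      stringsAsFactors = FALSE)
  e <- data.frame(i = as.integer(pmin(edges$i, edges$j)),
                  j = as.integer(pmax(edges$i, edges$j)),
                  occupancy = 1, correlation = exp(-edges$w),
                  weight = edges$w, capped = FALSE)
  e <- e[order(e$i, e$j), , drop = FALSE]
  rownames(e) <- NULL
  new("WeightedGraph", nodes = nodes, edges = e, wCap = wCap)
}

# Seeded random connected-ish graph with <= maxN nodes, U(0.1, 3) weights.
randomTestGraph <- function(seed, maxN = 8, p = 0.45) {
  set.seed(seed)
  n <- sample(3:maxN, 1)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  # guarantee a spanning path so source/sink questions are non-trivial
  spine <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
  sel <- unique(rbind(pairs[keep, , drop = FALSE], spine))
  edges <- data.frame(i = sel[, 1], j = sel[, 2],
                      w = round(runif(nrow(sel), 0.1, 3), 6))
  list(n = n, edges = edges, graph = makeTestGraph(n, edges))
}

# Adjacency list representation for the oracle DFS.
.oracleAdj <- function(n, edges) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- as.integer(edges$i[r]); j <- as.integer(edges$j[r]); w <- edges$w[r]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  adj
}

# Exhaustively enumerate every simple path from src; returns a list with
# integer paths and numeric lengths.  No pruning: the ground truth.
oracleAllSimplePaths <- function(n, edges, src) {
  src <- as.integer(src)
  adj <- .oracleAdj(n, edges)
  paths <- list(); lens <- numeric()
  rec <- function(v, visited, path, len) {
    paths[[length(paths) + 1L]] <<- path
    lens[[length(lens) + 1L]] <<- len
    a <- adj[[v]]
    if (is.null(a)) return()
    for (r in seq_len(nrow(a))) {
      u <- as.integer(a[r, 1])
      if (!visited[u]) {
        visited[u] <- TRUE
        rec(u, visited, c(path, u), len + a[r, 2])
        visited[u] <- FALSE
      }
    }
  }
  visited <- logical(n); visited[src] <- TRUE
  rec(src, visited, src, 0)
  list(paths = paths, lengths = lens)
}

# Oracle shortest distances from src to every node via the enumeration.
oracleShortestFrom <- function(n, edges, src) {
  all <- oracleAllSimplePaths(n, edges, src)
  ends <- vapply(all$paths, function(p) p[length(p)], integer(1))
  d <- rep(Inf, n)
  for (k in seq_along(ends)) d[ends[k]] <- min(d[ends[k]], all$lengths[k])
  d
}

# Oracle bounded path set: simple src->sink paths with length <= bound,
# as sorted "a-b-c" keys.
oraclePathSet <- function(n, edges, src, sink, bound) {
  all <- oracleAllSimplePaths(n, edges, src)
  ends <- vapply(all$paths, function(p) p[length(p)], integer(1))
  keep <- ends == sink & all$lengths <= bound + 1e-9
  sort(vapply(all$paths[keep], paste, character(1), collapse = "-"))
}

pathKeys <- function(pathset) {
  sort(vapply(pathList(pathset), paste, character(1), collapse = "-"))
}

# Direct coordinate-arithmetic distance between two atoms in one frame.
oracleDist <- function(xyz, f, a, b) {
  sqrt(sum((xyz[f, a, ] - xyz[f, b, ])^2))
}
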