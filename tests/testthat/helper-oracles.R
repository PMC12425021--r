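# Independent oracles, deliberately implemented without igraph or any
# package internals: plain-R BFS over an adjacency list, and union-find
# connected components.

# adjacency list from a 2-column character edge matrix
adjList <- function(edges) {
  nodesAll <- unique(c(edges[, 1L], edges[, 2L]))
  adj <- setNames(vector("list", length(nodesAll)), nodesAll)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# single-source BFS distances; Inf for unreachable
bfsOracle <- function(adj, source) {
  dist <- setNames(rep(Inf, length(adj)), names(adj))
  dist[source] <- 0
  frontier <- source
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- character(0)
    for (v in frontier) for (w in adj[[v]]) {
      if (is.infinite(dist[w])) { dist[w] <- d; nxt <- c(nxt, w) }
    }
    frontier <- unique(nxt)
  }
  dist
}

# separation oracle under the package's stated convention, built on bfsOracle
separationOracle <- function(edges, A, B) {
  adj <- adjList(edges)
  distTo <- function(v, S) {
    S <- setdiff(S, v)
    if (length(S) == 0L) return(Inf)
    min(bfsOracle(adj, v)[S])
  }
  nn <- function(from, to) {
    vals <- vapply(from, distTo, numeric(1), S = to)
    vals[is.finite(vals)]
  }
  dAA <- if (length(A) == 1L) 0 else mean(nn(A, A))
  dBB <- if (length(B) == 1L) 0 else mean(nn(B, B))
  cross <- c(nn(A, B), nn(B, A))
  dAB <- mean(cross)
  dAB - (dAA + dBB) / 2
}

proximityOracle <- function(edges, S, T_) {
  adj <- adjList(edges)
  mins <- vapply(T_, function(t) min(bfsOracle(adj, t)[S]), numeric(1))
  mean(mins[is.finite(mins)])
}

# union-find components; returns list of sorted member vectors
unionFindComponents <- function(nodesAll, edges) {
  parent <- setNames(nodesAll, nodesAll)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges[i, 1L]); rb <- find(edges[i, 2L])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodesAll, find, "")
  unname(lapply(split(nodesAll, roots), sort))
}

# random connected-ish test graph as an edge matrix
randomEdges <- function(n, nEdges, seed) {
  set.seed(seed)
  nodesAll <- sprintf("n%02d", seq_len(n))
  a <- sample(nodesAll, nEdges, replace = TRUE)
  b <- sample(nodesAll, nEdges, replace = TRUE)
  keep <- a != b
  cbind(a[keep], b[keep])
}
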