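# Graph substrate: interactome construction and I/O, shortest-path services,
# degree log-binning and degree-matched random sampling. Every null model in
# the package draws through this file.

#' Build an interactome from an edge table
#'
#' Constructs a simple undirected [Interactome-class] from a two-column
#' edge table of gene symbols. Symbols are whitespace-trimmed; self-loops
#' are dropped and duplicate (unordered) edges collapsed, with counts kept
#' in the load report.
#'
#' @param edges two-column character matrix or data.frame of gene symbols.
#' @return an [Interactome-class].
#' @examples
#' net <- interactomeFromEdges(cbind(c("A", "B", "A"), c("B", "C", "B")))
#' nodes(net)
#' loadReport(net)$duplicatesCollapsed
#' @export
interactomeFromEdges <- function(edges) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop("edge table needs two symbol columns")
  a <- trimws(as.character(edges[, 1L]))
  b <- trimws(as.character(edges[, 2L]))
  keep <- nzchar(a) & nzchar(b)
  a <- a[keep]; b <- b[keep]
  selfLoops <- a == b
  nLoops <- sum(selfLoops)
  a <- a[!selfLoops]; b <- b[!selfLoops]
  if (length(a) == 0L) stop("interactome is empty after cleaning")
  # canonical unordered orientation, then dedup
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  nDup <- sum(dup)
  g <- igraph::graph_from_edgelist(cbind(lo[!dup], hi[!dup]), directed = FALSE)
  obj <- new("Interactome", graph = g,
             report = list(nodes = igraph::vcount(g),
                           edges = igraph::ecount(g),
                           selfLoopsDropped = nLoops,
                           duplicatesCollapsed = nDup),
             cache = new.env(parent = emptyenv()))
  validObject(obj)
  obj
}

#' Load an interactome from an edge-list file
#'
#' Reads a TSV edge list (two symbol columns, optional header, `#` comments
#' ignored) or a SIF file (`A interacts B`, one or more partners per row)
#' into an [Interactome-class]. Cleaning follows [interactomeFromEdges()]:
#' self-loops dropped, duplicate edges collapsed, symbols trimmed.
#'
#' @param path file path.
#' @param fmt `"tsv"` (edge list) or `"sif"`.
#' @param restrictLCC keep only the largest connected component of the
#'   loaded graph (off by default; real interactomes carry small satellite
#'   components and unreachable distances are handled downstream).
#' @return an [Interactome-class]; `loadReport()` holds the cleaning counts.
#' @export
loadInteractome <- function(path, fmt = c("tsv", "sif"), restrictLCC = FALSE) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("interactome file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("interactome file has no data rows: ", path)
  pairs <- vector("list", length(keep))
  headerWords <- c("gene", "source", "target", "from", "to", "node1", "node2",
                   "genea", "geneb", "symbol1", "symbol2", "protein1", "protein2")
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (fmt == "sif" && length(fields) == 1L)
      fields <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    fields <- trimws(fields)
    if (fmt == "tsv") {
      fields <- fields[nzchar(fields)]
      if (length(fields) < 2L)
        stop("malformed row at line ", ln, ": need two symbol columns")
      if (i == 1L && any(tolower(fields[1:2]) %in% headerWords)) next
      pairs[[i]] <- cbind(fields[1L], fields[2L])
    } else {
      if (length(fields) < 3L)
        stop("malformed SIF row at line ", ln, ": need source, relation, target")
      tgt <- fields[-(1:2)]
      tgt <- tgt[nzchar(tgt)]
      pairs[[i]] <- cbind(fields[1L], tgt)
    }
  }
  edges <- do.call(rbind, pairs)
  if (is.null(edges) || nrow(edges) == 0L) stop("no edges parsed from ", path)
  net <- interactomeFromEdges(edges)
  if (restrictLCC) {
    comp <- igraph::components(net@graph)
    keepV <- names(comp$membership)[comp$membership == which.max(comp$csize)]
    g <- igraph::induced_subgraph(net@graph, keepV)
    net <- new("Interactome", graph = g,
               report = c(net@report[c("selfLoopsDropped", "duplicatesCollapsed")],
                          list(nodes = igraph::vcount(g), edges = igraph::ecount(g),
                               restrictedToLCC = TRUE)),
               cache = new.env(parent = emptyenv()))
  }
  net
}

#' @rdname nodes
#' @export
setMethod("nodes", "Interactome", function(x) igraph::V(x@graph)$name)

#' @rdname nodeDegrees
#' @export
setMethod("nodeDegrees", "Interactome", function(x) {
  d <- igraph::degree(x@graph)
  storage.mode(d) <- "integer"
  d
})

#' @rdname numEdges
#' @export
setMethod("numEdges", "Interactome", function(x) igraph::ecount(x@graph))

#' @rdname loadReport
#' @export
setMethod("loadReport", "Interactome", function(x) x@report)

setMethod("show", "Interactome", function(object) {
  cat("Interactome:", igraph::vcount(object@graph), "nodes,",
      igraph::ecount(object@graph), "edges\n")
  rp <- object@report
  if (!is.null(rp$selfLoopsDropped))
    cat("  cleaned:", rp$selfLoopsDropped, "self-loops dropped,",
        rp$duplicatesCollapsed, "duplicate edges collapsed\n")
})

# ---- distances ------------------------------------------------------------

# Full unweighted distance matrix, memoised per Interactome. Affordable up to
# a few thousand nodes; beyond that callers fall back to per-query BFS.
.distMatrix <- function(net) {
  if (is.null(net@cache$dist)) {
    if (igraph::vcount(net@graph) > 4000L) return(NULL)
    net@cache$dist <- igraph::distances(net@graph, algorithm = "unweighted")
  }
  net@cache$dist
}

# Distances between two node-name sets (rows = from, cols = to).
.pairDist <- function(net, from, to) {
  dm <- .distMatrix(net)
  if (!is.null(dm)) return(dm[from, to, drop = FALSE])
  igraph::distances(net@graph, v = from, to = to, algorithm = "unweighted")
}

#' Shortest distance from a gene to the nearest member of a gene set
#'
#' Unweighted (BFS) shortest-path distance from `source` to the closest
#' member of `targets`; 0 when `source` is itself a target, `Inf` when no
#' target is reachable.
#'
#' @param net an [Interactome-class].
#' @param source a gene symbol in the network.
#' @param targets non-empty character vector; members absent from the
#'   network are ignored, but at least one must map.
#' @return non-negative number, possibly `Inf`.
#' @export
minDistToSet <- function(net, source, targets) {
  stopifnot(length(source) == 1L)
  if (!source %in% nodes(net)) stop("source gene not in the network: ", source)
  targets <- intersect(targets, nodes(net))
  if (length(targets) == 0L) stop("no target gene maps to the network")
  if (source %in% targets) return(0)
  min(.pairDist(net, source, targets))
}

# ---- degree binning -------------------------------------------------------

#' Log-spaced degree bins with a minimum occupancy
#'
#' Samples the interactome's degree distribution with logarithmically spaced
#' degree boundaries (powers of two), then merges adjacent bins upward until
#' every bin holds at least `minOccupancy` nodes; an undersized tail is
#' absorbed into the bin below it. The resulting bins partition the node set
#' and drive all degree-matched null sampling.
#'
#' @param net an [Interactome-class].
#' @param minOccupancy occupancy floor per bin (default 100).
#' @return a [DegreeBinning-class].
#' @export
buildDegreeBins <- function(net, minOccupancy = 100L) {
  minOccupancy <- as.integer(minOccupancy)
  stopifnot(minOccupancy >= 1L)
  deg <- nodeDegrees(net)
  n <- length(deg)
  if (minOccupancy > n)
    warning("minOccupancy exceeds the node count; using a single bin")
  hi <- max(deg)
  # powers of two cover [0, hi]; degree-0 nodes land in the first interval
  breaks <- c(0, 2^(0:max(0, ceiling(log2(hi + 1)))))
  idx <- findInterval(deg, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  # merge undersized (or empty) bins upward until each reaches the floor
  i <- 1L
  nb <- length(counts)
  while (i < nb) {
    if (counts[i] < minOccupancy) {
      counts[i + 1L] <- counts[i + 1L] + counts[i]
      counts <- counts[-i]
      breaks <- breaks[-(i + 1L)]
      nb <- nb - 1L
    } else i <- i + 1L
  }
  # undersized or empty tail merges downward into the bin below it
  while (length(counts) > 1L && counts[length(counts)] < minOccupancy) {
    counts[length(counts) - 1L] <- counts[length(counts) - 1L] + counts[length(counts)]
    breaks <- breaks[-(length(breaks) - 1L)]
    counts <- counts[-length(counts)]
  }
  idx <- findInterval(deg, breaks, rightmost.closed = FALSE)
  idx[idx == length(breaks)] <- length(breaks) - 1L  # guard right edge
  bins <- split(names(deg), factor(idx, levels = seq_len(length(breaks) - 1L)))
  bins <- unname(bins)
  obj <- new("DegreeBinning", bins = bins, breaks = as.numeric(breaks),
             nodeBin = setNames(as.integer(idx), names(deg)),
             minOccupancy = minOccupancy)
  validObject(obj)
  obj
}

setMethod("show", "DegreeBinning", function(object) {
  occ <- lengths(object@bins)
  cat("DegreeBinning:", length(object@bins), "bins over",
      length(object@nodeBin), "nodes (min occupancy",
      paste0(object@minOccupancy, ")\n"))
  for (i in seq_along(object@bins))
    cat(sprintf("  bin %d: degrees [%g, %g), %d nodes\n", i,
                object@breaks[i], object@breaks[i + 1L], occ[i]))
})

# Precompute per-bin pools for a reference set so repeated null draws only
# pay for sampling. Pools are the full bins: reference genes stay eligible,
# which keeps the null distribution identical for observed and resampled
# sets (excluding them would bias every z for large or hub-rich references).
.matchPrep <- function(bins, reference) {
  binIdx <- bins@nodeBin[reference]
  if (anyNA(binIdx)) stop("reference genes missing from the binning: ",
                          paste(reference[is.na(binIdx)], collapse = ", "))
  occupied <- sort(unique(binIdx))
  lapply(occupied, function(b)
    list(pool = bins@bins[[b]], k = sum(binIdx == b)))
}

.drawMatched <- function(prep) {
  unlist(lapply(prep, function(p) p$pool[sample.int(length(p$pool), p$k)]),
         use.names = FALSE)
}

#' Draw a degree-matched random gene set
#'
#' For each reference gene, one gene is drawn uniformly without replacement
#' from that gene's degree bin, so every sample reproduces the reference
#' set's binned degree histogram exactly. Reference genes themselves remain
#' eligible (the standard null-model convention: the observed set must be a
#' possible draw from its own null), so a reference equal to a whole bin
#' simply returns that bin.
#'
#' @param net an [Interactome-class] (used only for validation).
#' @param bins a [DegreeBinning-class] built on `net`.
#' @param reference character vector of genes to match, all in the network.
#' @param seed integer seed; the draw is reproducible in isolation.
#' @return character vector of `length(reference)` distinct genes.
#' @export
sampleDegreeMatched <- function(net, bins, reference, seed = NULL) {
  reference <- unique(as.character(reference))
  missing <- setdiff(reference, nodes(net))
  if (length(missing)) stop("reference genes not in the network: ",
                            paste(head(missing, 5L), collapse = ", "))
  prep <- .matchPrep(bins, reference)
  withSeed(seed, .drawMatched(prep))
}
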