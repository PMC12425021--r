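# Small fixtures shared across test files. Everything is built in code.

pathNet <- function(syms = c("a", "b", "c", "d")) {
  interactomeFromEdges(cbind(syms[-length(syms)], syms[-1L]))
}

cliqueEdges <- function(syms) t(combn(syms, 2L))

# two 5-cliques joined by a single bridge edge
bridgedCliques <- function() {
  A <- paste0("a", 1:5); B <- paste0("b", 1:5)
  edges <- rbind(cliqueEdges(A), cliqueEdges(B), c("a1", "b1"))
  list(net = interactomeFromEdges(edges), A = A, B = B, edges = edges)
}

# a modest planted-module world reused by several files (cached per session)
.smallWorld <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthSpec(seed = 2024L, nNodes = 600L, meanDegree = 6,
                        modules = list(list(name = "Cell senescence",
                                            size = 15L, density = 0.8)))
      cache <<- synthInteractome(spec)
    }
    cache
  }
})

annotationFixture <- function() {
  data.frame(
    gene = c("g1", "g2", "g3", "g4", "g5", "g2"),
    hallmark = c("Cell senescence", "Cell senescence", "Cell senescence",
                 "Genomic instability", "Genomic instability",
                 "Genomic instability"),
    confidence = c(2L, 1L, 4L, 3L, 5L, 2L),
    stringsAsFactors = FALSE)
}
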