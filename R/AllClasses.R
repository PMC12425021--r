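#' @import methods
#' @importFrom stats sd setNames rnorm runif
#' @importFrom utils read.delim write.csv write.table head
NULL

#' Interactome: an undirected simple protein-protein interaction network
#'
#' Thin S4 wrapper around an \pkg{igraph} graph over gene symbols. The graph
#' is guaranteed simple (no self-loops, no multi-edges) and undirected; all
#' shortest-path services, degree bins and degree-matched nulls operate on it.
#' A per-object environment caches the all-pairs distance matrix so repeated
#' null-model evaluation does not recompute BFS trees.
#'
#' @slot graph an \code{igraph} object, undirected and simple, with vertex
#'   \code{name} attributes holding gene symbols.
#' @slot report named list describing how the object was built (counts of
#'   nodes, edges, dropped self-loops, collapsed duplicates).
#' @slot cache environment used internally to memoise distances.
#'
#' @seealso [loadInteractome()], [interactomeFromEdges()]
#' @export
setClass("Interactome",
  representation(graph = "ANY", report = "list", cache = "environment"))

setValidity("Interactome", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must be an igraph object")
  if (igraph::is_directed(g)) return("interactome must be undirected")
  if (any(igraph::which_loop(g))) return("interactome must not contain self-loops")
  if (any(igraph::which_multiple(g))) return("interactome must not contain duplicate edges")
  if (igraph::vcount(g) == 0L) return("interactome is empty")
  if (is.null(igraph::V(g)$name)) return("vertices must carry gene-symbol names")
  TRUE
})

#' DegreeBinning: log-spaced degree bins with a minimum occupancy
#'
#' Partition of the interactome's nodes into degree intervals with
#' logarithmically spaced boundaries, adjacent bins merged upward until each
#' holds at least \code{minOccupancy} nodes. Degree-matched null sampling
#' replaces each gene by a random gene from its own bin, preserving the
#' binned degree distribution of the reference set exactly.
#'
#' @slot bins list of character vectors, one per bin, ascending in degree.
#' @slot breaks numeric vector of degree interval boundaries (length
#'   \code{length(bins) + 1}); bin i covers degrees in
#'   \code{[breaks[i], breaks[i+1])}, last bin right-closed.
#' @slot nodeBin named integer vector mapping every node to its bin index.
#' @slot minOccupancy integer, the occupancy floor used at construction.
#'
#' @seealso [buildDegreeBins()], [sampleDegreeMatched()]
#' @export
setClass("DegreeBinning",
  representation(bins = "list", breaks = "numeric",
                 nodeBin = "integer", minOccupancy = "integer"))

setValidity("DegreeBinning", function(object) {
  all_nodes <- unlist(object@bins, use.names = FALSE)
  if (anyDuplicated(all_nodes)) return("bins must be pairwise disjoint")
  if (!setequal(all_nodes, names(object@nodeBin)))
    return("bins must partition exactly the nodes in nodeBin")
  if (length(object@breaks) != length(object@bins) + 1L)
    return("breaks must bound the bins")
  if (is.unsorted(object@breaks, strictly = TRUE))
    return("degree boundaries must be strictly ascending")
  TRUE
})

#' LCCResult: observed module size against a degree-matched null
#'
#' @slot observedSize integer size of the largest connected component (LCC)
#'   induced by the gene set.
#' @slot members character vector, the LCC's gene symbols.
#' @slot nullMean,nullSd moments of the null LCC-size distribution from
#'   degree-matched random gene sets.
#' @slot z standardized LCC size, \code{(observed - nullMean)/nullSd};
#'   \code{NA} when the null is degenerate (\code{nullSd == 0}).
#' @slot empiricalP smoothed empirical p-value, \code{(r + 1)/(n + 1)} where
#'   r counts null sizes >= observed.
#' @slot nRandom number of null replicates.
#' @export
setClass("LCCResult",
  representation(observedSize = "integer", members = "character",
                 nullMean = "numeric", nullSd = "numeric", z = "numeric",
                 empiricalP = "numeric", nRandom = "integer"))

#' SeparationResult: network separation of two gene sets
#'
#' Nearest-neighbour separation s_AB = d_AB - (d_AA + d_BB)/2, where within-
#' and cross-set terms are means of per-node distances to the closest other
#' member of the relevant set (the node itself never counts as its own
#' nearest neighbour). Unreachable node/set pairs are excluded from the means
#' and counted in \code{nUnreachable}.
#'
#' @slot sAB,dAB,dAA,dBB the separation and its three distance components.
#' @slot nUnreachable number of node-to-set distances dropped as infinite.
#' @export
setClass("SeparationResult",
  representation(sAB = "numeric", dAB = "numeric", dAA = "numeric",
                 dBB = "numeric", nUnreachable = "integer"))

#' OverlapResult: Jaccard overlap of two gene sets with resampling p-value
#'
#' @slot jaccard |A intersect B| / |A union B| (0 for an empty union).
#' @slot pValue smoothed resampling p-value against uniform random sets of
#'   the same sizes drawn from the universe.
#' @slot nCommon size of the intersection.
#' @export
setClass("OverlapResult",
  representation(jaccard = "numeric", pValue = "numeric", nCommon = "integer"))

#' ProximityResult: closest-distance drug-module proximity with null z-score
#'
#' Raw proximity is the mean, over network-mapped drug targets, of each
#' target's shortest-path distance to the nearest module gene. Significance
#' comes from re-measuring proximity for degree-matched random replacements
#' of both gene sets; \code{z < -1.96} is classed \code{"significant"},
#' \code{-1.96 <= z < -1.645} \code{"marginal"}, otherwise \code{"ns"}.
#'
#' @slot pRaw raw proximity (mean closest distance).
#' @slot nullMean,nullSd null-distribution moments.
#' @slot z standardized proximity; \code{NA} when the null is degenerate.
#' @slot nTargetsUsed,nTargetsDropped counts of targets that mapped to the
#'   network and were reachable, versus dropped.
#' @slot significance one of \code{"significant"}, \code{"marginal"},
#'   \code{"ns"}.
#' @slot degenerateNull TRUE when the null had zero spread.
#' @export
setClass("ProximityResult",
  representation(pRaw = "numeric", nullMean = "numeric", nullSd = "numeric",
                 z = "numeric", nTargetsUsed = "integer",
                 nTargetsDropped = "integer", significance = "character",
                 degenerateNull = "logical"))

#' PAGEResult: directional sign-concordance of a drug signature with aging
#'
#' Over the module genes measured with nonzero value in both the aging and
#' the drug signature, each gene contributes -sign(aging) * sign(drug): +1
#' when the drug opposes the age-associated change, -1 when it reinforces
#' it. pAGE is the (optionally magnitude-weighted) mean contribution, so
#' pAGE > 0 marks a pro-longevity (beneficial) direction and pAGE < 0 an
#' age-accelerating (deficient) one.
#'
#' @slot page the pAGE value in [-1, 1]; NA when no gene qualifies.
#' @slot z permutation z-score against random gene sets of the same size
#'   from the doubly-measured universe (NA until [pageSignificance()] fills
#'   it, or when the null is degenerate).
#' @slot nGenesUsed number of genes entering the mean.
#' @slot contributions named numeric vector of per-gene contributions.
#' @slot direction \code{"beneficial"}, \code{"deficient"} or
#'   \code{"undefined"}.
#' @export
setClass("PAGEResult",
  representation(page = "numeric", z = "numeric", nGenesUsed = "integer",
                 contributions = "numeric", direction = "character"))

#' ValidationSummary: capture accounting for an external drug cohort
#'
#' @slot cohort cohort name.
#' @slot nTotal,nSignificant,nMarginal cohort size and hit counts (best
#'   proximity z across hallmarks and levels; significant z < -1.96,
#'   marginal -1.96 <= z < -1.645).
#' @slot captureFraction (nSignificant + nMarginal)/nTotal.
#' @slot unscreened drugs in the cohort absent from the screen table.
#' @export
setClass("ValidationSummary",
  representation(cohort = "character", nTotal = "integer",
                 nSignificant = "integer", nMarginal = "integer",
                 captureFraction = "numeric", unscreened = "character"))

setValidity("ValidationSummary", function(object) {
  if (object@nTotal < 1L) return("cohort must be non-empty")
  cf <- (object@nSignificant + object@nMarginal) / object@nTotal
  if (abs(cf - object@captureFraction) > 1e-12)
    return("captureFraction must equal (nSignificant + nMarginal)/nTotal")
  TRUE
})
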