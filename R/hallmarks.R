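# Confidence-stratified hallmark gene sets, module (LCC) detection with
# degree-matched significance, pairwise separation / Jaccard overlap, and the
# union "longevity module".

#' The eleven hallmark-of-aging labels
#'
#' Canonical hallmark names accepted by the annotation readers and set
#' builders. Annotations carrying any other hallmark label are rejected.
#'
#' @return character vector of length 11.
#' @export
hallmarkNames <- function() {
  c("Genomic instability",
    "Telomere attrition",
    "Epigenetic alterations",
    "Loss of proteostasis",
    "Disabled macroautophagy",
    "Deregulated nutrient sensing",
    "Mitochondrial dysfunction",
    "Cell senescence",
    "Exhaustion of stem cells",
    "Altered intercellular communication",
    "Changes in the extracellular matrix structure")
}

#' Read gene-to-hallmark annotations
#'
#' Reads a TSV with columns `gene`, `hallmark`, `confidence` (evidence tier
#' 1 = strongest to 5 = weakest). Duplicate (gene, hallmark) pairs keep the
#' strongest (lowest) confidence.
#'
#' @param path TSV file path.
#' @return data.frame with columns gene, hallmark, confidence.
#' @export
readHallmarkAnnotations <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene", "hallmark", "confidence")
  if (!all(need %in% names(ann)))
    stop("annotation file needs columns: ", paste(need, collapse = ", "))
  ann <- ann[, need]
  ann$gene <- trimws(ann$gene)
  ann$hallmark <- trimws(ann$hallmark)
  ann$confidence <- as.integer(ann$confidence)
  .validateAnnotations(ann)
}

#' Read per-confidence-level GMT files as hallmark annotations
#'
#' One GMT file per confidence level; each GMT row is
#' `hallmark<TAB>description<TAB>gene...`. Levels are taken from the names
#' of `paths` (coercible to integers 1-5).
#'
#' @param paths named character vector of GMT paths; names are the levels.
#' @return data.frame as from [readHallmarkAnnotations()].
#' @export
readHallmarkGMT <- function(paths) {
  if (is.null(names(paths))) stop("paths must be named by confidence level")
  rows <- list()
  for (lv in names(paths)) {
    for (ln in readLines(paths[[lv]], warn = FALSE)) {
      if (!nzchar(trimws(ln))) next
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 3L) stop("malformed GMT row in ", paths[[lv]])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = trimws(f[-(1:2)]), hallmark = trimws(f[1L]),
        confidence = as.integer(lv), stringsAsFactors = FALSE)
    }
  }
  .validateAnnotations(do.call(rbind, rows))
}

.validateAnnotations <- function(ann) {
  bad <- setdiff(unique(ann$hallmark), hallmarkNames())
  if (length(bad))
    stop("unknown hallmark name(s): ", paste(bad, collapse = "; "),
         "\nvalid names are: ", paste(hallmarkNames(), collapse = "; "))
  if (any(is.na(ann$confidence)) || !all(ann$confidence %in% 1:5))
    stop("confidence must be an integer in 1..5")
  # duplicates keep the strongest evidence (lowest confidence)
  ann <- ann[order(ann$gene, ann$hallmark, ann$confidence), ]
  ann <- ann[!duplicated(ann[, c("gene", "hallmark")]), ]
  rownames(ann) <- NULL
  ann
}

#' Confidence-stratified hallmark gene sets
#'
#' Builds the cumulative gene set of each hallmark at a given evidence
#' level: all genes annotated to the hallmark with confidence `<= level`,
#' intersected with the network. Sets are therefore nested across levels.
#' Genes absent from the network are reported in the `"unmapped"` attribute,
#' never silently dropped; hallmarks with an empty set at this level trigger
#' a warning (some hallmarks carry no top-tier evidence).
#'
#' @param annotations data.frame from [readHallmarkAnnotations()].
#' @param net an [Interactome-class].
#' @param level confidence cut in 1..5 (1 keeps only the strongest tier).
#' @return named list (one element per hallmark present in `annotations`)
#'   of character gene vectors, with attribute `unmapped`.
#' @export
buildHallmarkSets <- function(annotations, net, level) {
  stopifnot(level %in% 1:5)
  annotations <- .validateAnnotations(annotations)
  keep <- annotations[annotations$confidence <= level, ]
  marks <- sort(unique(annotations$hallmark))
  netNodes <- nodes(net)
  unmapped <- character(0)
  sets <- setNames(vector("list", length(marks)), marks)
  for (h in marks) {
    g <- unique(keep$gene[keep$hallmark == h])
    off <- setdiff(g, netNodes)
    unmapped <- union(unmapped, off)
    sets[[h]] <- sort(intersect(g, netNodes))
    if (length(sets[[h]]) == 0L)
      warning("hallmark '", h, "' has no network-mapped genes at level ", level)
  }
  attr(sets, "unmapped") <- unmapped
  attr(sets, "level") <- as.integer(level)
  sets
}

#' Largest connected component induced by a gene set
#'
#' Node set of the largest connected component of the subgraph induced by
#' `genes`. Size ties are broken by the lexicographically smallest member
#' set, so the result is deterministic.
#'
#' @param net an [Interactome-class].
#' @param genes character vector (intersected with the network).
#' @return sorted character vector (empty for empty input).
#' @export
largestConnectedComponent <- function(net, genes) {
  genes <- intersect(unique(genes), nodes(net))
  if (length(genes) == 0L) return(character(0))
  sub <- igraph::induced_subgraph(net@graph, genes)
  comp <- igraph::components(sub)
  best <- which(comp$csize == max(comp$csize))
  cand <- lapply(best, function(b)
    sort(names(comp$membership)[comp$membership == b]))
  cand[[order(vapply(cand, paste, "", collapse = "\r"))[1L]]]
}

# Fast LCC size for null replicates: membership ids on a prebuilt subgraph
# machinery would still pay igraph construction; induced_subgraph on vertex
# ids is cheap enough at null set sizes (tens of genes).
.lccSize <- function(graph, vids) {
  if (length(vids) == 0L) return(0L)
  as.integer(max(igraph::components(igraph::induced_subgraph(graph, vids))$csize))
}

#' Significance of a gene set's largest connected component
#'
#' Compares the observed LCC size with the LCC sizes of `nRandom`
#' degree-matched random gene sets (same size, same binned degree
#' distribution; see [sampleDegreeMatched()]). Reports the z-score and a
#' smoothed empirical p-value, `(r + 1)/(nRandom + 1)` with r the number of
#' null LCCs at least as large as observed. `z > 1.96` is the conventional
#' module-significance cut and `z > 1.645` marginal significance.
#'
#' @param net an [Interactome-class].
#' @param genes gene set (at least 2 network-mapped genes).
#' @param bins optional [DegreeBinning-class]; built on demand.
#' @param nRandom null replicates (default 1000).
#' @param seed master seed; each replicate gets a spawned sub-seed.
#' @param minOccupancy passed to [buildDegreeBins()] when `bins` is NULL.
#' @return an [LCCResult-class].
#' @export
lccSignificance <- function(net, genes, bins = NULL, nRandom = 1000L,
                            seed = NULL, minOccupancy = 100L) {
  genes <- intersect(unique(genes), nodes(net))
  if (length(genes) < 2L) stop("need at least 2 network-mapped genes")
  if (is.null(bins)) bins <- buildDegreeBins(net, minOccupancy)
  members <- largestConnectedComponent(net, genes)
  observed <- length(members)
  prep <- .matchPrep(bins, genes)
  vidOf <- setNames(seq_along(nodes(net)), nodes(net))
  seeds <- spawnSeeds(seed, nRandom)
  nullSizes <- vapply(seq_len(nRandom), function(i) {
    smp <- withSeed(seeds[i], .drawMatched(prep))
    .lccSize(net@graph, vidOf[smp])
  }, integer(1))
  mu <- mean(nullSizes); sdev <- sd(nullSizes)
  new("LCCResult",
      observedSize = as.integer(observed), members = members,
      nullMean = mu, nullSd = sdev,
      z = if (sdev > 0) (observed - mu) / sdev else NA_real_,
      empiricalP = empiricalP(nullSizes, observed, "ge"),
      nRandom = as.integer(nRandom))
}

setMethod("show", "LCCResult", function(object) {
  cat(sprintf("LCC of %d genes | null %.2f +/- %.2f | z = %s | p = %.4g (n = %d)\n",
              object@observedSize, object@nullMean, object@nullSd,
              ifelse(is.na(object@z), "NA", sprintf("%.2f", object@z)),
              object@empiricalP, object@nRandom))
})

# Mean nearest-neighbour distance from each node of `from` to the set `to`,
# never counting a node as its own nearest neighbour. Infinite distances are
# dropped from the mean and counted.
.nnMean <- function(net, from, to) {
  if (length(from) == 0L || length(to) == 0L)
    return(list(mean = NA_real_, dropped = 0L))
  dm <- .pairDist(net, from, to)
  selfCol <- match(from, colnames(dm))
  vals <- vapply(seq_along(from), function(i) {
    row <- dm[i, ]
    if (!is.na(selfCol[i])) row[selfCol[i]] <- Inf   # exclude self
    min(row)
  }, numeric(1))
  finite <- is.finite(vals)
  list(mean = if (any(finite)) mean(vals[finite]) else Inf,
       dropped = sum(!finite))
}

#' Network separation of two gene sets
#'
#' Computes s_AB = d_AB - (d_AA + d_BB)/2 under the nearest-neighbour
#' convention: d_AA is the mean over genes a of the distance to the closest
#' other member of A (0 for a singleton set), and d_AB averages, over every
#' node of A and of B, its distance to the nearest member of the other set
#' (excluding itself, so identical sets separate by exactly 0). Unreachable
#' node/set pairs are excluded from the means and counted. Negative s_AB
#' marks overlapping network neighbourhoods, positive s_AB topologically
#' distinct modules.
#'
#' @param net an [Interactome-class].
#' @param setA,setB gene sets (non-empty after network intersection).
#' @return a [SeparationResult-class].
#' @export
separation <- function(net, setA, setB) {
  setA <- intersect(unique(setA), nodes(net))
  setB <- intersect(unique(setB), nodes(net))
  if (length(setA) == 0L || length(setB) == 0L)
    stop("both gene sets must map to the network")
  within <- function(s) {
    if (length(s) == 1L) return(list(mean = 0, dropped = 0L))
    .nnMean(net, s, s)
  }
  aa <- within(setA); bb <- within(setB)
  ab <- .nnMean(net, setA, setB)
  ba <- .nnMean(net, setB, setA)
  # pooled cross mean over all |A| + |B| node-level distances
  crossVals <- c(rep(ab$mean, length(setA) - ab$dropped),
                 rep(ba$mean, length(setB) - ba$dropped))
  crossDropped <- ab$dropped + ba$dropped
  dAB <- if (length(crossVals) && all(is.finite(crossVals))) mean(crossVals) else Inf
  new("SeparationResult",
      sAB = dAB - (aa$mean + bb$mean) / 2, dAB = dAB,
      dAA = aa$mean, dBB = bb$mean,
      nUnreachable = as.integer(aa$dropped + bb$dropped + crossDropped))
}

setMethod("show", "SeparationResult", function(object) {
  cat(sprintf("separation s_AB = %.3f (d_AB = %.3f, d_AA = %.3f, d_BB = %.3f",
              object@sAB, object@dAB, object@dAA, object@dBB))
  if (object@nUnreachable > 0L)
    cat(";", object@nUnreachable, "unreachable pairs dropped")
  cat(")\n")
})

#' Jaccard overlap of two gene sets with resampling significance
#'
#' Jaccard index |A intersect B| / |A union B| plus a smoothed resampling
#' p-value: sets of the same two sizes are drawn uniformly (without
#' replacement) from the universe and the fraction of null Jaccard values at
#' least as large as observed is reported with (r + 1)/(n + 1) smoothing.
#' Degree plays no role here — overlap is a set property, not a network one.
#'
#' @param setA,setB gene sets, subsets of `universe`.
#' @param universe the annotated-gene universe to resample from.
#' @param nRandom null replicates (default 1000).
#' @param seed master seed.
#' @return an [OverlapResult-class].
#' @export
jaccardOverlap <- function(setA, setB, universe, nRandom = 1000L, seed = NULL) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("both sets must be subsets of the universe")
  jac <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0L) 0 else length(intersect(a, b)) / u
  }
  obs <- jac(setA, setB)
  seeds <- spawnSeeds(seed, nRandom)
  nullJ <- vapply(seq_len(nRandom), function(i) withSeed(seeds[i], {
    a <- universe[sample.int(length(universe), length(setA))]
    b <- universe[sample.int(length(universe), length(setB))]
    jac(a, b)
  }), numeric(1))
  new("OverlapResult", jaccard = obs,
      pValue = empiricalP(nullJ, obs, "ge"),
      nCommon = length(intersect(setA, setB)))
}

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("Jaccard = %.3f (%d shared genes), resampling p = %.4g\n",
              object@jaccard, object@nCommon, object@pValue))
})

#' The longevity module: LCC of the union of all hallmark gene sets
#'
#' Merges the hallmark gene sets, takes the largest connected component of
#' the union, and annotates each member gene with the number of hallmarks it
#' belongs to (multi-hallmark genes are the connective tissue of the merged
#' module).
#'
#' @param net an [Interactome-class].
#' @param hallmarkSets named list of gene sets (at least two), e.g. from
#'   [buildHallmarkSets()].
#' @return list with `genes` (the union LCC) and `membership` (named integer
#'   vector: hallmark count per LCC gene).
#' @export
longevityModule <- function(net, hallmarkSets) {
  if (length(hallmarkSets) < 2L) stop("need at least two hallmark sets")
  all_genes <- unique(unlist(hallmarkSets, use.names = FALSE))
  lcc <- largestConnectedComponent(net, all_genes)
  counts <- table(unlist(lapply(hallmarkSets, unique), use.names = FALSE))
  membership <- setNames(as.integer(counts[lcc]), lcc)
  membership[is.na(membership)] <- 0L
  list(genes = lcc, membership = membership)
}
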