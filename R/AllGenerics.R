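#' Gene symbols of an interactome
#' @param x an [Interactome-class] object.
#' @return character vector of node names.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' Node degrees of an interactome
#' @param x an [Interactome-class] object.
#' @return named integer vector of degrees.
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))

#' Number of edges
#' @param x an [Interactome-class] object.
#' @return integer edge count.
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Load report of an interactome
#' @param x an [Interactome-class] object.
#' @return named list with nodes, edges, selfLoopsDropped,
#'   duplicatesCollapsed.
#' @export
setGeneric("loadReport", function(x) standardGeneric("loadReport"))
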