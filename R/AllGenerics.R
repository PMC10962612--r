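#' Accessor generics
#'
#' @param x an object of the corresponding mNFE class.
#' @param ... passed to methods.
#' @return `abundances` the abundance matrix; `taxonLineages` the lineage
#'   strings; `sampleDays`, `sampleIndividuals`, `sampleGroups` per-sample
#'   metadata vectors; `networkNodes`/`networkEdges` the node vector and the
#'   edge data.frame; `mnfe` the global score of an [MnfeResult-class];
#'   `perTaxonScores` its per-taxon differential table; `signalDays` /
#'   `firstSignal` the flagged days of a [SignalCall-class]; `dnbTaxa` the
#'   ranked taxa of a [DnbSet-class]; `fragilityAuc` the normalized AUC of a
#'   [FragilityCurve-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("abundances", function(x, ...) standardGeneric("abundances"))

#' @rdname accessors
#' @export
setGeneric("taxonLineages", function(x) standardGeneric("taxonLineages"))

#' @rdname accessors
#' @export
setGeneric("sampleDays", function(x) standardGeneric("sampleDays"))

#' @rdname accessors
#' @export
setGeneric("sampleIndividuals", function(x) standardGeneric("sampleIndividuals"))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("mnfe", function(x) standardGeneric("mnfe"))

#' @rdname accessors
#' @export
setGeneric("perTaxonScores", function(x) standardGeneric("perTaxonScores"))

#' @rdname accessors
#' @export
setGeneric("signalDays", function(x) standardGeneric("signalDays"))

#' @rdname accessors
#' @export
setGeneric("firstSignal", function(x) standardGeneric("firstSignal"))

#' @rdname accessors
#' @export
setGeneric("dnbTaxa", function(x) standardGeneric("dnbTaxa"))

#' @rdname accessors
#' @export
setGeneric("fragilityAuc", function(x) standardGeneric("fragilityAuc"))

#' Connectivity of an association network
#'
#' Node and edge counts of an [AssociationNetwork-class] (the two
#' connectivity properties used to compare group-level networks).
#'
#' @param x an `AssociationNetwork`.
#' @return named numeric `c(nodes = ..., edges = ...)`.
#' @examples
#' net <- asAssociationNetwork(data.frame(from = c("a", "a", "b"),
#'                                        to   = c("b", "c", "c"),
#'                                        weight = 1))
#' connectivity(net)  # triangle: 3 nodes, 3 edges
#' @export
setGeneric("connectivity", function(x) standardGeneric("connectivity"))
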