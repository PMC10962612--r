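#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' TaxonProfile: longitudinal taxon-abundance table
#'
#' A \linkS4class{SummarizedExperiment} holding a non-negative taxa x samples
#' abundance matrix (assay \code{"abundance"}), taxonomy lineage strings in
#' \code{rowData(x)$lineage} and per-sample metadata in \code{colData}
#' (\code{individual}, \code{day}, \code{group}).  Columns are kept ordered
#' by individual and collection day.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso [TaxonProfile()] for construction, [readTaxonProfile()] for file
#'   input, [aggregateToLevel()], [normalizeRelative()].
#' @exportClass TaxonProfile
setClass("TaxonProfile", contains = "SummarizedExperiment")

setValidity("TaxonProfile", function(object) {
    msg <- character()
    if (!("abundance" %in% assayNames(object)))
        msg <- c(msg, "assay 'abundance' is required")
    else {
        a <- assay(object, "abundance")
        if (!is.numeric(a)) msg <- c(msg, "abundance must be numeric")
        else {
            if (any(!is.finite(a))) msg <- c(msg, "abundance has non-finite entries")
            else if (any(a < 0)) msg <- c(msg, "abundance has negative entries")
        }
    }
    if (nrow(object) < 2L) msg <- c(msg, "at least 2 taxa required")
    if (ncol(object) < 2L) msg <- c(msg, "at least 2 samples required")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample id")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "taxon ids must be unique and non-NULL")
    cd <- colData(object)
    for (f in c("individual", "day"))
        if (!(f %in% colnames(cd))) msg <- c(msg, sprintf("colData field '%s' is required", f))
    if (all(c("individual", "day") %in% colnames(cd))) {
        byInd <- split(as.numeric(cd$day), as.character(cd$individual))
        bad <- vapply(byInd, function(d) any(diff(d) <= 0), logical(1))
        if (any(bad))
            msg <- c(msg, sprintf("collection days not strictly increasing within individual(s): %s",
                                  paste(names(byInd)[bad], collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' AssociationNetwork: undirected weighted taxon association graph
#'
#' Nodes are taxon ids retained after prevalence filtering; edges are
#' unordered taxon pairs with a signed weight (averaged neighborhood
#' regression coefficient).  The \code{provenance} list records how the
#' network was produced: \code{type} ("reference" for an ARN, "perturbed"
#' for an SSAN), \code{caseDay} (the day of the added case sample, NA for an
#' ARN), the lambda path, the selected lambda and the settings used.
#'
#' @slot nodes character vector of taxon ids.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{weight};
#'   \code{from < to} canonically, no self loops, no duplicates.
#' @slot provenance list of inference metadata.
#' @seealso [inferMbNetwork()], [buildSsan()], [extractLocal()],
#'   [connectivity()], [fragility()].
#' @exportClass AssociationNetwork
setClass("AssociationNetwork",
    representation(nodes = "character", edges = "data.frame",
                   provenance = "list"))

setValidity("AssociationNetwork", function(object) {
    msg <- character()
    e <- object@edges
    if (!all(c("from", "to", "weight") %in% colnames(e)))
        return("edges must have columns from, to, weight")
    if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node ids")
    if (nrow(e)) {
        if (any(e$from == e$to)) msg <- c(msg, "self loops are not allowed")
        if (any(e$from >= e$to)) msg <- c(msg, "edges must be stored with from < to")
        if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
            msg <- c(msg, "duplicate edges")
        if (!all(c(e$from, e$to) %in% object@nodes))
            msg <- c(msg, "edge endpoint not in node set")
        if (any(!is.finite(e$weight))) msg <- c(msg, "non-finite edge weight")
    }
    if (length(msg)) msg else TRUE
})

#' MnfeResult: one case sample scored against a reference set
#'
#' Stores the global score \code{deltaNfe(x)} = mean NFE over the SSAN's
#' local networks (n + 1 samples) minus mean NFE over the ARN's local
#' networks (n samples), together with both per-taxon NFE vectors and the
#' per-taxon differentials used for DNB ranking.
#'
#' @slot day numeric scalar, collection day of the case sample.
#' @slot nfeReference named numeric, NFE of each ARN local network.
#' @slot nfePerturbed named numeric, NFE of each SSAN local network.
#' @slot perTaxon data.frame(taxon, deltaNfe, onlyIn) where \code{onlyIn}
#'   flags taxa present in just one of the two networks ("" if in both).
#' @slot score numeric scalar, mean(nfePerturbed) - mean(nfeReference).
#' @exportClass MnfeResult
setClass("MnfeResult",
    representation(day = "numeric", nfeReference = "numeric",
                   nfePerturbed = "numeric", perTaxon = "data.frame",
                   score = "numeric"))

setValidity("MnfeResult", function(object) {
    msg <- character()
    if (length(object@score) != 1L) msg <- c(msg, "score must be scalar")
    mR <- if (length(object@nfeReference)) mean(object@nfeReference) else 0
    mP <- if (length(object@nfePerturbed)) mean(object@nfePerturbed) else 0
    if (length(object@score) == 1L && abs(object@score - (mP - mR)) > 1e-12)
        msg <- c(msg, "score does not equal the difference of stored means")
    if (length(msg)) msg else TRUE
})

#' GrnModel: eight-node regulatory network with a programmed bifurcation
#'
#' Hill-form dynamics on eight nodes.  Node 1 is the critical core: for
#' p < 0 its Hill amplitude and basal rate co-vary so that the operating
#' point stays pinned while the dominant Jacobian eigenvalue equals
#' \code{eigenSlope} * p (pure stability loss, reaching zero exactly at
#' p = 0, where the fixed point meets the fold tangency); for p >= 0 the
#' basal rate is pushed past the fold and the system escapes to the
#' distant high state.  Nodes 2-8 form a mixed activation/repression
#' cascade driven by node 1.  See [grnModel()] for the construction.
#'
#' @slot nodes character(8) node ids.
#' @slot edges data.frame(from, to, sign) signed directed regulation edges.
#' @slot params list of kinetic parameters: degradation \code{d}, Hill
#'   threshold \code{K} and coefficient \code{h} of the core, coupling
#'   thresholds, basal rates, \code{basalScale}, \code{eigenSlope},
#'   \code{stateScale}, and the solved \code{basalCritical} / tangency
#'   location \code{xSaddle}.
#' @slot sigma default additive noise strength for simulation.
#' @seealso [grnModel()], [simulateGrn()], [sweepAndScore()].
#' @exportClass GrnModel
setClass("GrnModel",
    representation(nodes = "character", edges = "data.frame",
                   params = "list", sigma = "numeric"))

setValidity("GrnModel", function(object) {
    msg <- character()
    if (length(object@nodes) != 8L) msg <- c(msg, "exactly 8 nodes required")
    if (object@sigma < 0) msg <- c(msg, "sigma must be non-negative")
    need <- c("d", "K", "h", "basalScale", "basalCritical", "xSaddle")
    if (!all(need %in% names(object@params)))
        msg <- c(msg, "incomplete kinetic parameter list")
    if (length(msg)) msg else TRUE
})

#' SignalCall: early-warning trigger decisions for one score series
#'
#' Day T fires when score_T > factor * score_(T-1); the first time point can
#' never fire.  The first flagged day is the headline tipping-point call;
#' all flagged days are kept.
#'
#' @slot individual individual id ("" if not applicable).
#' @slot days,scores the evaluated series, days strictly increasing.
#' @slot signalDays days at which the trigger fired (possibly empty).
#' @slot firstSignal numeric(1) first flagged day, or numeric(0) if none.
#' @slot onsetDay known clinical/programmed onset day(s), may be empty.
#' @slot factor the ratio threshold used (default 1.5).
#' @seealso [detectTipping()], [chaoSignal()].
#' @exportClass SignalCall
setClass("SignalCall",
    representation(individual = "character", days = "numeric",
                   scores = "numeric", signalDays = "numeric",
                   firstSignal = "numeric", onsetDay = "numeric",
                   factor = "numeric"))

setValidity("SignalCall", function(object) {
    msg <- character()
    if (any(diff(object@days) <= 0)) msg <- c(msg, "days must be strictly increasing")
    if (length(object@days) != length(object@scores))
        msg <- c(msg, "days and scores lengths differ")
    if (length(object@days) && length(object@signalDays) &&
        object@days[1L] %in% object@signalDays)
        msg <- c(msg, "the first time point cannot be a signal")
    if (!all(object@signalDays %in% object@days))
        msg <- c(msg, "signal days must be evaluated days")
    if (length(msg)) msg else TRUE
})

#' DnbSet: dynamic network biomarkers called at a critical state
#'
#' The top \code{fraction} (default 10\%, ceiling) of taxa ranked by their
#' per-taxon mNFE differential at the called day.  Ties at the cutoff are
#' broken by lexicographic taxon id.
#'
#' @slot individual individual id.
#' @slot day the critical-state day.
#' @slot taxa ranked DNB taxon ids (largest score first).
#' @slot scores scores parallel to \code{taxa}.
#' @slot fraction fraction of scored taxa retained.
#' @slot nScored total number of scored taxa the fraction applied to.
#' @slot group group label of the individual ("" if unknown).
#' @exportClass DnbSet
setClass("DnbSet",
    representation(individual = "character", day = "numeric",
                   taxa = "character", scores = "numeric",
                   fraction = "numeric", nScored = "integer",
                   group = "character"))

setValidity("DnbSet", function(object) {
    msg <- character()
    k <- as.integer(ceiling(object@fraction * object@nScored))
    if (length(object@taxa) != k)
        msg <- c(msg, sprintf("expected ceiling(%g * %d) = %d taxa, got %d",
                              object@fraction, object@nScored, k, length(object@taxa)))
    if (length(object@taxa) != length(object@scores))
        msg <- c(msg, "taxa and scores lengths differ")
    if (length(msg)) msg else TRUE
})

#' FragilityCurve: giant-component decay under random node removal
#'
#' For each repeat, nodes are removed one at a time in random (or
#' degree-descending) order; after each removal the fraction of the
#' remaining nodes that belong to the giant (largest) component is
#' recorded.  Curves are averaged across repeats on the common
#' removed-fraction grid and summarized by the trapezoid AUC (normalized to
#' [0, 1]).  A connected network starts at giant fraction 1; a network
#' with several components starts at its largest component's share.
#'
#' @slot fractions removed-node fraction grid, starting at 0.
#' @slot giantFraction mean giant-component fraction at each grid point.
#' @slot repeats,seed,mode how the curve was computed.
#' @slot auc normalized area under the curve, in [0, 1].
#' @seealso [fragility()].
#' @exportClass FragilityCurve
setClass("FragilityCurve",
    representation(fractions = "numeric", giantFraction = "numeric",
                   repeats = "integer", seed = "numeric", auc = "numeric",
                   mode = "character"))

setValidity("FragilityCurve", function(object) {
    msg <- character()
    if (length(object@fractions) != length(object@giantFraction))
        msg <- c(msg, "grid and curve lengths differ")
    if (length(object@fractions)) {
        if (abs(object@fractions[1L]) > 1e-12)
            msg <- c(msg, "grid must start at removal fraction 0")
        if (object@giantFraction[1L] > 1 + 1e-12 ||
            object@giantFraction[1L] <= 0)
            msg <- c(msg, "initial giant fraction must lie in (0, 1]")
    }
    if (object@auc < -1e-12 || object@auc > 1 + 1e-12)
        msg <- c(msg, "AUC must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
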