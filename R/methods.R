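#' @describeIn accessors abundance matrix of a TaxonProfile
#' @export
setMethod("abundances", "TaxonProfile", function(x, ...) assay(x, "abundance"))

#' @describeIn accessors lineage strings (NA where unknown)
#' @export
setMethod("taxonLineages", "TaxonProfile", function(x) {
    rd <- rowData(x)
    if ("lineage" %in% colnames(rd)) as.character(rd$lineage)
    else rep(NA_character_, nrow(x))
})

#' @describeIn accessors collection days
#' @export
setMethod("sampleDays", "TaxonProfile", function(x) as.numeric(colData(x)$day))

#' @describeIn accessors individual ids
#' @export
setMethod("sampleIndividuals", "TaxonProfile",
          function(x) as.character(colData(x)$individual))

#' @describeIn accessors group labels (NA where unknown)
#' @export
setMethod("sampleGroups", "TaxonProfile", function(x) {
    cd <- colData(x)
    if ("group" %in% colnames(cd)) as.character(cd$group)
    else rep(NA_character_, ncol(x))
})

#' @describeIn accessors node ids of an AssociationNetwork
#' @export
setMethod("networkNodes", "AssociationNetwork", function(x) x@nodes)

#' @describeIn accessors edge table of an AssociationNetwork
#' @export
setMethod("networkEdges", "AssociationNetwork", function(x) x@edges)

#' @export
setMethod("connectivity", "AssociationNetwork", function(x)
    c(nodes = length(x@nodes), edges = nrow(x@edges)))

#' @describeIn accessors global mNFE score
#' @export
setMethod("mnfe", "MnfeResult", function(x) x@score)

#' @describeIn accessors per-taxon NFE differential table
#' @export
setMethod("perTaxonScores", "MnfeResult", function(x) x@perTaxon)

#' @describeIn accessors all flagged days
#' @export
setMethod("signalDays", "SignalCall", function(x) x@signalDays)

#' @describeIn accessors first flagged day (numeric(0) if none)
#' @export
setMethod("firstSignal", "SignalCall", function(x) x@firstSignal)

#' @describeIn accessors ranked DNB taxa
#' @export
setMethod("dnbTaxa", "DnbSet", function(x) x@taxa)

#' @describeIn accessors normalized fragility AUC
#' @export
setMethod("fragilityAuc", "FragilityCurve", function(x) x@auc)

setMethod("show", "TaxonProfile", function(object) {
    cat(sprintf("TaxonProfile: %d taxa x %d samples\n", nrow(object), ncol(object)))
    ind <- unique(sampleIndividuals(object))
    grp <- table(sampleGroups(object), useNA = "ifany")
    cat(sprintf("  individuals: %d; groups: %s\n", length(ind),
        paste(sprintf("%s=%d", names(grp), grp), collapse = ", ")))
    callNextMethod()
})

setMethod("show", "AssociationNetwork", function(object) {
    pv <- object@provenance
    cat(sprintf("AssociationNetwork (%s): %d nodes, %d edges\n",
        if (is.null(pv$type)) "unknown" else pv$type,
        length(object@nodes), nrow(object@edges)))
    if (!is.null(pv$caseDay) && !is.na(pv$caseDay))
        cat(sprintf("  case day: %s\n", format(pv$caseDay)))
    if (!is.null(pv$lambda))
        cat(sprintf("  lambda: %.4g\n", pv$lambda))
    invisible(NULL)
})

setMethod("show", "MnfeResult", function(object) {
    cat(sprintf("MnfeResult: day %s, mNFE score %.6g\n", format(object@day),
        object@score))
    cat(sprintf("  locals: %d reference, %d perturbed\n",
        length(object@nfeReference), length(object@nfePerturbed)))
    invisible(NULL)
})

setMethod("show", "SignalCall", function(object) {
    cat(sprintf("SignalCall%s: %d time points, factor %.3g\n",
        if (nzchar(object@individual)) paste0(" [", object@individual, "]") else "",
        length(object@days), object@factor))
    if (length(object@firstSignal))
        cat(sprintf("  first signal at day %s (all: %s)\n",
            format(object@firstSignal),
            paste(format(object@signalDays), collapse = ", ")))
    else cat("  no signal\n")
    invisible(NULL)
})

setMethod("show", "DnbSet", function(object) {
    cat(sprintf("DnbSet [%s] day %s: %d of %d taxa (top %.0f%%)\n",
        object@individual, format(object@day), length(object@taxa),
        object@nScored, 100 * object@fraction))
    utils::head(data.frame(taxon = object@taxa, score = object@scores), 5L) |>
        print()
    invisible(NULL)
})

setMethod("show", "FragilityCurve", function(object) {
    cat(sprintf("FragilityCurve (%s removal, %d repeats): AUC = %.4f\n",
        object@mode, object@repeats, object@auc))
    invisible(NULL)
})
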