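#' Score every individual of a longitudinal cohort with mNFE
#'
#' Follows the two reference conventions jointly.  The association
#' networks are inferred from the pooled normal samples — every
#' individual's first `nRefTimePoints` collection days — which gives the
#' neighborhood regressions a stable sample size; one ARN is inferred from
#' that pool and each later sample yields an SSAN (same node set and
#' penalty, case sample standardized against the reference geometry).
#' The network-flow-entropy probabilities, in contrast, use each
#' individual's own first `nRefTimePoints` samples as the n reference
#' columns, so NFE_n runs over that individual's reference samples and
#' NFE_(n+1) adds the case sample, as in the per-individual single-sample
#' formulation.
#'
#' @param x a [TaxonProfile-class] of counts.
#' @param nRefTimePoints leading time points per individual forming the
#'   reference (default 2).
#' @param pseudocount zero replacement (default 0.5).
#' @param prevalenceMin,lambdaMinRatio,nLambda,starsSubsamples,starsInstability
#'   network-inference settings, see [inferMbNetwork()].
#' @param seed RNG seed (StARS subsampling).
#' @param keepResults keep the full [MnfeResult-class] objects (needed for
#'   DNB calling; default TRUE).
#' @return list with `scores` (data.frame individual, day, score),
#'   `results` (per-individual lists of MnfeResult), `arn`, and
#'   `referenceIds` (the pooled network reference).
#' @export
scoreCohort <- function(x, nRefTimePoints = 2L, pseudocount = 0.5,
                        prevalenceMin = 0.2, lambdaMinRatio = 0.01,
                        nLambda = 20L, starsSubsamples = 20L,
                        starsInstability = 0.05, seed = NULL,
                        keepResults = TRUE) {
    counts <- abundances(x)
    ind <- sampleIndividuals(x)
    day <- sampleDays(x)
    inds <- unique(ind)
    refIds <- unique(unlist(lapply(inds, function(i)
        referenceSplit(x, i, nRefTimePoints)$reference)))
    refMat <- counts[, refIds, drop = FALSE]
    arn <- inferMbNetwork(refMat, lambdaMinRatio = lambdaMinRatio,
        nLambda = nLambda, starsSubsamples = starsSubsamples,
        starsInstability = starsInstability, prevalenceMin = prevalenceMin,
        pseudocount = pseudocount, seed = seed)
    refOrdered <- refMat[, order(colnames(refMat)), drop = FALSE]
    rel <- .closeColumns(counts, pseudocount)
    scores <- NULL
    results <- list()
    for (i in inds) {
        sp <- referenceSplit(x, i, nRefTimePoints)
        ownRef <- sp$reference[ind[match(sp$reference, colnames(counts))] == i]
        nfeRefI <- networkNfe(arn, rel[arn@nodes, ownRef, drop = FALSE])
        sp$case <- setdiff(sp$case, refIds)
        resI <- list()
        for (sid in sp$case) {
            cs <- counts[, sid]
            names(cs) <- rownames(counts)
            dy <- day[match(sid, colnames(counts))]
            ssan <- buildSsan(refOrdered, cs, arn, day = dy)
            nfeP <- networkNfe(ssan,
                rel[ssan@nodes, c(ownRef, sid), drop = FALSE])
            r <- .mnfeAssemble(nfeRefI, nfeP, dy)
            scores <- rbind(scores, data.frame(individual = i, day = dy,
                                               score = mnfe(r)))
            if (keepResults) resI[[sid]] <- r
        }
        if (keepResults) results[[i]] <- resI
    }
    list(scores = scores, results = results, arn = arn,
         referenceIds = refIds)
}

#' Early-warning calls for every individual of a scored cohort
#'
#' Applies [detectTipping()] to each individual's mNFE score series.  The
#' cohort default is the two-sided deviation rule: on this pipeline's
#' score series a perturbed sample announces itself as a sharp departure
#' (here a collapse) from the individual's running baseline, which the
#' one-sided ratio rule cannot catch; the ratio rule remains available
#' via `method = "ratio"`.
#'
#' @param scores the `scores` data.frame from [scoreCohort()].
#' @param factor ratio threshold (used by `method = "ratio"`).
#' @param method,zThreshold see [detectTipping()]; cohort defaults are
#'   `"deviation"` with 4 running SDs.
#' @param truth optional truth table (individual, group, transitionDay)
#'   whose onset days are attached to the calls.
#' @return named list of [SignalCall-class], one per individual.
#' @export
detectCohort <- function(scores, factor = 1.5, method = "deviation",
                         zThreshold = 4, truth = NULL) {
    out <- list()
    for (i in unique(scores$individual)) {
        s <- scores[scores$individual == i, ]
        s <- s[order(s$day), ]
        onset <- if (!is.null(truth)) {
            td <- truth$transitionDay[truth$individual == i]
            td[!is.na(td)]
        } else numeric(0)
        out[[i]] <- detectTipping(s$day, s$score, factor = factor,
                                  method = method, zThreshold = zThreshold,
                                  individual = i, onsetDay = onset)
    }
    out
}

#' Sensitivity/specificity summary of cohort early-warning calls
#'
#' A symptomatic individual counts as detected when its first signal falls
#' at or before its programmed transition day; any signal on a control
#' individual is a false flag.
#'
#' @param calls list of [SignalCall-class] from [detectCohort()].
#' @param truth data.frame with individual, group, transitionDay.
#' @return list with counts: `nSymptomatic`, `nDetected`, `nControls`,
#'   `nFalseFlagged`, plus the per-individual table.
#' @export
evaluateCohortCalls <- function(calls, truth) {
    rows <- lapply(truth$individual, function(i) {
        cl <- calls[[i]]
        fs <- if (is.null(cl) || !length(firstSignal(cl))) NA_real_
              else firstSignal(cl)
        data.frame(individual = i,
                   group = truth$group[truth$individual == i],
                   transitionDay = truth$transitionDay[truth$individual == i],
                   firstSignal = fs)
    })
    tab <- do.call(rbind, rows)
    sym <- tab[tab$group != "control", ]
    ctl <- tab[tab$group == "control", ]
    list(nSymptomatic = nrow(sym),
         nDetected = sum(!is.na(sym$firstSignal) &
                         sym$firstSignal <= sym$transitionDay),
         nControls = nrow(ctl),
         nFalseFlagged = sum(!is.na(ctl$firstSignal)),
         table = tab)
}

#' DNB sets for the symptomatic individuals of a scored cohort
#'
#' For each individual with a signal, ranks taxa by their per-taxon mNFE
#' differential at the called critical-state day and keeps the top
#' `fraction` ([identifyDnb()]).
#'
#' @param scored result of [scoreCohort()] (with `keepResults = TRUE`).
#' @param calls result of [detectCohort()].
#' @param truth optional truth/group table (individual, group).
#' @param fraction DNB fraction (default 0.10).
#' @return named list of [DnbSet-class] for individuals with a signal.
#' @export
cohortDnbSets <- function(scored, calls, truth = NULL, fraction = 0.10) {
    out <- list()
    for (i in names(calls)) {
        fs <- firstSignal(calls[[i]])
        if (!length(fs)) next
        resI <- scored$results[[i]]
        days <- vapply(resI, function(r) r@day, numeric(1))
        r <- resI[[which(days == fs)[1L]]]
        pt <- perTaxonScores(r)
        sc <- stats::setNames(pt$deltaNfe, pt$taxon)
        grp <- if (!is.null(truth)) truth$group[truth$individual == i] else ""
        out[[i]] <- identifyDnb(sc, fraction = fraction, individual = i,
                                day = fs, group = grp)
    }
    out
}
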