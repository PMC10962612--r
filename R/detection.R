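#' Tipping-point detection on a score series
#'
#' Two trigger rules are provided.  The default `"ratio"` rule is the
#' sharp-increase criterion: day T is flagged iff
#' score_T > factor * score_(T-1); it is local (only consecutive time
#' points are compared) and invariant to rescaling the whole series, and
#' the first time point can never fire.  The `"deviation"` rule flags day
#' T when |score_T - mean(previous scores)| exceeds `zThreshold` running
#' standard deviations of the previous scores; it needs at least 3
#' baseline points and catches sharp moves in either direction, which
#' suits score series whose response to perturbation is a collapse rather
#' than a rise.  The first flagged day is the headline tipping-point
#' call; all flagged days are kept.
#'
#' @param days strictly increasing numeric days.
#' @param scores finite scores, one per day.
#' @param factor ratio threshold (default 1.5).
#' @param method `"ratio"` (default) or `"deviation"`.
#' @param zThreshold deviation-rule threshold in running SDs (default 4).
#' @param individual optional id carried into the call.
#' @param onsetDay optional known onset day(s) for comparison.
#' @return a [SignalCall-class].
#' @examples
#' detectTipping(1:3, c(1.0, 1.2, 2.0))  # fires at day 3 (2.0 > 1.8)
#' @export
detectTipping <- function(days, scores, factor = 1.5,
                          method = c("ratio", "deviation"), zThreshold = 4,
                          individual = "", onsetDay = numeric(0)) {
    method <- match.arg(method)
    days <- as.numeric(days); scores <- as.numeric(scores)
    if (length(days) < 2L) stop("at least 2 time points required")
    if (length(days) != length(scores)) stop("days and scores lengths differ")
    if (any(diff(days) <= 0)) stop("days must be strictly increasing")
    if (any(!is.finite(scores))) stop("scores must be finite")
    n <- length(scores)
    fired <- if (method == "ratio") {
        c(FALSE, scores[-1L] > factor * scores[-n])
    } else {
        f <- rep(FALSE, n)
        for (t in seq_len(n)[-seq_len(min(3L, n))]) {
            base <- scores[seq_len(t - 1L)]
            s <- stats::sd(base)
            if (s > 0 && abs(scores[t] - mean(base)) > zThreshold * s)
                f[t] <- TRUE
        }
        f
    }
    sig <- days[fired]
    new("SignalCall", individual = individual, days = days, scores = scores,
        signalDays = sig,
        firstSignal = if (length(sig)) sig[1L] else numeric(0),
        onsetDay = as.numeric(onsetDay), factor = factor)
}

#' Call dynamic network biomarkers at a critical state
#'
#' The top `fraction` (default 10\%) of taxa by score, with the count
#' rounded up (ceiling) and exact ties at the cutoff broken by
#' lexicographic taxon id.
#'
#' @param scores named numeric vector: per-taxon mNFE differential at the
#'   called day.
#' @param fraction fraction of taxa to keep, in (0, 1] (default 0.10).
#' @param individual,day,group bookkeeping fields for the returned set.
#' @return a [DnbSet-class].
#' @export
identifyDnb <- function(scores, fraction = 0.10, individual = "",
                        day = NA_real_, group = "") {
    if (!length(scores)) stop("empty score map")
    if (is.null(names(scores))) stop("scores must be named by taxon")
    stopifnot(fraction > 0, fraction <= 1)
    k <- as.integer(ceiling(fraction * length(scores)))
    ord <- order(-scores, names(scores))
    top <- ord[seq_len(k)]
    new("DnbSet", individual = individual, day = as.numeric(day),
        taxa = names(scores)[top], scores = unname(scores[top]),
        fraction = fraction, nScored = length(scores), group = group)
}

#' High-frequency species across individual DNB sets
#'
#' A taxon is a high-frequency species when it appears in the DNB sets of
#' at least `t1dMin` T1D-case individuals, or of at least `seroMin`
#' seroconverter individuals.
#'
#' @param dnbSets list of [DnbSet-class] objects with `group` set to
#'   "T1D-case" or "seroconverter".
#' @param t1dMin,seroMin occurrence thresholds (defaults 2 and 5).
#' @return sorted character vector of taxon ids.
#' @export
highFrequencySpecies <- function(dnbSets, t1dMin = 2L, seroMin = 5L) {
    grp <- vapply(dnbSets, function(d) d@group, character(1))
    countIn <- function(sets) {
        if (!length(sets)) return(character(0))
        table(unlist(lapply(sets, function(d) unique(d@taxa))))
    }
    t1d <- countIn(dnbSets[grp == "T1D-case"])
    ser <- countIn(dnbSets[grp == "seroconverter"])
    sort(union(names(t1d)[t1d >= t1dMin], names(ser)[ser >= seroMin]))
}

#' Dark species: DNB taxa without differential abundance
#'
#' Screens each DNB taxon for differential abundance across the sample
#' groups by the Kruskal-Wallis rank-sum test (chi-square approximation,
#' tie-corrected) and returns those DNB taxa that are NOT differential at
#' level `alpha` — taxa sensitive to the mNFE score yet invisible to
#' standard differential-abundance analysis.
#'
#' @param dnbTaxa character vector of DNB taxon ids.
#' @param x a [TaxonProfile-class] whose samples carry group labels.
#' @param alpha raw p-value threshold (default 0.05).
#' @param adjust apply Benjamini-Hochberg FDR before thresholding
#'   (default FALSE, matching the raw-threshold convention).
#' @return sorted character vector: the dark-species subset of `dnbTaxa`.
#' @export
darkSpecies <- function(dnbTaxa, x, alpha = 0.05, adjust = FALSE) {
    grp <- sampleGroups(x)
    if (any(is.na(grp))) stop("all samples need group labels")
    tabg <- table(grp)
    if (length(tabg) < 2L) stop("at least 2 groups required")
    if (any(tabg < 2L))
        stop("group(s) with fewer than 2 samples: ",
             paste(names(tabg)[tabg < 2L], collapse = ", "))
    dnbTaxa <- intersect(dnbTaxa, rownames(x))
    if (!length(dnbTaxa)) return(character(0))
    a <- abundances(x)
    p <- vapply(dnbTaxa, function(t)
        stats::kruskal.test(a[t, ], factor(grp))$p.value, numeric(1))
    if (adjust) p <- stats::p.adjust(p, "BH")
    sort(dnbTaxa[p > alpha])
}
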