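#' Chao1 richness estimate
#'
#' Bias-corrected form S_obs + F1*(F1 - 1) / (2*(F2 + 1)), where F1 and F2
#' are the singleton and doubleton counts; the correction keeps the
#' estimator defined when no doubletons are observed.  `bias = FALSE`
#' gives the classical S_obs + F1^2 / (2*F2) (falling back to the corrected
#' form when F2 = 0).  Chao1 needs genuine counts, so non-integer input is
#' refused rather than silently rounded.
#'
#' @param counts non-negative integer vector of per-taxon counts.
#' @param bias use the bias-corrected form (default TRUE).
#' @return the Chao1 estimate (>= observed richness).
#' @examples
#' chao1(c(1, 1, 2, 2, 3))  # 5 + 2*1/(2*3) = 5.333...
#' @export
chao1 <- function(counts, bias = TRUE) {
    if (any(counts < 0)) stop("negative counts")
    if (any(abs(counts - round(counts)) > 1e-8))
        stop("chao1 requires integer counts (got non-integer input)")
    counts <- round(counts)
    if (sum(counts) == 0) stop("all-zero count vector")
    sObs <- sum(counts > 0)
    f1 <- sum(counts == 1)
    f2 <- sum(counts == 2)
    if (bias || f2 == 0) sObs + f1 * (f1 - 1) / (2 * (f2 + 1))
    else sObs + f1^2 / (2 * f2)
}

#' Alpha-diversity suite
#'
#' Chao1 (bias-corrected), Shannon entropy (nats), Gini-Simpson index
#' (1 - sum p^2) and observed richness for one sample's counts.
#'
#' @inheritParams chao1
#' @return named numeric: chao1, shannon, simpson, richness.
#' @export
alphaSuite <- function(counts) {
    c(chao1 = chao1(counts),
      shannon = unname(vegan::diversity(counts, index = "shannon")),
      simpson = unname(vegan::diversity(counts, index = "simpson")),
      richness = sum(counts > 0))
}

#' Bray-Curtis dissimilarity
#'
#' sum |a - b| / sum (a + b), in [0, 1]; 0 for identical profiles, 1 for
#' disjoint supports.
#'
#' @param a,b non-negative numeric vectors on the same taxon index, not
#'   both all-zero.
#' @return dissimilarity in [0, 1].
#' @export
brayCurtis <- function(a, b) {
    stopifnot(length(a) == length(b))
    if (any(a < 0) || any(b < 0)) stop("negative abundances")
    tot <- sum(a + b)
    if (tot == 0) stop("both profiles are all-zero")
    sum(abs(a - b)) / tot
}

#' Ratio-rule signal on a Chao-index series
#'
#' Identical contract to [detectTipping()] applied to a per-time-point
#' Chao1 series: day T fires iff Chao_T > factor * Chao_(T-1).
#'
#' @inheritParams detectTipping
#' @param chao Chao1 values, one per day.
#' @return a [SignalCall-class].
#' @export
chaoSignal <- function(days, chao, factor = 1.5, individual = "",
                       onsetDay = numeric(0)) {
    detectTipping(days, chao, factor = factor, individual = individual,
                  onsetDay = onsetDay)
}

#' Per-sample alpha diversity of a profile
#'
#' @param x a [TaxonProfile-class] of counts (pre-normalization).
#' @return data.frame with sample id, individual, day, group and the four
#'   alpha-diversity indices.
#' @export
profileAlphaDiversity <- function(x) {
    a <- abundances(x)
    idx <- t(apply(a, 2L, alphaSuite))
    data.frame(sample_id = colnames(a), individual = sampleIndividuals(x),
               day = sampleDays(x), group = sampleGroups(x), idx,
               row.names = NULL)
}

#' Group comparison of an alpha-diversity index
#'
#' Wilcoxon rank-sum for two groups, Kruskal-Wallis for three or more.
#'
#' @param x a [TaxonProfile-class] with group labels.
#' @param index one of "chao1", "shannon", "simpson", "richness".
#' @return list with the per-group median values and the test p-value.
#' @export
diversityGroupTest <- function(x, index = c("chao1", "shannon", "simpson",
                                            "richness")) {
    index <- match.arg(index)
    d <- profileAlphaDiversity(x)
    if (any(is.na(d$group))) stop("all samples need group labels")
    v <- d[[index]]
    g <- factor(d$group)
    p <- if (nlevels(g) == 2L) stats::wilcox.test(v ~ g)$p.value
         else stats::kruskal.test(v, g)$p.value
    list(index = index, medians = tapply(v, g, stats::median), p.value = p)
}
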