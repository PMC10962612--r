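#' Center each species' log-abundances across samples
#'
#' Row i, column j becomes log(x_ij / geomean_j(x_i.)): each species is
#' divided by its geometric mean across samples, then logged.  This is the
#' per-species (across-sample) log-ratio centering used by the local
#' network-flow-entropy probabilities; it is distinct from the within-sample
#' CLR used for network inference (see [clrWithinSample()]).
#'
#' @param m strictly positive numeric matrix, species x samples.
#' @return matrix of the same shape; every row sums to 0.
#' @examples
#' clrBySpecies(rbind(c(1, 4)))  # -log(2), log(2)
#' @export
clrBySpecies <- function(m) {
    m <- as.matrix(m)
    if (any(m <= 0)) stop("clrBySpecies requires strictly positive entries")
    lm <- log(m)
    lm - rowMeans(lm)
}

#' Within-sample centered log-ratio transform
#'
#' Column j becomes log(x_.j) minus its mean over taxa: the standard CLR of
#' compositional data analysis, applied per sample.  Used to de-compose the
#' abundances before neighborhood-selection network inference.
#'
#' @param m strictly positive numeric matrix, taxa x samples.
#' @return matrix of the same shape; every column sums to 0.
#' @export
clrWithinSample <- function(m) {
    m <- as.matrix(m)
    if (any(m <= 0)) stop("clrWithinSample requires strictly positive entries")
    lm <- log(m)
    sweep(lm, 2L, colMeans(lm), "-")
}

#' Per-sample log-ratio distance between a center and a neighbor species
#'
#' Entry j is |log(x_ij / S(x_i)) - log(x_kj / S(x_k))| where S(.) is the
#' geometric mean across samples: the per-sample component of the Aitchison
#' distance between the two species' abundance series.  The absolute value
#' makes the downstream joint-probability normalization well defined.
#'
#' @param centerRow,neighborRow strictly positive numeric vectors of equal
#'   length (one abundance per sample).
#' @return non-negative numeric vector of per-sample distances.
#' @examples
#' pairwiseDistance(c(1, 4), c(4, 1))  # both entries 2*log(2)
#' @export
pairwiseDistance <- function(centerRow, neighborRow) {
    stopifnot(length(centerRow) == length(neighborRow))
    if (any(centerRow <= 0) || any(neighborRow <= 0))
        stop("pairwiseDistance requires strictly positive abundances")
    a <- log(centerRow) - mean(log(centerRow))
    b <- log(neighborRow) - mean(log(neighborRow))
    abs(a - b)
}

#' Binned mutual information with small-sample bias correction
#'
#' Plug-in (maximum-likelihood) estimate on an equal-width grid of
#' ceiling(n^(1/3)) bins per margin, in nats, with the Miller-Madow
#' occupied-cell correction applied to each entropy term; the corrected
#' estimate can dip below zero under independence and is clipped at 0.
#' A constant input carries no information and yields 0 (noted when
#' `options(mNFE.verbose = TRUE)`).
#'
#' @param x,y numeric vectors of equal length n >= 4.
#' @param bins bins per margin; default ceiling(n^(1/3)) (cube-root rule).
#' @return non-negative mutual information estimate in nats.
#' @seealso [binnedEntropy()]; `mutualInformation(x, x)` equals
#'   `binnedEntropy(x)` under the same binning.
#' @export
mutualInformation <- function(x, y, bins = NULL) {
    n <- length(x)
    stopifnot(n >= 4L, length(y) == n)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        if (getOption("mNFE.verbose", FALSE))
            message("mutualInformation: constant input, returning 0")
        return(0)
    }
    if (is.null(bins)) bins <- ceiling(n^(1/3))
    bx <- .binIndex(x, bins)
    by <- .binIndex(y, bins)
    pj <- tabulate(bx + bins * (by - 1L), nbins = bins * bins) / n
    px <- tabulate(bx, nbins = bins) / n
    py <- tabulate(by, nbins = bins) / n
    nz <- pj > 0
    denom <- as.vector(outer(px, py))
    mi <- sum(pj[nz] * log(pj[nz] / denom[nz]))
    # Miller-Madow: H_mm = H_ml + (occupied - 1) / (2n) per entropy term
    mm <- (sum(px > 0) - 1 + sum(py > 0) - 1 - (sum(nz) - 1)) / (2 * n)
    max(0, mi + mm)
}

#' Miller-Madow corrected entropy of a binned variable
#'
#' @inheritParams mutualInformation
#' @return entropy estimate in nats.
#' @export
binnedEntropy <- function(x, bins = NULL) {
    n <- length(x)
    if (stats::sd(x) == 0) return(0)
    if (is.null(bins)) bins <- ceiling(n^(1/3))
    px <- tabulate(.binIndex(x, bins), nbins = bins) / n
    nz <- px > 0
    -sum(px[nz] * log(px[nz])) + (sum(nz) - 1) / (2 * n)
}

.binIndex <- function(x, bins) {
    r <- range(x)
    pmin.int(bins, 1L + floor((x - r[1L]) / (r[2L] - r[1L]) * bins))
}

#' Extract a local (center + first-order neighbors) network
#'
#' @param network an [AssociationNetwork-class].
#' @param center a node id of the network.
#' @return list with `center`, sorted `neighbors` (taxon ids adjacent to the
#'   center) and `M` = neighborhood size including the center (degree + 1).
#' @export
extractLocal <- function(network, center) {
    if (!center %in% network@nodes)
        stop("center '", center, "' is not a node of the network")
    e <- network@edges
    nb <- sort(unique(c(e$to[e$from == center], e$from[e$to == center])))
    list(center = center, neighbors = nb, M = length(nb) + 1L)
}

#' Local joint/conditional probabilities of a neighborhood
#'
#' For a center species i with neighbors k = 1..M-1 over n samples:
#' the joint probability p(x_ij, x_kj) is the per-sample log-ratio distance
#' D(x_ij, x_kj) normalized over neighbors (uniform where all distances
#' vanish); the conditional probability p(x_kj | x_ij) is the center-
#' neighbor mutual information normalized over neighbors (uniform where all
#' MI vanish).
#'
#' @param abund strictly positive species x samples matrix containing the
#'   center and neighbor rows.
#' @param center,neighbors taxon ids (rownames of `abund`).
#' @param clr optional precomputed [clrBySpecies()] matrix for `abund`.
#' @param mi optional precomputed MI vector, one value per neighbor.
#' @return list with matrices/vectors `distances` (neighbors x samples),
#'   `joint` (neighbors x samples, columns sum to 1), `conditional`
#'   (sums to 1) and `mutualInformation`.
#' @export
localProbabilities <- function(abund, center, neighbors, clr = NULL, mi = NULL) {
    K <- length(neighbors)
    if (K == 0L) stop("empty neighborhood")
    if (is.null(clr)) clr <- clrBySpecies(abund[c(center, neighbors), , drop = FALSE])
    D <- abs(sweep(clr[neighbors, , drop = FALSE], 2L, clr[center, ], "-"))
    cs <- colSums(D)
    joint <- sweep(D, 2L, ifelse(cs == 0, 1, cs), "/")
    joint[, cs == 0] <- 1 / K
    if (is.null(mi))
        mi <- if (ncol(abund) >= 4L) vapply(neighbors, function(k)
                  mutualInformation(abund[center, ], abund[k, ]), numeric(1))
              else rep(0, K)  # too few samples to estimate MI: uniform conditional
    s <- sum(mi)
    conditional <- if (s > 0) mi / s else rep(1 / K, K)
    list(distances = D, joint = joint, conditional = conditional,
         mutualInformation = mi)
}

#' Network flow entropy of one local network
#'
#' NFE = -1/(M-1) * sum_k sum_j w_kj log w_kj over the M-1 neighbors k and
#' the n samples j, with flow weight
#' w_kj = x_ij * p(x_ij, x_kj) * p(x_kj | x_ij), where x_ij is the center's
#' within-sample relative abundance.  An isolated center (M = 1) has NFE 0
#' by convention.  All factors lie in (0, 1], so NFE >= 0.
#'
#' @inheritParams localProbabilities
#' @return non-negative scalar entropy (nats).
#' @export
localNfe <- function(abund, center, neighbors, clr = NULL, mi = NULL) {
    K <- length(neighbors)
    if (K == 0L) return(0)
    pr <- localProbabilities(abund, center, neighbors, clr = clr, mi = mi)
    w <- sweep(pr$joint * pr$conditional, 2L, abund[center, ], "*")
    lw <- w * log(w)
    lw[w == 0] <- 0
    -sum(lw) / K
}

#' NFE of every local network of an association network
#'
#' Computes, for each node of `network`, the network flow entropy of its
#' local (center + first-order neighbors) network over the given samples.
#' Mutual information values are computed once per edge and shared between
#' the two directions.
#'
#' @param network an [AssociationNetwork-class].
#' @param abund strictly positive species x samples matrix of within-sample
#'   relative abundances; rownames must cover the network's nodes.
#' @return named numeric vector, NFE per center node.
#' @export
networkNfe <- function(network, abund) {
    nodes <- network@nodes
    if (!all(nodes %in% rownames(abund)))
        stop("abundance matrix does not cover the network's nodes")
    if (!length(nodes)) stop("network has no nodes")
    sub <- abund[nodes, , drop = FALSE]
    clr <- clrBySpecies(sub)
    e <- network@edges
    miByEdge <- if (!nrow(e)) numeric(0)
        else if (ncol(sub) < 4L) rep(0, nrow(e))  # uniform conditionals
        else vapply(seq_len(nrow(e)), function(i)
            mutualInformation(sub[e$from[i], ], sub[e$to[i], ]), numeric(1))
    adj <- .adjacencyList(nodes, e, miByEdge)
    vapply(nodes, function(ct) {
        nb <- adj[[ct]]
        if (is.null(nb) || !length(nb$ids)) return(0)
        localNfe(sub, ct, nb$ids, clr = clr, mi = nb$mi)
    }, numeric(1))
}

.adjacencyList <- function(nodes, e, miByEdge) {
    adj <- structure(vector("list", length(nodes)), names = nodes)
    for (v in nodes) adj[[v]] <- list(ids = character(0), mi = numeric(0))
    if (nrow(e)) for (i in seq_len(nrow(e))) {
        a <- e$from[i]; b <- e$to[i]
        adj[[a]]$ids <- c(adj[[a]]$ids, b); adj[[a]]$mi <- c(adj[[a]]$mi, miByEdge[i])
        adj[[b]]$ids <- c(adj[[b]]$ids, a); adj[[b]]$mi <- c(adj[[b]]$mi, miByEdge[i])
    }
    adj
}

#' mNFE score of one case sample against a reference set
#'
#' The global score is the mean NFE over the SSAN's local networks computed
#' on the n + 1 mixed samples minus the mean NFE over the ARN's local
#' networks computed on the n reference samples.  Per-taxon differentials
#' (SSAN-local NFE minus ARN-local NFE; a side where the taxon is absent
#' contributes 0 and is flagged) feed DNB ranking.
#'
#' @param arn reference association network ([inferMbNetwork()]).
#' @param ssan sample-specific association network ([buildSsan()]).
#' @param reference a [TaxonProfile-class] of the n reference samples, or a
#'   non-negative taxa x samples matrix.
#' @param caseSample named non-negative numeric vector over the same taxon
#'   universe as `reference`.
#' @param day collection day of the case sample (bookkeeping).
#' @param pseudocount zero replacement applied before per-sample closure.
#' @param nfeReference optional precomputed [networkNfe()] vector for the
#'   ARN over the reference samples (saves recomputation when scoring many
#'   case samples against one reference set).
#' @return an [MnfeResult-class].
#' @export
mnfeScore <- function(arn, ssan, reference, caseSample, day = NA_real_,
                      pseudocount = 0.5, nfeReference = NULL) {
    refMat <- if (is(reference, "TaxonProfile")) abundances(reference)
              else as.matrix(reference)
    if (is.null(names(caseSample)) ||
        !identical(sort(names(caseSample)), sort(rownames(refMat))))
        stop("case sample must be named by the reference taxon universe")
    caseSample <- caseSample[rownames(refMat)]
    if (!length(arn@nodes) || !length(ssan@nodes))
        stop("empty network: no nodes after filtering")
    relRef <- .closeColumns(refMat, pseudocount)
    relMix <- .closeColumns(cbind(refMat, `.case` = caseSample), pseudocount)
    if (is.null(nfeReference)) nfeReference <- networkNfe(arn, relRef)
    nfePerturbed <- networkNfe(ssan, relMix)
    .mnfeAssemble(nfeReference, nfePerturbed, day)
}

# build an MnfeResult from the two per-local NFE vectors
.mnfeAssemble <- function(nfeReference, nfePerturbed, day = NA_real_) {
    all <- sort(union(names(nfeReference), names(nfePerturbed)))
    r <- ifelse(all %in% names(nfeReference), nfeReference[all], 0)
    p <- ifelse(all %in% names(nfePerturbed), nfePerturbed[all], 0)
    onlyIn <- ifelse(!(all %in% names(nfeReference)), "ssan",
              ifelse(!(all %in% names(nfePerturbed)), "arn", ""))
    new("MnfeResult", day = as.numeric(day),
        nfeReference = nfeReference, nfePerturbed = nfePerturbed,
        perTaxon = data.frame(taxon = all, deltaNfe = p - r, onlyIn = onlyIn,
                              row.names = NULL),
        score = mean(nfePerturbed) - mean(nfeReference))
}

.closeColumns <- function(m, pseudocount) {
    m <- m + pseudocount
    cs <- colSums(m)
    if (any(cs == 0)) stop("all-zero sample column")
    sweep(m, 2L, cs, "/")
}
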