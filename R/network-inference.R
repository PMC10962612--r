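#' Infer a microbial association network by neighborhood selection
#'
#' Implements the MB (Meinshausen-Buhlmann) estimator on within-sample
#' CLR-transformed abundances: each retained taxon is lasso-regressed on all
#' others along a shared log-spaced lambda path (`nLambda` values down to
#' `lambdaMinRatio` of the largest absolute pairwise correlation), the
#' penalty is chosen by StARS stability selection (edge-selection
#' instability averaged over `starsSubsamples` subsamples, largest density
#' whose monotonized instability stays below `starsInstability`), and the
#' selected neighborhoods are symmetrized by the OR rule.  The edge weight
#' is the signed average of the two regression coefficients; when the two
#' coefficients disagree in sign, the larger-magnitude coefficient's sign
#' wins.
#'
#' @param x a [TaxonProfile-class] or non-negative taxa x samples matrix of
#'   counts (or relative abundances).
#' @param lambdaMinRatio smallest lambda as a fraction of lambda_max
#'   (default 0.01).
#' @param nLambda number of lambda-path values (default 20).
#' @param stability `"stars"` (default) or `"fixed"` (use `lambda`, or the
#'   mid-path value; the fallback for very small sample sizes).
#' @param lambda fixed penalty for `stability = "fixed"`.
#' @param starsSubsamples,starsInstability StARS settings (defaults 20 and
#'   0.05).
#' @param prevalenceMin minimum fraction of samples in which a taxon must be
#'   non-zero to enter the network (default 0.2).
#' @param pseudocount zero replacement before closure and CLR (default 0.5).
#' @param seed RNG seed for the StARS subsampling.
#' @param nodes optional taxon subset to use instead of prevalence
#'   filtering (used by [buildSsan()] so SSANs share the ARN's node set).
#' @param refMoments optional list(center, scale) of per-taxon CLR moments
#'   used for standardization instead of the data's own moments; an SSAN
#'   passes the ARN's moments so the case sample is measured against the
#'   reference geometry rather than allowed to deflate it.
#' @return an [AssociationNetwork-class] with provenance (type, lambda
#'   path, selected lambda, settings).
#' @references Meinshausen & Buhlmann (2006) Ann. Statist. 34(3);
#'   Kurtz et al. (2015) PLoS Comput. Biol. 11(5) (SPIEC-EASI);
#'   Liu, Roeder & Wasserman (2010) NIPS (StARS).
#' @export
inferMbNetwork <- function(x, lambdaMinRatio = 0.01, nLambda = 20L,
                           stability = c("stars", "fixed"), lambda = NULL,
                           starsSubsamples = 20L, starsInstability = 0.05,
                           prevalenceMin = 0.2, pseudocount = 0.5,
                           seed = NULL, nodes = NULL, refMoments = NULL) {
    stability <- match.arg(stability)
    counts <- if (is(x, "TaxonProfile")) abundances(x) else as.matrix(x)
    n <- ncol(counts)
    if (n < 4L) stop("fewer samples than the minimum (4) for network inference")
    counts <- counts[, order(colnames(counts)), drop = FALSE]  # canonical order
    if (is.null(nodes)) {
        prev <- rowMeans(counts > 0)
        nodes <- rownames(counts)[prev >= prevalenceMin]
    } else {
        if (!all(nodes %in% rownames(counts))) stop("unknown taxa in 'nodes'")
    }
    sub <- counts[nodes, , drop = FALSE]
    clr <- clrWithinSample(.closeColumns(sub, pseudocount))
    keep <- apply(clr, 1L, stats::sd) > 0
    if (any(!keep)) {
        warning("dropping degenerate (constant) taxa: ",
                paste(rownames(clr)[!keep], collapse = ", "))
        clr <- clr[keep, , drop = FALSE]
    }
    m <- nrow(clr)
    if (m < 3L) stop("fewer than 3 taxa retained; cannot infer a network")
    X <- if (is.null(refMoments))
        scale(t(clr))
    else  # standardize against the reference geometry (SSAN case)
        scale(t(clr), center = refMoments$center[rownames(clr)],
              scale = refMoments$scale[rownames(clr)])
    path <- .lambdaPath(X, lambdaMinRatio, nLambda)
    if (stability == "fixed") {
        if (is.null(lambda)) lambda <- path[ceiling(nLambda / 2)]
        # short warm-start descent to the requested penalty (which may lie
        # off this data's own path)
        top <- max(path[1L], lambda * 1.05)
        path <- exp(seq(log(top), log(lambda), length.out = 5L))
        sel <- length(path)
        starsSummary <- NULL
    } else {
        st <- .stars(X, path, starsSubsamples, starsInstability, seed)
        sel <- st$index
        lambda <- path[sel]
        starsSummary <- st$instability
    }
    beta <- .mbCoefs(X, path[seq_len(sel)])[, , sel, drop = FALSE][, , 1L]
    edges <- .assembleEdges(beta, colnames(X))
    mom <- if (is.null(refMoments))
        list(center = stats::setNames(attr(X, "scaled:center"), colnames(X)),
             scale = stats::setNames(attr(X, "scaled:scale"), colnames(X)))
    else refMoments
    new("AssociationNetwork", nodes = colnames(X), edges = edges,
        provenance = list(type = "reference", caseDay = NA_real_,
            moments = mom,
            lambdaPath = path, lambda = lambda, lambdaIndex = sel,
            stability = stability, instability = starsSummary,
            settings = list(lambdaMinRatio = lambdaMinRatio,
                nLambda = nLambda, starsSubsamples = starsSubsamples,
                starsInstability = starsInstability,
                prevalenceMin = prevalenceMin, pseudocount = pseudocount,
                seed = seed),
            nSamples = n))
}

.lambdaPath <- function(X, lambdaMinRatio, nLambda) {
    S <- abs(stats::cor(X))
    diag(S) <- 0
    lmax <- max(S)
    if (lmax <= 0) lmax <- 1
    exp(seq(log(lmax), log(lmax * lambdaMinRatio), length.out = nLambda))
}

# lasso neighborhoods of every node along a shared lambda path
# returns beta[j, k, l] = coefficient of predictor k in the regression of j
.mbCoefs <- function(X, lambdaSeq) {
    m <- ncol(X)
    nl <- length(lambdaSeq)
    beta <- array(0, c(m, m, nl),
                  dimnames = list(colnames(X), colnames(X), NULL))
    for (j in seq_len(m)) {
        fit <- glmnet::glmnet(X[, -j, drop = FALSE], X[, j], family = "gaussian",
                              lambda = lambdaSeq, standardize = FALSE,
                              intercept = FALSE)
        b <- as.matrix(fit$beta)
        got <- ncol(b)
        beta[j, -j, seq_len(got)] <- b
        if (got < nl)  # glmnet stopped early; carry the last fit forward
            for (l in (got + 1L):nl) beta[j, -j, l] <- b[, got]
    }
    beta
}

# StARS: pick the densest lambda whose monotonized edge instability
# stays below the target
.stars <- function(X, path, nSub, target, seed) {
    n <- nrow(X); m <- ncol(X)
    b <- if (n > 144L) floor(10 * sqrt(n)) else ceiling(0.8 * n)
    b <- min(b, n - 1L)
    nl <- length(path)
    freq <- array(0, c(m, m, nl))
    .withSeed(seed, {
        for (s in seq_len(nSub)) {
            idx <- sample.int(n, b)
            bt <- .mbCoefs(X[idx, , drop = FALSE], path)
            for (l in seq_len(nl)) {
                a <- bt[, , l] != 0
                freq[, , l] <- freq[, , l] + (a | t(a))
            }
        }
    })
    theta <- freq / nSub
    nPairs <- m * (m - 1) / 2
    inst <- vapply(seq_len(nl), function(l) {
        th <- theta[, , l][upper.tri(theta[, , l])]
        sum(2 * th * (1 - th)) / nPairs
    }, numeric(1))
    instBar <- cummax(inst)
    ok <- which(instBar <= target)
    list(index = if (length(ok)) max(ok) else 1L, instability = inst)
}

.assembleEdges <- function(beta, nodes) {
    m <- length(nodes)
    from <- character(0); to <- character(0); w <- numeric(0)
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
        ba <- beta[a, b]; bb <- beta[b, a]
        if (ba == 0 && bb == 0) next
        nzv <- c(ba, bb)[c(ba, bb) != 0]
        sgn <- if (length(nzv) == 2L && prod(sign(nzv)) < 0)
                   sign(nzv[which.max(abs(nzv))])
               else sign(nzv[1L])
        pair <- sort(c(nodes[a], nodes[b]))
        from <- c(from, pair[1L]); to <- c(to, pair[2L])
        w <- c(w, sgn * mean(abs(nzv)))
    }
    data.frame(from = from, to = to, weight = w)
}

#' Build a sample-specific association network (SSAN)
#'
#' Adds one case sample to the reference samples and re-infers the network
#' on the n + 1 mixed columns.  The SSAN reuses the ARN's node set and
#' StARS-selected penalty (pass `stability = "stars"` to re-select), so
#' that ARN and SSAN are compared at matched sparsity.
#'
#' @param reference a [TaxonProfile-class] or taxa x samples matrix of the
#'   reference samples.
#' @param caseSample named non-negative vector over the reference's taxon
#'   universe.
#' @param arn the reference network returned by [inferMbNetwork()].
#' @param day case-sample collection day recorded in the provenance.
#' @param stability,seed see [inferMbNetwork()].
#' @param useRefMoments standardize the mixed matrix with the ARN's stored
#'   CLR moments instead of its own (measures the case sample strictly
#'   against the reference geometry; default FALSE, i.e. the mixed data is
#'   standardized as any other data set).
#' @return an [AssociationNetwork-class] with provenance type "perturbed".
#' @export
buildSsan <- function(reference, caseSample, arn, day = NA_real_,
                      stability = "fixed", seed = NULL,
                      useRefMoments = FALSE) {
    refMat <- if (is(reference, "TaxonProfile")) abundances(reference)
              else as.matrix(reference)
    if (is.null(names(caseSample)) ||
        !identical(sort(names(caseSample)), sort(rownames(refMat))))
        stop("taxon index mismatch between reference and case sample")
    mixed <- cbind(refMat, caseSample[rownames(refMat)])
    colnames(mixed) <- c(colnames(refMat), ".case")
    s <- arn@provenance$settings
    net <- inferMbNetwork(mixed, lambdaMinRatio = s$lambdaMinRatio,
        nLambda = s$nLambda, stability = stability,
        lambda = arn@provenance$lambda,
        starsSubsamples = s$starsSubsamples,
        starsInstability = s$starsInstability,
        pseudocount = s$pseudocount, seed = seed, nodes = arn@nodes,
        refMoments = if (useRefMoments) arn@provenance$moments else NULL)
    net@provenance$type <- "perturbed"
    net@provenance$caseDay <- as.numeric(day)
    net
}

#' Build an AssociationNetwork from an edge table
#'
#' Convenience constructor: canonicalizes edge direction (from < to),
#' drops self loops and duplicates, and takes the node set as the union of
#' `nodes` and all endpoints.
#'
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `weight` (default 1).
#' @param nodes optional additional (possibly isolated) node ids.
#' @param provenance optional provenance list.
#' @return an [AssociationNetwork-class].
#' @export
asAssociationNetwork <- function(edges, nodes = NULL, provenance = list()) {
    if (!nrow(edges)) {
        return(new("AssociationNetwork",
                   nodes = as.character(nodes %||% character(0)),
                   edges = data.frame(from = character(0), to = character(0),
                                      weight = numeric(0)),
                   provenance = provenance))
    }
    if (!"weight" %in% colnames(edges)) edges$weight <- 1
    a <- pmin(as.character(edges$from), as.character(edges$to))
    b <- pmax(as.character(edges$from), as.character(edges$to))
    keep <- a != b & !duplicated(paste(a, b, sep = "\r"))
    e <- data.frame(from = a[keep], to = b[keep], weight = edges$weight[keep])
    new("AssociationNetwork",
        nodes = sort(unique(c(as.character(nodes), e$from, e$to))),
        edges = e, provenance = provenance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an association network
#'
#' @param x an [AssociationNetwork-class].
#' @param path output file.
#' @param format `"edgelist"` (tab-delimited from/to/weight) or
#'   `"graphml"`.
#' @return invisibly, `path`.
#' @export
writeNetwork <- function(x, path, format = c("edgelist", "graphml")) {
    format <- match.arg(format)
    if (format == "edgelist")
        utils::write.table(x@edges, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    else
        igraph::write_graph(asIgraph(x), path, format = "graphml")
    invisible(path)
}

#' Convert to an igraph object
#'
#' @param x an [AssociationNetwork-class].
#' @return an undirected `igraph` graph with a `weight` edge attribute.
#' @export
asIgraph <- function(x) {
    igraph::graph_from_data_frame(x@edges, directed = FALSE,
                                  vertices = data.frame(name = x@nodes))
}

# evaluate code under a temporary RNG state
.withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        had <- exists(".Random.seed", globalenv(), inherits = FALSE)
        old <- if (had) get(".Random.seed", globalenv()) else NULL
        on.exit({
            if (had) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(seed)
    }
    force(code)
}
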