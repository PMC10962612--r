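# Shared fixtures and independent oracles.  Everything is generated in
# code at test time; the NFE oracle below is written directly from the
# probability definitions as an explicit double loop and must stay
# independent of the package implementation.

# latent Gaussian copula counts with a known chain conditional-dependence
# graph: taxa i and i+1 are partially correlated, everything else is
# conditionally independent
makeChainCounts <- function(n, m, partial = 0.45, seed = 1, meanLog = 4) {
    set.seed(seed)
    Omega <- diag(m)
    for (i in seq_len(m - 1L)) Omega[i, i + 1L] <- Omega[i + 1L, i] <- -partial
    Sigma <- stats::cov2cor(solve(Omega))
    z <- t(matrix(stats::rnorm(n * m), n) %*% chol(Sigma))
    cnt <- matrix(stats::rpois(n * m, exp(1.5 * z + meanLog)), m, n)
    dimnames(cnt) <- list(sprintf("t%02d", seq_len(m)),
                          sprintf("s%03d", seq_len(n)))
    cnt
}

chainEdgeF1 <- function(net, m) {
    e <- networkEdges(net)
    truth <- sprintf("t%02d|t%02d", seq_len(m - 1L), 2:m)
    est <- paste(e$from, e$to, sep = "|")
    tp <- length(intersect(est, truth))
    fp <- length(setdiff(est, truth))
    fn <- length(setdiff(truth, est))
    2 * tp / (2 * tp + fp + fn)
}

# small random strictly positive abundance matrix with named taxa
randomAbund <- function(m, n) {
    a <- matrix(stats::rexp(m * n) + 0.05, m, n)
    a <- sweep(a, 2L, colSums(a), "/")
    dimnames(a) <- list(paste0("x", seq_len(m)), paste0("s", seq_len(n)))
    a
}

# ---- independent oracles -------------------------------------------------

# binned MI, written independently: explicit cell-count loops,
# Miller-Madow correction, clip at zero
miOracle <- function(x, y, bins = ceiling(length(x)^(1 / 3))) {
    n <- length(x)
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) return(0)
    cut1 <- function(v) {
        lo <- min(v); hi <- max(v)
        idx <- floor((v - lo) / (hi - lo) * bins) + 1
        ifelse(idx > bins, bins, idx)
    }
    bx <- cut1(x); by <- cut1(y)
    joint <- matrix(0, bins, bins)
    for (i in seq_len(n)) joint[bx[i], by[i]] <- joint[bx[i], by[i]] + 1
    joint <- joint / n
    px <- rowSums(joint); py <- colSums(joint)
    mi <- 0
    for (a in seq_len(bins)) for (b in seq_len(bins))
        if (joint[a, b] > 0)
            mi <- mi + joint[a, b] * log(joint[a, b] / (px[a] * py[b]))
    mm <- (sum(px > 0) - 1 + sum(py > 0) - 1 - (sum(joint > 0) - 1)) / (2 * n)
    max(0, mi + mm)
}

# network flow entropy of one local network, brute force:
# every probability written out and summed in an explicit (k, j) loop
nfeOracle <- function(abund, center, neighbors) {
    K <- length(neighbors)
    if (K == 0L) return(0)
    n <- ncol(abund)
    geo <- function(r) exp(mean(log(r)))
    D <- matrix(0, K, n)
    for (k in seq_len(K)) for (j in seq_len(n))
        D[k, j] <- abs(log(abund[center, j] / geo(abund[center, ])) -
                       log(abund[neighbors[k], j] / geo(abund[neighbors[k], ])))
    joint <- matrix(0, K, n)
    for (j in seq_len(n)) {
        tot <- sum(D[, j])
        joint[, j] <- if (tot == 0) rep(1 / K, K) else D[, j] / tot
    }
    I <- numeric(K)
    for (k in seq_len(K))
        I[k] <- if (n >= 4) miOracle(abund[center, ], abund[neighbors[k], ]) else 0
    cond <- if (sum(I) > 0) I / sum(I) else rep(1 / K, K)
    total <- 0
    for (k in seq_len(K)) for (j in seq_len(n)) {
        w <- abund[center, j] * joint[k, j] * cond[k]
        if (w > 0) total <- total - w * log(w)
    }
    total / K
}

# write a small taxon table + metadata pair to temp files
writeToyProfileFiles <- function(counts, individual, day, group = "control",
                                 lineage = NULL, sep = "\t") {
    tf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
    df <- data.frame(taxon_id = rownames(counts), counts, check.names = FALSE)
    if (!is.null(lineage)) df$lineage <- lineage
    utils::write.table(df, tf, sep = sep, quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(sample_id = colnames(counts), individual_id = individual,
                   day = day, group = group),
        mf, sep = sep, quote = FALSE, row.names = FALSE)
    list(table = tf, metadata = mf)
}
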