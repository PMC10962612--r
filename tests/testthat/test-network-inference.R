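test_that("two proportional taxa are linked at every point of the path", {
    set.seed(3)
    n <- 60
    base <- matrix(rexp(8 * n) + 0.1, 8, n,
                   dimnames = list(paste0("x", 1:8), paste0("s", 1:n)))
    base["x2", ] <- base["x1", ] * 3          # exactly proportional pair
    clr <- clrWithinSample(sweep(base, 2, colSums(base), "/"))
    X <- scale(t(clr))
    path <- mNFE:::.lambdaPath(X, 0.01, 10)
    beta <- mNFE:::.mbCoefs(X, path)
    for (l in seq_along(path)[-1L])          # the very first point is empty
        expect_true(beta["x1", "x2", l] != 0 || beta["x2", "x1", l] != 0)
})

test_that("edge count is non-increasing in the penalty along the path", {
    cnt <- makeChainCounts(80, 12, seed = 4)
    clr <- clrWithinSample(sweep(cnt + 0.5, 2, colSums(cnt + 0.5), "/"))
    X <- scale(t(clr))
    path <- mNFE:::.lambdaPath(X, 0.01, 12)
    beta <- mNFE:::.mbCoefs(X, path)
    counts <- vapply(seq_along(path), function(l) {
        a <- beta[, , l] != 0
        sum((a | t(a))[upper.tri(a)])
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))      # path is decreasing in lambda
})

test_that("inferred networks are valid, symmetric-by-construction objects", {
    cnt <- makeChainCounts(60, 10, seed = 8)
    net <- inferMbNetwork(cnt, seed = 8)
    expect_s4_class(net, "AssociationNetwork")
    expect_true(validObject(net))
    e <- networkEdges(net)
    expect_true(all(e$from < e$to))
    expect_true(all(c(e$from, e$to) %in% networkNodes(net)))
})

test_that("sample order does not change the inferred network", {
    cnt <- makeChainCounts(50, 8, seed = 12)
    net1 <- inferMbNetwork(cnt, seed = 3)
    net2 <- inferMbNetwork(cnt[, sample(ncol(cnt))], seed = 3)
    expect_identical(networkEdges(net1), networkEdges(net2))
})

test_that("same inputs and seed give identical networks; settings are recorded", {
    cnt <- makeChainCounts(50, 8, seed = 21)
    net1 <- inferMbNetwork(cnt, seed = 7)
    net2 <- inferMbNetwork(cnt, seed = 7)
    expect_identical(networkEdges(net1), networkEdges(net2))
    expect_identical(net1@provenance$lambda, net2@provenance$lambda)
    expect_identical(net1@provenance$settings$seed, 7)
})

test_that("too few samples or unknown taxa are rejected", {
    cnt <- makeChainCounts(3, 8, seed = 2)
    expect_error(inferMbNetwork(cnt), "fewer samples")
    cnt2 <- makeChainCounts(20, 8, seed = 2)
    expect_error(inferMbNetwork(cnt2, nodes = c("t01", "nope")), "unknown taxa")
})

test_that("SSAN shares the reference node set and is deterministic", {
    cnt <- makeChainCounts(40, 10, seed = 31)
    arn <- inferMbNetwork(cnt, seed = 1)
    cs <- cnt[, 5L]; names(cs) <- rownames(cnt)
    s1 <- buildSsan(cnt, cs, arn, day = 7)
    s2 <- buildSsan(cnt, cs, arn, day = 7)
    expect_identical(networkNodes(s1), networkNodes(arn))
    expect_identical(networkEdges(s1), networkEdges(s2))
    expect_identical(s1@provenance$type, "perturbed")
    expect_identical(s1@provenance$caseDay, 7)
    expect_error(buildSsan(cnt, cs[-2L], arn), "taxon index mismatch")
})

test_that("a strong single-taxon perturbation changes edges near that taxon", {
    cnt <- makeChainCounts(30, 12, seed = 14)
    arn <- inferMbNetwork(cnt, stability = "fixed", seed = 1)
    cs <- cnt[, 8L]; names(cs) <- rownames(cnt)
    cs["t05"] <- cs["t05"] * 50
    ssan <- buildSsan(cnt, cs, arn, day = 1)
    key <- function(net) paste(networkEdges(net)$from, networkEdges(net)$to)
    flipped <- c(setdiff(key(arn), key(ssan)), setdiff(key(ssan), key(arn)))
    expect_gt(length(flipped), 0L)
    expect_gt(sum(grepl("t05", flipped)), 0L)  # a flip touches the perturbed taxon
})

test_that("asAssociationNetwork canonicalizes and deduplicates edges", {
    net <- asAssociationNetwork(
        data.frame(from = c("b", "a", "a", "c"), to = c("a", "b", "a", "a"),
                   weight = c(1, 2, 3, 4)))
    e <- networkEdges(net)
    expect_identical(nrow(e), 2L)            # a-b once, a-c once, no self loop
    expect_true(all(e$from < e$to))
})

test_that("networks serialize to edge lists and GraphML", {
    net <- asAssociationNetwork(
        data.frame(from = "a", to = "b", weight = -0.5), nodes = c("a", "b", "c"))
    f1 <- tempfile(fileext = ".tsv")
    writeNetwork(net, f1)
    back <- utils::read.table(f1, header = TRUE, sep = "\t")
    expect_equal(back$weight, -0.5)
    f2 <- tempfile(fileext = ".graphml")
    writeNetwork(net, f2, format = "graphml")
    g <- igraph::read_graph(f2, format = "graphml")
    expect_equal(igraph::vcount(g), 3)
})
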