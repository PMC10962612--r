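test_that("log-ratio centering matches hand values and centers exactly", {
    expect_equal(unname(clrBySpecies(rbind(c(1, 1, 1, 1)))[1, ]), rep(0, 4))
    expect_equal(unname(clrBySpecies(rbind(c(1, 4)))[1, ]), c(-log(2), log(2)))
    set.seed(1)
    m <- matrix(rexp(30) + 0.1, 5, 6)
    expect_equal(unname(rowSums(clrBySpecies(m))), rep(0, 5), tolerance = 1e-9)
    expect_equal(unname(colSums(clrWithinSample(m))), rep(0, 6), tolerance = 1e-9)
    expect_error(clrBySpecies(rbind(c(1, 0))), "positive")
})

test_that("pairwise log-ratio distance: identity, hand value, scale invariance", {
    x <- c(0.2, 0.5, 0.3)
    expect_equal(pairwiseDistance(x, x), rep(0, 3))
    expect_equal(pairwiseDistance(c(1, 4), c(4, 1)), c(2 * log(2), 2 * log(2)))
    y <- c(0.1, 0.7, 0.2)
    expect_equal(pairwiseDistance(x, y), pairwiseDistance(x * 17, y * 0.03))
    expect_error(pairwiseDistance(c(1, -1), c(1, 1)), "positive")
})

test_that("mutual information behaves on null, dependent, and identical input", {
    set.seed(42)
    nulls <- replicate(10, mutualInformation(runif(1000), runif(1000)))
    expect_lte(max(nulls), 0.05)
    x <- rnorm(5000); y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(5000)
    expect_lt(abs(mutualInformation(x, y) - (-0.5 * log(1 - 0.81))), 0.1)
    z <- rnorm(200)
    expect_equal(mutualInformation(z, z), binnedEntropy(z))
    expect_identical(mutualInformation(rep(1, 10), rnorm(10)), 0)
    # agrees with the independently coded estimator
    for (i in 1:5) {
        a <- rnorm(50); b <- a + rnorm(50)
        expect_equal(mutualInformation(a, b), miOracle(a, b), tolerance = 1e-12)
    }
})

test_that("extractLocal returns first-order neighborhoods", {
    net <- asAssociationNetwork(
        data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"), weight = 1),
        nodes = c("a", "b", "c", "z"))
    star <- extractLocal(net, "a")
    expect_identical(star$neighbors, c("b", "c"))
    expect_identical(star$M, 3L)
    iso <- extractLocal(net, "z")
    expect_identical(iso$neighbors, character(0))
    expect_identical(iso$M, 1L)
    path <- asAssociationNetwork(
        data.frame(from = c("a", "b"), to = c("b", "c"), weight = 1))
    expect_identical(extractLocal(path, "b")$neighbors, c("a", "c"))
    expect_error(extractLocal(net, "q"), "not a node")
})

test_that("local probabilities normalize and lie in [0, 1]", {
    set.seed(11)
    for (i in 1:25) {
        m <- sample(3:8, 1); n <- sample(4:10, 1)
        a <- randomAbund(m, n)
        nb <- rownames(a)[-1L]
        pr <- localProbabilities(a, rownames(a)[1L], nb)
        expect_equal(unname(colSums(pr$joint)), rep(1, n), tolerance = 1e-9)
        expect_equal(sum(pr$conditional), 1, tolerance = 1e-9)
        expect_true(all(pr$joint >= 0 & pr$joint <= 1))
        expect_true(all(pr$conditional >= 0 & pr$conditional <= 1))
        expect_true(all(pr$distances >= 0))
    }
    # degenerate: all neighbors identical to center -> uniform joint
    a <- rbind(x1 = c(0.3, 0.4), x2 = c(0.3, 0.4), x3 = c(0.3, 0.4))
    pr <- localProbabilities(a, "x1", c("x2", "x3"))
    expect_equal(unname(pr$joint), matrix(0.5, 2, 2))
})

test_that("localNfe: isolated center, non-negativity, neighbor-order invariance", {
    a <- randomAbund(6, 8)
    expect_identical(localNfe(a, "x1", character(0)), 0)
    v1 <- localNfe(a, "x1", c("x2", "x3", "x4"))
    v2 <- localNfe(a, "x1", c("x4", "x2", "x3"))
    expect_equal(v1, v2, tolerance = 1e-12)
    expect_gte(v1, 0)
})

test_that("localNfe equals the brute-force oracle on random instances", {
    set.seed(99)
    for (i in 1:40) {
        m <- sample(2:8, 1); n <- sample(4:10, 1)
        a <- randomAbund(m, n)
        nb <- sample(rownames(a)[-1L], sample(seq_len(m - 1L), 1))
        expect_equal(localNfe(a, "x1", nb), nfeOracle(a, "x1", nb),
                     tolerance = 1e-12)
    }
})

test_that("mnfeScore bookkeeping: score equals difference of stored means", {
    set.seed(5)
    cnt <- makeChainCounts(30, 10, seed = 5)
    arn <- inferMbNetwork(cnt, stability = "fixed", seed = 1)
    cs <- cnt[, 1L]; names(cs) <- rownames(cnt)
    ssan <- buildSsan(cnt, cs, arn, day = 99)
    r <- mnfeScore(arn, ssan, cnt, cs, day = 99)
    expect_equal(mnfe(r), mean(r@nfePerturbed) - mean(r@nfeReference),
                 tolerance = 1e-12)
    pt <- perTaxonScores(r)
    expect_setequal(pt$taxon, union(names(r@nfeReference), names(r@nfePerturbed)))
    expect_error(mnfeScore(arn, ssan, cnt, cs[-1L]), "taxon universe")
})

test_that("identical-input construction gives a zero score", {
    nfe <- c(a = 0.3, b = 0.5, c = 0.1)
    r <- mNFE:::.mnfeAssemble(nfe, nfe, day = 1)
    expect_identical(mnfe(r), 0)
    expect_equal(perTaxonScores(r)$deltaNfe, rep(0, 3))
})
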